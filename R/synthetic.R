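# Seeded synthetic-data generators. Each generator returns data in the
# format its analyser consumes, with the generating truth attached as an
# attribute, so every reduction has a parameter-recovery oracle.
#
# Seeding is local: the caller's RNG state is saved and restored, so
# generators neither depend on nor disturb global state.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic ITC thermogram with known injection heats
#'
#' Each injection adds a one-sided exponential power pulse
#' `(h/tau) exp(-(t - t_inj)/tau)` whose integrated area equals the true
#' heat, on top of a linear drift and additive Gaussian noise. Exothermic
#' heats are negative. The truth (heats, injection times) is attached.
#'
#' @param schedule An [injection_schedule()].
#' @param true_heats True per-injection heats in uJ, length
#'   `schedule$count + 1` (the first element is the small first injection).
#' @param peak_tau Instrument response time of the pulse, s. Default 8.
#' @param drift Linear baseline drift, uW/s. Default 0.
#' @param noise_sd Gaussian noise sd per sample, uW. Default 0.02.
#' @param dt Sampling interval, s. Default 0.05.
#' @param delay Equilibration time before the first injection, s. Default 60.
#' @param tail Extra trace beyond the last window, s. Default 10.
#' @param seed Optional integer seed.
#' @return A data frame (class `npw_thermogram`) with columns `time_s`,
#'   `power_uW`; attributes `truth` (list with `heats_uJ`, `times_s`,
#'   `peak_tau`, `drift`, `noise_sd`) and `delay`.
#' @examples
#' g <- gen_thermogram(true_heats = c(-1, seq(-10, -4.5, length.out = 12)),
#'                     seed = 1)
#' @export
gen_thermogram <- function(schedule = injection_schedule(),
                           true_heats, peak_tau = 8, drift = 0,
                           noise_sd = 0.02, dt = 0.05, delay = 60,
                           tail = 10, seed = NULL) {
  stopifnot(inherits(schedule, "npw_schedule"))
  if (length(true_heats) != schedule$count + 1)
    stop("true_heats must have length count + 1 (first small injection ",
         "included)", call. = FALSE)
  t_inj <- delay + (0:schedule$count) * schedule$interval
  t_end <- max(t_inj) + schedule$interval + tail
  t <- seq(0, t_end, by = dt)
  power <- drift * t
  for (k in seq_along(t_inj)) {
    dt_k <- t - t_inj[k]
    on <- dt_k >= 0
    power[on] <- power[on] + true_heats[k] / peak_tau * exp(-dt_k[on] / peak_tau)
  }
  if (noise_sd > 0)
    power <- power + .with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  out <- data.frame(time_s = t, power_uW = power)
  structure(out, class = c("npw_thermogram", "data.frame"),
            truth = list(heats_uJ = true_heats, times_s = t_inj,
                         peak_tau = peak_tau, drift = drift,
                         noise_sd = noise_sd),
            delay = delay)
}

#' @export
plot.npw_thermogram <- function(x, ...) {
  graphics::plot(x$time_s, x$power_uW, type = "l",
                 xlab = "time (s)", ylab = "differential power (uW)", ...)
  invisible(x)
}

#' Generate a synthetic emission spectrum
#'
#' Gaussian peak plus constant baseline and additive noise on a 1 nm grid
#' over the recorded emission range (490-700 nm by default).
#'
#' @param center Peak centre, nm (must lie in the grid).
#' @param sd Gaussian sd, nm. Default 25.
#' @param amplitude Peak amplitude, a.u. Default 100.
#' @param baseline Constant baseline, a.u. Default 5.
#' @param noise_sd Gaussian noise sd, a.u. Default 1.
#' @param range Wavelength range, nm. Default `c(490, 700)`.
#' @param seed Optional integer seed.
#' @return A data frame (class `npw_spectrum`) with columns `wavelength_nm`,
#'   `intensity` and a `truth` attribute.
#' @export
gen_spectrum <- function(center = 635, sd = 25, amplitude = 100,
                         baseline = 5, noise_sd = 1, range = c(490, 700),
                         seed = NULL) {
  w <- seq(range[1], range[2], by = 1)
  if (center < range[1] || center > range[2])
    stop("center must lie within the wavelength range", call. = FALSE)
  y <- amplitude * exp(-(w - center)^2 / (2 * sd^2)) + baseline
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(w), 0, noise_sd))
  out <- data.frame(wavelength_nm = w, intensity = y)
  structure(out, class = c("npw_spectrum", "data.frame"),
            truth = list(center = center, sd = sd, amplitude = amplitude,
                         baseline = baseline, noise_sd = noise_sd))
}

#' @export
plot.npw_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$intensity, type = "l",
                 xlab = "wavelength (nm)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Generate a synthetic correlogram for a particle mixture
#'
#' Wraps [simulate_correlogram()] on a logarithmic delay grid from 0.5 us to
#' 1 s and attaches the truth (populations, weights, decay rates).
#'
#' @inheritParams simulate_correlogram
#' @param n_delays Number of grid points. Default 200.
#' @return An `npw_correlogram` with a `truth` attribute.
#' @export
gen_correlogram <- function(populations, setup = optical_setup(),
                            beta = 0.8, noise_sd = 1e-3, n_delays = 200,
                            seed = NULL) {
  delays <- exp(seq(log(0.5), log(1e6), length.out = n_delays))
  cg <- simulate_correlogram(populations, setup, delays, beta, noise_sd, seed)
  attr(cg, "truth") <- list(
    diameters = attr(cg, "diameters"), weights = attr(cg, "weights"),
    rates = attr(cg, "rates"), beta = beta, noise_sd = noise_sd)
  cg
}

#' Generate a first-order calcein leakage time course
#'
#' `F(t) = F_control + F_max (1 - exp(-k_leak t))` plus noise: leakage
#' dilutes self-quenched calcein, so fluorescence rises toward the
#' post-lysis maximum with first-order kinetics.
#'
#' @param k_leak Leakage rate constant, 1/s (non-negative).
#' @param f_max Maximum fluorescence rise (a.u.). Default 100.
#' @param f_control Control (no-nanoparticle) fluorescence. Default 10.
#' @param noise_sd Gaussian noise sd, a.u. Default 1.
#' @param duration Duration, s. Default 600.
#' @param dt Sampling interval, s. Default 1.
#' @param seed Optional integer seed.
#' @return A data frame with columns `time_s`, `fluorescence` and a `truth`
#'   attribute.
#' @export
gen_leakage_series <- function(k_leak, f_max = 100, f_control = 10,
                               noise_sd = 1, duration = 600, dt = 1,
                               seed = NULL) {
  .check_num(k_leak, "k_leak", 0)
  t <- seq(0, duration, by = dt)
  f <- f_control + f_max * (1 - exp(-k_leak * t))
  if (noise_sd > 0)
    f <- f + .with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  structure(data.frame(time_s = t, fluorescence = f),
            truth = list(k_leak = k_leak, f_max = f_max,
                         f_control = f_control, noise_sd = noise_sd))
}

#' Generate a lognormal particle-size population
#'
#' Lognormal diameter sample parameterised by median and geometric standard
#' deviation, emulating measured size-distribution profiles.
#'
#' @param median_d Median diameter, nm.
#' @param gsd Geometric standard deviation (>= 1); `gsd = 1` gives a
#'   monodisperse sample.
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return A numeric vector of diameters with a `truth` attribute
#'   (`median_d`, `gsd`).
#' @export
gen_population <- function(median_d, gsd, n, seed = NULL) {
  .check_num(median_d, "median_d", 0, strict = TRUE)
  .check_num(gsd, "gsd", 1)
  n <- as.integer(.check_num(n, "n", 1))
  d <- if (gsd == 1) rep(median_d, n)
       else .with_seed(seed, stats::rlnorm(n, log(median_d), log(gsd)))
  structure(d, truth = list(median_d = median_d, gsd = gsd))
}
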