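# Reduction of multi-injection ITC differential-power traces to
# per-injection heats and surface-area-normalised enthalpies.
#
# Sign convention: exothermic heats are negative throughout (the instrument
# withdraws feedback power; the generator writes negative pulses).

#' Integrate an ITC thermogram into per-injection heats
#'
#' Splits the differential-power trace into one window per injection
#' (`[t_k, t_k + interval)`, injections at `delay + k * interval` for
#' `k = 0 .. count`, where `k = 0` is the small first injection). Within
#' each window a linear baseline is fitted through the 20 s immediately
#' before the injection and the final 20 s of the window, and the heat is
#' the trapezoidal integral of (power - baseline) in uJ. Affine drift is
#' absorbed by the baseline.
#'
#' @param trace A thermogram data frame with columns `time_s` (strictly
#'   increasing) and `power_uW`, e.g. from [gen_thermogram()] or
#'   [read_table()].
#' @param schedule An [injection_schedule()].
#' @param delay Equilibration time before the first injection, s. Default 60
#'   (taken from the trace attribute `delay` when present).
#' @param baseline_window Length of each baseline segment, s. Default 20.
#' @return An object of class `npw_heats`: a data frame with columns
#'   `injection` (0 = first small injection), `time_s`, `volume_uL`,
#'   `heat_uJ` and `discard` (TRUE for the first small injection, which is
#'   integrated but conventionally discarded).
#' @examples
#' g <- gen_thermogram(true_heats = c(-1, seq(-10, -4.5, length.out = 12)),
#'                     noise_sd = 0, seed = 1)
#' integrate_thermogram(g)
#' @export
integrate_thermogram <- function(trace, schedule = injection_schedule(),
                                 delay = NULL, baseline_window = 20) {
  stopifnot(inherits(schedule, "npw_schedule"))
  if (!all(c("time_s", "power_uW") %in% names(trace)))
    stop("trace must have columns time_s and power_uW", call. = FALSE)
  if (is.null(delay))
    delay <- if (!is.null(attr(trace, "delay"))) attr(trace, "delay") else 60
  t <- trace$time_s
  p <- trace$power_uW
  if (any(diff(t) <= 0)) stop("time_s must be strictly increasing",
                              call. = FALSE)
  t_inj <- delay + (0:schedule$count) * schedule$interval
  missing <- which(t_inj + schedule$interval > max(t) | t_inj - baseline_window < min(t))
  if (length(missing))
    stop("trace does not cover injection window(s): ",
         paste(missing - 1L, collapse = ", "), call. = FALSE)

  heat <- vapply(t_inj, function(t0) {
    t1 <- t0 + schedule$interval
    base_idx <- (t >= t0 - baseline_window & t < t0) |
                (t >= t1 - baseline_window & t < t1)
    fit <- stats::lm.fit(cbind(1, t[base_idx]), p[base_idx])
    win <- t >= t0 & t < t1
    resid <- p[win] - (fit$coefficients[1] + fit$coefficients[2] * t[win])
    tw <- t[win]
    sum(diff(tw) * (resid[-1] + resid[-length(resid)]) / 2)   # trapezoid, uJ
  }, numeric(1))

  out <- data.frame(injection = 0:schedule$count,
                    time_s = t_inj,
                    volume_uL = c(schedule$first_volume,
                                  rep(schedule$volume, schedule$count)),
                    heat_uJ = heat,
                    discard = c(TRUE, rep(FALSE, schedule$count)))
  class(out) <- c("npw_heats", "data.frame")
  out
}

#' Subtract a dilution (control) heat series
#'
#' Elementwise subtraction of a liposome-into-buffer control titration from
#' a sample titration, injection by injection.
#'
#' @param sample,control `npw_heats` objects (or data frames with a
#'   `heat_uJ` column) of equal length.
#' @return The sample with `heat_uJ` replaced by the difference.
#' @export
subtract_dilution <- function(sample, control) {
  if (nrow(sample) != nrow(control))
    stop("length mismatch: sample has ", nrow(sample), " injections, control ",
         nrow(control), call. = FALSE)
  sample$heat_uJ <- sample$heat_uJ - control$heat_uJ
  sample
}

#' Surface-area-normalised interaction enthalpy
#'
#' Normalises the heat of the first full liposome injection (which
#' represents complete interaction: the injected vesicle area is far below
#' the gold area in the cell) by the total gold surface area, giving
#' `delta_H = dQ / SA_Au` in mJ/m^2. When `sa_l` is supplied the chained
#' form `(dQ/SA_L) / (SA_Au/SA_L)` is also computed; it equals the direct
#' form identically and is carried as a consistency check. The mean over all
#' full injections is reported alongside the first-injection value.
#'
#' @param heats An `npw_heats` object (dilution-subtracted).
#' @param sa_au Total gold surface area in the cell, m^2; must be positive.
#' @param sa_l Total liposome surface area, m^2 (optional).
#' @param use Which injections define `delta_H`: `"first"` (default, the
#'   first non-discarded injection) or `"mean"` of all non-discarded ones.
#' @return An object of class `npw_enthalpy` with fields `delta_H` (mJ/m^2),
#'   `delta_H_first`, `delta_H_mean`, `chained` (mJ/m^2 or NA), `sa_au`,
#'   `sa_l`.
#' @export
normalize_enthalpy <- function(heats, sa_au, sa_l = NULL,
                               use = c("first", "mean")) {
  use <- match.arg(use)
  .check_num(sa_au, "sa_au", 0, strict = TRUE)
  q <- heats$heat_uJ[!heats$discard]               # uJ
  q_first <- q[1]
  to_mJ_m2 <- function(q_uJ) (q_uJ * 1e-6) / sa_au * 1e3
  dh_first <- to_mJ_m2(q_first)
  dh_mean <- to_mJ_m2(mean(q))
  chained <- NA_real_
  if (!is.null(sa_l)) {
    .check_num(sa_l, "sa_l", 0, strict = TRUE)
    chained <- ((q_first * 1e-6) / sa_l) / (sa_au / sa_l) * 1e3
  }
  structure(list(delta_H = if (use == "first") dh_first else dh_mean,
                 delta_H_first = dh_first, delta_H_mean = dh_mean,
                 chained = chained, sa_au = sa_au,
                 sa_l = if (is.null(sa_l)) NA_real_ else sa_l),
            class = "npw_enthalpy")
}

#' @export
print.npw_enthalpy <- function(x, ...) {
  cat(sprintf("delta_H = %.4g mJ/m^2 (first injection %.4g, mean %.4g; SA_Au = %.3g m^2)\n",
              x$delta_H, x$delta_H_first, x$delta_H_mean, x$sa_au))
  invisible(x)
}

#' Gibbs relation delta_G = delta_H - T * delta_S
#'
#' Solves the algebraic identity for whichever single quantity is missing.
#' Exactly two of `delta_G`, `delta_H`, `delta_S` must be supplied.
#'
#' @param delta_H Enthalpy change (any consistent energy unit).
#' @param delta_G Free energy change (same unit).
#' @param delta_S Entropy change (same unit per kelvin).
#' @param temperature Absolute temperature, K. Default 298.15.
#' @return A list with all three of `delta_G`, `delta_H`, `delta_S`.
#' @examples
#' gibbs_identity(delta_H = -2, delta_G = -5, temperature = 250)  # dS = 0.012
#' @export
gibbs_identity <- function(delta_H = NULL, delta_G = NULL, delta_S = NULL,
                           temperature = 298.15) {
  .check_num(temperature, "temperature", 0, strict = TRUE)
  given <- !c(H = is.null(delta_H), G = is.null(delta_G), S = is.null(delta_S))
  if (sum(given) != 2L)
    stop("underdetermined: supply exactly two of delta_H, delta_G, delta_S",
         call. = FALSE)
  if (!given["G"]) delta_G <- delta_H - temperature * delta_S
  else if (!given["H"]) delta_H <- delta_G + temperature * delta_S
  else delta_S <- (delta_H - delta_G) / temperature
  list(delta_G = delta_G, delta_H = delta_H, delta_S = delta_S,
       temperature = temperature)
}

#' @export
plot.npw_heats <- function(x, ...) {
  graphics::plot(x$injection, x$heat_uJ, type = "h", lwd = 3,
                 xlab = "injection", ylab = "heat (uJ)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
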