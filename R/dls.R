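# Forward dynamic light scattering model for nanoparticle/vesicle mixtures,
# cumulant analysis, and a two-mode population-shift metric.
#
# Intensity weighting is Rayleigh (d^6): adequate for the qualitative
# signal-dominance reasoning this module serves, although the largest
# particles here exceed the strict Rayleigh limit (see the vignette).

#' Scattering vector magnitude
#'
#' `q = 4 pi n sin(theta/2) / lambda` for the optical setup.
#'
#' @param setup An [optical_setup()].
#' @return q in 1/m.
#' @examples
#' scattering_vector(optical_setup())   # 2.65e7 1/m
#' @export
scattering_vector <- function(setup = optical_setup()) {
  stopifnot(inherits(setup, "npw_optics"))
  4 * pi * setup$refractive_index * sin(setup$angle * pi / 360) /
    (setup$wavelength * .nm)
}

#' Stokes--Einstein translational diffusivity
#'
#' `D = kB T / (3 pi eta d)` for a sphere of hydrodynamic diameter `d`.
#'
#' @param d Hydrodynamic diameter, nm (vectorised).
#' @param setup An [optical_setup()].
#' @return Diffusivity in m^2/s.
#' @examples
#' stokes_einstein_diffusivity(100, optical_setup(viscosity = 8.872e-4))
#' @export
stokes_einstein_diffusivity <- function(d, setup = optical_setup()) {
  stopifnot(inherits(setup, "npw_optics"))
  if (any(d <= 0)) stop("'d' must be positive", call. = FALSE)
  .kB * setup$temperature / (3 * pi * setup$viscosity * d * .nm)
}

.as_population_list <- function(populations) {
  if (inherits(populations, "npw_population")) populations <- list(populations)
  if (!length(populations)) stop("empty population list", call. = FALSE)
  lapply(populations, function(p) {
    stopifnot(inherits(p, "npw_population"))
    p
  })
}

# Rayleigh intensity weights, normalised to sum to 1
.intensity_weights <- function(populations) {
  d <- vapply(populations, `[[`, numeric(1), "diameter")
  n <- vapply(populations, `[[`, numeric(1), "number_concentration")
  w <- n * d^6
  w / sum(w)
}

#' Simulate an intensity autocorrelation function for a particle mixture
#'
#' The field correlation of a mixture is the intensity-weighted sum of
#' monodisperse exponentials, `g1(tau) = sum_i w_i exp(-D_i q^2 tau)` with
#' Rayleigh weights `w_i` proportional to `N_i d_i^6`; the measured
#' `g2 = 1 + beta g1^2` (Siegert relation) with coherence factor `beta`.
#' Because of the d^6 weighting, even a tiny number fraction of vesicles (or
#' vesicle-bound particles) dominates the signal over free small particles.
#'
#' @param populations A list of [population()] objects (or a single one).
#' @param setup An [optical_setup()].
#' @param delays Delay-time grid in microseconds. Default: 200 points,
#'   logarithmic from 0.5 us to 1 s.
#' @param beta Coherence factor. Default 0.8.
#' @param noise_sd Additive Gaussian noise sd on g2. Default 0.
#' @param seed Optional integer seed (local; the global RNG state is
#'   restored).
#' @return An object of class `npw_correlogram`: a data frame with columns
#'   `delay_us` and `g2`, and attributes `beta`, `weights`, `rates`
#'   (decay rates `D_i q^2` in 1/s) and `diameters`.
#' @examples
#' cg <- simulate_correlogram(list(population(10, 1e12), population(179, 1e12)))
#' attr(cg, "weights")   # vesicle mode carries ~all the intensity
#' @export
simulate_correlogram <- function(populations, setup = optical_setup(),
                                 delays = NULL, beta = 0.8, noise_sd = 0,
                                 seed = NULL) {
  populations <- .as_population_list(populations)
  stopifnot(inherits(setup, "npw_optics"))
  if (is.null(delays))
    delays <- exp(seq(log(0.5), log(1e6), length.out = 200))
  w <- .intensity_weights(populations)
  d <- vapply(populations, `[[`, numeric(1), "diameter")
  q <- scattering_vector(setup)
  rates <- stokes_einstein_diffusivity(d, setup) * q^2       # 1/s
  tau <- delays * 1e-6                                       # us -> s
  g1 <- as.vector(exp(-outer(tau, rates)) %*% w)
  g2 <- 1 + beta * g1^2
  if (noise_sd > 0)
    g2 <- g2 + .with_seed(seed, stats::rnorm(length(g2), 0, noise_sd))
  out <- data.frame(delay_us = delays, g2 = g2)
  structure(out, class = c("npw_correlogram", "data.frame"),
            beta = beta, weights = w, rates = rates, diameters = d)
}

#' Second-order cumulant analysis of a correlogram
#'
#' Fits `ln(g2 - 1) = ln(beta) - 2 Gamma tau + mu2 tau^2` by weighted least
#' squares over the decaying part of the curve (points with `g2 - 1` above a
#' fraction of the intercept, weighted by `(g2 - 1)^2` to undo the
#' log-transform noise amplification), then inverts `Gamma = D q^2` through
#' Stokes--Einstein to an intensity-weighted mean hydrodynamic diameter; the
#' polydispersity index is `mu2 / Gamma^2`.
#'
#' @param correlogram An `npw_correlogram` (or data frame with `delay_us`,
#'   `g2`).
#' @param setup An [optical_setup()]; must match the measurement.
#' @param threshold Fraction of the `g2 - 1` intercept below which points
#'   are dropped from the fit. Default 0.03.
#' @return An object of class `npw_cumulant` with fields `diameter` (nm),
#'   `pdi`, `gamma` (1/s), `beta_fit`; `coef()` returns them.
#' @examples
#' cg <- simulate_correlogram(population(100, 1e12))
#' cumulant_fit(cg)
#' @export
cumulant_fit <- function(correlogram, setup = optical_setup(),
                         threshold = 0.03) {
  tau <- correlogram$delay_us * 1e-6
  y <- correlogram$g2 - 1
  if (mean(y <= 0) > 0.5)
    stop("g2 - 1 is non-positive over more than half the delay range",
         call. = FALSE)
  intercept <- stats::median(y[seq_len(max(3L, floor(length(y) / 20)))])
  keep <- y > max(threshold * intercept, 0)
  tau_k <- tau[keep]; y_k <- y[keep]
  fit <- stats::lm(log(y_k) ~ tau_k + I(tau_k^2), weights = y_k^2)
  cf <- stats::coef(fit)
  gamma <- -cf[["tau_k"]] / 2
  if (!is.finite(gamma) || gamma <= 0)
    stop("cumulant fit failed: non-positive decay rate", call. = FALSE)
  # ln(g2-1) = ln beta - 2*Gamma*tau + mu2*tau^2  =>  quadratic coef = mu2
  mu2 <- cf[["I(tau_k^2)"]]
  q <- scattering_vector(setup)
  diff_coef <- gamma / q^2
  diameter <- .kB * setup$temperature /
    (3 * pi * setup$viscosity * diff_coef) / .nm
  structure(list(diameter = diameter, pdi = mu2 / gamma^2, gamma = gamma,
                 beta_fit = exp(cf[["(Intercept)"]]), n_points = sum(keep)),
            class = "npw_cumulant")
}

#' @export
print.npw_cumulant <- function(x, ...) {
  cat(sprintf("Cumulant fit: mean diameter %.1f nm, PDI %.3f (Gamma = %.3g 1/s)\n",
              x$diameter, x$pdi, x$gamma))
  invisible(x)
}

#' @export
coef.npw_cumulant <- function(object, ...) {
  c(diameter = object$diameter, pdi = object$pdi, gamma = object$gamma)
}

#' Shift of scattering intensity toward the slow (vesicle) mode
#'
#' Quantifies how much of the scattered intensity moved from the fast
#' (free-particle) decay mode to the slow (vesicle) mode between two
#' correlograms: both curves are reduced to `g1 = sqrt((g2-1)/beta)` and fit
#' jointly with a two-exponential model sharing the two decay rates, with a
#' free slow-mode weight per curve. The metric is the slow-mode weight after
#' minus before, in [-1, 1]; +1 means the signal moved entirely from the
#' particle mode to the vesicle mode (binding/adsorption), 0 means no
#' change.
#'
#' @param before,after `npw_correlogram` objects on matched delay grids.
#' @param setup An [optical_setup()].
#' @param beta Coherence factor used in the reduction. Default: the `beta`
#'   attribute of `before`, else 0.8.
#' @return An object of class `npw_shift` with fields `metric`,
#'   `slow_weight_before`, `slow_weight_after`, `rates` (fast, slow; 1/s)
#'   and `converged`.
#' @export
population_shift_metric <- function(before, after, setup = optical_setup(),
                                    beta = NULL) {
  if (nrow(before) != nrow(after) ||
      any(abs(before$delay_us - after$delay_us) >
          1e-9 * pmax(before$delay_us, 1)))
    stop("delay grids must match", call. = FALSE)
  if (is.null(beta)) {
    beta <- attr(before, "beta")
    if (is.null(beta)) beta <- 0.8
  }
  tau <- before$delay_us * 1e-6
  y_b <- sqrt(pmax(before$g2 - 1, 0) / beta)
  y_a <- sqrt(pmax(after$g2 - 1, 0) / beta)

  # initial rates from per-curve cumulant decays; force a spread
  g_init <- vapply(list(before, after), function(cg)
    tryCatch(cumulant_fit(cg, setup)$gamma, error = function(e) NA_real_),
    numeric(1))
  g_init <- g_init[is.finite(g_init)]
  if (!length(g_init)) stop("fit failure: no resolvable decay", call. = FALSE)
  g_fast0 <- max(g_init) * 2
  g_slow0 <- min(g_init) / 2

  df <- data.frame(tau = c(tau, tau), y = c(y_b, y_a),
                   is_after = rep(c(0, 1), each = length(tau)))
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ ifelse(is_after == 1, wa, wb) * exp(-exp(lgs) * tau) +
        (1 - ifelse(is_after == 1, wa, wb)) * exp(-exp(lgf) * tau),
    data = df,
    start = list(lgf = log(g_fast0), lgs = log(g_slow0),
                 wb = 0.5, wa = 0.5),
    lower = c(-Inf, -Inf, 0, 0), upper = c(Inf, Inf, 1, 1),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(metric = NA_real_, slow_weight_before = NA_real_,
                          slow_weight_after = NA_real_, rates = c(NA, NA),
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "npw_shift"))
  cf <- stats::coef(fit)
  rates <- sort(exp(c(cf[["lgf"]], cf[["lgs"]])), decreasing = TRUE)
  # identify the slow mode after fitting (rates may have swapped)
  slow_is_lgs <- exp(cf[["lgs"]]) <= exp(cf[["lgf"]])
  wb <- cf[["wb"]]; wa <- cf[["wa"]]
  if (!slow_is_lgs) { wb <- 1 - wb; wa <- 1 - wa }
  metric <- max(-1, min(1, wa - wb))
  structure(list(metric = metric, slow_weight_before = wb,
                 slow_weight_after = wa, rates = rates, converged = TRUE,
                 diagnostics = "converged"),
            class = "npw_shift")
}

#' @export
print.npw_shift <- function(x, ...) {
  if (!x$converged) cat("Population-shift fit failed:", x$diagnostics, "\n")
  else cat(sprintf(
    "Slow-mode intensity weight: %.3f -> %.3f (shift metric %+0.3f)\n",
    x$slow_weight_before, x$slow_weight_after, x$metric))
  invisible(x)
}

#' @export
plot.npw_correlogram <- function(x, ...) {
  graphics::plot(x$delay_us, x$g2, log = "x", type = "l",
                 xlab = "delay (us)", ylab = "g2", ...)
  invisible(x)
}
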