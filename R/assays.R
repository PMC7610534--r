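# Fluorescence assay reductions: calcein leakage, calcein calibration,
# Nile Red emission-peak fitting and shift classification.

#' Calcein leakage percentage
#'
#' `100 * (F_sample - F_control) / F_max`: the control (vesicles without
#' nanoparticles) is subtracted and the result normalised to the maximum
#' fluorescence after detergent lysis. Values may be negative when the
#' sample reads below the control; they are reported as-is with a warning.
#'
#' @param f_sample Sample fluorescence (a.u.); vectorised.
#' @param f_control Control fluorescence (a.u.).
#' @param f_max Maximum (post-lysis) fluorescence (a.u.); must be positive.
#' @param subtract_control_from_max If `TRUE`, normalise by
#'   `F_max - F_control` instead of the raw `F_max`. Default `FALSE`
#'   (the published normalisation).
#' @return Leakage in percent.
#' @examples
#' leakage_percent(55, 10, 100)   # 45 %
#' @export
leakage_percent <- function(f_sample, f_control, f_max,
                            subtract_control_from_max = FALSE) {
  if (any(!is.finite(f_max)) || any(f_max <= 0))
    stop("f_max must be positive", call. = FALSE)
  denom <- if (subtract_control_from_max) f_max - f_control else f_max
  if (any(denom <= 0)) stop("non-positive normalisation denominator",
                            call. = FALSE)
  out <- 100 * (f_sample - f_control) / denom
  if (any(out < 0)) warning("negative leakage value(s) reported as-is")
  out
}

#' Fit a Gaussian emission peak
#'
#' Least-squares fit of a single Gaussian plus constant baseline,
#' `I(w) = A * exp(-(w - c)^2 / (2 s^2)) + b`, to an emission spectrum; the
#' fitted centre is the emission maximum. Degenerate spectra (no peak) are
#' returned with `converged = FALSE` and a diagnostic message rather than an
#' error.
#'
#' @param spectrum Data frame with columns `wavelength_nm` (monotone grid of
#'   at least 10 points) and `intensity`.
#' @return An object of class `npw_peakfit` with fields `center`, `width`
#'   (Gaussian sd, nm), `amplitude`, `baseline`, `converged` and
#'   `diagnostics`; `coef()` returns the four parameters.
#' @examples
#' s <- gen_spectrum(center = 635, sd = 25, noise_sd = 0, seed = 1)
#' fit_emission_peak(s)
#' @export
fit_emission_peak <- function(spectrum) {
  if (!all(c("wavelength_nm", "intensity") %in% names(spectrum)))
    stop("spectrum must have columns wavelength_nm and intensity",
         call. = FALSE)
  w <- spectrum$wavelength_nm
  y <- spectrum$intensity
  if (length(w) < 10) stop("need at least 10 points", call. = FALSE)
  failed <- function(msg) structure(
    list(center = NA_real_, width = NA_real_, amplitude = NA_real_,
         baseline = NA_real_, converged = FALSE, diagnostics = msg),
    class = "npw_peakfit")

  b0 <- min(y)
  a0 <- max(y) - b0
  if (a0 <= 0 || !is.finite(a0)) return(failed("flat or degenerate spectrum"))
  c0 <- w[which.max(y)]
  above <- w[y - b0 > a0 / 2]
  s0 <- max(diff(range(above)) / 2.355, diff(range(w)) / 50)  # FWHM -> sd
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(w - cc)^2 / (2 * s^2)) + b,
                      start = list(A = a0, cc = c0, s = s0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  cf <- stats::coef(fit)
  if (cf[["s"]] <= 0 || cf[["cc"]] < min(w) || cf[["cc"]] > max(w) ||
      cf[["A"]] <= 0)
    return(failed("fitted peak outside the recorded range"))
  structure(list(center = unname(cf[["cc"]]), width = abs(unname(cf[["s"]])),
                 amplitude = unname(cf[["A"]]), baseline = unname(cf[["b"]]),
                 converged = TRUE, diagnostics = "converged", fit = fit),
            class = "npw_peakfit")
}

#' @export
print.npw_peakfit <- function(x, ...) {
  if (!x$converged)
    cat("Peak fit did not converge:", x$diagnostics, "\n")
  else
    cat(sprintf("Gaussian peak: center %.2f nm, sd %.2f nm, amplitude %.3g, baseline %.3g\n",
                x$center, x$width, x$amplitude, x$baseline))
  invisible(x)
}

#' @export
coef.npw_peakfit <- function(object, ...) {
  c(center = object$center, width = object$width,
    amplitude = object$amplitude, baseline = object$baseline)
}

#' Classify an emission-maximum shift
#'
#' Signed shift of a solvatochromic probe's emission maximum relative to a
#' reference. A blue shift (negative) indicates a decrease in environment
#' polarity -- for Nile Red in a bilayer, displacement of water from the
#' probe's surroundings; shifts within the noise threshold are labelled
#' `"NONE"`.
#'
#' @param reference_center Reference emission maximum, nm.
#' @param sample_center Sample emission maximum, nm.
#' @param threshold Magnitude below which the shift is called `"NONE"`, nm.
#'   Default 1.
#' @return A list with `shift` (nm, sample minus reference) and `label`
#'   (`"BLUE"`, `"RED"` or `"NONE"`).
#' @examples
#' emission_shift(646, 635)   # -11 nm, BLUE
#' @export
emission_shift <- function(reference_center, sample_center, threshold = 1) {
  if (!is.finite(reference_center) || !is.finite(sample_center))
    stop("centers must be finite", call. = FALSE)
  shift <- sample_center - reference_center
  label <- if (abs(shift) <= threshold) "NONE"
           else if (shift < 0) "BLUE" else "RED"
  list(shift = shift, label = label)
}

#' Calcein calibration curve
#'
#' Ordinary least-squares line through concentration/fluorescence standards,
#' with an inverse predictor mapping a measured fluorescence back to a total
#' calcein amount (the input to [vesicles_from_calcein()]).
#'
#' @param concentration Standard concentrations (or amounts).
#' @param fluorescence Measured fluorescence of the standards (a.u.).
#' @return An object of class `npw_calibration`; `coef()` gives intercept
#'   and slope, `predict()` maps concentration to fluorescence, and the
#'   `$inverse(f)` function maps fluorescence to concentration.
#' @examples
#' cal <- calcein_calibration(1:5, 2 * (1:5))
#' cal$inverse(10)   # 5
#' @export
calcein_calibration <- function(concentration, fluorescence) {
  if (length(concentration) < 3 || length(fluorescence) != length(concentration))
    stop("need at least 3 matched standards", call. = FALSE)
  fit <- stats::lm(fluorescence ~ concentration)
  slope <- stats::coef(fit)[["concentration"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  if (!is.finite(slope) || slope == 0)
    stop("zero slope: standards carry no signal", call. = FALSE)
  structure(list(fit = fit, intercept = intercept, slope = slope,
                 inverse = function(f) unname((f - intercept) / slope)),
            class = "npw_calibration")
}

#' @export
coef.npw_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.npw_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(concentration = newdata)
  stats::predict(object$fit, newdata = newdata)
}

#' @export
print.npw_calibration <- function(x, ...) {
  cat(sprintf("Calcein calibration: F = %.4g + %.4g * conc (n = %d)\n",
              x$intercept, x$slope, length(stats::fitted(x$fit))))
  invisible(x)
}
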