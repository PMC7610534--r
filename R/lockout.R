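# Isoperimetric tension-lockout model.
#
# Each fully engulfed particle consumes membrane area (the wrap) and, when
# water cannot equilibrate on the engulfment timescale, adds the wrapped
# volume to the enclosed volume. A closed membrane of area A can enclose at
# most V with A >= (36 pi)^(1/3) V^(2/3) (isoperimetric inequality); a
# vesicle that starts as a sphere sits exactly on that bound, so engulfment
# is only possible up to a maximum areal strain of the remaining membrane.
# This is a surrogate for the maximum-tension lockout criterion: the strain
# limit is calibrated, not derived (see the methods vignette).

#' Membrane area and enclosed volume consumed by one wrapped particle
#'
#' The wrap is a sphere of radius `a = d/2 + wrap_margin` (the particle plus
#' half the bilayer); its area `4 pi a^2` is drawn from the vesicle membrane
#' and its volume `(4/3) pi a^3` is lost from the lumen capacity.
#'
#' @param d Particle core diameter in nm (non-negative; `d = 0` gives the
#'   margin-only shell).
#' @param params A [lockout_params()].
#' @return A list with `area_cost` (nm^2) and `volume_cost` (nm^3).
#' @examples
#' wrap_geometry(10, lockout_params())   # a = 7 nm wrap
#' @export
wrap_geometry <- function(d, params = lockout_params()) {
  stopifnot(inherits(params, "npw_lockout_params"))
  .check_num(d, "d", 0)
  a <- d / 2 + params$wrap_margin
  list(area_cost = 4 * pi * a^2, volume_cost = 4 / 3 * pi * a^3)
}

#' Feasibility of engulfing n particles
#'
#' Tests whether a vesicle can hold `n` fully engulfed particles of diameter
#' `d`: after removing `n` wraps, the remaining membrane area, stretched by
#' at most `max_area_strain`, must still satisfy the isoperimetric bound for
#' the enclosed volume (original volume plus `n` wrap volumes in the
#' impermeable mode; original volume only when `water_permeable`).
#'
#' @param vesicle A [vesicle_spec()].
#' @param d Particle core diameter in nm.
#' @param n Number of engulfed particles (non-negative integer).
#' @param params A [lockout_params()].
#' @return A list with `feasible` (logical) and `required_strain`, the areal
#'   strain the remaining membrane would need (`Inf` when the wraps consume
#'   the whole membrane); `required_strain` is 0 at `n = 0` (the sphere sits
#'   exactly on the isoperimetric bound).
#' @examples
#' engulfment_feasible(vesicle_spec(179), 10, 2)
#' @export
engulfment_feasible <- function(vesicle, d, n, params = lockout_params()) {
  stopifnot(inherits(vesicle, "npw_vesicle"),
            inherits(params, "npw_lockout_params"))
  n <- as.integer(.check_num(n, "n", 0))
  g <- wrap_geometry(d, params)
  area_left <- vesicle$area - n * g$area_cost
  if (area_left <= 0)
    return(list(feasible = FALSE, required_strain = Inf))
  vol <- vesicle$volume + if (params$water_permeable) 0 else n * g$volume_cost
  required <- (36 * pi)^(1 / 3) * vol^(2 / 3) / area_left - 1
  list(feasible = required <= params$max_area_strain,
       required_strain = required)
}

#' Engulfment capacity of a vesicle
#'
#' Scans `n = 1, 2, ...` until engulfment becomes infeasible and returns the
#' capacity together with the strain ladder (the areal strain each `n`
#' would require). For a 179 nm vesicle and 10 nm particles the default
#' calibration gives capacity 2: two engulfed particles already bring the
#' membrane to its strain limit and lock out further complete wrapping.
#'
#' @inheritParams engulfment_feasible
#' @return An object of class `npw_budget` with fields `capacity`,
#'   `strain_ladder` (required strain for `n = 1 .. capacity + 1`; the last
#'   entry is the first infeasible step), `diameter` and `max_area_strain`.
#' @examples
#' engulfment_capacity(vesicle_spec(179), 10)
#' @export
engulfment_capacity <- function(vesicle, d, params = lockout_params()) {
  .check_num(d, "d", 0, strict = TRUE)
  ladder <- numeric(0)
  n <- 0L
  repeat {
    n <- n + 1L
    f <- engulfment_feasible(vesicle, d, n, params)
    ladder[n] <- f$required_strain
    if (!f$feasible) break
  }
  structure(list(capacity = n - 1L, strain_ladder = ladder, diameter = d,
                 max_area_strain = params$max_area_strain),
            class = "npw_budget")
}

#' Largest fully engulfable particle diameter
#'
#' Largest integer diameter (nm grid) for which at least one complete
#' engulfment is feasible, scanned over 1..floor(vesicle diameter). Under the
#' default calibration a 179 nm vesicle admits only particles below 16 nm --
#' i.e. diameters < ~15 nm can enter before lockout is complete.
#'
#' @inheritParams engulfment_feasible
#' @return Largest feasible integer diameter in nm (0 if none).
#' @examples
#' max_engulfable_diameter(vesicle_spec(179))
#' @export
max_engulfable_diameter <- function(vesicle, params = lockout_params()) {
  stopifnot(inherits(vesicle, "npw_vesicle"))
  dmax <- 0L
  for (d in seq_len(floor(vesicle$outer_diameter))) {
    if (engulfment_feasible(vesicle, d, 1L, params)$feasible) dmax <- d
  }
  dmax
}

#' @export
print.npw_budget <- function(x, ...) {
  cat(sprintf("Engulfment budget: capacity %d particle(s) of %g nm (strain limit %g)\n",
              x$capacity, x$diameter, x$max_area_strain))
  cat("Required strain by n:\n")
  print(round(x$strain_ladder, 5))
  invisible(x)
}
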