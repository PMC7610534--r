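# Closed-form elastic wrapping energetics.
#
# Spontaneous wrapping of a spherical particle by a fluid bilayer trades the
# adhesion energy gained over the contact area against the bending energy of
# the membrane; membrane tension adds a second, larger limiting size above
# which full wrapping is again allowed. All lengths are nm at the interface;
# energies are SI internally.

.require_W <- function(adhesion) {
  if (!inherits(adhesion, "npw_adhesion"))
    stop("'adhesion' must be an adhesion_spec()", call. = FALSE)
  if (adhesion$adhesion_strength <= 0)
    stop("no adhesion: adhesion_strength must be > 0", call. = FALSE)
  adhesion$adhesion_strength
}

#' Tensionless critical diameter for full wrapping
#'
#' Smallest particle diameter at which spontaneous full wrapping of a sphere
#' by a tensionless membrane is energetically allowed,
#' `dc = 2 * sqrt(2 k / |W|)`, where `k` is the bending modulus (J) and `|W|`
#' the adhesion strength (N/m). With `k = 8.4e-20` J (20 kT) and the
#' bare-gold adhesion `|W| = 0.042` N/m this gives 4 nm; for weakly adhering
#' silica surfaces (a few mJ/m^2) it is 20-25 nm.
#'
#' @param membrane A [membrane_spec()].
#' @param adhesion An [adhesion_spec()] with `adhesion_strength > 0`.
#' @return Critical diameter in nm.
#' @examples
#' critical_diameter_tensionless(membrane_spec(), adhesion_spec(0.042))
#' @export
critical_diameter_tensionless <- function(membrane, adhesion) {
  stopifnot(inherits(membrane, "npw_membrane"))
  W <- .require_W(adhesion)
  2 * sqrt(2 * membrane$bending_modulus / W) / .nm
}

#' Critical diameter for full wrapping under membrane tension
#'
#' Tension opposes the extra membrane area drawn into a wrap, raising the
#' limiting size for complete wrapping to
#' `dc_sigma = 2 * sqrt(2 k / (|W| - sigma))`. When `sigma >= |W|` the
#' adhesion gain can never pay the tension cost and full wrapping is
#' unreachable at any size (`Inf` is returned).
#'
#' @inheritParams critical_diameter_tensionless
#' @return Critical diameter in nm, or `Inf` when `tension >= |W|`.
#' @examples
#' m <- membrane_spec(bending_modulus = 1e-19, tension = 1e-3)
#' critical_diameter_with_tension(m, adhesion_spec(0.002))
#' @export
critical_diameter_with_tension <- function(membrane, adhesion) {
  stopifnot(inherits(membrane, "npw_membrane"))
  W <- .require_W(adhesion)
  if (membrane$tension >= W) return(Inf)
  2 * sqrt(2 * membrane$bending_modulus / (W - membrane$tension)) / .nm
}

#' Curvature-corrected contact energy of a wrapped particle
#'
#' Per-area contact energy of a spherical particle of wrap radius `a` on a
#' supported bilayer, `w(a) = -kw + m/a - 2*kappa_slb/a^2`: the flat-surface
#' absorption strength `-kw` corrected by two curvature terms whose
#' coefficients are fitted, surface-specific constants. Negative values mean
#' net adhesion at that size; `w -> -kw` as `a -> Inf`.
#'
#' @param wrap_radius Wrap radius `a` in nm (nominal particle radius plus the
#'   wrap margin, half the bilayer thickness); must be positive.
#' @param adhesion An [adhesion_spec()] with `flat_strength_kw`,
#'   `linear_coeff_m` and `slb_modulus` set (zero is allowed).
#' @return Contact energy in N/m (J/m^2); negative is adhesive.
#' @examples
#' au <- adhesion_spec(0.042, flat_strength_kw = 0.042,
#'                     linear_coeff_m = 0, slb_modulus = 0)
#' contact_energy(5, au)   # flat-surface limit: -0.042 N/m at every size
#' @export
contact_energy <- function(wrap_radius, adhesion) {
  stopifnot(inherits(adhesion, "npw_adhesion"))
  if (any(!is.finite(wrap_radius)) || any(wrap_radius <= 0))
    stop("'wrap_radius' must be positive", call. = FALSE)
  cf <- unlist(adhesion[c("flat_strength_kw", "linear_coeff_m", "slb_modulus")])
  if (anyNA(cf))
    stop("contact-energy constants (flat_strength_kw, linear_coeff_m, ",
         "slb_modulus) must be supplied", call. = FALSE)
  a <- wrap_radius * .nm
  -cf[[1]] + cf[[2]] / a - 2 * cf[[3]] / a^2
}

#' Critical diameter for adhesion
#'
#' Smallest wrap diameter above which the contact energy is negative
#' (adhesive) for all larger sizes: the larger root of
#' `kw a^2 - m a + 2 kappa_slb = 0`, doubled. When the discriminant
#' `m^2 - 8 kw kappa_slb` is negative the contact energy is negative at
#' every size and 0 is returned -- the bare-gold case, for which the theory
#' predicts adhesion at all particle sizes (uncharged silica polymorphs, by
#' contrast, have finite adhesion critical diameters).
#'
#' @param adhesion An [adhesion_spec()] with the contact-energy constants set
#'   and `flat_strength_kw > 0`.
#' @return Critical wrap diameter in nm (0 when adhesive at all sizes).
#' @examples
#' adhesion_critical_diameter(adhesion_spec(0.042, 0.042, 0, 0))  # gold: 0
#' @export
adhesion_critical_diameter <- function(adhesion) {
  stopifnot(inherits(adhesion, "npw_adhesion"))
  kw <- adhesion$flat_strength_kw
  m <- adhesion$linear_coeff_m
  ks <- adhesion$slb_modulus
  if (anyNA(c(kw, m, ks)))
    stop("contact-energy constants must be supplied", call. = FALSE)
  if (kw <= 0)
    stop("non-adhesive flat limit: flat_strength_kw must be > 0",
         call. = FALSE)
  disc <- m^2 - 8 * kw * ks
  if (disc < 0) return(0)
  a_crit <- (m + sqrt(disc)) / (2 * kw)   # larger root, metres
  2 * a_crit / .nm
}

#' Classify the wrapping state of a particle
#'
#' Partitions particle diameters into the three regimes of the wrapping
#' theory: below `dc` a particle adheres but bending is too costly to wrap
#' it; between `dc` and `dc_sigma` it is partially wrapped (tension blocks
#' completion); at and above `dc_sigma` full wrapping is energetically
#' allowed. With zero tension `dc_sigma = dc` and the partial regime is
#' empty.
#'
#' @param d Particle diameter in nm.
#' @inheritParams critical_diameter_tensionless
#' @return An object of class `npw_wrapping` with fields `label` (one of
#'   `"ADHERED_UNWRAPPED"`, `"PARTIALLY_WRAPPED"`, `"FULLY_WRAPPED"`),
#'   `diameter`, `dc` and `dc_sigma` (nm).
#' @examples
#' m <- membrane_spec(bending_modulus = 1e-19, tension = 1e-3)
#' classify_wrapping(25, m, adhesion_spec(0.002))
#' @export
classify_wrapping <- function(d, membrane, adhesion) {
  .check_num(d, "d", 0, strict = TRUE)
  dc <- critical_diameter_tensionless(membrane, adhesion)
  dcs <- critical_diameter_with_tension(membrane, adhesion)
  label <- if (d < dc) "ADHERED_UNWRAPPED"
           else if (d < dcs) "PARTIALLY_WRAPPED"
           else "FULLY_WRAPPED"
  structure(list(label = label, diameter = d, dc = dc, dc_sigma = dcs),
            class = "npw_wrapping")
}

#' @export
print.npw_wrapping <- function(x, ...) {
  cat(sprintf("d = %g nm: %s  (dc = %.3g nm, dc_sigma = %.3g nm)\n",
              x$diameter, x$label, x$dc, x$dc_sigma))
  invisible(x)
}
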