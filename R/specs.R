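# Physical constants (SI)
.kB <- 1.380649e-23          # Boltzmann constant, J/K
.NAvogadro <- 6.02214e23     # Avogadro number, 1/mol
.nm <- 1e-9                  # metres per nanometre

.check_num <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric of length %d", name, len),
         call. = FALSE)
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad)
    stop(sprintf("'%s' must be %s %g", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  x
}

#' Membrane mechanical specification
#'
#' Bundles the mechanical parameters of a fluid lipid bilayer: the bending
#' modulus `k` (energy scale of curvature deformation, about 20 kT for fluid
#' phosphatidylcholine membranes), the lateral tension `sigma`, the bilayer
#' thickness and the area per lipid molecule.
#'
#' @param bending_modulus Bending modulus in joules. Default `8.4e-20` J
#'   (approximately 20 kT at 298 K, the canonical fluid-PC value).
#' @param tension Membrane tension in N/m, non-negative. Default 0
#'   (tensionless membrane).
#' @param thickness Bilayer thickness in nm. Default 4.
#' @param area_per_lipid Area per lipid molecule in square Angstrom.
#'   Default 71 (DOPC/POPC).
#' @return An object of class `npw_membrane`.
#' @examples
#' membrane_spec()                       # tensionless 20 kT membrane
#' membrane_spec(tension = 1e-3)         # 1 mN/m lateral tension
#' @export
membrane_spec <- function(bending_modulus = 8.4e-20, tension = 0,
                          thickness = 4, area_per_lipid = 71) {
  .check_num(bending_modulus, "bending_modulus", 0, strict = TRUE)
  .check_num(tension, "tension", 0)
  .check_num(thickness, "thickness", 0, strict = TRUE)
  .check_num(area_per_lipid, "area_per_lipid", 0, strict = TRUE)
  structure(list(bending_modulus = bending_modulus, tension = tension,
                 thickness = thickness, area_per_lipid = area_per_lipid),
            class = "npw_membrane")
}

#' Nanoparticle--membrane adhesion specification
#'
#' Holds the adhesion energetics of a nanoparticle surface against a lipid
#' bilayer: the (positive-magnitude) adhesion strength `|W|` used by the
#' critical-diameter expressions, and the three constants of the
#' curvature-corrected contact energy for a particle on a supported bilayer,
#' `w(a) = -kw + m/a - 2*kappa_slb/a^2`, where `a` is the wrap radius.
#'
#' `flat_strength_kw`, `linear_coeff_m` and `slb_modulus` are fitted,
#' surface-specific constants with no universal defaults; they must be
#' supplied explicitly (zero is a valid value) before calling
#' [contact_energy()] or [adhesion_critical_diameter()].
#'
#' @param adhesion_strength Magnitude of the adhesion energy per unit contact
#'   area, `|W|`, in N/m (J/m^2); non-negative. Bare gold on PC bilayers is
#'   about 0.042 N/m.
#' @param flat_strength_kw Flat-surface absorption strength `kw` in N/m.
#' @param linear_coeff_m Linear curvature coefficient `m` in J/m.
#' @param slb_modulus Supported-bilayer bending constant `kappa_slb` in J.
#' @return An object of class `npw_adhesion`.
#' @examples
#' gold <- adhesion_spec(adhesion_strength = 0.042)
#' @export
adhesion_spec <- function(adhesion_strength, flat_strength_kw = NA_real_,
                          linear_coeff_m = NA_real_, slb_modulus = NA_real_) {
  .check_num(adhesion_strength, "adhesion_strength", 0)
  structure(list(adhesion_strength = adhesion_strength,
                 flat_strength_kw = flat_strength_kw,
                 linear_coeff_m = linear_coeff_m,
                 slb_modulus = slb_modulus),
            class = "npw_adhesion")
}

#' Vesicle geometry specification
#'
#' Spherical large-unilamellar-vesicle geometry. Area and volume are derived
#' from the outer diameter and satisfy the isoperimetric equality
#' `A0 = (36*pi)^(1/3) * V0^(2/3)` exactly (the sphere is the minimal-area
#' enclosure of its volume).
#'
#' @param outer_diameter Outer vesicle diameter in nm; must exceed twice the
#'   bilayer thickness.
#' @param thickness Bilayer thickness in nm. Default 4.
#' @return An object of class `npw_vesicle` with fields `outer_diameter`,
#'   `thickness`, `area` (nm^2), `volume` (nm^3) and `lumen_diameter` (nm).
#' @examples
#' vesicle_spec(179)  # the study's mean LUV diameter
#' @export
vesicle_spec <- function(outer_diameter, thickness = 4) {
  .check_num(outer_diameter, "outer_diameter", 0, strict = TRUE)
  .check_num(thickness, "thickness", 0, strict = TRUE)
  if (outer_diameter <= 2 * thickness)
    stop("'outer_diameter' must exceed twice the bilayer thickness",
         call. = FALSE)
  structure(list(outer_diameter = outer_diameter,
                 thickness = thickness,
                 area = pi * outer_diameter^2,
                 volume = pi * outer_diameter^3 / 6,
                 lumen_diameter = outer_diameter - 2 * thickness),
            class = "npw_vesicle")
}

#' Engulfment lockout parameters
#'
#' Parameters of the isoperimetric area-strain lockout model: full engulfment
#' of a wrapped particle consumes membrane area and (in the impermeable mode)
#' adds the wrapped volume to the enclosed volume; engulfment is feasible
#' while the sphere-minimal area of the enclosed volume stays within a
#' maximum areal strain of the remaining membrane.
#'
#' @param wrap_margin Extra wrap radius beyond the particle radius, in nm
#'   (half the bilayer thickness). Default 2.
#' @param max_area_strain Maximum admissible areal strain (dimensionless).
#'   Default 0.0133, within the accepted lysis-strain range of fluid PC
#'   bilayers.
#' @param water_permeable If `TRUE`, the enclosed water volume equilibrates
#'   and engulfment adds no volume; default `FALSE` (volume conserved, the
#'   engulfed particle displaces lumen capacity).
#' @return An object of class `npw_lockout_params`.
#' @export
lockout_params <- function(wrap_margin = 2, max_area_strain = 0.0133,
                           water_permeable = FALSE) {
  .check_num(wrap_margin, "wrap_margin", 0)
  .check_num(max_area_strain, "max_area_strain", 0)
  stopifnot(is.logical(water_permeable), length(water_permeable) == 1L)
  structure(list(wrap_margin = wrap_margin,
                 max_area_strain = max_area_strain,
                 water_permeable = water_permeable),
            class = "npw_lockout_params")
}

# molar masses (g/mol) of the lipids used in the study
.lipid_masses <- c(DOPC = 786.1, POPC = 760.1, `DOPC/POPC` = 773.1)

#' Lipid specification
#'
#' @param name Lipid name. `"DOPC"`, `"POPC"` and the equimolar mean
#'   `"DOPC/POPC"` carry built-in molar masses; any other name requires
#'   `molar_mass`.
#' @param molar_mass Molar mass in g/mol; overrides the built-in value.
#' @param area_per_lipid Area per lipid in square Angstrom. Default 71.
#' @return An object of class `npw_lipid`.
#' @examples
#' lipid_spec("DOPC")
#' lipid_spec("DOPC/POPC")   # 773.1 g/mol mean, the dosimetry default
#' @export
lipid_spec <- function(name = "DOPC/POPC", molar_mass = NULL,
                       area_per_lipid = 71) {
  if (is.null(molar_mass)) {
    if (!name %in% names(.lipid_masses))
      stop("unknown lipid '", name, "': supply 'molar_mass'", call. = FALSE)
    molar_mass <- unname(.lipid_masses[name])
  }
  .check_num(molar_mass, "molar_mass", 0, strict = TRUE)
  .check_num(area_per_lipid, "area_per_lipid", 0, strict = TRUE)
  structure(list(name = name, molar_mass = molar_mass,
                 area_per_lipid = area_per_lipid),
            class = "npw_lipid")
}

#' Nanoparticle stock specification
#'
#' @param core_diameter Core diameter in nm.
#' @param number_concentration Particles per mL of stock; non-negative.
#' @return An object of class `npw_nanoparticle`.
#' @seealso [aunp_stocks()] for the supplier stock concentrations used in
#'   the study.
#' @export
nanoparticle_spec <- function(core_diameter, number_concentration = 0) {
  .check_num(core_diameter, "core_diameter", 0, strict = TRUE)
  .check_num(number_concentration, "number_concentration", 0)
  structure(list(core_diameter = core_diameter,
                 number_concentration = number_concentration),
            class = "npw_nanoparticle")
}

#' Supplier concentrations of the citrate-stabilised gold nanoparticle stocks
#'
#' Number concentrations (particles per mL at 0.05 mg/mL gold) for the six
#' particle sizes used in the study, as provided by the supplier.
#'
#' @return A data frame with columns `diameter_nm` and `particles_per_ml`.
#' @examples
#' aunp_stocks()
#' @export
aunp_stocks <- function() {
  data.frame(diameter_nm = c(5, 10, 25, 35, 50, 60),
             particles_per_ml = c(4.76e13, 6.40e12, 3.72e11,
                                  1.16e11, 3.97e10, 2.30e10))
}

#' Vesicle preparation specification
#'
#' @param lipid_mass_concentration Lipid mass concentration in mg/mL.
#'   Default 2.5.
#' @param vesicle_diameter Mean outer vesicle diameter in nm. Default 179.
#' @param bilayer_thickness Bilayer thickness in nm. Default 4.
#' @param calcein_concentration Encapsulated calcein concentration in mol/L.
#'   Default 0.050 (self-quenching regime).
#' @return An object of class `npw_preparation`.
#' @export
preparation_spec <- function(lipid_mass_concentration = 2.5,
                             vesicle_diameter = 179,
                             bilayer_thickness = 4,
                             calcein_concentration = 0.050) {
  .check_num(lipid_mass_concentration, "lipid_mass_concentration", 0)
  .check_num(vesicle_diameter, "vesicle_diameter", 0, strict = TRUE)
  .check_num(bilayer_thickness, "bilayer_thickness", 0, strict = TRUE)
  .check_num(calcein_concentration, "calcein_concentration", 0, strict = TRUE)
  structure(list(lipid_mass_concentration = lipid_mass_concentration,
                 vesicle_diameter = vesicle_diameter,
                 bilayer_thickness = bilayer_thickness,
                 calcein_concentration = calcein_concentration),
            class = "npw_preparation")
}

#' Isothermal titration calorimetry injection schedule
#'
#' Defaults mirror the study's protocol: a first 0.4 uL injection followed by
#' 12 consecutive 3 uL injections at 150 s intervals, 0.5 uL/s, into a 205 uL
#' cell at 25 C.
#'
#' @param first_volume Volume of the first (small, discardable) injection, uL.
#' @param volume Volume of each subsequent injection, uL.
#' @param count Number of full injections after the first. Default 12.
#' @param interval Time between injections, s. Default 150.
#' @param rate Injection rate, uL/s. Default 0.5.
#' @param cell_volume Calorimeter cell volume, uL. Default 205.
#' @param temperature Cell temperature, K. Default 298.15.
#' @return An object of class `npw_schedule`.
#' @export
injection_schedule <- function(first_volume = 0.4, volume = 3, count = 12,
                               interval = 150, rate = 0.5,
                               cell_volume = 205, temperature = 298.15) {
  for (nm in c("first_volume", "volume", "interval", "rate",
               "cell_volume", "temperature"))
    .check_num(get(nm), nm, 0, strict = TRUE)
  count <- as.integer(.check_num(count, "count", 1))
  if (interval <= volume / rate)
    stop("'interval' must exceed the injection duration", call. = FALSE)
  structure(list(first_volume = first_volume, volume = volume, count = count,
                 interval = interval, rate = rate, cell_volume = cell_volume,
                 temperature = temperature),
            class = "npw_schedule")
}

#' Dynamic light scattering optical setup
#'
#' Defaults mirror the study's backscatter instrument: 630 nm laser,
#' detection at 173 degrees, aqueous dispersant at 25 C.
#'
#' @param wavelength Laser wavelength in vacuo, nm. Default 630.
#' @param angle Scattering angle, degrees in (0, 180). Default 173.
#' @param refractive_index Dispersant refractive index. Default 1.33 (water).
#' @param temperature Temperature, K. Default 298.15.
#' @param viscosity Dispersant viscosity, Pa s. Default 8.90e-4 (water, 25 C).
#' @return An object of class `npw_optics`.
#' @export
optical_setup <- function(wavelength = 630, angle = 173,
                          refractive_index = 1.33, temperature = 298.15,
                          viscosity = 8.90e-4) {
  .check_num(wavelength, "wavelength", 0, strict = TRUE)
  .check_num(angle, "angle", 0, strict = TRUE)
  if (angle >= 180) stop("'angle' must be in (0, 180)", call. = FALSE)
  .check_num(refractive_index, "refractive_index", 0, strict = TRUE)
  .check_num(temperature, "temperature", 0, strict = TRUE)
  .check_num(viscosity, "viscosity", 0, strict = TRUE)
  structure(list(wavelength = wavelength, angle = angle,
                 refractive_index = refractive_index,
                 temperature = temperature, viscosity = viscosity),
            class = "npw_optics")
}

#' Scattering population
#'
#' One monodisperse population in a dynamic light scattering mixture.
#'
#' @param diameter Hydrodynamic diameter, nm.
#' @param number_concentration Particles per mL (any consistent relative
#'   unit; only ratios between populations matter for intensity weights).
#' @return An object of class `npw_population`.
#' @export
population <- function(diameter, number_concentration) {
  .check_num(diameter, "diameter", 0, strict = TRUE)
  .check_num(number_concentration, "number_concentration", 0)
  structure(list(diameter = diameter,
                 number_concentration = number_concentration),
            class = "npw_population")
}

#' @export
print.npw_membrane <- function(x, ...) {
  kT <- x$bending_modulus / (.kB * 298.15)
  cat(sprintf(
    "Membrane: k = %.3g J (%.1f kT at 298 K), sigma = %.3g N/m, h = %g nm, a_lipid = %g A^2\n",
    x$bending_modulus, kT, x$tension, x$thickness, x$area_per_lipid))
  invisible(x)
}

#' @export
print.npw_vesicle <- function(x, ...) {
  cat(sprintf(
    "Vesicle: D = %g nm (lumen %g nm), A0 = %.4g nm^2, V0 = %.4g nm^3\n",
    x$outer_diameter, x$lumen_diameter, x$area, x$volume))
  invisible(x)
}
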