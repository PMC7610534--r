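# CSV readers/writers with schema validation, and the demo pipeline.
# One tabular dialect throughout: plain CSV with units embedded in the
# header names (time_s, power_uW, wavelength_nm, delay_us, ...).

.npw_schemas <- list(
  thermogram  = list(cols = c("time_s", "power_uW"), axis = "time_s"),
  heats       = list(cols = c("injection", "heat_uJ"), axis = NULL),
  spectrum    = list(cols = c("wavelength_nm", "intensity"),
                     axis = "wavelength_nm"),
  correlogram = list(cols = c("delay_us", "g2"), axis = "delay_us"),
  plate       = list(cols = c("well", "F_sample", "F_control", "F_max"),
                     axis = NULL),
  standards   = list(cols = c("concentration", "fluorescence"), axis = NULL),
  populations = list(cols = c("diameter_nm", "particles_per_ml"), axis = NULL)
)

#' Read and validate an instrument table
#'
#' Reads a CSV and validates it against one of the package's table schemas:
#' required columns must be present (the error names the missing column) and
#' the schema's axis column (time, wavelength or delay) must be strictly
#' increasing.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"thermogram"`, `"heats"`, `"spectrum"`,
#'   `"correlogram"`, `"plate"`, `"standards"`, `"populations"`.
#' @return A validated data frame.
#' @export
read_table <- function(path, schema = names(.npw_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- .npw_schemas[[schema]]
  x <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(sc$cols, names(x))
  if (length(missing))
    stop(sprintf("%s table '%s' is missing column(s): %s", schema, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (cn in setdiff(sc$cols, "well"))
    if (!is.numeric(x[[cn]]))
      stop(sprintf("column '%s' must be numeric", cn), call. = FALSE)
  if (!is.null(sc$axis) && any(diff(x[[sc$axis]]) <= 0))
    stop(sprintf("column '%s' must be strictly increasing", sc$axis),
         call. = FALSE)
  x
}

#' Write a table as CSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Parameters for [run_pipeline()], defaulting to the study conditions:
#' bare-gold adhesion on a 20 kT tensionless PC membrane, a 179 nm vesicle
#' with the default lockout calibration, 2.5 mg/mL DOPC/POPC preparation,
#' the supplier nanoparticle stocks, and seeded synthetic instrument traces.
#'
#' @param seed Integer seed for all synthetic stages. Default 1.
#' @param np_diameter Nanoparticle diameter for the ITC/DLS stages, nm.
#'   Default 5.
#' @return A named list of class `npw_config`.
#' @export
pipeline_config <- function(seed = 1, np_diameter = 5) {
  stocks <- aunp_stocks()
  if (!np_diameter %in% stocks$diameter_nm)
    stop("np_diameter must be one of the supplier sizes: ",
         paste(stocks$diameter_nm, collapse = ", "), call. = FALSE)
  structure(list(
    seed = seed,
    membrane = membrane_spec(),
    adhesion = adhesion_spec(adhesion_strength = 0.042),
    vesicle = vesicle_spec(179),
    lockout = lockout_params(),
    prep = preparation_spec(),
    lipid = lipid_spec("DOPC/POPC"),
    schedule = injection_schedule(),
    optics = optical_setup(),
    np_diameter = np_diameter,
    np_count_per_ml = stocks$particles_per_ml[
      stocks$diameter_nm == np_diameter]),
    class = "npw_config")
}

#' Run the full demonstration pipeline
#'
#' Executes every analysis stage on the study conditions plus seeded
#' synthetic instrument data: wrapping theory (critical diameters),
#' engulfment lockout (capacity and maximum engulfable size), dosimetry
#' (liposome concentration, area ratios, surface areas), ITC (generate,
#' integrate, dilution-subtract, normalise), assays (spectrum peak fit and
#' shift, leakage), and DLS (mixture correlograms, cumulant fit, population
#' shift). Optionally writes a JSON summary, the intermediate CSV tables and
#' a parameter log.
#'
#' @param config An [pipeline_config()] list.
#' @param output_dir Optional directory; when given, writes `summary.json`,
#'   the stage CSVs and `run.log` there.
#' @return A list of stage results; `$summary` holds the headline numbers.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 1))
#' res$summary
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  if (!inherits(config, "npw_config"))
    stop("usage error: 'config' must come from pipeline_config()",
         call. = FALSE)
  seed <- config$seed

  # theory
  dc <- critical_diameter_tensionless(config$membrane, config$adhesion)
  dcs <- critical_diameter_with_tension(config$membrane, config$adhesion)

  # lockout
  budget10 <- engulfment_capacity(config$vesicle, 10, config$lockout)
  dmax <- max_engulfable_diameter(config$vesicle, config$lockout)

  # dosimetry
  n_lip <- liposomes_per_ml(config$prep, config$lipid)
  ratios <- area_ratio(config$prep$vesicle_diameter, c(5, 10, 25, 60))
  np <- nanoparticle_spec(config$np_diameter, config$np_count_per_ml)
  cell_ml <- config$schedule$cell_volume * 1e-3
  sa_au <- np_surface_area_per_ml(np) * cell_ml
  sa_l <- liposome_surface_area_per_ml(config$prep, config$lipid) * cell_ml

  # itc on synthetic traces
  true_heats <- c(-1, seq(-10, -4.5, length.out = config$schedule$count))
  tg <- gen_thermogram(config$schedule, true_heats, seed = seed)
  ctrl <- gen_thermogram(config$schedule,
                         rep(-0.4, config$schedule$count + 1), seed = seed + 1)
  heats <- subtract_dilution(integrate_thermogram(tg, config$schedule),
                             integrate_thermogram(ctrl, config$schedule))
  enthalpy <- normalize_enthalpy(heats, sa_au = sa_au, sa_l = sa_l)

  # assays on synthetic spectra
  ref <- fit_emission_peak(gen_spectrum(center = 646, noise_sd = 0.5,
                                        seed = seed))
  smp <- fit_emission_peak(gen_spectrum(center = 635, noise_sd = 0.5,
                                        seed = seed + 1))
  shift <- emission_shift(ref$center, smp$center)
  leak <- leakage_percent(55, 10, 100)

  # dls: start from equal-intensity free-particle and vesicle modes, then
  # move the particle intensity into the vesicle mode (binding)
  n_np <- 1e12
  n_ves <- n_np / (179 / config$np_diameter)^6
  before <- gen_correlogram(list(population(config$np_diameter, n_np),
                                 population(179, n_ves)),
                            config$optics, seed = seed)
  after <- gen_correlogram(list(population(config$np_diameter, 1e-6 * n_np),
                                population(179, 2 * n_ves)),
                           config$optics, seed = seed + 1)
  cum <- cumulant_fit(after, config$optics)
  shift_dls <- population_shift_metric(before, after, config$optics)

  summary <- list(
    critical_diameter_nm = dc,
    critical_diameter_tension_nm = dcs,
    capacity_10nm = budget10$capacity,
    max_engulfable_diameter_nm = dmax,
    liposomes_per_ml = n_lip,
    area_ratio_5nm = ratios[1], area_ratio_10nm = ratios[2],
    area_ratio_25nm = ratios[3], area_ratio_60nm = ratios[4],
    delta_H_mJ_m2 = enthalpy$delta_H,
    emission_shift_nm = shift$shift, emission_shift_label = shift$label,
    leakage_percent = leak,
    dls_mean_diameter_nm = cum$diameter,
    dls_population_shift = shift_dls$metric)

  res <- list(summary = summary, heats = heats, enthalpy = enthalpy,
              budget = budget10, reference_peak = ref, sample_peak = smp,
              correlograms = list(before = before, after = after),
              config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_table(tg, file.path(output_dir, "thermogram.csv"))
    write_table(heats, file.path(output_dir, "heats.csv"))
    write_table(before, file.path(output_dir, "correlogram_before.csv"))
    write_table(after, file.path(output_dir, "correlogram_after.csv"))
    log_lines <- c(
      sprintf("seed = %d", seed),
      sprintf("bending_modulus_J = %g", config$membrane$bending_modulus),
      sprintf("tension_N_m = %g", config$membrane$tension),
      sprintf("adhesion_strength_N_m = %g", config$adhesion$adhesion_strength),
      sprintf("vesicle_diameter_nm = %g", config$vesicle$outer_diameter),
      sprintf("max_area_strain = %g", config$lockout$max_area_strain),
      sprintf("wrap_margin_nm = %g", config$lockout$wrap_margin),
      sprintf("lipid = %s (%g g/mol)", config$lipid$name,
              config$lipid$molar_mass),
      sprintf("lipid_mass_concentration_mg_ml = %g",
              config$prep$lipid_mass_concentration),
      sprintf("np_diameter_nm = %g", config$np_diameter),
      sprintf("np_count_per_ml = %g", config$np_count_per_ml))
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  res
}
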