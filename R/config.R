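# Run configuration: YAML with one section per model component and explicit
# unit suffixes in key names (the formulas mix nm/um/mm/cm; suffixed keys
# keep conversions at this boundary only).

config_schema <- list(
  particle = c("radius_nm", "material"),
  optics = c("n_medium", "wavelength_nm", "sigma_abs_nm2", "Qa", "Qs_prime"),
  cell = c("radius_um"),
  tissue = c("radius_mm", "depth_mm", "cell_spacing_um", "volume_fraction",
             "thermal_conductivity_w_mk", "baseline_c", "mu_a_medium_cm",
             "mu_s_prime_medium_cm"),
  beam = c("shape", "intensity_wcm2", "RL_mm", "L1_mm", "L2_mm", "P1_mm",
           "P2_mm", "n_inner", "n_outer", "Rc_mm", "outer_phase_rad"),
  grid = c("preset", "nodes", "nx", "nz", "plane"),
  damage = c("threshold_c", "arrhenius_a_per_s", "activation_energy_j_mol")
)

default_config <- function() {
  list(
    particle = list(radius_nm = 20, material = "Au"),
    optics = list(n_medium = 1.40, wavelength_nm = NULL, sigma_abs_nm2 = NULL,
                  Qa = NULL, Qs_prime = NULL),
    cell = list(radius_um = 10),
    tissue = list(radius_mm = 2, depth_mm = 2, cell_spacing_um = 50,
                  volume_fraction = 5.6e-6, thermal_conductivity_w_mk = 0.55,
                  baseline_c = 37, mu_a_medium_cm = 32.26,
                  mu_s_prime_medium_cm = 1.3),
    beam = list(shape = "full", intensity_wcm2 = 15),
    grid = list(preset = "coarse", plane = FALSE),
    damage = list(threshold_c = 52, arrhenius_a_per_s = 3.1e98,
                  activation_energy_j_mol = 6.28e5),
    seed = 1L,
    output_dir = NULL
  )
}

#' Run configuration
#'
#' Builds a validated run configuration, merging user settings over the
#' packaged defaults (the worked gold-nanosphere scenario: 20 nm particles,
#' volume fraction 5.6e-6, full-coverage beam at 15 W/cm²). Unknown keys
#' anywhere in the structure are rejected, every offending key reported.
#'
#' @param settings nested list with any of the sections `particle`,
#'   `optics`, `cell`, `tissue`, `beam`, `grid`, `damage` plus `seed` and
#'   `output_dir`; see the packaged `default_config.yaml` for all keys.
#' @return An object of class `run_config`.
#' @export
run_config <- function(settings = list()) {
  base <- default_config()
  top_ok <- c(names(config_schema), "seed", "output_dir")
  bad <- character(0)
  bad <- c(bad, setdiff(names(settings), top_ok))
  for (sec in intersect(names(settings), names(config_schema))) {
    extra <- setdiff(names(settings[[sec]]), config_schema[[sec]])
    if (length(extra)) bad <- c(bad, paste0(sec, "$", extra))
  }
  if (length(bad))
    stop_bad_arg("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(base, settings, keep.null = TRUE)
  # cross-field validation happens in the constructors at run time; check
  # the cheap structural constraints here
  if (!cfg$beam$shape %in% c("full", "spot", "ring", "spot_array"))
    stop_bad_arg("beam$shape must be full, spot, ring or spot_array")
  if (!is.null(cfg$grid$preset) &&
      !cfg$grid$preset %in% c("coarse", "default", "fine"))
    stop_bad_arg("grid$preset must be coarse, default or fine")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_beam <- function(cfg) {
  b <- cfg$beam
  beam_spec(shape = b$shape, I0_wcm2 = b$intensity_wcm2,
            RL_mm = b$RL_mm, L1_mm = b$L1_mm, L2_mm = b$L2_mm,
            P1_mm = b$P1_mm, P2_mm = b$P2_mm,
            n_inner = if (is.null(b$n_inner)) 8L else b$n_inner,
            n_outer = if (is.null(b$n_outer)) 8L else b$n_outer,
            Rc_mm = if (is.null(b$Rc_mm)) 0.15 else b$Rc_mm,
            outer_phase = b$outer_phase_rad)
}

config_tissue <- function(cfg) {
  t <- cfg$tissue
  tissue_spec(radius_mm = t$radius_mm, depth_mm = t$depth_mm,
              cell_spacing_um = t$cell_spacing_um, fv = t$volume_fraction,
              kappa_w_mk = t$thermal_conductivity_w_mk,
              baseline_c = t$baseline_c,
              medium = medium_optics(t$mu_a_medium_cm,
                                     t$mu_s_prime_medium_cm))
}

config_grid <- function(cfg, tissue) {
  g <- cfg$grid
  if (isTRUE(g$plane)) {
    tumor_plane_grid(tissue,
                     nx = if (is.null(g$nx)) 101L else g$nx,
                     nz = if (is.null(g$nz)) 81L else g$nz)
  } else {
    tumor_grid(tissue, preset = if (is.null(g$preset)) "coarse" else g$preset,
               n = g$nodes)
  }
}

# resolve particle optics: Mie unless explicit overrides are given
config_optics <- function(cfg, log) {
  particle <- particle_spec(cfg$particle$radius_nm, cfg$particle$material)
  o <- cfg$optics
  need_mie <- is.null(o$sigma_abs_nm2) || is.null(o$Qa) || is.null(o$Qs_prime)
  if (need_mie) {
    table <- gold_optical_constants(n_medium = o$n_medium)
    wl <- o$wavelength_nm
    if (is.null(wl)) {
      wl <- plasmon_peak(particle, table)$wavelength_nm
      log(sprintf("plasmon peak scan 400-700 nm -> %g nm", wl))
    }
    eff <- mie_efficiencies(particle, wl, table)
    mie <- list(sigma_abs_nm2 = absorption_cross_section(eff, particle),
                Qa = eff$Qabs,
                Qs_prime = reduced_scattering_efficiency(eff))
  } else {
    mie <- list()
  }
  res <- list(
    particle = particle,
    sigma_abs_nm2 = if (is.null(o$sigma_abs_nm2)) mie$sigma_abs_nm2 else o$sigma_abs_nm2,
    Qa = if (is.null(o$Qa)) mie$Qa else o$Qa,
    Qs_prime = if (is.null(o$Qs_prime)) mie$Qs_prime else o$Qs_prime)
  log(sprintf("optics: R = %g nm, sigma_abs = %.4f nm^2, Qa = %.4f, Qs' = %.4f",
              particle$radius_nm, res$sigma_abs_nm2, res$Qa, res$Qs_prime))
  res
}

#' Run a complete scenario
#'
#' Deterministic pipeline from a [run_config()]: particle optics (Mie or
#' explicit overrides) -> composite attenuation coefficients -> cell
#' lattice and per-cell source strengths under the beam -> temperature
#' field -> [therapy_report()]. Identical config and seed give
#' byte-identical report JSON.
#'
#' @param config a [run_config()] (or plain list of settings).
#' @return list with `field` (rise [temperature_field()]), `report`
#'   ([therapy_report()]), `optics` (`composite_optics`), `log` (character
#'   lines of the resolved parameters), invisibly writing `field.csv`,
#'   `report.json` and `run.log` to `output_dir` when set.
#' @export
run_scenario <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  set.seed(config$seed)
  lines <- character(0)
  log <- function(msg) lines <<- c(lines, msg)
  log(sprintf("seed: %d", config$seed))

  opt <- config_optics(config, log)
  tissue <- config_tissue(config)
  beam <- config_beam(config)
  att <- nanoparticle_attenuation(tissue$fv, opt$Qa, opt$Qs_prime,
                                  opt$particle$radius_nm)
  comp <- composite_coefficients(tissue$medium, att, tissue$fv)
  log(sprintf("composite optics: mu_a = %.4f cm^-1, mu_s' = %.4f cm^-1 (fv = %g)",
              comp$mu_a_cm, comp$mu_s_prime_cm, tissue$fv))
  grid <- config_grid(config, tissue)
  d <- grid_dims(grid)
  log(sprintf("grid: %d x %d x %d nodes", d[1], d[2], d[3]))
  cell <- cell_spec(radius_um = config$cell$radius_um)
  field <- tissue_field(tissue, beam, comp, opt$particle, opt$sigma_abs_nm2,
                        grid, cell)
  log(sprintf("lit cells: %d; max dT = %.4f K", attr(field, "n_sources"),
              max(field$values)))
  dmg <- config$damage
  report <- therapy_report(
    field, tissue, beam, threshold_c = dmg$threshold_c,
    arrhenius = arrhenius_params(dmg$arrhenius_a_per_s,
                                 dmg$activation_energy_j_mol))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_field_csv(field, file.path(config$output_dir, "field.csv"))
    write_report_json(report, file.path(config$output_dir, "report.json"))
    writeLines(lines, file.path(config$output_dir, "run.log"))
  }
  list(field = field, report = report, optics = comp, log = lines)
}

#' Compare irradiation shapes on a shared scenario
#'
#' Runs one scenario per config and tabulates the therapy metrics. All
#' configs must share the tissue and grid sections (same tumor, same
#' evaluation grid); rows follow the input order.
#'
#' @param configs list of [run_config()]s (or settings lists).
#' @return data.frame with one row per beam shape.
#' @export
compare_shapes <- function(configs) {
  configs <- lapply(configs, function(cf)
    if (inherits(cf, "run_config")) cf else run_config(cf))
  if (length(configs) == 0L) stop_bad_arg("no configs supplied")
  ref <- configs[[1]]
  for (cf in configs[-1]) {
    if (!identical(unclass(cf)$tissue, unclass(ref)$tissue) ||
        !identical(unclass(cf)$grid, unclass(ref)$grid))
      stop_bad_arg("all configs must share tissue and grid sections")
  }
  rows <- lapply(configs, function(cf) {
    rep <- run_scenario(cf)$report
    data.frame(shape = rep$beam_shape, I0_wcm2 = rep$I0_wcm2,
               T_B_c = rep$T_B_c, T_C_c = rep$T_C_c, T_D_c = rep$T_D_c,
               uniformity = rep$uniformity,
               overheating_mm3 = rep$overheating_volume_mm3,
               delivered_power_w = rep$delivered_power_w)
  })
  do.call(rbind, rows)
}
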