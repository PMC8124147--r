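#' Therapy-quality report for a computed field
#'
#' Summarizes a tumor temperature field into the quantities used to judge a
#' treatment plan: reference-point temperatures (B/C/D), tumor temperature
#' uniformity, overheated healthy-tissue volume, minimum Arrhenius damage
#' times at the reference points, and delivered optical power.
#'
#' @param field a [temperature_field()] of rises in K on a 3D grid.
#' @param tissue the [tissue_spec()] the field was computed for.
#' @param beam the [beam_spec()] used.
#' @param threshold_c overheating threshold in °C (must exceed baseline).
#' @param arrhenius an [arrhenius_params()].
#' @param points_m reference points, default [reference_points()].
#' @return An object of class `therapy_report` (a list).
#' @export
therapy_report <- function(field, tissue, beam, threshold_c = 52,
                           arrhenius = arrhenius_params(),
                           points_m = reference_points(tissue)) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(tissue, "tissue_spec"), inherits(beam, "beam_spec"))
  if (threshold_c <= tissue$baseline_c)
    stop_bad_arg("threshold_c must exceed the baseline temperature")
  abs_field <- absolute_temperature(field)
  mask <- tumor_mask(field$grid, tissue)
  refs <- reference_temperatures(abs_field, points_m)
  t_min <- setNames(min_damage_time(refs + 273.15, arrhenius), names(refs))
  structure(list(
    T_B_c = unname(refs["B"]), T_C_c = unname(refs["C"]),
    T_D_c = unname(refs["D"]),
    uniformity = uniformity(abs_field, mask),
    overheating_volume_mm3 = overheating_volume(abs_field, mask, threshold_c),
    threshold_c = threshold_c,
    t_min_s = as.list(t_min),
    delivered_power_w = delivered_power(beam, tissue$radius_mm),
    beam_shape = beam$shape,
    I0_wcm2 = beam$I0_wcm2,
    baseline_c = tissue$baseline_c,
    max_T_c = max(abs_field$values),
    n_sources = attr(field, "n_sources")
  ), class = "therapy_report")
}

#' @export
print.therapy_report <- function(x, ...) {
  cat(sprintf("<therapy_report> beam = %s (I0 = %g W/cm^2)\n", x$beam_shape,
              x$I0_wcm2))
  cat(sprintf("  T_B = %.2f  T_C = %.2f  T_D = %.2f degC (max %.2f)\n",
              x$T_B_c, x$T_C_c, x$T_D_c, x$max_T_c))
  cat(sprintf("  tumor uniformity (max-min)/mean = %.3f\n", x$uniformity))
  cat(sprintf("  overheated healthy tissue > %.0f degC: %.3f mm^3\n",
              x$threshold_c, x$overheating_volume_mm3))
  cat(sprintf("  delivered power: %.3f W\n", x$delivered_power_w))
  invisible(x)
}

#' Serialize a therapy report to JSON
#'
#' @param report a [therapy_report()].
#' @param path file path; the JSON is written deterministically (same
#'   report, same bytes).
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "therapy_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write isotherm polylines as CSV
#'
#' @param contours result of [isotherm_extract()].
#' @param path file path; polylines are concatenated with a `segment`
#'   index column.
#' @return the path, invisibly.
#' @export
write_isotherms_csv <- function(contours, path) {
  if (length(contours) == 0L) {
    writeLines("segment,x_mm,z_mm", path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(seq_along(contours), function(i) {
    cbind(segment = i, contours[[i]])
  }))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
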