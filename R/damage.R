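#' Arrhenius damage parameters
#'
#' Defaults are the widely used Henriques-Moritz coefficients for thermal
#' damage of soft tissue (frequency factor `A = 3.1e98` 1/s, activation
#' energy `Ea = 6.28e5` J/mol). They are literature values for generic soft
#' tissue, not tumor-specific; override for other tissues.
#'
#' @param A_per_s frequency factor in 1/s, `> 0`.
#' @param Ea_j_mol activation energy in J/mol, `> 0`.
#' @param R_gas gas constant in J/(mol·K).
#' @return An object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(A_per_s = 3.1e98, Ea_j_mol = 6.28e5,
                             R_gas = 8.314) {
  if (A_per_s <= 0 || Ea_j_mol <= 0)
    stop_bad_arg("A_per_s and Ea_j_mol must be > 0")
  structure(list(A_per_s = as.numeric(A_per_s),
                 Ea_j_mol = as.numeric(Ea_j_mol),
                 R_gas = as.numeric(R_gas)),
            class = "arrhenius_params")
}

#' Arrhenius thermal damage integral at constant temperature
#'
#' \eqn{\Omega(t) = A e^{-E_a/(R T)} t}; tissue is taken as irreversibly
#' damaged once \eqn{\Omega \ge 1}.
#'
#' @param T_k absolute temperature(s) in K, `> 0`.
#' @param t_s exposure time(s) in s, `>= 0`.
#' @param params an [arrhenius_params()].
#' @return dimensionless damage measure `Omega` (log-domain evaluation, so
#'   very large `A` and `Ea` do not overflow).
#' @export
damage_rate <- function(T_k, t_s, params = arrhenius_params()) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (any(T_k <= 0)) stop_bad_arg("temperature must be > 0 K")
  if (any(t_s < 0)) stop_bad_arg("time must be >= 0")
  out <- exp(log(params$A_per_s) - params$Ea_j_mol / (params$R_gas * T_k) +
               log(t_s))
  out[t_s == 0] <- 0
  out
}

#' Minimum exposure time for irreversible damage
#'
#' Inverts \eqn{\Omega = 1}: \eqn{t_{min} = 1 / (A e^{-E_a/(R T)})};
#' strictly decreasing in temperature.
#'
#' @inheritParams damage_rate
#' @return time in s.
#' @export
min_damage_time <- function(T_k, params = arrhenius_params()) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (any(T_k <= 0)) stop_bad_arg("temperature must be > 0 K")
  exp(params$Ea_j_mol / (params$R_gas * T_k) - log(params$A_per_s))
}

#' Tumor occupancy mask on a grid
#'
#' @param grid a [field_grid()].
#' @param tissue a [tissue_spec()].
#' @return logical array over the grid: inside the tumor cylinder?
#' @export
tumor_mask <- function(grid, tissue) {
  stopifnot(inherits(grid, "field_grid"), inherits(tissue, "tissue_spec"))
  RT <- tissue$radius_mm * MM
  depth <- tissue$depth_mm * MM
  rho <- sqrt(outer(grid$x^2, grid$y^2, `+`))
  inz <- grid$z >= 0 & grid$z <= depth
  outer(rho <= RT, inz, `&`)
}

# per-node integration volumes of a (possibly non-uniform) grid, m^3
node_volumes <- function(grid) {
  w <- function(ax) {
    if (length(ax) == 1L) return(1)
    mid <- (ax[-1] + ax[-length(ax)]) / 2
    diff(c(ax[1], mid, ax[length(ax)]))
  }
  outer(outer(w(grid$x), w(grid$y), `*`), w(grid$z), `*`)
}

#' Overheated healthy-tissue volume
#'
#' Volume of non-tumor grid nodes whose absolute temperature exceeds a
#' threshold (default 52 °C), integrated with per-node cell volumes.
#'
#' @param field an absolute-temperature [temperature_field()] (a rise field
#'   is converted using its baseline).
#' @param mask logical array marking tumor nodes (same grid); see
#'   [tumor_mask()].
#' @param threshold_c overheating threshold in °C.
#' @return volume in mm³.
#' @export
overheating_volume <- function(field, mask, threshold_c = 52) {
  stopifnot(inherits(field, "temperature_field"))
  field <- absolute_temperature(field)
  if (!identical(dim(mask), dim(field$values)))
    stop_bad_arg("tumor mask and field are on different grids")
  vol <- node_volumes(field$grid)
  hot <- !mask & field$values > threshold_c
  sum(vol[hot]) / MM^3
}

#' Default reference points B, C, D
#'
#' B: tumor side at mid-depth (`rho = RT, z = depth/2`); C: bottom centre
#' (`rho = 0, z = depth`); D: top side edge (`rho = RT, z = 0`). A uniform
#' treatment wants B, C and D at similar temperatures: under full-coverage
#' light with strong attenuation the side (B) runs hotter than the bottom
#' centre (C) for deep tumors, and cooler for shallow ones.
#'
#' @param tissue a [tissue_spec()].
#' @return 3 x 3 matrix (rows B, C, D) of positions in metres.
#' @export
reference_points <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_spec"))
  RT <- tissue$radius_mm * MM
  d <- tissue$depth_mm * MM
  m <- rbind(B = c(RT, 0, d / 2), C = c(0, 0, d), D = c(RT, 0, 0))
  colnames(m) <- c("x", "y", "z")
  m
}

# trilinear interpolation of a field at points (m); errors outside the grid
interp_field <- function(field, points_m) {
  g <- field$grid
  points_m <- matrix(as.numeric(points_m), ncol = 3)
  axes <- list(g$x, g$y, g$z)
  idx <- matrix(1L, nrow(points_m), 3)
  frac <- matrix(0, nrow(points_m), 3)
  for (a in 1:3) {
    ax <- axes[[a]]
    p <- points_m[, a]
    if (any(p < ax[1] - 1e-12 | p > ax[length(ax)] + 1e-12))
      stop_bad_arg("point outside the field grid on axis ", c("x", "y", "z")[a])
    if (length(ax) == 1L) next
    i <- findInterval(p, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ax) - 1L)
    idx[, a] <- i
    frac[, a] <- (p - ax[i]) / (ax[i + 1] - ax[i])
  }
  nax <- vapply(axes, length, integer(1))
  out <- numeric(nrow(points_m))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    if ((cx && nax[1] == 1) || (cy && nax[2] == 1) || (cz && nax[3] == 1)) next
    w <- (if (cx) frac[, 1] else 1 - frac[, 1]) *
      (if (cy) frac[, 2] else 1 - frac[, 2]) *
      (if (cz) frac[, 3] else 1 - frac[, 3])
    out <- out + w * field$values[cbind(idx[, 1] + cx, idx[, 2] + cy,
                                        idx[, 3] + cz)]
  }
  out
}

#' Temperatures at the reference points
#'
#' Trilinear interpolation of the field at the configured points.
#'
#' @param field a [temperature_field()].
#' @param points_m matrix (n x 3) of points in metres, e.g.
#'   [reference_points()]; row names are kept.
#' @return named numeric vector of temperatures (K rise or °C, matching the
#'   field).
#' @export
reference_temperatures <- function(field, points_m) {
  stopifnot(inherits(field, "temperature_field"))
  setNames(interp_field(field, points_m), rownames(points_m))
}

#' Tumor temperature uniformity
#'
#' `(max - min) / mean` of the field over tumor nodes; 0 is perfectly
#' uniform.
#'
#' @inheritParams overheating_volume
#' @return dimensionless uniformity measure.
#' @export
uniformity <- function(field, mask) {
  stopifnot(inherits(field, "temperature_field"))
  v <- field$values[mask]
  if (length(v) == 0L) stop_bad_arg("tumor mask selects no grid nodes")
  (max(v) - min(v)) / mean(v)
}

#' Extract an isotherm in the x-z plane
#'
#' Marching-squares contour of the field slice at the y node nearest
#' `y_mm`, at a given temperature level. Levels outside the slice range
#' yield an empty list.
#'
#' @param field a [temperature_field()].
#' @param level temperature level (same units as the field values).
#' @param y_mm lateral position of the slice in mm.
#' @return list of contour polylines, each a data.frame with `x_mm`,
#'   `z_mm`.
#' @export
isotherm_extract <- function(field, level, y_mm = 0) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$grid
  iy <- which.min(abs(g$y - y_mm * MM))
  slice <- field$values[, iy, ]
  if (level < min(slice) || level > max(slice)) return(list())
  cl <- grDevices::contourLines(x = g$x, y = g$z, z = slice, levels = level)
  lapply(cl, function(p) data.frame(x_mm = p$x / MM, z_mm = p$y / MM))
}

#' Deepest axial point of an isotherm
#'
#' Follows the temperature profile down the tumor axis (`x = y = 0`) and
#' returns the greatest depth at which it still reaches `level`
#' (linearly interpolated between nodes). Used to track how the cold side
#' of an isotherm moves with nanoparticle loading.
#'
#' @inheritParams isotherm_extract
#' @return depth in mm (`NA` if the axis never reaches the level).
#' @export
axial_isotherm_depth <- function(field, level) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$grid
  ix <- which.min(abs(g$x)); iy <- which.min(abs(g$y))
  prof <- field$values[ix, iy, ]
  above <- prof >= level
  if (!any(above)) return(NA_real_)
  i <- max(which(above))
  if (i == length(prof)) return(g$z[i] / MM)
  # interpolate the crossing between node i (>= level) and i+1 (< level)
  z0 <- g$z[i]; z1 <- g$z[i + 1]
  t0 <- prof[i]; t1 <- prof[i + 1]
  (z0 + (t0 - level) / (t0 - t1) * (z1 - z0)) / MM
}
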