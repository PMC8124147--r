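#' Regular evaluation grid
#'
#' Axes are given in metres and must be strictly increasing; an axis may be
#' a single coordinate (e.g. `y = 0` for a plane).
#'
#' @param x,y,z numeric axes in metres.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(x, y, z) {
  for (ax in list(x, y, z)) {
    if (length(ax) < 1L || !all(is.finite(ax)))
      stop_bad_arg("grid axes must be finite and non-empty")
    if (length(ax) > 1L && any(diff(ax) <= 0))
      stop_bad_arg("grid axes must be strictly increasing")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "field_grid")
}

#' Grid preset spanning a tumor and its surroundings
#'
#' Cubic-count 3D grid covering twice the tumor extent in each direction:
#' laterally `[-2 RT, 2 RT]`, in depth `[-depth/2, 3 depth/2]`.
#'
#' @param tissue a [tissue_spec()].
#' @param preset `"coarse"` (33 nodes/axis), `"default"` (49) or `"fine"`
#'   (81); or pass `n` directly.
#' @param n nodes per axis, overriding the preset.
#' @return a [field_grid()].
#' @export
tumor_grid <- function(tissue, preset = c("default", "coarse", "fine"),
                       n = NULL) {
  stopifnot(inherits(tissue, "tissue_spec"))
  if (is.null(n)) {
    preset <- match.arg(preset)
    n <- c(coarse = 33L, default = 49L, fine = 81L)[[preset]]
  }
  RT <- tissue$radius_mm * MM
  d <- tissue$depth_mm * MM
  field_grid(seq(-2 * RT, 2 * RT, length.out = n),
             seq(-2 * RT, 2 * RT, length.out = n),
             seq(-d / 2, 3 * d / 2, length.out = n))
}

#' Plane grid through the tumor axis (y = 0)
#'
#' @inheritParams tumor_grid
#' @param nx,nz node counts along x and z.
#' @return a [field_grid()] with a single y node at 0.
#' @export
tumor_plane_grid <- function(tissue, nx = 101L, nz = 81L) {
  stopifnot(inherits(tissue, "tissue_spec"))
  RT <- tissue$radius_mm * MM
  d <- tissue$depth_mm * MM
  field_grid(seq(-2 * RT, 2 * RT, length.out = nx), 0,
             seq(-d / 2, 3 * d / 2, length.out = nz))
}

grid_dims <- function(grid) c(length(grid$x), length(grid$y), length(grid$z))

#' All grid nodes as a point matrix
#'
#' @param grid a [field_grid()].
#' @return matrix (n x 3) in metres, x varying fastest, then y, then z.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  g <- expand.grid(x = grid$x, y = grid$y, z = grid$z,
                   KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(g))
}

#' Temperature field container
#'
#' @param grid a [field_grid()].
#' @param values numeric array of dim `(nx, ny, nz)`; temperature rise in K
#'   (`absolute = FALSE`) or absolute temperature in °C.
#' @param baseline_c baseline temperature in °C.
#' @param absolute logical; are `values` absolute temperatures?
#' @return An object of class `temperature_field`.
#' @export
temperature_field <- function(grid, values, baseline_c = 37,
                              absolute = FALSE) {
  stopifnot(inherits(grid, "field_grid"))
  dims <- grid_dims(grid)
  values <- array(as.numeric(values), dim = dims)
  if (any(!is.finite(values)))
    stop_bad_arg("temperature values must be finite")
  if (!absolute && any(values < 0))
    stop_bad_arg("temperature rise must be >= 0")
  structure(list(grid = grid, values = values,
                 baseline_c = as.numeric(baseline_c),
                 absolute = isTRUE(absolute)),
            class = "temperature_field")
}

#' Set of point heat sources
#'
#' Each source deposits `strength_w` watts; the conduction kernel is clamped
#' at `clamp_radius_m` (the physical radius of the heated object: particle
#' radius at the nanoscale, cell radius at the cell/tissue scale), inside
#' which the temperature rise is constant.
#'
#' @param positions_m matrix (n x 3) of source positions in metres.
#' @param strength_w source strengths in W (recycled), `>= 0`.
#' @param clamp_radius_m clamp radius in metres, `> 0`.
#' @return An object of class `heat_source_set`.
#' @export
heat_source_set <- function(positions_m, strength_w, clamp_radius_m) {
  positions_m <- as.matrix(positions_m)
  if (nrow(positions_m) > 0 && ncol(positions_m) != 3L)
    stop_bad_arg("positions_m must have three columns")
  if (any(!is.finite(positions_m))) stop_bad_arg("positions must be finite")
  strength_w <- rep_len(as.numeric(strength_w), nrow(positions_m))
  if (any(strength_w < 0)) stop_bad_arg("strengths must be >= 0")
  if (clamp_radius_m <= 0) stop_bad_arg("clamp_radius_m must be > 0")
  structure(list(positions_m = positions_m, strength_w = strength_w,
                 clamp_radius_m = as.numeric(clamp_radius_m)),
            class = "heat_source_set")
}

#' Steady-state temperature rise around a single nanoparticle
#'
#' Closed form \eqn{\Delta T(r) = \sigma_{abs} I / (4\pi\kappa\,\max(r,
#' R_{NP}))}: the rise is constant inside the particle and decays as 1/r
#' outside.
#'
#' @param sigma_abs_nm2 absorption cross-section in nm².
#' @param I_wcm2 local light intensity in W/cm².
#' @param kappa_w_mk thermal conductivity in W/(K·m), `> 0`.
#' @param radius_nm particle radius in nm, `> 0`.
#' @param point either distances from the particle centre in metres, or a
#'   matrix (n x 3) of positions in metres.
#' @return temperature rise in K at each point.
#' @export
single_particle_dT <- function(sigma_abs_nm2, I_wcm2, kappa_w_mk, radius_nm,
                               point) {
  if (kappa_w_mk <= 0) stop_bad_arg("thermal conductivity must be > 0")
  if (radius_nm <= 0) stop_bad_arg("radius_nm must be > 0")
  r <- if (is.matrix(point)) sqrt(rowSums(point^2)) else abs(as.numeric(point))
  P <- sigma_abs_nm2 * NM^2 * I_wcm2 * WCM2
  P / (4 * pi * kappa_w_mk * pmax(r, radius_nm * NM))
}

#' Superpose point heat sources on a grid (direct sum)
#'
#' Exact evaluation of \eqn{\Delta T(p) = \sum_i P_i / (4\pi\kappa\,
#' \max(|p - p_i|, R_c))} at every grid node. This is the oracle path; for
#' large well-resolved problems see [fast_field()].
#'
#' @param sources a [heat_source_set()]; an empty set yields a zero field.
#' @param kappa_w_mk thermal conductivity in W/(K·m).
#' @param grid a [field_grid()].
#' @param baseline_c baseline temperature in °C carried by the field.
#' @return a [temperature_field()] of temperature rises in K.
#' @export
superpose <- function(sources, kappa_w_mk, grid, baseline_c = 37) {
  stopifnot(inherits(sources, "heat_source_set"), inherits(grid, "field_grid"))
  if (kappa_w_mk <= 0) stop_bad_arg("thermal conductivity must be > 0")
  dims <- grid_dims(grid)
  if (nrow(sources$positions_m) == 0L) {
    return(temperature_field(grid, array(0, dims), baseline_c))
  }
  v <- .cpp_direct_sum_grid(grid$x, grid$y, grid$z, sources$positions_m,
                            sources$strength_w, sources$clamp_radius_m,
                            kappa_w_mk)
  temperature_field(grid, array(v, dims), baseline_c)
}

#' Evaluate a source set at arbitrary points
#'
#' @inheritParams superpose
#' @param points_m matrix (n x 3) in metres.
#' @return temperature rises in K.
#' @export
superpose_at <- function(sources, kappa_w_mk, points_m) {
  stopifnot(inherits(sources, "heat_source_set"))
  points_m <- as.matrix(points_m)
  if (nrow(sources$positions_m) == 0L) return(numeric(nrow(points_m)))
  .cpp_direct_sum(points_m, sources$positions_m, sources$strength_w,
                  sources$clamp_radius_m, kappa_w_mk)
}

#' Exact per-particle field of nanoparticle-loaded cells
#'
#' Sums the clamped particle kernel over every particle of every cell: each
#' cell carries an identical particle lattice offset to its centre.
#'
#' @param cell_centers_m matrix (n x 3) of cell centres in metres (a single
#'   cell at the origin by default).
#' @param cell a [cell_spec()] with a resolvable particle lattice.
#' @param particle a [particle_spec()].
#' @param sigma_abs_nm2 absorption cross-section in nm².
#' @param I_wcm2 light intensity in W/cm² (constant across a cell; Beer
#'   attenuation is negligible at the micron scale).
#' @param kappa_w_mk thermal conductivity in W/(K·m).
#' @param grid a [field_grid()].
#' @param baseline_c baseline temperature in °C.
#' @return a [temperature_field()] of rises in K.
#' @export
cell_field_exact <- function(cell_centers_m = matrix(0, 1, 3), cell, particle,
                             sigma_abs_nm2, I_wcm2, kappa_w_mk, grid,
                             baseline_c = 37) {
  stopifnot(inherits(cell, "cell_spec"), inherits(particle, "particle_spec"))
  if (is.null(cell$spacing_nm))
    stop_bad_arg("cell_spec needs spacing_nm (or n_particles) to build the lattice")
  lat <- particle_lattice(cell$radius_um, cell$spacing_nm)
  nlat <- nrow(lat)
  ncell <- nrow(cell_centers_m)
  pos <- lat[rep(seq_len(nlat), times = ncell), , drop = FALSE] +
    cell_centers_m[rep(seq_len(ncell), each = nlat), , drop = FALSE]
  P <- sigma_abs_nm2 * NM^2 * I_wcm2 * WCM2
  src <- heat_source_set(pos, P, particle$radius_nm * NM)
  superpose(src, kappa_w_mk, grid, baseline_c)
}

#' Coarse-grained per-cell field
#'
#' Replaces each cell by one point source of strength
#' \eqn{N_{np}\,\sigma_{abs} I} clamped at the cell radius. Agrees with the
#' exact per-particle sum outside the cells; inside a cell it is lower,
#' since the near-particle peaks are averaged away.
#'
#' @inheritParams cell_field_exact
#' @param n_particles particles per cell (source strength multiplier).
#' @param cell_radius_um clamp radius (the cell radius) in µm.
#' @return a [temperature_field()] of rises in K.
#' @export
cell_field_coarse <- function(cell_centers_m, n_particles, sigma_abs_nm2,
                              I_wcm2, kappa_w_mk, cell_radius_um, grid,
                              baseline_c = 37) {
  P <- n_particles * sigma_abs_nm2 * NM^2 * I_wcm2 * WCM2
  src <- heat_source_set(cell_centers_m, P, cell_radius_um * UM)
  superpose(src, kappa_w_mk, grid, baseline_c)
}

#' Tissue-scale heat sources for a beam and loading
#'
#' Builds the per-cell source set for [tissue_field()]: cells on the tumor
#' lattice, each of strength \eqn{N_{np}\,\sigma_{abs}\,I_0\,
#' \mathrm{mask}(x_j, y_j)\, e^{-(\mu_a+\mu_s') z_j}} — the beam footprint
#' gates a cell laterally (collimated beam, no lateral spreading) and
#' Beer-Lambert attenuation is evaluated at the cell's own depth. Unlit
#' cells are dropped.
#'
#' @inheritParams cell_field_exact
#' @param tissue a [tissue_spec()].
#' @param beam a [beam_spec()].
#' @param optics a `composite_optics` from [composite_coefficients()].
#' @return a [heat_source_set()] (possibly empty when `fv = 0`).
#' @export
tissue_sources <- function(tissue, beam, optics, particle, sigma_abs_nm2,
                           cell = cell_spec()) {
  stopifnot(inherits(tissue, "tissue_spec"), inherits(beam, "beam_spec"),
            inherits(optics, "composite_optics"))
  centers <- cell_lattice(tissue)
  nnp <- particles_per_cell(tissue$fv, tissue$cell_spacing_um,
                            particle$radius_nm)
  if (nnp == 0L || nrow(centers) == 0L) {
    return(heat_source_set(centers[0, , drop = FALSE], numeric(0),
                           cell$radius_um * UM))
  }
  lit <- beam_mask(beam, centers[, 1] / MM, centers[, 2] / MM) == 1L
  centers <- centers[lit, , drop = FALSE]
  Iz <- intensity_at_depth(beam$I0_wcm2, optics, centers[, 3] / MM)
  P <- nnp * sigma_abs_nm2 * NM^2 * Iz * WCM2
  heat_source_set(centers, P, cell$radius_um * UM)
}

#' Millimetre-scale tumor temperature field
#'
#' Per-cell point-source superposition over the whole tumor with
#' Beer-Lambert depth attenuation and the beam footprint mask; clamp radius
#' is the cell radius. Steady state in an infinite homogeneous medium —
#' no boundary conditions and no blood perfusion.
#'
#' @inheritParams tissue_sources
#' @param grid a [field_grid()].
#' @return a [temperature_field()] of rises in K, with attribute
#'   `"n_sources"` (number of lit cells).
#' @export
tissue_field <- function(tissue, beam, optics, particle, sigma_abs_nm2, grid,
                         cell = cell_spec()) {
  src <- tissue_sources(tissue, beam, optics, particle, sigma_abs_nm2, cell)
  fld <- superpose(src, tissue$kappa_w_mk, grid, tissue$baseline_c)
  attr(fld, "n_sources") <- nrow(src$positions_m)
  fld
}

#' Absolute temperature field
#'
#' @param field a [temperature_field()] of rises in K.
#' @return the field with `values = baseline + rise` in °C and
#'   `absolute = TRUE`.
#' @export
absolute_temperature <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  if (field$absolute) return(field)
  temperature_field(field$grid, field$values + field$baseline_c,
                    field$baseline_c, absolute = TRUE)
}

#' @export
print.temperature_field <- function(x, ...) {
  d <- grid_dims(x$grid)
  cat(sprintf(
    "<temperature_field> %dx%dx%d grid, %s in [%.4g, %.4g] %s, baseline %.1f degC\n",
    d[1], d[2], d[3], if (x$absolute) "T" else "dT",
    min(x$values), max(x$values), if (x$absolute) "degC" else "K",
    x$baseline_c))
  invisible(x)
}

#' Export / import a field as flat CSV
#'
#' Long format with columns `x_mm`, `y_mm`, `z_mm` and `dT_K` (or `T_C` for
#' absolute fields); intended for small grids and external plotting.
#'
#' @param field a [temperature_field()].
#' @param path file path.
#' @return `read_field_csv()` reconstructs the `temperature_field`.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  pts <- grid_points(field$grid)
  df <- data.frame(x_mm = pts[, 1] / MM, y_mm = pts[, 2] / MM,
                   z_mm = pts[, 3] / MM, value = as.vector(field$values))
  names(df)[4] <- if (field$absolute) "T_C" else "dT_K"
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @param baseline_c baseline to attach on import.
#' @export
read_field_csv <- function(path, baseline_c = 37) {
  df <- read.table(path, header = TRUE, sep = ",")
  absolute <- "T_C" %in% names(df)
  val_col <- if (absolute) "T_C" else "dT_K"
  if (!all(c("x_mm", "y_mm", "z_mm", val_col) %in% names(df)))
    stop_bad_arg("field CSV must have columns x_mm, y_mm, z_mm and dT_K/T_C")
  gx <- sort(unique(df$x_mm)) * MM
  gy <- sort(unique(df$y_mm)) * MM
  gz <- sort(unique(df$z_mm)) * MM
  grid <- field_grid(gx, gy, gz)
  ix <- match(df$x_mm * MM, gx); iy <- match(df$y_mm * MM, gy)
  iz <- match(df$z_mm * MM, gz)
  vals <- array(NA_real_, grid_dims(grid))
  vals[cbind(ix, iy, iz)] <- df[[val_col]]
  temperature_field(grid, vals, baseline_c, absolute = absolute)
}
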