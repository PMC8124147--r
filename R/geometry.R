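#' Cell specification
#'
#' A spherical cell holding a cubic lattice of nanoparticles. Either the
#' lattice spacing `spacing_nm` or the target particle count `n_particles`
#' may be given; the missing one is derived so that `n_particles` lattice
#' points fit the cell volume (\eqn{d_1^3 N = (4/3)\pi R_{cell}^3}).
#'
#' @param radius_um cell radius in µm, `> 0`. Mammalian cells are tens of
#'   µm across; default 10 µm.
#' @param spacing_nm intra-cell particle lattice spacing d1 in nm.
#' @param n_particles target number of particles per cell.
#' @return An object of class `cell_spec` with both fields filled when
#'   derivable.
#' @export
cell_spec <- function(radius_um = 10, spacing_nm = NULL, n_particles = NULL) {
  if (radius_um <= 0) stop_bad_arg("radius_um must be > 0")
  if (is.null(spacing_nm) && !is.null(n_particles)) {
    if (n_particles < 1) stop_bad_arg("n_particles must be >= 1 to derive spacing")
    spacing_nm <- ((4 / 3) * pi * (radius_um * UM)^3 / n_particles)^(1 / 3) / NM
  }
  if (!is.null(spacing_nm) && spacing_nm <= 0)
    stop_bad_arg("spacing_nm must be > 0")
  structure(list(radius_um = as.numeric(radius_um),
                 spacing_nm = if (is.null(spacing_nm)) NULL else as.numeric(spacing_nm),
                 n_particles = if (is.null(n_particles)) NULL else as.integer(round(n_particles))),
            class = "cell_spec")
}

#' Tumor tissue specification
#'
#' A cylindrical tumor (axis along z, illuminated face at z = 0, z
#' increasing downward) holding a cubic lattice of cells, embedded in an
#' infinite homogeneous medium.
#'
#' @param radius_mm tumor radius in mm, `> 0`.
#' @param depth_mm tumor depth in mm, `> 0`.
#' @param cell_spacing_um centre-to-centre cell lattice spacing in µm.
#' @param fv nanoparticle volume fraction in the tumor.
#' @param kappa_w_mk thermal conductivity in W/(K·m), `> 0`.
#' @param baseline_c baseline (body) temperature in °C.
#' @param medium a [medium_optics()] for the unloaded tissue.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(radius_mm = 2, depth_mm = 2, cell_spacing_um = 50,
                        fv = 5.6e-6, kappa_w_mk = 0.55, baseline_c = 37,
                        medium = medium_optics()) {
  if (radius_mm <= 0 || depth_mm <= 0 || cell_spacing_um <= 0)
    stop_bad_arg("radius_mm, depth_mm and cell_spacing_um must be > 0")
  if (kappa_w_mk <= 0) stop_bad_arg("thermal conductivity must be > 0")
  if (fv < 0 || fv >= 1) stop_bad_arg("fv must be in [0, 1)")
  stopifnot(inherits(medium, "medium_optics"))
  structure(list(radius_mm = as.numeric(radius_mm),
                 depth_mm = as.numeric(depth_mm),
                 cell_spacing_um = as.numeric(cell_spacing_um),
                 fv = as.numeric(fv), kappa_w_mk = as.numeric(kappa_w_mk),
                 baseline_c = as.numeric(baseline_c), medium = medium),
            class = "tissue_spec")
}

# deterministic cubic lattice indices [-nmax, nmax] kept by a predicate;
# lexicographic ordering by (ix, iy, iz)
lattice_points <- function(span, spacing, keep) {
  nmax <- floor(span / spacing)
  idx <- seq(-nmax, nmax)
  pts <- as.matrix(expand.grid(iz = idx, iy = idx, ix = idx))[, 3:1, drop = FALSE]
  pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  xyz <- pts * spacing
  dimnames(xyz) <- NULL
  xyz[keep(xyz), , drop = FALSE]
}

#' Nanoparticle lattice inside a spherical cell
#'
#' Cubic lattice with spacing `spacing_nm`, centred on the cell centre;
#' points are kept iff they lie within the cell radius. Ordering is
#' deterministic (lexicographic by grid index).
#'
#' @param radius_um cell radius in µm.
#' @param spacing_nm lattice spacing d1 in nm, `> 0`.
#' @return numeric matrix (n x 3) of positions in metres, centred on the
#'   cell centre.
#' @export
particle_lattice <- function(radius_um, spacing_nm) {
  if (spacing_nm <= 0) stop_bad_arg("spacing_nm must be > 0")
  R <- radius_um * UM
  d <- spacing_nm * NM
  lattice_points(R, d, function(p) sqrt(rowSums(p^2)) <= R)
}

#' Cell lattice inside the tumor cylinder
#'
#' Cubic lattice with the tissue's cell spacing. Lateral (x, y) positions
#' are integer multiples of the spacing about the axis; depth levels sit at
#' half-integer multiples so that every cell centre lies strictly inside
#' `[0, depth]`. Points are kept iff inside the cylinder
#' (\eqn{\rho \le R_T}, \eqn{0 \le z \le} depth).
#'
#' @param tissue a [tissue_spec()].
#' @return numeric matrix (n x 3) of cell centres in metres.
#' @export
cell_lattice <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_spec"))
  a <- tissue$cell_spacing_um * UM
  RT <- tissue$radius_mm * MM
  depth <- tissue$depth_mm * MM
  nmax <- floor(RT / a)
  lat <- seq(-nmax, nmax) * a
  nz <- floor(depth / a)
  zs <- if (nz < 1L) depth / 2 else (seq_len(nz) - 0.5) * a
  g <- expand.grid(x = lat, y = lat, z = zs)
  g <- g[order(g$x, g$y, g$z), , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- NULL
  keep <- sqrt(m[, 1]^2 + m[, 2]^2) <= RT & m[, 3] >= 0 & m[, 3] <= depth
  m[keep, , drop = FALSE]
}

#' Particles per cell realizing a tissue-wide volume fraction
#'
#' Allocates one cell per cubic lattice box of side `cell_spacing_um`, so
#' that `n` particles per cell reproduce the bulk volume fraction:
#' \eqn{N = \mathrm{round}(f_v a^3 / ((4/3)\pi R_{NP}^3))}.
#'
#' @param fv volume fraction, `>= 0`.
#' @param cell_spacing_um cell lattice spacing in µm.
#' @param radius_nm particle radius in nm.
#' @return integer particle count.
#' @examples
#' particles_per_cell(5.6e-6, 50, 20)  # 20890
#' @export
particles_per_cell <- function(fv, cell_spacing_um, radius_nm) {
  if (fv < 0) stop_bad_arg("fv must be >= 0")
  vp <- (4 / 3) * pi * (radius_nm * NM)^3
  as.integer(round(fv * (cell_spacing_um * UM)^3 / vp))
}

#' Seeded random particle positions in a sphere
#'
#' Uniform random placement alternative to [particle_lattice()], intended
#' for robustness checks of lattice-based results.
#'
#' @param n number of positions.
#' @param radius_um sphere radius in µm.
#' @param seed integer RNG seed.
#' @return numeric matrix (n x 3) of positions in metres.
#' @export
random_positions_in_sphere <- function(n, radius_um, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  R <- radius_um * UM
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- R * stats::runif(n)^(1 / 3)
  u * r
}

#' Write / read positions as tabular text
#'
#' Positions are exchanged in µm in three tab-separated columns
#' `x_um`, `y_um`, `z_um`.
#'
#' @param positions_m numeric matrix (n x 3) in metres.
#' @param path file path.
#' @return `read_positions()` returns the matrix in metres.
#' @export
write_positions <- function(positions_m, path) {
  df <- data.frame(x_um = positions_m[, 1] / UM,
                   y_um = positions_m[, 2] / UM,
                   z_um = positions_m[, 3] / UM)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("x_um", "y_um", "z_um") %in% names(df)))
    stop_bad_arg("positions file must have columns x_um, y_um, z_um")
  unname(as.matrix(df[, c("x_um", "y_um", "z_um")])) * UM
}
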