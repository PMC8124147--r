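#' Fast gridded superposition (FFT particle-mesh)
#'
#' Approximates [superpose()] on a regular 3D grid in near-linear time:
#' source strengths are spread onto the grid by cloud-in-cell (trilinear)
#' weights, the clamped kernel is applied by zero-padded FFT convolution,
#' and the mesh error is removed exactly within `correction_cells` grid
#' cells of every source (mesh image contributions are subtracted and the
#' true clamped kernel added back). With at least two nodes per clamp
#' radius and the default correction window the result agrees with the
#' direct sum to within 0.5% maximum relative error.
#'
#' Falls back to the direct sum (with a warning) when the grid cannot
#' support the mesh: fewer than four nodes on an axis, or grid spacing
#' coarser than the clamp radius.
#'
#' @inheritParams superpose
#' @param correction_cells half-width of the exact near-field window, in
#'   grid cells.
#' @return a [temperature_field()] of rises in K.
#' @export
fast_field <- function(sources, kappa_w_mk, grid, baseline_c = 37,
                       correction_cells = 8L) {
  stopifnot(inherits(sources, "heat_source_set"), inherits(grid, "field_grid"))
  dims <- grid_dims(grid)
  if (nrow(sources$positions_m) == 0L)
    return(temperature_field(grid, array(0, dims), baseline_c))
  clamp <- sources$clamp_radius_m
  h <- vapply(list(grid$x, grid$y, grid$z),
              function(ax) if (length(ax) > 1) ax[2] - ax[1] else 0, numeric(1))
  regular <- all(vapply(list(grid$x, grid$y, grid$z), function(ax) {
    length(ax) < 3 || max(abs(diff(diff(ax)))) < 1e-9 * (ax[2] - ax[1])
  }, logical(1)))
  if (any(dims < 4L) || !regular || max(h) > clamp) {
    warning("grid cannot support the particle-mesh path ",
            "(needs >= 4 nodes per axis, regular spacing <= clamp radius); ",
            "falling back to the direct sum", call. = FALSE)
    return(superpose(sources, kappa_w_mk, grid, baseline_c))
  }
  pos <- sources$positions_m
  inside <- pos[, 1] >= grid$x[1] & pos[, 1] <= grid$x[dims[1]] &
    pos[, 2] >= grid$y[1] & pos[, 2] <= grid$y[dims[2]] &
    pos[, 3] >= grid$z[1] & pos[, 3] <= grid$z[dims[3]]
  if (!all(inside))
    stop_bad_arg("fast_field requires all sources inside the grid; ",
                 sum(!inside), " source(s) outside")

  # cloud-in-cell deposition
  W <- array(0, dims)
  fx <- (pos[, 1] - grid$x[1]) / h[1]
  fy <- (pos[, 2] - grid$y[1]) / h[2]
  fz <- (pos[, 3] - grid$z[1]) / h[3]
  ix <- pmin(pmax(floor(fx), 0), dims[1] - 2); tx <- fx - ix
  iy <- pmin(pmax(floor(fy), 0), dims[2] - 2); ty <- fy - iy
  iz <- pmin(pmax(floor(fz), 0), dims[3] - 2); tz <- fz - iz
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- sources$strength_w *
      (if (cx) tx else 1 - tx) * (if (cy) ty else 1 - ty) *
      (if (cz) tz else 1 - tz)
    idx <- cbind(ix + cx + 1, iy + cy + 1, iz + cz + 1)
    # accumulate duplicates
    lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
    acc <- rowsum(w, lin)
    W[as.integer(rownames(acc))] <- W[as.integer(rownames(acc))] + acc[, 1]
  }

  # zero-padded FFT convolution with the clamped kernel
  pd <- 2L * dims
  Wp <- array(0, pd)
  Wp[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- W
  off <- function(n2, n, hh) {
    i <- 0:(n2 - 1)
    ifelse(i <= n, i, i - n2) * hh
  }
  ox <- off(pd[1], dims[1], h[1])
  oy <- off(pd[2], dims[2], h[2])
  oz <- off(pd[3], dims[3], h[3])
  R2 <- outer(outer(ox^2, oy^2, `+`), oz^2, `+`)
  K <- 1 / (4 * pi * kappa_w_mk * pmax(sqrt(R2), clamp))
  v <- Re(fft(fft(Wp) * fft(K), inverse = TRUE)) / prod(pd)
  v <- v[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
  v <- array(v, dims)

  # exact near-field correction (in place)
  vv <- as.vector(v)
  .cpp_cic_correct(vv, grid$x, grid$y, grid$z, pos, sources$strength_w,
                   clamp, kappa_w_mk, as.integer(correction_cells))
  vv <- pmax(vv, 0)  # guard against negative round-off far from sources
  temperature_field(grid, array(vv, dims), baseline_c)
}

#' @importFrom stats fft
NULL
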