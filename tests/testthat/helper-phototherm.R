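# Shared fixtures: the worked gold-nanosphere scenario and small oracles.

# printed parameter set of the worked example
gold_params <- list(
  radius_nm = 20,
  sigma_abs_nm2 = 4292.98,
  I_wcm2 = 15,
  kappa = 0.55,
  Qa = 3.4,
  Qs_prime = 0.27,
  fv = 5.6e-6,
  mu_a_m = 32.26,
  mu_s_m = 1.3,
  cell_spacing_um = 50,
  cell_radius_um = 10
)

# pure-R direct superposition, the independent oracle for the compiled path
r_direct_sum <- function(points, src, strength, clamp, kappa) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt((points[i, 1] - src[, 1])^2 + (points[i, 2] - src[, 2])^2 +
                (points[i, 3] - src[, 3])^2)
    sum(strength / pmax(d, clamp)) / (4 * pi * kappa)
  }, numeric(1))
}

# cubic grid helper (metres)
cube_grid <- function(half, n) {
  ax <- seq(-half, half, length.out = n)
  field_grid(ax, ax, ax)
}

# small absorbing-particle table with constant optical constants
flat_table <- function(n = 0.5, k = 2.0, n_medium = 1.33) {
  optical_constants_table(c(300, 900), c(n, n), c(k, k), n_medium)
}
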