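test_that("single-particle temperature rise follows the clamped kernel", {
  p <- gold_params
  # closed form at the particle surface:
  # sigma I / (4 pi kappa R) = 4292.98e-18 * 15e4 / (4 pi 0.55 20e-9)
  surf <- p$sigma_abs_nm2 * 1e-18 * p$I_wcm2 * 1e4 /
    (4 * pi * p$kappa * p$radius_nm * 1e-9)
  expect_equal(surf, 4.658516e-3, tolerance = 1e-6)
  got <- single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa, p$radius_nm,
                            20e-9)
  expect_equal(got, surf)
  # constant inside the particle
  expect_equal(single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa,
                                  p$radius_nm, c(0, 5e-9, 19e-9)),
               rep(surf, 3))
  # 1/r outside: half the surface value at two radii
  expect_equal(single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa,
                                  p$radius_nm, 40e-9), surf / 2)
  # accepts points as a matrix
  expect_equal(single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa,
                                  p$radius_nm, cbind(30e-9, 0, 0)),
               single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa,
                                  p$radius_nm, 30e-9))
  expect_error(single_particle_dT(1, 1, 0, 20, 1e-9), "> 0")
})

test_that("compiled superposition agrees with a pure-R oracle", {
  set.seed(99)
  src <- matrix(runif(60, -1e-6, 1e-6), ncol = 3)
  w <- runif(20, 0.5, 2) * 1e-10
  g <- cube_grid(2e-6, 7)
  sources <- heat_source_set(src, w, 50e-9)
  fld <- superpose(sources, 0.55, g)
  pts <- grid_points(g)
  expect_equal(as.vector(fld$values),
               r_direct_sum(pts, src, w, 50e-9, 0.55), tolerance = 1e-12)
  expect_equal(superpose_at(sources, 0.55, pts),
               as.vector(fld$values), tolerance = 1e-12)
})

test_that("superposition is linear and reduces to the single-source form", {
  p <- gold_params
  P <- p$sigma_abs_nm2 * 1e-18 * p$I_wcm2 * 1e4
  clamp <- p$radius_nm * 1e-9
  g <- cube_grid(500e-9, 9)
  one <- superpose(heat_source_set(matrix(0, 1, 3), P, clamp), p$kappa, g)
  expect_equal(as.vector(one$values),
               single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa,
                                  p$radius_nm, grid_points(g)))
  # linearity: two sources = sum of the single-source fields
  s1 <- matrix(c(-2e-7, 0, 0), 1); s2 <- matrix(c(2e-7, 1e-7, 0), 1)
  f1 <- superpose(heat_source_set(s1, P, clamp), p$kappa, g)
  f2 <- superpose(heat_source_set(s2, P, clamp), p$kappa, g)
  f12 <- superpose(heat_source_set(rbind(s1, s2), P, clamp), p$kappa, g)
  expect_equal(f12$values, f1$values + f2$values, tolerance = 1e-12)
  # empty set: zero field, not an error
  z <- superpose(heat_source_set(matrix(0, 0, 3), numeric(0), clamp),
                 p$kappa, g)
  expect_true(all(z$values == 0))
})

test_that("temperature rise scales exactly with intensity", {
  p <- gold_params
  g <- cube_grid(1e-6, 7)
  set.seed(3)
  src <- matrix(runif(30, -5e-7, 5e-7), ncol = 3)
  mk <- function(I) superpose(heat_source_set(
    src, p$sigma_abs_nm2 * 1e-18 * I * 1e4, 2e-8), p$kappa, g)
  expect_equal(mk(30)$values, 2 * mk(15)$values, tolerance = 1e-12)
})

test_that("far field of a compact source set approaches a point source", {
  set.seed(17)
  src <- matrix(runif(150, -1e-5, 1e-5), ncol = 3)   # diameter ~ 2e-5 m
  w <- runif(50, 0.5, 1.5) * 1e-8
  sources <- heat_source_set(src, w, 1e-6)
  r_far <- 10 * 2e-5  # ten source-set diameters
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1 / sqrt(2), 0, 1 / sqrt(2)))
  dT <- superpose_at(sources, 0.55, dirs * r_far)
  expect_equal(dT, rep(sum(w) / (4 * pi * 0.55 * r_far), 3),
               tolerance = 0.02)
})

test_that("exact cell field reduces correctly and matches its far field", {
  p <- gold_params
  cs <- cell_spec(2, spacing_nm = 500)  # small test cell, 2 um
  lat <- particle_lattice(cs$radius_um, cs$spacing_nm)
  g <- cube_grid(5e-6, 11)
  fe <- cell_field_exact(matrix(0, 1, 3), cs, particle_spec(p$radius_nm),
                         p$sigma_abs_nm2, p$I_wcm2, p$kappa, g)
  # one cell, one particle at the centre reduces to the single-particle form
  one <- cell_spec(0.01, spacing_nm = 500)  # lattice = centre only
  f1 <- cell_field_exact(matrix(0, 1, 3), one, particle_spec(p$radius_nm),
                         p$sigma_abs_nm2, p$I_wcm2, p$kappa, g)
  expect_equal(as.vector(f1$values),
               single_particle_dT(p$sigma_abs_nm2, p$I_wcm2, p$kappa,
                                  p$radius_nm, grid_points(g)))
  # two cells = sum of two shifted one-cell fields
  ctrs <- rbind(c(-3e-6, 0, 0), c(3e-6, 0, 0))
  f2 <- cell_field_exact(ctrs, cs, particle_spec(p$radius_nm),
                         p$sigma_abs_nm2, p$I_wcm2, p$kappa, g)
  fa <- cell_field_exact(ctrs[1, , drop = FALSE], cs,
                         particle_spec(p$radius_nm), p$sigma_abs_nm2,
                         p$I_wcm2, p$kappa, g)
  fb <- cell_field_exact(ctrs[2, , drop = FALSE], cs,
                         particle_spec(p$radius_nm), p$sigma_abs_nm2,
                         p$I_wcm2, p$kappa, g)
  expect_equal(f2$values, fa$values + fb$values, tolerance = 1e-12)
  # beyond 10 cell radii the cell acts as one point source of the total power
  P <- p$sigma_abs_nm2 * 1e-18 * p$I_wcm2 * 1e4
  far <- superpose_at(heat_source_set(lat, P, p$radius_nm * 1e-9), p$kappa,
                      cbind(10 * cs$radius_um * 1e-6, 0, 0))
  expect_equal(far, nrow(lat) * P / (4 * pi * p$kappa * 10 * cs$radius_um * 1e-6),
               tolerance = 0.01)
})

test_that("coarse per-cell field matches the exact field outside cells only", {
  p <- gold_params
  cs <- cell_spec(p$cell_radius_um, n_particles = 2000)
  lat <- particle_lattice(cs$radius_um, cs$spacing_nm)
  g <- field_grid(seq(-30e-6, 30e-6, length.out = 61), 0,
                  seq(-30e-6, 30e-6, length.out = 61))
  fe <- cell_field_exact(matrix(0, 1, 3), cs, particle_spec(p$radius_nm),
                         p$sigma_abs_nm2, p$I_wcm2, p$kappa, g)
  fc <- cell_field_coarse(matrix(0, 1, 3), nrow(lat), p$sigma_abs_nm2,
                          p$I_wcm2, p$kappa, cs$radius_um, g)
  pts <- grid_points(g)
  r <- sqrt(rowSums(pts^2))
  dif <- as.vector(fe$values) - as.vector(fc$values)
  outside <- r > cs$radius_um * 1e-6
  # nearly identical outside, much larger (positive) mismatch at the centre
  expect_lt(max(abs(dif[outside])), 0.02 * max(abs(dif)))
  ctr <- which.min(r)
  expect_gt(as.vector(fe$values)[ctr], as.vector(fc$values)[ctr])
})

test_that("tissue sources honour the beam mask, depth attenuation and fv", {
  p <- gold_params
  tis <- tissue_spec(radius_mm = 0.3, depth_mm = 0.3)
  comp <- composite_coefficients(
    medium_optics(p$mu_a_m, p$mu_s_m),
    nanoparticle_attenuation(p$fv, p$Qa, p$Qs_prime, p$radius_nm), p$fv)
  src <- tissue_sources(tis, beam_spec("full", 15), comp,
                        particle_spec(p$radius_nm), p$sigma_abs_nm2)
  expect_equal(nrow(src$positions_m), nrow(cell_lattice(tis)))
  # strengths follow Beer attenuation at each source depth
  nnp <- particles_per_cell(p$fv, p$cell_spacing_um, p$radius_nm)
  expect_equal(src$strength_w,
               nnp * p$sigma_abs_nm2 * 1e-18 * 1e4 *
                 intensity_at_depth(15, comp, src$positions_m[, 3] / 1e-3),
               tolerance = 1e-12)
  # a spot beam with tiny radius lights only on-axis cells
  spot <- tissue_sources(tis, beam_spec("spot", 15, RL_mm = 0.01), comp,
                         particle_spec(p$radius_nm), p$sigma_abs_nm2)
  expect_true(all(abs(spot$positions_m[, 1:2]) < 1e-12))
  # fv = 0: no sources, zero field
  tis0 <- tissue_spec(radius_mm = 0.3, depth_mm = 0.3, fv = 0)
  f0 <- tissue_field(tis0, beam_spec("full", 15), comp,
                     particle_spec(p$radius_nm), p$sigma_abs_nm2,
                     tumor_grid(tis0, n = 9L))
  expect_true(all(f0$values == 0))
})

test_that("absolute temperature adds the baseline and keeps ordering", {
  g <- cube_grid(1e-3, 5)
  f <- temperature_field(g, array(seq(0, 15, length.out = 125), c(5, 5, 5)),
                         baseline_c = 37)
  a <- absolute_temperature(f)
  expect_equal(max(a$values), 52)
  expect_equal(min(a$values), 37)
  expect_equal(order(a$values), order(f$values))
  expect_true(a$absolute)
  expect_identical(absolute_temperature(a), a)
})

test_that("fields survive a CSV round trip", {
  g <- field_grid(seq(-1e-3, 1e-3, length.out = 5),
                  seq(-1e-3, 1e-3, length.out = 4),
                  seq(0, 2e-3, length.out = 6))
  f <- temperature_field(g, array(runif(120), c(5, 4, 6)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  f2 <- read_field_csv(path)
  expect_equal(f2$values, f$values, tolerance = 1e-6)
  expect_equal(f2$grid$x, f$grid$x, tolerance = 1e-9)
})
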