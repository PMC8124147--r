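test_that("the damage integral inverts against the minimum damage time", {
  p <- arrhenius_params()
  expect_equal(damage_rate(330, 0, p), 0)
  t1 <- min_damage_time(330, p)
  expect_equal(damage_rate(330, t1, p), 1, tolerance = 1e-12)
  # strictly decreasing time with temperature
  Ts <- seq(315, 350, by = 5)
  expect_true(all(diff(min_damage_time(Ts, p)) < 0))
  expect_error(damage_rate(-1, 1, p), "> 0")
  expect_error(min_damage_time(0, p), "> 0")
  expect_error(arrhenius_params(A_per_s = -1), "> 0")
})

test_that("damage accumulates monotonically in temperature and time", {
  p <- arrhenius_params()
  Ts <- seq(310, 350, by = 2.5)
  ts <- seq(1, 600, length.out = 9)
  om <- outer(Ts, ts, function(T, t) damage_rate(T, t, p))
  expect_true(all(diff(om) > 0))        # in T at fixed t
  expect_true(all(t(diff(t(om))) > 0))  # in t at fixed T
})

test_that("default coefficients reproduce a high-precision evaluation", {
  # frozen from an independent 40-digit evaluation of
  # exp(Ea/R (1/330 - 1/335)) and 1/(A exp(-Ea/(R 330)))
  p <- arrhenius_params()
  expect_equal(min_damage_time(330, p) / min_damage_time(335, p),
               30.45768636554500, tolerance = 1e-10)
  expect_equal(min_damage_time(330, p), 8.247670342773843, tolerance = 1e-10)
})

test_that("overheating volume integrates the hot healthy region", {
  tis <- tissue_spec(radius_mm = 1, depth_mm = 1)
  n <- 41
  g <- tumor_grid(tis, n = n)
  mask <- tumor_mask(g, tis)
  # cold everywhere: zero
  cold <- temperature_field(g, array(0, rep(n, 3)), baseline_c = 37)
  expect_equal(overheating_volume(cold, mask), 0)
  # uniformly hot: the whole healthy part of the domain
  hot <- temperature_field(g, array(60, rep(n, 3)), baseline_c = 37,
                           absolute = TRUE)
  vol_domain <- diff(range(g$x)) * diff(range(g$y)) * diff(range(g$z)) / 1e-9
  got <- overheating_volume(hot, mask)
  vol_tumor <- pi * 1^2 * 1  # mm^3
  expect_equal(got + vol_tumor, vol_domain, tolerance = 0.05)
  # synthetic hot ball of known radius centred in the healthy region
  ctr <- c(0, 0, -0.25e-3)  # above the tumor face
  rb <- 0.2e-3
  pts <- grid_points(g)
  rr <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
               (pts[, 3] - ctr[3])^2)
  vals <- array(ifelse(rr < rb, 60, 37), rep(n, 3))
  ball <- temperature_field(g, vals, 37, absolute = TRUE)
  vol_ball <- 4 / 3 * pi * (rb / 1e-3)^3
  h_mm <- diff(g$z[1:2]) / 1e-3
  # within one voxel layer of the analytic ball volume
  shell <- 4 * pi * (rb / 1e-3)^2 * h_mm
  expect_lt(abs(overheating_volume(ball, mask) - vol_ball), shell)
  # monotone non-increasing in the threshold
  f55 <- overheating_volume(ball, mask, threshold_c = 55)
  expect_lte(f55, overheating_volume(ball, mask, threshold_c = 52))
  expect_error(overheating_volume(ball, tumor_mask(tumor_grid(tis, n = 11L),
                                                   tis)), "different grids")
})

test_that("reference temperatures interpolate trilinearly", {
  g <- field_grid(seq(0, 1e-3, length.out = 5), seq(0, 1e-3, length.out = 5),
                  seq(0, 1e-3, length.out = 5))
  # uniform field: every point reads the same value
  u <- temperature_field(g, array(42, c(5, 5, 5)), 37, absolute = TRUE)
  pts <- rbind(A = c(2e-4, 3e-4, 9e-4), B = c(0, 0, 0))
  expect_equal(unname(reference_temperatures(u, pts)), c(42, 42))
  # a node reads its exact value
  set.seed(5)
  v <- array(runif(125, 30, 60), c(5, 5, 5))
  f <- temperature_field(g, v, 37, absolute = TRUE)
  expect_equal(unname(reference_temperatures(f, rbind(c(g$x[2], g$y[3],
                                                        g$z[4])))),
               v[2, 3, 4])
  # interpolant bounded by the surrounding 8 node values
  q <- c(g$x[2] + 0.4 * diff(g$x[2:3]), g$y[3] + 0.7 * diff(g$y[3:4]),
         g$z[1] + 0.2 * diff(g$z[1:2]))
  got <- unname(reference_temperatures(f, rbind(q)))
  corner <- v[2:3, 3:4, 1:2]
  expect_gte(got, min(corner))
  expect_lte(got, max(corner))
  expect_error(reference_temperatures(f, rbind(c(2e-3, 0, 0))), "outside")
})

test_that("reference point defaults sit on the tumor boundary", {
  tis <- tissue_spec(radius_mm = 2, depth_mm = 2)
  pts <- reference_points(tis)
  expect_equal(rownames(pts), c("B", "C", "D"))
  expect_equal(unname(pts["B", ]), c(2e-3, 0, 1e-3))  # side, mid-depth
  expect_equal(unname(pts["C", ]), c(0, 0, 2e-3))     # bottom centre
  expect_equal(unname(pts["D", ]), c(2e-3, 0, 0))     # top edge
})

test_that("isotherms follow a radially symmetric monotone field", {
  # synthetic single-source field: dT = c / max(r, r0), exactly radial
  g <- field_grid(seq(-1e-3, 1e-3, length.out = 81), 0,
                  seq(-1e-3, 1e-3, length.out = 81))
  src <- heat_source_set(matrix(0, 1, 3), 1e-4, 5e-5)
  f <- superpose(src, 0.55, g)
  lev <- unname(stats::quantile(f$values, 0.7))
  cont <- isotherm_extract(f, lev)
  expect_gte(length(cont), 1)
  seg <- cont[[1]]
  # contour vertices lie on a circle of the radius implied by the level
  r_expect <- 1e-4 / (4 * pi * 0.55 * lev)
  r_got <- sqrt(seg$x_mm^2 + seg$z_mm^2) * 1e-3
  expect_equal(max(abs(r_got - r_expect)) / r_expect, 0, tolerance = 0.02)
  # nesting: a higher level encloses a smaller region
  lev2 <- unname(stats::quantile(f$values, 0.9))
  cont2 <- isotherm_extract(f, lev2)
  expect_lt(max(abs(cont2[[1]]$x_mm)), max(abs(seg$x_mm)))
  # out-of-range level: empty
  expect_equal(isotherm_extract(f, 10 * max(f$values)), list())
})

test_that("axial isotherm depth finds the deepest crossing", {
  g <- field_grid(0, 0, seq(0, 2e-3, length.out = 21))
  prof <- seq(50, 30, length.out = 21)  # cooling with depth
  f <- temperature_field(g, array(prof, c(1, 1, 21)), 37, absolute = TRUE)
  # level 40 is crossed exactly half way down
  expect_equal(axial_isotherm_depth(f, 40), 1, tolerance = 1e-9)
  expect_true(is.na(axial_isotherm_depth(f, 60)))
  expect_equal(axial_isotherm_depth(f, 20), 2)  # never drops below: full depth
})

test_that("tumor uniformity is zero for a flat field", {
  tis <- tissue_spec(radius_mm = 1, depth_mm = 1)
  g <- tumor_grid(tis, n = 21L)
  mask <- tumor_mask(g, tis)
  u <- temperature_field(g, array(45, rep(21, 3)), 37, absolute = TRUE)
  expect_equal(uniformity(u, mask), 0)
  v <- temperature_field(g, array(seq(40, 50, length.out = 21^3),
                                  rep(21, 3)), 37, absolute = TRUE)
  expect_gt(uniformity(v, mask), 0)
})
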