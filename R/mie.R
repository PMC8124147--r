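#' Nanoparticle specification
#'
#' @param radius_nm particle radius in nm, `> 0`.
#' @param material material identifier; `"Au"` resolves to the vendored gold
#'   table via [gold_optical_constants()].
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(radius_nm = 20, material = "Au") {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1L ||
      !is.finite(radius_nm) || radius_nm <= 0)
    stop_bad_arg("radius_nm must be a single positive number")
  structure(list(radius_nm = as.numeric(radius_nm),
                 material = as.character(material)),
            class = "particle_spec")
}

# Mie series for one (m, x): scattering coefficients via the
# logarithmic-derivative downward recurrence (Bohren & Huffman), with the
# standard truncation nstop = x + 4 x^(1/3) + 2.
mie_series <- function(m, x) {
  if (!is.finite(x) || x <= 0) stop_bad_arg("size parameter must be > 0")
  if (!is.finite(Re(m)) || !is.finite(Im(m)))
    stop_bad_arg("non-finite refractive index")
  nstop <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- max(nstop, ceiling(Mod(m * x))) + 16L
  mx <- m * x
  # downward recurrence for the logarithmic derivative D_n(mx)
  D <- complex(length.out = nmx + 1L)
  for (i in nmx:1) {
    D[i] <- i / mx - 1 / (D[i + 1L] + i / mx)
  }
  n <- seq_len(nstop)
  # Riccati-Bessel psi, chi by upward recurrence (real argument x)
  psi <- numeric(nstop); chi <- numeric(nstop)
  psi_m1 <- cos(x); psi_0 <- sin(x)     # psi_{-1}, psi_0
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  pm2 <- psi_m1; pm1 <- psi_0; cm2 <- chi_m1; cm1 <- chi_0
  for (i in n) {
    psi[i] <- (2 * i - 1) / x * pm1 - pm2
    chi[i] <- (2 * i - 1) / x * cm1 - cm2
    pm2 <- pm1; pm1 <- psi[i]
    cm2 <- cm1; cm1 <- chi[i]
  }
  xi <- complex(real = psi, imaginary = -chi)
  psi_prev <- c(psi_0, psi[-nstop])
  xi_prev <- complex(real = psi_prev, imaginary = -c(chi_0, chi[-nstop]))
  Dn <- D[n + 1L]  # D_n, n = 1..nstop (D[1] is D_0)
  ta <- Dn / m + n / x
  tb <- Dn * m + n / x
  a <- (ta * psi - psi_prev) / (ta * xi - xi_prev)
  b <- (tb * psi - psi_prev) / (tb * xi - xi_prev)
  list(a = a, b = b, n = n, x = x)
}

#' Mie efficiencies of a single sphere
#'
#' Computes the extinction, scattering and absorption efficiency factors and
#' the scattering anisotropy `g` for a homogeneous sphere in a non-absorbing
#' medium, from the tabulated particle optical constants.
#'
#' @param particle a [particle_spec()].
#' @param wavelength_nm vacuum wavelength in nm (inside the table range).
#' @param table an [optical_constants_table()]; defaults to the gold table
#'   in a medium of index 1.40.
#' @return An object of class `mie_efficiencies` with elements `Qext`,
#'   `Qsca`, `Qabs`, `g`, `wavelength_nm`, `size_parameter`, `m`.
#' @examples
#' eff <- mie_efficiencies(particle_spec(20), 532)
#' absorption_cross_section(eff, particle_spec(20))
#' @export
mie_efficiencies <- function(particle, wavelength_nm,
                             table = gold_optical_constants()) {
  stopifnot(inherits(particle, "particle_spec"))
  if (length(wavelength_nm) != 1L)
    stop_bad_arg("wavelength_nm must be a single wavelength; ",
                 "use plasmon_peak() for scans")
  np <- refractive_index(table, wavelength_nm)  # range-checked there
  m <- np / table$n_medium
  x <- 2 * pi * table$n_medium * particle$radius_nm / wavelength_nm
  s <- mie_series(m, x)
  n <- s$n; a <- s$a; b <- s$b
  Qext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  Qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  Qabs <- Qext - Qsca
  nn <- n[-length(n)]
  gsum <- sum(nn * (nn + 2) / (nn + 1) *
                Re(a[-length(a)] * Conj(a[-1]) + b[-length(b)] * Conj(b[-1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- 4 / (x^2 * Qsca) * gsum
  structure(list(Qext = Qext, Qsca = Qsca, Qabs = Qabs, g = g,
                 wavelength_nm = wavelength_nm, size_parameter = x, m = m),
            class = "mie_efficiencies")
}

#' Absorption cross-section of a sphere
#'
#' \eqn{\sigma_{abs} = Q_{abs} \pi R^2} in nm².
#'
#' @param eff a `mie_efficiencies` object (or a bare `Qabs` value).
#' @param particle a [particle_spec()].
#' @return cross-section in nm².
#' @export
absorption_cross_section <- function(eff, particle) {
  Qabs <- if (inherits(eff, "mie_efficiencies")) eff$Qabs else as.numeric(eff)
  if (Qabs < 0) stop_bad_arg("Qabs must be >= 0")
  Qabs * pi * particle$radius_nm^2
}

#' Reduced scattering efficiency
#'
#' \eqn{Q_s' = Q_{sca} (1 - g)}: the scattering efficiency discounted by the
#' forward-scattering anisotropy, the single-particle analogue of the
#' reduced scattering coefficient.
#'
#' @param eff a `mie_efficiencies` object.
#' @return dimensionless `Qs'`.
#' @export
reduced_scattering_efficiency <- function(eff) {
  stopifnot(inherits(eff, "mie_efficiencies"))
  eff$Qsca * (1 - eff$g)
}

#' Locate the plasmon absorption peak
#'
#' Scans the absorption cross-section over a wavelength grid and returns the
#' grid wavelength maximizing it. Ties break toward the shorter wavelength.
#'
#' @inheritParams mie_efficiencies
#' @param lambda_range length-2 numeric, scan interval in nm (inside the
#'   table coverage).
#' @param lambda_step scan step in nm, `> 0`.
#' @return A list of class `plasmon_peak`: `wavelength_nm` (the peak),
#'   `sigma_abs_nm2` (cross-section there) and `scan` (data.frame of the
#'   whole scan).
#' @export
plasmon_peak <- function(particle, table = gold_optical_constants(),
                         lambda_range = c(400, 700), lambda_step = 1) {
  if (!is.numeric(lambda_step) || lambda_step <= 0)
    stop_bad_arg("lambda_step must be > 0")
  if (length(lambda_range) != 2L || diff(lambda_range) < 0)
    stop_bad_arg("lambda_range must be an increasing length-2 interval")
  grid <- seq(lambda_range[1], lambda_range[2], by = lambda_step)
  if (length(grid) == 0L) stop_bad_arg("empty wavelength scan grid")
  sig <- vapply(grid, function(wl) {
    absorption_cross_section(mie_efficiencies(particle, wl, table), particle)
  }, numeric(1))
  i <- which.max(sig)  # first maximum = shortest wavelength on ties
  structure(list(wavelength_nm = grid[i], sigma_abs_nm2 = sig[i],
                 scan = data.frame(wavelength_nm = grid, sigma_abs_nm2 = sig)),
            class = "plasmon_peak")
}

#' @export
print.mie_efficiencies <- function(x, ...) {
  cat(sprintf(
    "<mie_efficiencies> lambda = %.1f nm, x = %.4f\n  Qext = %.4f  Qsca = %.4f  Qabs = %.4f  g = %.4f\n",
    x$wavelength_nm, x$size_parameter, x$Qext, x$Qsca, x$Qabs, x$g))
  invisible(x)
}

#' @export
print.plasmon_peak <- function(x, ...) {
  cat(sprintf("<plasmon_peak> %.0f nm, sigma_abs = %.1f nm^2 (%d-point scan)\n",
              x$wavelength_nm, x$sigma_abs_nm2, nrow(x$scan)))
  invisible(x)
}
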