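#' Optical coefficients of the unloaded tissue medium
#'
#' @param mu_a_cm absorption coefficient in cm^-1, `>= 0`.
#' @param mu_s_prime_cm reduced scattering coefficient in cm^-1, `>= 0`.
#' @return An object of class `medium_optics`.
#' @export
medium_optics <- function(mu_a_cm = 32.26, mu_s_prime_cm = 1.3) {
  if (mu_a_cm < 0 || mu_s_prime_cm < 0)
    stop_bad_arg("attenuation coefficients must be >= 0")
  structure(list(mu_a_cm = as.numeric(mu_a_cm),
                 mu_s_prime_cm = as.numeric(mu_s_prime_cm)),
            class = "medium_optics")
}

#' Nanoparticle contribution to tissue attenuation
#'
#' For monodisperse spheres at volume fraction `fv` the added coefficients
#' are \eqn{\mu_{a,n} = 0.75 f_v Q_a / R} and
#' \eqn{\mu_{s,n}' = 0.75 f_v Q_s' / R} (number density times cross-section,
#' written through the efficiency factors).
#'
#' @param fv nanoparticle volume fraction, `>= 0`.
#' @param Qa absorption efficiency factor.
#' @param Qs_prime reduced scattering efficiency factor.
#' @param radius_nm particle radius in nm, `> 0`.
#' @return list with `mu_a_n_cm` and `mu_s_n_prime_cm` (cm^-1).
#' @examples
#' nanoparticle_attenuation(5.6e-6, 3.4, 0.27, 20)  # ~7.14 and ~0.567 cm^-1
#' @export
nanoparticle_attenuation <- function(fv, Qa, Qs_prime, radius_nm) {
  if (!is.numeric(fv) || fv < 0) stop_bad_arg("fv must be >= 0")
  if (radius_nm <= 0) stop_bad_arg("radius_nm must be > 0")
  r_cm <- radius_nm * NM / CM
  list(mu_a_n_cm = 0.75 * fv * Qa / r_cm,
       mu_s_n_prime_cm = 0.75 * fv * Qs_prime / r_cm)
}

#' Composite tumor attenuation coefficients
#'
#' Component-wise sum of the medium and nanoparticle contributions:
#' \eqn{\mu_a = \mu_{a,m} + \mu_{a,n}}, \eqn{\mu_s' = \mu_{s,m}' +
#' \mu_{s,n}'}.
#'
#' @param medium a [medium_optics()].
#' @param np_att result of [nanoparticle_attenuation()].
#' @param fv nanoparticle volume fraction (bookkeeping field), in `[0, 1)`.
#' @return An object of class `composite_optics` with fields `mu_a_cm`,
#'   `mu_s_prime_cm`, `mu_a_n_cm`, `mu_s_n_prime_cm`, `fv`.
#' @export
composite_coefficients <- function(medium, np_att, fv = 0) {
  stopifnot(inherits(medium, "medium_optics"))
  if (!all(c("mu_a_n_cm", "mu_s_n_prime_cm") %in% names(np_att)))
    stop_bad_arg("np_att must come from nanoparticle_attenuation()")
  if (fv < 0 || fv >= 1) stop_bad_arg("fv must be in [0, 1)")
  structure(list(
    mu_a_cm = medium$mu_a_cm + np_att$mu_a_n_cm,
    mu_s_prime_cm = medium$mu_s_prime_cm + np_att$mu_s_n_prime_cm,
    mu_a_n_cm = np_att$mu_a_n_cm,
    mu_s_n_prime_cm = np_att$mu_s_n_prime_cm,
    fv = as.numeric(fv)), class = "composite_optics")
}

#' Total attenuation coefficient
#'
#' @param optics a `composite_optics` (or `medium_optics`) object.
#' @return \eqn{\mu_a + \mu_s'} in cm^-1.
#' @export
total_attenuation <- function(optics) {
  if (inherits(optics, "medium_optics"))
    return(optics$mu_a_cm + optics$mu_s_prime_cm)
  stopifnot(inherits(optics, "composite_optics"))
  optics$mu_a_cm + optics$mu_s_prime_cm
}

#' Beer-Lambert intensity at depth
#'
#' Collimated-beam exponential attenuation
#' \eqn{I(z) = I_0 e^{-(\mu_a + \mu_s') z}}, with depth measured from the
#' illuminated surface of the nanoparticle-loaded region.
#'
#' @param I0_wcm2 surface intensity in W/cm^2.
#' @param optics a `composite_optics` (or `medium_optics`) object.
#' @param z_mm depth(s) in mm, `>= 0`.
#' @return intensity in W/cm^2 at each depth.
#' @export
intensity_at_depth <- function(I0_wcm2, optics, z_mm) {
  if (any(z_mm < 0)) stop_bad_arg("depth z_mm must be >= 0")
  mu_t <- total_attenuation(optics)           # cm^-1
  I0_wcm2 * exp(-mu_t * z_mm * MM / CM)
}

#' @export
print.composite_optics <- function(x, ...) {
  cat(sprintf(
    "<composite_optics> mu_a = %.3f cm^-1 (np %.3f), mu_s' = %.3f cm^-1 (np %.3f), fv = %g\n",
    x$mu_a_cm, x$mu_a_n_cm, x$mu_s_prime_cm, x$mu_s_n_prime_cm, x$fv))
  invisible(x)
}
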