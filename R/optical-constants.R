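#' Tabulated complex refractive index of a particle material
#'
#' Container for wavelength-indexed optical constants of the nanoparticle
#' material together with the (real) refractive index of the surrounding
#' medium. Values between tabulated wavelengths are obtained by linear
#' interpolation of the real and imaginary parts separately.
#'
#' @param wavelength_nm numeric, strictly increasing wavelengths in nm.
#' @param n numeric, real part of the particle refractive index.
#' @param k numeric, imaginary part (extinction coefficient), `>= 0`.
#' @param n_medium real refractive index of the host medium, `>= 1`.
#'   Default 1.40, a standard value for soft tissue; use 1.33 for water.
#' @return An object of class `optical_constants_table`.
#' @seealso [gold_optical_constants()] for the vendored gold table.
#' @export
optical_constants_table <- function(wavelength_nm, n, k, n_medium = 1.40) {
  wavelength_nm <- as.numeric(wavelength_nm)
  n <- as.numeric(n)
  k <- as.numeric(k)
  if (length(wavelength_nm) < 2L)
    stop_bad_arg("need at least two tabulated wavelengths")
  if (length(n) != length(wavelength_nm) || length(k) != length(wavelength_nm))
    stop_bad_arg("wavelength_nm, n and k must have equal length")
  if (!all(is.finite(wavelength_nm)) || !all(is.finite(n)) || !all(is.finite(k)))
    stop_bad_arg("optical constants must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop_bad_arg("wavelengths must be strictly increasing")
  if (any(k < 0))
    stop_bad_arg("imaginary part k of the refractive index must be >= 0")
  if (!is.numeric(n_medium) || length(n_medium) != 1L || n_medium < 1)
    stop_bad_arg("n_medium must be a single number >= 1")
  structure(
    list(wavelength_nm = wavelength_nm, n = n, k = k,
         n_medium = as.numeric(n_medium)),
    class = "optical_constants_table"
  )
}

#' Gold optical constants (Johnson & Christy 1972)
#'
#' Loads the vendored gold n,k table transcribed from the Johnson & Christy
#' (1972) bulk-film measurements, the de-facto standard dataset for
#' plasmonics. No size-dependent (electron mean-free-path) correction is
#' applied. Any other material table in the same three-column format
#' (`wavelength_nm`, `n`, `k`, tab- or space-separated, `#` comments) can be
#' loaded with `read_optical_constants()`.
#'
#' @inheritParams optical_constants_table
#' @param path optional path to an alternative table file.
#' @return An `optical_constants_table`.
#' @export
gold_optical_constants <- function(n_medium = 1.40, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "au_johnson_christy_1972.tsv",
                        package = "phototherm", mustWork = TRUE)
  read_optical_constants(path, n_medium = n_medium)
}

#' @rdname gold_optical_constants
#' @export
read_optical_constants <- function(path, n_medium = 1.40) {
  tab <- read.table(path, header = TRUE, comment.char = "#")
  need <- c("wavelength_nm", "n", "k")
  if (!all(need %in% names(tab)))
    stop_bad_arg("optical constants file must have columns: ",
                 paste(need, collapse = ", "))
  tab <- tab[order(tab$wavelength_nm), , drop = FALSE]
  optical_constants_table(tab$wavelength_nm, tab$n, tab$k, n_medium = n_medium)
}

#' Interpolated complex refractive index
#'
#' @param table an `optical_constants_table`.
#' @param wavelength_nm wavelengths in nm, inside the tabulated range.
#' @return complex vector of particle refractive indices `n + ik`.
#' @export
refractive_index <- function(table, wavelength_nm) {
  stopifnot(inherits(table, "optical_constants_table"))
  rng <- range(table$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop_bad_arg("wavelength outside tabulated range [",
                 rng[1], ", ", rng[2], "] nm")
  nr <- approx(table$wavelength_nm, table$n, xout = wavelength_nm)$y
  ni <- approx(table$wavelength_nm, table$k, xout = wavelength_nm)$y
  complex(real = nr, imaginary = ni)
}

#' @export
print.optical_constants_table <- function(x, ...) {
  cat(sprintf(
    "<optical_constants_table> %d wavelengths, %.1f-%.1f nm, n_medium = %.3f\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    x$n_medium))
  invisible(x)
}
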