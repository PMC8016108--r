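# Exact unit conversions for the declared unit set. User-facing values are
# GPa / MPa, micrometres / millimetres and degrees; all internal computation
# is SI (Pa, m, rad).

#' Unit conversions
#'
#' Exact conversions between the user-facing units (micrometres, millimetres,
#' GPa, MPa, degrees) and the internal SI units (m, Pa, rad).
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6
#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6
#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3
#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3
#' @rdname units
#' @export
gpa_to_pa <- function(x) x * 1e9
#' @rdname units
#' @export
pa_to_gpa <- function(x) x * 1e-9
#' @rdname units
#' @export
mpa_to_pa <- function(x) x * 1e6
#' @rdname units
#' @export
deg_to_rad <- function(x) x * pi / 180
#' @rdname units
#' @export
rad_to_deg <- function(x) x * 180 / pi

#' Logarithmically spaced grid
#'
#' @param from,to Positive endpoints.
#' @param n Number of points.
#' @return Numeric vector of `n` log-spaced values from `from` to `to`.
#' @export
log_space <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 1)
  if (n == 1) return(sqrt(from * to))
  exp(seq(log(from), log(to), length.out = n))
}
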