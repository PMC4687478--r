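#' Tabulated one-dimensional potential energy curve
#'
#' A potential curve tabulates the energy `E(q)` felt by the migrating
#' hydrogen nucleus as a function of its displacement `q` (angstrom)
#' along the donor-to-acceptor direction. The displacement origin sits
#' at a reference O–H bond length `r0`, and bond lengths follow the
#' collinear-migration convention `R(q) = r0 + q`.
#'
#' The object is a tibble with columns `q` and `energy` plus attributes
#' `r0` (angstrom) and `label` (free-text provenance). Invariants:
#' strictly increasing `q`, at least 5 samples, all energies finite.
#'
#' @param q Displacement samples in angstrom, strictly increasing.
#' @param energy Potential samples in kcal/mol, same length as `q`.
#' @param r0 Reference O–H bond length at `q = 0`, angstrom.
#' @param label Free-text provenance tag.
#' @return A `vibhb_curve` tibble.
#' @examples
#' q <- seq(-0.4, 0.6, 0.05)
#' potential_curve(q, 50 * q^2, r0 = 1.0, label = "toy harmonic")
#' @export
potential_curve <- function(q, energy, r0, label = "") {
  curve <- tibble::tibble(q = as.numeric(q), energy = as.numeric(energy))
  attr(curve, "r0") <- as.numeric(r0)
  attr(curve, "label") <- as.character(label)
  class(curve) <- c("vibhb_curve", class(curve))
  validate_curve(curve)
}

validate_curve <- function(curve) {
  if (!all(c("q", "energy") %in% names(curve))) {
    abort("a potential curve needs `q` and `energy` columns",
          class = "vibhb_format_error")
  }
  if (nrow(curve) < 5L) {
    abort("a potential curve needs at least 5 samples",
          class = "vibhb_format_error")
  }
  if (length(curve$energy) != length(curve$q)) {
    abort("`q` and `energy` must have equal length",
          class = "vibhb_format_error")
  }
  if (anyNA(curve$q) || anyNA(curve$energy) ||
      !all(is.finite(curve$energy)) || !all(is.finite(curve$q))) {
    abort("potential curve contains missing or non-finite values",
          class = "vibhb_format_error")
  }
  if (any(diff(curve$q) <= 0)) {
    abort("`q` must be strictly increasing",
          class = "vibhb_format_error")
  }
  r0 <- attr(curve, "r0")
  if (is.null(r0) || !is.finite(r0)) {
    abort("potential curve needs a finite reference bond length `r0`",
          class = "vibhb_format_error")
  }
  curve
}

#' @rdname potential_curve
#' @param curve A `vibhb_curve`.
#' @export
curve_r0 <- function(curve) attr(curve, "r0")

#' @rdname potential_curve
#' @export
curve_label <- function(curve) attr(curve, "label") %||% ""

#' Map displacement to O-H bond length
#'
#' Applies the collinear-migration convention `R = r0 + q`.
#'
#' @param curve A `vibhb_curve`.
#' @param q Displacements (angstrom); defaults to the curve's samples.
#' @return Bond lengths in angstrom.
#' @export
bond_length <- function(curve, q = curve$q) {
  curve_r0(curve) + q
}

# Cubic-spline interpolant of a curve (exact at the tabulated nodes).
curve_fun <- function(curve) {
  splinefun(curve$q, curve$energy, method = "fmm")
}

#' Resample a curve on a denser uniform grid
#'
#' Cubic-spline resampling over the tabulated span; the interpolant
#' passes through the original nodes exactly and reproduces cubic
#' polynomials to machine precision.
#'
#' @param curve A `vibhb_curve`.
#' @param n_points Number of uniform output samples; at least the
#'   tabulated count.
#' @return A `vibhb_curve` on the denser grid.
#' @export
interpolate_curve <- function(curve, n_points) {
  curve <- validate_curve(curve)
  n_points <- as.integer(n_points)
  if (n_points < 5L) {
    abort("`n_points` must be at least 5", class = "vibhb_parameter_error")
  }
  if (n_points < nrow(curve)) {
    abort("`n_points` must not be below the tabulated sample count",
          class = "vibhb_parameter_error")
  }
  qq <- seq(min(curve$q), max(curve$q), length.out = n_points)
  potential_curve(qq, curve_fun(curve)(qq),
                  r0 = curve_r0(curve), label = curve_label(curve))
}

#' @export
print.vibhb_curve <- function(x, ...) {
  cat(sprintf(
    "<potential curve> %d samples, q in [%g, %g] angstrom, R0 = %g angstrom\n",
    nrow(x), min(x$q), max(x$q), curve_r0(x)
  ))
  if (nzchar(curve_label(x))) cat("label:", curve_label(x), "\n")
  NextMethod()
}
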