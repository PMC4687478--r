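#' Uniform solver grid
#'
#' Defines the uniform grid of displacement values on which the nuclear
#' Hamiltonian is discretised. The solver places hard (Dirichlet) walls
#' one grid spacing outside the first and last node, so the grid should
#' span the full tabulated range of the potential curve.
#'
#' @param q_start,q_end Grid range in angstrom; `q_start < q_end`.
#' @param n_points Number of grid nodes (>= 5; production runs use
#'   around 1000).
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(-0.45, 0.75, 61)
#' grid_spacing(g)
#' @export
grid_spec <- function(q_start, q_end, n_points) {
  stopifnot(is.numeric(q_start), is.numeric(q_end), is.numeric(n_points))
  n_points <- as.integer(n_points)
  if (!is.finite(q_start) || !is.finite(q_end) || q_start >= q_end) {
    abort("grid requires finite q_start < q_end",
          class = "vibhb_parameter_error")
  }
  if (n_points < 5L) {
    abort("grid requires at least 5 points",
          class = "vibhb_parameter_error")
  }
  structure(
    list(q_start = q_start, q_end = q_end, n_points = n_points),
    class = "grid_spec"
  )
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  seq(grid$q_start, grid$q_end, length.out = grid$n_points)
}

#' @rdname grid_spec
#' @export
grid_spacing <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  (grid$q_end - grid$q_start) / (grid$n_points - 1)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> [%g, %g] angstrom, %d points (spacing %.6g)\n",
    x$q_start, x$q_end, x$n_points, grid_spacing(x)
  ))
  invisible(x)
}

# Default production grid over a curve's tabulated span.
default_grid <- function(curve, n_points = 1001L) {
  grid_spec(min(curve$q), max(curve$q), n_points)
}
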