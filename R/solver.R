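#' Solve the 1D nuclear Schroedinger equation on a potential curve
#'
#' Discretises the nuclear Hamiltonian
#' \deqn{H = -\frac{\hbar^2}{2m}\frac{d^2}{dq^2} + V(q)}
#' on a uniform grid and returns the lowest vibrational eigenstates.
#' The kinetic operator is the Colbert–Miller discrete variable
#' representation for a finite interval (sine DVR), which imposes hard
#' Dirichlet walls one grid spacing outside the end nodes — the natural
#' boundary condition for unrelaxed scans that rise steeply at both
#' ends — and is spectrally accurate for smooth potentials. The
#' potential is evaluated on the grid through the curve's cubic-spline
#' interpolant. Energies are referenced to the curve's energy zero (the
#' global minimum for generated curves), not to the ground state.
#'
#' If the ground-state amplitude at either end node exceeds 1e-6 a
#' boundary-leakage warning is raised: the box is too small for the
#' states requested.
#'
#' @param curve A `vibhb_curve`.
#' @param mass `"H"`, `"D"`, a mass in amu, or a [particle_mass()].
#' @param grid A [grid_spec()] within the curve's tabulated span;
#'   default 1001 points over the full span.
#' @param n_states Number of lowest states to return (default 3).
#' @return A `vibhb_spectrum`: eigenvalues `energies` (kcal/mol,
#'   ascending), `wavefunctions` (grid-normalised columns,
#'   `sum(psi^2) * dq = 1`), the grid, mass, and curve metadata.
#' @examples
#' eq <- make_pyp_equilibrium_fixture()
#' sp <- solve_states(eq, "H")
#' tidy(sp)
#' @export
solve_states <- function(curve, mass, grid = NULL, n_states = 3L) {
  solve_impl(curve, mass, grid, n_states, kinetic = kinetic_dvr,
             method = "sine-dvr")
}

#' @describeIn solve_states Independent cross-check solver using the
#'   3-point finite-difference Laplacian (second-order accurate) with
#'   the same boundary convention; used to validate the DVR results.
#' @export
solve_states_fd <- function(curve, mass, grid = NULL, n_states = 3L) {
  solve_impl(curve, mass, grid, n_states, kinetic = kinetic_fd,
             method = "fd3")
}

# Colbert-Miller sine DVR on the open interval (q1 - dq, qn + dq):
# grid nodes are the N-1 interior points of an N-interval box.
kinetic_dvr <- function(n, dq, mass) {
  nbox <- n + 1L
  box_len <- nbox * dq
  pref <- .hbar2 / (2 * mass) * pi^2 / (2 * box_len^2)
  i <- seq_len(n)
  dif <- outer(i, i, `-`)
  sum_ <- outer(i, i, `+`)
  tm <- (-1)^dif *
    (1 / sin(pi * dif / (2 * nbox))^2 - 1 / sin(pi * sum_ / (2 * nbox))^2)
  diag(tm) <- (2 * nbox^2 + 1) / 3 - 1 / sin(pi * i / nbox)^2
  pref * tm
}

# 3-point finite difference with Dirichlet nodes just outside the grid
kinetic_fd <- function(n, dq, mass) {
  pref <- .hbar2 / (2 * mass * dq^2)
  tm <- diag(2, n)
  idx <- seq_len(n - 1L)
  tm[cbind(idx, idx + 1L)] <- -1
  tm[cbind(idx + 1L, idx)] <- -1
  pref * tm
}

solve_impl <- function(curve, mass, grid, n_states, kinetic, method) {
  curve <- validate_curve(curve)
  mass <- as_particle_mass(mass)
  if (is.null(grid)) grid <- default_grid(curve)
  stopifnot(inherits(grid, "grid_spec"))
  n_states <- as.integer(n_states)
  if (n_states < 1L) {
    abort("`n_states` must be at least 1", class = "vibhb_parameter_error")
  }
  if (n_states > grid$n_points) {
    abort("`n_states` exceeds the number of grid points",
          class = "vibhb_parameter_error")
  }
  eps <- 1e-9
  if (grid$q_start < min(curve$q) - eps ||
      grid$q_end > max(curve$q) + eps) {
    abort("solver grid must lie within the curve's tabulated span",
          class = "vibhb_parameter_error")
  }
  q <- grid_points(grid)
  dq <- grid_spacing(grid)
  v <- curve_fun(curve)(q)
  h <- kinetic(grid$n_points, dq, mass$mass)
  diag(h) <- diag(h) + v
  es <- eigen(h, symmetric = TRUE)
  ord <- order(es$values)[seq_len(n_states)]
  energies <- es$values[ord]
  psi <- es$vectors[, ord, drop = FALSE] / sqrt(dq)
  # sign convention: first non-negligible amplitude positive
  for (j in seq_len(ncol(psi))) {
    nz <- which(abs(psi[, j]) > 1e-8 * max(abs(psi[, j])))[1]
    if (psi[nz, j] < 0) psi[, j] <- -psi[, j]
  }
  if (max(abs(psi[c(1L, nrow(psi)), 1L])) > 1e-6) {
    warn("ground-state amplitude at the grid boundary exceeds 1e-6; enlarge the grid range",
         class = "vibhb_boundary_leakage")
  }
  structure(
    list(
      energies = energies,
      wavefunctions = psi,
      grid = grid,
      mass = mass,
      r0 = curve_r0(curve),
      curve_label = curve_label(curve),
      method = method
    ),
    class = "vibhb_spectrum"
  )
}

#' Zero-point energy of a vibrational spectrum
#'
#' The ground-state level above the potential minimum (the curve's
#' energy zero), in kcal/mol.
#'
#' @param spectrum A `vibhb_spectrum`.
#' @export
zero_point_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "vibhb_spectrum"))
  spectrum$energies[[1]]
}

#' @export
print.vibhb_spectrum <- function(x, ...) {
  cat(sprintf(
    "<vibrational spectrum> %s (%.6f amu), %d states, %s, %d-point grid\n",
    x$mass$isotope_label, x$mass$mass, length(x$energies), x$method,
    x$grid$n_points
  ))
  if (nzchar(x$curve_label)) cat("curve:", x$curve_label, "\n")
  cat("levels (kcal/mol):",
      paste(sprintf("%.4f", x$energies), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a vibrational spectrum into a level table
#'
#' @param x A `vibhb_spectrum`.
#' @param ... Unused.
#' @return One row per state: `state` (vibrational quantum number,
#'   from 0), `energy` (kcal/mol above the potential minimum),
#'   `mean_r` (vibrationally averaged bond length, angstrom).
#' @method tidy vibhb_spectrum
#' @export
tidy.vibhb_spectrum <- function(x, ...) {
  tibble::tibble(
    state = seq_along(x$energies) - 1L,
    energy = x$energies,
    mean_r = purrr::map_dbl(seq_along(x$energies) - 1L,
                            ~ expectation_bond_length(x, .x))
  )
}

#' @rdname tidy.vibhb_spectrum
#' @return For `glance()`: a one-row summary with the isotope, mass,
#'   state count, zero-point energy, first excitation gap, grid size
#'   and method.
#' @method glance vibhb_spectrum
#' @export
glance.vibhb_spectrum <- function(x, ...) {
  tibble::tibble(
    isotope = x$mass$isotope_label,
    mass = x$mass$mass,
    n_states = length(x$energies),
    zpe = zero_point_energy(x),
    first_gap = if (length(x$energies) >= 2) {
      x$energies[[2]] - x$energies[[1]]
    } else {
      NA_real_
    },
    n_grid = x$grid$n_points,
    method = x$method
  )
}

#' Export a spectrum as TSV files
#'
#' Writes a level table (`state`, `energy_kcal_per_mol`) to `path` and
#' the gridded wavefunctions to a `_wavefunctions.tsv` sidecar.
#'
#' @param spectrum A `vibhb_spectrum`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "vibhb_spectrum"))
  lev <- data.frame(
    state = seq_along(spectrum$energies) - 1L,
    energy_kcal_per_mol = sprintf("%.12g", spectrum$energies)
  )
  utils::write.table(lev, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- sub("(\\.[^.]*)?$", "_wavefunctions.tsv", path)
  wf <- as.data.frame(apply(spectrum$wavefunctions, 2,
                            function(x) sprintf("%.12g", x)))
  names(wf) <- paste0("psi_", seq_along(spectrum$energies) - 1L)
  wf <- cbind(q_angstrom = sprintf("%.12g", grid_points(spectrum$grid)),
              wf)
  utils::write.table(wf, side, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
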