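#' Analytic model potentials
#'
#' Generators for the model families used both as solver test oracles
#' (harmonic, Morse) and as proton-transfer model curves (asymmetric
#' double well). All generators place the global minimum at 0 kcal/mol
#' and sample the analytic form on the supplied grid.
#'
#' @name potential_models
NULL

#' @describeIn potential_models Harmonic well
#'   `E(q) = k/2 (q - q_min)^2`. With force constant
#'   `k = m omega^2` the exact levels are `hbar omega (n + 1/2)`.
#' @param force_constant Force constant `k`, kcal mol-1 angstrom-2 (> 0).
#' @param q_min Position of the minimum, angstrom (inside the grid).
#' @param r0 Reference bond length at `q = 0`, angstrom.
#' @param grid A [grid_spec()] to sample on.
#' @export
make_harmonic <- function(force_constant, q_min = 0, r0 = 1.0, grid) {
  if (!is.numeric(force_constant) || force_constant <= 0) {
    abort("`force_constant` must be positive",
          class = "vibhb_parameter_error")
  }
  if (q_min < grid$q_start || q_min > grid$q_end) {
    abort("`q_min` must lie inside the grid range",
          class = "vibhb_parameter_error")
  }
  q <- grid_points(grid)
  potential_curve(q, 0.5 * force_constant * (q - q_min)^2,
                  r0 = r0,
                  label = sprintf("harmonic k=%g", force_constant))
}

#' @describeIn potential_models Morse well
#'   `E(q) = D_e (1 - exp(-a (q - q_min)))^2`: anharmonic, stiff inner
#'   wall, dissociation plateau `D_e`. Bound levels follow the closed
#'   form `hbar omega (n+1/2) - [hbar omega (n+1/2)]^2 / (4 D_e)` with
#'   `omega = a sqrt(2 D_e / m)`.
#' @param d_e Well depth `D_e`, kcal/mol (> 0).
#' @param a Range parameter, angstrom-1 (> 0).
#' @export
make_morse <- function(d_e, a, q_min = 0, r0 = 1.0, grid) {
  if (!is.numeric(d_e) || d_e <= 0 || !is.numeric(a) || a <= 0) {
    abort("`d_e` and `a` must be positive",
          class = "vibhb_parameter_error")
  }
  q <- grid_points(grid)
  potential_curve(q, d_e * (1 - exp(-a * (q - q_min)))^2,
                  r0 = r0,
                  label = sprintf("morse D_e=%g a=%g", d_e, a))
}

# --- double well -----------------------------------------------------------
#
# The curve is the lowest-degree polynomial satisfying six constraints:
# E = 0, E' = 0 at min1_q; E = barrier_height, E' = 0 at barrier_q;
# E = asymmetry, E' = 0 at min2_q.
#
# The derivative is constructed directly as
#   E'(q) = (q - m1)(q - b)(q - m2) * g(q),   g(q) = u + w (q - s)^2,
# so the stationary points and their min/max/min character are exact by
# construction whenever g > 0 (E'' at each point is g times a factor of
# known sign). Integrating from m1 gives a degree-4 (w = 0) or degree-6
# polynomial with E(m1) = 0, and the two remaining energy constraints
# E(b) = h, E(m2) = asym are linear in (u, w). The envelope centre s is
# taken from a small fixed candidate list (well midpoint, barrier, ...)
# and the first solution whose g stays positive over the sampled window
# is used, deterministically. In the symmetric case the system is
# singular and the w = 0 solution is exactly the quartic
# a (q - m1)^2 (q - m2)^2. Constraint sets for which no candidate keeps
# g > 0 (e.g. a strongly asymmetric pair of wells with the barrier
# pinned at the midpoint) admit no confining member of this family and
# raise a construction error. All six constraints are re-verified on
# the analytic polynomial to 1e-8 before sampling.

# ascending-power coefficients of prod (q - r) over roots r
poly_from_roots <- function(roots) {
  cf <- 1
  for (r in roots) cf <- c(0, cf) - r * c(cf, 0)
  cf
}

poly_eval <- function(cf, q) {
  drop(outer(q, seq_along(cf) - 1, `^`) %*% cf)
}

poly_deriv <- function(cf) {
  n <- length(cf)
  if (n <= 1) return(0)
  cf[-1] * seq_len(n - 1)
}

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

poly_antideriv <- function(cf) {
  c(0, cf / seq_along(cf))
}

dw_polynomial <- function(m1, b, m2, h, asym, q_lo, q_hi) {
  p3 <- poly_from_roots(c(m1, b, m2))
  a0 <- poly_antideriv(p3)
  j0b <- poly_eval(a0, b) - poly_eval(a0, m1)
  j0m <- poly_eval(a0, m2) - poly_eval(a0, m1)
  # candidate envelope centres, tried in fixed order
  centres <- c((m1 + m2) / 2, b, (b + m2) / 2, (m1 + b) / 2, m1, m2)
  for (s in centres) {
    a2 <- poly_antideriv(poly_mult(p3, poly_from_roots(c(s, s))))
    j2b <- poly_eval(a2, b) - poly_eval(a2, m1)
    j2m <- poly_eval(a2, m2) - poly_eval(a2, m1)
    mat <- matrix(c(j0b, j0m, j2b, j2m), 2L)
    scale <- max(abs(mat))
    if (abs(det(mat)) > 1e-10 * scale^2) {
      uw <- solve(mat, c(h, asym))
    } else {
      # symmetric-constraint degeneracy: quartic branch (w = 0)
      uw <- c(h / j0b, 0)
      if (abs(uw[1] * j0m - asym) > 1e-8) next
    }
    u <- uw[[1]]
    w <- uw[[2]]
    # g = u + w (q - s)^2 must stay positive over the sampled window
    # or the stationary structure (and edge confinement) is lost; its
    # minimum there is at an endpoint or at s
    g <- function(q) u + w * (q - s)^2
    if (u <= 0 || min(g(q_lo), g(q_hi), u) <= 0) next
    ecf <- u * c(a0, numeric(length(a2) - length(a0))) + w * a2
    ecf[1] <- ecf[1] - poly_eval(ecf, m1)
    # drop trailing zeros (quartic branch)
    while (length(ecf) > 1 && abs(ecf[length(ecf)]) < 1e-300) {
      ecf <- ecf[seq_len(length(ecf) - 1L)]
    }
    attr(ecf, "envelope") <- c(u = u, w = w, s = s)
    return(ecf)
  }
  abort("infeasible constraint set: no member of the polynomial family keeps a positive derivative envelope over the sampled range (stationary energies too asymmetric for these positions)",
        class = "vibhb_construction_error")
}

dw_verify <- function(cf, m1, b, m2, h, asym) {
  checks <- c(
    "E(min1_q) = 0" = abs(poly_eval(cf, m1)),
    "E(barrier_q) = barrier_height" = abs(poly_eval(cf, b) - h),
    "E(min2_q) = asymmetry" = abs(poly_eval(cf, m2) - asym)
  )
  d1 <- poly_deriv(cf)
  checks <- c(checks, c(
    "E'(min1_q) = 0" = abs(poly_eval(d1, m1)),
    "E'(barrier_q) = 0" = abs(poly_eval(d1, b)),
    "E'(min2_q) = 0" = abs(poly_eval(d1, m2))
  ))
  bad <- names(checks)[checks > 1e-8]
  d2 <- poly_deriv(d1)
  if (poly_eval(d2, m1) <= 0) bad <- c(bad, "min1_q is a minimum")
  if (poly_eval(d2, b) >= 0) bad <- c(bad, "barrier_q is a maximum")
  if (poly_eval(d2, m2) <= 0) bad <- c(bad, "min2_q is a minimum")
  if (length(bad)) {
    abort(paste0("infeasible constraint set; violated: ",
                 paste(bad, collapse = "; ")),
          class = "vibhb_construction_error")
  }
  invisible(cf)
}

#' @describeIn potential_models Asymmetric double well: the
#'   lowest-degree polynomial with a minimum of 0 at `min1_q`, a
#'   maximum of `barrier_height` at `barrier_q`, and a second minimum
#'   of `asymmetry` at `min2_q`. The analytic polynomial coefficients
#'   (ascending powers) are attached as attribute `"coefficients"`.
#' @param min1_q,barrier_q,min2_q Stationary-point positions, angstrom,
#'   with `min1_q < barrier_q < min2_q`.
#' @param barrier_height Barrier energy above the global minimum,
#'   kcal/mol (> `asymmetry`).
#' @param asymmetry Energy of the second minimum above the first,
#'   kcal/mol (>= 0).
#' @export
make_double_well <- function(min1_q, barrier_q, min2_q, barrier_height,
                             asymmetry = 0, r0 = 1.0, grid) {
  if (!(min1_q < barrier_q && barrier_q < min2_q)) {
    abort("stationary points must satisfy min1_q < barrier_q < min2_q",
          class = "vibhb_parameter_error")
  }
  if (barrier_height <= 0 || asymmetry < 0 ||
      barrier_height <= asymmetry) {
    abort("need barrier_height > asymmetry >= 0",
          class = "vibhb_parameter_error")
  }
  cf <- dw_polynomial(min1_q, barrier_q, min2_q, barrier_height,
                      asymmetry, grid$q_start, grid$q_end)
  dw_verify(cf, min1_q, barrier_q, min2_q, barrier_height, asymmetry)
  q <- grid_points(grid)
  curve <- potential_curve(
    q, poly_eval(cf, q), r0 = r0,
    label = sprintf("double-well barrier=%g asym=%g",
                    barrier_height, asymmetry)
  )
  attr(curve, "coefficients") <- cf
  curve
}

# default sampling emulating a QM scan along the migration coordinate
pyp_default_grid <- function() grid_spec(-0.45, 0.75, 61L)

#' PYP-like fixture curves
#'
#' Model curves calibrated to the printed features of the Glu46–pCA
#' hydrogen bond of photoactive yellow protein (PYP). They stand in for
#' unpublished QM/MM potential scans and are calibrated only to scalar
#' features, not to digitized figures.
#'
#' `make_pyp_equilibrium_fixture()` emulates the optimized (equilibrium)
#' geometry with its short O...O distance of 2.47 angstrom: a single
#' anharmonic well (Morse form, `D_e` = 90 kcal/mol, `a` = 1.1
#' angstrom-1) with its minimum at the equilibrium bond length
#' R = 1.08 angstrom, a stiff inner wall and a softer outer wall.
#'
#' `make_pyp_crystal_fixture()` emulates the neutron-crystal geometry
#' (O...O 2.56 angstrom): an asymmetric double well with its global
#' minimum at R = 1.06 angstrom (q = -0.15 relative to the crystal bond
#' length R0 = 1.21 angstrom), a 2.36 kcal/mol barrier at q = +0.10
#' (R = 1.31 angstrom), and a shallower acceptor-side minimum whose
#' position and offset are fixture parameters.
#'
#' @param grid A [grid_spec()]; defaults to q in [-0.45, 0.75] angstrom
#'   at 0.02 angstrom spacing.
#' @return A `vibhb_curve`.
#' @examples
#' barrier_analysis(make_pyp_crystal_fixture())
#' @export
make_pyp_equilibrium_fixture <- function(grid = pyp_default_grid()) {
  curve <- make_morse(d_e = 90, a = 1.1, q_min = 0, r0 = 1.08,
                      grid = grid)
  attr(curve, "label") <- "equilibrium-like, O...O 2.47 A"
  curve
}

#' @rdname make_pyp_equilibrium_fixture
#' @param min2_q Acceptor-side minimum position, angstrom (default
#'   +0.35, i.e. R = 1.56 angstrom, about 1 angstrom from the acceptor
#'   oxygen).
#' @param asymmetry Acceptor-side minimum energy above the global
#'   minimum, kcal/mol (default 1.0).
#' @export
make_pyp_crystal_fixture <- function(grid = pyp_default_grid(),
                                     min2_q = 0.35, asymmetry = 1.0) {
  curve <- make_double_well(
    min1_q = -0.15, barrier_q = 0.10, min2_q = min2_q,
    barrier_height = 2.36, asymmetry = asymmetry,
    r0 = 1.21, grid = grid
  )
  attr(curve, "label") <- "crystal-like, O...O 2.56 A"
  curve
}
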