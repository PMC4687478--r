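#' Vibrationally averaged O-H bond length
#'
#' Position expectation value of a vibrational eigenstate mapped to
#' bond length through the collinear convention:
#' \deqn{\langle R \rangle_i = R_0 + \sum_k q_k |\psi_i(q_k)|^2 \Delta q.}
#'
#' @param spectrum A `vibhb_spectrum`.
#' @param state Vibrational quantum number (0 = ground state).
#' @param curve Optional `vibhb_curve` supplying `R0`; defaults to the
#'   curve metadata stored in the spectrum.
#' @return Bond length in angstrom.
#' @export
expectation_bond_length <- function(spectrum, state = 0L, curve = NULL) {
  stopifnot(inherits(spectrum, "vibhb_spectrum"))
  state <- as.integer(state)
  if (state < 0L || state >= length(spectrum$energies)) {
    abort(sprintf("state %d is outside the solved range 0..%d",
                  state, length(spectrum$energies) - 1L),
          class = "vibhb_parameter_error")
  }
  r0 <- if (is.null(curve)) spectrum$r0 else curve_r0(curve)
  q <- grid_points(spectrum$grid)
  dq <- grid_spacing(spectrum$grid)
  psi2 <- spectrum$wavefunctions[, state + 1L]^2
  r0 + sum(q * psi2) * dq
}

#' Boltzmann populations of vibrational states
#'
#' Normalised weights
#' \deqn{w_i = \exp(-(\epsilon_i - \epsilon_0)/k_B T) \; / \;
#'       \sum_j \exp(-(\epsilon_j - \epsilon_0)/k_B T),}
#' shifted by the lowest level for numerical stability (the shift
#' cancels, so the weights are invariant to any constant added to the
#' energies).
#'
#' @param energies Level energies in kcal/mol.
#' @param temperature Temperature in K (> 0); default 300 K.
#' @return Weights summing to 1.
#' @examples
#' boltzmann_weights(c(2.02, 5.46, 10.14), 300)
#' @export
boltzmann_weights <- function(energies, temperature = 300) {
  if (!is.numeric(energies) || length(energies) < 1L ||
      anyNA(energies)) {
    abort("`energies` must be a non-empty numeric vector",
          class = "vibhb_parameter_error")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be positive",
          class = "vibhb_parameter_error")
  }
  w <- exp(-(energies - min(energies)) / (.kB * temperature))
  w / sum(w)
}

#' Boltzmann thermal average of state-resolved values
#'
#' Weighted mean \eqn{R_T = \sum_i R_i w_i} of per-state values (for
#' bond lengths, the thermally averaged length at temperature T) using
#' [boltzmann_weights()].
#'
#' @param values Per-state values (e.g. bond lengths in angstrom).
#' @param energies Matching level energies, kcal/mol.
#' @inheritParams boltzmann_weights
#' @return The thermal average, same units as `values`.
#' @examples
#' # proton levels / averaged lengths at the PYP equilibrium geometry
#' thermal_average(c(1.17, 1.23, 1.21), c(2.02, 5.46, 10.14), 300)
#' @export
thermal_average <- function(values, energies, temperature = 300) {
  if (length(values) != length(energies)) {
    abort("`values` and `energies` must have equal length",
          class = "vibhb_parameter_error")
  }
  sum(values * boltzmann_weights(energies, temperature))
}

#' Excitation energies above the ground state
#'
#' @param spectrum A `vibhb_spectrum`, or a numeric vector of level
#'   energies (kcal/mol, ascending).
#' @return `energies[i] - energies[0]` for the excited states.
#' @export
excitation_gaps <- function(spectrum) {
  energies <- if (inherits(spectrum, "vibhb_spectrum")) {
    spectrum$energies
  } else {
    as.numeric(spectrum)
  }
  if (length(energies) < 2L) {
    abort("need at least 2 states to form excitation gaps",
          class = "vibhb_parameter_error")
  }
  energies[-1L] - energies[[1L]]
}

#' Stationary-point analysis of a potential curve
#'
#' Locates all interior minima and maxima of the curve's cubic-spline
#' interpolant (sign changes of the derivative refined by bracketed
#' root-finding to 1e-10 angstrom) and classifies the curve:
#' `"double-well"` when a maximum lies between two minima, otherwise
#' `"single-well"`. The barrier height is the energy of that maximum
#' above the global minimum. Endpoint extrema are never counted as
#' wells.
#'
#' @param curve A `vibhb_curve`.
#' @return A tibble with one row per stationary point (`type`, `q`,
#'   `R`, `energy`) carrying attributes `classification`,
#'   `barrier_height`, `barrier_q` (both `NA` for single wells),
#'   `q_min`, `r_min` and `e_min` for the global minimum.
#' @examples
#' barrier_analysis(make_pyp_crystal_fixture())
#' @export
barrier_analysis <- function(curve) {
  curve <- validate_curve(curve)
  f <- curve_fun(curve)
  q_lo <- min(curve$q)
  q_hi <- max(curve$q)
  scan <- seq(q_lo, q_hi, length.out = max(2001L, 10L * nrow(curve)))
  d <- f(scan, deriv = 1)
  flips <- which(d[-length(d)] * d[-1L] < 0)
  roots <- purrr::map_dbl(flips, function(i) {
    uniroot(function(x) f(x, deriv = 1),
            lower = scan[i], upper = scan[i + 1L],
            tol = 1e-10)$root
  })
  # exact zeros of the scan (e.g. a node is the stationary point)
  roots <- sort(unique(c(roots, scan[d == 0 & scan > q_lo & scan < q_hi])))
  if (length(roots) > 1L) {
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  }
  if (!length(roots)) {
    abort("curve has no interior stationary point",
          class = "vibhb_degenerate_curve_error")
  }
  type <- ifelse(f(roots, deriv = 2) > 0, "minimum", "maximum")
  out <- tibble::tibble(
    type = type,
    q = roots,
    R = bond_length(curve, roots),
    energy = f(roots)
  )
  minima <- which(out$type == "minimum")
  if (!length(minima)) {
    abort("curve has no interior minimum",
          class = "vibhb_degenerate_curve_error")
  }
  gmin <- minima[which.min(out$energy[minima])]
  interior_max <- which(
    out$type == "maximum" &
      out$q > min(out$q[minima]) & out$q < max(out$q[minima])
  )
  if (length(minima) >= 2L && length(interior_max)) {
    top <- interior_max[which.max(out$energy[interior_max])]
    attr(out, "classification") <- "double-well"
    attr(out, "barrier_height") <- out$energy[top] - out$energy[gmin]
    attr(out, "barrier_q") <- out$q[top]
  } else {
    attr(out, "classification") <- "single-well"
    attr(out, "barrier_height") <- NA_real_
    attr(out, "barrier_q") <- NA_real_
  }
  attr(out, "q_min") <- out$q[gmin]
  attr(out, "r_min") <- out$R[gmin]
  attr(out, "e_min") <- out$energy[gmin]
  class(out) <- c("vibhb_barrier", class(out))
  out
}

#' @export
print.vibhb_barrier <- function(x, ...) {
  cat(sprintf("<stationary-point analysis> %s\n",
              attr(x, "classification")))
  if (!is.na(attr(x, "barrier_height"))) {
    cat(sprintf("barrier: %.4f kcal/mol at q = %.4f angstrom\n",
                attr(x, "barrier_height"), attr(x, "barrier_q")))
  }
  NextMethod()
}

#' Classify a hydrogen bond by barrier vs zero-point energy
#'
#' A proton-transfer well behaves as a low-barrier hydrogen bond (LBHB)
#' when the proton's zero-point energy reaches the top of the barrier:
#' the proton is then delocalised across both wells rather than bound
#' on the donor side. The rule applied is
#' `zpe >= barrier_height - tolerance` for `"ZPE-dominated
#' (LBHB-like)"`, otherwise `"barrier-localized"`; single-well curves
#' are `"no-barrier (single-well)"`. The remaining gap
#' `barrier_height - zpe` is reported when positive (for a deuteron on
#' the PYP crystal curve this gap is what keeps the heavier isotope
#' localised).
#'
#' @param curve A `vibhb_curve`.
#' @param spectrum_h Proton spectrum solved on `curve` (may be `NULL`
#'   for single-well curves).
#' @param tolerance Classification tolerance in kcal/mol (default 0.5).
#' @return One-row tibble: `classification`, `barrier_height`, `zpe`,
#'   `zpe_barrier_gap`, `tolerance`.
#' @export
lbhb_classify <- function(curve, spectrum_h = NULL, tolerance = 0.5) {
  ba <- barrier_analysis(curve)
  if (attr(ba, "classification") == "single-well") {
    return(tibble::tibble(
      classification = "no-barrier (single-well)",
      barrier_height = NA_real_,
      zpe = if (is.null(spectrum_h)) NA_real_ else
        zero_point_energy(spectrum_h),
      zpe_barrier_gap = NA_real_,
      tolerance = tolerance
    ))
  }
  if (is.null(spectrum_h)) {
    abort("a solved proton spectrum is required to classify a double well",
          class = "vibhb_parameter_error")
  }
  barrier <- attr(ba, "barrier_height")
  zpe <- zero_point_energy(spectrum_h)
  gap <- barrier - zpe
  tibble::tibble(
    classification = if (zpe >= barrier - tolerance) {
      "ZPE-dominated (LBHB-like)"
    } else {
      "barrier-localized"
    },
    barrier_height = barrier,
    zpe = zpe,
    zpe_barrier_gap = if (gap > 0) gap else NA_real_,
    tolerance = tolerance
  )
}

#' Per-state thermal report for one isotope
#'
#' Assembles the level/average-length table for one solved spectrum:
#' per state the energy, the vibrationally averaged bond length, and
#' the Boltzmann weight; the thermally averaged bond length `R_T` is
#' attached as an attribute. If four or more states were solved and
#' truncating to three moves `R_T` by more than 0.005 angstrom, a
#' convergence warning is raised.
#'
#' @param spectrum A `vibhb_spectrum`.
#' @param curve Optional curve supplying `R0` (defaults to spectrum
#'   metadata).
#' @inheritParams boltzmann_weights
#' @return A `vibhb_thermal_report` tibble (`state`, `energy`,
#'   `mean_r`, `weight`) with attributes `r_t`, `temperature`,
#'   `isotope`.
#' @export
thermal_report <- function(spectrum, curve = NULL, temperature = 300) {
  stopifnot(inherits(spectrum, "vibhb_spectrum"))
  states <- seq_along(spectrum$energies) - 1L
  mean_r <- purrr::map_dbl(states,
                           ~ expectation_bond_length(spectrum, .x, curve))
  w <- boltzmann_weights(spectrum$energies, temperature)
  r_t <- sum(mean_r * w)
  if (length(states) >= 4L) {
    r_t3 <- thermal_average(mean_r[1:3], spectrum$energies[1:3],
                            temperature)
    if (abs(r_t - r_t3) > 0.005) {
      warn("thermal average not converged with 3 states (R_T moves by > 0.005 angstrom)",
           class = "vibhb_thermal_convergence")
    }
  }
  out <- tibble::tibble(
    state = states,
    energy = spectrum$energies,
    mean_r = mean_r,
    weight = w
  )
  attr(out, "r_t") <- r_t
  attr(out, "temperature") <- temperature
  attr(out, "isotope") <- spectrum$mass$isotope_label
  class(out) <- c("vibhb_thermal_report", class(out))
  out
}

#' @export
print.vibhb_thermal_report <- function(x, ...) {
  cat(sprintf("<thermal report> %s at %g K, R_T = %.4f angstrom\n",
              attr(x, "isotope"), attr(x, "temperature"),
              attr(x, "r_t")))
  NextMethod()
}

#' H/D isotope comparison on one potential curve
#'
#' Pairs a proton and a deuteron spectrum solved on the same curve and
#' grid and derives the isotope observables: ground-state averaged
#' bond lengths and their difference, quantum elongation (ground-state
#' average minus the bond length at the potential minimum — the purely
#' nuclear-quantum part of the bond-length extension), thermal
#' elongation (`R_T` minus the ground-state average), and the first
#' excitation gap of each isotope.
#'
#' @param spectrum_h,spectrum_d Spectra for the light and heavy
#'   isotope, solved on the same curve and grid.
#' @param curve The shared `vibhb_curve`.
#' @inheritParams boltzmann_weights
#' @return A `vibhb_isotope_comparison` tibble, one row per isotope,
#'   with columns `isotope`, `zpe`, `first_gap`, `mean_r_ground`,
#'   `r_t`, `quantum_elongation`, `thermal_elongation`, and attributes
#'   `delta_mean_r_ground` (light minus heavy), `r_min`,
#'   `temperature`.
#' @export
isotope_report <- function(spectrum_h, spectrum_d, curve,
                           temperature = 300) {
  stopifnot(inherits(spectrum_h, "vibhb_spectrum"),
            inherits(spectrum_d, "vibhb_spectrum"))
  gh <- spectrum_h$grid
  gd <- spectrum_d$grid
  if (gh$n_points != gd$n_points || gh$q_start != gd$q_start ||
      gh$q_end != gd$q_end) {
    abort("the two spectra must be solved on the same grid",
          class = "vibhb_parameter_error")
  }
  r_min <- attr(barrier_analysis(curve), "r_min")
  one <- function(sp) {
    rep_ <- thermal_report(sp, curve, temperature)
    tibble::tibble(
      isotope = sp$mass$isotope_label,
      zpe = zero_point_energy(sp),
      first_gap = excitation_gaps(sp)[[1]],
      mean_r_ground = rep_$mean_r[[1]],
      r_t = attr(rep_, "r_t"),
      quantum_elongation = rep_$mean_r[[1]] - r_min,
      thermal_elongation = attr(rep_, "r_t") - rep_$mean_r[[1]]
    )
  }
  out <- dplyr::bind_rows(one(spectrum_h), one(spectrum_d))
  attr(out, "delta_mean_r_ground") <-
    out$mean_r_ground[[1]] - out$mean_r_ground[[2]]
  attr(out, "r_min") <- r_min
  attr(out, "temperature") <- temperature
  class(out) <- c("vibhb_isotope_comparison", class(out))
  out
}

#' @export
print.vibhb_isotope_comparison <- function(x, ...) {
  cat(sprintf(
    "<isotope comparison> at %g K; ground-state delta<R> (light - heavy) = %.4f angstrom\n",
    attr(x, "temperature"), attr(x, "delta_mean_r_ground")
  ))
  NextMethod()
}
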