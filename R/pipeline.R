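#' Build a named fixture or model curve
#'
#' Dispatcher used by the pipeline and the command-line driver.
#' `"pyp_equilibrium"` and `"pyp_crystal"` take no mandatory
#' parameters; `"harmonic"`, `"morse"` and `"double_well"` forward
#' `...` to their generators and require a `grid`.
#'
#' @param name One of `"pyp_equilibrium"`, `"pyp_crystal"`,
#'   `"harmonic"`, `"morse"`, `"double_well"`.
#' @param ... Generator parameters (see [make_harmonic()],
#'   [make_morse()], [make_double_well()],
#'   [make_pyp_crystal_fixture()]).
#' @return A `vibhb_curve`.
#' @export
fixture_curve <- function(name, ...) {
  switch(
    name,
    pyp_equilibrium = make_pyp_equilibrium_fixture(...),
    pyp_crystal = make_pyp_crystal_fixture(...),
    harmonic = make_harmonic(...),
    morse = make_morse(...),
    double_well = make_double_well(...),
    abort(paste0("unknown fixture '", name, "'"),
          class = "vibhb_usage_error")
  )
}

#' Run the full hydrogen-bond vibrational analysis
#'
#' End-to-end driver: load or generate a potential curve, solve the
#' nuclear Schroedinger equation for each requested isotope, and
#' assemble the level/average-length report, the stationary-point and
#' LBHB analyses, and (when both H and D are solved) the isotope
#' comparison. The whole pipeline is deterministic: identical inputs
#' give identical outputs.
#'
#' @param curve A `vibhb_curve`, a curve file path, or a fixture name
#'   accepted by [fixture_curve()].
#' @param isotopes Character vector of isotopes to solve (presets
#'   `"H"`, `"D"`).
#' @param n_states Number of vibrational states per isotope.
#' @param temperature Temperature for thermal averaging, K.
#' @param n_grid Solver grid points over the curve span.
#' @return A `vibhb_report` list: `curve`, `spectra` (named list),
#'   `thermal` (named list of [thermal_report()] tibbles), `barrier`,
#'   `lbhb`, `isotope` (or `NULL`), `params`.
#' @examples
#' rep <- run_hbond_analysis("pyp_crystal")
#' rep
#' tidy(rep)
#' @export
run_hbond_analysis <- function(curve, isotopes = c("H", "D"),
                               n_states = 3L, temperature = 300,
                               n_grid = 1001L) {
  if (is.character(curve)) {
    curve <- if (file.exists(curve)) read_curve(curve)
             else fixture_curve(curve)
  }
  curve <- validate_curve(curve)
  grid <- default_grid(curve, n_grid)
  spectra <- purrr::map(rlang::set_names(isotopes),
                        ~ solve_states(curve, .x, grid, n_states))
  thermal <- purrr::map(spectra, thermal_report, curve = curve,
                        temperature = temperature)
  barrier <- barrier_analysis(curve)
  lbhb <- if ("H" %in% isotopes) {
    lbhb_classify(curve, spectra[["H"]])
  } else {
    lbhb_classify(curve, spectra[[1]])
  }
  isotope <- NULL
  if (all(c("H", "D") %in% isotopes) && n_states >= 2L) {
    isotope <- isotope_report(spectra[["H"]], spectra[["D"]], curve,
                              temperature)
  }
  structure(
    list(
      curve = curve,
      spectra = spectra,
      thermal = thermal,
      barrier = barrier,
      lbhb = lbhb,
      isotope = isotope,
      params = list(
        isotopes = isotopes, n_states = n_states,
        temperature = temperature, n_grid = n_grid,
        constants = list(hbar2 = .hbar2, kB = .kB)
      )
    ),
    class = "vibhb_report"
  )
}

#' @export
print.vibhb_report <- function(x, ...) {
  cat("Hydrogen-bond 1D nuclear vibrational analysis\n")
  if (nzchar(curve_label(x$curve))) {
    cat("curve:", curve_label(x$curve), "\n")
  }
  cat(sprintf("R0 = %.2f angstrom; %s", curve_r0(x$curve),
              x$lbhb$classification[[1]]))
  if (!is.na(x$lbhb$barrier_height[[1]])) {
    cat(sprintf(" (barrier %.2f kcal/mol, proton ZPE %.2f kcal/mol)",
                x$lbhb$barrier_height[[1]], x$lbhb$zpe[[1]]))
  }
  cat("\n\n")
  for (iso in names(x$thermal)) {
    tr <- x$thermal[[iso]]
    cat(iso, "  state  epsilon  <R>\n")
    for (i in rev(seq_len(nrow(tr)))) {
      cat(sprintf("   %6d  %7.2f  %.2f\n",
                  tr$state[[i]], tr$energy[[i]], tr$mean_r[[i]]))
    }
    cat(sprintf("      R_T (%g K)  %.2f\n", attr(tr, "temperature"),
                attr(tr, "r_t")))
  }
  if (!is.null(x$isotope)) {
    cat(sprintf(
      "\nground-state delta<R> (H - D): %.2f angstrom\n",
      attr(x$isotope, "delta_mean_r_ground")
    ))
  }
  invisible(x)
}

#' @rdname run_hbond_analysis
#' @param x A `vibhb_report`.
#' @param ... Unused.
#' @return For `tidy()`: one row per isotope and state (`isotope`,
#'   `state`, `energy`, `mean_r`, `weight`, `r_t`).
#' @method tidy vibhb_report
#' @export
tidy.vibhb_report <- function(x, ...) {
  purrr::imap(x$thermal, function(tr, iso) {
    dplyr::mutate(tibble::as_tibble(tr), isotope = iso,
                  r_t = attr(tr, "r_t"), .before = 1)
  }) |>
    purrr::list_rbind()
}

#' @rdname run_hbond_analysis
#' @method glance vibhb_report
#' @export
glance.vibhb_report <- function(x, ...) {
  dplyr::bind_cols(
    x$lbhb[, c("classification", "barrier_height", "zpe")],
    tibble::tibble(
      temperature = x$params$temperature,
      n_states = x$params$n_states,
      n_grid = x$params$n_grid,
      delta_mean_r_ground = if (is.null(x$isotope)) NA_real_ else
        attr(x$isotope, "delta_mean_r_ground")
    )
  )
}

#' Write a report to disk (TSV and/or JSON)
#'
#' The TSV mirrors the per-state table layout (`isotope`, `state`,
#' `epsilon_kcal_per_mol`, `mean_R_angstrom`, `R_T_angstrom`) rounded
#' to 2 decimals as conventionally printed; the JSON carries full
#' precision, the barrier/LBHB analyses, the isotope comparison, and a
#' provenance block with the physical constants and run parameters.
#' Output bytes depend only on the report contents.
#'
#' @param report A `vibhb_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "vibhb_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  long <- tidy.vibhb_report(report)
  if ("tsv" %in% formats) {
    p <- file.path(dir, "report.tsv")
    out <- data.frame(
      isotope = long$isotope,
      state = long$state,
      epsilon_kcal_per_mol = sprintf("%.2f", long$energy),
      mean_R_angstrom = sprintf("%.2f", long$mean_r),
      R_T_angstrom = sprintf("%.2f", long$r_t)
    )
    utils::write.table(out, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    payload <- list(
      curve = list(
        label = curve_label(report$curve),
        r0_angstrom = curve_r0(report$curve)
      ),
      levels = long,
      barrier = list(
        classification = attr(report$barrier, "classification"),
        barrier_height_kcal_per_mol = attr(report$barrier,
                                           "barrier_height"),
        barrier_q_angstrom = attr(report$barrier, "barrier_q"),
        r_min_angstrom = attr(report$barrier, "r_min"),
        stationary_points = tibble::as_tibble(report$barrier)
      ),
      lbhb = report$lbhb,
      isotope_comparison = if (is.null(report$isotope)) NULL else {
        list(
          table = tibble::as_tibble(report$isotope),
          delta_mean_r_ground_angstrom = attr(report$isotope,
                                              "delta_mean_r_ground")
        )
      },
      params = report$params
    )
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
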