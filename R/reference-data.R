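#' Published reference levels for the PYP Glu46-pCA hydrogen bond
#'
#' Bundled reference data: vibrational energy levels and vibrationally
#' averaged O-H bond lengths for a proton and a deuteron in the
#' Glu46-pCA hydrogen bond of photoactive yellow protein, at the
#' optimized (equilibrium, O...O 2.47 angstrom) and neutron-crystal
#' (O...O 2.56 angstrom) geometries. Values are as printed (2
#' decimals). These tables let the thermal-averaging stage be
#' exercised on published inputs independently of the eigensolver and
#' of the (unpublished) potential scans behind them.
#'
#' @param structure `"equilibrium"` or `"crystal"`.
#' @return A tibble (`isotope`, `state`, `energy`, `mean_r`) with
#'   attribute `r_min` (bond length at the energy minimum, angstrom).
#' @examples
#' ref <- pyp_reference_levels("equilibrium")
#' ref |>
#'   dplyr::group_by(isotope) |>
#'   dplyr::summarise(r_t = thermal_average(mean_r, energy, 300))
#' @export
pyp_reference_levels <- function(structure = c("equilibrium",
                                               "crystal")) {
  structure <- match.arg(structure)
  path <- system.file(
    "extdata", paste0("pyp_", structure, "_levels.tsv"),
    package = "vibhb", mustWork = TRUE
  )
  r_min <- NA_real_
  for (ln in readLines(path)) {
    if (grepl("^#\\s*r_min_angstrom=", ln)) {
      r_min <- as.numeric(sub("^#\\s*r_min_angstrom=", "", ln))
    }
  }
  raw <- read.delim(path, comment.char = "#",
                    stringsAsFactors = FALSE)
  out <- tibble::tibble(
    isotope = raw$isotope,
    state = as.integer(raw$state),
    energy = raw$energy_kcal_per_mol,
    mean_r = raw$mean_R_angstrom
  )
  attr(out, "r_min") <- r_min
  attr(out, "structure") <- structure
  out
}
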