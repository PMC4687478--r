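# Unit system: angstrom (length), amu (mass), kcal/mol (energy).
# hbar^2 is derived from CODATA 2018 SI values and the thermochemical
# calorie; in these units hbar^2/(2 * 1 amu) ~ 0.0482 kcal mol^-1 A^2.
.hbar2 <- local({
  hbar <- 1.054571817e-34 # J s
  amu <- 1.66053906660e-27 # kg
  avogadro <- 6.02214076e23 # mol^-1
  joule_per_kcalmol <- 4184 / avogadro
  hbar^2 / (amu * 1e-20) / joule_per_kcalmol
})

.kB <- 0.0019872041 # kcal mol^-1 K^-1

# Bare nuclear masses: the migrating particle is a lone nucleus moving in
# the frozen field of all other atoms, so no reduced mass is applied.
.mass_presets <- c(H = 1.007276, D = 2.013553)

#' Physical constants used by the solver
#'
#' The package works throughout in angstrom / amu / kcal/mol units. This
#' returns the constants frozen into the package, derived from CODATA
#' values: `hbar2` (\eqn{\hbar^2}, the kinetic-energy prefactor is
#' `hbar2 / (2 m)`), the Boltzmann constant `kB`, and the preset bare
#' nuclear masses of the proton and deuteron.
#'
#' @return A tibble with columns `constant`, `value`, `units`.
#' @examples
#' vib_constants()
#' @export
vib_constants <- function() {
  tibble::tibble(
    constant = c("hbar2", "kB", "mass_H", "mass_D"),
    value = c(.hbar2, .kB, .mass_presets[["H"]], .mass_presets[["D"]]),
    units = c(
      "kcal mol-1 amu angstrom2",
      "kcal mol-1 K-1",
      "amu",
      "amu"
    )
  )
}

#' Nuclear mass of the migrating particle
#'
#' Preset bare nuclear masses are provided for the proton (`"H"`,
#' 1.007276 amu) and the deuteron (`"D"`, 2.013553 amu); any other mass
#' can be supplied explicitly and is labelled `"custom"` unless a label
#' is given.
#'
#' @param isotope `"H"`, `"D"`, or a free-text label for a custom mass.
#' @param mass Mass in amu; required unless `isotope` is a preset.
#' @return A `particle_mass` object (list with `mass`, `isotope_label`).
#' @examples
#' particle_mass("H")
#' particle_mass("custom", mass = 3.0)
#' @export
particle_mass <- function(isotope = "H", mass = NULL) {
  stopifnot(is.character(isotope), length(isotope) == 1L)
  if (is.null(mass)) {
    if (!isotope %in% names(.mass_presets)) {
      abort(
        paste0("no preset mass for isotope '", isotope,
               "'; supply `mass` in amu"),
        class = "vibhb_parameter_error"
      )
    }
    mass <- .mass_presets[[isotope]]
  }
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) ||
      mass <= 0) {
    abort("`mass` must be a single positive finite number (amu)",
          class = "vibhb_parameter_error")
  }
  structure(
    list(mass = as.numeric(mass), isotope_label = isotope),
    class = "particle_mass"
  )
}

# Coerce "H"/"D", a bare number, or a particle_mass to particle_mass.
as_particle_mass <- function(x) {
  if (inherits(x, "particle_mass")) return(x)
  if (is.character(x)) return(particle_mass(x))
  if (is.numeric(x)) return(particle_mass("custom", mass = x))
  abort("cannot interpret `mass`: give \"H\", \"D\", a number in amu, or a particle_mass object",
        class = "vibhb_parameter_error")
}

#' @export
print.particle_mass <- function(x, ...) {
  cat(sprintf("<particle_mass> %s: %.6f amu\n", x$isotope_label, x$mass))
  invisible(x)
}
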