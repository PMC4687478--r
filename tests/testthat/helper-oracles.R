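# Independent closed-form oracles. Constants are derived here from
# CODATA SI values directly, independently of the package's table.
oracle_hbar2 <- local({
  hbar <- 1.054571817e-34
  amu <- 1.66053906660e-27
  avogadro <- 6.02214076e23
  hbar^2 / (amu * 1e-20) / (4184 / avogadro)
})
oracle_kB <- 1.380649e-23 * 6.02214076e23 / 4184

mass_H <- 1.007276
mass_D <- 2.013553

# force constant giving hbar*omega = 1 kcal/mol for m = 1 amu
k_unit <- 1 / oracle_hbar2

harmonic_levels <- function(k, m, n) {
  sqrt(oracle_hbar2 * k / m) * (seq_len(n) - 0.5)
}

morse_levels <- function(d_e, a, m, n) {
  hw <- a * sqrt(2 * d_e * oracle_hbar2 / m)
  v <- seq_len(n) - 0.5
  hw * v - (hw * v)^2 / (4 * d_e)
}

box_levels <- function(box_len, m, n) {
  seq_len(n)^2 * pi^2 * oracle_hbar2 / (2 * m * box_len^2)
}

trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# count interior sign changes of a wavefunction, ignoring noise tails
count_nodes <- function(psi) {
  s <- sign(psi[abs(psi) > 1e-4 * max(abs(psi))])
  sum(diff(s) != 0)
}

solve_quiet <- function(...) suppressWarnings(solve_states(...))
solve_fd_quiet <- function(...) suppressWarnings(solve_states_fd(...))
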