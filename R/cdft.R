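# Conceptual-DFT reactivity descriptors from frontier molecular orbital
# energies (finite-difference / Koopmans-type approximations):
#   chemical potential  mu    ~ (E_LUMO + E_HOMO) / 2      [eV]
#   chemical hardness   eta   ~  E_LUMO - E_HOMO           [eV]
#   softness            S     =  1 / eta                   [1/eV]
#   electrophilicity    omega =  mu^2 / (2 eta)            [eV]
# and condensed Fukui functions from atomic electron populations of the
# N-1, N and N+1 electron states.

check_gap <- function(e_homo, e_lumo) {
  if (any(e_lumo <= e_homo))
    stop("invalid frontier energies: E_LUMO must exceed E_HOMO")
}

#' Chemical potential from frontier orbital energies
#' @param e_homo,e_lumo HOMO and LUMO energies in eV (`e_lumo > e_homo`).
#' @return mu = (e_lumo + e_homo)/2, in eV (the electron escaping tendency;
#'   negative for bound systems).
#' @export
chemical_potential <- function(e_homo, e_lumo) {
  check_gap(e_homo, e_lumo)
  (e_lumo + e_homo) / 2
}

#' Chemical hardness from frontier orbital energies
#' @inheritParams chemical_potential
#' @return eta = e_lumo - e_homo, in eV (> 0): resistance of the species to
#'   change of its electronic configuration.
#' @export
hardness <- function(e_homo, e_lumo) {
  check_gap(e_homo, e_lumo)
  e_lumo - e_homo
}

#' Global softness
#' @param eta Chemical hardness in eV (> 0).
#' @return S = 1/eta, in 1/eV.
#' @export
softness <- function(eta) {
  if (any(eta <= 0)) stop("hardness must be positive")
  1 / eta
}

#' Electrophilicity index
#'
#' Stabilisation energy of the system on saturation with electrons from
#' the environment.
#'
#' @param mu Chemical potential in eV.
#' @param eta Chemical hardness in eV (> 0).
#' @return omega = mu^2 / (2 eta), in eV (>= 0).
#' @export
electrophilicity <- function(mu, eta) {
  if (any(eta <= 0)) stop("hardness must be positive")
  mu^2 / (2 * eta)
}

#' Global reactivity descriptor table
#'
#' Computes mu, eta, S and omega for each row of a frontier-orbital energy
#' table, in the layout of published descriptor tables (4 decimals,
#' half-up) when `rounded = TRUE`; full precision otherwise.
#'
#' @param orbitals Data frame with columns `name`, `E_HOMO`, `E_LUMO` (eV),
#'   e.g. from [read_orbital_table()].
#' @param rounded Round the descriptor columns to 4 decimals (half-up).
#' @return Data frame with columns `name`, `mu`, `eta`, `softness`,
#'   `electrophilicity`.
#' @examples
#' tab <- data.frame(name = "x", E_HOMO = -7.4227, E_LUMO = -1.9295)
#' reactivity_table(tab)
#' @export
reactivity_table <- function(orbitals, rounded = TRUE) {
  stopifnot(all(c("name", "E_HOMO", "E_LUMO") %in% names(orbitals)))
  mu <- chemical_potential(orbitals$E_HOMO, orbitals$E_LUMO)
  eta <- hardness(orbitals$E_HOMO, orbitals$E_LUMO)
  out <- data.frame(name = orbitals$name, mu = mu, eta = eta,
                    softness = softness(eta),
                    electrophilicity = electrophilicity(mu, eta))
  if (rounded)
    for (cc in c("mu", "eta", "softness", "electrophilicity"))
      out[[cc]] <- round_half_up(out[[cc]], 4)
  out
}

#' Condensed Fukui functions from atomic populations
#'
#' Finite-difference condensed Fukui functions per atom:
#' \eqn{f_k^+ = q_k(N+1) - q_k(N)} (susceptibility to nucleophilic attack)
#' and \eqn{f_k^- = q_k(N) - q_k(N-1)} (electrophilic attack), where
#' `q_k` are atomic *electron populations*. If the table holds net atomic
#' charges instead, set `input = "charge"` and the signs are converted
#' (population = -charge up to the nuclear constant, which cancels in the
#' differences).
#'
#' @param pop Data frame with columns `atom_id`, `q_Nminus1`, `q_N`,
#'   `q_Nplus1` (one molecule; see [read_population_table()]).
#' @param input `"population"` (default) or `"charge"`.
#' @return Data frame with columns `atom_id`, `f_plus`, `f_minus`, and
#'   logical flags `max_f_plus`, `max_f_minus` marking the preferred
#'   nucleophilic- and electrophilic-attack sites.
#' @export
fukui_functions <- function(pop, input = c("population", "charge")) {
  input <- match.arg(input)
  req <- c("atom_id", "q_Nminus1", "q_N", "q_Nplus1")
  miss <- setdiff(req, names(pop))
  if (length(miss) > 0)
    stop("population table missing column(s): ", paste(miss, collapse = ", "))
  s <- if (input == "population") 1 else -1
  f_plus <- s * (pop$q_Nplus1 - pop$q_N)
  f_minus <- s * (pop$q_N - pop$q_Nminus1)
  data.frame(atom_id = pop$atom_id, f_plus = f_plus, f_minus = f_minus,
             max_f_plus = seq_along(f_plus) == which.max(f_plus),
             max_f_minus = seq_along(f_minus) == which.max(f_minus))
}

#' Write a reactivity descriptor table as CSV
#' @param tab Output of [reactivity_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_reactivity_csv <- function(tab, path) {
  out <- data.frame(Compound = tab$name,
                    `C.Potential.eV` = sprintf("%.4f", tab$mu),
                    `C.Hardness.eV` = sprintf("%.4f", tab$eta),
                    `Softness.1.eV` = sprintf("%.4f", tab$softness),
                    `Electrophilicity.eV` = sprintf("%.4f",
                                                    tab$electrophilicity),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
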