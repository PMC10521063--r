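# Synthetic-data generators with known ground truth. They emulate the
# study design this package targets: a congeneric series of rigid
# macrocyclic ligands differing only at two substitution sites, a pocket
# of pseudo-residues with an additive pairwise energy model (so the
# per-residue decomposition has an exact oracle), activities planted as a
# linear function of grid-field columns, and descriptor tables with known
# values. Every generator is a pure function of (seed, parameters).

# -- rigid macrocyclic scaffold ----------------------------------------
# 12-membered ring (10 C, 1 N, 1 O), radius 2.8 A, fixed pucker; two
# designated substitution sites. Deterministic: the series shares these
# coordinates exactly.
scaffold_atoms <- function() {
  n <- 12
  ang <- 2 * pi * (seq_len(n) - 1) / n
  el <- rep("C", n); el[4] <- "N"; el[10] <- "O"
  q <- rep(0.00, n); q[4] <- -0.30; q[10] <- -0.35
  q[c(3, 5)] <- 0.15; q[c(9, 11)] <- 0.17   # atoms flanking heteroatoms
  data.frame(element = el,
             x = 2.8 * cos(ang), y = 2.8 * sin(ang),
             z = 0.35 * rep_len(c(1, -1), n),
             charge = q)
}

scaffold_sites <- function() c(2L, 8L)  # the two substitution sites

#' Default substituent library for the synthetic ligand series
#'
#' Small rigid groups (local coordinates: x outward from the ring, z along
#' the ring normal) with fixed partial charges, covering hydrogen-bond
#' donors/acceptors and bulky/apolar cases.
#'
#' @return Named list; each entry has `atoms` (element, x, y, z, charge)
#'   and `bonds` (indices local to the group, 0 = the ring site atom).
#' @export
default_substituents <- function() {
  g <- function(el, x, y, z, q, bonds)
    list(atoms = data.frame(element = el, x = x, y = y, z = z, charge = q),
         bonds = bonds)
  list(
    H    = g("H", 1.0, 0, 0, 0.05, rbind(c(0, 1))),
    OH   = g(c("O", "H"), c(1.40, 1.80), c(0, 0.85), c(0, 0),
             c(-0.40, 0.30), rbind(c(0, 1), c(1, 2))),
    OMe  = g(c("O", "C"), c(1.40, 2.25), c(0, 1.15), c(0, 0),
             c(-0.35, 0.10), rbind(c(0, 1), c(1, 2))),
    NH2  = g(c("N", "H", "H"), c(1.40, 1.95, 1.95), c(0, 0.80, -0.80),
             c(0, 0.3, -0.3), c(-0.50, 0.25, 0.25),
             rbind(c(0, 1), c(1, 2), c(1, 3))),
    Me   = g("C", 1.52, 0, 0, 0.00, rbind(c(0, 1))),
    keto = g("O", 1.25, 0, 0, -0.45, rbind(c(0, 1))),
    F    = g("F", 1.35, 0, 0, -0.20, rbind(c(0, 1))),
    NMe2 = g(c("N", "C", "C"), c(1.40, 2.10, 2.10), c(0, 1.20, -1.20),
             c(0, 0.2, -0.2), c(-0.35, 0.05, 0.05),
             rbind(c(0, 1), c(1, 2), c(1, 3)))
  )
}

# local substituent frame at a ring site: x -> outward radial, y -> in
# plane tangent, z -> ring normal.
site_frame <- function(p) {
  u <- c(p[1], p[2], 0); u <- u / sqrt(sum(u^2))
  w <- c(0, 0, 1)
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

#' Generate a rigid congeneric ligand series
#'
#' All ligands share the scaffold coordinates exactly and differ only in
#' the substituents placed at the two designated ring sites, drawn from
#' the library under the given seed.
#'
#' @param seed Integer RNG seed.
#' @param n Number of ligands (>= 1).
#' @param substituents Substituent library, see [default_substituents()].
#' @return List of `molecule`s named `L01`, `L02`, ...; each carries
#'   attributes `sub1`, `sub2` (library keys used at the two sites).
#' @export
gen_ligand_series <- function(seed, n, substituents = default_substituents()) {
  stopifnot(n >= 1)
  if (length(substituents) == 0) stop("empty substituent library")
  base <- scaffold_atoms()
  sites <- scaffold_sites()
  ring_bonds <- cbind(seq_len(nrow(base)),
                      c(seq_len(nrow(base))[-1], 1L))
  keys <- names(substituents)
  pick <- withr_seed(seed, function() {
    matrix(sample(keys, 2 * n, replace = TRUE), ncol = 2)
  })
  lapply(seq_len(n), function(i) {
    atoms <- base
    bonds <- ring_bonds
    subs <- pick[i, ]
    for (s in 1:2) {
      site <- sites[s]
      lib <- substituents[[subs[s]]]
      Fm <- site_frame(as.numeric(base[site, c("x", "y", "z")]))
      loc <- as.matrix(lib$atoms[, c("x", "y", "z")])
      glob <- loc %*% t(Fm) +
        matrix(as.numeric(base[site, c("x", "y", "z")]),
               nrow(loc), 3, byrow = TRUE)
      off <- nrow(atoms)
      atoms <- rbind(atoms, data.frame(element = lib$atoms$element,
                                       x = glob[, 1], y = glob[, 2],
                                       z = glob[, 3],
                                       charge = lib$atoms$charge))
      bb <- lib$bonds
      bb_i <- ifelse(bb[, 1] == 0, site, bb[, 1] + off)
      bb_j <- ifelse(bb[, 2] == 0, site, bb[, 2] + off)
      bonds <- rbind(bonds, cbind(bb_i, bb_j))
    }
    m <- molecule(sprintf("L%02d", i), atoms, bonds, role = "ligand")
    attr(m, "sub1") <- subs[1]; attr(m, "sub2") <- subs[2]
    m
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# -- additive toy energy model -----------------------------------------

#' Pairwise Lennard-Jones + Coulomb energy between two molecules
#'
#' The additive toy Hamiltonian of the synthetic pocket:
#' \eqn{\sum 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + 332.0636 q_1
#' q_2 / r} over all intermolecular atom pairs (kcal/mol).
#'
#' @param mol_a,mol_b `molecule`s with partial charges.
#' @param epsilon LJ well depth, kcal/mol (default 0.1).
#' @param sigma LJ zero-crossing distance, Angstrom (default 3.4).
#' @return Scalar energy in kcal/mol.
#' @export
pair_interaction <- function(mol_a, mol_b, epsilon = 0.1, sigma = 3.4) {
  xa <- coords(mol_a); xb <- coords(mol_b)
  qa <- mol_a$atoms$charge; qb <- mol_b$atoms$charge
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  r <- sqrt(pmax(d2, 1e-12))
  sr6 <- (sigma / r)^6
  sum(4 * epsilon * (sr6^2 - sr6) + .coulomb_k * outer(qa, qb) / r)
}

# internal (non-bonded intramolecular) energy under the same Hamiltonian;
# any consistent definition cancels in E_AM - E_L - E_M.
self_energy <- function(mol, epsilon = 0.1, sigma = 3.4) {
  x <- coords(mol); q <- mol$atoms$charge
  n <- nrow(x)
  if (n < 2) return(0)
  bonded <- matrix(FALSE, n, n)
  if (nrow(mol$bonds) > 0)
    bonded[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) next
    r <- max(sqrt(sum((x[i, ] - x[j, ])^2)), 1e-6)
    sr6 <- (sigma / r)^6
    e <- e + 4 * epsilon * (sr6^2 - sr6) + .coulomb_k * q[i] * q[j] / r
  }
  e
}

# pseudo-residue templates: charged donor/acceptor and apolar probes
residue_templates <- function() {
  list(
    Lys = data.frame(element = c("N", "H", "C"),
                     x = c(0, 0.6, -1.4), y = c(0, 0.8, 0.3), z = 0,
                     charge = c(0.20, 0.35, 0.05)),
    Asp = data.frame(element = c("C", "O", "O"),
                     x = c(0, 1.1, -0.6), y = c(0, 0.6, 1.0), z = 0,
                     charge = c(0.30, -0.45, -0.45)),
    Gly = data.frame(element = c("C", "N"),
                     x = c(0, 1.4), y = 0, z = 0,
                     charge = c(0.05, -0.05))
  )
}

#' Generate a pseudo-residue pocket with consistent energy tables
#'
#' Places `n_residues` small pseudo-residues around the ligand at seeded
#' random directions and distances, and evaluates the additive toy
#' Hamiltonian to produce mutually consistent energy tables:
#' `E_AM = E_L + E_M + interaction`, so the true per-residue interaction
#' terms are known exactly.
#'
#' @param seed Integer RNG seed.
#' @param ligand A `molecule` with charges (e.g. from
#'   [gen_ligand_series()]).
#' @param n_residues Number of pseudo-residues (>= 1).
#' @param r_range Distance range (Angstrom) of residue anchors from the
#'   ligand centroid, default `c(5, 11)`.
#' @return List with `residues` (a `residue_set`), `complex_energies`
#'   (ligand, residue, energy), `ligand_energies`, `residue_energies`
#'   (system_id, energy) and `truth` (residue, interaction): the exact
#'   pairwise interaction terms.
#' @export
gen_pocket <- function(seed, ligand, n_residues, r_range = c(5, 11)) {
  stopifnot(n_residues >= 1)
  tmpl <- residue_templates()
  placed <- withr_seed(seed, function() {
    lapply(seq_len(n_residues), function(k) {
      type <- sample(names(tmpl), 1)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- stats::runif(1, r_range[1], r_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      list(type = type, dir = u, dist = r, spin = ang)
    })
  })
  cen <- colMeans(coords(ligand))
  res_list <- lapply(seq_along(placed), function(k) {
    pl <- placed[[k]]
    at <- tmpl[[pl$type]]
    # spin the template about z, then translate to the anchor
    cs <- cos(pl$spin); sn <- sin(pl$spin)
    x <- at$x * cs - at$y * sn
    y <- at$x * sn + at$y * cs
    anchor <- cen + pl$dir * pl$dist
    molecule(sprintf("%s%d", pl$type, k),
             data.frame(element = at$element,
                        x = x + anchor[1], y = y + anchor[2],
                        z = at$z + anchor[3], charge = at$charge),
             role = "residue")
  })
  rset <- residue_set(res_list)
  e_l <- self_energy(ligand)
  res_rows <- lapply(res_list, function(r) {
    e_m <- self_energy(r)
    inter <- pair_interaction(ligand, r)
    data.frame(residue = r$name, e_m = e_m, inter = inter)
  })
  rr <- do.call(rbind, res_rows)
  list(
    residues = rset,
    complex_energies = data.frame(ligand = ligand$name, residue = rr$residue,
                                  energy = e_l + rr$e_m + rr$inter),
    ligand_energies = data.frame(system_id = ligand$name, energy = e_l),
    residue_energies = data.frame(system_id = rr$residue, energy = rr$e_m),
    truth = data.frame(residue = rr$residue, interaction = rr$inter)
  )
}

#' Energy tables for a ligand series against a fixed pocket
#'
#' Evaluates the toy Hamiltonian for every ligand-residue combination,
#' yielding the three mutually consistent tables the interaction-energy
#' stage consumes.
#'
#' @param ligands List of `molecule`s with charges.
#' @param residues A `residue_set`.
#' @return List with `complex_energies` (ligand, residue, energy),
#'   `ligand_energies` and `residue_energies` (system_id, energy), and
#'   `truth` (ligand, residue, interaction).
#' @export
pocket_energy_tables <- function(ligands, residues) {
  if (inherits(residues, "residue_set")) residues <- residues$residues
  e_m <- vapply(residues, self_energy, numeric(1))
  rows <- list(); truth <- list()
  lig_e <- numeric(length(ligands))
  for (i in seq_along(ligands)) {
    lig <- ligands[[i]]
    lig_e[i] <- self_energy(lig)
    for (j in seq_along(residues)) {
      inter <- pair_interaction(lig, residues[[j]])
      rows[[length(rows) + 1]] <- data.frame(
        ligand = lig$name, residue = residues[[j]]$name,
        energy = lig_e[i] + e_m[j] + inter)
      truth[[length(truth) + 1]] <- data.frame(
        ligand = lig$name, residue = residues[[j]]$name,
        interaction = inter)
    }
  }
  list(
    complex_energies = do.call(rbind, rows),
    ligand_energies = data.frame(
      system_id = vapply(ligands, function(m) m$name, character(1)),
      energy = lig_e),
    residue_energies = data.frame(
      system_id = vapply(residues, function(r) r$name, character(1)),
      energy = unname(e_m)),
    truth = do.call(rbind, truth)
  )
}

#' Generate activities with a planted linear field dependence
#'
#' `y = X beta`, affinely rescaled into the observed pIC50 range
#' `[5.57, 8.04]` of the reference data set, plus `N(0, sigma^2)` noise.
#' The pre-noise values and the planted coefficients are retained for
#' parameter-recovery tests.
#'
#' @param X Numeric field matrix (rows = ligands).
#' @param beta Coefficient vector, `length(beta) == ncol(X)`.
#' @param sigma Noise standard deviation (pIC50 units).
#' @param seed Integer RNG seed.
#' @param range Target activity range, default `c(5.57, 8.04)`.
#' @return List with `y` (named by rownames of `X`), and `truth`
#'   (`beta`, `y_true` pre-noise, `sigma`, `seed`).
#' @export
gen_activities <- function(X, beta, sigma, seed, range = c(5.57, 8.04)) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X))
    stop("beta length (", length(beta), ") != ncol(X) (", ncol(X), ")")
  raw <- as.vector(X %*% beta)
  span <- diff(base::range(raw))
  y_true <- if (span > 0) {
    (raw - min(raw)) / span * diff(range) + range[1]
  } else {
    rep(mean(range), length(raw))
  }
  noise <- withr_seed(seed, function() stats::rnorm(length(raw), 0, sigma))
  y <- y_true + noise
  names(y) <- rownames(X)
  list(y = y, truth = list(beta = beta, y_true = y_true, sigma = sigma,
                           seed = seed))
}

#' Generate frontier-orbital and population tables with known descriptors
#'
#' Orbital energies are drawn with HOMO in [-8, -6] eV and gap in [4, 7]
#' eV (bracketing typical closed-shell organic values); atomic populations
#' conserve exactly one electron between the N and N +/- 1 states, so the
#' condensed Fukui functions sum to 1 by construction.
#'
#' @param seed Integer RNG seed.
#' @param names Compound names (nonempty).
#' @param n_atoms Atoms per compound in the population table, default 6.
#' @return List with `orbitals` (name, E_HOMO, E_LUMO) and `populations`
#'   (name, atom_id, q_Nminus1, q_N, q_Nplus1).
#' @export
gen_descriptor_tables <- function(seed, names, n_atoms = 6) {
  stopifnot(length(names) >= 1)
  withr_seed(seed, function() {
    homo <- stats::runif(length(names), -8, -6)
    gap <- stats::runif(length(names), 4, 7)
    orb <- data.frame(name = names, E_HOMO = homo, E_LUMO = homo + gap)
    pops <- lapply(seq_along(names), function(i) {
      q_n <- stats::runif(n_atoms, 0.5, 8)
      fp <- stats::rgamma(n_atoms, 1); fp <- fp / sum(fp)
      fm <- stats::rgamma(n_atoms, 1); fm <- fm / sum(fm)
      data.frame(name = names[i], atom_id = seq_len(n_atoms),
                 q_Nminus1 = q_n - fm, q_N = q_n, q_Nplus1 = q_n + fp)
    })
    list(orbitals = orb, populations = do.call(rbind, pops))
  })
}

#' Compose a full synthetic scenario
#'
#' Generates the ligand series, a shared pocket around the series frame
#' with consistent energy tables, the field matrix, planted-coefficient
#' activities, and descriptor tables — everything the pipeline consumes,
#' with ground truth attached. Activities are planted on the `n_signal`
#' highest-variance field columns.
#'
#' @param seed Integer RNG seed; sub-generators use fixed offsets of it.
#' @param n_ligands Number of ligands, default 40.
#' @param n_residues Pseudo-residues in the pocket, default 10.
#' @param sigma Activity noise SD (pIC50 units), default 0.1.
#' @param n_signal Number of planted field columns, default 3.
#' @param spacing Field grid spacing, Angstrom, default 2.
#' @return List with components `ligands`, `pocket`, `grid`, `X` (field
#'   matrix), `activities`, `descriptors`, `truth` (planted columns,
#'   coefficients, true component count) and `seed`.
#' @export
synthetic_scenario <- function(seed, n_ligands = 40, n_residues = 10,
                               sigma = 0.1, n_signal = 3, spacing = 2.0) {
  ligands <- gen_ligand_series(seed, n_ligands)
  pocket <- gen_pocket(seed + 1L, ligands[[1]], n_residues)
  grid <- field_grid(ligands, spacing = spacing)
  X <- compute_fields(ligands, grid)
  keep <- usable_columns(X)
  ord <- keep[order(apply(X[, keep, drop = FALSE], 2, stats::sd),
                    decreasing = TRUE)]
  planted <- sort(ord[seq_len(min(n_signal, length(ord)))])
  beta_full <- numeric(ncol(X))
  beta_vals <- withr_seed(seed + 2L, function()
    stats::runif(length(planted), 0.5, 1.5) *
      rep_len(c(1, -1), length(planted)))
  beta_full[planted] <- beta_vals
  act <- gen_activities(X, beta_full, sigma, seed + 3L)
  desc <- gen_descriptor_tables(seed + 4L,
                                vapply(ligands, function(m) m$name,
                                       character(1)))
  list(ligands = ligands, pocket = pocket, grid = grid, X = X,
       activities = act$y,
       descriptors = desc,
       truth = list(planted_columns = planted, beta = beta_vals,
                    y_true = act$truth$y_true, sigma = sigma,
                    n_components = length(planted)),
       seed = seed)
}
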