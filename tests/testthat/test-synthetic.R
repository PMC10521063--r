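test_that("ligand series are deterministic, share the scaffold, and differ
           only at the substitution sites", {
  s1 <- gen_ligand_series(42, 5)
  s2 <- gen_ligand_series(42, 5)
  expect_identical(lapply(s1, coords), lapply(s2, coords))
  expect_identical(vapply(s1, function(m) attr(m, "sub1"), character(1)),
                   vapply(s2, function(m) attr(m, "sub1"), character(1)))
  ns <- nrow(mqsar:::scaffold_atoms())
  scafs <- lapply(s1, function(m) coords(m)[seq_len(ns), ])
  for (k in 2:5) expect_identical(scafs[[k]], scafs[[1]])
  # a different seed reshuffles the substituents
  s3 <- gen_ligand_series(43, 5)
  expect_false(identical(vapply(s1, n_atoms, integer(1)),
                         vapply(s3, n_atoms, integer(1))) &&
                 identical(lapply(s1, coords), lapply(s3, coords)))
  expect_error(gen_ligand_series(1, 3, substituents = list()),
               "empty substituent library")
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(1234)
  a <- rnorm(1)
  set.seed(1234)
  invisible(gen_ligand_series(9, 2))
  expect_identical(rnorm(1), a)
})

test_that("the toy pocket energies are additive and consistent", {
  set.seed(2)
  lig <- gen_ligand_series(7, 1)[[1]]
  pocket <- gen_pocket(8, lig, 6)
  # E_AM - E_L - E_M reproduces the stored truth exactly
  prof <- build_profile(pocket$complex_energies, pocket$ligand_energies,
                        pocket$residue_energies, lig$name)
  expect_equal(prof$IE, pocket$truth$interaction[
    match(prof$residue, pocket$truth$residue)], tolerance = 1e-12)
  # additivity: summed per-residue truths equal the ligand interaction
  # with the merged pocket
  allres <- do.call(rbind, lapply(pocket$residues$residues, function(r)
    r$atoms[, c("element", "x", "y", "z", "charge")]))
  merged <- molecule("pocket", allres, role = "complex-member")
  expect_equal(sum(pocket$truth$interaction), pair_interaction(lig, merged),
               tolerance = 1e-9)
  # a residue placed very far interacts negligibly
  farpocket <- gen_pocket(8, lig, 1, r_range = c(400, 500))
  expect_lt(abs(farpocket$truth$interaction), 1e-3)
})

test_that("opposite charges at hydrogen-bond distance attract in the toy
           Hamiltonian", {
  don <- molecule("don", data.frame(element = "O", x = 0, y = 0, z = 0,
                                    charge = -0.4), role = "residue")
  acc <- molecule("acc", data.frame(element = "N", x = 3.0, y = 0, z = 0,
                                    charge = 0.4), role = "residue")
  expect_lt(pair_interaction(don, acc), 0)
})

test_that("planted activities are reproducible, exact at zero noise, and
           carry the requested noise level", {
  set.seed(3)
  X <- matrix(rnorm(200 * 6), 200)
  beta <- c(1, -2, 0.5, 0, 0, 1)
  a0 <- gen_activities(X, beta, sigma = 0, seed = 10)
  expect_equal(a0$y, a0$truth$y_true)
  expect_equal(range(a0$y), c(5.57, 8.04), tolerance = 1e-9)
  a1 <- gen_activities(X, beta, sigma = 0.1, seed = 10)
  a2 <- gen_activities(X, beta, sigma = 0.1, seed = 10)
  expect_identical(a1$y, a2$y)
  expect_equal(sd(a1$y - a1$truth$y_true), 0.1, tolerance = 0.2)
  expect_error(gen_activities(X, beta[-1], 0.1, 1), "beta length")
})

test_that("generated descriptor tables satisfy the descriptor identities", {
  d <- gen_descriptor_tables(17, paste0("c", 1:8))
  expect_true(all(d$orbitals$E_LUMO > d$orbitals$E_HOMO))
  gaps <- d$orbitals$E_LUMO - d$orbitals$E_HOMO
  expect_true(all(gaps >= 4 & gaps <= 7))
  tab <- reactivity_table(d$orbitals, rounded = FALSE)
  expect_equal(tab$electrophilicity, tab$mu^2 / (2 * tab$eta))
  expect_equal(tab$softness, 1 / tab$eta)
  for (nm in unique(d$populations$name)) {
    f <- fukui_functions(d$populations[d$populations$name == nm, ])
    expect_equal(sum(f$f_plus), 1, tolerance = 1e-9)
    expect_equal(sum(f$f_minus), 1, tolerance = 1e-9)
  }
})

test_that("scenario composition is reproducible and its truth record is
           self-consistent", {
  sc1 <- synthetic_scenario(5, n_ligands = 8, n_residues = 4)
  sc2 <- synthetic_scenario(5, n_ligands = 8, n_residues = 4)
  expect_identical(sc1$activities, sc2$activities)
  expect_identical(sc1$X, sc2$X)
  expect_equal(length(sc1$truth$planted_columns), sc1$truth$n_components)
  # the planted columns are usable (not filtered) field columns
  expect_true(all(sc1$truth$planted_columns %in%
                    mqsar:::usable_columns(sc1$X)))
})
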