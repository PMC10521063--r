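unit_shell <- function(x = 0) {
  structure(list(shells = data.frame(x = x, y = 0, z = 0, alpha = 1, ne = 1),
                 molecule = "u"), class = "density_model")
}

test_that("overlap measure matches the Gaussian-product closed form", {
  a <- unit_shell()
  expect_equal(overlap_similarity(a, a), (1 / (2 * pi))^1.5,
               tolerance = 1e-12)
  expect_equal(overlap_similarity(a, unit_shell(50)), 0, tolerance = 1e-100)
  set.seed(21)
  for (k in 1:5) {
    m1 <- rand_shell_model(sample(2:5, 1))
    m2 <- rand_shell_model(sample(2:5, 1))
    expect_equal(overlap_similarity(m1, m2), overlap_similarity(m2, m1))
  }
})

test_that("Coulomb measure matches its closed form and limits", {
  a <- unit_shell()
  expect_equal(coulomb_similarity(a, a), 2 * sqrt(0.5 / pi),
               tolerance = 1e-12)
  # far apart: point-charge limit 1/R
  expect_equal(coulomb_similarity(a, unit_shell(10)), 0.1, tolerance = 1e-10)
  # bilinearity: doubling the electrons of one side doubles Z
  b2 <- unit_shell(3); b2$shells$ne <- 2
  expect_equal(coulomb_similarity(a, b2),
               2 * coulomb_similarity(a, unit_shell(3)), tolerance = 1e-12)
})

test_that("analytic measures agree with independent quadrature", {
  skip_if_not_installed("pracma")
  set.seed(77)
  for (k in 1:4) {
    a <- rand_shell_model(sample(2:6, 1))
    b <- rand_shell_model(sample(2:6, 1))
    zo <- overlap_similarity(a, b)
    zc <- coulomb_similarity(a, b)
    expect_equal(zo, quad_overlap(a, b), tolerance = 1e-6)
    expect_equal(zc, quad_coulomb(a, b), tolerance = 1e-4)
  }
})

test_that("Carbo index: arithmetic, bounds, identity", {
  expect_equal(carbo_index(4, 9, 5), 5 / 6)
  expect_error(carbo_index(0, 9, 5), "positive")
  a <- unit_shell()
  expect_equal(carbo_index(overlap_similarity(a, a), overlap_similarity(a, a),
                           overlap_similarity(a, a)), 1)
  set.seed(13)
  for (k in 1:10) {
    m1 <- rand_shell_model(3); m2 <- rand_shell_model(3)
    ci <- carbo_index(overlap_similarity(m1, m1), overlap_similarity(m2, m2),
                      overlap_similarity(m1, m2))
    expect_gt(ci, 0)
    expect_lte(ci, 1 + 1e-12)  # Cauchy-Schwarz
  }
})

test_that("Carbo index is invariant under uniform electron scaling", {
  set.seed(3)
  m1 <- rand_shell_model(4); m2 <- rand_shell_model(4)
  base <- carbo_index(overlap_similarity(m1, m1), overlap_similarity(m2, m2),
                      overlap_similarity(m1, m2))
  m1$shells$ne <- m1$shells$ne * 3.7
  m2$shells$ne <- m2$shells$ne * 3.7
  scaled <- carbo_index(overlap_similarity(m1, m1),
                        overlap_similarity(m2, m2),
                        overlap_similarity(m1, m2))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("generalised distance family: examples, limits, errors", {
  expect_equal(generalized_distance(4, 9, 5, 2, 2), sqrt(3))
  expect_equal(generalized_distance(4, 9, 5, 2, 0), sqrt(13))
  expect_equal(generalized_distance(7, 7, 7, 2, 2), 0)  # identical objects
  expect_error(generalized_distance(1, 1, 10, 2, 2), "radicand")
  expect_error(generalized_distance(1, 1, 0, 2, 3), "<= k")
  expect_equal(infinite_order_distance(4, 9), 9)
  expect_equal(infinite_order_distance(4, 4), 4)
  expect_equal(infinite_order_distance(9, 4), infinite_order_distance(4, 9))
})

test_that("Euclidean distance index satisfies the metric axioms", {
  set.seed(41)
  for (rep in 1:8) {
    ms <- lapply(1:3, function(i) rand_shell_model(sample(2:4, 1)))
    Z <- outer(1:3, 1:3, Vectorize(function(i, j)
      overlap_similarity(ms[[i]], ms[[j]])))
    d <- function(i, j) euclidean_distance_index(Z[i, i], Z[j, j], Z[i, j])
    expect_equal(d(1, 1), 0, tolerance = 1e-8)
    expect_equal(d(1, 2), d(2, 1))
    expect_gte(d(1, 2), 0)
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-9)
  }
})

test_that("Z is invariant under a common rigid motion of both molecules", {
  set.seed(9)
  w1 <- rand_toy_molecule(5, "a"); w2 <- rand_toy_molecule(5, "b")
  d1 <- build_density(w1); d2 <- build_density(w2)
  R <- rand_rotation(); tr <- c(-3, 5, 1)
  d1q <- build_density(transform_molecule(w1, R, tr))
  d2q <- build_density(transform_molecule(w2, R, tr))
  expect_equal(overlap_similarity(d1q, d2q), overlap_similarity(d1, d2),
               tolerance = 1e-10)
  expect_equal(coulomb_similarity(d1q, d2q), coulomb_similarity(d1, d2),
               tolerance = 1e-10)
})

test_that("similarity_matrix reproduces per-pair calls and its index
           matrices have the right structure", {
  set.seed(55)
  mols <- gen_ligand_series(8, 3)
  sm <- similarity_matrix(mols, "overlap", align = FALSE)
  # oracle: direct per-pair computation
  d <- lapply(mols, build_density)
  for (i in 1:3) for (j in 1:3)
    expect_equal(sm$Z[i, j], overlap_similarity(d[[i]], d[[j]]),
                 tolerance = 1e-12)
  expect_true(isSymmetric(sm$Z))
  expect_equal(unname(diag(sm$carbo)), rep(1, 3))
  expect_equal(unname(diag(sm$euclidean)), rep(0, 3))
  # three copies of one molecule: Carbo all 1, Euclidean all 0
  copies <- lapply(1:3, function(i) {
    m <- mols[[1]]; m$name <- paste0("c", i); m
  })
  smc <- similarity_matrix(copies, "overlap", align = FALSE)
  expect_equal(unname(smc$carbo), matrix(1, 3, 3), tolerance = 1e-10)
  expect_equal(max(abs(smc$euclidean)), 0, tolerance = 1e-5)
})

test_that("lower-triangle CSV export writes 4-decimal tables", {
  set.seed(55)
  mols <- gen_ligand_series(8, 3)
  sm <- similarity_matrix(mols, "overlap", align = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  export_similarity_csv(sm, f, "carbo")
  tab <- read.csv(f, check.names = FALSE)
  expect_equal(tab$name, sm$labels)
  expect_equal(as.numeric(tab[[2]][1]), 1)
  expect_true(is.na(tab[[4]][1]) || tab[[4]][1] == "")  # upper triangle blank
})
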