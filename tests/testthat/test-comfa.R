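# small helper: a grid object with hand-chosen probe points
manual_grid <- function(points, origin = c(-50, -50, -50), span = 100,
                        probe = list(element = "C", charge = 1.0,
                                     epsilon = 0.1, sigma = 3.4)) {
  structure(list(origin = origin, spacing = span, dims = c(2L, 2L, 2L),
                 points = points, probe = probe),
            class = "field_grid")
}

test_that("electrostatic field follows the distance-dependent-dielectric
           Coulomb law and the cap", {
  at <- molecule("ion", data.frame(element = "N", x = 0, y = 0, z = 0,
                                   charge = 1))
  g <- manual_grid(rbind(c(1, 0, 0), c(100, 0, 0)))
  X <- compute_fields(list(at), g)
  # 332.0636 * 1 * 1 / (1 * 1^2) = 332.06 kcal/mol, capped at +30
  expect_equal(unname(X[1, "e_1"]), 30)
  # uncapped value at 25 A: 332.0636 / 625
  expect_equal({
    g2 <- manual_grid(rbind(c(25, 0, 0), c(100, 0, 0)))
    unname(compute_fields(list(at), g2)[1, "e_1"])
  }, 332.0636 / 625, tolerance = 1e-9)
  # far point: both fields essentially zero
  expect_lt(abs(X[1, "e_2"]), 0.05)
  expect_lt(abs(X[1, "s_2"]), 1e-6)
  expect_error(compute_fields(list(), g), "empty molecule list")
})

test_that("steric field is the probe Lennard-Jones energy, capped", {
  at <- molecule("c", data.frame(element = "C", x = 0, y = 0, z = 0,
                                 charge = 0))
  sig <- (mqsar:::atom_lj_sigma("C") + 3.4) / 2
  r <- 3.9
  g <- manual_grid(rbind(c(r, 0, 0), c(0.5, 0, 0)))
  X <- compute_fields(list(at), g)
  expect_equal(unname(X[1, "s_1"]),
               4 * sqrt(0.1 * 0.1) * ((sig / r)^12 - (sig / r)^6),
               tolerance = 1e-9)
  expect_equal(unname(X[1, "s_2"]), 30)  # deep core contact hits the cap
})

test_that("fields are invariant under a common rigid motion of molecules
           and grid", {
  set.seed(61)
  mols <- gen_ligand_series(14, 3)
  grid <- field_grid(mols, spacing = 3)
  X <- compute_fields(mols, grid)
  R <- rand_rotation(); tr <- c(4, -6, 2)
  molsq <- lapply(mols, transform_molecule, rotation = R, translation = tr)
  gridq <- grid
  gridq$points <- sweep(grid$points %*% t(R), 2, tr, "+")
  gridq$origin <- c(-100, -100, -100); gridq$dims <- c(2L, 2L, 2L)
  gridq$spacing <- 200  # disable the bounding-box check, geometry is moved
  Xq <- compute_fields(molsq, gridq)
  expect_equal(unname(Xq), unname(X), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the grid must enclose every molecule and charges are required", {
  mols <- gen_ligand_series(14, 2)
  grid <- field_grid(mols[1], spacing = 3, margin = 1)
  far <- transform_molecule(mols[[2]], diag(3), c(50, 0, 0))
  expect_error(compute_fields(list(far), grid), "outside the field grid")
  nochg <- mols[[1]]
  nochg$atoms$charge <- NA_real_
  expect_error(compute_fields(list(nochg), grid), "partial charges")
})

test_that("PLS fits an exact linear field dependence and R2 is monotone in
           the component count", {
  set.seed(71)
  n <- 25
  # y exactly linear in all 3 field columns: 3 components give an exact fit
  X <- matrix(rnorm(n * 3), n)
  y <- as.vector(X %*% c(2, -1, 0.5))
  fit <- fit_pls(X, y, 3, min_sd = 0, block_scale = FALSE)
  expect_gte(fit$r2, 0.999)
  # training R2 never decreases with the component count on fixed data
  Xw <- matrix(rnorm(n * 10), n)
  yw <- as.vector(Xw %*% rnorm(10)) + rnorm(n, 0, 0.5)
  r2s <- vapply(1:6, function(k)
    fit_pls(Xw, yw, k, min_sd = 0, block_scale = FALSE)$r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-10))
  expect_error(fit_pls(X, rep(1, n), 2, min_sd = 0), "constant activity")
  expect_error(fit_pls(X, y, n + 1, min_sd = 0), "n_components")
})

test_that("NIPALS PLS agrees with the independent Krylov-subspace oracle", {
  set.seed(81)
  for (k in c(1, 3, 5)) {
    X <- matrix(rnorm(30 * 12), 30)
    y <- rnorm(30)
    fit <- fit_pls(X, y, k, min_sd = 0, block_scale = FALSE)
    expect_equal(fit$fitted, krylov_pls_fitted(X, y, k), tolerance = 1e-6)
  }
})

test_that("field-block contributions are percentages summing to 100", {
  set.seed(91)
  X <- matrix(rnorm(20 * 10), 20)
  attr(X, "field") <- rep(c("steric", "electrostatic"), each = 5)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 2, min_sd = 0)
  expect_equal(sum(fit$contributions), 100, tolerance = 1e-6)
  expect_true(all(fit$contributions >= 0))
  expect_setequal(names(fit$contributions), c("steric", "electrostatic"))
})

test_that("leave-one-out q2 is near 1 for noiseless signal and <= 0 for
           unrelated activities", {
  set.seed(111)
  # noiseless signal spanned by the two columns: near-perfect prediction
  X2 <- matrix(rnorm(20 * 2), 20)
  y <- as.vector(X2 %*% c(1, -1))
  expect_gte(loo_q2(X2, y, 2, min_sd = 0, block_scale = FALSE), 0.99)
  X <- matrix(rnorm(20 * 15), 20)
  q2_null <- replicate(10, loo_q2(X, rnorm(20), 2, min_sd = 0,
                                  block_scale = FALSE))
  expect_lte(mean(q2_null), 0)
  expect_error(loo_q2(X[1:2, ], y[1:2], 1), "at least 3")
})

test_that("contribution contours partition points like a plain sort", {
  set.seed(121)
  mols <- gen_ligand_series(23, 12)
  grid <- field_grid(mols, spacing = 3)
  X <- compute_fields(mols, grid)
  y <- rnorm(length(mols), 7, 0.6)
  fit <- fit_pls(X, y, 2)
  cc <- contribution_contours(fit, grid)
  expect_setequal(unique(cc$set), c("favorable", "unfavorable"))
  for (b in unique(fit$field)) {
    sel <- fit$field == b
    v <- sort(fit$coef_scaled[sel] * fit$col_sd[sel])
    n <- length(v)
    fav <- cc$contribution[cc$field == b & cc$set == "favorable"]
    # the favourable set is exactly the top tail of the sorted values
    expect_equal(sort(fav), unname(v[v >= v[ceiling(0.8 * n)]]))
  }
  # symmetric +/- contributions at 50/50 levels give equal-size sets
  Xs <- matrix(rnorm(20 * 8), 20)
  attr(Xs, "field") <- rep("steric", 8)
  fs <- fit_pls(Xs, rnorm(20), 2, min_sd = 0)
  gsym <- manual_grid(matrix(rnorm(24), 8))
  csym <- contribution_contours(fs, gsym, levels = c(0.5, 0.5))
  expect_equal(sum(csym$set == "favorable"), sum(csym$set == "unfavorable"))
  expect_error(contribution_contours(list(), grid), "qsar_model")
})
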