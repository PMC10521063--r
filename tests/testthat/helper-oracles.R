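# Independent oracles and random-case generators shared by the tests.

# random multi-shell density model (direct construction, bypassing
# build_density so exponents/occupations are arbitrary)
rand_shell_model <- function(k, name = "rand") {
  sh <- data.frame(x = runif(k, -2, 2), y = runif(k, -2, 2),
                   z = runif(k, -2, 2),
                   alpha = runif(k, 0.5, 3), ne = runif(k, 1, 8))
  structure(list(shells = sh, molecule = name), class = "density_model")
}

# tensor-product Gauss-Legendre nodes/weights over a 3-D box
gl_grid3 <- function(lo, hi, n) {
  gx <- pracma::gaussLegendre(n, lo[1], hi[1])
  gy <- pracma::gaussLegendre(n, lo[2], hi[2])
  gz <- pracma::gaussLegendre(n, lo[3], hi[3])
  list(pts = as.matrix(expand.grid(gx$x, gy$x, gz$x)),
       w = as.vector(outer(as.vector(outer(gx$w, gy$w)), gz$w)))
}

model_box <- function(models, pad = 6) {
  sh <- do.call(rbind, lapply(models, function(m) m$shells))
  half <- pad / sqrt(min(sh$alpha))
  list(lo = sapply(sh[, c("x", "y", "z")], min) - half,
       hi = sapply(sh[, c("x", "y", "z")], max) + half)
}

# numerical overlap integral of two densities by 3-D quadrature
quad_overlap <- function(da, db, n = 70) {
  bx <- model_box(list(da, db))
  g <- gl_grid3(bx$lo, bx$hi, n)
  sum(g$w * evaluate_density(da, g$pts) * evaluate_density(db, g$pts))
}

# numerical electron count of a density
quad_electrons <- function(da, n = 70) {
  bx <- model_box(list(da))
  g <- gl_grid3(bx$lo, bx$hi, n)
  sum(g$w * evaluate_density(da, g$pts))
}

# radial electrostatic potential of one spherical Gaussian shell via the
# shell theorem (numeric 1-D integrals + spline), independent of the
# erf closed form
shell_potential_fn <- function(alpha, ne, rmax) {
  rho <- function(s) ne * (alpha / pi)^1.5 * exp(-alpha * s^2)
  rg <- seq(1e-6, rmax, length.out = 1200)
  V <- vapply(rg, function(r) {
    inner <- integrate(function(s) s^2 * rho(s), 0, r,
                       rel.tol = 1e-10)$value
    outer_ <- integrate(function(s) s * rho(s), r, Inf,
                        rel.tol = 1e-10)$value
    4 * pi * (inner / r + outer_)
  }, numeric(1))
  splinefun(rg, V)
}

# numerical Coulomb integral: quadrature of rho_A times the numerically
# integrated potential of B
quad_coulomb <- function(da, db, n = 60) {
  bx <- model_box(list(da), pad = 6)
  g <- gl_grid3(bx$lo, bx$hi, n)
  shB <- db$shells
  span <- max(dist(rbind(as.matrix(da$shells[, 1:3]),
                         as.matrix(shB[, 1:3, drop = FALSE]))), 1)
  rmax <- 2 * (span + max(abs(c(bx$hi - bx$lo))))
  VB <- numeric(nrow(g$pts))
  for (s in seq_len(nrow(shB))) {
    Vf <- shell_potential_fn(shB$alpha[s], shB$ne[s], rmax)
    r <- sqrt((g$pts[, 1] - shB$x[s])^2 + (g$pts[, 2] - shB$y[s])^2 +
                (g$pts[, 3] - shB$z[s])^2)
    VB <- VB + Vf(pmax(r, 1e-6))
  }
  sum(g$w * evaluate_density(da, g$pts) * VB)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random "toy molecule": n heavy atoms with pairwise separation >= 1.2 A,
# connected by a random spanning tree plus a few extra bonds
rand_toy_molecule <- function(n = 8, name = "toy") {
  els <- c("C", "C", "C", "N", "O", "S")
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- runif(3, -3, 3)
  for (i in 2:n) {
    repeat {
      p <- runif(3, -3, 3)
      if (min(sqrt(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2))) >= 1.2) break
    }
    pts[i, ] <- p
  }
  bonds <- cbind(2:n, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  extra <- min(3, n - 2)
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    bonds <- rbind(bonds, ij)
  }
  molecule(name, data.frame(element = sample(els, n, replace = TRUE),
                            x = pts[, 1], y = pts[, 2], z = pts[, 3]),
           bonds)
}

# PLS1 oracle via the Krylov-subspace characterisation: the k-component
# PLS1 coefficient vector is the least-squares solution restricted to
# span{X'y, (X'X)X'y, ..., (X'X)^(k-1) X'y} (centred data)
krylov_pls_fitted <- function(X, y, k) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  K <- matrix(NA_real_, ncol(X), k)
  v <- s
  for (a in seq_len(k)) {
    K[, a] <- v / sqrt(sum(v^2))
    v <- crossprod(Xc, Xc %*% v)
  }
  Z <- Xc %*% K
  gam <- qr.solve(Z, yc)
  as.vector(Z %*% gam) + mean(y)
}

# path to a packaged literature fixture
fixture_path <- function(file) {
  system.file("extdata", file, package = "mqsar", mustWork = TRUE)
}

# literature per-residue IE values as plain profiles for ranking tests
oxime_profiles <- function() {
  tab <- read.csv(fixture_path("oxime_ie_literature.csv"))
  lapply(split(tab, tab$ligand), function(d)
    data.frame(residue = d$residue, IE = d$IE))
}
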