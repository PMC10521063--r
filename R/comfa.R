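# CoMFA-style 3D-QSAR: steric (Lennard-Jones) and electrostatic (Coulomb,
# distance-dependent dielectric) probe energies on a rectangular grid
# around a pre-aligned ligand series, regressed against activity by
# partial least squares with leave-one-out cross-validation. The probe is
# an sp3-carbon-like atom with +1 e charge; energies are capped at +/- 30
# kcal/mol, standard published CoMFA conventions.

.coulomb_k <- 332.0636  # kcal A / (mol e^2)

#' Define a rectangular field grid around a ligand set
#'
#' @param mols List of aligned `molecule`s the grid must enclose.
#' @param spacing Grid spacing in Angstrom (> 0), default 2.0.
#' @param margin Margin beyond the bounding box, Angstrom, default 4.0.
#' @param probe List with the probe definition: `element`, `charge` (e),
#'   `epsilon` (kcal/mol), `sigma` (A, LJ zero-crossing diameter).
#' @return Object of class `field_grid`: list with `origin`, `spacing`,
#'   `dims` (points per axis), `points` (n x 3 matrix) and `probe`.
#' @export
field_grid <- function(mols, spacing = 2.0, margin = 4.0,
                       probe = list(element = "C", charge = 1.0,
                                    epsilon = 0.1, sigma = 3.4)) {
  stopifnot(spacing > 0, length(mols) >= 1)
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  # axes always reach (at least) hi so the box truly encloses the set
  axes <- lapply(1:3, function(k) {
    n <- ceiling((hi[k] - lo[k]) / spacing) + 1
    lo[k] + (seq_len(n) - 1) * spacing
  })
  dims <- vapply(axes, length, integer(1))
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 points = pts, probe = probe),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d x %d points, spacing %.2f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

# probe-atom LJ parameters by Lorentz-Berthelot combination; per-atom
# sigma from the vdW radius (minimum at r_i + r_probe).
atom_lj_sigma <- function(elements) {
  2 * element_info(elements)$r_vdw / 2^(1 / 6)
}

#' Compute steric and electrostatic fields for aligned molecules
#'
#' For every molecule and grid point: steric energy as the Lennard-Jones
#' 6-12 interaction of the probe with all atoms, electrostatic energy as
#' the Coulomb interaction with a distance-dependent dielectric
#' `eps = r` (i.e. `332.0636 q_i q_p / r^2`); both capped at
#' `+/- cutoff` kcal/mol. Molecules must share one frame (aligned
#' upstream) and fall inside the grid; partial charges are required for
#' the electrostatic block.
#'
#' @param mols List of aligned `molecule`s with `charge` filled in.
#' @param grid A `field_grid`.
#' @param cutoff Energy cap in kcal/mol, default 30.
#' @param epsilon_atom LJ well depth assigned to every ligand atom
#'   (kcal/mol), default 0.1.
#' @return Matrix, rows = molecules (named), columns = `s_<point>` then
#'   `e_<point>`; attributes `grid` and `field` (type per column).
#' @export
compute_fields <- function(mols, grid, cutoff = 30, epsilon_atom = 0.1) {
  if (length(mols) == 0) stop("empty molecule list")
  pts <- grid$points
  np <- nrow(pts)
  lo <- grid$origin
  hi <- lo + (grid$dims - 1) * grid$spacing
  probe <- grid$probe
  eps_p <- probe$epsilon
  sig_p <- probe$sigma
  out <- matrix(NA_real_, length(mols), 2 * np)
  rownames(out) <- vapply(mols, function(m) m$name, character(1))
  colnames(out) <- c(paste0("s_", seq_len(np)), paste0("e_", seq_len(np)))
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    xyz <- coords(mol)
    if (any(sweep(xyz, 2, lo, "<") | sweep(xyz, 2, hi, ">")))
      stop("molecule '", mol$name, "' lies outside the field grid")
    q <- mol$atoms$charge
    if (anyNA(q))
      stop("molecule '", mol$name,
           "' lacks partial charges needed for the electrostatic field")
    sig <- (atom_lj_sigma(mol$atoms$element) + sig_p) / 2
    eps <- sqrt(epsilon_atom * eps_p)
    ster <- numeric(np); elec <- numeric(np)
    for (a in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
        (pts[, 3] - xyz[a, 3])^2
      d2 <- pmax(d2, 1e-12)
      sr6 <- (sig[a]^2 / d2)^3
      ster <- ster + 4 * eps * (sr6^2 - sr6)
      elec <- elec + .coulomb_k * probe$charge * q[a] / d2
    }
    out[m, ] <- c(pmin(pmax(ster, -cutoff), cutoff),
                  pmin(pmax(elec, -cutoff), cutoff))
  }
  attr(out, "grid") <- grid
  attr(out, "field") <- rep(c("steric", "electrostatic"), each = np)
  out
}

# Drop near-constant columns (CoMFA "minimum sigma" filter) and return the
# kept index set. Applied once, before model fitting.
usable_columns <- function(X, min_sd = 0.05) {
  which(apply(X, 2, stats::sd) >= min_sd)
}

#' Fit a PLS field-activity model
#'
#' Mean-centres activity and field columns (optionally CoMFA-std block
#' scaling: each field block divided by its pooled standard deviation so
#' steric and electrostatic blocks enter with equal weight), drops
#' near-constant columns (`sd < min_sd`), and fits univariate-response
#' partial least squares (NIPALS) with `n_components` latent variables.
#'
#' @param X Field matrix from [compute_fields()] (or any numeric matrix;
#'   a `field` attribute, if present, defines the blocks).
#' @param y Activity vector (e.g. pIC50), one value per row of `X`.
#' @param n_components Number of latent components (>= 1, at most
#'   `nrow(X) - 1`).
#' @param min_sd Column standard-deviation filter threshold, default 0.05.
#' @param block_scale Apply CoMFA-std block scaling (default `TRUE`).
#' @return Object of class `qsar_model`: coefficients (on the original
#'   column scale), fitted values, `r2`, per-block contribution
#'   percentages (`contributions`, summing to 100), and the preprocessing
#'   recipe needed by [predict.qsar_model()].
#' @export
fit_pls <- function(X, y, n_components, min_sd = 0.05, block_scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (stats::sd(y) == 0) stop("constant activity vector")
  keep <- usable_columns(X, min_sd)
  if (length(keep) == 0) stop("no usable (non-constant) field columns")
  if (n_components < 1 || n_components > min(nrow(X) - 1, length(keep)))
    stop("n_components must be in [1, min(rows - 1, usable columns)]")
  field <- attr(X, "field")
  field <- if (is.null(field)) rep("field", ncol(X)) else field
  Xk <- X[, keep, drop = FALSE]
  fieldk <- field[keep]
  xm <- colMeans(Xk)
  Xc <- sweep(Xk, 2, xm)
  bscale <- rep(1, length(keep))
  if (block_scale) {
    for (b in unique(fieldk)) {
      sel <- fieldk == b
      s <- sqrt(mean(Xc[, sel, drop = FALSE]^2))
      if (s > 0) bscale[sel] <- s
    }
    Xc <- sweep(Xc, 2, bscale, "/")
  }
  ym <- mean(y)
  fit <- pls1_nipals(Xc, y - ym, n_components)
  coef_scaled <- fit$coef
  coef_orig <- coef_scaled / bscale
  fitted <- as.vector(Xc %*% coef_scaled) + ym
  r2 <- 1 - sum((y - fitted)^2) / sum((y - ym)^2)
  contrib_raw <- tapply(abs(coef_scaled) *
                          apply(Xc, 2, stats::sd), fieldk, sum)
  contrib <- 100 * contrib_raw / sum(contrib_raw)
  structure(list(n_components = n_components, coef = coef_orig,
                 coef_scaled = coef_scaled, keep = keep, x_mean = xm,
                 block_scale = bscale, y_mean = ym, field = fieldk,
                 fitted = fitted, r2 = r2,
                 contributions = contrib,
                 col_sd = apply(Xc, 2, stats::sd)),
            class = "qsar_model")
}

# Univariate-response PLS by NIPALS on centred data. Returns the
# regression coefficient vector B with yhat = X B.
pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  Xr <- X; yr <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1; break }
    w <- w / nw
    t <- as.vector(Xr %*% w)
    tt <- sum(t^2)
    p_a <- crossprod(Xr, t) / tt
    q_a <- sum(yr * t) / tt
    Xr <- Xr - tcrossprod(t, p_a)
    yr <- yr - t * q_a
    W[, a] <- w; P[, a] <- p_a; qv[a] <- q_a
  }
  if (ncomp == 0) return(list(coef = numeric(p)))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), qv)
  list(coef = as.vector(B))
}

#' Predict activities from a fitted QSAR model
#' @param object A `qsar_model`.
#' @param newdata Field matrix with the same columns as the training `X`.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  Xk <- as.matrix(newdata)[, object$keep, drop = FALSE]
  Xc <- sweep(sweep(Xk, 2, object$x_mean), 2, object$block_scale, "/")
  as.vector(Xc %*% object$coef_scaled) + object$y_mean
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %d components, R2 = %.3f; contributions: %s\n",
              x$n_components, x$r2,
              paste(sprintf("%s %.1f%%", names(x$contributions),
                            x$contributions), collapse = ", ")))
  invisible(x)
}

#' Leave-one-out cross-validated q2
#'
#' One-compound-out refits of the PLS model; predictive squared
#' correlation \eqn{q^2 = 1 - PRESS / \sum (y - \bar y)^2}. At most 1,
#' negative when the model predicts worse than the activity mean.
#'
#' @inheritParams fit_pls
#' @return Scalar q2.
#' @export
loo_q2 <- function(X, y, n_components, min_sd = 0.05, block_scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for cross-validation")
  field <- attr(X, "field")
  press <- 0
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    attr(Xi, "field") <- field
    fit <- fit_pls(Xi, y[-i], n_components, min_sd = min_sd,
                   block_scale = block_scale)
    pred <- predict(fit, X[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Field-contribution contour point sets
#'
#' For each field type, ranks grid points by the contribution product
#' `|coefficient| x column sd` signed by the coefficient, and labels the
#' points at or above the upper percentile level as `favorable` and at or
#' below the lower level as `unfavorable` — the 80%/20% contribution
#' contours of CoMFA maps. Percentile levels are order statistics
#' (`ceiling(q * n)`-th smallest value), so the partition matches a plain
#' sort of the contribution values.
#'
#' @param model A fitted `qsar_model`.
#' @param grid The `field_grid` used to build the field matrix.
#' @param levels Numeric length-2: lower and upper percentile levels as
#'   fractions, default `c(0.2, 0.8)`.
#' @return Data frame with columns `field`, `x`, `y`, `z`, `contribution`,
#'   `set` (`"favorable"` / `"unfavorable"`).
#' @export
contribution_contours <- function(model, grid, levels = c(0.2, 0.8)) {
  if (!inherits(model, "qsar_model")) stop("model must be a fitted qsar_model")
  np <- nrow(grid$points)
  # column index within the full matrix -> grid point and field type
  col_idx <- model$keep
  pt_idx <- ifelse(col_idx > np, col_idx - np, col_idx)
  contrib <- model$coef_scaled * model$col_sd
  out <- list()
  for (b in unique(model$field)) {
    sel <- model$field == b
    v <- contrib[sel]
    n <- length(v)
    sv <- sort(v)
    lo_thr <- sv[max(1, ceiling(levels[1] * n))]
    hi_thr <- sv[max(1, ceiling(levels[2] * n))]
    set <- rep(NA_character_, n)
    set[v >= hi_thr] <- "favorable"
    set[v <= lo_thr] <- "unfavorable"
    keep <- !is.na(set)
    pts <- grid$points[pt_idx[sel][keep], , drop = FALSE]
    out[[b]] <- data.frame(field = b, x = pts[, 1], y = pts[, 2],
                           z = pts[, 3], contribution = v[keep],
                           set = set[keep])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
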