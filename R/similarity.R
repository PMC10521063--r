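# Molecular quantum similarity measures over promolecular Gaussian
# densities. For normalised s-Gaussians every measure has a closed form:
#   overlap of two shells:  N1 N2 (a1 a2 / (pi (a1+a2)))^(3/2)
#                           * exp(-a1 a2 R^2 / (a1+a2))
#   Coulomb of two shells:  N1 N2 erf(sqrt(mu) R)/R,  mu = a1 a2/(a1+a2),
#                           with the R->0 limit 2 N1 N2 sqrt(mu/pi).

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

shell_pair_terms <- function(a, b) {
  sa <- a$shells; sb <- b$shells
  R2 <- outer(sa$x, sb$x, "-")^2 + outer(sa$y, sb$y, "-")^2 +
    outer(sa$z, sb$z, "-")^2
  list(R2 = R2,
       NN = outer(sa$ne, sb$ne),
       aa = outer(sa$alpha, sb$alpha),
       as = outer(sa$alpha, sb$alpha, "+"))
}

#' Overlap similarity measure between two densities
#'
#' The operator-weighted integral \eqn{Z_{AB} = \int \rho_A(r) \rho_B(r) dr}
#' (Dirac-delta operator): the volume shared by the two electron density
#' functions. Computed analytically over all Gaussian shell pairs.
#'
#' @param a,b `density_model` objects.
#' @return Positive scalar, in electrons^2 / A^3.
#' @export
overlap_similarity <- function(a, b) {
  stopifnot(nrow(a$shells) > 0, nrow(b$shells) > 0)
  t <- shell_pair_terms(a, b)
  sum(t$NN * (t$aa / (pi * t$as))^1.5 * exp(-t$aa / t$as * t$R2))
}

#' Coulomb similarity measure between two densities
#'
#' \eqn{Z_{AB} = \iint \rho_A(r_1) |r_1 - r_2|^{-1} \rho_B(r_2) dr_1 dr_2}:
#' the electrostatic repulsion energy between the two charge densities
#' (in electrons^2 / A with the atomic-unit Coulomb constant absorbed).
#' For coincident shell centres the analytic \eqn{R \to 0} limit is used.
#'
#' @param a,b `density_model` objects.
#' @param r_switch Centre distance (Angstrom) below which the coincident
#'   limit replaces the erf(R)/R form (removes 0/0; default 1e-9).
#' @return Positive scalar.
#' @export
coulomb_similarity <- function(a, b, r_switch = 1e-9) {
  stopifnot(nrow(a$shells) > 0, nrow(b$shells) > 0)
  t <- shell_pair_terms(a, b)
  mu <- t$aa / t$as
  R <- sqrt(t$R2)
  near <- R < r_switch
  val <- matrix(0, nrow(R), ncol(R))
  val[near] <- 2 * t$NN[near] * sqrt(mu[near] / pi)
  if (any(!near))
    val[!near] <- t$NN[!near] * erf_(sqrt(mu[!near]) * R[!near]) / R[!near]
  sum(val)
}

#' Carbo similarity index
#'
#' Cosine-like index \eqn{C_{IJ} = Z_{IJ} / \sqrt{Z_{II} Z_{JJ}}}, in
#' (0, 1] for overlap-type measures; equals 1 for identical densities.
#'
#' @param z_ii,z_jj Self-similarities (> 0).
#' @param z_ij Cross-similarity.
#' @return Scalar index.
#' @export
carbo_index <- function(z_ii, z_jj, z_ij) {
  if (any(c(z_ii, z_jj) <= 0)) stop("self-similarities must be positive")
  z_ij / sqrt(z_ii * z_jj)
}

#' Generalised similarity distance
#'
#' \eqn{D_{IJ}(k, x) = [k (Z_{II} + Z_{JJ})/2 - x Z_{IJ}]^{1/2}} with
#' \eqn{x \in [0, k]}; `k = x = 2` gives the Euclidean distance index
#' \eqn{\sqrt{Z_{II} + Z_{JJ} - 2 Z_{IJ}}}, zero for identical objects.
#'
#' @param z_ii,z_jj,z_ij Similarity measures.
#' @param k,x Order parameters, `0 <= x <= k`.
#' @return Nonnegative scalar distance.
#' @export
generalized_distance <- function(z_ii, z_jj, z_ij, k = 2, x = 2) {
  if (x < 0 || x > k) stop("require 0 <= x <= k")
  rad <- k * (z_ii + z_jj) / 2 - x * z_ij
  if (rad < -1e-12 * max(abs(c(z_ii, z_jj, 1))))
    stop("negative radicand in generalised distance")
  sqrt(max(rad, 0))
}

#' Euclidean distance index
#' @inheritParams generalized_distance
#' @return `generalized_distance(z_ii, z_jj, z_ij, 2, 2)`.
#' @export
euclidean_distance_index <- function(z_ii, z_jj, z_ij)
  generalized_distance(z_ii, z_jj, z_ij, 2, 2)

#' Infinite-order distance index
#'
#' The limit member of the distance family: the larger of the two
#' self-similarities, symmetric in its arguments.
#'
#' @param z_ii,z_jj Positive self-similarities.
#' @return `max(z_ii, z_jj)`.
#' @export
infinite_order_distance <- function(z_ii, z_jj) {
  if (any(c(z_ii, z_jj) <= 0)) stop("self-similarities must be positive")
  max(z_ii, z_jj)
}

#' Pairwise similarity matrices for a molecule set
#'
#' Builds (optionally after pairwise rigid superposition of each pair onto
#' a common frame) the symmetric matrix of similarity measures
#' \eqn{Z_{IJ}} for the chosen operator, plus the derived Carbo and
#' Euclidean index matrices. Pairs whose alignment fails are recorded and
#' skipped (`NA` entries).
#'
#' @param mols List of `molecule` objects (>= 2) with unique names.
#' @param operator `"overlap"` or `"coulomb"`.
#' @param align Superpose each pair before measuring (requires bonds for
#'   the triad search; see [superpose()]).
#' @param tol Alignment distance tolerance in Angstrom.
#' @param exponent_scale Passed to [build_density()].
#' @return An object of class `similarity_matrix`: list with `labels`, `Z`,
#'   `carbo`, `euclidean`, `operator`, and `skipped` (data frame of failed
#'   pairs).
#' @export
similarity_matrix <- function(mols, operator = c("overlap", "coulomb"),
                              align = TRUE, tol = 0.30,
                              exponent_scale = 1.5) {
  operator <- match.arg(operator)
  stopifnot(length(mols) >= 2)
  labels <- vapply(mols, function(m) m$name, character(1))
  if (anyDuplicated(labels)) stop("molecule names must be unique")
  n <- length(mols)
  zfun <- if (operator == "overlap") overlap_similarity else coulomb_similarity
  dens <- lapply(mols, build_density, exponent_scale = exponent_scale)
  Z <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  skipped <- data.frame(i = character(0), j = character(0),
                        reason = character(0))
  for (i in seq_len(n)) Z[i, i] <- zfun(dens[[i]], dens[[i]])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dj <- dens[[j]]
      if (align) {
        al <- tryCatch(superpose(mols[[i]], mols[[j]], tol = tol),
                       error = function(e) e)
        if (inherits(al, "error")) {
          skipped <- rbind(skipped, data.frame(
            i = labels[i], j = labels[j], reason = conditionMessage(al)))
          next
        }
        dj <- build_density(transform_molecule(mols[[j]], al$rotation,
                                               al$translation),
                            exponent_scale = exponent_scale)
      }
      Z[i, j] <- Z[j, i] <- zfun(dens[[i]], dj)
    }
  }
  carbo <- Z / sqrt(outer(diag(Z), diag(Z)))
  eucl <- sqrt(pmax(outer(diag(Z), diag(Z), "+") - 2 * Z, 0))
  structure(list(labels = labels, Z = Z, carbo = carbo, euclidean = eucl,
                 operator = operator, skipped = skipped),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s operator, %d molecules (%d pairs skipped)\n",
              x$operator, length(x$labels), nrow(x$skipped)))
  invisible(x)
}

#' Export an index matrix as lower-triangle CSV
#'
#' Writes the lower triangle (diagonal included) with 4-decimal formatting,
#' the layout of published similarity tables. Full precision is kept in the
#' in-memory object; only the export is rounded.
#'
#' @param sm A `similarity_matrix`.
#' @param path Output CSV path.
#' @param which One of `"Z"`, `"carbo"`, `"euclidean"`.
#' @return Invisibly, `path`.
#' @export
export_similarity_csv <- function(sm, path, which = c("carbo", "Z", "euclidean")) {
  which <- match.arg(which)
  m <- sm[[which]]
  m[upper.tri(m)] <- NA
  out <- as.data.frame(ifelse(is.na(m), "",
                              sprintf("%.4f", round_half_up(m, 4))))
  names(out) <- sm$labels
  out <- cbind(name = sm$labels, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
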