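# Topo-geometrical superposition: rigid alignment of two molecules on
# their common heavy-atom substructure. Bonded heavy-atom pairs (duos) are
# extended to bonded triads; distance-compatible triads of the two
# molecules seed a least-squares (Kabsch) transform which is then grown
# greedily over all heavy atoms and refit. Molecules are treated as rigid
# bodies; input coordinates are never mutated.

#' Enumerate bonded heavy-atom pairs (duos)
#'
#' Hydrogens are excluded from the whole superposition process.
#'
#' @param mol A `molecule` with bond information.
#' @return Data frame with columns `i`, `j` (atom ids, `i < j`), `ei`, `ej`
#'   (elements, sorted within the pair for canonical comparison) and `d`
#'   (bond length, Angstrom). Zero rows when no heavy-atom bond exists.
#' @export
enumerate_duos <- function(mol) {
  b <- mol$bonds
  el <- mol$atoms$element
  keep <- is_heavy(el[b$i]) & is_heavy(el[b$j])
  b <- b[keep, , drop = FALSE]
  xyz <- coords(mol)
  d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
  e1 <- el[b$i]; e2 <- el[b$j]
  swap <- e1 > e2
  data.frame(i = b$i, j = b$j,
             ei = ifelse(swap, e2, e1), ej = ifelse(swap, e1, e2),
             d = d, row.names = NULL)
}

# Triads: bonded extensions of duos. For duo (i, j), every heavy atom k
# bonded to i or j forms triad {i, j, k}; stored with sorted atom ids,
# deduplicated, in lexicographic order. Near-degenerate (collinear)
# triangles are dropped: they do not pin down a rotation.
enumerate_triads <- function(mol, min_area = 0.05) {
  duos <- enumerate_duos(mol)
  if (nrow(duos) == 0) return(empty_triads())
  el <- mol$atoms$element
  xyz <- coords(mol)
  adj <- split(c(mol$bonds$j, mol$bonds$i), c(mol$bonds$i, mol$bonds$j))
  tri <- list()
  for (r in seq_len(nrow(duos))) {
    i <- duos$i[r]; j <- duos$j[r]
    nb <- unique(c(adj[[as.character(i)]], adj[[as.character(j)]]))
    nb <- setdiff(nb[is_heavy(el[nb])], c(i, j))
    for (k in nb) tri[[length(tri) + 1]] <- sort(c(i, j, k))
  }
  if (length(tri) == 0) return(empty_triads())
  tri <- unique(do.call(rbind, tri))
  tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  d12 <- sqrt(rowSums((xyz[tri[, 1], , drop = FALSE] -
                         xyz[tri[, 2], , drop = FALSE])^2))
  d13 <- sqrt(rowSums((xyz[tri[, 1], , drop = FALSE] -
                         xyz[tri[, 3], , drop = FALSE])^2))
  d23 <- sqrt(rowSums((xyz[tri[, 2], , drop = FALSE] -
                         xyz[tri[, 3], , drop = FALSE])^2))
  # Heron's formula for triangle area
  s <- (d12 + d13 + d23) / 2
  area <- sqrt(pmax(s * (s - d12) * (s - d13) * (s - d23), 0))
  out <- data.frame(a1 = tri[, 1], a2 = tri[, 2], a3 = tri[, 3],
                    e1 = el[tri[, 1]], e2 = el[tri[, 2]], e3 = el[tri[, 3]],
                    d12 = d12, d13 = d13, d23 = d23, area = area)
  out[out$area >= min_area, , drop = FALSE]
}

empty_triads <- function() {
  data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
             e1 = character(0), e2 = character(0), e3 = character(0),
             d12 = numeric(0), d13 = numeric(0), d23 = numeric(0),
             area = numeric(0))
}

# side lengths of triad vertices in a given vertex order
.perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Match distance-compatible atom triads between two molecules
#'
#' Two triads match under a vertex correspondence when corresponding
#' elements agree and each of the three corresponding side lengths differs
#' by at most `tol`. The first admissible vertex permutation (in a fixed
#' lexicographic order) is kept, making the result deterministic.
#'
#' @param mol_a,mol_b `molecule` objects with bonds.
#' @param tol Side-length tolerance in Angstrom (> 0), default 0.30.
#' @return Data frame, one row per matched pair: atom ids `a1..a3` (in
#'   `mol_a`) and `b1..b3` (corresponding atoms of `mol_b`).
#' @export
match_triads <- function(mol_a, mol_b, tol = 0.30) {
  stopifnot(tol > 0)
  ta <- enumerate_triads(mol_a)
  tb <- enumerate_triads(mol_b)
  out <- list()
  if (nrow(ta) == 0 || nrow(tb) == 0) {
    return(data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
                      b1 = integer(0), b2 = integer(0), b3 = integer(0)))
  }
  side <- function(tr, u, v) {
    key <- paste(sort(c(u, v)), collapse = "")
    switch(key, "12" = tr$d12, "13" = tr$d13, "23" = tr$d23)
  }
  for (ia in seq_len(nrow(ta))) {
    ea <- c(ta$e1[ia], ta$e2[ia], ta$e3[ia])
    da <- c(ta$d12[ia], ta$d13[ia], ta$d23[ia])
    for (ib in seq_len(nrow(tb))) {
      for (p in seq_len(nrow(.perms3))) {
        pp <- .perms3[p, ]
        eb <- c(tb$e1[ib], tb$e2[ib], tb$e3[ib])[pp]
        if (!identical(ea, eb)) next
        db <- c(side(tb[ib, ], pp[1], pp[2]),
                side(tb[ib, ], pp[1], pp[3]),
                side(tb[ib, ], pp[2], pp[3]))
        if (all(abs(da - db) <= tol)) {
          bid <- c(tb$a1[ib], tb$a2[ib], tb$a3[ib])[pp]
          out[[length(out) + 1]] <-
            c(ta$a1[ia], ta$a2[ia], ta$a3[ia], bid)
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
                      b1 = integer(0), b2 = integer(0), b3 = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(a1 = m[, 1], a2 = m[, 2], a3 = m[, 3],
             b1 = m[, 4], b2 = m[, 5], b3 = m[, 6])
}

# Kabsch least-squares rigid fit: rotation R and translation t minimising
# || q R^T + t - p || for point sets p (target) and q (moving).
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(q, 2, cq), sweep(p, 2, cp))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cp - as.vector(R %*% cq)
  list(rotation = R, translation = t)
}

#' Rigid superposition of two molecules
#'
#' Seeds a transform from each matched triad (least-squares fit of the
#' three point pairs), extends it greedily by mapping heavy atoms of the
#' first molecule to the nearest unclaimed same-element heavy atom of the
#' second within `tol`, refits on all matched pairs, and keeps the
#' candidate with the most matched atoms (ties: lowest rmsd, then smallest
#' atom-id triple). The returned rotation/translation move `mol_b` onto
#' `mol_a`; neither input is modified.
#'
#' @param mol_a Reference `molecule`.
#' @param mol_b Moving `molecule`.
#' @param tol Distance tolerance in Angstrom, default 0.30.
#' @return Object of class `alignment`: list with `rotation` (3x3, det +1),
#'   `translation`, `pairs` (data frame `atom_a`, `atom_b`), `rmsd`
#'   (Angstrom), `cost` (Gaussian-kernel overlap index in `[0, 1]`, 1 at
#'   structural identity) and `molecule_b` (the transformed copy of
#'   `mol_b`).
#' @export
superpose <- function(mol_a, mol_b, tol = 0.30) {
  mt <- match_triads(mol_a, mol_b, tol = tol)
  if (nrow(mt) == 0)
    stop("alignment failure: no distance-compatible triads between '",
         mol_a$name, "' and '", mol_b$name, "'")
  pa <- coords(mol_a); pb <- coords(mol_b)
  el_a <- mol_a$atoms$element; el_b <- mol_b$atoms$element
  heavy_a <- which(is_heavy(el_a)); heavy_b <- which(is_heavy(el_b))
  best <- NULL
  for (r in seq_len(nrow(mt))) {
    ida <- c(mt$a1[r], mt$a2[r], mt$a3[r])
    idb <- c(mt$b1[r], mt$b2[r], mt$b3[r])
    seed <- kabsch(pa[ida, , drop = FALSE], pb[idb, , drop = FALSE])
    qb <- sweep(pb %*% t(seed$rotation), 2, seed$translation, "+")
    pairs <- greedy_pairs(pa, qb, el_a, el_b, heavy_a, heavy_b, tol)
    if (nrow(pairs) < 3) next
    fit <- kabsch(pa[pairs$atom_a, , drop = FALSE],
                  pb[pairs$atom_b, , drop = FALSE])
    qb2 <- sweep(pb %*% t(fit$rotation), 2, fit$translation, "+")
    rmsd <- sqrt(mean(rowSums((pa[pairs$atom_a, , drop = FALSE] -
                                 qb2[pairs$atom_b, , drop = FALSE])^2)))
    cand <- list(rotation = fit$rotation, translation = fit$translation,
                 pairs = pairs, rmsd = rmsd, triad = ida)
    if (is.null(best) ||
        nrow(pairs) > nrow(best$pairs) ||
        (nrow(pairs) == nrow(best$pairs) && rmsd < best$rmsd - 1e-12) ||
        (nrow(pairs) == nrow(best$pairs) && abs(rmsd - best$rmsd) <= 1e-12 &&
           triad_less(ida, best$triad)))
      best <- cand
  }
  if (is.null(best))
    stop("alignment failure: no triad seed extended to >= 3 atom pairs")
  mol_bt <- transform_molecule(mol_b, best$rotation, best$translation)
  cost <- alignment_cost(
    coords(mol_a)[heavy_a, , drop = FALSE],
    coords(mol_bt)[heavy_b, , drop = FALSE])
  structure(list(rotation = best$rotation, translation = best$translation,
                 pairs = best$pairs, rmsd = best$rmsd, cost = cost,
                 molecule_b = mol_bt),
            class = "alignment")
}

triad_less <- function(a, b) {
  for (k in 1:3) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# One-to-one greedy matching of heavy atoms by increasing distance,
# same-element only, within tol.
greedy_pairs <- function(pa, qb, el_a, el_b, heavy_a, heavy_b, tol) {
  cand <- list()
  for (ia in heavy_a) {
    jb <- heavy_b[el_b[heavy_b] == el_a[ia]]
    if (length(jb) == 0) next
    dd <- sqrt(rowSums((qb[jb, , drop = FALSE] -
                          matrix(pa[ia, ], length(jb), 3, byrow = TRUE))^2))
    ok <- dd <= tol
    if (any(ok))
      cand[[length(cand) + 1]] <- data.frame(atom_a = ia, atom_b = jb[ok],
                                             d = dd[ok])
  }
  if (length(cand) == 0)
    return(data.frame(atom_a = integer(0), atom_b = integer(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d, cand$atom_a, cand$atom_b), , drop = FALSE]
  used_a <- logical(nrow(qb) + nrow(pa)); used_b <- logical(nrow(qb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_a[cand$atom_a[r]] && !used_b[cand$atom_b[r]]) {
      keep[r] <- TRUE
      used_a[cand$atom_a[r]] <- TRUE
      used_b[cand$atom_b[r]] <- TRUE
    }
  }
  out <- cand[keep, c("atom_a", "atom_b"), drop = FALSE]
  out[order(out$atom_a), , drop = FALSE]
}

#' Gaussian-kernel alignment quality index
#'
#' Quality of a superposition of two heavy-atom point sets in a common
#' frame: \eqn{C_{IJ} = d_{IJ} / \sqrt{d_{II} d_{JJ}}} with
#' \eqn{d_{XY} = \sum_i \sum_j \exp(-|x_i - y_j|^2)}. The Gaussian kernel
#' is positive definite, so Cauchy-Schwarz bounds the index to `[0, 1]`;
#' it equals 1 exactly at structural identity and decays to 0 as the
#' structures separate.
#'
#' @param xa,xb Heavy-atom coordinate matrices (n x 3), same frame.
#' @return Scalar in `[0, 1]`.
#' @export
alignment_cost <- function(xa, xb) {
  kern <- function(p, q) {
    d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
    sum(exp(-pmax(d2, 0)))
  }
  kern(xa, xb) / sqrt(kern(xa, xa) * kern(xb, xb))
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d atom pairs, rmsd %.4g A, cost %.4f\n",
              nrow(x$pairs), x$rmsd, x$cost))
  invisible(x)
}
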