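#' Build a promolecular Gaussian density model
#'
#' Represents the molecular electron density as a sum of spherical atomic
#' densities, one normalised s-Gaussian per atom carrying the atomic number
#' as its electron count:
#' \deqn{\rho(r) = \sum_a N_a (\alpha_a/\pi)^{3/2} e^{-\alpha_a |r - c_a|^2}}
#' Default exponents are derived from tabulated covalent radii as
#' \eqn{\alpha = (c / r_{cov})^2} with a single calibration constant
#' `exponent_scale`. Similarity *indices* (ratios of similarity measures)
#' are robust to this choice; the absolute measures are not, and no claim
#' of agreement with ab initio densities is made. A multi-shell parameter
#' set (element -> list of (exponent, electrons) pairs, e.g. from a JSON
#' file) may be supplied to override the one-shell default; per-element
#' shell electrons must then sum to the atomic number.
#'
#' @param mol A `molecule`.
#' @param parameter_set Optional named list: element symbol -> data frame or
#'   list with components `exponent` (1/A^2) and `electrons`.
#' @param exponent_scale Calibration constant `c` of the default exponent
#'   rule (dimensionless, default 1.5).
#' @return An object of class `density_model`: a list with `shells` (data
#'   frame `x`, `y`, `z`, `alpha`, `ne`) and `molecule` (the name).
#' @examples
#' w <- molecule("water", data.frame(element = c("O", "H", "H"),
#'   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0))
#' d <- build_density(w)
#' sum(d$shells$ne)  # 10 electrons
#' @export
build_density <- function(mol, parameter_set = NULL, exponent_scale = 1.5) {
  info <- element_info(mol$atoms$element)
  xyz <- coords(mol)
  if (is.null(parameter_set)) {
    shells <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         alpha = (exponent_scale / info$r_cov)^2,
                         ne = as.numeric(info$number))
  } else {
    rows <- lapply(seq_len(nrow(info)), function(a) {
      el <- info$symbol[a]
      par <- parameter_set[[el]]
      if (is.null(par)) stop("no density parameters for element ", el)
      par <- as.data.frame(par)
      if (!isTRUE(all.equal(sum(par$electrons), info$number[a])))
        stop("shell electrons for ", el, " do not sum to its atomic number")
      data.frame(x = xyz[a, 1], y = xyz[a, 2], z = xyz[a, 3],
                 alpha = par$exponent, ne = par$electrons)
    })
    shells <- do.call(rbind, rows)
  }
  if (any(shells$alpha <= 0) || any(shells$ne <= 0))
    stop("shell exponents and electron counts must be positive")
  structure(list(shells = shells, molecule = mol$name),
            class = "density_model")
}

#' Read a density parameter set from JSON
#'
#' Format: an object mapping element symbols to arrays of
#' `{"exponent": ..., "electrons": ...}` records, so tabulated atomic
#' shell expansions can be dropped in without code changes.
#'
#' @param path JSON file path.
#' @return Named list usable as `parameter_set` in [build_density()].
#' @export
read_density_parameters <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  lapply(raw, as.data.frame)
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> %s: %d shells, %.1f electrons\n",
              x$molecule, nrow(x$shells), sum(x$shells$ne)))
  invisible(x)
}

#' Total electron count of a density model
#' @param model A `density_model`.
#' @return Numeric electron count (sum of shell occupations).
#' @export
total_electrons <- function(model) sum(model$shells$ne)

#' Evaluate a promolecular density at points
#'
#' @param model A `density_model`.
#' @param points Numeric 3-vector or n x 3 matrix of evaluation points
#'   (Angstrom).
#' @return Numeric vector of density values (electrons / A^3), nonnegative.
#' @export
evaluate_density <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  sh <- model$shells
  out <- numeric(nrow(points))
  for (s in seq_len(nrow(sh))) {
    dx <- points[, 1] - sh$x[s]
    dy <- points[, 2] - sh$y[s]
    dz <- points[, 3] - sh$z[s]
    r2 <- dx * dx + dy * dy + dz * dz
    out <- out + sh$ne[s] * (sh$alpha[s] / pi)^1.5 * exp(-sh$alpha[s] * r2)
  }
  out
}
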