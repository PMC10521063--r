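# Per-residue interaction-energy decomposition for a ligand bound in a
# pocket: I.E = E_AM - E_L - E_M, where E_AM is the energy of the
# ligand-residue pair system, E_L the ligand alone and E_M the residue
# alone. Negative values stabilise the complex. Energies are consumed
# from tables (kcal/mol by default); the engine that produced them
# (semi-empirical, force field, ...) is deliberately external.

#' Ligand-residue interaction energy
#' @param e_am Energy of the ligand+residue system.
#' @param e_l Ligand energy.
#' @param e_m Residue energy.
#' @return `e_am - e_l - e_m` (same unit as the inputs; negative =
#'   stabilising).
#' @export
interaction_energy <- function(e_am, e_l, e_m) e_am - e_l - e_m

#' Build a per-residue interaction-energy profile for one ligand
#'
#' @param complex_energies Energy table of ligand-residue pair systems:
#'   data frame with columns `ligand`, `residue`, `energy` (or `system_id`
#'   of the form `"ligand:residue"` plus `energy`).
#' @param ligand_energies Energy table (`system_id`, `energy`) holding the
#'   isolated-ligand energies.
#' @param residue_energies Energy table (`system_id`, `energy`) holding the
#'   isolated-residue energies.
#' @param ligand Name of the ligand to profile.
#' @param series Optional series tag (e.g. `"11-hydroxy"`) stored on the
#'   result.
#' @return Object of class `ie_profile`: data frame with columns `ligand`,
#'   `residue`, `E_AM`, `E_L`, `E_M`, `IE`, ordered as in the complex
#'   table, with attributes `ligand` and `series`. Missing energy rows are
#'   an error naming the offending residue.
#' @export
build_profile <- function(complex_energies, ligand_energies,
                          residue_energies, ligand, series = NA_character_) {
  ce <- as.data.frame(complex_energies)
  if (!("ligand" %in% names(ce)) && "system_id" %in% names(ce)) {
    parts <- strsplit(as.character(ce$system_id), ":", fixed = TRUE)
    ce$ligand <- vapply(parts, `[[`, character(1), 1)
    ce$residue <- vapply(parts, function(p) paste(p[-1], collapse = ":"),
                         character(1))
  }
  stopifnot(all(c("ligand", "residue", "energy") %in% names(ce)))
  ce <- ce[ce$ligand == ligand, , drop = FALSE]
  if (nrow(ce) == 0) stop("no complex energies for ligand '", ligand, "'")
  if (anyDuplicated(ce$residue))
    stop("duplicate residue rows for ligand '", ligand, "'")
  il <- match(ligand, ligand_energies$system_id)
  if (is.na(il)) stop("missing ligand energy for '", ligand, "'")
  e_l <- ligand_energies$energy[il]
  im <- match(ce$residue, residue_energies$system_id)
  if (anyNA(im))
    stop("missing residue energy for: ",
         paste(ce$residue[is.na(im)], collapse = ", "))
  e_m <- residue_energies$energy[im]
  out <- data.frame(ligand = ligand, residue = ce$residue,
                    E_AM = ce$energy, E_L = e_l, E_M = e_m,
                    IE = interaction_energy(ce$energy, e_l, e_m))
  attr(out, "ligand") <- ligand
  attr(out, "series") <- series
  class(out) <- c("ie_profile", "data.frame")
  out
}

#' Rank binding-site residues by mean interaction energy
#'
#' Averages I.E per residue across a set of ligand profiles and ranks
#' ascending (most negative = most favourable = rank 1; ties broken by
#' residue name). The `top_n` most favourable residues are flagged as
#' candidate "critical" residues of the pocket.
#'
#' @param profiles A single `ie_profile` or a list of them.
#' @param top_n How many top-ranked residues to flag (default 4).
#' @return Data frame with columns `residue`, `n`, `mean_IE`, `rank`,
#'   `critical`, sorted by rank.
#' @export
rank_critical <- function(profiles, top_n = 4) {
  if (inherits(profiles, "ie_profile") || is.data.frame(profiles))
    profiles <- list(profiles)
  if (length(profiles) == 0) stop("no profiles supplied")
  all_ie <- do.call(rbind, lapply(profiles, function(p)
    data.frame(residue = p$residue, IE = p$IE)))
  agg <- stats::aggregate(IE ~ residue, data = all_ie,
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(residue = agg$residue,
                    n = agg$IE[, "n"],
                    mean_IE = agg$IE[, "mean"])
  out <- out[order(out$mean_IE, out$residue), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$critical <- out$rank <= top_n
  rownames(out) <- NULL
  out
}

#' Per-series summary of interaction-energy profiles
#'
#' Groups profiles by their series tag (ligand families sharing a
#' substitution pattern) and aggregates I.E per residue. Profiles with an
#' unknown/missing tag are grouped as `"other"` with a warning.
#'
#' @param profiles List of `ie_profile` objects carrying `series`
#'   attributes.
#' @param known_series Optional character vector of expected tags.
#' @return Data frame with columns `series`, `residue`, `n`, `mean_IE`,
#'   `min_IE`, `max_IE`.
#' @export
series_summary <- function(profiles, known_series = NULL) {
  if (inherits(profiles, "ie_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    s <- attr(p, "series")
    if (is.null(s) || is.na(s) ||
        (!is.null(known_series) && !(s %in% known_series))) {
      warning("profile for ligand '", attr(p, "ligand"),
              "' has unknown series tag; grouped as 'other'")
      s <- "other"
    }
    data.frame(series = s, residue = p$residue, IE = p$IE)
  })
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(IE ~ series + residue, data = long, FUN = function(v)
    c(n = length(v), mean = mean(v), min = min(v), max = max(v)))
  out <- data.frame(series = agg$series, residue = agg$residue,
                    n = agg$IE[, "n"], mean_IE = agg$IE[, "mean"],
                    min_IE = agg$IE[, "min"], max_IE = agg$IE[, "max"])
  out[order(out$series, out$residue), , drop = FALSE]
}

#' Write interaction-energy profiles as CSV
#' @param profiles List of `ie_profile` objects (or one).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "ie_profile")) profiles <- list(profiles)
  long <- do.call(rbind, lapply(profiles, function(p) {
    d <- as.data.frame(p)
    d$series <- attr(p, "series")
    d
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
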