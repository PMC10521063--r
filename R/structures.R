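#' Construct a molecule
#'
#' The shared structural container of the package: an ordered atom table,
#' an optional bond list, and a role tag. Coordinates are in Angstrom
#' throughout; partial charges (elementary charge units) are optional and
#' only required by the electrostatic field stage.
#'
#' @param name Molecule identifier.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`; extra columns (e.g. PDB residue metadata) are
#'   retained.
#' @param bonds Two-column matrix or data frame of 1-based atom indices, or
#'   `NULL` for no bond information.
#' @param role One of `"ligand"`, `"residue"`, `"complex-member"`.
#' @return An object of class `molecule` with components `name`, `atoms`
#'   (including an `atom_id` column), `bonds` and `role`.
#' @examples
#' m <- molecule("water",
#'   data.frame(element = c("O", "H", "H"),
#'              x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0))
#' n_atoms(m)
#' @export
molecule <- function(name, atoms, bonds = NULL,
                     role = c("ligand", "residue", "complex-member")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(atoms))
  req <- c("element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("molecule must contain at least one atom")
  atoms$element <- normalize_element(atoms$element)
  element_info(atoms$element)  # errors on unknown symbols
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atomic coordinates")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  atoms$atom_id <- seq_len(nrow(atoms))
  if (!is.null(bonds) && NROW(bonds) > 0) {
    bonds <- as.data.frame(bonds)[, 1:2]
    names(bonds) <- c("i", "j")
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$i < 1 | bonds$j < 1 |
            bonds$i > nrow(atoms) | bonds$j > nrow(atoms)))
      stop("bond references a non-existent atom")
    # canonical order: i < j, sorted
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- unique(bonds[order(bonds$i, bonds$j), , drop = FALSE])
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0))
  }
  structure(list(name = name, atoms = atoms, bonds = bonds, role = role),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds, role=%s\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$role))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atomic coordinates as a matrix
#' @param mol A `molecule`.
#' @return Numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Apply a rigid transform to a molecule
#'
#' @param mol A `molecule`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed molecule (coordinates `x R^T + t`).
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(mol, xyz)
}

#' Construct a residue set
#'
#' A named collection of residue molecules, e.g. the amino acids lining a
#' binding pocket. Residue names must be unique.
#'
#' @param residues List of `molecule` objects with unique `name`s.
#' @param source Optional identifier of the structure file of origin.
#' @return An object of class `residue_set`.
#' @export
residue_set <- function(residues, source = NA_character_) {
  stopifnot(is.list(residues), length(residues) >= 1)
  nm <- vapply(residues, function(r) r$name, character(1))
  if (anyDuplicated(nm)) stop("residue names must be unique within a set")
  names(residues) <- nm
  structure(list(residues = residues, source = source), class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("<residue_set> %d residues: %s\n", length(x$residues),
              paste(utils::head(names(x$residues), 8), collapse = ", ")))
  invisible(x)
}

#' @export
length.residue_set <- function(x) length(x$residues)

#' Read a molecular structure file
#'
#' Dispatches on format (or the file extension when `format = "auto"`).
#' XYZ files yield a single `molecule` (no bonds); SDF (V2000) files yield a
#' `molecule` per record with bonds; PDB files yield a list with the ligand
#' (HETATM records, or a configured residue name) and a `residue_set` built
#' from the ATOM records, with chain/residue metadata retained on each atom.
#'
#' @param path File path.
#' @param format `"auto"`, `"xyz"`, `"pdb"` or `"sdf"`.
#' @param ligand_resname For PDB input, residue name(s) to treat as the
#'   ligand instead of the HETATM criterion; `NULL` for the default.
#' @return A `molecule`, a list of `molecule`s (SDF with multiple records),
#'   or for PDB a list with elements `ligand` (may be `NULL`) and
#'   `residues` (a `residue_set`).
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb", "sdf"),
                           ligand_resname = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", sdf = "sdf", sd = "sdf",
                     stop("cannot infer structure format from extension '",
                          ext, "'"))
  }
  switch(format,
         xyz = read_xyz(path),
         pdb = read_pdb_complex(path, ligand_resname = ligand_resname),
         sdf = read_sdf(path))
}

# -- XYZ ---------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("XYZ parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: expected atom count")
  if (length(lines) < n + 2)
    stop("XYZ parse error at line ", length(lines) + 1,
         ": expected ", n, " atom records, found ", max(0, length(lines) - 2))
  recs <- lines[3:(n + 2)]
  parts <- strsplit(trimws(recs), "\\s+")
  for (k in seq_along(parts)) {
    if (length(parts[[k]]) < 4)
      stop("XYZ parse error at line ", k + 2, ": expected 'element x y z'")
  }
  el <- vapply(parts, `[[`, character(1), 1)
  xyz <- t(vapply(parts, function(p)
    suppressWarnings(as.numeric(p[2:4])), numeric(3)))
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))[1]
    stop("XYZ parse error at line ", bad + 2, ": non-numeric coordinate")
  }
  nm <- sub("\\.[^.]*$", "", basename(path))
  molecule(nm, data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3]))
}

#' Write a molecule to an XYZ file
#' @param mol A `molecule`.
#' @param path Output file path.
#' @param comment Second-line comment string.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(mol, path, comment = mol$name) {
  xyz <- coords(mol)
  lines <- c(as.character(n_atoms(mol)), comment,
             sprintf("%-3s %14.8f %14.8f %14.8f",
                     mol$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# -- SDF (V2000) via ChemmineR -----------------------------------------

read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdfset <- ChemmineR::read.SDFset(path)
  out <- lapply(seq_along(sdfset), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3])
    bonds <- if (NROW(bb) > 0) data.frame(i = bb[, 1], j = bb[, 2]) else NULL
    nm <- ChemmineR::sdfid(sdf)
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("mol", k)
    molecule(nm, atoms, bonds)
  })
  if (length(out) == 1) out[[1]] else out
}

#' Write molecules to an SDF (V2000) file
#' @param mols A `molecule` or list of `molecule`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  blocks <- vapply(mols, function(m) {
    xyz <- coords(m)
    na <- n_atoms(m); nb <- nrow(m$bonds)
    c(
      paste(c(m$name, "  mqsar", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
              sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                      xyz[, 1], xyz[, 2], xyz[, 3], m$atoms$element),
              if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0",
                                  m$bonds$i, m$bonds$j, rep(1L, nb)),
              "M  END", "$$$$"), collapse = "\n")
    )
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

# -- PDB via bio3d ------------------------------------------------------

read_pdb_complex <- function(path, ligand_resname = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # keep altLoc blank or 'A'
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  if (is.null(ligand_resname)) {
    lig_rows <- at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT"))
  } else {
    lig_rows <- at$resid %in% ligand_resname
  }
  res_rows <- !lig_rows & at$type == "ATOM"
  mk_atoms <- function(d) {
    data.frame(element = pdb_element(d), x = d$x, y = d$y, z = d$z,
               resname = d$resid, resno = d$resno, chain = d$chain,
               insert = ifelse(is.na(d$insert), "", d$insert),
               stringsAsFactors = FALSE)
  }
  ligand <- NULL
  if (any(lig_rows)) {
    d <- at[lig_rows, ]
    ligand <- molecule(paste0(d$resid[1], d$resno[1]), mk_atoms(d),
                       role = "ligand")
  }
  residues <- NULL
  if (any(res_rows)) {
    d <- at[res_rows, ]
    key <- paste(d$chain, d$resno, d$insert, d$resid, sep = "_")
    split_d <- split(d, factor(key, levels = unique(key)))
    res_list <- lapply(split_d, function(g) {
      molecule(paste0(g$resid[1], g$resno[1]), mk_atoms(g), role = "residue")
    })
    residues <- residue_set(unname(res_list), source = basename(path))
  }
  list(ligand = ligand, residues = residues)
}

pdb_element <- function(d) {
  el <- trimws(d$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the first alphabetic character(s) of the atom name
    nm <- gsub("[^A-Za-z].*$", "", trimws(d$elety[miss]))
    el[miss] <- substr(nm, 1, 1)
  }
  normalize_element(el)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below `scale` times the sum
#' of their covalent radii. Used for formats (XYZ, PDB) that carry no
#' explicit connectivity.
#'
#' @param mol A `molecule`.
#' @param scale Multiplier on the covalent-radius sum (default 1.25).
#' @return The molecule with its `bonds` table replaced.
#' @export
infer_bonds <- function(mol, scale = 1.25) {
  xyz <- coords(mol)
  rc <- element_info(mol$atoms$element)$r_cov
  n <- nrow(xyz)
  if (n < 2) return(mol)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rc, rc, "+") * scale
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  bonds <- if (nrow(hit) > 0) data.frame(i = hit[, 1], j = hit[, 2]) else NULL
  molecule(mol$name, mol$atoms[, setdiff(names(mol$atoms), "atom_id")],
           bonds, mol$role)
}

#' Select binding-site residues around a ligand
#'
#' Whole-residue selection: a residue is kept when any of its atoms lies
#' within `radius` of any ligand atom, the criterion used when rescoring a
#' docked pocket at a 5 Angstrom cutoff.
#'
#' @param residues A `residue_set` (or list of residue `molecule`s).
#' @param ligand The ligand `molecule`.
#' @param radius Cutoff distance in Angstrom (> 0), default 5.
#' @return A `residue_set` containing the selected residues, in input order.
#' @export
select_active_site <- function(residues, ligand, radius = 5) {
  if (inherits(residues, "residue_set")) residues <- residues$residues
  stopifnot(radius > 0)
  if (is.null(ligand) || n_atoms(ligand) < 1) stop("empty ligand")
  lig <- coords(ligand)
  keep <- vapply(residues, function(r) {
    rc <- coords(r)
    # min pairwise distance residue-ligand
    d2 <- outer(rowSums(rc^2), rowSums(lig^2), "+") - 2 * rc %*% t(lig)
    sqrt(max(0, min(d2))) <= radius
  }, logical(1))
  if (!any(keep)) stop("no residues within ", radius, " Angstrom of ligand")
  residue_set(residues[keep])
}

# -- Tabular inputs -----------------------------------------------------

# Values pasted from papers often carry decimal commas; normalise on ingest.
normalize_decimal <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(gsub(",", ".", trimws(as.character(x))))
}

#' Read an energy table
#'
#' Reads a CSV or JSON table of system energies (columns `system_id`,
#' `energy`). Decimal commas are normalised to points; duplicate system ids
#' and non-numeric energies are errors. The energy unit is carried as the
#' `unit` attribute (kcal/mol by default).
#'
#' @param path CSV or JSON file path.
#' @param unit Energy unit label stored as metadata.
#' @return Data frame with columns `system_id`, `energy` and attribute
#'   `unit`.
#' @export
read_energy_table <- function(path, unit = "kcal/mol") {
  tab <- read_table_any(path)
  req <- c("system_id", "energy")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("energy table missing column(s): ", paste(miss, collapse = ", "))
  tab$energy <- normalize_decimal(tab$energy)
  if (anyNA(tab$energy)) stop("non-numeric energy value in ", path)
  if (anyDuplicated(tab$system_id))
    stop("duplicate system_id in energy table: ",
         paste(unique(tab$system_id[duplicated(tab$system_id)]),
               collapse = ", "))
  out <- tab[, req]
  attr(out, "unit") <- unit
  out
}

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Read an activity table (name, pIC50)
#' @param path CSV or JSON path with columns `name` and `pIC50`.
#' @return Data frame with numeric `pIC50`.
#' @export
read_activity_table <- function(path) {
  tab <- read_table_any(path)
  if (!all(c("name", "pIC50") %in% names(tab)))
    stop("activity table must have columns name, pIC50")
  tab$pIC50 <- normalize_decimal(tab$pIC50)
  if (anyNA(tab$pIC50)) stop("non-numeric pIC50 in ", path)
  tab
}

#' Read a frontier-orbital energy table (name, E_HOMO, E_LUMO in eV)
#' @param path CSV or JSON path.
#' @return Data frame with numeric `E_HOMO`, `E_LUMO`.
#' @export
read_orbital_table <- function(path) {
  tab <- read_table_any(path)
  if (!all(c("name", "E_HOMO", "E_LUMO") %in% names(tab)))
    stop("orbital table must have columns name, E_HOMO, E_LUMO")
  tab$E_HOMO <- normalize_decimal(tab$E_HOMO)
  tab$E_LUMO <- normalize_decimal(tab$E_LUMO)
  if (anyNA(tab$E_HOMO) || anyNA(tab$E_LUMO))
    stop("non-numeric orbital energy in ", path)
  tab
}

#' Read an atomic population table
#'
#' Columns: `name`, `atom_id`, `q_Nminus1`, `q_N`, `q_Nplus1` — atomic
#' electron populations of the N-1, N and N+1 electron states.
#'
#' @param path CSV or JSON path.
#' @return Data frame with numeric population columns.
#' @export
read_population_table <- function(path) {
  tab <- read_table_any(path)
  req <- c("name", "atom_id", "q_Nminus1", "q_N", "q_Nplus1")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("population table missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("q_Nminus1", "q_N", "q_Nplus1"))
    tab[[cc]] <- normalize_decimal(tab[[cc]])
  tab
}
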