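test_that("XYZ read/write round-trips elements and coordinates", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water",
               "O  0.0000  0.0000  0.0000",
               "H  0.9572  0.0000  0.0000",
               "H -0.2400  0.9270  0.0000"), f)
  m <- read_structure(f, "xyz")
  expect_s3_class(m, "molecule")
  expect_equal(m$atoms$element, c("O", "H", "H"))
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, f2)
  m2 <- read_structure(f2)
  expect_equal(m2$atoms$element, m$atoms$element)
  expect_lt(max(abs(coords(m2) - coords(m))), 1e-4)
})

test_that("malformed XYZ input fails with a line-addressed parse error", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "claims five atoms", "C 0 0 0", "C 1 0 0",
               "C 0 1 0", "C 0 0 1"), f)
  expect_error(read_structure(f), "parse error")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "bad coord", "C 0 0 0", "C one 0 0"), f2)
  expect_error(read_structure(f2), "line 4")
})

test_that("SDF read/write round-trips bonds", {
  skip_if_not_installed("ChemmineR")
  m <- molecule("eth", data.frame(element = c("C", "C", "O"),
                                  x = c(0, 1.5, 2.2), y = c(0, 0, 1.1),
                                  z = 0),
                bonds = rbind(c(1, 2), c(2, 3)))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, f)
  m2 <- read_structure(f, "sdf")
  expect_equal(m2$atoms$element, m$atoms$element)
  expect_lt(max(abs(coords(m2) - coords(m))), 1e-4)
  expect_equal(m2$bonds, m$bonds)
})

test_that("PDB complexes split into ligand and per-residue set", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- function(type, serial, name, res, ch, resno, x, y, z, el)
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            type, serial, name, res, ch, resno, x, y, z, el)
  writeLines(c(
    fmt("ATOM", 1, "N", "LYS", "A", 58, 0, 0, 0, "N"),
    fmt("ATOM", 2, "CA", "LYS", "A", 58, 1.4, 0, 0, "C"),
    fmt("ATOM", 3, "N", "ASP", "A", 54, 8, 0, 0, "N"),
    fmt("ATOM", 4, "CA", "ASP", "A", 54, 9.4, 0, 0, "C"),
    fmt("HETATM", 5, "C1", "LIG", "A", 900, 4, 0, 0, "C"),
    fmt("HETATM", 6, "O1", "LIG", "A", 900, 5.2, 0.5, 0, "O"),
    "END"), f)
  cx <- read_structure(f, "pdb")
  expect_length(cx$residues, 2L)
  expect_setequal(names(cx$residues$residues), c("LYS58", "ASP54"))
  expect_equal(n_atoms(cx$ligand), 2L)
  expect_equal(cx$ligand$atoms$element, c("C", "O"))
})

test_that("active-site selection keeps whole residues by the any-atom rule", {
  lig <- molecule("lig", data.frame(element = "C", x = 0, y = 0, z = 0))
  at <- function(d) data.frame(element = c("C", "N"), x = c(d, d + 1.4),
                               y = 0, z = 0)
  near <- molecule("R1", at(4.9), role = "residue")
  far <- molecule("R2", at(6.0), role = "residue")
  sel <- select_active_site(residue_set(list(near, far)), lig, radius = 5)
  expect_equal(names(sel$residues), "R1")
  expect_error(select_active_site(residue_set(list(near)), NULL, 5),
               "empty ligand")
})

test_that("synthetic pocket selection matches a brute-force distance check
           and is translation invariant", {
  set.seed(31)
  lig <- gen_ligand_series(5, 1)[[1]]
  pocket <- gen_pocket(6, lig, 10, r_range = c(3.5, 12))
  sel <- select_active_site(pocket$residues, lig, radius = 5)
  # oracle: all-pairs distances
  keep <- vapply(pocket$residues$residues, function(r) {
    dmin <- min(as.matrix(pracma::distmat(coords(r), coords(lig))))
    dmin <= 5
  }, logical(1))
  expect_setequal(names(sel$residues), names(keep)[keep])
  # joint rigid translation leaves the selection unchanged
  sh <- c(11, -4, 7)
  lig2 <- transform_molecule(lig, diag(3), sh)
  res2 <- residue_set(lapply(pocket$residues$residues, transform_molecule,
                             rotation = diag(3), translation = sh))
  sel2 <- select_active_site(res2, lig2, radius = 5)
  expect_setequal(names(sel2$residues), names(sel$residues))
})

test_that("energy tables validate columns, duplicates and decimal commas", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system_id,energy", "a,-1.5", "b,-2.5", "c,\"-3,25\""), f)
  tab <- read_energy_table(f)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$energy, c(-1.5, -2.5, -3.25))  # comma normalised
  expect_equal(attr(tab, "unit"), "kcal/mol")
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(system_id = c("a", "b", "c"),
                                  energy = c(-1.5, -2.5, -3.25)), fj)
  expect_equal(read_energy_table(fj)$energy, tab$energy)
  fd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system_id,energy", "a,-1", "a,-2"), fd)
  expect_error(read_energy_table(fd), "duplicate")
  fm <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system_id,value", "a,-1"), fm)
  expect_error(read_energy_table(fm), "missing column")
})

test_that("molecule construction enforces its invariants", {
  at <- data.frame(element = c("C", "H"), x = 0:1, y = 0, z = 0)
  expect_error(molecule("m", at[0, ]), "at least one atom")
  expect_error(molecule("m", at, bonds = rbind(c(1, 1))), "self-bonds")
  expect_error(molecule("m", at, bonds = rbind(c(1, 3))), "non-existent")
  expect_error(molecule("m", data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unknown element")
  expect_error(molecule("m", data.frame(element = "C", x = Inf, y = 0, z = 0)),
               "non-finite")
})
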