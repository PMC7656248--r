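# Topology/trajectory I/O and the atom-selection grammar.

test_that("topology classification counts ions, waters and peptide atoms", {
  top <- topology(
    name = c("LA", "O", "O", "OD1", "OD2", "OD1", "O", "OE1"),
    resname = c("LA", "HOH", "HOH", "ASP", "ASP", "ASN", "TRP", "GLU"),
    resid = c(1, 101, 102, 3, 3, 5, 9, 11))
  expect_identical(as.integer(table(top$class)[c("ion", "water", "peptide")]),
                   c(1L, 2L, 5L))
})

test_that("topology invariants reject malformed inputs", {
  # a two-oxygen water residue is invalid
  expect_error(topology(c("O", "O"), c("HOH", "HOH"), c(101, 101)),
               "exactly one oxygen")
})

test_that("PDB round trip preserves topology and coordinates to format precision", {
  spec <- traj_spec(n_frames = 3, water_count = 6, seed = 21)
  gen <- generate_complex_trajectory(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(gen$traj, gen$top, path, "pdb")
  top2 <- read_topology(path)
  expect_identical(top2$name, gen$top$name)
  expect_identical(top2$resname, gen$top$resname)
  expect_identical(top2$resid, gen$top$resid)
  expect_identical(top2$class, gen$top$class)
  tr2 <- read_trajectory(path, top2)
  expect_equal(dim(tr2$coords)[1], 3)
  expect_lt(max(abs(tr2$coords - gen$traj$coords)), 1e-3)
  expect_equal(tr2$box[1, ], gen$traj$box[1, ], tolerance = 1e-3)
})

test_that("PDB coordinates are Angstrom on disk, nm in memory", {
  fx <- make_fixed_traj(rbind(c(1, 1, 1), c(1.25, 1, 1)), box = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(fx$traj, fx$top, path, "pdb")
  rec <- grep("^(ATOM|HETATM)", readLines(path), value = TRUE)
  expect_equal(as.numeric(substr(rec[1], 31, 38)), 10)     # 1 nm = 10 A
  expect_equal(as.numeric(substr(rec[2], 31, 38)), 12.5)
  tr <- read_trajectory(path, fx$top)
  expect_equal(tr$coords[1, 2, 1], 1.25, tolerance = 1e-9)
})

test_that("XYZ round trip with sidecar box is lossless to write precision", {
  spec <- traj_spec(n_frames = 4, water_count = 4, seed = 8)
  gen <- generate_complex_trajectory(spec)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(gen$traj, gen$top, path, "xyz")
  tr2 <- read_trajectory(path, gen$top)
  expect_equal(dim(tr2$coords)[1], 4)
  expect_lt(max(abs(tr2$coords - gen$traj$coords)), 1e-6)
  # no sidecar means no box: must error, never a silent infinite box
  file.remove(paste0(path, ".box"))
  expect_error(read_trajectory(path, gen$top), "box")
})

test_that("CSV result tables round trip", {
  df <- data.frame(ion = c("La", "Lu"), mean_nm = c(0.256, 0.238),
                   n_frames = c(100L, 100L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(df, path)
  expect_equal(read_result_csv(path), df)
})

test_that("malformed trajectory files produce informative errors", {
  fx <- make_fixed_traj(rbind(c(1, 1, 1), c(2, 1, 1)), box = 5, nf = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(fx$traj, fx$top, path, "pdb")
  lines <- readLines(path)
  # drop one atom record from the second model: error must name frame 2
  second_atom <- grep("^HETATM", lines)
  writeLines(lines[-second_atom[4]], path)
  expect_error(read_trajectory(path, fx$top), "frame 2")
  # no CRYST1: error
  writeLines(lines[!grepl("^CRYST1", lines)], path)
  expect_error(read_trajectory(path, fx$top), "CRYST1|box")
  # duplicate serials
  dup <- lines
  dup[second_atom[2]] <- sub(" 2 ", " 1 ", dup[second_atom[2]])
  writeLines(dup, path)
  expect_error(read_topology(path), "duplicate")
})

test_that("the selection grammar resolves names, residues and boolean algebra", {
  spec <- traj_spec(n_frames = 2, water_count = 3, seed = 5)
  gen <- generate_complex_trajectory(spec)
  top <- gen$top
  n5 <- select_atoms(top, "resid 5 and name OD1")
  expect_length(n5, 1)
  expect_identical(top$resname[n5], "ASN")
  wox <- select_atoms(top, "resname HOH and name O")
  expect_length(wox, 3)
  d3 <- select_atoms(top, "resid 3 and ( name OD1 or name OD2 )")
  expect_length(d3, 2)
  none <- select_atoms(top, "resid 99")
  expect_length(none, 0)
  notw <- select_atoms(top, "not resname HOH")
  expect_setequal(as.integer(notw), which(top$resname != "HOH"))
  # |A or B| + |A and B| = |A| + |B|
  exprs <- c("resname HOH", "name OD1", "resid 3", "name O")
  for (a in exprs) for (b in exprs) {
    n_or <- length(select_atoms(top, paste(a, "or", b)))
    n_and <- length(select_atoms(top, paste(a, "and", b)))
    expect_equal(n_or + n_and,
                 length(select_atoms(top, a)) + length(select_atoms(top, b)))
  }
})

test_that("selection syntax errors name the offending token", {
  top <- make_fixed_traj(rbind(c(1, 1, 1)), box = 5)$top
  expect_error(select_atoms(top, "resid five"), "integer")
  expect_error(select_atoms(top, "chain A"), "unknown keyword")
  expect_error(select_atoms(top, "( resid 1"), "\\)")
  expect_error(select_atoms(top, "resid 1 name O"), "trailing")
})
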