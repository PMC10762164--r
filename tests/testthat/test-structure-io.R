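test_that("a minimal single-atom PDB record parses to the stated fields", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 1L)
  expect_equal(coords(m), matrix(c(1, 2, 3), 1), tolerance = 1e-9)
  expect_equal(m$resid, 1L)
  expect_equal(m$chain, "A")
  expect_equal(m$name, "CA")
})

test_that("PDB write/read round-trips coordinates to format precision", {
  m <- make_toy_pentamer(tilt_m4 = 15, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2), nrow(m))
  expect_lt(max(abs(coords(m) - coords(m2))), 1e-3)
  expect_identical(m2$resid, m$resid)
  expect_identical(m2$chain, m$chain)
})

test_that("mmCIF write/read round-trips through bio3d", {
  m <- make_toy_pentamer(seed = 3)
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, f)
  m2 <- suppressWarnings(read_structure(f))
  expect_lt(max(abs(coords(m) - coords(m2))), 1e-3)
  expect_identical(m2$resid, m$resid)
  expect_identical(m2$name, m$name)
})

test_that("a waters-only file gives an empty protein selection, not an error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  m <- read_structure(f)
  sel <- select_atoms(m, "protein")
  expect_s3_class(sel, "atom_selection")
  expect_length(selection_indices(sel), 0)
})

test_that("altloc conformers collapse to the highest-occupancy one", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 2)       # B has the higher occupancy
})

test_that("read_frames preserves frame order and checks atom counts", {
  fs <- make_toy_bilayer_series(n_lipids = 12, n_frames = 4, noise_sd = 0.5,
                                seed = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_frames(fs, f)
  fs2 <- read_frames(f, dt_ps = 200)
  expect_equal(n_frames(fs2), 4L)
  expect_lt(max(abs(fs$frames - fs2$frames)), 1e-3)

  # frame times: index 1251 at dt 200 ps marks the 250 ns point
  expect_equal((1251 - 1) * 200 / 1000, 250)

  top <- fs$topology
  bad <- withr::local_tempfile(fileext = ".pdb")
  short <- top[-1, ]
  class(short) <- c("structure_model", "data.frame")
  writeLines(c("MODEL     1",
               discmetrics:::pdb_atom_records(top),
               "ENDMDL", "MODEL     2",
               discmetrics:::pdb_atom_records(short, coords(short)),
               "ENDMDL", "END"), bad)
  suppressWarnings(expect_error(read_frames(bad, dt_ps = 200),
                                "frame|atom"))
})

test_that("selection algebra satisfies inclusion-exclusion and grammar combos", {
  m <- make_toy_pentamer(seed = 5)
  a <- select_atoms(m, "chain A B")
  b <- select_atoms(m, "resid 230:247")
  expect_equal(length(selection_indices(selection_union(a, b))) +
                 length(selection_indices(selection_intersect(a, b))),
               length(selection_indices(a)) + length(selection_indices(b)))
  # grammar: and/or/not with parentheses
  c1 <- select_atoms(m, "(chain A or chain B) and resid 230:247")
  c2 <- selection_intersect(a, b)
  expect_identical(selection_indices(c1), selection_indices(c2))
  n_all <- nrow(m)
  expect_length(selection_indices(select_atoms(m, "not all")), 0)
  expect_length(selection_indices(select_atoms(m, "all")), n_all)
  expect_error(select_atoms(m, "resid 201:322 and"), "parse")
  expect_error(select_atoms(m, "flavour blue"), "parse")
})

test_that("MRC maps round-trip and canonicalise permuted axis order", {
  mm <- make_toy_density_map(shape = c(20, 24, 16), voxel_size = 1.5,
                             disc_radius = 12, disc_height = 8,
                             noise_sd = 0.2, seed = 21)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(mm, f)
  mm2 <- read_density_map(f)
  expect_equal(dim(mm2$grid), dim(mm$grid))
  expect_lt(max(abs(mm2$grid - mm$grid)), 1e-6)
  expect_equal(mm2$voxel_size, mm$voxel_size, tolerance = 1e-6)
  expect_equal(mm2$origin, mm$origin, tolerance = 1e-5)

  # write a permuted-axis twin by hand and check canonicalisation:
  # store sections along x (mapc=3, mapr=1, maps=2)
  g <- mm$grid
  perm_arr <- aperm(g, c(3, 1, 2))
  con <- file(f, "r+b")
  writeBin(as.integer(dim(perm_arr)), con, size = 4, endian = "little")
  seek(con, 4 * 16, rw = "w")
  writeBin(as.integer(c(3, 1, 2)), con, size = 4, endian = "little")
  seek(con, 4 * 7, rw = "w")
  writeBin(as.integer(dim(g)), con, size = 4, endian = "little")  # mx,my,mz
  seek(con, 1024, rw = "w")
  writeBin(as.numeric(perm_arr), con, size = 4, endian = "little")
  close(con)
  mm3 <- read_density_map(f)
  expect_equal(dim(mm3$grid), dim(g))
  expect_lt(max(abs(mm3$grid - g)), 1e-6)

  # truncated file is a format error
  bytes <- readBin(f, "raw", 2000)
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeBin(bytes, tf)
  expect_error(read_density_map(tf), "truncated")
})
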