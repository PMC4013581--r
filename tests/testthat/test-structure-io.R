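test_that("hand-written PDB fixture is parsed field-for-field", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "TITLE     three atom fixture",
    "ATOM      1  N   ALA A   1      11.104  13.207   2.100  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.560  13.300   2.000  1.00  0.00           C",
    "ATOM      3  O   GLY A   2      -1.234   0.050  99.999  1.00  0.00           O",
    "END"), f)
  st <- read_pdb(f)
  expect_s3_class(st, "Structure")
  expect_equal(nrow(st$atoms), 3L)
  expect_equal(st$atoms$name, c("N", "CA", "O"))
  expect_equal(st$atoms$element, c("N", "C", "O"))
  expect_equal(st$atoms$resid, c(1L, 1L, 2L))
  expect_equal(coords(st),
               matrix(c(11.104, 13.207, 2.100,
                        12.560, 13.300, 2.000,
                        -1.234, 0.050, 99.999), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(st$atoms$mass, element_mass(c("N", "C", "O")))
})

test_that("multi-model files return the requested model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL", "END"), f)
  expect_equal(as.numeric(coords(read_pdb(f))), c(0, 0, 0))
  expect_equal(as.numeric(coords(read_pdb(f, model = 2))), c(1, 2, 3))
  expect_error(read_pdb(f, model = 3), "model")
})

test_that("unknown element column falls back to atom-name inference with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  OG1 THR A   2       7.600   0.000   0.000  1.00  0.00",
    "ATOM      4 1HB  ALA A   2       9.000   0.000   0.000  1.00  0.00",
    "END"), f)
  expect_warning(st <- read_pdb(f), "inferred from the atom name")
  # hand-parsed expectation for each atom name
  expect_equal(st$atoms$element, c("N", "C", "O", "H"))
})

test_that("parser reports malformed records and missing files", {
  expect_error(read_pdb(file.path(tempdir(), "no-such-file-xyz.pdb")),
               "no such file")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       bad..   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_pdb(f), "line 2")
})

test_that("reader agrees with an independent PDB parser on a generated file", {
  toy <- make_two_state_toy(40, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$open, f)
  st <- read_pdb(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(coords(st),
               matrix(ref$xyz, ncol = 3, byrow = TRUE), tolerance = 1e-9)
  expect_equal(st$atoms$resid, ref$atom$resno)
})

test_that("trajectory round-trips coordinates and time stamps through multi-model PDB", {
  tr <- make_correlated_trajectory(5, 50, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(n_frames(tr2), 50L)
  expect_equal(tr2$times, tr$times)
  for (k in c(1L, 17L, 50L)) {
    expect_lte(max(abs(tr2$frames[[k]] - tr$frames[[k]])), 0.001)
  }
  # a second write/read cycle is lossless (quantization happened once)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr2, f2)
  tr3 <- read_trajectory(f2)
  expect_identical(tr3$frames, tr2$frames)
})

test_that("containers reject invariant violations", {
  at <- data.frame(name = "CA", element = "C", resid = 1L, resname = "GLY",
                   chain = "A", x = 0, y = 0, z = 0)
  expect_error(structure_new(at[0, ]), "at least one atom")
  expect_error(structure_new(transform(at, x = NaN)), "finite")
  expect_error(trajectory_new(at, list(), numeric()), "at least one frame")
  expect_error(trajectory_new(at, list(matrix(0, 1, 3), matrix(0, 1, 3)),
                              c(2, 1)), "strictly increasing")
  expect_error(trajectory_new(at, list(matrix(0, 2, 3)), 1), "1 x 3")
})

test_that("packaged segment tables carry the documented element ranges", {
  open <- default_segments("open")
  closed <- default_segments("closed")
  expect_equal(open[["β1"]]$ranges[[1]], c(11L, 13L))
  expect_equal(open[["β1"]]$class, "strand")
  expect_equal(closed[["β8″"]]$ranges[[1]], c(190L, 200L))
  expect_equal(segment_residues(open, "β7/8"),
               sort(c(170:174, 184:191)))
  expect_length(segment_residues(open, "β7/8"), 13L)
  # the closed fold has no separate first strand; its N-terminus is part of
  # the extended first helix
  expect_null(closed[["β1"]])
  expect_equal(closed[["αA"]]$ranges[[1]], c(12L, 37L))
  # all residues covered by the tables fall inside the 1..205 chain
  for (tab in list(open, closed)) {
    for (nm in names(tab)) {
      rr <- segment_residues(tab, nm)
      expect_true(all(rr >= 1 & rr <= 205))
    }
  }
  expect_error(default_segments("halfway"))
})

test_that("segment tables round-trip through the plain-text config", {
  f <- withr::local_tempfile()
  sg <- default_segments("open")
  write_segments(sg, f)
  sg2 <- read_segments(f)
  expect_equal(names(sg2), names(sg))
  for (nm in names(sg)) {
    expect_equal(segment_residues(sg2, nm), segment_residues(sg, nm))
  }
})
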