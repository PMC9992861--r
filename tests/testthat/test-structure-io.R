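test_that("multi-model PDB files round-trip at fixed-point precision", {
  ens <- make_peptide_ensemble(n_frames = 2, n_res = 5)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, tf)
  back <- read_pdb_ensemble(tf)
  expect_equal(n_frames(back), 2L)
  expect_equal(nrow(back$atoms), nrow(ens$atoms))
  for (i in 1:2)
    expect_lt(max(abs(back$coords[[i]] - ens$coords[[i]])), 5e-4)
  expect_equal(back$atoms$atom_name, ens$atoms$atom_name)
  expect_equal(back$atoms$residue_number, ens$atoms$residue_number)
})

test_that("round-trip property holds over random ensembles", {
  for (seed in 1:5) {
    ens <- make_peptide_ensemble(n_frames = 3, n_res = 8, with_h = TRUE,
                                 seed = seed)
    tf <- withr::local_tempfile(fileext = ".pdb")
    write_pdb_ensemble(ens, tf)
    back <- read_pdb_ensemble(tf)
    delta <- max(mapply(function(a, b) max(abs(a - b)),
                        back$coords, ens$coords))
    expect_lt(delta, 5e-4)
  }
})

test_that("a single-atom record is written in standard fixed columns", {
  atoms <- data.frame(atom_serial = 1L, atom_name = "CA",
                      residue_name = "GLY", chain_id = "A",
                      residue_number = 1L, element = "C", occupancy = 1)
  ens <- new_ensemble(atoms, list(matrix(c(1, 2, 3), 1)))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, tf)
  atom_line <- grep("^ATOM", readLines(tf), value = TRUE)
  expect_equal(substr(atom_line, 31, 54), "   1.000   2.000   3.000")
})

test_that("written ensembles are readable by an independent PDB reader", {
  skip_if_not_installed("bio3d")
  ens <- make_peptide_ensemble(n_frames = 3, n_res = 6, seed = 11)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, tf)
  ref <- bio3d::read.pdb(tf, multi = TRUE)
  expect_equal(dim(ref$xyz)[1], 3L)
  for (i in 1:3) {
    theirs <- matrix(ref$xyz[i, ], ncol = 3, byrow = TRUE)
    expect_lt(max(abs(theirs - round(ens$coords[[i]], 3))), 1e-9)
  }
  expect_equal(ref$atom$resno[seq_len(nrow(ens$atoms))],
               ens$atoms$residue_number)
})

test_that("inconsistent models and malformed records are rejected with context", {
  lines <- c("MODEL 1",
             "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ATOM      2  CB  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL",
             "MODEL 2",
             "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  expect_error(read_pdb_ensemble(tf), "model 2")

  writeLines(c("ATOM      1  CA  GLY A   1       bad      0.000   0.000  1.00  0.00           C"), tf)
  expect_error(read_pdb_ensemble(tf), "line 1")

  writeLines(c("ATOM      1  CA  GLY A   1A      0.000   0.000   0.000  1.00  0.00           C"), tf)
  expect_error(read_pdb_ensemble(tf), "insertion")
})

test_that("alternate locations resolve to highest occupancy, ties to smallest id", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AGLY A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BGLY A   1       4.000   0.000   0.000  0.50  0.00           C")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  ens <- read_pdb_ensemble(tf)
  expect_equal(nrow(ens$atoms), 2L)
  expect_equal(ens$coords[[1]][, 1], c(2, 3))  # B wins CA, A wins CB tie
})

test_that("writer rejects empty ensembles and unrepresentable coordinates", {
  ens <- make_peptide_ensemble(n_frames = 1)
  empty <- ens; empty$coords <- list()
  expect_error(write_pdb_ensemble(empty, tempfile()), "empty")
  big <- ens; big$coords[[1]][1, 1] <- 12345.0
  expect_error(write_pdb_ensemble(big, tempfile()), "range")
})

test_that("two-column boost logs parse, validate order, and clamp noise", {
  tf <- withr::local_tempfile()
  writeLines(c("# comment", "0 1.5", "1 2.0"), tf)
  log <- read_boost_log(tf, "two_column")
  expect_equal(log$frame_index, 0:1)
  expect_equal(log$dV, c(1.5, 2.0))

  writeLines(c("1 2.0", "0 1.5"), tf)
  expect_error(read_boost_log(tf, "two_column"), "increasing")

  writeLines(c("0 -0.5", "1 1.0"), tf)
  expect_warning(log <- read_boost_log(tf, "two_column"), "clamped")
  expect_equal(log$dV, c(0, 1.0))
})

test_that("amber-style logs need an explicit boost column", {
  tf <- withr::local_tempfile()
  writeLines(c("# step temp etot dV", "1 300 -100 1.5", "2 300 -99 2.5"), tf)
  expect_error(read_boost_log(tf, "amber_gamd"), "boost_column")
  log <- read_boost_log(tf, "amber_gamd", boost_column = 4)
  expect_equal(log$frame_index, 0:1)
  expect_equal(log$dV, c(1.5, 2.5))
})

test_that("generated boost logs round-trip with matching bookkeeping", {
  set.seed(3)
  dv <- abs(rnorm(1000))
  tf <- withr::local_tempfile()
  write_boost_log(dv, tf)
  log <- read_boost_log(tf, "two_column")
  expect_equal(nrow(log), 1000L)
  expect_equal(sum(log$dV), sum(dv), tolerance = 1e-9)
})

test_that("boost pairing is validated before analysis", {
  ens <- make_peptide_ensemble(n_frames = 3)
  expect_error(attach_boost(ens, data.frame(frame_index = 0:1,
                                            dV = c(1, 2))),
               "3 frames")
  ens <- attach_boost(ens, data.frame(frame_index = 0:2, dV = 1:3))
  expect_equal(ens$frame_meta$boost_dV, c(1, 2, 3))
})

test_that("motif selections resolve deterministically with filters", {
  ens <- make_peptide_ensemble(n_frames = 2, n_res = 5, with_h = TRUE)
  one_ca <- resolve_selection(ens, motif_definition("m", "A", 3, 3, "CA"))
  expect_length(one_ca, 1L)
  expect_equal(ens$atoms$atom_name[one_ca], "CA")

  heavy <- resolve_selection(ens, motif_definition("m", "A", 2, 2, "heavy"))
  expect_length(heavy, 4L)   # N CA C O; three hydrogens excluded
  all_at <- resolve_selection(ens, motif_definition("m", "A", 2, 2, "all"))
  expect_length(all_at, 7L)

  expect_error(resolve_selection(ens, motif_definition("m", "Z", 1, 2)),
               "chain 'Z'")
  expect_error(resolve_selection(ens, motif_definition("gap", "A", 90, 99)),
               "gap")
  # idempotent and sorted
  expect_identical(heavy, sort(heavy))
  expect_identical(heavy,
                   resolve_selection(ens,
                                     motif_definition("m", "A", 2, 2,
                                                      "heavy")))
})

test_that("motif YAML configs load into definitions", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("CM_loop:", "  chain: A", "  start: 2", "  end: 4",
               "  filter: CA",
               "HLH:", "  chain: A", "  start: 1", "  end: 5"), tf)
  motifs <- read_motif_config(tf)
  expect_named(motifs, c("CM_loop", "HLH"))
  expect_equal(motifs$CM_loop$atom_filter, "CA")
  expect_equal(motifs$HLH$atom_filter, "all")
  expect_equal(motifs$CM_loop$residue_range, c(2L, 4L))
})
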