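test_that("atom-pair distances match the closed form", {
  atoms <- data.frame(atom_serial = 1:2, atom_name = c("CA", "CA"),
                      residue_name = "GLY", chain_id = "A",
                      residue_number = 1:2, element = "C", occupancy = 1)
  ens <- new_ensemble(atoms, list(rbind(c(0, 0, 0), c(3, 4, 0)),
                                  rbind(c(1, 1, 1), c(1, 1, 1))))
  d <- distance_cv(ens, atom_anchor("A", 1), atom_anchor("A", 2))
  expect_equal(d$values, c(5, 0))
  expect_equal(d$unit, "A")
})

test_that("distance series agrees with direct per-frame evaluation", {
  ens <- make_peptide_ensemble(n_frames = 100, n_res = 4, seed = 9)
  a <- atom_anchor("A", 1, "CA"); b <- atom_anchor("A", 3, "O")
  d <- distance_cv(ens, a, b)
  ia <- which(ens$atoms$residue_number == 1 & ens$atoms$atom_name == "CA")
  ib <- which(ens$atoms$residue_number == 3 & ens$atoms$atom_name == "O")
  direct <- sapply(ens$coords, function(m)
    sqrt((m[ia, 1] - m[ib, 1])^2 + (m[ia, 2] - m[ib, 2])^2 +
           (m[ia, 3] - m[ib, 3])^2))
  expect_equal(d$values, direct, tolerance = 1e-12)
})

test_that("ambiguous anchors are rejected", {
  ens <- make_peptide_ensemble()
  expect_error(distance_cv(ens, atom_anchor("A", 1, "XX"),
                           atom_anchor("A", 2, "CA")), "0 atoms")
})

test_that("cleft width is the CA-CA distance alias", {
  ens <- make_toy_motor(n_frames = 3, cleft_distance = 15,
                        crossing_angle = 10, loop_jitter_sd = 0)
  m <- toy_motor_motifs()
  cw <- cleft_width(ens, m$cleft_a, m$cleft_b)
  expect_equal(cw$name, "cleft_width")
  expect_equal(cw$values, rep(15, 3), tolerance = 1e-9)
  expect_equal(cw$values,
               distance_cv(ens, m$cleft_a, m$cleft_b)$values)
  same <- cleft_width(ens, m$cleft_a, m$cleft_a)
  expect_equal(same$values, rep(0, 3))
})

test_that("axis fitting recovers exact lines with N-to-C orientation", {
  pts <- cbind(0, 0, 0:5)
  expect_equal(fit_axis(pts), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fit_axis(pts[6:1, ]), c(0, 0, -1), tolerance = 1e-12)
  expect_error(fit_axis(pts[1:2, ]), "3 points")
  expect_error(fit_axis(matrix(1, 5, 3)), "degenerate")
})

test_that("axis fitting recovers the known axis of an ideal helix", {
  helix <- ideal_helix(12)
  ax <- fit_axis(helix)
  ang <- acos(min(1, sum(ax * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  # rotated helix: axis rotates with it
  rot <- euler_rotation(0.3, 1.1, -0.4)
  ax2 <- fit_axis(helix %*% t(rot))
  truth <- as.numeric(rot %*% c(0, 0, 1))
  expect_lt(acos(min(1, sum(ax2 * truth))) * 180 / pi, 1)
})

test_that("crossing angles recover planted rotations and are symmetric", {
  m <- toy_motor_motifs()
  for (planted in c(0, 22, 90)) {
    ens <- make_toy_motor(n_frames = 4, cleft_distance = 15,
                          crossing_angle = planted, loop_jitter_sd = 0)
    ang <- crossing_angle(ens, m$helixA, m$helixB)
    expect_equal(ang$values, rep(planted, 4), tolerance = 1)
    sym <- crossing_angle(ens, m$helixB, m$helixA)
    expect_equal(ang$values, sym$values, tolerance = 1e-9)
    # the exactly straight strands recover the angle with no fit error
    strand <- crossing_angle(ens, m$strandA, m$strandB)
    expect_equal(strand$values, rep(planted, 4), tolerance = 1e-9)
  }
})

test_that("collective variables are invariant under rigid-body motion", {
  m <- toy_motor_motifs()
  ens <- make_toy_motor(n_frames = 5, cleft_distance = 17,
                        crossing_angle = 35, loop_jitter_sd = 0.2, seed = 4)
  moved <- rigid_transform_ensemble(ens, seed = 99)
  d0 <- distance_cv(ens, m$cleft_a, m$cleft_b)$values
  d1 <- distance_cv(moved, m$cleft_a, m$cleft_b)$values
  expect_equal(d0, d1, tolerance = 1e-6)
  a0 <- crossing_angle(ens, m$helixA, m$strandB)$values
  a1 <- crossing_angle(moved, m$helixA, m$strandB)$values
  expect_equal(a0, a1, tolerance = 1e-6)
  # quadrature CV: invariant up to the lattice resolution, not exactly
  c0 <- contact_area(ens, m$all_A, m$all_B, n_points = 960)$values
  c1 <- contact_area(moved, m$all_A, m$all_B, n_points = 960)$values
  expect_lt(max(abs(c0 - c1)), 1)
})

test_that("Kabsch superposition handles identity, translation, rotation", {
  set.seed(5)
  ref <- matrix(rnorm(30), 10)
  same <- kabsch_superpose(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  shifted <- kabsch_superpose(ref, sweep(ref, 2, c(5, 5, 5), `+`))
  expect_equal(shifted$rmsd, 0, tolerance = 1e-12)
  expect_equal(shifted$translation, c(5, 5, 5), tolerance = 1e-9)

  for (seed in 1:5) {
    set.seed(seed)
    rot <- random_rotation()
    moved <- ref %*% t(rot)
    fit <- kabsch_superpose(ref, moved)
    expect_lt(fit$rmsd, 1e-9)
    expect_lt(max(abs(fit$rotation - rot)), 1e-9)
  }
  expect_error(kabsch_superpose(ref, ref[1:5, ]), "mismatch")
  expect_error(kabsch_superpose(cbind(0, 0, 1:5), cbind(0, 0, 5:1)),
               "degenerate")
})

test_that("Kabsch RMSD matches the rotation-grid brute force", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(rnorm(15), 5)
    q <- matrix(rnorm(15), 5)
    fit <- kabsch_superpose(p, q)
    brute <- brute_force_rmsd(p, q)
    expect_gte(brute - fit$rmsd, -1e-9)   # Kabsch is the optimum
    expect_lt(abs(brute - fit$rmsd), 1e-3)
  }
})

test_that("RMSD series is zero for copies and tracks planted noise", {
  ref <- make_peptide_ensemble(n_frames = 1, n_res = 25, seed = 2)
  sel <- motif_definition("core", "A", 1, 25, "all")
  copies <- ref
  copies$coords <- rep(ref$coords, 5)
  copies$frame_meta <- copies$frame_meta[rep(1, 5), ]
  expect_equal(rmsd_series(copies, ref, sel)$values, rep(0, 5),
               tolerance = 1e-9)

  set.seed(8)
  sigma <- 0.5
  noisy <- ref
  noisy$coords <- lapply(1:200, function(i)
    ref$coords[[1]] + matrix(rnorm(length(ref$coords[[1]]), 0, sigma),
                             ncol = 3))
  noisy$frame_meta <- noisy$frame_meta[rep(1, 200), ]
  mean_rmsd <- mean(rmsd_series(noisy, ref, sel)$values)
  expect_equal(mean_rmsd, sigma * sqrt(3), tolerance = 0.05)
})

test_that("fitting one motif isolates the displacement of another", {
  ref <- make_toy_motor(n_frames = 1, cleft_distance = 15,
                        crossing_angle = 20, loop_jitter_sd = 0)
  m <- toy_motor_motifs()
  shift <- c(2, -1, 2)   # |shift| = 3
  moved <- ref
  ib <- which(ref$atoms$chain_id == "B")
  moved$coords[[1]][ib, ] <- sweep(moved$coords[[1]][ib, ], 2, shift, `+`)
  rs <- rmsd_series(moved, ref, fit_selection = m$all_A,
                    measure_selection = m$all_B)
  expect_equal(rs$values, sqrt(sum(shift^2)), tolerance = 1e-9)
})

test_that("RMSD series rejects unmatched atoms with context", {
  ens <- make_peptide_ensemble(n_frames = 2, n_res = 5)
  ref <- make_peptide_ensemble(n_frames = 1, n_res = 3)
  expect_error(rmsd_series(ens, ref, motif_definition("m", "A", 1, 5)),
               "not found in reference")
})

test_that("superposition agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  p <- matrix(rnorm(36), 12)
  q <- p %*% t(random_rotation()) + matrix(rnorm(36, sd = 0.3), 12)
  ours <- kabsch_superpose(p, q)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(q)), as.vector(t(p)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
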