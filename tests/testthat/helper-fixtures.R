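# Shared fixture builders and independent oracles.

# random peptide-like ensemble with a valid atom table; optionally includes
# hydrogens so the "heavy" filter is exercised
make_peptide_ensemble <- function(n_frames = 2, n_res = 5, chain = "A",
                                  with_h = FALSE, seed = 42) {
  set.seed(seed)
  names <- if (with_h) c("N", "CA", "C", "O", "HA", "HB2", "HB3") else
    c("N", "CA", "C", "O")
  elem <- substr(names, 1, 1)
  atoms <- data.frame(
    atom_name = rep(names, n_res),
    residue_name = "ALA",
    chain_id = chain,
    residue_number = rep(seq_len(n_res), each = length(names)),
    element = rep(elem, n_res),
    occupancy = 1,
    stringsAsFactors = FALSE)
  atoms$atom_serial <- seq_len(nrow(atoms))
  coords <- lapply(seq_len(n_frames), function(i)
    matrix(stats::rnorm(nrow(atoms) * 3, sd = 5), ncol = 3))
  new_ensemble(atoms[, c("atom_serial", "atom_name", "residue_name",
                         "chain_id", "residue_number", "element",
                         "occupancy")], coords)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

rigid_transform_ensemble <- function(ens, seed = 1) {
  set.seed(seed)
  ens$coords <- lapply(ens$coords, function(xyz) {
    rot <- random_rotation()
    sweep(xyz %*% t(rot), 2, stats::rnorm(3, sd = 20), `+`)
  })
  ens
}

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# independent superposition oracle: exhaustive Euler-angle grid followed by
# Nelder-Mead polish of the best grid point (never calls the Kabsch path)
brute_force_rmsd <- function(mobile, reference, step_deg = 15) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  step <- step_deg * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi - step, by = step),
                      b = seq(0, pi, by = step),
                      c = seq(0, 2 * pi - step, by = step))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# analytic buried area between two spheres of (probe-inflated) radii r1, r2
# at center distance d < r1 + r2: spherical-cap areas on each sphere
analytic_cap_buried <- function(r1, r2, d) {
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  c(cap1 = 2 * pi * r1 * max(0, h1), cap2 = 2 * pi * r2 * max(0, h2))
}

# single-frame two-atom ensemble with carbon atoms at the given separation
two_atom_ensemble <- function(d, chains = c("A", "B")) {
  atoms <- data.frame(atom_serial = 1:2, atom_name = "C1",
                      residue_name = "LIG", chain_id = chains,
                      residue_number = c(1L, 1L), element = "C",
                      occupancy = 1, stringsAsFactors = FALSE)
  new_ensemble(atoms, list(rbind(c(0, 0, 0), c(d, 0, 0))))
}

# builds a complete on-disk toy-state fixture and a matching config
make_state_fixture <- function(dir, state = "toyA", cleft = list(mean = 15, sd = 1),
                               angle = list(mean = 22, sd = 2),
                               n_frames = 60, seed = 101,
                               clusters = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(2); boosts <- character(2)
  for (r in 1:2) {
    ens <- make_toy_motor(n_frames = n_frames, cleft_distance = cleft,
                          crossing_angle = angle, loop_jitter_sd = 0.1,
                          cluster_centers = clusters, seed = seed + r)
    paths[r] <- file.path(dir, sprintf("%s_rep%d.pdb", state, r))
    write_pdb_ensemble(ens, paths[r])
    boosts[r] <- file.path(dir, sprintf("%s_rep%d.dat", state, r))
    set.seed(seed + 10 + r)
    write_boost_log(abs(rnorm(n_frames, 1, 0.2)), boosts[r])
  }
  list(
    state_label = state,
    ensemble_paths = as.list(paths),
    boost_paths = as.list(boosts),
    boost_dialect = "two_column",
    motifs = list(
      helixA = list(chain = "A", start = 1, end = 12, filter = "CA"),
      strandB = list(chain = "B", start = 13, end = 18, filter = "CA"),
      all_B = list(chain = "B", start = 1, end = 18, filter = "all")),
    distance_cvs = list(
      cleft_width = list(list(chain = "A", residue = 6, atom = "CA"),
                         list(chain = "B", residue = 6, atom = "CA"))),
    angle_cvs = list(hf_rotation = list("helixA", "strandB")),
    profiles_2d = list(list("hf_rotation", "cleft_width")),
    temperature = 300,
    reweighting = list(bins_1d = 12, bins_2d = 8, cumulant_order = 2,
                       min_count = 3, depth_threshold = 0.5),
    clustering = list(selection = "all_B", cutoff = 2.0),
    output_dir = file.path(dir, "out"))
}
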