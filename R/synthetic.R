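# Ground-truth-bearing synthetic inputs: toy two-domain motor ensembles
# with planted collective-variable values, boosted samples from known 1D/2D
# potentials with the GaMD boost form, and Gaussian-mixture CV series.
#
# Sampling is at the distribution level (no dynamics): the analysis
# pipeline only needs (cv, dV) pairs with known truth.

#' Ideal alpha-helix Calpha trace
#'
#' @param n_res number of residues (>= 3).
#' @param radius helix radius, angstrom (default 2.3).
#' @param rise rise per residue along the axis, angstrom (default 1.5).
#' @param twist rotation per residue, degrees (default 100).
#' @return `n_res x 3` coordinate matrix; the helix axis is +z and runs N
#'   to C.
#' @export
ideal_helix <- function(n_res, radius = 2.3, rise = 1.5, twist = 100) {
  i <- seq_len(n_res) - 1L
  th <- i * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

.rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
}

# resolve a per-frame value spec: scalar, per-frame vector, or
# list(mean =, sd =) sampled i.i.d. normal
.per_frame <- function(spec, n) {
  if (is.list(spec)) return(stats::rnorm(n, spec$mean, spec$sd))
  if (length(spec) == 1L) return(rep(as.numeric(spec), n))
  if (length(spec) != n) stop("per-frame spec has wrong length")
  as.numeric(spec)
}

.toy_atoms <- function() {
  one_chain <- function(ch) data.frame(
    atom_name = "CA", residue_name = "ALA", chain_id = ch,
    residue_number = 1:18, element = "C", occupancy = 1,
    stringsAsFactors = FALSE)
  a <- rbind(one_chain("A"), one_chain("B"))
  a$atom_serial <- seq_len(nrow(a))
  a[, c("atom_serial", "atom_name", "residue_name", "chain_id",
        "residue_number", "element", "occupancy")]
}

# one rigid domain: a 12-residue ideal helix (residues 1-12) continued by a
# 6-residue straight strand (residues 13-18) along the helix axis
.toy_domain <- function() {
  helix <- ideal_helix(12)
  strand <- cbind(4, 0, 12 * 1.5 + (0:5) * 3.4)
  rbind(helix, strand)
}

#' Generate a toy two-domain motor ensemble with planted CV values
#'
#' Two Calpha-only rigid domains (each a 12-residue ideal helix plus a
#' 6-residue strand) are positioned so that before jitter the planted cleft
#' distance and inter-domain crossing angle are realized exactly: domain B
#' is domain A rotated by the planted angle about the y axis and translated
#' so the anchor atoms (residue 6 of each chain) sit exactly the planted
#' cleft distance apart along x. Optional planted conformers realize
#' distinct cluster structure. Ground truth (per-frame cleft, angle,
#' conformer labels) is recorded in the `"ground_truth"` attribute; matching
#' motif and anchor definitions come from [toy_motor_motifs()].
#'
#' @param n_frames number of frames.
#' @param cleft_distance planted anchor-anchor distance, angstrom: scalar,
#'   per-frame vector, or `list(mean =, sd =)`.
#' @param crossing_angle planted inter-domain angle, degrees (same forms).
#' @param loop_jitter_sd per-coordinate Gaussian jitter, angstrom.
#' @param cluster_centers optional list of conformer specs, each
#'   `list(cleft =, angle =, weight =)`; overrides `cleft_distance` and
#'   `crossing_angle`.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return An `Ensemble` with attribute `ground_truth` (list: `cleft`,
#'   `angle`, `labels`).
#' @export
make_toy_motor <- function(n_frames = 100, cleft_distance = 15,
                           crossing_angle = 22, loop_jitter_sd = 0.1,
                           cluster_centers = NULL, seed = 1) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (loop_jitter_sd < 0) stop("jitter must be nonnegative")
  set.seed(seed)
  if (!is.null(cluster_centers)) {
    wts <- vapply(cluster_centers, `[[`, numeric(1), "weight")
    if (abs(sum(wts) - 1) > 1e-8) stop("conformer weights must sum to 1")
    counts <- diff(round(cumsum(c(0, wts)) * n_frames))
    labels <- sample(rep(seq_along(cluster_centers), counts))
    cleft <- vapply(cluster_centers, `[[`, numeric(1), "cleft")[labels]
    angle <- vapply(cluster_centers, `[[`, numeric(1), "angle")[labels]
  } else {
    labels <- rep(1L, n_frames)
    cleft <- .per_frame(cleft_distance, n_frames)
    angle <- .per_frame(crossing_angle, n_frames)
  }
  if (any(cleft < 0)) stop("infeasible geometry: negative cleft distance")
  domain <- .toy_domain()
  anchor_row <- 6L   # CA of residue 6
  coords <- lapply(seq_len(n_frames), function(f) {
    b <- domain %*% t(.rot_y(angle[f]))
    shift <- domain[anchor_row, ] + c(cleft[f], 0, 0) - b[anchor_row, ]
    b <- sweep(b, 2, shift, `+`)
    xyz <- rbind(domain, b)
    if (loop_jitter_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, loop_jitter_sd),
                          ncol = 3)
    xyz
  })
  ens <- new_ensemble(.toy_atoms(), coords)
  attr(ens, "ground_truth") <- list(cleft = cleft, angle = angle,
                                    labels = labels)
  ens
}

#' Motif and anchor definitions matching [make_toy_motor()]
#'
#' @return List with motifs `helixA`, `strandA`, `helixB`, `strandB`,
#'   `all_A`, `all_B` and anchors `cleft_a`, `cleft_b`.
#' @export
toy_motor_motifs <- function() {
  list(helixA = motif_definition("helixA", "A", 1, 12, "CA"),
       strandA = motif_definition("strandA", "A", 13, 18, "CA"),
       helixB = motif_definition("helixB", "B", 1, 12, "CA"),
       strandB = motif_definition("strandB", "B", 13, 18, "CA"),
       all_A = motif_definition("all_A", "A", 1, 18, "all"),
       all_B = motif_definition("all_B", "B", 1, 18, "all"),
       cleft_a = atom_anchor("A", 6, "CA"),
       cleft_b = atom_anchor("B", 6, "CA"))
}

# named potentials, kcal/mol
.potential_fun <- function(potential) {
  form <- potential$form
  if (form == "harmonic") {
    k <- potential$k; x0 <- potential$x0
    function(x) 0.5 * k * (x - x0)^2
  } else if (form == "double_well") {
    b <- potential$barrier; half <- potential$separation / 2
    function(x) b * ((x / half)^2 - 1)^2
  } else if (form == "gaussian_2d") {
    mu <- potential$mean
    prec <- solve(matrix(unlist(potential$cov), 2, 2))
    function(x) {
      d <- cbind(x[, 1] - mu[1], x[, 2] - mu[2])
      0.5 * rowSums((d %*% prec) * d)
    }
  } else stop("unknown potential form '", form, "'")
}

# GaMD boost: dV = 0.5 k_boost (E - V)^2 where V < E, else 0
gamd_boost <- function(v, E, k_boost) {
  ifelse(v < E, 0.5 * k_boost * (E - v)^2, 0)
}

#' Draw boosted samples from a known potential
#'
#' Samples follow the biased density `p*(x) proportional to
#' exp(-beta (V + dV))` with the GaMD boost `dV = k_boost (E - V)^2 / 2`
#' applied where `V < E`. 1D potentials are sampled exactly by inverse CDF
#' on a dense grid; the 2D Gaussian-basin potential uses Metropolis
#' sampling (proposal sd = 5 grid spacings, burn-in 1e4 steps, thinning 5).
#' The exact per-sample boost and the true anchored free energy on the
#' analysis grid are returned, so reweighting can be validated by recovery.
#'
#' @param potential list: `form = "harmonic"` (`k`, `x0`),
#'   `"double_well"` (`barrier` kcal/mol, `separation` CV units; wells at
#'   +/- separation/2, barrier at 0), or `"gaussian_2d"` (`mean`, `cov`).
#' @param boost list with `E` (threshold, kcal/mol) and `k_boost`
#'   (kcal/mol per (kcal/mol)^2); `k_boost = 0` disables the boost.
#' @param temperature Kelvin.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param grid_n grid resolution for inverse-CDF sampling and `F_true`.
#' @param range optional sampling range (1D: length 2; 2D: list of two).
#' @return List with `samples` (vector or 2-column matrix), `dV`, `grid`,
#'   `F_true` (`V - min V` on the grid), and the echoed spec.
#' @export
sample_boosted <- function(potential, boost = list(E = 0, k_boost = 0),
                           temperature = 300, n_samples = 1e4, seed = 1,
                           grid_n = 2001, range = NULL) {
  vf <- .potential_fun(potential)
  beta <- 1 / (kB * temperature)
  set.seed(seed)
  if (potential$form == "gaussian_2d") {
    if (is.null(range)) {
      s <- sqrt(diag(matrix(unlist(potential$cov), 2, 2)))
      range <- list(potential$mean[1] + c(-6, 6) * s[1],
                    potential$mean[2] + c(-6, 6) * s[2])
    }
    gx <- seq(range[[1]][1], range[[1]][2], length.out = 101)
    gy <- seq(range[[2]][1], range[[2]][2], length.out = 101)
    vgrid <- matrix(vf(as.matrix(expand.grid(gx, gy))), 101, 101)
    target <- function(x) {
      v <- vf(rbind(x))
      v + gamd_boost(v, boost$E, boost$k_boost)
    }
    prop_sd <- 5 * diff(gx[1:2])
    burn <- 1e4; thin <- 5
    n_iter <- burn + thin * n_samples
    out <- matrix(NA_real_, n_samples, 2)
    cur <- unlist(potential$mean)
    e_cur <- target(cur)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      prop <- cur + stats::rnorm(2, 0, prop_sd)
      e_prop <- target(prop)
      if (log(stats::runif(1)) < -beta * (e_prop - e_cur)) {
        cur <- prop; e_cur <- e_prop
      }
      if (it > burn && (it - burn) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- cur
      }
    }
    v_s <- vf(out)
    return(list(samples = out, dV = gamd_boost(v_s, boost$E, boost$k_boost),
                grid = list(x = gx, y = gy),
                F_true = vgrid - min(vgrid),
                potential = potential, boost = boost,
                temperature = temperature))
  }
  if (is.null(range)) {
    range <- if (potential$form == "double_well") {
      half <- potential$separation / 2
      c(-1, 1) * (half + 2.5)
    } else {
      potential$x0 + c(-1, 1) * sqrt(2 * 12 / potential$k)
    }
  }
  grid <- seq(range[1], range[2], length.out = grid_n)
  v <- vf(grid)
  if (!all(is.finite(v)) || min(v) < -1e6)
    stop("potential must be bounded below on the sampling range")
  vtot <- v + gamd_boost(v, boost$E, boost$k_boost)
  p <- exp(-beta * (vtot - min(vtot)))
  cdf <- cumsum((p[-1] + p[-grid_n]) / 2 * diff(grid))
  cdf <- c(0, cdf / cdf[length(cdf)])
  u <- stats::runif(n_samples)
  x <- stats::approx(cdf, grid, xout = u, ties = "ordered")$y
  v_s <- vf(x)
  list(samples = x, dV = gamd_boost(v_s, boost$E, boost$k_boost),
       grid = grid, F_true = v - min(v),
       potential = potential, boost = boost, temperature = temperature)
}

#' Gaussian-mixture collective-variable series with known modes
#'
#' @param modes list of `c(position, sd, weight)` triples (or lists with
#'   those names); weights must sum to 1.
#' @param n number of samples.
#' @param seed integer seed.
#' @param name CV name.
#' @param unit CV unit.
#' @return A `CVSeries` with attribute `ground_truth` (the mode table and
#'   per-sample component labels).
#' @export
make_bimodal_series <- function(modes, n = 1e4, seed = 1,
                                name = "distance", unit = "A") {
  tab <- do.call(rbind, lapply(modes, function(m) {
    m <- unlist(m)
    if (length(m) != 3L) stop("each mode needs (position, sd, weight)")
    data.frame(position = m[[1]], sd = m[[2]], weight = m[[3]])
  }))
  if (abs(sum(tab$weight) - 1) > 1e-8) stop("mode weights must sum to 1")
  if (any(tab$sd <= 0)) stop("mode sd must be positive")
  set.seed(seed)
  comp <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$weight)
  vals <- stats::rnorm(n, tab$position[comp], tab$sd[comp])
  if (unit == "A") vals <- abs(vals)   # distances are nonnegative
  out <- new_cv_series(name, unit, vals)
  attr(out, "ground_truth") <- list(modes = tab, labels = comp)
  out
}

#' Write a two-column boost log
#'
#' @param dV per-frame boost potentials, kcal/mol.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_boost_log <- function(dV, path) {
  writeLines(c("# frame dV_kcal_mol",
               sprintf("%d %.10g", seq_along(dV) - 1L, dV)), path)
  invisible(path)
}
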