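# Cumulant-expansion reweighting of boosted ensembles into 1D/2D potentials
# of mean force, and basin detection on the resulting landscapes.
#
# GaMD adds a nonnegative boost dV to frames whose potential energy falls
# below a threshold; the biased bin probability p* relates to the true one
# through  p(j) = p*(j) <exp(beta dV)>_j / Z.  The log of the bin-local
# exponential average is expanded in cumulants of dV,
#   ln <exp(beta dV)>_j = beta C1 + beta^2 C2 / 2 + beta^3 C3 / 6 + ...
# (C1 bin mean, C2 bin variance, C3 bin third central moment), truncated at
# `cumulant_order`. The global normalisation cancels when the profile is
# anchored to zero at its minimum.

#' Boltzmann constant in kcal/(mol K)
#' @export
kB <- 0.0019872041

#' Concatenate boosted replica ensembles
#'
#' Replicas are concatenated in list order; each frame keeps its replica id
#' (assigned from the list position when absent). All replicas must share an
#' identical topology and carry boost potentials.
#'
#' @param ensembles list of `Ensemble` objects with `boost_dV` attached.
#' @return A single combined `Ensemble`.
#' @export
combine_replicas <- function(ensembles) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1L)
  ref <- ensembles[[1]]
  key <- function(a) paste(a$chain_id, a$residue_number, a$atom_name,
                           collapse = "\r")
  for (i in seq_along(ensembles)) {
    e <- ensembles[[i]]
    if (!inherits(e, "Ensemble")) stop("replica ", i, " is not an Ensemble")
    if (!identical(key(e$atoms), key(ref$atoms)))
      stop("replica ", i, ": topology differs from replica 1")
    if (anyNA(e$frame_meta$boost_dV))
      stop("replica ", i, ": boost potentials missing")
  }
  coords <- do.call(c, lapply(ensembles, `[[`, "coords"))
  meta <- do.call(rbind, lapply(seq_along(ensembles), function(i) {
    m <- ensembles[[i]]$frame_meta
    if (all(m$replica_id == m$replica_id[1]) && m$replica_id[1] == 0L &&
        length(ensembles) > 1L)
      m$replica_id <- i - 1L
    m
  }))
  rownames(meta) <- NULL
  new_ensemble(ref$atoms, coords, meta)
}

.bin_edges <- function(x, bins) {
  if (length(bins) > 1L) {
    if (is.unsorted(bins, strictly = TRUE)) stop("bin edges must be monotone")
    return(as.numeric(bins))
  }
  lo <- min(x); hi <- max(x)
  if (hi == lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  seq(lo, hi, length.out = bins + 1L)
}

.bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  idx
}

# cumulant correction per bin, in kcal/mol: C1 + beta C2/2 + beta^2 C3/6
.cumulant_term <- function(dv, beta, order) {
  m1 <- mean(dv)
  out <- m1
  if (order >= 2L) {
    c2 <- mean((dv - m1)^2)
    out <- out + beta * c2 / 2
  }
  if (order >= 3L) {
    c3 <- mean((dv - m1)^3)
    out <- out + beta^2 * c3 / 6
  }
  out
}

.new_profile <- function(dims, edges, pmf, counts, mask, temperature, order) {
  structure(list(dims = dims, bin_edges = edges,
                 bin_mids = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
                 pmf = pmf, counts = counts, mask = mask,
                 temperature = temperature, cumulant_order = order),
            class = "FreeEnergyProfile")
}

#' @export
print.FreeEnergyProfile <- function(x, ...) {
  cat("FreeEnergyProfile:", x$dims, "D,",
      paste(vapply(x$bin_edges, function(e) length(e) - 1L, 1L),
            collapse = " x "),
      "bins,", sum(!x$mask), "sampled,", x$temperature, "K, cumulant order",
      x$cumulant_order, "\n")
  invisible(x)
}

#' One-dimensional reweighted potential of mean force
#'
#' Histograms the collective variable, applies the bin-local
#' cumulant-expansion reweighting of the boost potential, and anchors the
#' minimum of the profile at zero. Bins with fewer than `min_count` frames
#' are masked (pmf `NA`). With `dV` identically zero the result is exactly
#' the histogram PMF `-kB T ln p`, anchored.
#'
#' @param cv `CVSeries` or numeric vector.
#' @param dV per-frame boost potentials, kcal/mol (`NULL` means no boost).
#' @param temperature Kelvin.
#' @param bins bin count or explicit edge vector.
#' @param cumulant_order truncation order, 1-3 (default 2, standard GaMD
#'   practice).
#' @param min_count minimum frames per bin for the pmf to be defined.
#' @return A `FreeEnergyProfile`.
#' @export
pmf_1d <- function(cv, dV = NULL, temperature = 300, bins = 50,
                   cumulant_order = 2L, min_count = 20L) {
  x <- cv_values(cv)
  if (is.null(dV)) dV <- rep(0, length(x))
  dV <- cv_values(dV)
  if (length(dV) != length(x))
    stop("cv and dV have different lengths (", length(x), " vs ",
         length(dV), ")")
  if (temperature <= 0) stop("temperature must be positive")
  if (!cumulant_order %in% 1:3) stop("cumulant_order must be 1, 2 or 3")
  edges <- .bin_edges(x, bins)
  nb <- length(edges) - 1L
  idx <- .bin_index(x, edges)
  counts <- tabulate(idx, nb)
  mask <- counts < min_count
  if (all(mask)) stop("all bins are under-sampled (min_count = ",
                      min_count, ")")
  kT <- kB * temperature
  beta <- 1 / kT
  pmf <- rep(NA_real_, nb)
  for (j in which(!mask)) {
    p_star <- counts[j] / length(x)
    corr <- .cumulant_term(dV[which(idx == j)], beta, cumulant_order)
    pmf[j] <- -kT * log(p_star) - corr
  }
  pmf <- pmf - min(pmf, na.rm = TRUE)
  .new_profile(1L, list(edges), pmf, counts, mask, temperature,
               as.integer(cumulant_order))
}

#' Two-dimensional reweighted potential of mean force
#'
#' As [pmf_1d()] on a 2D histogram of two collective variables.
#'
#' @param cv1,cv2 `CVSeries` or numeric vectors of equal length.
#' @param dV per-frame boost potentials, kcal/mol (`NULL` means no boost).
#' @param temperature Kelvin.
#' @param bins per-dimension bin count (scalar or length-2) or list of two
#'   edge vectors.
#' @param cumulant_order truncation order, 1-3.
#' @param min_count minimum frames per bin.
#' @return A `FreeEnergyProfile` with `pmf`, `counts`, `mask` as matrices
#'   (rows index `cv1` bins).
#' @export
pmf_2d <- function(cv1, cv2, dV = NULL, temperature = 300, bins = 40,
                   cumulant_order = 2L, min_count = 20L) {
  x <- cv_values(cv1); y <- cv_values(cv2)
  if (length(x) != length(y)) stop("cv1 and cv2 have different lengths")
  if (is.null(dV)) dV <- rep(0, length(x))
  dV <- cv_values(dV)
  if (length(dV) != length(x)) stop("cv and dV have different lengths")
  if (temperature <= 0) stop("temperature must be positive")
  if (!cumulant_order %in% 1:3) stop("cumulant_order must be 1, 2 or 3")
  if (is.list(bins)) {
    e1 <- .bin_edges(x, bins[[1]]); e2 <- .bin_edges(y, bins[[2]])
  } else {
    if (length(bins) == 1L) bins <- c(bins, bins)
    e1 <- .bin_edges(x, bins[1]); e2 <- .bin_edges(y, bins[2])
  }
  n1 <- length(e1) - 1L; n2 <- length(e2) - 1L
  i1 <- .bin_index(x, e1); i2 <- .bin_index(y, e2)
  flat <- (i1 - 1L) * n2 + i2
  counts <- matrix(tabulate(flat, n1 * n2), nrow = n1, ncol = n2,
                   byrow = TRUE)
  mask <- counts < min_count
  if (all(mask)) stop("all bins are under-sampled")
  kT <- kB * temperature
  beta <- 1 / kT
  pmf <- matrix(NA_real_, n1, n2)
  for (j in which(!mask)) {
    r <- (j - 1L) %% n1 + 1L; c <- (j - 1L) %/% n1 + 1L
    sel <- which(flat == (r - 1L) * n2 + c)
    p_star <- counts[r, c] / length(x)
    pmf[r, c] <- -kT * log(p_star) -
      .cumulant_term(dV[sel], beta, cumulant_order)
  }
  pmf <- pmf - min(pmf, na.rm = TRUE)
  .new_profile(2L, list(e1, e2), pmf, counts, mask, temperature,
               as.integer(cumulant_order))
}

#' Detect and label energy basins on a free-energy profile
#'
#' Local minima over the unmasked bin graph (2-neighborhood in 1D,
#' 4-neighborhood in 2D). Minima whose depth below their lowest connecting
#' saddle is smaller than `depth_threshold` are merged into the deeper
#' neighboring basin (persistence criterion). Surviving basins are labeled
#' `m1`, `m2`, ... by ascending free energy, so `m1` is the global minimum.
#'
#' @param profile a `FreeEnergyProfile`.
#' @param depth_threshold minimum basin depth (kcal/mol) relative to its
#'   lowest saddle.
#' @return Object of class `BasinSet`: data.frame with `label`, bin indices,
#'   `pmf_value`, and bin-center coordinates.
#' @export
find_basins <- function(profile, depth_threshold = 0) {
  stopifnot(inherits(profile, "FreeEnergyProfile"))
  if (profile$dims == 1L) {
    pmf <- profile$pmf
    pos <- which(!profile$mask)
    neighbor_bins <- function(i) c(i - 1L, i + 1L)
  } else {
    pmf <- as.vector(profile$pmf)   # column-major over (i1, i2)
    n1 <- nrow(profile$pmf); n2 <- ncol(profile$pmf)
    pos <- which(!as.vector(profile$mask))
    neighbor_bins <- function(i) {
      r <- (i - 1L) %% n1 + 1L; c <- (i - 1L) %/% n1 + 1L
      c(if (r > 1L) i - 1L, if (r < n1) i + 1L,
        if (c > 1L) i - n1, if (c < n2) i + n1)
    }
  }
  vals <- pmf[pos]
  ord <- order(vals, pos)
  comp <- rep(NA_integer_, length(pos))   # union-find id per processed bin
  parent <- integer(0)
  root_min <- numeric(0)                  # birth pmf per component
  root_bin <- integer(0)                  # bin index of the component minimum
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  retained <- list()
  for (k in ord) {
    nb_k <- match(neighbor_bins(pos[k]), pos)
    nb_k <- nb_k[!is.na(nb_k)]
    nb_k <- nb_k[!is.na(comp[nb_k])]
    roots <- unique(vapply(nb_k, function(j) find_root(comp[j]),
                           integer(1)))
    if (length(roots) == 0L) {
      rid <- length(parent) + 1L
      parent[rid] <- rid
      root_min[rid] <- vals[k]
      root_bin[rid] <- pos[k]
      comp[k] <- rid
    } else {
      deepest <- roots[which.min(root_min[roots])]
      for (r in roots[roots != deepest]) {
        # vals[k] is the saddle connecting component r to a deeper one
        if (vals[k] - root_min[r] >= depth_threshold)
          retained[[length(retained) + 1L]] <-
            list(bin = root_bin[r], pmf = root_min[r])
        parent[r] <- deepest
      }
      comp[k] <- deepest
    }
  }
  # components never merged away survive (the global minimum among them)
  for (r in which(parent == seq_along(parent)))
    retained[[length(retained) + 1L]] <- list(bin = root_bin[r],
                                              pmf = root_min[r])
  df <- do.call(rbind, lapply(retained, function(b) {
    if (profile$dims == 1L) {
      data.frame(bin1 = b$bin, bin2 = NA_integer_, pmf_value = b$pmf,
                 cv1 = profile$bin_mids[[1]][b$bin], cv2 = NA_real_)
    } else {
      n1 <- nrow(profile$pmf)
      r1 <- (b$bin - 1L) %% n1 + 1L; c1 <- (b$bin - 1L) %/% n1 + 1L
      data.frame(bin1 = r1, bin2 = c1, pmf_value = b$pmf,
                 cv1 = profile$bin_mids[[1]][r1],
                 cv2 = profile$bin_mids[[2]][c1])
    }
  }))
  df <- df[order(df$pmf_value, df$bin1), , drop = FALSE]
  df <- cbind(label = paste0("m", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  class(df) <- c("BasinSet", "data.frame")
  df
}

#' Flag bins where the boost distribution departs from Gaussian
#'
#' The cumulant expansion truncated at second order is reliable when the
#' per-bin boost-potential distribution is near-Gaussian. Bins whose
#' absolute skewness exceeds `skew_threshold` are flagged; bins with fewer
#' than `min_count` frames are `NA`.
#'
#' @param dV_by_bin list of numeric vectors, boost potentials per bin (see
#'   [split_dv_by_bin()]).
#' @param skew_threshold absolute skewness above which a bin is flagged.
#' @param min_count minimum frames for the diagnostic to be computed.
#' @return Logical vector, one flag per bin.
#' @export
anharmonicity_check <- function(dV_by_bin, skew_threshold = 0.5,
                                min_count = 20L) {
  vapply(dV_by_bin, function(dv) {
    if (length(dv) < min_count) return(NA)
    m <- mean(dv)
    s2 <- mean((dv - m)^2)
    if (s2 < 1e-12) return(FALSE)
    skew <- mean((dv - m)^3) / s2^1.5
    abs(skew) > skew_threshold
  }, logical(1))
}

#' Split per-frame boost potentials by the bins of a collective variable
#'
#' @param cv `CVSeries` or numeric vector.
#' @param dV per-frame boost potentials.
#' @param bins bin count or explicit edges (as in [pmf_1d()]).
#' @return List of numeric vectors, one per bin.
#' @export
split_dv_by_bin <- function(cv, dV, bins = 50) {
  x <- cv_values(cv); dV <- cv_values(dV)
  edges <- .bin_edges(x, bins)
  idx <- .bin_index(x, edges)
  lapply(seq_len(length(edges) - 1L), function(j) dV[which(idx == j)])
}
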