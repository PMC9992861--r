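# Ensemble clustering (GROMOS leader algorithm), centroid extraction, and
# 1D distribution characterisation (KDE, peaks, most-probable values).

#' Pairwise RMSD matrix over a selection
#'
#' Entry (i, j) is the Kabsch superposition RMSD between frames i and j
#' restricted to the selection.
#'
#' @param ensemble an `Ensemble` with at least 2 frames.
#' @param selection a [motif_definition()], or a list of them whose
#'   resolved selections are pooled (needed when the conformational change
#'   of interest is the relative arrangement of several chains or motifs).
#' @return Symmetric numeric matrix (angstrom) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(ensemble, selection) {
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("pairwise RMSD needs at least 2 frames")
  idx <- if (inherits(selection, "MotifDefinition"))
    resolve_selection(ensemble, selection)
  else
    sort(unique(unlist(lapply(selection, resolve_selection,
                              ensemble = ensemble))))
  xyz <- lapply(ensemble$coords, function(m) m[idx, , drop = FALSE])
  out <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      r <- tryCatch(kabsch_superpose(xyz[[i]], xyz[[j]])$rmsd,
                    error = function(e)
                      stop("frames ", i, "/", j, ": ",
                           conditionMessage(e), call. = FALSE))
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  out
}

#' Cluster an ensemble with the GROMOS leader algorithm
#'
#' Iteratively, the frame with the most neighbors within `cutoff` becomes a
#' cluster center; it and its neighbors are removed and the procedure
#' repeats on the remainder. Ties are broken by lowest frame index. Cluster
#' ids are 0-based and ordered by descending population; the centroid of
#' each cluster is the member minimizing mean RMSD to the other members.
#'
#' @param matrix symmetric pairwise RMSD matrix (angstrom).
#' @param cutoff neighbor cutoff, angstrom (default 2.0).
#' @return Object of class `ClusterResult`: list with `assignment` (0-based
#'   per-frame id), `populations`, `centroid_frames` (1-based frame
#'   indices), `cutoff`.
#' @export
cluster_leader <- function(matrix, cutoff = 2.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  nf <- nrow(matrix)
  remaining <- rep(TRUE, nf)
  assignment <- rep(NA_integer_, nf)
  centers <- integer(0)
  cid <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    nb_counts <- vapply(idx, function(i)
      sum(matrix[i, idx] < cutoff), integer(1))   # includes self
    center <- idx[which.max(nb_counts)]           # which.max: lowest on ties
    members <- idx[matrix[center, idx] < cutoff]
    assignment[members] <- cid
    centers <- c(centers, center)
    remaining[members] <- FALSE
    cid <- cid + 1L
  }
  pops <- tabulate(assignment + 1L, cid)
  # reorder ids by descending population (ties: earliest center frame)
  ord <- order(-pops, centers)
  relabel <- integer(cid); relabel[ord] <- seq_len(cid) - 1L
  assignment <- relabel[assignment + 1L]
  pops <- pops[ord]
  centroids <- vapply(seq_len(cid) - 1L, function(k)
    centroid_frame(matrix, which(assignment == k)), integer(1))
  structure(list(assignment = assignment, populations = pops,
                 centroid_frames = centroids, cutoff = cutoff),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", length(x$populations), "cluster(s), cutoff",
      x$cutoff, "A\n  populations:",
      paste(x$populations, collapse = " "), "\n")
  invisible(x)
}

#' Centroid frame of a cluster
#'
#' The member minimizing mean RMSD to the other members; ties broken by
#' lowest frame index.
#'
#' @param matrix pairwise RMSD matrix.
#' @param member_indices 1-based frame indices of the cluster members.
#' @return The centroid's 1-based frame index.
#' @export
centroid_frame <- function(matrix, member_indices) {
  if (length(member_indices) == 0L) stop("empty member list")
  if (length(member_indices) == 1L) return(as.integer(member_indices))
  sub <- matrix[member_indices, member_indices, drop = FALSE]
  as.integer(member_indices[which.min(rowMeans(sub))])
}

#' Gaussian kernel density of a collective variable
#'
#' Density on a 512-point grid spanning the data range padded by three
#' bandwidths. Optional per-frame weights (e.g. reweighting factors) are
#' normalized internally. `bandwidth = "auto"` uses Silverman's rule.
#' A zero-variance series yields a degenerate single-delta report rather
#' than an error.
#'
#' @param cv `CVSeries` or numeric vector with at least 10 values.
#' @param weights optional nonnegative per-frame weights.
#' @param bandwidth numeric bandwidth in CV units, or `"auto"`.
#' @param n_grid grid size.
#' @return List of class `density_curve` with `x`, `y`, `bandwidth`,
#'   `degenerate`.
#' @export
density_1d <- function(cv, weights = NULL, bandwidth = "auto",
                       n_grid = 512L) {
  x <- cv_values(cv)
  if (length(x) < 10L) stop("density_1d needs at least 10 values")
  if (!is.null(weights)) {
    if (length(weights) != length(x)) stop("weights length mismatch")
    if (any(weights < 0)) stop("weights must be nonnegative")
    weights <- weights / sum(weights)
  }
  if (stats::sd(x) < 1e-12) {
    return(structure(list(x = x[1], y = Inf, bandwidth = 0,
                          degenerate = TRUE), class = "density_curve"))
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(x) else
    as.numeric(bandwidth)
  d <- stats::density(x, bw = bw, kernel = "gaussian", weights = weights,
                      n = n_grid, cut = 3)
  structure(list(x = d$x, y = d$y, bandwidth = bw, degenerate = FALSE),
            class = "density_curve")
}

#' Detect peaks in a density curve
#'
#' Local maxima whose topographic prominence is at least
#' `prominence_fraction` of the global maximum density, ordered by
#' descending density.
#'
#' @param curve a `density_curve` from [density_1d()].
#' @param prominence_fraction fraction of the global maximum density.
#' @return Object of class `PeakReport`: data.frame with `position`,
#'   `density`, `prominence`; attribute `bandwidth`.
#' @export
find_peaks_1d <- function(curve, prominence_fraction = 0.05) {
  if (isTRUE(curve$degenerate)) {
    out <- data.frame(position = curve$x[1], density = Inf, prominence = Inf)
    attr(out, "bandwidth") <- 0
    class(out) <- c("PeakReport", "data.frame")
    return(out)
  }
  y <- curve$y
  n <- length(y)
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(is_peak, function(i) {
    h <- y[i]
    # walk outward until a higher point; prominence relative to the higher
    # of the two valley floors (global max: full height)
    left <- y[seq_len(i - 1L)]
    right <- y[seq(i + 1L, n)]
    lmin <- if (any(left > h)) min(y[max(which(left > h)):i]) else 0
    rmin <- if (any(right > h)) min(y[i:(i + min(which(right > h)))]) else 0
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence_fraction * max(y)
  out <- data.frame(position = curve$x[is_peak[keep]],
                    density = y[is_peak[keep]],
                    prominence = prom[keep])
  out <- out[order(-out$density), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bandwidth") <- curve$bandwidth
  class(out) <- c("PeakReport", "data.frame")
  out
}

#' Summary statistics of a collective variable distribution
#'
#' @param cv `CVSeries` or numeric vector.
#' @param weights optional per-frame weights.
#' @return List with `most_probable` (highest-density position), `mean`,
#'   `sd` (weighted when weights are given).
#' @export
state_summary <- function(cv, weights = NULL) {
  x <- cv_values(cv)
  if (stats::sd(x) < 1e-12)
    return(list(most_probable = x[1], mean = x[1], sd = 0))
  curve <- density_1d(x, weights = weights)
  mp <- curve$x[which.max(curve$y)]
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  w <- w / sum(w)
  m <- sum(w * x)
  list(most_probable = mp, mean = m, sd = sqrt(sum(w * (x - m)^2)))
}
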