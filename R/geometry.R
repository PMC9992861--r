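# Per-frame collective variables: distances, cleft width, crossing angles,
# buried contact areas, and superposition RMSD.

#' Construct a named collective-variable series
#'
#' @param name CV name.
#' @param unit one of `"A"` (angstrom), `"deg"`, `"A^2"`.
#' @param values per-frame numeric values, same order as the ensemble.
#' @return An object of class `CVSeries`.
#' @export
new_cv_series <- function(name, unit = c("A", "deg", "A^2"), values) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("CV '", name, "': non-finite values")
  if (unit == "deg" && any(values < 0 | values > 180))
    stop("CV '", name, "': angles must lie in [0, 180] degrees")
  if (unit == "A^2" && any(values < 0))
    stop("CV '", name, "': areas must be nonnegative")
  structure(list(name = name, unit = unit, values = values),
            class = "CVSeries")
}

#' @export
print.CVSeries <- function(x, ...) {
  cat("CVSeries '", x$name, "' (", x$unit, "), ", length(x$values),
      " frames, range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

cv_values <- function(cv) if (inherits(cv, "CVSeries")) cv$values else
  as.numeric(cv)

#' Define a single-atom anchor
#'
#' @param chain_id single-character chain id.
#' @param residue_number author residue number.
#' @param atom_name PDB atom name (e.g. `"CA"`, `"CD"`, `"NZ"`).
#' @return An object of class `AtomAnchor`.
#' @export
atom_anchor <- function(chain_id, residue_number, atom_name = "CA") {
  structure(list(chain_id = chain_id,
                 residue_number = as.integer(residue_number),
                 atom_name = atom_name),
            class = "AtomAnchor")
}

resolve_anchor <- function(ensemble, anchor) {
  a <- ensemble$atoms
  idx <- which(a$chain_id == anchor$chain_id &
                 a$residue_number == anchor$residue_number &
                 a$atom_name == anchor$atom_name)
  if (length(idx) != 1L)
    stop("anchor ", anchor$chain_id, "/", anchor$residue_number, "/",
         anchor$atom_name, " resolves to ", length(idx),
         " atoms (need exactly 1)")
  idx
}

#' Atom-pair distance collective variable
#'
#' Euclidean distance between two uniquely resolved atoms, per frame.
#'
#' @param ensemble an `Ensemble`.
#' @param a,b [atom_anchor()] objects.
#' @param name CV name (default `"distance"`).
#' @return A `CVSeries` in angstrom.
#' @export
distance_cv <- function(ensemble, a, b, name = "distance") {
  ia <- resolve_anchor(ensemble, a)
  ib <- resolve_anchor(ensemble, b)
  vals <- vapply(ensemble$coords, function(xyz)
    sqrt(sum((xyz[ia, ] - xyz[ib, ])^2)), numeric(1))
  new_cv_series(name, "A", vals)
}

#' Actin-binding cleft width
#'
#' The cleft width is measured as the Calpha-Calpha distance between a
#' residue preceding the CM loop and a residue of the helix-loop-helix
#' motif (e.g. V417 and K542 in human cardiac myosin); it reports the
#' open/closed state of the cleft between the upper and lower 50-kDa
#' subdomains.
#'
#' @param ensemble an `Ensemble`.
#' @param res_a,res_b [atom_anchor()] objects; atom name defaults to `"CA"`.
#' @return A `CVSeries` named `"cleft_width"` in angstrom.
#' @export
cleft_width <- function(ensemble, res_a, res_b) {
  out <- distance_cv(ensemble, res_a, res_b, name = "cleft_width")
  out
}

#' Fit the directed axis of a secondary-structure element
#'
#' Principal component of the centered Calpha positions, sign-oriented so
#' the axis points from the first residue toward the last (N to C). For
#' five or more points the positions are first smoothed by averaging
#' residues two apart (`(p[i] + p[i+2]) / 2`), which suppresses the
#' helical-wheel component that would otherwise tilt the principal axis of
#' a short helix; collinear strands are unaffected by the smoothing.
#'
#' @param coords ordered `n x 3` matrix of Calpha coordinates, `n >= 3`.
#' @return Unit 3-vector.
#' @export
fit_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("fit_axis needs at least 3 points")
  n <- nrow(coords)
  pts <- if (n >= 5L)
    (coords[1:(n - 2L), , drop = FALSE] +
       coords[3:n, , drop = FALSE]) / 2 else coords
  centered <- sweep(pts, 2, colMeans(pts))
  if (max(abs(centered)) < 1e-9)
    stop("degenerate geometry: all points coincide")
  sv <- svd(centered, nu = 0, nv = 1)
  axis <- sv$v[, 1]
  chord <- coords[nrow(coords), ] - coords[1, ]
  if (sum(axis * chord) < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}

#' Crossing angle between two secondary-structure elements
#'
#' Per frame, the axes of both elements are fitted to their Calpha atoms
#' (directed N to C) and the angle between them is reported in degrees,
#' range \eqn{[0, 180]}. Directed axes distinguish parallel from
#' antiparallel packing, which the undirected \eqn{[0, 90]} convention
#' cannot.
#'
#' @param ensemble an `Ensemble`.
#' @param elem1,elem2 [motif_definition()] objects; their Calpha atoms are
#'   used regardless of the stored filter.
#' @param name CV name.
#' @return A `CVSeries` in degrees.
#' @export
crossing_angle <- function(ensemble, elem1, elem2, name = "crossing_angle") {
  ca1 <- motif_definition(elem1$name, elem1$chain_id, elem1$residue_range[1],
                          elem1$residue_range[2], "CA")
  ca2 <- motif_definition(elem2$name, elem2$chain_id, elem2$residue_range[1],
                          elem2$residue_range[2], "CA")
  i1 <- resolve_selection(ensemble, ca1)
  i2 <- resolve_selection(ensemble, ca2)
  if (length(i1) < 3L || length(i2) < 3L)
    stop("crossing_angle: both elements need >= 3 CA atoms")
  vals <- vapply(ensemble$coords, function(xyz) {
    a1 <- tryCatch(fit_axis(xyz[i1, ]), error = function(e)
      stop("element ", elem1$name, ": ", conditionMessage(e), call. = FALSE))
    a2 <- tryCatch(fit_axis(xyz[i2, ]), error = function(e)
      stop("element ", elem2$name, ": ", conditionMessage(e), call. = FALSE))
    d <- max(-1, min(1, sum(a1 * a2)))
    acos(d) * 180 / pi
  }, numeric(1))
  new_cv_series(name, "deg", vals)
}

# Bondi-style van der Waals radii (angstrom) by element
.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

vdw_radii <- function(elements, radii = .default_vdw, default = 1.70) {
  r <- unname(radii[toupper(elements)])
  r[is.na(r)] <- default
  r
}

# deterministic Fibonacci sphere lattice of n unit vectors
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Shrake-Rupley core: accessible area of each atom in `subset`, occluded by
# all atoms in `system` (indices into coords/radii). Radii are already
# probe-inflated.
.sasa_core <- function(coords, radii, subset, system, n_points) {
  lattice <- fibonacci_sphere(n_points)
  sys_xyz <- coords[system, , drop = FALSE]
  sys_r2 <- radii[system]^2
  vapply(subset, function(i) {
    ri <- radii[i]
    pts <- sweep(lattice * ri, 2, coords[i, ], `+`)
    others <- system[system != i]
    if (length(others)) {
      d_cent <- sqrt(colSums((t(coords[others, , drop = FALSE]) -
                                coords[i, ])^2))
      near <- others[d_cent < ri + radii[others]]
      acc <- rep(TRUE, n_points)
      for (j in near) {
        dx <- pts[, 1] - coords[j, 1]
        dy <- pts[, 2] - coords[j, 2]
        dz <- pts[, 3] - coords[j, 3]
        acc <- acc & (dx * dx + dy * dy + dz * dz >= radii[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    4 * pi * ri^2 * frac
  }, numeric(1))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area with probe-inflated van der Waals radii, using a
#' deterministic Fibonacci sphere lattice. Only the atoms in `atom_subset`
#' form the system: they occlude each other and nothing else does.
#'
#' @param coords `n x 3` coordinate matrix (angstrom) of one frame.
#' @param elements per-atom element symbols (length `n`).
#' @param atom_subset indices of the atoms forming the system.
#' @param probe_radius probe radius, angstrom (water: 1.4).
#' @param n_sphere_points lattice size; quadrature error shrinks roughly as
#'   `1/n`.
#' @param radii named per-element radius overrides, angstrom.
#' @param default_radius fallback radius for unlisted elements.
#' @return Numeric vector of per-atom areas (angstrom squared) for
#'   `atom_subset`.
#' @export
sasa <- function(coords, elements, atom_subset = seq_len(nrow(coords)),
                 probe_radius = 1.4, n_sphere_points = 960,
                 radii = .default_vdw, default_radius = 1.70) {
  coords <- as.matrix(coords)
  if (length(atom_subset) == 0L) stop("empty atom subset")
  r <- vdw_radii(elements, radii, default_radius) + probe_radius
  .sasa_core(coords, r, atom_subset, atom_subset, n_sphere_points)
}

#' Buried contact area between two atom groups
#'
#' Per frame, `(SASA_A + SASA_B - SASA_AB) / 2` where `SASA_A` and `SASA_B`
#' are the summed accessible areas of each group computed in isolation and
#' `SASA_AB` is computed for the combined system. The default pairwise mode
#' ignores all other atoms; `context = TRUE` includes the rest of the
#' structure as occluders in every term.
#'
#' @param ensemble an `Ensemble`.
#' @param group_a,group_b disjoint [motif_definition()] objects.
#' @param probe probe radius, angstrom.
#' @param n_points sphere lattice size.
#' @param context include all remaining atoms as occluders.
#' @param name CV name.
#' @return A `CVSeries` in angstrom squared.
#' @export
contact_area <- function(ensemble, group_a, group_b, probe = 1.4,
                         n_points = 960, context = FALSE,
                         name = "contact_area") {
  ia <- resolve_selection(ensemble, group_a)
  ib <- resolve_selection(ensemble, group_b)
  if (length(intersect(ia, ib)))
    stop("contact_area: groups '", group_a$name, "' and '", group_b$name,
         "' share atoms")
  r <- vdw_radii(ensemble$atoms$element) + probe
  rest <- if (context)
    setdiff(seq_len(nrow(ensemble$atoms)), c(ia, ib)) else integer(0)
  vals <- vapply(ensemble$coords, function(xyz) {
    sa <- sum(.sasa_core(xyz, r, ia, c(ia, rest), n_points))
    sb <- sum(.sasa_core(xyz, r, ib, c(ib, rest), n_points))
    sab <- sum(.sasa_core(xyz, r, c(ia, ib), c(ia, ib, rest), n_points))
    max(0, (sa + sb - sab) / 2)
  }, numeric(1))
  new_cv_series(name, "A^2", vals)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto
#' `reference`, with the reflection corrected so the rotation is proper
#' (determinant +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights optional nonnegative per-point weights.
#' @return List with `rotation` (3x3), `translation` (3-vector) such that
#'   `mobile %*% t(rotation) + translation` superposes onto `reference`,
#'   and `rmsd` (angstrom, post-fit, weighted root mean square).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point count mismatch: ", nrow(mobile), " vs ", nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs >= 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  mc <- colSums(mobile * w); rc <- colSums(reference * w)
  p <- sweep(mobile, 2, mc); q <- sweep(reference, 2, rc)
  cov <- t(p * w) %*% q
  sv <- svd(cov)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: rank-deficient covariance")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - q)^2)))
  list(rotation = rot, translation = as.numeric(rc - rot %*% mc), rmsd = rmsd)
}

# match selection atoms between an ensemble topology and a reference atom
# table by (chain, residue number, atom name)
.match_atoms <- function(ens_atoms, ref_atoms, idx) {
  key <- function(a, i) paste(a$chain_id[i], a$residue_number[i],
                              a$atom_name[i])
  k <- key(ens_atoms, idx)
  ref_key <- key(ref_atoms, seq_len(nrow(ref_atoms)))
  m <- match(k, ref_key)
  if (anyNA(m)) {
    miss <- k[is.na(m)]
    stop("atoms not found in reference: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  m
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is superposed on the reference over `fit_selection` and the
#' RMSD is reported over `measure_selection`. Atoms are matched by
#' (chain, residue number, atom name); the selections default to heavy
#' atoms via their motif filters.
#'
#' @param ensemble an `Ensemble`.
#' @param reference single-frame `Ensemble` (or the same topology).
#' @param fit_selection,measure_selection [motif_definition()] objects;
#'   `measure_selection` defaults to `fit_selection`.
#' @param name CV name.
#' @return A `CVSeries` in angstrom.
#' @export
rmsd_series <- function(ensemble, reference, fit_selection,
                        measure_selection = fit_selection,
                        name = "rmsd") {
  stopifnot(inherits(reference, "Ensemble"))
  ref_xyz <- reference$coords[[1]]
  ifit <- resolve_selection(ensemble, fit_selection)
  imeas <- resolve_selection(ensemble, measure_selection)
  rfit <- .match_atoms(ensemble$atoms, reference$atoms, ifit)
  rmeas <- .match_atoms(ensemble$atoms, reference$atoms, imeas)
  vals <- vapply(ensemble$coords, function(xyz) {
    fit <- kabsch_superpose(xyz[ifit, , drop = FALSE],
                            ref_xyz[rfit, , drop = FALSE])
    moved <- xyz[imeas, , drop = FALSE] %*% t(fit$rotation)
    moved <- sweep(moved, 2, fit$translation, `+`)
    sqrt(mean(rowSums((moved - ref_xyz[rmeas, , drop = FALSE])^2)))
  }, numeric(1))
  new_cv_series(name, "A", vals)
}
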