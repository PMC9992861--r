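# Multi-model PDB ensembles, boost-potential logs and motif selections.
#
# An ensemble is a list with class "Ensemble":
#   atoms      data.frame topology shared by all frames (atom_serial,
#              atom_name, residue_name, chain_id, residue_number, element,
#              occupancy, altloc)
#   coords     list of n_atoms x 3 matrices (angstrom), one per frame
#   frame_meta data.frame with one row per frame (replica_id, state_label,
#              boost_dV); boost_dV is NA until a boost log is attached

#' Construct an ensemble from a topology and per-frame coordinates
#'
#' @param atoms data.frame with columns `atom_serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_number`, `element`, `occupancy`.
#' @param coords list of numeric `n_atoms x 3` matrices, one per frame.
#' @param frame_meta optional data.frame with one row per frame; columns
#'   `replica_id`, `state_label`, `boost_dV` are filled with defaults when
#'   absent.
#' @return An object of class `Ensemble`.
#' @export
new_ensemble <- function(atoms, coords, frame_meta = NULL) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1L)
  n_atoms <- nrow(atoms)
  for (i in seq_along(coords)) {
    xyz <- coords[[i]]
    if (!is.matrix(xyz) || ncol(xyz) != 3L || nrow(xyz) != n_atoms)
      stop("frame ", i, ": coordinates must be a ", n_atoms, " x 3 matrix")
    if (!all(is.finite(xyz)))
      stop("frame ", i, ": non-finite coordinates")
  }
  n_frames <- length(coords)
  if (is.null(frame_meta)) {
    frame_meta <- data.frame(replica_id = rep(0L, n_frames),
                             state_label = rep("custom", n_frames),
                             boost_dV = rep(NA_real_, n_frames))
  }
  stopifnot(nrow(frame_meta) == n_frames)
  for (col in c("replica_id", "state_label", "boost_dV")) {
    if (is.null(frame_meta[[col]]))
      frame_meta[[col]] <- switch(col, replica_id = 0L,
                                  state_label = "custom", boost_dV = NA_real_)
  }
  structure(list(atoms = atoms, coords = coords, frame_meta = frame_meta),
            class = "Ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble an `Ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$coords)

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", n_frames(x), "frame(s),", nrow(x$atoms), "atoms, chains:",
      paste(unique(x$atoms$chain_id), collapse = " "), "\n")
  if (any(is.finite(x$frame_meta$boost_dV)))
    cat("  boost potentials attached (kcal/mol)\n")
  invisible(x)
}

# fixed wwPDB v3.3 columns for one ATOM/HETATM line
.parse_atom_lines <- function(lines, line_numbers) {
  sub_num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(lines, a, b)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("unparseable ATOM record at line ", line_numbers[bad[1]],
           ": ", lines[bad[1]], call. = FALSE)
    v
  }
  icode <- trimws(substr(lines, 27, 27))
  if (any(icode != ""))
    stop("insertion codes are not supported (line ",
         line_numbers[which(icode != "")[1]], ")", call. = FALSE)
  name <- trimws(substr(lines, 13, 16))
  element <- trimws(substr(lines, 77, 78))
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  # infer element from the atom name when columns 77-78 are blank
  guess <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  element <- ifelse(element == "", guess, element)
  data.frame(
    atom_serial = as.integer(sub_num(7, 11)),
    atom_name = name,
    altloc = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    residue_number = as.integer(sub_num(23, 26)),
    x = sub_num(31, 38), y = sub_num(39, 46), z = sub_num(47, 54),
    occupancy = occ,
    element = element,
    stringsAsFactors = FALSE)
}

# altloc policy: keep the highest-occupancy location; ties go to the
# lexicographically smallest altloc id
.resolve_altloc <- function(df) {
  if (all(df$altloc %in% c(" ", "")))
    return(df)
  key <- paste(df$chain_id, df$residue_number, df$atom_name, sep = "\r")
  ord <- order(key, -df$occupancy, df$altloc)
  df <- df[ord, ]
  keep <- !duplicated(paste(df$chain_id, df$residue_number, df$atom_name,
                            sep = "\r"))
  df <- df[keep, ]
  df[order(df$atom_serial), ]
}

#' Read a multi-model PDB file as an ensemble
#'
#' One frame per `MODEL`/`ENDMDL` block; a file without MODEL records is read
#' as a single implicit model. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by altloc id); hydrogens are
#' retained. All models must share an identical
#' (chain, residue number, atom name) sequence.
#'
#' @param path path to a PDB file.
#' @return An [new_ensemble()] `Ensemble`.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0L) {
    blocks <- list(which(is_atom))
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    if (length(ends) < length(model_starts)) ends <- c(ends, length(lines))
    blocks <- mapply(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, ends[seq_along(model_starts)], SIMPLIFY = FALSE)
  }
  blocks <- Filter(length, blocks)
  if (length(blocks) == 0L) stop("no ATOM records found in ", path)

  frames <- lapply(blocks, function(idx) {
    .resolve_altloc(.parse_atom_lines(lines[idx], idx))
  })
  ref <- frames[[1]]
  ref_key <- paste(ref$chain_id, ref$residue_number, ref$atom_name)
  for (i in seq_along(frames)[-1]) {
    f <- frames[[i]]
    if (nrow(f) != nrow(ref))
      stop("topology mismatch: model ", i, " has ", nrow(f),
           " atoms, model 1 has ", nrow(ref), call. = FALSE)
    if (!identical(paste(f$chain_id, f$residue_number, f$atom_name), ref_key))
      stop("topology mismatch: model ", i,
           " differs from model 1 in atom identity", call. = FALSE)
  }
  atoms <- ref[, c("atom_serial", "atom_name", "residue_name", "chain_id",
                   "residue_number", "element", "occupancy")]
  rownames(atoms) <- NULL
  coords <- lapply(frames, function(f) unname(as.matrix(f[, c("x", "y", "z")])))
  new_ensemble(atoms, coords)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble an `Ensemble`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "Ensemble"))
  if (n_frames(ensemble) < 1L) stop("empty ensemble")
  a <- ensemble$atoms
  # PDB names: element code right-justified in columns 13-14
  nm <- ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name), a$atom_name)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$coords[[i]]
    if (any(xyz >= 10000 | xyz <= -1000))
      stop("coordinates out of PDB fixed-column range in frame ", i)
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$atom_serial, nm, a$residue_name, a$chain_id, a$residue_number,
      xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a per-frame boost-potential log
#'
#' Dialects: `"two_column"` is whitespace-separated `<frame> <dV>` lines with
#' `#` comments; `"amber_gamd"` skips `#` header lines and extracts the total
#' boost energy from an explicitly given column (`boost_column`, required —
#' the column layout of engine logs varies and is never guessed). Frames are
#' 0-based and must be strictly increasing (`two_column`) or are taken in row
#' order (`amber_gamd`). Slightly negative values (numerical noise) are
#' clamped to zero; values below `-1e-6` kcal/mol additionally raise a
#' warning.
#'
#' @param path path to the log file.
#' @param dialect `"two_column"` or `"amber_gamd"`.
#' @param boost_column 1-based column index of the total boost energy
#'   (required for `"amber_gamd"`).
#' @return data.frame with columns `frame_index` (0-based) and `dV`
#'   (kcal/mol).
#' @export
read_boost_log <- function(path, dialect = c("two_column", "amber_gamd"),
                           boost_column = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no data lines in boost log ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  if (dialect == "two_column") {
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad)) stop("malformed boost-log line ", bad[1])
    frame <- as.integer(vapply(fields, `[`, "", 1L))
    dv <- as.numeric(vapply(fields, `[`, "", 2L))
    if (anyNA(frame) || anyNA(dv)) stop("non-numeric boost-log entry")
    if (any(diff(frame) <= 0))
      stop("boost log frame indices must be strictly increasing")
  } else {
    if (is.null(boost_column))
      stop("'boost_column' is required for the amber_gamd dialect")
    dv <- as.numeric(vapply(fields, function(f) {
      if (length(f) < boost_column)
        stop("boost log row has fewer than ", boost_column, " columns")
      f[boost_column]
    }, ""))
    if (anyNA(dv)) stop("non-numeric boost energy column")
    frame <- seq_along(dv) - 1L
  }
  if (any(dv < -1e-6))
    warning("negative boost potentials clamped to zero (min ",
            format(min(dv)), " kcal/mol)")
  dv[dv < 0] <- 0
  data.frame(frame_index = frame, dV = dv)
}

#' Attach boost potentials to an ensemble
#'
#' @param ensemble an `Ensemble`.
#' @param boost data.frame from [read_boost_log()] (or any with a `dV`
#'   column), one record per frame.
#' @return The ensemble with `frame_meta$boost_dV` filled.
#' @export
attach_boost <- function(ensemble, boost) {
  stopifnot(inherits(ensemble, "Ensemble"))
  if (nrow(boost) != n_frames(ensemble))
    stop("boost log has ", nrow(boost), " records but the ensemble has ",
         n_frames(ensemble), " frames")
  ensemble$frame_meta$boost_dV <- boost$dV
  ensemble
}

#' Define a structural motif by chain and residue range
#'
#' @param name motif name (e.g. `"CM_loop"`, `"HLH"`, `"HF_helix"`,
#'   `"beta5"`).
#' @param chain_id single-character chain identifier.
#' @param start,end inclusive residue range in author numbering.
#' @param atom_filter `"all"`, `"heavy"` (excludes hydrogens), `"CA"`, or a
#'   character vector of atom names.
#' @return An object of class `MotifDefinition`.
#' @export
motif_definition <- function(name, chain_id, start, end, atom_filter = "all") {
  stopifnot(is.character(name), nchar(chain_id) == 1L)
  if (start > end) stop("motif ", name, ": start > end")
  structure(list(name = name, chain_id = chain_id,
                 residue_range = c(as.integer(start), as.integer(end)),
                 atom_filter = atom_filter),
            class = "MotifDefinition")
}

#' Resolve a motif to atom indices in an ensemble topology
#'
#' Selection is topology-level: it does not depend on any frame. Indices are
#' returned sorted and 1-based.
#'
#' @param ensemble an `Ensemble`.
#' @param motif a [motif_definition()].
#' @return Sorted integer vector of atom indices.
#' @export
resolve_selection <- function(ensemble, motif) {
  stopifnot(inherits(ensemble, "Ensemble"), inherits(motif, "MotifDefinition"))
  a <- ensemble$atoms
  if (!motif$chain_id %in% a$chain_id)
    stop("motif ", motif$name, ": chain '", motif$chain_id,
         "' not present in topology")
  sel <- a$chain_id == motif$chain_id &
    a$residue_number >= motif$residue_range[1] &
    a$residue_number <= motif$residue_range[2]
  filt <- motif$atom_filter
  if (length(filt) == 1L && filt == "heavy") {
    sel <- sel & toupper(a$element) != "H"
  } else if (length(filt) == 1L && filt == "CA") {
    sel <- sel & a$atom_name == "CA"
  } else if (!(length(filt) == 1L && filt == "all")) {
    sel <- sel & a$atom_name %in% filt
  }
  idx <- which(sel)
  if (length(idx) == 0L)
    stop("motif ", motif$name, ": selection is empty")
  sort(idx)
}

#' Read motif definitions from a YAML configuration file
#'
#' Schema: a mapping of motif name to `{chain, start, end, filter}`;
#' `filter` defaults to `"all"`.
#'
#' @param path YAML file path.
#' @return Named list of [motif_definition()] objects.
#' @export
read_motif_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    m <- cfg[[nm]]
    motif_definition(nm, m$chain, m$start, m$end,
                     if (is.null(m$filter)) "all" else unlist(m$filter))
  })
  names(out) <- names(cfg)
  out
}
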