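# Per-state orchestration: load ensembles and boosts, compute CVs, reweight
# to free-energy profiles, detect basins and peaks, cluster, and write a
# provenance-carrying report.

#' Validate an analysis configuration
#'
#' The configuration is a list (or YAML file) with fields `state_label`,
#' `ensemble_paths`, optional `boost_paths` + `boost_dialect` (+
#' `boost_column` for the amber dialect), `motifs` (name -> chain/start/
#' end/filter), `distance_cvs` (name -> two anchors, each
#' chain/residue/atom), optional `angle_cvs` (name -> two motif names),
#' optional `contact_cvs` (name -> two motif names), optional `profiles_2d`
#' (list of CV-name pairs), `temperature`, `reweighting` (bins, order,
#' min_count, depth_threshold), `clustering` (selection motif name,
#' cutoff), optional `reference_path` + `reference_selection`, and
#' `output_dir`. All cross-reference and existence errors are collected and
#' reported at once.
#'
#' @param config list or path to a YAML file.
#' @return The config (class `motor_config`) when valid; otherwise an error
#'   whose message lists every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  if (is.null(config$state_label)) add("missing 'state_label'")
  if (is.null(config$ensemble_paths) || length(config$ensemble_paths) == 0L)
    add("missing 'ensemble_paths'")
  for (p in config$ensemble_paths)
    if (!file.exists(p)) add(paste0("ensemble file not found: ", p))
  if (!is.null(config$boost_paths)) {
    for (p in config$boost_paths)
      if (!file.exists(p)) add(paste0("boost file not found: ", p))
    if (length(config$boost_paths) != length(config$ensemble_paths))
      add("boost_paths and ensemble_paths must have the same length")
    if (identical(config$boost_dialect, "amber_gamd") &&
        is.null(config$boost_column))
      add("amber_gamd dialect requires 'boost_column'")
  }
  motif_names <- names(config$motifs)
  for (nm in motif_names) {
    m <- config$motifs[[nm]]
    if (is.null(m$chain) || is.null(m$start) || is.null(m$end))
      add(paste0("motif '", nm, "' needs chain/start/end"))
    else if (m$start > m$end)
      add(paste0("motif '", nm, "': start > end"))
  }
  for (nm in names(config$distance_cvs)) {
    d <- config$distance_cvs[[nm]]
    if (length(d) != 2L)
      add(paste0("distance CV '", nm, "' needs exactly two anchors"))
  }
  check_motif_pair <- function(kind, nm, pair) {
    for (m in pair)
      if (!m %in% motif_names)
        add(paste0(kind, " CV '", nm, "' references undefined motif '",
                   m, "'"))
  }
  for (nm in names(config$angle_cvs))
    check_motif_pair("angle", nm, unlist(config$angle_cvs[[nm]]))
  for (nm in names(config$contact_cvs))
    check_motif_pair("contact", nm, unlist(config$contact_cvs[[nm]]))
  cv_names <- c(names(config$distance_cvs), names(config$angle_cvs),
                names(config$contact_cvs))
  for (pair in config$profiles_2d)
    for (nm in unlist(pair))
      if (!nm %in% cv_names)
        add(paste0("2D profile references undefined CV '", nm, "'"))
  for (sel_name in unlist(config$clustering$selection))
    if (!sel_name %in% motif_names)
      add(paste0("clustering selection references undefined motif '",
                 sel_name, "'"))
  if (!is.null(config$temperature) && config$temperature <= 0)
    add("temperature must be positive")
  if (is.null(config$output_dir)) add("missing 'output_dir'")
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  class(config) <- c("motor_config", class(config))
  config
}

.cfg_motifs <- function(config) {
  out <- lapply(names(config$motifs), function(nm) {
    m <- config$motifs[[nm]]
    motif_definition(nm, m$chain, m$start, m$end,
                     if (is.null(m$filter)) "all" else unlist(m$filter))
  })
  names(out) <- names(config$motifs)
  out
}

.stage <- function(name, quiet) {
  if (!quiet) message("[motorscape] stage=", name, " status=start")
  name
}

#' Run the full per-state analysis
#'
#' Stages, in fixed order: load ensembles, pair boost logs, compute CVs,
#' distribution summaries and peaks, 1D (and configured 2D) reweighted
#' free-energy profiles with basin labels, clustering, RMSD to a reference
#' when given, and report writing (JSON plus CSV side tables). Any stage
#' failure aborts with the stage name. The report is deterministic for a
#' fixed config apart from its `timestamp` field.
#'
#' @param config a validated config (see [validate_config()]); a raw list
#'   or YAML path is validated first.
#' @param quiet suppress stage log messages.
#' @return The state report, invisibly also written to
#'   `output_dir/report_<state>.json`.
#' @export
run_state_analysis <- function(config, quiet = FALSE) {
  if (!inherits(config, "motor_config")) config <- validate_config(config)
  temperature <- config$temperature %||% 300
  rw <- config$reweighting %||% list()
  bins1 <- rw$bins_1d %||% 50
  bins2 <- rw$bins_2d %||% 40
  order <- rw$cumulant_order %||% 2
  min_count <- rw$min_count %||% 20
  depth <- rw$depth_threshold %||% 0.5
  stage <- "load"
  report <- tryCatch({
    .stage("load", quiet)
    parts <- lapply(config$ensemble_paths, read_pdb_ensemble)
    stage <- "pair_boosts"
    .stage("pair_boosts", quiet)
    if (!is.null(config$boost_paths)) {
      dialect <- config$boost_dialect %||% "two_column"
      for (i in seq_along(parts)) {
        log <- read_boost_log(config$boost_paths[[i]], dialect,
                              boost_column = config$boost_column)
        parts[[i]] <- attach_boost(parts[[i]], log)
      }
      ens <- combine_replicas(parts)
      dv <- ens$frame_meta$boost_dV
    } else {
      ens <- if (length(parts) == 1L) parts[[1]] else {
        for (i in seq_along(parts))
          parts[[i]]$frame_meta$boost_dV <- 0
        e <- combine_replicas(parts)
        e$frame_meta$boost_dV <- NA_real_
        e
      }
      dv <- rep(0, n_frames(ens))
    }
    ens$frame_meta$state_label <- config$state_label
    motifs <- .cfg_motifs(config)
    stage <- "collective_variables"
    .stage("collective_variables", quiet)
    cvs <- list()
    for (nm in names(config$distance_cvs)) {
      d <- config$distance_cvs[[nm]]
      anch <- lapply(d, function(a)
        atom_anchor(a$chain, a$residue, a$atom %||% "CA"))
      cvs[[nm]] <- distance_cv(ens, anch[[1]], anch[[2]], name = nm)
    }
    for (nm in names(config$angle_cvs)) {
      pair <- unlist(config$angle_cvs[[nm]])
      cvs[[nm]] <- crossing_angle(ens, motifs[[pair[1]]], motifs[[pair[2]]],
                                  name = nm)
    }
    for (nm in names(config$contact_cvs)) {
      pair <- unlist(config$contact_cvs[[nm]])
      cvs[[nm]] <- contact_area(ens, motifs[[pair[1]]], motifs[[pair[2]]],
                                name = nm)
    }
    stage <- "distributions"
    .stage("distributions", quiet)
    summaries <- lapply(cvs, function(cv) {
      s <- state_summary(cv)
      pk <- find_peaks_1d(density_1d(cv))
      list(unit = cv$unit, most_probable = s$most_probable, mean = s$mean,
           sd = s$sd,
           peaks = data.frame(position = pk$position, density = pk$density))
    })
    stage <- "free_energy_profiles"
    .stage("free_energy_profiles", quiet)
    profiles <- lapply(cvs, function(cv)
      pmf_1d(cv, dv, temperature = temperature, bins = bins1,
             cumulant_order = order, min_count = min_count))
    profiles_2d <- lapply(config$profiles_2d, function(pair) {
      pair <- unlist(pair)
      pmf_2d(cvs[[pair[1]]], cvs[[pair[2]]], dv, temperature = temperature,
             bins = bins2, cumulant_order = order, min_count = min_count)
    })
    names(profiles_2d) <- vapply(config$profiles_2d, function(p)
      paste(unlist(p), collapse = "__"), "")
    stage <- "basins"
    .stage("basins", quiet)
    basins <- lapply(c(profiles, profiles_2d), find_basins,
                     depth_threshold = depth)
    stage <- "clustering"
    .stage("clustering", quiet)
    clusters <- NULL
    if (!is.null(config$clustering)) {
      sel <- motifs[unlist(config$clustering$selection)]
      if (length(sel) == 1L) sel <- sel[[1]]
      mat <- pairwise_rmsd_matrix(ens, sel)
      clusters <- cluster_leader(mat, config$clustering$cutoff %||% 2.0)
    }
    stage <- "reference_rmsd"
    .stage("reference_rmsd", quiet)
    ref_rmsd <- NULL
    if (!is.null(config$reference_path)) {
      ref <- read_pdb_ensemble(config$reference_path)
      sel <- motifs[[config$reference_selection]]
      rs <- rmsd_series(ens, ref, sel)
      ref_rmsd <- list(mean = mean(rs$values), sd = stats::sd(rs$values),
                       selection = config$reference_selection)
    }
    stage <- "report"
    .stage("report", quiet)
    list(state_label = config$state_label,
         n_frames = n_frames(ens),
         temperature = temperature,
         cv_summaries = summaries,
         profiles_1d = lapply(profiles, unclass),
         profiles_2d = lapply(profiles_2d, unclass),
         basins = lapply(basins, function(b) as.data.frame(unclass(b))),
         clusters = if (!is.null(clusters)) unclass(clusters),
         reference_rmsd = ref_rmsd,
         provenance = list(
           package_version = as.character(utils::packageVersion("motorscape")),
           input_hashes = as.list(tools::md5sum(
             unlist(c(config$ensemble_paths, config$boost_paths)))),
           settings = list(bins_1d = bins1, bins_2d = bins2,
                           cumulant_order = order, min_count = min_count,
                           depth_threshold = depth),
           timestamp = format(Sys.time(), tz = "UTC")))
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(config$output_dir,
                         paste0("report_", config$state_label, ".json"))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  for (nm in names(report$profiles_1d)) {
    p <- report$profiles_1d[[nm]]
    utils::write.csv(
      data.frame(bin_center = p$bin_mids[[1]], pmf = p$pmf,
                 count = p$counts, masked = p$mask),
      file.path(config$output_dir, paste0("pmf1d_", nm, ".csv")),
      row.names = FALSE)
  }
  if (!quiet) message("[motorscape] report written to ", json_path)
  invisible(report)
}

#' Compare the CV summaries and basin locations of two state reports
#'
#' @param report_a,report_b reports from [run_state_analysis()].
#' @return data.frame with per-CV deltas of most-probable values
#'   (`b - a`) and of the global-minimum (m1) basin position.
#' @export
compare_states <- function(report_a, report_b) {
  shared <- intersect(names(report_a$cv_summaries),
                      names(report_b$cv_summaries))
  if (length(shared) == 0L)
    stop("reports share no collective variables")
  rows <- lapply(shared, function(nm) {
    sa <- report_a$cv_summaries[[nm]]; sb <- report_b$cv_summaries[[nm]]
    ba <- report_a$basins[[nm]]; bb <- report_b$basins[[nm]]
    data.frame(cv = nm, unit = sa$unit,
               most_probable_a = sa$most_probable,
               most_probable_b = sb$most_probable,
               delta_most_probable = sb$most_probable - sa$most_probable,
               delta_m1 = if (!is.null(ba) && !is.null(bb))
                 bb$cv1[1] - ba$cv1[1] else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
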