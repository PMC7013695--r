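#' Build a run configuration for [run_analysis()]
#'
#' @param trajectories character vector of multi-model PDB paths.
#' @param map_config path to a residue-mapping YAML (see
#'   [read_map_config()]), or a list as returned by it.
#' @param out_dir output directory for the report tables.
#' @param analyses which battery components to run.
#' @param ga_resnos residue ids of the alpha5 C-terminal five in the G-alpha
#'   chain.
#' @param trend_threshold dead-band for the coupling classifier (A/ns).
#' @param window optional c(min, max) time window in ns for the trend fit.
#' @param dt ns per frame used when reading trajectories.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(trajectories, map_config, out_dir = "switchmd_out",
                       analyses = c("coupling", "switches", "channel", "pca"),
                       ga_resnos = 351:355, trend_threshold = 5e-4,
                       window = NULL, dt = 1, log_level = "info") {
  structure(list(trajectories = trajectories, map_config = map_config,
                 out_dir = out_dir, analyses = analyses, ga_resnos = ga_resnos,
                 trend_threshold = trend_threshold, window = window, dt = dt,
                 log_level = log_level),
            class = "run_config")
}

#' Run the full hallmark battery over one or more trajectories
#'
#' Each trajectory is read, analysed with [build_activation_report()] and
#' written to its own subdirectory of `out_dir`. Trajectories fail in
#' isolation: an unresolvable label or missing chain is recorded and the run
#' continues. When PCA is enabled and at least two trajectories succeed, the
#' pairwise covariance-overlap matrix over the TM6 C-alpha subspace is
#' computed and written as `overlap.tsv`.
#'
#' @param config a [run_config()] (paths must exist at call time).
#' @return list of class `run_result`: `reports` (named list), `overlap`
#'   (matrix or `NULL`), `failed` (named character vector of per-trajectory
#'   errors), `status` (0 when no trajectory failed entirely).
#' @export
run_analysis <- function(config) {
  missing <- config$trajectories[!file.exists(config$trajectories)]
  if (length(missing))
    smd_stop(paste("trajectory file(s) not found:", paste(missing, collapse = ", ")),
             "switchmd_io_error")
  mp <- if (is.character(config$map_config)) read_map_config(config$map_config)
        else config$map_config
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("switchmd %s analysis run", utils::packageVersion("switchmd")),
                 sprintf("config_hash=%s", config_hash(unclass(config))))
  logi <- function(...) log_lines <<- c(log_lines, sprintf(...))

  reports <- list()
  covs <- list()
  failed <- character()
  labels <- make.unique(sub("\\.pdb$", "", basename(config$trajectories)), sep = "_")
  for (k in seq_along(config$trajectories)) {
    path <- config$trajectories[k]
    label <- labels[k]
    t0 <- proc.time()[3]
    res <- tryCatch({
      traj <- read_trajectory(path, dt = config$dt)
      cfg <- list(ga_chain = mp$ga_chain, ga_resnos = config$ga_resnos,
                  trend_threshold = config$trend_threshold,
                  trend_window = config$window,
                  channel = if ("channel" %in% config$analyses) channel_spec() else FALSE,
                  pca = "pca" %in% config$analyses)
      rep <- build_activation_report(traj, mp$map, cfg)
      write_report(rep, file.path(config$out_dir, label))
      if ("pca" %in% config$analyses && is.null(rep$errors$pca)) {
        fit <- receptor_ca_selection(traj, mp$map)
        covs[[label]] <- build_covariance(traj, fit, tm_ca_selection(traj, mp$map, 6L))
      }
      for (e in names(rep$errors)) logi("%s: metric '%s' failed: %s", label, e, rep$errors[[e]])
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[label] <- conditionMessage(res)
      logi("%s: FAILED: %s", label, conditionMessage(res))
    } else {
      reports[[label]] <- res
      logi("%s: done in %.1f s (%d frames)", label, proc.time()[3] - t0, res$n_frames)
    }
  }

  overlap <- NULL
  if (length(covs) >= 2L) {
    overlap <- overlap_matrix(covs)
    odf <- data.frame(label = rownames(overlap), overlap, check.names = FALSE)
    write_tsv_with_header(odf, file.path(config$out_dir, "overlap.tsv"),
                          list(generator = paste0("switchmd ",
                                                  utils::packageVersion("switchmd")),
                               config_hash = config_hash(unclass(config))))
    logi("overlap matrix written for %d trajectories", length(covs))
  }
  if (config$log_level != "quiet") writeLines(log_lines, log_path)
  structure(list(reports = reports, overlap = overlap, failed = failed,
                 status = if (length(failed)) 1L else 0L),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result: %d report(s), %d failure(s)\n",
              length(x$reports), length(x$failed)))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-20s trend=%s kink=%s open=%.2f\n", nm,
                r$coupling$classification %||% "NA", r$kink_class %||% "NA",
                r$channel_open_fraction %||% NA))
  }
  if (!is.null(x$overlap)) {
    cat("  covariance overlap:\n")
    print(round(x$overlap, 3))
  }
  invisible(x)
}

#' Generate a synthetic trajectory and write it with its ground truth
#'
#' Writes `trajectory.pdb` (multi-model), `truth.tsv` (per-frame planted
#' labels), `spec.yaml` (the full specification, seed included) and
#' `map.yaml` (the residue-mapping config) into `out_dir`, and prints the
#' seed used.
#'
#' @param spec a [synthetic_spec()], a preset name (see
#'   [synthetic_preset()]), or a path to a YAML file of spec fields.
#' @param out_dir output directory, created if missing.
#' @param n_frames,seed forwarded when `spec` is a preset name.
#' @return paths of written files, invisibly.
#' @export
run_simulate <- function(spec, out_dir, n_frames = 1000L, seed = 1L) {
  if (is.character(spec) && file.exists(spec)) {
    fields <- yaml::read_yaml(spec)
    bad <- setdiff(names(fields), names(formals(synthetic_spec)))
    if (length(bad))
      smd_stop(paste("unknown spec field(s):", paste(bad, collapse = ", ")),
               "switchmd_validation_error")
    spec <- do.call(synthetic_spec, fields)
  } else if (is.character(spec)) {
    spec <- synthetic_preset(spec, n_frames = n_frames, seed = seed)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gen <- generate_trajectory(spec)
  p_traj <- file.path(out_dir, "trajectory.pdb")
  p_truth <- file.path(out_dir, "truth.tsv")
  p_spec <- file.path(out_dir, "spec.yaml")
  p_map <- file.path(out_dir, "map.yaml")
  write_trajectory(gen$traj, p_traj)
  write.table(gen$truth, p_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(spec), p_spec)
  write_map_config(gen$map, p_map, ga_chain = "G",
                   special = list(icl3_arg = 560L, ga_alpha5 = 351:355))
  message(sprintf("synthetic trajectory written (%d frames, seed %d)",
                  spec$n_frames, spec$seed))
  invisible(c(p_traj, p_truth, p_spec, p_map))
}
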