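# polynomial rolling hash of a config list; stable across runs for
# identical configs
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_tsv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unlist(meta)), con)
  if (is.null(df) || nrow(df) == 0L) {
    if (!is.null(df)) writeLines(paste(names(df), collapse = "\t"), con)
    return(invisible(path))
  }
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Write an activation report as a set of tab-separated tables
#'
#' One table per metric family — `distances.tsv` (per-frame distance and
#' kink series), `switches.tsv` (chi1 and rotamer states), `channel.tsv`
#' (per-frame open flag), `interface.tsv` (pair summaries), `pca.tsv`
#' (projections) and `summary.tsv` (scalar battery results). Each file
#' starts with `# key=value` run-metadata lines (package version, source,
#' config hash) and is round-trip readable with [read_report_table()].
#'
#' @param report an [build_activation_report()] result.
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      smd_stop(sprintf("cannot create output directory %s", out_dir), "switchmd_io_error")
  }
  probe <- file.path(out_dir, ".switchmd_write_test")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, error = function(e) FALSE)
  if (!isTRUE(ok))
    smd_stop(sprintf("output directory %s is not writable", out_dir), "switchmd_io_error")
  unlink(probe)

  meta <- list(generator = paste0("switchmd ", as.character(utils::packageVersion("switchmd"))),
               source = report$source,
               config_hash = config_hash(report$config),
               channel_cutoffs = if (!isFALSE(report$config$channel))
                 sprintf("link=%.2fA,attach=%.2fA,radius=%.2fA (package-defined, not visual)",
                         report$config$channel$link_cutoff,
                         report$config$channel$attach_cutoff,
                         report$config$channel$cylinder_radius) else "disabled")
  paths <- character()
  nf <- report$n_frames
  frame_col <- data.frame(frame = seq_len(nf), time = report$times)

  dist_df <- frame_col
  if (!is.null(report$coupling_series)) dist_df$receptor_alpha5 <- report$coupling_series$value
  if (!is.null(report$ionic_lock)) dist_df$ionic_lock <- report$ionic_lock$value
  if (!is.null(report$tm5_tm7)) dist_df$tm5_tm7 <- report$tm5_tm7$value
  if (!is.null(report$kink)) dist_df$tm6_kink <- report$kink
  paths <- c(paths, write_tsv_with_header(dist_df, file.path(out_dir, "distances.tsv"), meta))

  sw_df <- frame_col
  if (!is.null(report$switches))
    for (lb in names(report$switches)) {
      sw_df[[paste0("chi1_", lb)]] <- report$switches[[lb]]$chi1
      sw_df[[paste0("state_", lb)]] <- report$switches[[lb]]$state
    }
  paths <- c(paths, write_tsv_with_header(sw_df, file.path(out_dir, "switches.tsv"), meta))

  ch_df <- if (is.null(report$channel_series)) {
    data.frame(frame = integer(), time = numeric(), open = logical())
  } else cbind(frame_col, open = report$channel_series)
  paths <- c(paths, write_tsv_with_header(ch_df, file.path(out_dir, "channel.tsv"), meta))

  if (!is.null(report$interface))
    paths <- c(paths, write_tsv_with_header(report$interface,
                                            file.path(out_dir, "interface.tsv"), meta))

  pca_df <- if (is.null(report$pca)) {
    data.frame(frame = integer(), time = numeric(), PC1 = numeric(), PC2 = numeric())
  } else {
    pr <- report$pca$projections
    data.frame(frame = seq_len(nrow(pr)), time = report$pca$times,
               PC1 = pr[, 1], PC2 = if (ncol(pr) > 1) pr[, 2] else NA_real_)
  }
  paths <- c(paths, write_tsv_with_header(pca_df, file.path(out_dir, "pca.tsv"), meta))

  summ <- summary(report)
  summ_df <- data.frame(metric = names(unclass(summ)),
                        value = vapply(unclass(summ), function(x)
                          if (is.numeric(x)) sprintf("%.6f", x) else as.character(x),
                          character(1)))
  paths <- c(paths, write_tsv_with_header(summ_df, file.path(out_dir, "summary.tsv"), meta))
  invisible(paths)
}

#' Read back a report table written by [write_report()]
#' @param path a `.tsv` written by [write_report()].
#' @return data frame; metadata lines are attached as the `"meta"` attribute.
#' @export
read_report_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) <= 1L) {
    if (length(body) == 1L)
      setNames(data.frame(matrix(nrow = 0, ncol = length(strsplit(body, "\t")[[1]]))),
               strsplit(body, "\t")[[1]])
    else data.frame()
  } else {
    read.delim(text = paste(body, collapse = "\n"), sep = "\t",
               stringsAsFactors = FALSE)
  }
  attr(df, "meta") <- meta
  df
}
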