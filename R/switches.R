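# Default selections for the receptor/G-alpha approach metric: centroid of
# five conserved intracellular-facing receptor C-alphas vs the centroid of the
# C-alphas of the last five alpha5 residues of G-alpha.
RECEPTOR_COM_LABELS <- c("7.53", "2.46", "3.46", "5.54", "6.40")
SWITCH_LABELS <- c("6.48", "6.44", "6.55", "7.53")

#' Classify a chi1 angle into a rotamer state
#'
#' Half-open 120-degree bins: gauche- for (-120, 0], gauche+ for (0, 120],
#' trans otherwise. The canonical states sit near -60, +60 and 180 degrees.
#'
#' @param chi1 angle(s) in degrees, range (-180, 180].
#' @return character vector: `"gauche-"`, `"gauche+"` or `"trans"`.
#' @export
rotamer_classify <- function(chi1) {
  out <- rep("trans", length(chi1))
  out[chi1 > -120 & chi1 <= 0] <- "gauche-"
  out[chi1 > 0 & chi1 <= 120] <- "gauche+"
  out
}

#' chi1 time series and rotamer states for the microswitch residues
#'
#' Tracks the side-chain torsions of the classic activation switches: the
#' W6.48 rotamer toggle, the F6.44 transmission switch, H6.55 and the Y7.53
#' NPxxY toggle.
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @param labels BW labels of chi1-capable residues.
#' @return named list of data frames (class `switch_series`) with columns
#'   `time`, `chi1`, `state`.
#' @export
switch_timeseries <- function(traj, map, labels = SWITCH_LABELS) {
  out <- lapply(labels, function(lb) {
    r <- resolve_bw(map, lb)
    chi <- chi1_angle(traj, r$chain, r$resno)
    structure(data.frame(time = traj$times, chi1 = chi, state = rotamer_classify(chi)),
              class = c("switch_series", "data.frame"), residue_label = lb)
  })
  names(out) <- labels
  out
}

# per-frame minimum distance between two explicit atom groups
min_pair_distance_series <- function(traj, idxA, idxB) {
  best <- rep(Inf, n_frames(traj))
  pair <- matrix(NA_integer_, n_frames(traj), 2L)
  for (i in idxA) for (j in idxB) {
    d <- traj$xyz[, 3L * i - (2:0), drop = FALSE] - traj$xyz[, 3L * j - (2:0), drop = FALSE]
    dd <- sqrt(rowSums(d^2))
    upd <- dd < best
    best[upd] <- dd[upd]
    pair[upd, 1L] <- i; pair[upd, 2L] <- j
  }
  list(distance = best, pair = pair)
}

residue_atom_idx <- function(traj, chain, resno, elety) {
  a <- traj$atoms
  which(a$chain == chain & a$resno == resno & a$elety %in% elety)
}

#' TM3-TM6 ionic-lock distance
#'
#' Minimum distance between the R3.50 guanidinium nitrogens (NE, NH1, NH2)
#' and the E6.30 carboxylate oxygens (OE1, OE2). The salt bridge stabilises
#' the inactive receptor state (about 3 A in the inactive D2 crystal
#' structure) and breaks on activation.
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @param frame frame index or `NULL` for the whole trajectory.
#' @return distance(s) in A.
#' @export
ionic_lock_distance <- function(traj, map, frame = NULL) {
  r350 <- resolve_bw(map, "3.50"); e630 <- resolve_bw(map, "6.30")
  iN <- residue_atom_idx(traj, r350$chain, r350$resno, c("NE", "NH1", "NH2"))
  iO <- residue_atom_idx(traj, e630$chain, e630$resno, c("OE1", "OE2"))
  if (length(iN) == 0L)
    smd_stop("R3.50 guanidinium atoms (NE/NH1/NH2) missing", "switchmd_missing_atom")
  if (length(iO) == 0L)
    smd_stop("E6.30 carboxylate atoms (OE1/OE2) missing", "switchmd_missing_atom")
  d <- min_pair_distance_series(traj, iN, iO)$distance
  if (is.null(frame)) d else d[frame]
}

#' TM5-TM7 distance at the conserved tyrosines
#'
#' C-alpha to C-alpha distance between Y5.58 and Y7.53; small values
#' accompany TM6 bending in active-like conformations (19.4 A in the
#' inactive D2 crystal structure).
#'
#' @inheritParams ionic_lock_distance
#' @return distance(s) in A.
#' @export
tm5_tm7_distance <- function(traj, map, frame = NULL) {
  y558 <- resolve_bw(map, "5.58"); y753 <- resolve_bw(map, "7.53")
  i5 <- residue_atom_idx(traj, y558$chain, y558$resno, "CA")
  i7 <- residue_atom_idx(traj, y753$chain, y753$resno, "CA")
  if (length(i5) == 0L || length(i7) == 0L)
    smd_stop("C-alpha missing for Y5.58 or Y7.53", "switchmd_missing_atom")
  d <- traj$xyz[, 3L * i5[1] - (2:0), drop = FALSE] - traj$xyz[, 3L * i7[1] - (2:0), drop = FALSE]
  d <- sqrt(rowSums(d^2))
  if (is.null(frame)) d else d[frame]
}

#' Receptor/G-alpha approach series
#'
#' Per-frame distance between the centroid of the C-alphas of five conserved
#' receptor residues (Y7.53, L2.46, I3.46, T5.54, V6.40) and the centroid of
#' the C-alphas of the five C-terminal alpha5 residues of G-alpha.
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @param ga_chain G-alpha chain id.
#' @param ga_resnos residue ids of the alpha5 C-terminal five (numbering
#'   differs between G-alpha subtypes, so always explicit).
#' @param receptor_labels BW labels of the receptor probe residues.
#' @return a [distance_series()].
#' @export
coupling_series <- function(traj, map, ga_chain, ga_resnos,
                            receptor_labels = RECEPTOR_COM_LABELS) {
  rec <- unlist(lapply(receptor_labels, function(lb) {
    r <- resolve_bw(map, lb)
    residue_atom_idx(traj, r$chain, r$resno, "CA")
  }))
  ga <- atom_select(traj, chain = ga_chain, resno = ga_resnos, elety = "CA")
  if (length(rec) != length(receptor_labels) || length(ga) != length(ga_resnos))
    smd_stop("coupling selection incomplete (missing C-alpha atoms)", "switchmd_missing_atom")
  com_distance_series(traj, rec, ga, label = "receptor_alpha5_com")
}

#' Best-fit-line trend of a distance series
#'
#' Ordinary least-squares fit of distance against time; the sign of the slope
#' classifies the pair as approaching (slope below `-threshold`), receding
#' (above `+threshold`) or flat. The threshold guards against classifying
#' noise as drift; the default 0.0005 A/ns corresponds to 0.5 A over 1 us.
#'
#' @param series a [distance_series()] (or data frame with `time`, `value`).
#' @param threshold classification dead-band in A/ns.
#' @param window optional c(min, max) time window (ns) to fit on.
#' @return list of class `coupling_trend`: `slope` (A/ns), `intercept` (A),
#'   `classification`, `threshold`.
#' @export
coupling_trend <- function(series, threshold = 5e-4, window = NULL) {
  t <- series$time; v <- series$value
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  if (length(t) < 2L || var(t) == 0)
    smd_stop("trend fit needs >= 2 frames with distinct times", "switchmd_degenerate_input")
  slope <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
  intercept <- mean(v) - slope * mean(t)
  cls <- if (slope < -threshold) "approaching" else if (slope > threshold) "receding" else "flat"
  structure(list(slope = slope, intercept = intercept,
                 classification = cls, threshold = threshold),
            class = "coupling_trend")
}

#' @export
print.coupling_trend <- function(x, ...) {
  cat(sprintf("coupling trend: slope %+.5f A/ns (threshold %.5f) -> %s\n",
              x$slope, x$threshold, x$classification))
  invisible(x)
}

# side-chain heavy atoms; Gly falls back to CA with a warning
sidechain_rows <- function(traj, chain, resno) {
  a <- traj$atoms
  rows <- which(a$chain == chain & a$resno == resno & !a$water &
                  !(a$elesy %in% c("H", "D")) & !grepl("^[0-9]*H", a$elety) &
                  !(a$elety %in% c("N", "CA", "C", "O", "OXT")))
  if (length(rows) == 0L) {
    rows <- which(a$chain == chain & a$resno == resno & a$elety == "CA")
    if (length(rows) > 0L)
      warning(sprintf("residue %s/%d has no side-chain heavy atoms; using C-alpha",
                      chain, resno))
  }
  if (length(rows) == 0L)
    smd_stop(sprintf("residue %s/%d not found", chain, resno), "switchmd_mapping_error")
  rows
}

#' Time-averaged side-chain centroid distances for residue pairs
#'
#' For each pair, the per-frame distance between the unweighted side-chain
#' heavy-atom centroids is computed and summarised as mean +/- sd over the
#' window (used for ICL3 R233 vs the G-alpha contact residues over the last
#' part of a run).
#'
#' @param traj an `md_trajectory`.
#' @param pairs list of pairs; each element is
#'   `list(a = list(chain=, resno=), b = list(chain=, resno=))`.
#' @param frames frame window (default all).
#' @return data frame: `pair`, `mean`, `sd` (A).
#' @export
interface_residue_distances <- function(traj, pairs, frames = seq_len(n_frames(traj))) {
  if (length(frames) == 0L) smd_stop("empty frame window", "switchmd_degenerate_input")
  rows <- lapply(pairs, function(p) {
    selA <- sidechain_rows(traj, p$a$chain, p$a$resno)
    selB <- sidechain_rows(traj, p$b$chain, p$b$resno)
    d <- com_series(traj, selA)[frames, , drop = FALSE] -
      com_series(traj, selB)[frames, , drop = FALSE]
    dd <- sqrt(rowSums(d^2))
    data.frame(pair = sprintf("%s%d-%s%d", p$a$chain, p$a$resno, p$b$chain, p$b$resno),
               mean = mean(dd), sd = if (length(dd) > 1L) sd(dd) else 0)
  })
  do.call(rbind, rows)
}

#' Heavy-atom hydrogen-bond check between two residues
#'
#' True when any polar heavy-atom pair (N or O on both sides) lies within
#' 3.5 A. Hydrogens are often absent from MD coordinate dumps, so no angle
#' term is applied.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param donor,acceptor `list(chain=, resno=)` residue addresses.
#' @param cutoff heavy-atom distance cutoff in A.
#' @return list: `present`, `distance`, `donor_atom`, `acceptor_atom`.
#' @export
hbond_present <- function(traj, frame, donor, acceptor, cutoff = 3.5) {
  polar <- function(chain, resno) {
    a <- traj$atoms
    which(a$chain == chain & a$resno == resno & a$elesy %in% c("N", "O"))
  }
  iD <- polar(donor$chain, donor$resno); iA <- polar(acceptor$chain, acceptor$resno)
  if (length(iD) == 0L || length(iA) == 0L)
    smd_stop("no polar heavy atoms on donor or acceptor residue", "switchmd_missing_atom")
  co <- frame_coords(traj, frame)
  d2 <- outer(rowSums(co[iD, , drop = FALSE]^2), rowSums(co[iA, , drop = FALSE]^2), `+`) -
    2 * tcrossprod(co[iD, , drop = FALSE], co[iA, , drop = FALSE])
  k <- arrayInd(which.min(d2), dim(d2))
  best <- sqrt(max(d2[k], 0))
  list(present = best <= cutoff, distance = best,
       donor_atom = traj$atoms$elety[iD[k[1]]],
       acceptor_atom = traj$atoms$elety[iA[k[2]]])
}

#' Assemble the activation-hallmark report for one trajectory
#'
#' Runs the full battery: receptor/G-alpha approach trend, ionic lock,
#' TM5-TM7 tyrosine distance, TM6 kink, chi1 microswitches, water-channel
#' open fraction, interface residue distances and (optionally) C-alpha PCA.
#' Individual metric failures are caught and recorded in `$errors`; the rest
#' of the battery still runs.
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @param config list; recognised entries: `ga_chain`, `ga_resnos` (alpha5
#'   C-terminal five), `receptor_labels`, `interface_pairs`, `channel`
#'   (a [channel_spec()], or `FALSE` to skip), `trend_threshold` (A/ns),
#'   `trend_window` (ns), `kink_threshold` (degrees), `pca` (logical),
#'   `switch_labels`.
#' @return object of class `activation_report`.
#' @export
build_activation_report <- function(traj, map, config = list()) {
  cfg <- utils::modifyList(list(
    ga_chain = "G", ga_resnos = 351:355,
    receptor_labels = RECEPTOR_COM_LABELS,
    switch_labels = SWITCH_LABELS,
    interface_pairs = NULL, channel = channel_spec(),
    trend_threshold = 5e-4, trend_window = NULL,
    kink_threshold = 15, pca = FALSE), config)
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  coupling_d <- grab("coupling", coupling_series(traj, map, cfg$ga_chain, cfg$ga_resnos,
                                                 cfg$receptor_labels))
  coupling <- if (is.null(coupling_d)) NULL else
    tryCatch(coupling_trend(coupling_d, cfg$trend_threshold, cfg$trend_window),
             error = function(e) structure(list(slope = NA_real_, intercept = NA_real_,
                                                classification = "degenerate",
                                                threshold = cfg$trend_threshold),
                                           class = "coupling_trend"))
  kink <- grab("kink", tm6_kink(traj, map))
  report <- structure(list(
    coupling = coupling,
    coupling_series = coupling_d,
    ionic_lock = grab("ionic_lock",
                      distance_series(traj$times, ionic_lock_distance(traj, map), "ionic_lock")),
    tm5_tm7 = grab("tm5_tm7",
                   distance_series(traj$times, tm5_tm7_distance(traj, map), "tm5_tm7")),
    kink = kink,
    kink_class = if (is.null(kink)) NULL else
      ifelse(mean(kink) >= cfg$kink_threshold, "bent", "straight"),
    switches = grab("switches", switch_timeseries(traj, map, cfg$switch_labels)),
    channel_series = if (isFALSE(cfg$channel)) NULL else
      grab("channel",
           vapply(seq_len(n_frames(traj)),
                  function(f) channel_continuity(traj, map, cfg$channel, f)$open, logical(1))),
    interface = if (is.null(cfg$interface_pairs)) NULL else
      grab("interface", interface_residue_distances(traj, cfg$interface_pairs)),
    pca = if (isTRUE(cfg$pca))
      grab("pca", {
        sel <- receptor_ca_selection(traj, map)
        pca_project(build_covariance(traj, sel, tm_ca_selection(traj, map, 6L)), traj)
      }) else NULL,
    n_frames = n_frames(traj),
    times = traj$times,
    config = cfg,
    errors = errors,
    source = traj$source), class = "activation_report")
  if (!is.null(report$channel_series))
    report$channel_open_fraction <- mean(report$channel_series)
  report$errors <- errors
  report
}

#' @export
print.activation_report <- function(x, ...) {
  cat("activation_report:", x$source, sprintf("(%d frames)\n", x$n_frames))
  if (!is.null(x$coupling))
    cat(sprintf("  receptor/alpha5 trend : %+.5f A/ns -> %s\n",
                x$coupling$slope, x$coupling$classification))
  if (!is.null(x$ionic_lock))
    cat(sprintf("  ionic lock R3.50-E6.30: %.2f A (mean)\n", mean(x$ionic_lock$value)))
  if (!is.null(x$tm5_tm7))
    cat(sprintf("  Y5.58-Y7.53 (CA)      : %.2f A (mean)\n", mean(x$tm5_tm7$value)))
  if (!is.null(x$kink))
    cat(sprintf("  TM6 kink at 6.48      : %.1f deg (mean) -> %s\n",
                mean(x$kink), x$kink_class))
  if (!is.null(x$channel_open_fraction))
    cat(sprintf("  water channel open    : %.2f of frames\n", x$channel_open_fraction))
  if (!is.null(x$switches))
    for (s in x$switches)
      cat(sprintf("  chi1 %-5s            : %s (modal state)\n", attr(s, "residue_label"),
                  names(sort(table(s$state), decreasing = TRUE))[1]))
  if (length(x$errors))
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.activation_report <- function(object, ...) {
  out <- list(
    source = object$source,
    n_frames = object$n_frames,
    slope = if (!is.null(object$coupling)) object$coupling$slope else NA_real_,
    trend = if (!is.null(object$coupling)) object$coupling$classification else NA_character_,
    ionic_lock_mean = if (!is.null(object$ionic_lock)) mean(object$ionic_lock$value) else NA_real_,
    tm5_tm7_mean = if (!is.null(object$tm5_tm7)) mean(object$tm5_tm7$value) else NA_real_,
    kink_mean = if (!is.null(object$kink)) mean(object$kink) else NA_real_,
    kink_class = object$kink_class %||% NA_character_,
    channel_open_fraction = object$channel_open_fraction %||% NA_real_)
  class(out) <- "summary.activation_report"
  out
}

#' @export
print.summary.activation_report <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}
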