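#' Water-channel detection parameters
#'
#' The channel is probed along the axis joining the orthosteric-site locus
#' (3.32 C-alpha) and the NPxxY gate (7.53 C-alpha). Water oxygens within
#' `cylinder_radius` of that segment are candidate channel waters; they are
#' linked when within `link_cutoff` (a hydrogen-bond heavy-atom distance) and
#' the channel is open when a linked path connects waters attached (within
#' `attach_cutoff`) to both endpoints. Published channel calls of this kind
#' are typically visual; these numeric cutoffs are this package's own
#' operational definition and are recorded in output metadata.
#'
#' @param top_ref,bottom_ref BW labels of the axis endpoints.
#' @param cylinder_radius A, lateral capture radius around the axis.
#' @param link_cutoff A, O-O distance linking two waters.
#' @param attach_cutoff A, water-to-endpoint attachment distance.
#' @param axial_margin A, axial extension beyond the endpoints.
#' @param barrier_labels BW labels of the hydrophobic-barrier residues.
#' @return list of class `channel_spec`.
#' @export
channel_spec <- function(top_ref = "3.32", bottom_ref = "7.53",
                         cylinder_radius = 8, link_cutoff = 3.5,
                         attach_cutoff = 4.0, axial_margin = 3,
                         barrier_labels = c("2.42", "2.43", "3.43", "3.46", "6.36")) {
  stopifnot(cylinder_radius > 0, link_cutoff > 0, attach_cutoff > 0)
  structure(list(top_ref = top_ref, bottom_ref = bottom_ref,
                 cylinder_radius = cylinder_radius, link_cutoff = link_cutoff,
                 attach_cutoff = attach_cutoff, axial_margin = axial_margin,
                 barrier_labels = barrier_labels),
            class = "channel_spec")
}

channel_axis_points <- function(traj, map, spec, frame) {
  ends <- lapply(c(spec$top_ref, spec$bottom_ref), function(lb) {
    r <- resolve_bw(map, lb)
    i <- residue_atom_idx(traj, r$chain, r$resno, "CA")
    if (length(i) == 0L)
      smd_stop(sprintf("C-alpha missing for channel endpoint %s", lb), "switchmd_missing_atom")
    frame_coords(traj, frame)[i[1], ]
  })
  list(top = ends[[1]], bottom = ends[[2]])
}

# distance from points (n x 3) to segment a-b, plus axial coordinate in [0,1]
point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2L, a)
  t <- as.vector(rel %*% ab) / len2
  tc <- pmin(1, pmax(0, t))
  closest <- outer(tc, ab) + matrix(a, nrow(pts), 3L, byrow = TRUE)
  list(dist = sqrt(rowSums((pts - closest)^2)), t = t,
       axial = t * sqrt(len2))
}

#' Select water oxygens inside the channel cylinder
#'
#' Water oxygens within the capture radius of the 3.32-7.53 axis segment and
#' axially between the endpoints (with a small margin).
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @param spec a [channel_spec()].
#' @param frame frame index.
#' @return integer atom indices of selected water oxygens (possibly empty).
#' @export
select_channel_waters <- function(traj, map, spec = channel_spec(), frame = 1L) {
  wat <- which(traj$atoms$water & traj$atoms$elesy == "O")
  if (length(wat) == 0L) wat <- which(traj$atoms$water & traj$atoms$elety == "O")
  if (length(wat) == 0L) return(integer(0))
  ax <- channel_axis_points(traj, map, spec, frame)
  pts <- frame_coords(traj, frame)[wat, , drop = FALSE]
  seg_len <- sqrt(sum((ax$bottom - ax$top)^2))
  ps <- point_segment(pts, ax$top, ax$bottom)
  keep <- ps$dist <= spec$cylinder_radius &
    ps$axial >= -spec$axial_margin & ps$axial <= seg_len + spec$axial_margin
  wat[keep]
}

#' Water-channel continuity in one frame
#'
#' Builds a graph on the channel waters with edges for O-O distances within
#' the link cutoff and asks whether a path connects any water attached to the
#' top endpoint to any water attached to the bottom endpoint.
#'
#' @inheritParams select_channel_waters
#' @return list: `open` (logical), `n_waters`, `path_length` (number of
#'   waters on the shortest connecting path; `NA` when closed).
#' @export
channel_continuity <- function(traj, map, spec = channel_spec(), frame = 1L) {
  wat <- select_channel_waters(traj, map, spec, frame)
  if (length(wat) == 0L)
    return(list(open = FALSE, n_waters = 0L, path_length = NA_integer_))
  ax <- channel_axis_points(traj, map, spec, frame)
  pts <- frame_coords(traj, frame)[wat, , drop = FALSE]
  d_top <- sqrt(rowSums(sweep(pts, 2L, ax$top)^2))
  d_bot <- sqrt(rowSums(sweep(pts, 2L, ax$bottom)^2))
  src <- which(d_top <= spec$attach_cutoff)
  dst <- which(d_bot <= spec$attach_cutoff)
  if (length(src) == 0L || length(dst) == 0L)
    return(list(open = FALSE, n_waters = length(wat), path_length = NA_integer_))
  dd <- as.matrix(stats::dist(pts))
  adj <- dd <= spec$link_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  dists <- igraph::distances(g, v = src, to = dst)
  if (all(is.infinite(dists)))
    return(list(open = FALSE, n_waters = length(wat), path_length = NA_integer_))
  list(open = TRUE, n_waters = length(wat),
       path_length = as.integer(min(dists)) + 1L)
}

#' Water occupancy of the hydrophobic barrier
#'
#' Counts water oxygens within 4 A of any heavy atom of the five barrier
#' residues (2.42, 2.43, 3.43, 3.46, 6.36) that separate the orthosteric
#' site from the intracellular side; their wetting marks activation.
#'
#' @inheritParams select_channel_waters
#' @param cutoff A, water-to-residue heavy-atom distance.
#' @return list: `count`, `per_residue` (named counts).
#' @export
barrier_occupancy <- function(traj, map, spec = channel_spec(), frame = 1L, cutoff = 4.0) {
  wat <- which(traj$atoms$water & (traj$atoms$elesy == "O" | traj$atoms$elety == "O"))
  per <- setNames(integer(length(spec$barrier_labels)), spec$barrier_labels)
  if (length(wat) == 0L) return(list(count = 0L, per_residue = per))
  co <- frame_coords(traj, frame)
  wpts <- co[wat, , drop = FALSE]
  near <- matrix(FALSE, length(wat), length(spec$barrier_labels))
  for (k in seq_along(spec$barrier_labels)) {
    r <- resolve_bw(map, spec$barrier_labels[k])
    rows <- heavy_rows(traj, r$chain, r$resno)
    if (length(rows) == 0L) next
    rp <- co[rows, , drop = FALSE]
    d2 <- outer(rowSums(wpts^2), rowSums(rp^2), `+`) - 2 * tcrossprod(wpts, rp)
    near[, k] <- apply(d2 <= cutoff^2 + 1e-12, 1L, any)
    per[k] <- sum(near[, k])
  }
  list(count = sum(apply(near, 1L, any)), per_residue = per)
}

#' Fraction of frames with an open water channel
#' @inheritParams select_channel_waters
#' @return value in [0, 1].
#' @export
channel_open_fraction <- function(traj, map, spec = channel_spec()) {
  mean(vapply(seq_len(n_frames(traj)),
              function(f) channel_continuity(traj, map, spec, f)$open, logical(1)))
}
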