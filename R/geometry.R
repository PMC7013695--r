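#' A labelled per-frame distance series
#' @param times frame times (ns).
#' @param values distances (A), same length.
#' @param label series label.
#' @return data frame of class `distance_series` with columns `time`, `value`.
#' @export
distance_series <- function(times, values, label = "") {
  if (length(times) != length(values))
    smd_stop("times and values must have equal length", "switchmd_structure_error")
  structure(data.frame(time = times, value = values),
            class = c("distance_series", "data.frame"), label = label)
}

# --- dihedrals -------------------------------------------------------------

# vectorised core: xyz is frames x 3N, i* are atom indices
dihedral_xyz <- function(xyz, i1, i2, i3, i4) {
  p <- function(i) xyz[, c(3L * i - 2L, 3L * i - 1L, 3L * i), drop = FALSE]
  b1 <- p(i2) - p(i1); b2 <- p(i3) - p(i2); b3 <- p(i4) - p(i3)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (any(rowSums(n1^2) < 1e-12) || any(rowSums(n2^2) < 1e-12))
    smd_stop("degenerate dihedral: three consecutive points are collinear",
             "switchmd_geometry_error")
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi               # IUPAC sign
  ang[ang <= -180] <- ang[ang <= -180] + 360   # range (-180, 180]
  ang
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention (clockwise positive looking from `p2` to `p3`),
#' reported in degrees in the range (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (A).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  xyz <- matrix(c(p1, p2, p3, p4), nrow = 1L)
  dihedral_xyz(xyz, 1L, 2L, 3L, 4L)
}

# gamma atom naming for chi1 = N-CA-CB-gamma
chi1_gamma_atom <- function(resid) {
  switch(resid,
         ILE = , VAL = "CG1",
         SER = "OG", THR = "OG1", CYS = "SG",
         GLY = , ALA = NA_character_,
         "CG")
}

chi1_atom_indices <- function(traj, chain, resno) {
  a <- traj$atoms
  rows <- which(a$chain == chain & a$resno == resno & !a$water)
  if (length(rows) == 0L)
    smd_stop(sprintf("residue %s/%d not found", chain, resno), "switchmd_mapping_error")
  resid <- a$resid[rows[1]]
  gam <- chi1_gamma_atom(resid)
  if (is.na(gam))
    smd_stop(sprintf("chi1 undefined for %s %s/%d (no gamma atom)", resid, chain, resno),
             "switchmd_unsupported_residue")
  idx <- vapply(c("N", "CA", "CB", gam), function(nm) {
    i <- rows[a$elety[rows] == nm]
    if (length(i) == 0L)
      smd_stop(sprintf("missing atom %s in %s %s/%d", nm, resid, chain, resno),
               "switchmd_missing_atom")
    i[1]
  }, integer(1))
  idx
}

#' chi1 side-chain torsion of a residue
#'
#' The first side-chain torsion N-CA-CB-gamma, with the gamma atom chosen by
#' residue type (CG; CG1 for Ile/Val; OG for Ser; OG1 for Thr; SG for Cys).
#' Gly and Ala have no chi1 and raise an unsupported-residue error.
#'
#' @param traj an `md_trajectory`.
#' @param chain,resno residue address.
#' @param frame single frame index, or `NULL` for the whole trajectory.
#' @return angle(s) in degrees, one per requested frame.
#' @export
chi1_angle <- function(traj, chain, resno, frame = NULL) {
  idx <- chi1_atom_indices(traj, chain, resno)
  xyz <- if (is.null(frame)) traj$xyz else traj$xyz[frame, , drop = FALSE]
  dihedral_xyz(xyz, idx[1], idx[2], idx[3], idx[4])
}

# --- centers and distances -------------------------------------------------

#' Unweighted center (centroid) of an atom selection
#'
#' Centers of mass here are unweighted geometric centroids of the stated
#' atoms: the analyses use all-C-alpha or all-heavy-atom selections, where
#' mass weighting would be irrelevant or unreproducible without mass tables.
#'
#' @param traj an `md_trajectory`.
#' @param sel integer atom indices.
#' @param frame frame index.
#' @return numeric 3-vector (A).
#' @export
com_coords <- function(traj, sel, frame = 1L) {
  if (length(sel) == 0L) smd_stop("empty selection", "switchmd_selection_error")
  colMeans(frame_coords(traj, frame)[sel, , drop = FALSE])
}

# per-frame centroid of a selection: frames x 3 matrix
com_series <- function(traj, sel) {
  cbind(rowMeans(traj$xyz[, 3L * sel - 2L, drop = FALSE]),
        rowMeans(traj$xyz[, 3L * sel - 1L, drop = FALSE]),
        rowMeans(traj$xyz[, 3L * sel, drop = FALSE]))
}

#' Per-frame distance between the centroids of two selections
#' @param traj an `md_trajectory`.
#' @param selA,selB integer atom index vectors.
#' @param label series label.
#' @return a [distance_series()].
#' @export
com_distance_series <- function(traj, selA, selB, label = "com") {
  if (length(selA) == 0L || length(selB) == 0L)
    smd_stop("empty selection", "switchmd_selection_error")
  d <- com_series(traj, selA) - com_series(traj, selB)
  distance_series(traj$times, sqrt(rowSums(d^2)), label)
}

# --- superposition, RMSD, RMSF --------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimising
#' the RMSD of `R %*% p + t` onto the reference points.
#'
#' @param mobile,reference N x 3 coordinate matrices (N >= 3, not collinear).
#' @return list with `R` (3 x 3), `t` (length 3), `rmsd` of the fit points.
#' @export
kabsch <- function(mobile, reference) {
  if (nrow(mobile) < 3L || nrow(mobile) != nrow(reference))
    smd_stop("need >= 3 paired points for superposition", "switchmd_geometry_error")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  if (svd(P)$d[2] < 1e-9)   # second singular value ~ 0 => points on a line
    smd_stop("collinear fit points", "switchmd_geometry_error")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cr - as.vector(R %*% cm)
  fitted <- P %*% t(R)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Superpose a frame onto a reference frame
#' @param mobile,reference N x 3 coordinate matrices of whole frames.
#' @param fit_sel atom indices used to compute the fit.
#' @return list: `coords` (transformed mobile), `R`, `t`, `fit_rmsd`.
#' @export
superpose_frames <- function(mobile, reference, fit_sel) {
  k <- kabsch(mobile[fit_sel, , drop = FALSE], reference[fit_sel, , drop = FALSE])
  coords <- sweep(mobile %*% t(k$R), 2L, k$t, `+`)
  list(coords = coords, R = k$R, t = k$t, fit_rmsd = k$rmsd)
}

#' Per-frame C-alpha RMSD after superposition
#'
#' Each frame is least-squares fitted on `fit_sel` to the reference frame,
#' then the RMSD is measured over `measure_sel`.
#'
#' @param traj an `md_trajectory`.
#' @param fit_sel,measure_sel atom index vectors; `measure_sel` defaults to
#'   `fit_sel`.
#' @param ref_frame reference frame index (default first).
#' @return a [distance_series()].
#' @export
rmsd_series <- function(traj, fit_sel, measure_sel = fit_sel, ref_frame = 1L) {
  ref <- frame_coords(traj, ref_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    sp <- superpose_frames(frame_coords(traj, i), ref, fit_sel)
    sqrt(mean(rowSums((sp$coords[measure_sel, , drop = FALSE] -
                         ref[measure_sel, , drop = FALSE])^2)))
  }, numeric(1))
  distance_series(traj$times, vals, "rmsd")
}

#' Per-atom RMSF about the time-average position
#'
#' Frames are superposed on `fit_sel` (to the first frame), atom mean
#' positions computed, and the root-mean-square deviation of each requested
#' atom about its mean reported.
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param fit_sel atom indices used for superposition.
#' @param atoms atom indices to report (default `fit_sel`).
#' @return named numeric vector (A), one entry per atom.
#' @export
rmsf_profile <- function(traj, fit_sel, atoms = fit_sel) {
  if (n_frames(traj) < 2L) smd_stop("RMSF needs >= 2 frames", "switchmd_structure_error")
  ref <- frame_coords(traj, 1L)
  fitted <- lapply(seq_len(n_frames(traj)), function(i)
    superpose_frames(frame_coords(traj, i), ref, fit_sel)$coords[atoms, , drop = FALSE])
  arr <- simplify2array(fitted)                 # atoms x 3 x frames
  mu <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mu)^2
  out <- sqrt(apply(dev2, 1L, mean) * 3)        # mean over xyz&frames times 3
  names(out) <- paste0(traj$atoms$chain[atoms], traj$atoms$resno[atoms], ".",
                       traj$atoms$elety[atoms])
  out
}

# --- residue-pair minimum distances ---------------------------------------

heavy_rows <- function(traj, chain, resno) {
  a <- traj$atoms
  which(a$chain == chain & a$resno %in% resno &
          !(a$elesy %in% c("H", "D")) & !grepl("^[0-9]*H", a$elety))
}

#' Residue-pair minimum heavy-atom distance matrix and contact mask
#'
#' Entry (i, j) is the smallest heavy-atom to heavy-atom distance between
#' residue i of set A and residue j of set B; contacts are distances at or
#' below 3 A, the threshold used to mark residue contacts on distance maps.
#' Over a frame window the per-frame minimum distances are time-averaged
#' before thresholding.
#'
#' @param traj an `md_trajectory`.
#' @param setA,setB data frames with columns `chain`, `resno`.
#' @param frames frame window (default all frames).
#' @param contact_cutoff contact threshold in A (default 3.0).
#' @return list: `distance` (A x B matrix, A), `contact` (logical matrix).
#' @export
residue_min_distance <- function(traj, setA, setB, frames = seq_len(n_frames(traj)),
                                 contact_cutoff = 3.0) {
  if (nrow(setA) == 0L || nrow(setB) == 0L)
    smd_stop("empty residue set", "switchmd_selection_error")
  rowsA <- lapply(seq_len(nrow(setA)), function(i) heavy_rows(traj, setA$chain[i], setA$resno[i]))
  rowsB <- lapply(seq_len(nrow(setB)), function(i) heavy_rows(traj, setB$chain[i], setB$resno[i]))
  if (any(lengths(rowsA) == 0L) || any(lengths(rowsB) == 0L))
    smd_stop("residue with no heavy atoms in set", "switchmd_selection_error")
  acc <- matrix(0, nrow(setA), nrow(setB))
  for (f in frames) {
    co <- frame_coords(traj, f)
    for (i in seq_along(rowsA)) {
      A <- co[rowsA[[i]], , drop = FALSE]
      for (j in seq_along(rowsB)) {
        B <- co[rowsB[[j]], , drop = FALSE]
        d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
        acc[i, j] <- acc[i, j] + sqrt(max(min(d2), 0))
      }
    }
  }
  dist <- acc / length(frames)
  dimnames(dist) <- list(paste0(setA$chain, setA$resno), paste0(setB$chain, setB$resno))
  list(distance = dist, contact = dist <= contact_cutoff)
}

# --- helix axes and TM6 kink ----------------------------------------------

#' Principal axis of a run of C-alpha atoms
#'
#' The largest-variance direction of the point set, oriented from the first
#' toward the last residue. For runs of 7 or more residues the points are
#' first averaged over one helical turn (a 5-point kernel whose weights
#' cancel the 100 degrees/residue radial harmonic exactly), so the fitted
#' axis follows the helix centerline rather than the surface spiral; this
#' removes the partial-turn wobble that otherwise tilts the principal axis
#' of short helix segments by several degrees. Shorter runs (and therefore
#' exactly collinear point sets) use the raw principal axis.
#'
#' @param coords N x 3 matrix of consecutive C-alpha positions (N >= 5).
#' @param twist helical twist in degrees/residue used by the smoothing
#'   kernel (default 100, the ideal alpha-helix value).
#' @return list: `axis` (unit 3-vector), `centroid`.
#' @export
helix_axis <- function(coords, twist = 100) {
  n <- nrow(coords)
  if (n < 5L) smd_stop("helix axis needs >= 5 C-alpha atoms", "switchmd_geometry_error")
  pts <- coords
  if (n >= 7L) {
    tw <- twist * pi / 180
    a <- -(1 + 2 * cos(tw)) / (2 * cos(2 * tw))
    w <- c(a, 1, 1, 1, a); w <- w / sum(w)
    pts <- t(vapply(3:(n - 2L), function(i)
      colSums(coords[(i - 2L):(i + 2L), , drop = FALSE] * w), numeric(3)))
  }
  mu <- colMeans(pts)
  cc <- sweep(pts, 2L, mu)
  ax <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  if (sum(ax * (coords[n, ] - coords[1, ])) < 0) ax <- -ax
  list(axis = ax / sqrt(sum(ax^2)), centroid = colMeans(coords))
}

tm6_ca_coords <- function(traj, map, positions, frame) {
  resnos <- map$anchors[["6"]] + (positions - 50L)
  resnos <- resnos[resnos >= map$spans[6, 1] & resnos <= map$spans[6, 2]]
  sel <- atom_select(traj, chain = map$chain, resno = resnos, elety = "CA")
  if (length(sel) < 5L)
    smd_stop("TM6 segment has fewer than 5 mapped C-alpha atoms", "switchmd_mapping_error")
  ord <- order(traj$atoms$resno[sel])
  frame_coords(traj, frame)[sel[ord], , drop = FALSE]
}

#' TM6 kink angle at the rotamer toggle position
#'
#' Angle between the principal axes of the TM6 segments above and below the
#' 6.48 toggle (6.30-6.47 vs 6.49-6.60, clipped to the mapped span). Straight
#' helices score near 0; activation-style bending below W6.48 raises the
#' angle.
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @param frame frame index, or `NULL` for all frames.
#' @param average if `TRUE`, superpose all frames on the TM6 C-alphas,
#'   average the coordinates and report the single kink of the mean
#'   structure. Per-frame kinks of a straight helix fold coordinate noise
#'   into a small positive angle; the mean structure suppresses that bias
#'   and is the estimator to use when recovering a planted bend.
#' @return kink angle(s) in degrees, in [0, 180).
#' @export
tm6_kink <- function(traj, map, frame = NULL, average = FALSE) {
  kink_of <- function(lowc, upc) {
    lower <- helix_axis(lowc)$axis
    upper <- helix_axis(upc)$axis
    acos(pmin(1, pmax(-1, sum(lower * upper)))) * 180 / pi
  }
  if (average) {
    resnos <- map$anchors[["6"]] + (30:60 - 50L)
    sel <- atom_select(traj, chain = map$chain, resno = resnos, elety = "CA")
    ref <- frame_coords(traj, 1L)
    acc_low <- 0; acc_up <- 0
    for (f in seq_len(n_frames(traj))) {
      co <- superpose_frames(frame_coords(traj, f), ref, sel)$coords
      acc_low <- acc_low + tm6_ca_coords_from(co, traj, map, 30:47)
      acc_up <- acc_up + tm6_ca_coords_from(co, traj, map, 49:60)
    }
    return(kink_of(acc_low / n_frames(traj), acc_up / n_frames(traj)))
  }
  frames <- if (is.null(frame)) seq_len(n_frames(traj)) else frame
  vapply(frames, function(f)
    kink_of(tm6_ca_coords(traj, map, 30:47, f), tm6_ca_coords(traj, map, 49:60, f)),
    numeric(1))
}

tm6_ca_coords_from <- function(co, traj, map, positions) {
  resnos <- map$anchors[["6"]] + (positions - 50L)
  resnos <- resnos[resnos >= map$spans[6, 1] & resnos <= map$spans[6, 2]]
  sel <- atom_select(traj, chain = map$chain, resno = resnos, elety = "CA")
  co[sel[order(traj$atoms$resno[sel])], , drop = FALSE]
}
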