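# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles, sharing no code with the package internals.

# dihedral via the two plane normals, signed by the triple product
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# all-pairs minimum distance between two coordinate sets
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# breadth-first search connectivity between two node sets on a geometric graph
oracle_bfs_connected <- function(pts, cutoff, src, dst) {
  if (length(src) == 0L || length(dst) == 0L) return(FALSE)
  n <- nrow(pts)
  visited <- rep(FALSE, n)
  queue <- src
  visited[src] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% dst) return(TRUE)
    for (u in seq_len(n)) {
      if (!visited[u] && sqrt(sum((pts[v, ] - pts[u, ])^2)) <= cutoff) {
        visited[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  any(visited[dst])
}

# covariance by explicit outer-product accumulation
oracle_covariance <- function(X) {
  mu <- colMeans(X)
  acc <- matrix(0, ncol(X), ncol(X))
  for (f in seq_len(nrow(X))) {
    d <- X[f, ] - mu
    acc <- acc + outer(d, d)
  }
  acc / nrow(X)
}

# random symmetric positive semi-definite matrix
random_spd <- function(n, rank = n) {
  M <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(M)
}

# ---- handcrafted PDB fixtures --------------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, het = FALSE, altloc = " ", icode = " ",
                          element = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, altloc, resn, chain,
          resno, icode, x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(path, models) {
  lines <- character()
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, models[[m]])
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# append free water oxygens to a trajectory (same positions in every frame
# unless a frames x (3*nw) matrix is given)
add_waters <- function(traj, wpos) {
  nw <- nrow(wpos)
  if (nw == 0L) return(traj)
  wat <- data.frame(elety = "O", resid = "HOH", resno = 9000L + seq_len(nw),
                    chain = "W", elesy = "O", water = TRUE)
  flat <- as.vector(t(wpos))
  xyz <- cbind(traj$xyz, matrix(flat, n_frames(traj), 3L * nw, byrow = TRUE))
  md_trajectory(xyz, rbind(traj$atoms, wat), times = traj$times,
                source = traj$source)
}

# a bundle without waters, shared by water-channel tests
bare_bundle <- function(...) {
  generate_bundle(synthetic_spec(n_frames = 1, noise_sigma = 0,
                                 channel_state = "none", ...))
}

# Synthetic stand-in for the inactive-state D2 receptor crystal geometry
# (the deposited structure is not redistributed here): a bundle whose
# R3.50/E6.30 charged-group minimum is built at 3.0 A and whose TM7 is
# shifted so the Y5.58-Y7.53 C-alpha distance is exactly 19.4 A.
make_inactive_reference_pdb <- function(path) {
  g <- bare_bundle(lock_distance = 3.0)
  traj <- g$traj; map <- g$map
  i5 <- atom_select(traj, chain = "R", resno = resolve_bw(map, "5.58")$resno, elety = "CA")
  i7 <- atom_select(traj, chain = "R", resno = resolve_bw(map, "7.53")$resno, elety = "CA")
  co <- frame_coords(traj, 1)
  v <- co[i7, ] - co[i5, ]
  d_now <- sqrt(sum(v^2))
  shift <- (19.4 / d_now - 1) * v
  tm7 <- which(traj$atoms$chain == "R" &
                 traj$atoms$resno >= map$spans[7, 1] & traj$atoms$resno <= map$spans[7, 2])
  xyz <- traj$xyz
  for (row in tm7) xyz[1, 3 * row - (2:0)] <- xyz[1, 3 * row - (2:0)] + shift
  traj2 <- md_trajectory(xyz, traj$atoms, times = traj$times, source = "synthetic_inactive_ref")
  write_trajectory(traj2, path)
  list(path = path, map = map)
}
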