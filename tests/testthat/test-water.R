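# water tests share one bundle; waters are appended at chosen positions
channel_frame <- function(wpos, ...) {
  g <- bare_bundle(...)
  list(traj = add_waters(g$traj, wpos), map = g$map)
}

axis_endpoints <- function(g) {
  co <- frame_coords(g$traj, 1)
  a <- g$traj$atoms
  top <- co[which(a$resno == resolve_bw(g$map, "3.32")$resno & a$elety == "CA"), ]
  bottom <- co[which(a$resno == resolve_bw(g$map, "7.53")$resno & a$elety == "CA"), ]
  list(top = top, bottom = bottom)
}

test_that("channel waters are selected by cylinder geometry", {
  g <- bare_bundle()
  ax <- axis_endpoints(g)
  mid <- (ax$top + ax$bottom) / 2
  lateral <- mid + 20 * c(1, 0, 0)
  cf <- channel_frame(rbind(mid, lateral))
  sel <- select_channel_waters(cf$traj, cf$map)
  watrows <- which(cf$traj$atoms$water)
  expect_true(watrows[1] %in% sel)
  expect_false(watrows[2] %in% sel)

  # random waters: equals the brute-force point-to-segment filter
  set.seed(12)
  spec <- channel_spec()
  rnd <- matrix(rnorm(300, sd = 15), ncol = 3) +
    matrix(mid, 100, 3, byrow = TRUE)
  cf2 <- channel_frame(rnd)
  sel2 <- select_channel_waters(cf2$traj, cf2$map, spec)
  u <- ax$bottom - ax$top; L <- sqrt(sum(u^2)); u <- u / L
  manual <- vapply(seq_len(100), function(i) {
    p <- rnd[i, ] - ax$top
    t <- sum(p * u)
    tc <- min(max(t, 0), L)
    d <- sqrt(sum((p - tc * u)^2))
    d <= spec$cylinder_radius && t >= -spec$axial_margin && t <= L + spec$axial_margin
  }, logical(1))
  expect_identical(which(cf2$traj$atoms$water) %in% sel2, manual)
})

test_that("continuity follows hydrogen-bond connectivity of the water graph", {
  g <- bare_bundle()
  ax <- axis_endpoints(g)
  u <- ax$bottom - ax$top; L <- sqrt(sum(u^2)); u <- u / L

  none <- channel_frame(matrix(numeric(0), 0, 3))
  expect_false(channel_continuity(none$traj, none$map)$open)

  chain <- t(sapply(seq(0.5, L - 0.5, by = 3.0), function(s) ax$top + s * u))
  open <- channel_frame(chain)
  res <- channel_continuity(open$traj, open$map)
  expect_true(res$open)
  expect_gt(res$path_length, 2L)

  gap <- chain[-(5:6), , drop = FALSE]    # removes ~6 A of the wire
  closed <- channel_frame(gap)
  expect_false(channel_continuity(closed$traj, closed$map)$open)
})

test_that("continuity agrees with a breadth-first-search oracle on random fixtures", {
  g <- bare_bundle()
  ax <- axis_endpoints(g)
  u <- ax$bottom - ax$top; L <- sqrt(sum(u^2)); u <- u / L
  spec <- channel_spec()
  set.seed(77)
  for (i in 1:100) {
    nw <- sample(5:25, 1)
    s <- runif(nw, -2, L + 2)
    lat <- matrix(rnorm(2 * nw, sd = 3), nw, 2)
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
           u[1] * ref[2] - u[2] * ref[1]); v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    pts <- matrix(ax$top, nw, 3, byrow = TRUE) + outer(s, u) +
      outer(lat[, 1], v) + outer(lat[, 2], w)
    cf <- channel_frame(pts)
    got <- channel_continuity(cf$traj, cf$map, spec)$open
    inside <- vapply(seq_len(nw), function(k) {
      t <- sum((pts[k, ] - ax$top) * u)
      d <- sqrt(sum((pts[k, ] - ax$top - min(max(t, 0), L) * u)^2))
      d <= spec$cylinder_radius && t >= -spec$axial_margin && t <= L + spec$axial_margin
    }, logical(1))
    sub <- pts[inside, , drop = FALSE]
    src <- which(sqrt(rowSums(sweep(sub, 2, ax$top)^2)) <= spec$attach_cutoff)
    dst <- which(sqrt(rowSums(sweep(sub, 2, ax$bottom)^2)) <= spec$attach_cutoff)
    want <- oracle_bfs_connected(sub, spec$link_cutoff, src, dst)
    expect_identical(got, want)
  }
})

test_that("adding waters never closes an open channel", {
  g <- bare_bundle()
  ax <- axis_endpoints(g)
  u <- ax$bottom - ax$top; L <- sqrt(sum(u^2)); u <- u / L
  chain <- t(sapply(seq(0.5, L - 0.5, by = 3.0), function(s) ax$top + s * u))
  set.seed(5)
  for (i in 1:20) {
    extra <- matrix(rnorm(30, sd = 10), 10, 3) +
      matrix((ax$top + ax$bottom) / 2, 10, 3, byrow = TRUE)
    cf <- channel_frame(rbind(chain, extra))
    expect_true(channel_continuity(cf$traj, cf$map)$open)
  }
})

test_that("barrier occupancy counts waters near the five barrier residues", {
  g <- bare_bundle()
  expect_equal(barrier_occupancy(g$traj, g$map, frame = 1)$count, 0L)
  a <- g$traj$atoms
  m636 <- resolve_bw(g$map, "6.36")$resno
  ca <- frame_coords(g$traj, 1)[which(a$resno == m636 & a$elety == "CA"), ]
  cf <- channel_frame(rbind(ca + c(3, 0, 0), ca + c(40, 0, 0)))
  occ <- barrier_occupancy(cf$traj, cf$map, frame = 1)
  expect_equal(occ$count, 1L)
  expect_equal(unname(occ$per_residue["6.36"]), 1L)
  # random fixture vs enumeration
  set.seed(9)
  rnd <- matrix(rnorm(60, sd = 10), 20, 3) + matrix(ca, 20, 3, byrow = TRUE)
  cf2 <- channel_frame(rnd)
  occ2 <- barrier_occupancy(cf2$traj, cf2$map, frame = 1)
  spec <- channel_spec()
  co <- frame_coords(cf2$traj, 1)
  atm <- cf2$traj$atoms
  brows <- unlist(lapply(spec$barrier_labels, function(lb)
    which(atm$chain == "R" & atm$resno == resolve_bw(cf2$map, lb)$resno &
            !(atm$elesy %in% c("H", "D")))))
  wrows <- which(atm$water)
  manual <- sum(vapply(wrows, function(wi)
    any(sqrt(colSums((t(co[brows, , drop = FALSE]) - co[wi, ])^2)) <= 4.0),
    logical(1)))
  expect_equal(occ2$count, manual)
})

test_that("open fraction averages per-frame continuity", {
  alt <- generate_trajectory(synthetic_spec(n_frames = 20, noise_sigma = 0,
                                            channel_state = "alternating"))
  expect_equal(channel_open_fraction(alt$traj, alt$map), 0.5)
  opn <- generate_trajectory(synthetic_spec(n_frames = 10, noise_sigma = 0,
                                            channel_state = "open"))
  expect_equal(channel_open_fraction(opn$traj, opn$map), 1.0)
  blk <- generate_trajectory(synthetic_spec(n_frames = 10, noise_sigma = 0.5,
                                            channel_state = "blocked", seed = 8))
  expect_equal(channel_open_fraction(blk$traj, blk$map), 0.0)
})
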