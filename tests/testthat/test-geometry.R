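test_that("dihedrals follow the sign convention and match the independent oracle", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, -1, 0)), 180)
  set.seed(42)
  for (i in 1:100) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "switchmd_geometry_error")
})

test_that("chi1 uses residue-specific gamma atoms and flags unsupported residues", {
  g <- generate_bundle(synthetic_spec(n_frames = 1, noise_sigma = 0,
                                      rotamer = list("6.48" = list(states = c(-60, 180), p_flip = 0),
                                                     "7.53" = list(states = c(47.5, 180), p_flip = 0))))
  w <- resolve_bw(g$map, "6.48")
  expect_equal(chi1_angle(g$traj, w$chain, w$resno, frame = 1), -60, tolerance = 1e-6)
  y <- resolve_bw(g$map, "7.53")
  expect_equal(chi1_angle(g$traj, y$chain, y$resno, frame = 1), 47.5, tolerance = 1e-6)
  # an alanine has no gamma atom
  ala <- g$traj$atoms$resno[g$traj$atoms$resid == "ALA" & g$traj$atoms$chain == "R"][1]
  expect_error(chi1_angle(g$traj, "R", ala, frame = 1),
               class = "switchmd_unsupported_residue")
  # a chi1-capable residue missing its CB
  keep <- which(!(g$traj$atoms$resno == w$resno & g$traj$atoms$elety == "CB"))
  cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
  maimed <- md_trajectory(g$traj$xyz[, cols, drop = FALSE],
                          g$traj$atoms[keep, ], times = g$traj$times)
  expect_error(chi1_angle(maimed, w$chain, w$resno, frame = 1),
               class = "switchmd_missing_atom")
})

test_that("centroids and centroid distances equal brute-force means", {
  xyz <- matrix(c(0, 0, 0, 2, 0, 0, 1, 3, 5, -1, 2, 2, 4, 4, 4), nrow = 1)
  at <- data.frame(elety = "CA", resid = "ALA", resno = 1:5, chain = "R",
                   elesy = "C", water = FALSE)
  tr <- md_trajectory(xyz, at)
  expect_equal(com_coords(tr, 3L), c(1, 3, 5))
  expect_equal(com_coords(tr, 1:2), c(1, 0, 0))
  expect_equal(com_coords(tr, 1:5), colMeans(matrix(xyz, ncol = 3, byrow = TRUE)))
  expect_equal(com_distance_series(tr, 1:3, 1:3)$value, 0)
  tr2 <- md_trajectory(rbind(xyz, xyz), at)
  d <- com_distance_series(tr2, 1L, 2L)
  expect_equal(d$value, c(2, 2))
})

test_that("Kabsch superposition removes rigid motion and is near-optimal", {
  set.seed(7)
  P <- matrix(rnorm(30), 10, 3)
  expect_lt(kabsch(P, P)$rmsd, 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  expect_lt(kabsch(Q, P)$rmsd, 1e-9)
  # optimality: no random rotation beats the fitted one
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(A, B)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rand_rmsd <- replicate(2000, {
    M <- matrix(rnorm(9), 3, 3); qr_ <- qr(M)
    Rr <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(Rr) < 0) Rr[, 1] <- -Rr[, 1]
    sqrt(mean(rowSums((Ac %*% t(Rr) - Bc)^2)))
  })
  expect_lte(fit$rmsd, min(rand_rmsd) + 1e-12)
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch(line, line + 1), class = "switchmd_geometry_error")
  # cross-check against the reference implementation in bio3d
  fitted <- bio3d::fit.xyz(as.vector(t(B)), as.vector(t(A)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(kabsch(A, B)$rmsd,
               sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - B)^2))),
               tolerance = 1e-6)
})

test_that("RMSD and RMSF follow closed-form expectations for isotropic jitter", {
  set.seed(21)
  n_at <- 200; nf <- 100; sigma <- 0.4
  base <- matrix(rnorm(3 * n_at, sd = 8), n_at, 3)
  at <- data.frame(elety = "CA", resid = "ALA", resno = seq_len(n_at),
                   chain = "R", elesy = "C", water = FALSE)
  flat <- as.vector(t(base))
  xyz <- rbind(flat,
               t(replicate(nf, flat + rnorm(3 * n_at, sd = sigma))))
  tr <- md_trajectory(xyz, at)
  rs <- rmsd_series(tr, seq_len(n_at))
  expect_equal(rs$value[1], 0, tolerance = 1e-10)
  expect_equal(mean(rs$value[-1]), sigma * sqrt(3), tolerance = 0.05)

  # rigid motion only: zero RMSD after fitting
  th <- 0.5; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- as.vector(t(base %*% t(R) + 5))
  tr2 <- md_trajectory(rbind(flat, moved), at)
  expect_lt(rmsd_series(tr2, seq_len(n_at))$value[2], 1e-9)

  # RMSF: a single jittered atom among fixed ones
  set.seed(22)
  nf2 <- 2000
  base2 <- matrix(rnorm(60, sd = 6), 20, 3)
  at2 <- at[1:20, ]; at2$resno <- 1:20
  xyz2 <- t(replicate(nf2, {
    fr <- base2
    fr[20, ] <- fr[20, ] + rnorm(3, sd = sigma)
    as.vector(t(fr))
  }))
  tr3 <- md_trajectory(xyz2, at2)
  prof <- rmsf_profile(tr3, fit_sel = 1:19, atoms = 1:20)
  expect_lt(max(prof[1:19]), 1e-9)
  expect_equal(unname(prof[20]), sigma * sqrt(3), tolerance = 0.05)
  # frame order is irrelevant
  perm <- sample(nf2)
  tr4 <- md_trajectory(xyz2[perm, ], at2)
  expect_equal(unname(rmsf_profile(tr4, 1:19, atoms = 20)),
               unname(prof[20]), tolerance = 1e-9)
})

test_that("minimum-distance matrices and contact calls equal brute force", {
  set.seed(31)
  n_res <- 6
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r)
    data.frame(elety = c("N", "CA", "CB"), resid = "LEU", resno = r,
               chain = rep(c("A", "B"), each = 3 * n_res / 2)[3 * r], elesy = c("N", "C", "C"),
               water = FALSE)))
  atoms$chain <- rep(c("A", "B"), each = 3 * n_res / 2)
  xyz <- matrix(rnorm(2 * 3 * nrow(atoms), sd = 4), nrow = 2)
  tr <- md_trajectory(xyz, atoms)
  setA <- data.frame(chain = "A", resno = 1:3)
  setB <- data.frame(chain = "B", resno = 4:6)
  res <- residue_min_distance(tr, setA, setB, frames = 1L)
  for (i in 1:3) for (j in 1:3) {
    co <- frame_coords(tr, 1)
    A <- co[atoms$chain == "A" & atoms$resno == i, ]
    B <- co[atoms$chain == "B" & atoms$resno == j + 3, ]
    expect_equal(res$distance[i, j], oracle_min_dist(A, B), tolerance = 1e-12)
  }
  expect_identical(res$contact, res$distance <= 3.0)
  # threshold behaviour on constructed residues
  two <- md_trajectory(matrix(c(0, 0, 0, 2.5, 0, 0), 1),
                       data.frame(elety = "CA", resid = "GLY", resno = 1:2,
                                  chain = c("A", "B"), elesy = "C", water = FALSE))
  r2 <- residue_min_distance(two, data.frame(chain = "A", resno = 1),
                             data.frame(chain = "B", resno = 2))
  expect_equal(r2$distance[1, 1], 2.5)
  expect_true(r2$contact[1, 1])
  two$xyz[1, 4] <- 3.5
  r3 <- residue_min_distance(two, data.frame(chain = "A", resno = 1),
                             data.frame(chain = "B", resno = 2))
  expect_false(r3$contact[1, 1])
})

test_that("helix axes and the TM6 kink recover constructed geometry", {
  line <- cbind(0, 0, seq(0, 10, length.out = 6))
  ax <- helix_axis(line)
  expect_equal(abs(ax$axis), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(ax$axis[3], 1)
  # ideal helix along z
  hel <- t(sapply(0:17, function(i) {
    a <- 100 * i * pi / 180
    c(2.3 * cos(a), 2.3 * sin(a), 1.5 * i)
  }))
  axh <- helix_axis(hel)$axis
  expect_gt(sum(axh * c(0, 0, 1)), cos(1 * pi / 180))
  # reversing the run flips the orientation
  expect_equal(helix_axis(hel[18:1, ])$axis, -axh, tolerance = 1e-9)
  expect_error(helix_axis(hel[1:4, ]), class = "switchmd_geometry_error")

  g0 <- bare_bundle(tm6_bend = 0)
  expect_lt(tm6_kink(g0$traj, g0$map, 1), 5)
  g30 <- bare_bundle(tm6_bend = 30)
  expect_equal(tm6_kink(g30$traj, g30$map, 1), 30, tolerance = 3)
  # kink is invariant under global rigid motion
  th <- 1.1; R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  co <- matrix(g30$traj$xyz[1, ], ncol = 3, byrow = TRUE) %*% t(R) + 7
  rot <- md_trajectory(matrix(as.vector(t(co)), 1), g30$traj$atoms)
  expect_equal(tm6_kink(rot, g30$map, 1), tm6_kink(g30$traj, g30$map, 1),
               tolerance = 1e-9)
})
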