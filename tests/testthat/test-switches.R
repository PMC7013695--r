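test_that("rotamer bins follow the half-open 120-degree rule", {
  expect_equal(rotamer_classify(-60), "gauche-")
  expect_equal(rotamer_classify(180), "trans")
  expect_equal(rotamer_classify(-120), "trans")      # boundary: half-open bins
  expect_equal(rotamer_classify(c(60, 0, 120.0001, -0.0001)),
               c("gauche+", "gauche-", "trans", "gauche-"))
})

test_that("switch time series track planted two-state flips exactly when noiseless", {
  spec <- synthetic_spec(n_frames = 200, noise_sigma = 0, seed = 5,
                         rotamer = list("6.48" = list(states = c(-60, 180), p_flip = 0.1),
                                        "6.44" = list(states = c(180, -60), p_flip = 0.05)))
  g <- generate_trajectory(spec)
  sw <- switch_timeseries(g$traj, g$map)
  expect_named(sw, c("6.48", "6.44", "6.55", "7.53"))
  for (lb in names(sw)) {
    expect_equal(nrow(sw[[lb]]), 200L)
    expect_identical(sw[[lb]]$state, g$truth[[paste0("state_", lb)]])
  }
  expect_gt(length(unique(sw[["6.48"]]$state)), 1L)  # the chain actually flips
  # static residues have constant chi1
  expect_equal(var(sw[["6.55"]]$chi1), 0, tolerance = 1e-12)
})

test_that("the ionic lock equals the enumeration oracle and the planted bridge", {
  g <- bare_bundle(lock_distance = 3.0)
  expect_equal(ionic_lock_distance(g$traj, g$map, frame = 1), 3.0, tolerance = 1e-9)
  gn <- generate_trajectory(synthetic_spec(n_frames = 5, noise_sigma = 0.5,
                                           lock_distance = 4, seed = 9,
                                           channel_state = "none"))
  r <- resolve_bw(gn$map, "3.50"); e <- resolve_bw(gn$map, "6.30")
  for (f in 1:5) {
    co <- frame_coords(gn$traj, f)
    a <- gn$traj$atoms
    iN <- which(a$resno == r$resno & a$elety %in% c("NE", "NH1", "NH2"))
    iO <- which(a$resno == e$resno & a$elety %in% c("OE1", "OE2"))
    expect_equal(ionic_lock_distance(gn$traj, gn$map, frame = f),
                 oracle_min_dist(co[iN, , drop = FALSE], co[iO, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("the TM5-TM7 tyrosine distance is a plain C-alpha distance", {
  g <- bare_bundle()
  y5 <- resolve_bw(g$map, "5.58"); y7 <- resolve_bw(g$map, "7.53")
  co <- frame_coords(g$traj, 1)
  a <- g$traj$atoms
  i5 <- which(a$resno == y5$resno & a$elety == "CA")
  i7 <- which(a$resno == y7$resno & a$elety == "CA")
  expect_equal(tm5_tm7_distance(g$traj, g$map, frame = 1),
               sqrt(sum((co[i5, ] - co[i7, ])^2)), tolerance = 1e-12)
})

test_that("coupling trends classify analytic and noisy drifts", {
  t <- 0:99
  expect_equal(coupling_trend(distance_series(t, rep(8, 100)))$classification, "flat")
  lin <- distance_series(t, 20 - 0.002 * t)
  tr <- coupling_trend(lin, threshold = 0.001)
  expect_equal(tr$slope, -0.002, tolerance = 1e-12)
  expect_equal(tr$intercept, 20, tolerance = 1e-9)
  expect_equal(tr$classification, "approaching")
  expect_error(coupling_trend(distance_series(0, 5)), class = "switchmd_degenerate_input")
  # noiseless generator recovery is exact
  g0 <- generate_trajectory(synthetic_spec(n_frames = 50, noise_sigma = 0,
                                           drift_slope = -0.0031, channel_state = "none"))
  s0 <- coupling_trend(coupling_series(g0$traj, g0$map, "G", 351:355))$slope
  expect_equal(s0, -0.0031, tolerance = 1e-9)
})

test_that("slope classification stays accurate across a drift grid under noise", {
  grid <- c(-0.004, -0.002, 0, 0.002, 0.004)
  thr <- 5e-4
  correct <- 0; total <- 0
  for (s in grid) {
    for (seed in 1:30) {
      g <- generate_trajectory(synthetic_spec(n_frames = 300, noise_sigma = 0.5,
                                              drift_slope = s, seed = 1000 + seed,
                                              channel_state = "none"))
      cls <- coupling_trend(coupling_series(g$traj, g$map, "G", 351:355),
                            threshold = thr)$classification
      if (abs(s) > thr) {
        total <- total + 1
        truth <- if (s < 0) "approaching" else "receding"
        correct <- correct + (cls == truth)
      }
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("interface distances and hydrogen-bond checks match direct recomputation", {
  g <- bare_bundle()
  pairs <- list(list(a = list(chain = "R", resno = 560L),
                     b = list(chain = "G", resno = 351L)))
  res <- suppressWarnings(interface_residue_distances(g$traj, pairs))
  expect_equal(res$sd, 0)
  # drifting series: window vs full both equal direct recomputation
  gd <- generate_trajectory(synthetic_spec(n_frames = 40, noise_sigma = 0,
                                           drift_slope = 0.05, channel_state = "none"))
  full <- interface_residue_distances(gd$traj, pairs)
  lastw <- interface_residue_distances(gd$traj, pairs, frames = 21:40)
  a <- gd$traj$atoms
  selA <- which(a$chain == "R" & a$resno == 560L &
                  !(a$elety %in% c("N", "CA", "C", "O", "OXT")))
  selB <- which(a$chain == "G" & a$resno == 351L &
                  !(a$elety %in% c("N", "CA", "C", "O", "OXT")))
  direct <- vapply(seq_len(40), function(f) {
    co <- frame_coords(gd$traj, f)
    sqrt(sum((colMeans(co[selA, , drop = FALSE]) - colMeans(co[selB, , drop = FALSE]))^2))
  }, numeric(1))
  expect_equal(full$mean, mean(direct), tolerance = 1e-9)
  expect_equal(lastw$mean, mean(direct[21:40]), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(full$mean, lastw$mean)))
  # glycine falls back to C-alpha with a warning
  gly_pair <- list(list(a = list(chain = "G", resno = 353L),
                        b = list(chain = "R", resno = 560L)))
  expect_warning(interface_residue_distances(g$traj, gly_pair), "C-alpha")
  expect_error(interface_residue_distances(g$traj, pairs, frames = integer(0)),
               class = "switchmd_degenerate_input")
})

test_that("hydrogen bonds are detected by polar heavy-atom proximity", {
  g <- bare_bundle()
  # R560 guanidinium vs D351 carboxylate: move D351 oxygens to 2.9 A from NH1
  a <- g$traj$atoms
  nh1 <- which(a$chain == "R" & a$resno == 560L & a$elety == "NH1")
  od1 <- which(a$chain == "G" & a$resno == 351L & a$elety == "OD1")
  xyz <- g$traj$xyz
  xyz[1, 3 * od1 - (2:0)] <- xyz[1, 3 * nh1 - (2:0)] + c(2.9, 0, 0)
  tr <- md_trajectory(xyz, a)
  hb <- hbond_present(tr, 1, list(chain = "R", resno = 560L),
                      list(chain = "G", resno = 351L))
  expect_true(hb$present)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$donor_atom, "NH1")
  xyz[1, 3 * od1 - (2:0)] <- xyz[1, 3 * nh1 - (2:0)] + c(4.2, 0, 0)
  a2 <- a; od2 <- which(a$chain == "G" & a$resno == 351L & a$elety == "OD2")
  xyz[1, 3 * od2 - (2:0)] <- xyz[1, 3 * nh1 - (2:0)] + c(9, 0, 0)
  tr2 <- md_trajectory(xyz, a2)
  hb2 <- hbond_present(tr2, 1, list(chain = "R", resno = 560L),
                       list(chain = "G", resno = 351L))
  # brute-force over all polar pairs
  iD <- which(a$chain == "R" & a$resno == 560L & a$elesy %in% c("N", "O"))
  iA <- which(a$chain == "G" & a$resno == 351L & a$elesy %in% c("N", "O"))
  co <- frame_coords(tr2, 1)
  expect_equal(hb2$distance,
               oracle_min_dist(co[iD, , drop = FALSE], co[iA, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("activation reports discriminate presets and degrade gracefully", {
  act <- generate_trajectory(synthetic_preset("active-coupled", n_frames = 150, seed = 3))
  ina <- generate_trajectory(synthetic_preset("inactive-decoupled", n_frames = 150, seed = 3))
  ra <- build_activation_report(act$traj, act$map)
  ri <- build_activation_report(ina$traj, ina$map)
  expect_equal(ra$coupling$classification, "approaching")
  expect_equal(ri$coupling$classification, "receding")
  expect_equal(ra$kink_class, "bent")
  expect_equal(ri$kink_class, "straight")
  expect_equal(ra$channel_open_fraction, 1.0)
  expect_equal(ri$channel_open_fraction, 0.0)
  expect_length(ra$errors, 0L)

  # one-frame trajectory: distances present, trend degenerate
  one <- generate_bundle(synthetic_spec(n_frames = 1, noise_sigma = 0))
  r1 <- build_activation_report(one$traj, one$map, list(channel = FALSE))
  expect_equal(r1$coupling$classification, "degenerate")
  expect_equal(length(r1$ionic_lock$value), 1L)
  # disabling the channel drops only the channel fields
  expect_null(r1$channel_series)
  expect_false(is.null(r1$tm5_tm7))
})
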