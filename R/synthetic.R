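#' Specification for a synthetic receptor/G-alpha/water trajectory
#'
#' The generator emulates the statistical structure of activation-hallmark
#' data: a linear receptor/G-alpha approach (or retreat) with Gaussian
#' coordinate noise, two-state chi1 rotamer kinetics on the microswitch
#' residues, a TM6 bend of known angle at the 6.48 position, a salt bridge at
#' a planted distance, and an internal water column that is open, blocked at
#' the hydrophobic barrier, or alternating. Every planted quantity is echoed
#' back as ground truth so analyses can be validated against it.
#'
#' @param n_frames number of frames (>= 1).
#' @param dt ns per frame.
#' @param seed integer seed; one random stream drives, in order, the rotamer
#'   Markov chains (per switch, in label order) and then the coordinate
#'   noise.
#' @param drift_slope A/ns applied to the alpha5 helix along the
#'   receptor-to-alpha5 axis (negative = approaching).
#' @param noise_sigma Gaussian noise sd per coordinate axis (A).
#' @param tm6_bend degrees of planted TM6 bend at position 6.48.
#' @param rotamer named list per switch label:
#'   `list(states = c(deg, deg), p_flip = probability/frame)`.
#' @param channel_state `"open"`, `"blocked"`, `"alternating"` or `"none"`.
#' @param lock_distance planted R3.50/E6.30 minimum charged-group distance (A).
#' @param alpha5_distance0 initial receptor/alpha5 centroid distance (A).
#' @param bundle_radius radius of the circle carrying the 7 helices (A).
#' @param helix_rise,helix_twist ideal alpha-helix rise (A/residue) and twist
#'   (deg/residue).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames = 1000L, dt = 1, seed = 1L,
                           drift_slope = 0, noise_sigma = 0.5, tm6_bend = 0,
                           rotamer = NULL, channel_state = "open",
                           lock_distance = 3.0, alpha5_distance0 = 12,
                           bundle_radius = 12, helix_rise = 1.5,
                           helix_twist = 100) {
  if (n_frames < 1L) smd_stop("n_frames must be >= 1", "switchmd_validation_error")
  if (noise_sigma < 0) smd_stop("noise_sigma must be >= 0", "switchmd_validation_error")
  if (!channel_state %in% c("open", "blocked", "alternating", "none"))
    smd_stop("channel_state must be open/blocked/alternating/none", "switchmd_validation_error")
  default_rot <- list(
    "6.48" = list(states = c(-60, 180), p_flip = 0),
    "6.44" = list(states = c(180, -60), p_flip = 0),
    "6.55" = list(states = c(180, 60),  p_flip = 0),
    "7.53" = list(states = c(-60, 180), p_flip = 0))
  if (!is.null(rotamer)) default_rot[names(rotamer)] <- rotamer
  for (r in default_rot)
    if (r$p_flip < 0 || r$p_flip > 1)
      smd_stop("p_flip must be in [0, 1]", "switchmd_validation_error")
  structure(list(n_frames = as.integer(n_frames), dt = dt, seed = as.integer(seed),
                 drift_slope = drift_slope, noise_sigma = noise_sigma,
                 tm6_bend = tm6_bend, rotamer = default_rot,
                 channel_state = channel_state, lock_distance = lock_distance,
                 alpha5_distance0 = alpha5_distance0,
                 bundle_radius = bundle_radius, helix_rise = helix_rise,
                 helix_twist = helix_twist),
            class = "synthetic_spec")
}

#' Named preset specifications
#'
#' Four end-to-end scenarios with known hallmark patterns:
#' `"active-coupled"` (approaching alpha5, bent TM6, open channel, broken
#' lock), `"inactive-decoupled"` (receding alpha5, straight TM6, blocked
#' channel, formed lock), `"blocked-barrier"` (waters above and below the
#' hydrophobic barrier only), `"alternating-channel"` (channel open on even
#' frames only).
#'
#' @param name preset name.
#' @param n_frames,seed passed through to [synthetic_spec()].
#' @return a [synthetic_spec()].
#' @export
synthetic_preset <- function(name, n_frames = 1000L, seed = 1L) {
  switch(name,
    "active-coupled" = synthetic_spec(n_frames = n_frames, seed = seed,
                                      drift_slope = -0.003, tm6_bend = 30,
                                      channel_state = "open", lock_distance = 12),
    "inactive-decoupled" = synthetic_spec(n_frames = n_frames, seed = seed,
                                          drift_slope = 0.003, tm6_bend = 0,
                                          channel_state = "blocked", lock_distance = 3),
    "blocked-barrier" = synthetic_spec(n_frames = n_frames, seed = seed,
                                       drift_slope = 0, tm6_bend = 0,
                                       channel_state = "blocked", lock_distance = 3),
    "alternating-channel" = synthetic_spec(n_frames = n_frames, seed = seed,
                                           drift_slope = 0, tm6_bend = 0,
                                           channel_state = "alternating", lock_distance = 3),
    smd_stop(sprintf("unknown preset '%s'", name), "switchmd_validation_error"))
}

# ideal helix residue index within a chain: resno = 100*h + p - 29 for BW
# position p in 30..70 (anchor x.50 at 100*h + 21)
SYN_POSITIONS <- 30:70
syn_resno <- function(h, p) 100L * h + p - 29L

# residue names planted along the bundle (motifs included so autodetection
# can be validated against ground truth)
syn_resnames <- function() {
  nm <- list()
  set <- function(h, p, name) nm[[as.character(syn_resno(h, p))]] <<- name
  set(2, 42, "LEU"); set(2, 43, "ILE"); set(2, 46, "LEU")
  set(3, 32, "ASP"); set(3, 43, "LEU"); set(3, 46, "ILE")
  set(3, 49, "ASP"); set(3, 50, "ARG"); set(3, 51, "TYR")      # DRY
  set(5, 43, "SER"); set(5, 46, "SER"); set(5, 50, "PRO")
  set(5, 54, "THR"); set(5, 58, "TYR")
  set(6, 30, "GLU"); set(6, 36, "MET"); set(6, 40, "VAL")
  set(6, 44, "PHE"); set(6, 47, "CYS"); set(6, 48, "TRP"); set(6, 50, "PRO") # CWxP
  set(6, 55, "HIS")
  set(7, 49, "ASN"); set(7, 50, "PRO"); set(7, 53, "TYR")      # NPxxY
  nm
}

# place atom D given A, B, C with bond C-D = r, angle B-C-D = theta and
# dihedral A-B-C-D = phi (degrees)
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

rot_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2)); th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# deterministic scaffold: coordinates, atom table, map and auxiliary indices
syn_scaffold <- function(spec) {
  if (spec$bundle_radius < 6)
    smd_stop("bundle radius too small: helices would overlap", "switchmd_generation_error")
  rise <- spec$helix_rise; twist <- spec$helix_twist
  n_res <- length(SYN_POSITIONS)
  resnames <- syn_resnames()
  atoms <- list(); coords <- list()
  add_atom <- function(elety, resid, resno, chain, elesy, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(elety = elety, resid = resid,
                                               resno = resno, chain = chain,
                                               elesy = elesy)
    coords[[length(coords) + 1L]] <<- xyz
  }

  ca_pos <- new.env()  # "resno" -> CA coordinates, receptor chain
  for (h in 1:7) {
    ang0 <- 2 * pi * (h - 1) / 7
    center <- c(spec$bundle_radius * cos(ang0), spec$bundle_radius * sin(ang0), 0)
    up <- (h %% 2L == 1L)
    pts <- t(vapply(seq_len(n_res) - 1L, function(i) {
      a <- twist * i * pi / 180
      z <- rise * (i - (n_res - 1) / 2)
      center + c(2.3 * cos(a), 2.3 * sin(a), if (up) z else -z)
    }, numeric(3)))
    if (h == 6L && spec$tm6_bend != 0) {
      # bend the extracellular-side segment (positions > 48) about the 6.48 CA
      i48 <- which(SYN_POSITIONS == 48L)
      pivot <- pts[i48, ]
      seg_axis <- helix_axis(pts)$axis
      radial <- center - c(0, 0, center[3])
      bend_ax <- c(seg_axis[2] * radial[3] - seg_axis[3] * radial[2],
                   seg_axis[3] * radial[1] - seg_axis[1] * radial[3],
                   seg_axis[1] * radial[2] - seg_axis[2] * radial[1])
      R <- rot_about_axis(bend_ax, spec$tm6_bend)
      above <- which(SYN_POSITIONS > 48L)
      pts[above, ] <- t(R %*% (t(pts[above, , drop = FALSE]) - pivot) + pivot)
    }
    for (i in seq_len(n_res)) {
      p <- SYN_POSITIONS[i]
      rn <- syn_resno(h, p)
      resid <- resnames[[as.character(rn)]] %||% "ALA"
      add_atom("CA", resid, rn, "R", "C", pts[i, ])
      assign(as.character(rn), pts[i, ], envir = ca_pos)
    }
  }
  ca <- function(h, p) get(as.character(syn_resno(h, p)), envir = ca_pos)

  # chi1-capable switch side chains: N, CB and the gamma atom at the planted
  # chi1, built from internal coordinates (gamma position precomputed for
  # both rotamer states so frames can toggle without rebuilding)
  switch_defs <- list("6.48" = c(6L, 48L), "6.44" = c(6L, 44L),
                      "6.55" = c(6L, 55L), "7.53" = c(7L, 53L))
  switch_aux <- list()
  for (lb in names(switch_defs)) {
    hp <- switch_defs[[lb]]
    rn <- syn_resno(hp[1], hp[2])
    CA <- ca(hp[1], hp[2])
    prev <- ca_prev <- get(as.character(rn - 1L), envir = ca_pos)
    u <- (prev - CA); u <- u / sqrt(sum(u^2))
    Npos <- CA + 1.46 * u
    radial <- CA - c(0, 0, CA[3])
    w <- c(u[2] * radial[3] - u[3] * radial[2],
           u[3] * radial[1] - u[1] * radial[3],
           u[1] * radial[2] - u[2] * radial[1])
    w <- w / sqrt(sum(w^2))
    CB <- CA + 1.53 * (cos(110.5 * pi / 180) * u + sin(110.5 * pi / 180) * w)
    states <- spec$rotamer[[lb]]$states
    gpos <- lapply(states, function(chi) nerf_place(Npos, CA, CB, 1.52, 114, chi))
    resid <- resnames[[as.character(rn)]]
    gname <- chi1_gamma_atom(resid)
    add_atom("N", resid, rn, "R", "N", Npos)
    add_atom("CB", resid, rn, "R", "C", CB)
    add_atom("CG0", resid, rn, "R", "C", gpos[[1]])  # renamed below
    switch_aux[[lb]] <- list(gamma_name = gname, states = states,
                             p_flip = spec$rotamer[[lb]]$p_flip,
                             gamma_pos = gpos)
  }

  # ionic lock: R3.50 guanidinium vs E6.30 carboxylate at the planted minimum
  cR <- ca(3, 50); cE <- ca(6, 30)
  u <- cE - cR; D <- sqrt(sum(u^2)); u <- u / D
  perp <- c(-u[2], u[1], 0); perp <- perp / sqrt(sum(perp^2))
  a <- (D - spec$lock_distance) / 2
  NH1 <- cR + a * u
  OE1 <- cE - a * u
  add_atom("CB", "ARG", syn_resno(3, 50), "R", "C", cR + 0.4 * a * u)
  add_atom("NE", "ARG", syn_resno(3, 50), "R", "N", NH1 - 1.3 * u)
  add_atom("NH1", "ARG", syn_resno(3, 50), "R", "N", NH1)
  add_atom("NH2", "ARG", syn_resno(3, 50), "R", "N", NH1 + 1.0 * perp - 0.3 * u)
  add_atom("CB", "GLU", syn_resno(6, 30), "R", "C", cE - 0.4 * a * u)
  add_atom("OE1", "GLU", syn_resno(6, 30), "R", "O", OE1)
  add_atom("OE2", "GLU", syn_resno(6, 30), "R", "O", OE1 - 1.0 * perp + 0.3 * u)

  # ICL3 arginine stub below TM5 (no BW label; addressed by residue id)
  icl3_pos <- ca(5, 30) + c(0, 0, -6)
  add_atom("CA", "ARG", 560L, "R", "C", icl3_pos)
  add_atom("CB", "ARG", 560L, "R", "C", icl3_pos + c(0.9, 0, -1.2))
  add_atom("NE", "ARG", 560L, "R", "N", icl3_pos + c(1.8, 0, -2.4))
  add_atom("NH1", "ARG", 560L, "R", "N", icl3_pos + c(2.6, 0.8, -3.0))
  add_atom("NH2", "ARG", 560L, "R", "N", icl3_pos + c(2.6, -0.8, -3.0))

  # alpha5 mimic: 8-residue helix, C-terminal five D351..F355, centred
  # directly "below" the receptor probe centroid so drift is collinear
  probe_ca <- rbind(ca(7, 53), ca(2, 46), ca(3, 46), ca(5, 54), ca(6, 40))
  probe_com <- colMeans(probe_ca)
  ga_names <- c("ALA", "ALA", "ALA", "ASP", "CYS", "GLY", "LEU", "PHE")
  ga_resno <- 348:355
  ga_local <- t(vapply(0:7, function(i) {
    a <- spec$helix_twist * i * pi / 180
    c(2.3 * cos(a), 2.3 * sin(a), spec$helix_rise * (i - 3.5))
  }, numeric(3)))
  ga_ca5 <- colMeans(ga_local[4:8, , drop = FALSE])
  offset <- probe_com + c(0, 0, -spec$alpha5_distance0) - ga_ca5
  ga_pts <- sweep(ga_local, 2L, offset, `+`)
  for (i in seq_len(8)) {
    add_atom("CA", ga_names[i], ga_resno[i], "G", "C", ga_pts[i, ])
    if (ga_names[i] != "GLY")
      add_atom("CB", ga_names[i], ga_resno[i], "G", "C", ga_pts[i, ] + c(1.0, 1.0, 0.4))
    if (ga_names[i] == "ASP") {
      add_atom("OD1", "ASP", ga_resno[i], "G", "O", ga_pts[i, ] + c(1.8, 1.8, 0.8))
      add_atom("OD2", "ASP", ga_resno[i], "G", "O", ga_pts[i, ] + c(2.2, 1.2, 1.2))
    }
  }

  # water column along the 3.32 -> 7.53 axis: 5 oxygens per 1.5 A level
  top <- ca(3, 32); bottom <- ca(7, 53)
  axis <- bottom - top; L <- sqrt(sum(axis^2)); axis <- axis / L
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(axis[2] * ref[3] - axis[3] * ref[2],
         axis[3] * ref[1] - axis[1] * ref[3],
         axis[1] * ref[2] - axis[2] * ref[1]); v <- v / sqrt(sum(v^2))
  w <- c(axis[2] * v[3] - axis[3] * v[2],
         axis[3] * v[1] - axis[1] * v[3],
         axis[1] * v[2] - axis[2] * v[1])
  levels <- seq(0.5, L - 0.5, by = 1.5)
  offs <- rbind(c(0, 0), 1.2 * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  wopen <- do.call(rbind, lapply(levels, function(s) {
    t(apply(offs, 1L, function(o) top + s * axis + o[1] * v + o[2] * w))
  }))
  in_gap <- rep(levels > L / 3 & levels < 2 * L / 3, each = nrow(offs))
  wblocked <- wopen
  wblocked[in_gap, ] <- wblocked[in_gap, , drop = FALSE] +
    matrix(30 * v, sum(in_gap), 3L, byrow = TRUE)
  first_water <- length(atoms) + 1L
  init_w <- switch(spec$channel_state, blocked = wblocked, wopen)
  if (spec$channel_state != "none")
    for (i in seq_len(nrow(wopen)))
      add_atom("O", "HOH", 9000L + i, "W", "O", init_w[i, ])

  atom_df <- do.call(rbind, atoms)
  atom_df$water <- atom_df$resid %in% c("HOH", "TIP3", "SOL", "WAT")
  coord_mat <- do.call(rbind, coords)

  # gamma atoms were tagged CG0; give them their residue-specific names
  g0 <- which(atom_df$elety == "CG0")
  for (i in g0) {
    atom_df$elety[i] <- chi1_gamma_atom(atom_df$resid[i])
    atom_df$elesy[i] <- substr(atom_df$elety[i], 1L, 1L)
  }

  anchors <- setNames(vapply(1:7, function(h) syn_resno(h, 50L), integer(1)),
                      as.character(1:7))
  spans <- cbind(first = vapply(1:7, function(h) syn_resno(h, 30L), integer(1)),
                 last = vapply(1:7, function(h) syn_resno(h, 70L), integer(1)))
  map <- bw_map(anchors, chain = "R", spans = spans)

  water_rows <- if (spec$channel_state == "none") integer(0) else
    which(atom_df$water)
  list(coords = coord_mat, atoms = atom_df, map = map,
       switch_aux = switch_aux,
       ga_rows = which(atom_df$chain == "G"),
       water_rows = water_rows, water_open = wopen, water_blocked = wblocked,
       drift_unit = c(0, 0, -1), d0 = spec$alpha5_distance0,
       gamma_rows = setNames(g0, names(switch_aux)))
}

#' Generate a single-frame synthetic receptor bundle
#'
#' Builds the 7-helix C-alpha bundle (ideal helices on a circle, TM6 bent by
#' the requested angle at 6.48), microswitch side chains at the planted chi1,
#' the R3.50/E6.30 salt-bridge pair at the planted distance, an 8-residue
#' alpha5 mimic and the water column. Deterministic: no noise is applied.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `traj` (1-frame [md_trajectory()]), `map` (a [bw_map()]),
#'   `truth` (planted values: chi1 per switch, `tm6_bend`, `lock_distance`,
#'   `alpha5_distance`, anchor table).
#' @export
generate_bundle <- function(spec) {
  sc <- syn_scaffold(spec)
  traj <- md_trajectory(matrix(as.vector(t(sc$coords)), nrow = 1L), sc$atoms,
                        times = 0, source = "synthetic_bundle")
  truth <- list(
    chi1 = vapply(sc$switch_aux, function(s) s$states[1], numeric(1)),
    tm6_bend = spec$tm6_bend, lock_distance = spec$lock_distance,
    alpha5_distance = spec$alpha5_distance0,
    anchors = sc$map$anchors,
    channel_open = spec$channel_state %in% c("open", "alternating"))
  list(traj = traj, map = sc$map, truth = truth)
}

#' Generate a synthetic trajectory with per-frame ground truth
#'
#' Frame `t` displaces the alpha5 mimic along the receptor-to-alpha5 axis by
#' `drift_slope * t * dt`, evolves each switch chi1 by a two-state Markov
#' rule, toggles the water column for the alternating channel state, and
#' finally adds i.i.d. Gaussian noise to every coordinate. One seeded random
#' stream is used: first the rotamer chains (switch labels in order), then
#' the noise, so results are fully reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `traj` (an [md_trajectory()]), `map`, `spec` (echo), `truth`
#'   (data frame with per-frame `time`, `alpha5_distance` before noise,
#'   `channel_open`, and one `state_<label>` column per switch).
#' @export
generate_trajectory <- function(spec) {
  sc <- syn_scaffold(spec)
  nf <- spec$n_frames
  n_at <- nrow(sc$atoms)
  base <- as.vector(t(sc$coords))
  xyz <- matrix(base, nrow = nf, ncol = 3L * n_at, byrow = TRUE)
  times <- (seq_len(nf) - 1) * spec$dt

  set.seed(spec$seed)

  # rotamer Markov chains (draws consumed even when p_flip = 0, so truth is
  # invariant to which switches are perturbed)
  states <- matrix(1L, nf, length(sc$switch_aux),
                   dimnames = list(NULL, names(sc$switch_aux)))
  for (k in seq_along(sc$switch_aux)) {
    p <- sc$switch_aux[[k]]$p_flip
    if (nf > 1L) {
      flips <- stats::runif(nf - 1L) < p
      states[, k] <- 1L + (cumsum(c(FALSE, flips)) %% 2L)
    }
  }
  for (k in seq_along(sc$switch_aux)) {
    row <- sc$gamma_rows[[k]]
    cols <- 3L * row - (2:0)
    gp <- sc$switch_aux[[k]]$gamma_pos
    xyz[, cols] <- t(vapply(states[, k], function(s) gp[[s]], numeric(3)))
  }

  # alpha5 drift, collinear with the probe axis so the planted distance is
  # exactly d0 + slope * time before noise
  shift <- spec$drift_slope * times
  for (row in sc$ga_rows) {
    cols <- 3L * row - (2:0)
    xyz[, cols] <- xyz[, cols] + outer(shift, sc$drift_unit)
  }
  alpha5_distance <- sc$d0 + spec$drift_slope * times

  # channel state per frame
  channel_open <- switch(spec$channel_state,
                         open = rep(TRUE, nf),
                         blocked = rep(FALSE, nf),
                         alternating = (seq_len(nf) %% 2L) == 1L,
                         none = rep(FALSE, nf))
  if (spec$channel_state == "alternating" && length(sc$water_rows)) {
    wcols <- xyz_cols(sc$water_rows)
    open_flat <- as.vector(t(sc$water_open))
    blocked_flat <- as.vector(t(sc$water_blocked))
    xyz[channel_open, wcols] <- matrix(open_flat, sum(channel_open),
                                       length(wcols), byrow = TRUE)
    xyz[!channel_open, wcols] <- matrix(blocked_flat, sum(!channel_open),
                                        length(wcols), byrow = TRUE)
  }

  if (spec$noise_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sigma), nrow = nf)

  truth <- data.frame(time = times, alpha5_distance = alpha5_distance,
                      channel_open = channel_open)
  for (k in seq_along(sc$switch_aux)) {
    st <- sc$switch_aux[[k]]
    truth[[paste0("state_", names(sc$switch_aux)[k])]] <-
      rotamer_classify(st$states[states[, k]])
  }
  traj <- md_trajectory(xyz, sc$atoms, times = times, source = "synthetic")
  list(traj = traj, map = sc$map, spec = spec, truth = truth)
}
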