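#' Simulate a synthetic treadmill-walking trial
#'
#' Generates a seeded, fully reproducible gait trial with the structure the
#' downstream pipeline assumes: a stance-confined double-bump vertical
#' ground reaction force, braking/propulsion and lateral shear, force-plate
#' moments obtained by inverting the COP equations from a prescribed COP
#' trajectory (heel-to-toe progression sagittally, one lateral excursion per
#' stride), an 8-segment body model whose mass-weighted centroid sways about
#' a mean walking posture, pelvis/chest trunk markers with a smooth
#' inclination oscillation, and heel-strike events at every stride boundary.
#' Force-plate channels are emitted at `grf_rate` and kinematics at
#' `kin_rate`, mirroring the two acquisition rates of a gait laboratory.
#'
#' The perturbed condition applies stride-varying random amplitude
#' modulation — a per-stride Gaussian draw times a half-sine window confined
#' to the stance phase — to the source channels driving
#' `config$perturb_targets`. With `perturb_gain = 0` the perturbed generator
#' is bit-identical to the balanced one under the same seed: the random
#' draws are always consumed, only their multiplier changes.
#'
#' @param config A [gait_sim_config()].
#' @return An object of class `wbi_trial`: list with elements `grf` and
#'   `kin` (see [channel_table()]), `seg_masses` (named, sums to subject
#'   mass), `events` (heel-strike times, s), `height`, `mass`,
#'   `belt_offset_h`, `condition` and the generating `config`.
#' @export
#' @examples
#' tr <- simulate_trial(gait_sim_config(n_strides = 4, seed = 7))
#' tr
simulate_trial <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  T_ <- cfg$stride_period
  n <- cfg$n_strides
  sf <- cfg$stance_fraction
  bw <- cfg$subject_mass * 9.81           # body weight, N
  h0 <- cfg$subject_height
  gain <- if (cfg$perturbed) cfg$perturb_gain else 0

  # --- per-stride variability and perturbation draws (fixed order) --------
  jit <- matrix(stats::rnorm(n * 8L, 1, 0.04), n, 8L,
                dimnames = list(NULL, c("fz", "fx", "fy", "copx", "copy",
                                        "comy", "comz", "sway")))
  pchan <- c("copx", "copy", "comx", "comy", "comz",
             "shear_x", "shear_y", "trunk_sway")
  pert <- matrix(stats::rnorm(n * length(pchan)), n, length(pchan),
                 dimnames = list(NULL, pchan))
  amp <- perturb_channel_amplitudes(cfg$perturb_targets, bw)

  # effective per-stride, per-channel modulation (0 when gain is 0)
  pmod <- sweep(pert, 2L, gain * amp[pchan], `*`)

  halfsine <- function(u) ifelse(u >= 0 & u <= 1, sin(pi * u), 0)

  stride_phase <- function(t) {
    si <- pmin(floor(t / T_) + 1L, n)
    phi <- t / T_ - (si - 1L)
    list(si = si, phi = phi, u = phi / sf, stance = phi < sf)
  }

  # --- force-plate channels at grf_rate -----------------------------------
  ng <- round(n * T_ * cfg$grf_rate) + 1L
  tg <- (seq_len(ng) - 1L) / cfg$grf_rate
  sp <- stride_phase(tg)
  st <- sp$stance
  u <- ifelse(st, sp$u, 0)
  si <- sp$si
  hs <- ifelse(st, halfsine(sp$u), 0)

  # double-bump vertical GRF: sin(pi*u)*(1 + 0.5*cos(2*pi*u)) peaks ~0.707
  # at u ~ 0.25/0.75 with a mid-stance valley at 0.5 of it
  fz <- ifelse(st, 1.556 * bw * jit[si, "fz"] *
                 sin(pi * u) * (1 + 0.5 * cos(2 * pi * u)), 0)
  fx <- ifelse(st, -0.18 * bw * jit[si, "fx"] * sin(2 * pi * u), 0) +
    pmod[si, "shear_x"] * hs
  fy <- ifelse(st, 0.05 * bw * jit[si, "fy"] * sin(pi * u), 0) +
    pmod[si, "shear_y"] * hs

  # prescribed COP trajectory (stance only), then invert the COP equations
  copx <- ifelse(st, -0.12 * jit[si, "copx"] + 0.27 * u, 0) +
    pmod[si, "copx"] * hs
  copy <- ifelse(st, 0.03 * jit[si, "copy"] * sin(pi * u), 0) +
    pmod[si, "copy"] * hs
  my <- -cfg$belt_offset_h * fx - copx * fz
  mx <- cfg$belt_offset_h * fy - copy * fz

  nz <- cfg$noise_sd
  grf <- list(
    Fx = fx + stats::rnorm(ng, 0, 2 * nz),
    Fy = fy + stats::rnorm(ng, 0, 2 * nz),
    Fz = fz + stats::rnorm(ng, 0, 2 * nz),
    Mx = mx + stats::rnorm(ng, 0, 0.5 * nz),
    My = my + stats::rnorm(ng, 0, 0.5 * nz),
    Mz = stats::rnorm(ng, 0, 0.5 * nz)
  )

  # --- kinematics at kin_rate ---------------------------------------------
  nk <- round(n * T_ * cfg$kin_rate) + 1L
  tk <- (seq_len(nk) - 1L) / cfg$kin_rate
  kp <- stride_phase(tk)
  ksi <- kp$si
  kphi <- kp$phi
  khs <- ifelse(kp$stance, halfsine(kp$u), 0)

  seg <- segment_model(cfg$subject_mass, h0)

  # whole-body sway applied to every segment (shifts the COM directly);
  # all components vanish at stride boundaries so per-stride amplitude
  # jitter introduces no discontinuities
  sway_x <- 0.010 * sin(4 * pi * kphi) + pmod[ksi, "comx"] * khs
  sway_y <- 0.020 * jit[ksi, "comy"] * sin(2 * pi * kphi) +
    pmod[ksi, "comy"] * khs
  sway_z <- 0.012 * jit[ksi, "comz"] * (cos(4 * pi * kphi) - 1) / 2 +
    pmod[ksi, "comz"] * khs

  # alternating leg swing (left/right antiphase, equal masses: cancels in
  # the COM so the sway terms above fully control COM dynamics)
  leg_amp <- c(thigh = 0.05, shank = 0.11, foot = 0.16) * h0 / 1.75
  kin <- list()
  for (s in rownames(seg)) {
    base <- seg[s, c("x0", "y0", "z0")]
    x <- rep(base[["x0"]], nk)
    z <- rep(base[["z0"]], nk)
    side <- if (grepl("_l$", s)) 0 else pi
    part <- sub("_[lr]$", "", s)
    if (part %in% names(leg_amp)) {
      x <- x + leg_amp[[part]] * sin(2 * pi * kphi + side)
      if (part == "foot")
        z <- z + 0.02 * pmax(0, -sin(2 * pi * kphi + side))
    }
    kin[[paste0(s, ".x")]] <- x + sway_x
    kin[[paste0(s, ".y")]] <- base[["y0"]] + sway_y
    kin[[paste0(s, ".z")]] <- z + sway_z
  }

  # trunk inclination: constant forward lean plus coronal sway, so the
  # (unsigned) angle to vertical never touches zero and stays smooth
  lean <- 0.08 + 0.02 * sin(2 * pi * kphi + pi / 3)
  sway <- (0.030 * jit[ksi, "sway"]) * sin(2 * pi * kphi) +
    pmod[ksi, "trunk_sway"] * khs
  l_trunk <- 0.30 * h0
  dz <- sqrt(pmax(1 - sin(lean)^2 - sin(sway)^2, 0))
  kin[["chest.x"]] <- kin[["pelvis.x"]] + l_trunk * sin(lean)
  kin[["chest.y"]] <- kin[["pelvis.y"]] + l_trunk * sin(sway)
  kin[["chest.z"]] <- kin[["pelvis.z"]] + l_trunk * dz

  kin <- lapply(kin, function(v) v + stats::rnorm(nk, 0, 3e-4 * nz))

  trial <- structure(list(
    grf = channel_table(grf, rate = cfg$grf_rate, start_time = 0),
    kin = channel_table(kin, rate = cfg$kin_rate, start_time = 0),
    seg_masses = stats::setNames(seg[, "mass"], rownames(seg)),
    events = (0:n) * T_,
    height = h0,
    mass = cfg$subject_mass,
    belt_offset_h = cfg$belt_offset_h,
    condition = if (cfg$perturbed) "perturbed" else "balanced",
    config = cfg
  ), class = "wbi_trial")
  validate_trial(trial)
  trial
}

# 8-segment mass model; fractions sum to 1 exactly. Mean centroid heights
# are fractions of stature about a mid-pelvis origin (x = 0 progression,
# y = 0 midline, z above belt).
segment_model <- function(mass, height) {
  frac <- c(trunk_head = 0.478, pelvis = 0.142,
            thigh_l = 0.100, thigh_r = 0.100,
            shank_l = 0.0465, shank_r = 0.0465,
            foot_l = 0.0435, foot_r = 0.0435)
  zf <- c(trunk_head = 0.70, pelvis = 0.55,
          thigh_l = 0.41, thigh_r = 0.41,
          shank_l = 0.21, shank_r = 0.21,
          foot_l = 0.05, foot_r = 0.05)
  yf <- c(trunk_head = 0, pelvis = 0,
          thigh_l = 0.06, thigh_r = -0.06,
          shank_l = 0.06, shank_r = -0.06,
          foot_l = 0.07, foot_r = -0.07)
  cbind(mass = frac * mass, x0 = 0, y0 = yf * height, z0 = zf * height)
}

# Perturbation amplitude per source channel, summed over the targeted
# metrics that drive it. Units: m for trajectories, N for shear forces,
# rad for trunk sway.
perturb_channel_amplitudes <- function(targets, bw) {
  amp <- c(copx = 0, copy = 0, comx = 0, comy = 0, comz = 0,
           shear_x = 0, shear_y = 0, trunk_sway = 0)
  add <- function(ch, a) amp[ch] <<- amp[ch] + a
  for (tg in targets) {
    switch(tg,
      COPx = add("copx", 0.03), VCOPx = add("copx", 0.03),
      COPy = add("copy", 0.02), VCOPy = add("copy", 0.02),
      MOS = add("copy", 0.015),
      COMx = add("comx", 0.012), ACOMx = add("comx", 0.012),
      COMy = add("comy", 0.012), ACOMy = add("comy", 0.012),
      COMz = add("comz", 0.012), ACOMz = add("comz", 0.012),
      ACOM = {
        add("comx", 0.006); add("comy", 0.006); add("comz", 0.006)
      },
      COP_CMP = {
        add("shear_x", 0.04 * bw); add("shear_y", 0.02 * bw)
      },
      AANG = add("trunk_sway", 0.05),
      stop("unknown perturbation target: ", tg)
    )
  }
  amp
}

#' Simulate a balanced/perturbed condition pair
#'
#' Draws two deterministic sub-seeds from `config$seed` and returns one
#' trial with the perturbation off and one with it on (at
#' `config$perturb_gain`), emulating the two gait conditions the index is
#' fitted between. With `perturb_gain = 0` the two trials are independent
#' draws from the same distribution, which is the null configuration used
#' to calibrate the selection stage.
#'
#' @inheritParams simulate_trial
#' @return List with elements `balanced` and `perturbed`, both `wbi_trial`.
#' @export
simulate_condition_pair <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  bal_cfg <- config
  bal_cfg$perturbed <- FALSE
  bal_cfg$seed <- sub[1L]
  per_cfg <- config
  per_cfg$perturbed <- TRUE
  per_cfg$seed <- sub[2L]
  list(balanced = simulate_trial(bal_cfg),
       perturbed = simulate_trial(per_cfg))
}

validate_trial <- function(trial) {
  if (any(trial$seg_masses <= 0))
    stop("trial validation: segment masses must be positive", call. = FALSE)
  rel <- abs(sum(trial$seg_masses) - trial$mass) / trial$mass
  if (rel > 1e-6)
    stop("trial validation: segment masses sum to ",
         signif(sum(trial$seg_masses), 8), " but subject mass is ",
         trial$mass, " (relative error ", signif(rel, 3), " > 1e-6)",
         call. = FALSE)
  if (is.unsorted(trial$events, strictly = TRUE))
    stop("trial validation: heel-strike events must be strictly increasing",
         call. = FALSE)
  invisible(trial)
}

#' @export
print.wbi_trial <- function(x, ...) {
  cat("<wbi_trial> ", x$condition, " condition\n", sep = "")
  cat(sprintf("  GRF: %d samples @ %g Hz; kinematics: %d samples @ %g Hz\n",
              length(x$grf$series[[1L]]), x$grf$rate,
              length(x$kin$series[[1L]]), x$kin$rate))
  cat(sprintf("  %d heel strikes (%d strides); subject %.2f m / %.1f kg\n",
              length(x$events), length(x$events) - 1L, x$height, x$mass))
  invisible(x)
}
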