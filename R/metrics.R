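#' Center of pressure from force-plate forces and moments
#'
#' `COPx = (-h*Fx - My)/Fz`, `COPy = (h*Fy - Mx)/Fz`, where `h` is the
#' height difference between the belt surface and the force-plate origin.
#' The zero-moment point is treated as coincident with the COP, so no
#' separate channel is produced. Samples where `|Fz|` falls below the
#' support threshold are marked invalid (`NA`) rather than divided through:
#' the defining equations are singular in swing.
#'
#' @param fx,fy,fz Ground-reaction force components, N.
#' @param mx,my Ground-reaction moments about x and y, N·m.
#' @param h Belt-to-origin height offset, m.
#' @param fz_threshold Minimum vertical force (N) for a sample to count as
#'   supported.
#' @return List with `COPx`, `COPy` (m, `NA` outside support) and the
#'   logical `valid` mask.
#' @export
#' @examples
#' compute_cop(0, 0, 700, 0, -70, h = 0)$COPx  # 0.1 m
compute_cop <- function(fx, fy, fz, mx, my, h = 0, fz_threshold = 30) {
  valid <- is.finite(fz) & abs(fz) > fz_threshold
  copx <- copy <- rep(NA_real_, length(fz))
  copx[valid] <- (-h * fx[valid] - my[valid]) / fz[valid]
  copy[valid] <- (h * fy[valid] - mx[valid]) / fz[valid]
  list(COPx = copx, COPy = copy, valid = valid)
}

#' Finite-difference derivative of a uniformly sampled series
#'
#' Central differences on interior points, one-sided at the ends; `NA`
#' samples propagate to every sample whose stencil touches them. Applied
#' after the pipeline's low-pass smoothing stage.
#'
#' @param x Numeric vector (length >= 3).
#' @param rate Sampling rate, Hz.
#' @param order 1 (velocity) or 2 (acceleration).
#' @return Numeric vector, same length as `x`.
#' @export
differentiate <- function(x, rate, order = 1L) {
  n <- length(x)
  if (n < 3L)
    stop("differentiate: series must have at least 3 samples", call. = FALSE)
  if (!order %in% c(1L, 2L))
    stop("differentiate: `order` must be 1 or 2", call. = FALSE)
  if (order == 1L) {
    c((x[2L] - x[1L]) * rate,
      (x[3:n] - x[1:(n - 2L)]) * rate / 2,
      (x[n] - x[n - 1L]) * rate)
  } else {
    d2 <- (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) * rate^2
    c(d2[1L], d2, d2[length(d2)])
  }
}

#' Whole-body center of mass from segment centroids
#'
#' Mass-weighted mean of the per-segment centroid trajectories:
#' `COM = sum(m_i * com_i) / M`.
#'
#' @param centroids Named list of n-by-3 matrices (columns x, y, z; m), one
#'   per segment.
#' @param masses Named numeric vector of segment masses (kg), names matching
#'   `centroids`.
#' @param total_mass Optional declared body mass; if given, the segment
#'   masses must sum to it within 1e-6 relative tolerance.
#' @return List with `COMx`, `COMy`, `COMz` (m).
#' @export
compute_com <- function(centroids, masses, total_mass = NULL) {
  if (!length(centroids))
    stop("compute_com: at least one segment required", call. = FALSE)
  if (any(masses <= 0))
    stop("compute_com: segment masses must be positive", call. = FALSE)
  if (!setequal(names(centroids), names(masses)))
    stop("compute_com: centroid and mass segment names differ",
         call. = FALSE)
  M <- sum(masses)
  if (!is.null(total_mass) && abs(M - total_mass) / total_mass > 1e-6)
    stop("validation error: segment masses sum to ", signif(M, 8),
         " kg, declared body mass is ", total_mass, " kg", call. = FALSE)
  acc <- 0
  for (s in names(centroids))
    acc <- acc + masses[[s]] * centroids[[s]]
  com <- acc / M
  list(COMx = com[, 1L], COMy = com[, 2L], COMz = com[, 3L])
}

#' COM acceleration channels
#'
#' Second finite differences of the COM position per axis and their
#' Euclidean resultant `ACOM = sqrt(ACOMx^2 + ACOMy^2 + ACOMz^2)`.
#'
#' @param com List with `COMx`, `COMy`, `COMz` as from [compute_com()].
#' @param rate Sampling rate, Hz.
#' @return List with `ACOMx`, `ACOMy`, `ACOMz`, `ACOM` (m/s^2).
#' @export
compute_acom <- function(com, rate) {
  ax <- differentiate(com$COMx, rate, 2L)
  ay <- differentiate(com$COMy, rate, 2L)
  az <- differentiate(com$COMz, rate, 2L)
  list(ACOMx = ax, ACOMy = ay, ACOMz = az,
       ACOM = sqrt(ax^2 + ay^2 + az^2))
}

#' Centroidal moment pivot and its distance to the COP
#'
#' `CMPx = COMx - (Fx/Fz)*COMz`, `CMPy = COMy - (Fy/Fz)*COMz`: the ground
#' point through which the GRF line of action would pass the COM. Samples
#' without support are invalid (`NA`). `compute_cop_cmp()` is the planar
#' Euclidean COP-to-CMP distance, a rotational-demand metric.
#'
#' @param com List with `COMx`, `COMy`, `COMz`.
#' @param fx,fy,fz GRF components, N.
#' @param fz_threshold Support threshold, N.
#' @return `compute_cmp()`: list with `CMPx`, `CMPy`, `valid`.
#' @export
compute_cmp <- function(com, fx, fy, fz, fz_threshold = 30) {
  valid <- is.finite(fz) & abs(fz) > fz_threshold
  cmpx <- cmpy <- rep(NA_real_, length(fz))
  cmpx[valid] <- com$COMx[valid] - (fx[valid] / fz[valid]) * com$COMz[valid]
  cmpy[valid] <- com$COMy[valid] - (fy[valid] / fz[valid]) * com$COMz[valid]
  list(CMPx = cmpx, CMPy = cmpy, valid = valid)
}

#' @rdname compute_cmp
#' @param copx,copy COP coordinates, m.
#' @param cmpx,cmpy CMP coordinates, m.
#' @return `compute_cop_cmp()`: non-negative distances (m), `NA` where
#'   either point is invalid.
#' @export
compute_cop_cmp <- function(copx, copy, cmpx, cmpy) {
  sqrt((copx - cmpx)^2 + (copy - cmpy)^2)
}

#' Margin of stability on one axis
#'
#' Velocity-extrapolated COP minus velocity-extrapolated COM:
#' `MOS = (COP + VCOP/w0) - (COM + VCOM/w0)` with the inverted-pendulum
#' frequency `w0 = sqrt(g/l)`, `l` the COM height above the belt.
#'
#' @param cop,vcop COP position (m) and velocity (m/s) on the chosen axis.
#' @param com,vcom COM position and velocity on the same axis.
#' @param l COM height, m (> 0); the pipeline uses the trial-mean COM
#'   height.
#' @param g Gravitational acceleration, m/s^2.
#' @return Numeric vector (m).
#' @export
compute_mos <- function(cop, vcop, com, vcom, l, g = 9.81) {
  if (!is.finite(l) || l <= 0)
    stop("compute_mos: COM height `l` must be positive", call. = FALSE)
  if (!is.finite(g) || g <= 0)
    stop("compute_mos: `g` must be positive", call. = FALSE)
  w0 <- sqrt(g / l)
  (cop + vcop / w0) - (com + vcom / w0)
}

#' Trunk angular acceleration
#'
#' The trunk inclination is the (unsigned) angle between the pelvis-to-chest
#' vector and the vertical axis; its second finite difference is the
#' angular-acceleration channel.
#'
#' @param pelvis,chest n-by-3 trajectories (m).
#' @param rate Sampling rate, Hz.
#' @return List with `angle` (rad) and `AANG` (rad/s^2).
#' @export
compute_aang <- function(pelvis, chest, rate) {
  d <- chest - pelvis
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-9))
    stop("compute_aang: pelvis and chest points coincide", call. = FALSE)
  ang <- acos(pmin(pmax(d[, 3L] / nrm, -1), 1))
  list(angle = ang, AANG = differentiate(ang, rate, 2L))
}

#' Detect heel strikes from the vertical GRF
#'
#' Upward crossings of a force threshold, separated by at least the
#' refractory interval. The 30 N default is the common force-plate
#' convention; the refractory default of a quarter of a nominal stride
#' suppresses chatter around the crossing.
#'
#' @param fz Vertical GRF on a uniform grid, N.
#' @param rate Sampling rate, Hz.
#' @param threshold Crossing threshold, N.
#' @param refractory Minimum spacing between events, s.
#' @param start_time Time of the first sample, s.
#' @return Strictly increasing event times (s); empty if none found.
#' @export
detect_heel_strikes <- function(fz, rate, threshold = 30,
                                refractory = 0.275, start_time = 0) {
  n <- length(fz)
  if (n < 2L) return(numeric(0))
  up <- which(fz[-1L] > threshold & fz[-n] <= threshold) + 1L
  if (!length(up)) return(numeric(0))
  keep <- up[1L]
  for (i in up[-1L])
    if ((i - keep[length(keep)]) / rate >= refractory) keep <- c(keep, i)
  start_time + (keep - 1L) / rate
}

#' Segment a time grid into strides
#'
#' One slice per consecutive heel-strike pair, covering `[e_k, e_{k+1})` on
#' the grid; slices are contiguous, non-overlapping and ordered.
#'
#' @param events Strictly increasing heel-strike times, s.
#' @param times Sample times of the analysis grid, s.
#' @return Object of class `stride_slices`: list of integer index vectors.
#' @export
segment_strides <- function(events, times) {
  if (is.unsorted(events, strictly = TRUE))
    stop("segment_strides: events must be strictly increasing", call. = FALSE)
  inside <- events >= times[1L] - 1e-9 &
    events <= times[length(times)] + 1e-9
  ev <- events[inside]
  if (length(ev) < 2L)
    stop("insufficient gait cycles: need at least 2 heel strikes within ",
         "the grid span", call. = FALSE)
  slices <- vector("list", length(ev) - 1L)
  for (k in seq_len(length(ev) - 1L)) {
    idx <- which(times >= ev[k] - 1e-9 & times < ev[k + 1L] - 1e-9)
    if (length(idx) < 2L)
      stop("segment_strides: stride ", k, " spans fewer than 2 samples",
           call. = FALSE)
    slices[[k]] <- idx
  }
  structure(slices, class = "stride_slices", events = ev)
}

#' Compute the 14 balance-metric channels of a trial
#'
#' Runs the full signal path: zero-phase low-pass filtering of the
#' force-plate (default 15 Hz) and kinematic (default 6 Hz) channels,
#' decimation of the filtered GRF onto the kinematics grid, then the COP,
#' COP velocity, COM position/velocity/acceleration, CMP offset, margin of
#' stability (coronal axis by default) and trunk angular-acceleration
#' channels. Velocity/acceleration channels are finite differences of the
#' smoothed series. COP-dependent channels are `NA` outside support.
#'
#' @param trial A `wbi_trial`.
#' @param grf_cutoff,kin_cutoff Low-pass cut-offs, Hz.
#' @param fz_threshold Support threshold, N.
#' @param mos_axis `"y"` (coronal, default) or `"x"` (sagittal).
#' @param g Gravitational acceleration, m/s^2.
#' @return Object of class `wbi_metrics`: list with `channels` (the 14
#'   named series), `aux` (COM velocities, pendulum frequency `w0`, COM
#'   height `l`), `time`, `rate`, `valid` and `events`.
#' @export
compute_metrics <- function(trial, grf_cutoff = 15, kin_cutoff = 6,
                            fz_threshold = 30, mos_axis = c("y", "x"),
                            g = 9.81) {
  mos_axis <- match.arg(mos_axis)
  rate <- trial$kin$rate
  grf <- resample_to_grid(filter_table(trial$grf, grf_cutoff), rate)
  kin <- filter_table(trial$kin, kin_cutoff)

  n <- min(length(grf$series$Fz), length(kin$series[[1L]]))
  gs <- lapply(grf$series, `[`, seq_len(n))
  ks <- lapply(kin$series, `[`, seq_len(n))
  time <- grf$start_time + (seq_len(n) - 1L) / rate

  cop <- compute_cop(gs$Fx, gs$Fy, gs$Fz, gs$Mx, gs$My,
                     h = trial$belt_offset_h, fz_threshold = fz_threshold)
  vcopx <- differentiate(cop$COPx, rate, 1L)
  vcopy <- differentiate(cop$COPy, rate, 1L)

  segs <- names(trial$seg_masses)
  centroids <- lapply(segs, function(s)
    cbind(ks[[paste0(s, ".x")]], ks[[paste0(s, ".y")]],
          ks[[paste0(s, ".z")]]))
  names(centroids) <- segs
  com <- compute_com(centroids, trial$seg_masses, total_mass = trial$mass)
  vcom <- list(VCOMx = differentiate(com$COMx, rate, 1L),
               VCOMy = differentiate(com$COMy, rate, 1L),
               VCOMz = differentiate(com$COMz, rate, 1L))
  acom <- compute_acom(com, rate)

  cmp <- compute_cmp(com, gs$Fx, gs$Fy, gs$Fz, fz_threshold = fz_threshold)
  cop_cmp <- compute_cop_cmp(cop$COPx, cop$COPy, cmp$CMPx, cmp$CMPy)

  l <- mean(com$COMz, na.rm = TRUE)
  mos <- if (mos_axis == "y")
    compute_mos(cop$COPy, vcopy, com$COMy, vcom$VCOMy, l, g)
  else
    compute_mos(cop$COPx, vcopx, com$COMx, vcom$VCOMx, l, g)

  pelvis <- centroids$pelvis
  if (is.null(pelvis))
    stop("compute_metrics: trial has no `pelvis` segment for the trunk ",
         "angle", call. = FALSE)
  chest <- cbind(ks[["chest.x"]], ks[["chest.y"]], ks[["chest.z"]])
  if (!ncol(chest) || is.null(ks[["chest.x"]]))
    stop("compute_metrics: trial has no chest marker channels", call. = FALSE)
  aang <- compute_aang(pelvis, chest, rate)

  events <- trial$events
  if (is.null(events) || length(events) < 2L)
    events <- detect_heel_strikes(gs$Fz, rate, threshold = fz_threshold,
                                  start_time = time[1L])

  structure(list(
    channels = list(
      COPx = cop$COPx, VCOPx = vcopx, COPy = cop$COPy, VCOPy = vcopy,
      ACOMx = acom$ACOMx, ACOMy = acom$ACOMy, ACOMz = acom$ACOMz,
      ACOM = acom$ACOM,
      COMx = com$COMx, COMy = com$COMy, COMz = com$COMz,
      COP_CMP = cop_cmp, MOS = mos, AANG = aang$AANG
    ),
    aux = c(vcom, list(w0 = sqrt(g / l), l = l, g = g,
                       trunk_angle = aang$angle)),
    time = time, rate = rate, valid = cop$valid, events = events
  ), class = "wbi_metrics")
}

#' @export
print.wbi_metrics <- function(x, ...) {
  cat(sprintf("<wbi_metrics> %d channels x %d samples @ %g Hz\n",
              length(x$channels), length(x$time), x$rate))
  cat(sprintf("  support: %.1f%% of samples; %d heel strikes; l = %.3f m\n",
              100 * mean(x$valid), length(x$events), x$aux$l))
  invisible(x)
}

#' Write a metric series as TSV
#'
#' One row per sample, one column per channel; invalid (out-of-support)
#' samples are written as empty cells.
#'
#' @param metrics A `wbi_metrics`.
#' @param path Output path.
#' @export
write_metrics <- function(metrics, path) {
  df <- as.data.frame(metrics$channels)
  df <- cbind(time = metrics$time, df)
  txt <- vapply(df, function(v) {
    out <- formatC(v, format = "g", digits = 17)
    out[is.na(v)] <- ""
    out
  }, character(nrow(df)))
  writeLines(c(sprintf("# rate: %g", metrics$rate),
               paste(colnames(df), collapse = "\t"),
               apply(txt, 1L, paste, collapse = "\t")), path)
  invisible(path)
}
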