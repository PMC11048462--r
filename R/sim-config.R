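#' Configuration for the synthetic treadmill-gait generator
#'
#' Bundles and validates every knob of the synthetic-gait generator. The
#' defaults describe a healthy adult walking on an instrumented treadmill:
#' stride period 1.1 s, force plate sampled at 1000 Hz, marker-derived
#' kinematics at 100 Hz, stance occupying the first 60% of each gait cycle.
#' The perturbed condition emulates external interference applied during the
#' support phase only: stride-varying random amplitude modulation, confined
#' to a half-sine window over stance, on the source channels that drive the
#' configured target metrics.
#'
#' @param stride_period Stride (heel-strike to ipsilateral heel-strike)
#'   duration in seconds.
#' @param n_strides Number of full strides to simulate (>= 2).
#' @param grf_rate Force-plate sampling rate in Hz.
#' @param kin_rate Kinematic sampling rate in Hz.
#' @param subject_height Subject stature in metres.
#' @param subject_mass Subject body mass in kg.
#' @param stance_fraction Fraction of the gait cycle spent in stance,
#'   in (0, 1].
#' @param perturbed Logical; if `TRUE` the stance-confined perturbation is
#'   applied with gain `perturb_gain`.
#' @param perturb_gain Non-negative multiplier on the perturbation amplitude.
#'   `0` reproduces the balanced condition exactly under the same seed.
#' @param perturb_targets Character vector of balance-metric names whose
#'   driving channels receive the perturbation; subset of
#'   [balance_metric_names()].
#' @param noise_sd Dimensionless multiplier on the per-channel measurement
#'   noise (1 = nominal force-plate/mocap noise; 0 = noiseless).
#' @param belt_offset_h Height difference (m) between the belt surface and
#'   the force-plate coordinate origin (the `h` of the COP equations).
#' @param seed Integer RNG seed; identical configs give bit-identical trials.
#'
#' @return An object of class `gait_sim_config`.
#' @seealso [simulate_trial()], [simulate_condition_pair()]
#' @export
#' @examples
#' cfg <- gait_sim_config(n_strides = 5, seed = 1)
#' cfg
gait_sim_config <- function(stride_period = 1.1,
                            n_strides = 30L,
                            grf_rate = 1000,
                            kin_rate = 100,
                            subject_height = 1.75,
                            subject_mass = 68,
                            stance_fraction = 0.60,
                            perturbed = FALSE,
                            perturb_gain = 2,
                            perturb_targets = c("COPy", "VCOPy", "ACOMy",
                                                "COMz", "AANG"),
                            noise_sd = 1,
                            belt_offset_h = 0,
                            seed = 1L) {
  cfg <- list(
    stride_period = as.numeric(stride_period),
    n_strides = as.integer(n_strides),
    grf_rate = as.numeric(grf_rate),
    kin_rate = as.numeric(kin_rate),
    subject_height = as.numeric(subject_height),
    subject_mass = as.numeric(subject_mass),
    stance_fraction = as.numeric(stance_fraction),
    perturbed = isTRUE(perturbed),
    perturb_gain = as.numeric(perturb_gain),
    perturb_targets = as.character(perturb_targets),
    noise_sd = as.numeric(noise_sd),
    belt_offset_h = as.numeric(belt_offset_h),
    seed = as.integer(seed)
  )
  class(cfg) <- "gait_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid configuration: `", field, "` must be a positive number",
           call. = FALSE)
  }
  for (f in c("stride_period", "grf_rate", "kin_rate",
              "subject_height", "subject_mass"))
    check_pos(f)
  if (is.na(cfg$n_strides) || cfg$n_strides < 2L)
    stop("invalid configuration: `n_strides` must be >= 2", call. = FALSE)
  sf <- cfg$stance_fraction
  if (!is.finite(sf) || sf <= 0 || sf > 1)
    stop("invalid configuration: `stance_fraction` must lie in (0, 1]",
         call. = FALSE)
  if (!is.finite(cfg$perturb_gain) || cfg$perturb_gain < 0)
    stop("invalid configuration: `perturb_gain` must be >= 0", call. = FALSE)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("invalid configuration: `noise_sd` must be >= 0", call. = FALSE)
  if (!is.finite(cfg$belt_offset_h))
    stop("invalid configuration: `belt_offset_h` must be finite",
         call. = FALSE)
  bad <- setdiff(cfg$perturb_targets, balance_metric_names())
  if (length(bad))
    stop("invalid configuration: unknown `perturb_targets`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.na(cfg$seed))
    stop("invalid configuration: `seed` must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat("<gait_sim_config>\n")
  cat(sprintf("  %d strides of %.3f s (stance %.0f%%), GRF %g Hz / kin %g Hz\n",
              x$n_strides, x$stride_period, 100 * x$stance_fraction,
              x$grf_rate, x$kin_rate))
  cat(sprintf("  subject: %.2f m, %.1f kg; noise x%g; seed %d\n",
              x$subject_height, x$subject_mass, x$noise_sd, x$seed))
  if (x$perturbed)
    cat(sprintf("  perturbed: gain %g on {%s}\n", x$perturb_gain,
                paste(x$perturb_targets, collapse = ", ")))
  else cat("  balanced condition\n")
  invisible(x)
}

#' Names of the 14 balance-metric channels
#'
#' The canonical ordering used throughout the package: COP position and
#' velocity on the sagittal (x) and coronal (y) axes, COM acceleration per
#' axis and its resultant, COM position per axis, the COP-to-CMP distance,
#' the margin of stability and trunk angular acceleration.
#'
#' @return Character vector of length 14.
#' @export
balance_metric_names <- function() {
  c("COPx", "VCOPx", "COPy", "VCOPy",
    "ACOMx", "ACOMy", "ACOMz", "ACOM",
    "COMx", "COMy", "COMz",
    "COP_CMP", "MOS", "AANG")
}

# Metrics whose defining equations are singular in swing; per-stride features
# for these use stance-valid samples only.
stance_only_metrics <- function() {
  c("COPx", "VCOPx", "COPy", "VCOPy", "COP_CMP", "MOS")
}
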