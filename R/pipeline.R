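#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: the synthetic-gait
#' generator settings (or paths to two recorded trials), the filter
#' cut-offs, the support threshold, the MOS axis, the selection and gate
#' levels, the retention threshold and the weight normalization. Validated
#' up front so stage errors name the offending field early.
#'
#' @param sim A [gait_sim_config()] used to simulate the condition pair;
#'   ignored when both `balanced_dir` and `perturbed_dir` are given.
#' @param balanced_dir,perturbed_dir Optional directories of recorded
#'   trials (see [write_trial()]).
#' @param grf_cutoff,kin_cutoff Low-pass cut-offs, Hz.
#' @param fz_threshold Support/heel-strike force threshold, N.
#' @param mos_axis `"y"` or `"x"`.
#' @param alpha Feature-selection significance level.
#' @param alpha_norm Normality/homoscedasticity gate level.
#' @param n_mc Lilliefors Monte-Carlo null size.
#' @param pc_threshold Cumulative-contribution retention threshold.
#' @param weight_norm `"sum"` or `"l2"` component weighting.
#' @param seed Seed for the selection stage's Monte-Carlo null.
#' @return Object of class `wbi_pipeline_config`.
#' @export
pipeline_config <- function(sim = gait_sim_config(),
                            balanced_dir = NULL, perturbed_dir = NULL,
                            grf_cutoff = 15, kin_cutoff = 6,
                            fz_threshold = 30, mos_axis = "y",
                            alpha = 0.01, alpha_norm = 0.05, n_mc = 1000L,
                            pc_threshold = 0.85,
                            weight_norm = "sum", seed = 1L) {
  cfg <- list(sim = sim, balanced_dir = balanced_dir,
              perturbed_dir = perturbed_dir,
              grf_cutoff = grf_cutoff, kin_cutoff = kin_cutoff,
              fz_threshold = fz_threshold, mos_axis = mos_axis,
              alpha = alpha, alpha_norm = alpha_norm,
              n_mc = as.integer(n_mc), pc_threshold = pc_threshold,
              weight_norm = weight_norm, seed = as.integer(seed))
  class(cfg) <- "wbi_pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (d in c(cfg$balanced_dir, cfg$perturbed_dir))
    if (!is.null(d) && !dir.exists(d))
      stop("pipeline config: trial directory does not exist: ", d,
           call. = FALSE)
  if (!is.null(cfg$sim)) validate_sim_config(cfg$sim)
  chk <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || !is.finite(v) || v < lo || v > hi)
      stop("pipeline config: `", field, "` must lie in [", lo, ", ", hi,
           "]", call. = FALSE)
  }
  chk("alpha", 1e-6, 1); chk("alpha_norm", 1e-6, 1)
  chk("pc_threshold", 0.01, 1); chk("fz_threshold", 0, Inf)
  chk("grf_cutoff", 1e-3, Inf); chk("kin_cutoff", 1e-3, Inf)
  if (!cfg$mos_axis %in% c("x", "y"))
    stop("pipeline config: `mos_axis` must be \"x\" or \"y\"", call. = FALSE)
  if (!cfg$weight_norm %in% c("sum", "l2"))
    stop("pipeline config: `weight_norm` must be \"sum\" or \"l2\"",
         call. = FALSE)
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim:` block
#' mirrors [gait_sim_config()].
#'
#' @param path YAML file.
#' @return A `wbi_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(gait_sim_config, y$sim)
  else gait_sim_config()
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full walking-balance pipeline
#'
#' simulate (or load) a balanced/perturbed trial pair, compute the balance
#' metrics, extract per-stride features, select the effective features,
#' fit the index model and score both conditions. All artifacts are
#' written under `out_dir` together with a run manifest carrying the
#' resolved configuration, its hash and the package version; identical
#' configurations and seeds reproduce every artifact byte for byte.
#'
#' @param config A `wbi_pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `selection`, `model`, `wbi_balanced`,
#'   `wbi_perturbed` and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (!quiet)
    message("[", stage, "] ", ...)

  say("simulate", "preparing condition pair")
  if (!is.null(config$balanced_dir) && !is.null(config$perturbed_dir)) {
    pair <- list(balanced = read_trial(config$balanced_dir),
                 perturbed = read_trial(config$perturbed_dir))
  } else {
    pair <- simulate_condition_pair(config$sim)
    write_trial(pair$balanced, file.path(out_dir, "trial_balanced"))
    write_trial(pair$perturbed, file.path(out_dir, "trial_perturbed"))
  }

  say("metrics", "computing the 14 balance-metric channels")
  feats <- lapply(pair, function(tr) {
    met <- compute_metrics(tr, grf_cutoff = config$grf_cutoff,
                           kin_cutoff = config$kin_cutoff,
                           fz_threshold = config$fz_threshold,
                           mos_axis = config$mos_axis)
    write_metrics(met, file.path(out_dir,
                                 paste0("metrics_", tr$condition, ".tsv")))
    extract_features(met, condition = tr$condition,
                     height = tr$height, mass = tr$mass)
  })
  say("features", sprintf("%d + %d strides x %d features",
                          nrow(feats$balanced), nrow(feats$perturbed),
                          ncol(feats$balanced)))
  write_features(feats$balanced, file.path(out_dir,
                                           "features_balanced.tsv"))
  write_features(feats$perturbed, file.path(out_dir,
                                            "features_perturbed.tsv"))

  say("select", sprintf("gated two-sample tests at alpha = %g",
                        config$alpha))
  selection <- select_features(feats$balanced, feats$perturbed,
                               alpha = config$alpha,
                               alpha_norm = config$alpha_norm,
                               n_mc = config$n_mc, seed = config$seed)
  write_selection(selection, file.path(out_dir, "selection.json"))
  say("select", sum(selection$selected), " effective features")

  say("fit", "constructing the index model")
  model <- fit_index(feats$balanced, feats$perturbed, selection,
                     threshold = config$pc_threshold,
                     weight_norm = config$weight_norm)
  write_index_model(model, file.path(out_dir, "model.json"))

  say("score", "scoring both conditions")
  wbi_bal <- score_wbi(model, feats$balanced)
  wbi_per <- score_wbi(model, feats$perturbed)
  write_wbi_series(wbi_bal, file.path(out_dir, "wbi_balanced.tsv"))
  write_wbi_series(wbi_per, file.path(out_dir, "wbi_perturbed.tsv"))

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_path,
                       auto_unbox = TRUE, digits = I(17))
  manifest <- list(
    package = "wbi",
    version = as.character(utils::packageVersion("wbi")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    artifacts = list.files(out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  say("done", sprintf("mean WBI balanced %.3f vs perturbed %.3f",
                      mean(wbi_bal$wbi), mean(wbi_per$wbi)))
  invisible(list(selection = selection, model = model,
                 wbi_balanced = wbi_bal, wbi_perturbed = wbi_per,
                 out_dir = out_dir))
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out
}
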