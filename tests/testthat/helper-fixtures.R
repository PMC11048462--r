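# Shared fixtures: small, fast generator configs and hand-built metric
# series for contract tests.

small_config <- function(...) {
  defaults <- list(n_strides = 8L, grf_rate = 500, kin_rate = 100,
                   seed = 42L)
  do.call(gait_sim_config, utils::modifyList(defaults, list(...)))
}

# A wbi_metrics object built directly from given channels (all valid).
make_metrics <- function(channels, rate = 100, events = NULL) {
  n <- length(channels[[1L]])
  time <- (seq_len(n) - 1L) / rate
  if (is.null(events)) events <- c(0, time[n] + 1 / rate)
  structure(list(channels = channels,
                 aux = list(l = 1, g = 9.81, w0 = sqrt(9.81)),
                 time = time, rate = rate,
                 valid = rep(TRUE, n), events = events),
            class = "wbi_metrics")
}

# Constant-valued channel set with the full 14 metric names.
constant_channels <- function(n, value = 1) {
  stats::setNames(rep(list(rep(value, n)), 14L), balance_metric_names())
}
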