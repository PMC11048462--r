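#' Root mean square of a sample
#'
#' `sqrt(mean(x^2))` — the "effective value" characteristic.
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
rms <- function(x) {
  if (!length(x) || anyNA(x))
    stop("rms: input must be non-empty and free of NA", call. = FALSE)
  sqrt(mean(x^2))
}

#' The three per-stride time-domain characteristics
#'
#' RMS (effective value), Var (sample variance, n-1 denominator) and Range
#' (max - min): the trio applied to every balance-metric channel within
#' every stride.
#'
#' @param x Numeric vector with at least 2 values.
#' @return Named numeric vector `c(RMS=, Var=, Range=)`.
#' @export
#' @examples
#' time_domain_features(c(1, 2, 3))  # RMS sqrt(14/3), Var 1, Range 2
time_domain_features <- function(x) {
  if (length(x) < 2L || anyNA(x))
    stop("time_domain_features: need >= 2 non-NA samples", call. = FALSE)
  c(RMS = rms(x), Var = stats::var(x), Range = max(x) - min(x))
}

feature_labels <- function(metrics = balance_metric_names()) {
  as.vector(t(outer(metrics, c("RMS", "Var", "Range"), paste, sep = ".")))
}

#' Per-stride feature matrix of a trial
#'
#' Reduces each stride of each metric channel to its RMS, Var and Range,
#' giving one row per stride and 42 labelled columns (14 metrics x 3
#' characteristics) named `metric.characteristic` (e.g. `COPy.Range`).
#' Metrics whose defining equations hold only in stance (COP, its velocity,
#' the COP-CMP offset, MOS) are reduced over the stride's valid stance
#' samples only; strides with fewer than 2 valid samples for some metric
#' are dropped with a warning reporting the count.
#'
#' @param metrics A `wbi_metrics` from [compute_metrics()].
#' @param slices Optional [segment_strides()] result; defaults to the
#'   metric series' own heel-strike events.
#' @param condition Condition tag stored on the matrix (defaults to
#'   `"unknown"`).
#' @param height,mass Subject anthropometry carried for later scaling.
#' @return Object of class `wbi_features`: numeric matrix strides x
#'   features with attributes `condition`, `height`, `mass`, `scaled`.
#' @export
extract_features <- function(metrics, slices = NULL, condition = "unknown",
                             height = NA_real_, mass = NA_real_) {
  if (is.null(slices))
    slices <- segment_strides(metrics$events, metrics$time)
  labs <- feature_labels(names(metrics$channels))
  rows <- vector("list", length(slices))
  ok <- logical(length(slices))
  for (k in seq_along(slices)) {
    idx <- slices[[k]]
    vals <- numeric(0)
    good <- TRUE
    for (m in names(metrics$channels)) {
      x <- metrics$channels[[m]][idx]
      x <- x[is.finite(x)]
      if (length(x) < 2L) { good <- FALSE; break }
      vals <- c(vals, time_domain_features(x))
    }
    ok[k] <- good
    if (good) rows[[k]] <- vals
  }
  if (!all(ok))
    warning(sum(!ok), " of ", length(slices),
            " strides dropped: fewer than 2 valid samples for some metric",
            call. = FALSE)
  if (!any(ok))
    stop("extract_features: no stride has enough valid samples",
         call. = FALSE)
  mat <- do.call(rbind, rows[ok])
  colnames(mat) <- labs
  rownames(mat) <- paste0("stride_", which(ok))
  structure(mat, class = c("wbi_features", "matrix", "array"),
            condition = condition, height = height, mass = mass,
            scaled = FALSE)
}

#' Extract features directly from a trial
#'
#' Convenience wrapper: [compute_metrics()] then [extract_features()],
#' carrying the trial's condition tag and anthropometry.
#'
#' @param trial A `wbi_trial`.
#' @param ... Passed to [compute_metrics()].
#' @return A `wbi_features` matrix.
#' @export
trial_features <- function(trial, ...) {
  met <- compute_metrics(trial, ...)
  extract_features(met, condition = trial$condition,
                   height = trial$height, mass = trial$mass)
}

#' @export
print.wbi_features <- function(x, ...) {
  cat(sprintf("<wbi_features> %d strides x %d features (%s condition%s)\n",
              nrow(x), ncol(x), attr(x, "condition"),
              if (isTRUE(attr(x, "scaled"))) ", dimensionless" else ""))
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' Header row of `metric.characteristic` labels; `# key: value` comment
#' lines carry the condition tag and anthropometry.
#'
#' @param features A `wbi_features`.
#' @param path File path.
#' @export
write_features <- function(features, path) {
  hdr <- c(sprintf("# condition: %s", attr(features, "condition")),
           sprintf("# height: %.17g", attr(features, "height")),
           sprintf("# mass: %.17g", attr(features, "mass")),
           sprintf("# scaled: %s", isTRUE(attr(features, "scaled"))))
  body <- apply(features, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(c(hdr, paste(colnames(features), collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- sub(paste0("^#\\s*", key, ":\\s*"), "",
             grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE))
    if (length(m)) m[1L] else NA_character_
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  mat <- do.call(rbind, lapply(body[-1L], function(ln)
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1L]])))
  colnames(mat) <- cols
  rownames(mat) <- paste0("stride_", seq_len(nrow(mat)))
  structure(mat, class = c("wbi_features", "matrix", "array"),
            condition = get("condition"),
            height = as.numeric(get("height")),
            mass = as.numeric(get("mass")),
            scaled = identical(get("scaled"), "TRUE"))
}
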