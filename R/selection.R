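#' Monte-Carlo null table for the Lilliefors statistic
#'
#' The Lilliefors statistic is the Kolmogorov-Smirnov distance between the
#' empirical CDF of a sample and a normal CDF with the sample's own mean
#' and standard deviation; its null distribution depends only on the sample
#' size. This helper draws `n_mc` standard-normal samples of size `n` under
#' a fixed seed and returns their sorted statistics, so a table can be
#' shared across many tests of equal-sized samples.
#'
#' @param n Sample size.
#' @param n_mc Number of Monte-Carlo null draws.
#' @param seed Integer seed.
#' @return Sorted numeric vector of `n_mc` null statistics.
#' @export
lilliefors_null_table <- function(n, n_mc = 1000L, seed = 1L) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n_mc * n), n_mc, n)
  sort(apply(z, 1L, lilliefors_statistic))
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  s <- sort(x)
  p <- stats::pnorm(s, mean(x), stats::sd(x))
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n))
}

#' Lilliefors normality test with a Monte-Carlo p-value
#'
#' Composite-normality test: KS statistic against the normal with estimated
#' mean and sd, p-value from the empirical null
#' `p = (1 + #\{D* >= D\}) / (n_mc + 1)` so p is never exactly zero and is
#' monotone non-increasing in the statistic.
#'
#' @param x Numeric sample (>= 4 values, not constant).
#' @param n_mc Monte-Carlo null size (ignored when `null_table` is given).
#' @param seed Seed for the null draws.
#' @param null_table Optional precomputed [lilliefors_null_table()].
#' @return List with `statistic` and `p.value`.
#' @export
lilliefors <- function(x, n_mc = 1000L, seed = 1L, null_table = NULL) {
  if (length(x) < 4L)
    stop("lilliefors: need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("lilliefors: degenerate sample (constant values)", call. = FALSE)
  d <- lilliefors_statistic(x)
  if (is.null(null_table))
    null_table <- lilliefors_null_table(length(x), n_mc, seed)
  n_mc <- length(null_table)
  n_ge <- n_mc - findInterval(d, null_table, left.open = TRUE)
  list(statistic = d, p.value = (1 + n_ge) / (n_mc + 1))
}

#' Two-sample Bartlett test of variance homogeneity
#'
#' Bartlett's statistic against chi-square with 1 degree of freedom; a thin
#' wrapper over the standard implementation with degenerate-sample checks.
#'
#' @param x,y Numeric samples (>= 2 values each, not constant).
#' @return Two-sided p-value.
#' @export
bartlett_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("bartlett_p: need at least 2 observations per sample",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("bartlett_p: degenerate sample (constant values)", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), stats::var(y), tolerance = 1e-12)))
    return(1)
  stats::bartlett.test(list(x, y))$p.value
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test. For `length(x) + length(y) <= 12` the p-value
#' is exact by full enumeration of all rank assignments (ties handled via
#' midranks); otherwise the normal approximation with tie and continuity
#' corrections is used. The p-value is the null probability of a rank-sum
#' deviation from its expectation at least as large as observed.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (rank sum of `x`), `p.value` and `method`.
#' @export
rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("rank_sum: both samples must be non-empty", call. = FALSE)
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  ew <- m * mean(r)
  if (N <= 12L) {
    combos <- utils::combn(N, m)
    ws <- colSums(matrix(r[combos], nrow = m))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-12)
    list(statistic = w, p.value = p, method = "exact")
  } else {
    ties <- table(r)
    sig2 <- m * (N - m) / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = w, p.value = 1,
                               method = "normal"))
    z <- (abs(w - ew) - 0.5) / sqrt(sig2)
    list(statistic = w, p.value = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal")
  }
}

#' Normality/homoscedasticity-gated two-sample test
#'
#' The decision tree used per feature: if both samples pass the Lilliefors
#' normality test at `alpha_norm`, a Bartlett test decides between the
#' pooled-variance Student t-test (homogeneous variances) and Welch's
#' unequal-variance t-test (the "corrected" t-test); if either sample fails
#' normality, the Wilcoxon rank-sum test is used. All tests are two-sided.
#' Constant samples short-circuit to the rank-sum branch, where ties are
#' handled.
#'
#' @param x,y Numeric samples (>= 4 values each).
#' @param alpha_norm Gate level for the Lilliefors and Bartlett tests.
#' @param n_mc,seed Monte-Carlo controls for the Lilliefors null.
#' @param null_tables Optional named list of precomputed null tables keyed
#'   by `as.character(sample size)`.
#' @return List with `test` (`"t"`, `"welch_t"` or `"rank_sum"`),
#'   `p.value`, and the gate p-values `p_norm_x`, `p_norm_y`, `p_bartlett`.
#' @export
choose_and_run_test <- function(x, y, alpha_norm = 0.05, n_mc = 1000L,
                                seed = 1L, null_tables = NULL) {
  if (length(x) < 4L || length(y) < 4L)
    stop("choose_and_run_test: need at least 4 observations per sample",
         call. = FALSE)
  get_table <- function(n) {
    key <- as.character(n)
    if (!is.null(null_tables) && !is.null(null_tables[[key]]))
      null_tables[[key]]
    else lilliefors_null_table(n, n_mc, seed)
  }
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  p_nx <- p_ny <- p_b <- NA_real_
  if (!degenerate) {
    p_nx <- lilliefors(x, null_table = get_table(length(x)))$p.value
    p_ny <- lilliefors(y, null_table = get_table(length(y)))$p.value
  }
  if (!degenerate && p_nx >= alpha_norm && p_ny >= alpha_norm) {
    p_b <- bartlett_p(x, y)
    if (p_b >= alpha_norm) {
      res <- stats::t.test(x, y, var.equal = TRUE)
      list(test = "t", p.value = res$p.value,
           p_norm_x = p_nx, p_norm_y = p_ny, p_bartlett = p_b)
    } else {
      res <- stats::t.test(x, y, var.equal = FALSE)
      list(test = "welch_t", p.value = res$p.value,
           p_norm_x = p_nx, p_norm_y = p_ny, p_bartlett = p_b)
    }
  } else {
    list(test = "rank_sum", p.value = rank_sum(x, y)$p.value,
         p_norm_x = p_nx, p_norm_y = p_ny, p_bartlett = p_b)
  }
}

#' Select the effective features between two gait conditions
#'
#' For each shared feature column, compares the balanced-condition and
#' perturbed-condition stride samples with the gated two-sample test of
#' [choose_and_run_test()] and flags features with two-sided `p < alpha`
#' as effective. No multiple-testing correction is applied by default,
#' matching the method's use of a strict per-feature level (`alpha = 0.01`);
#' Benjamini-Hochberg adjustment is available as an option.
#'
#' @param balanced,perturbed `wbi_features` matrices sharing column labels,
#'   each with >= 4 strides.
#' @param alpha Per-feature significance level.
#' @param alpha_norm Gate level for the normality/homoscedasticity tests.
#' @param n_mc,seed Monte-Carlo controls for the Lilliefors null (one table
#'   is built per distinct sample size and reused across features).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `wbi_selection`: a data frame with one row per
#'   feature (`feature`, `metric`, `characteristic`, the gate p-values,
#'   `test`, `p`, `selected`) and attributes `alpha`, `alpha_norm`, `n_x`,
#'   `n_y`.
#' @export
select_features <- function(balanced, perturbed, alpha = 0.01,
                            alpha_norm = 0.05, n_mc = 1000L, seed = 1L,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labs <- colnames(balanced)
  if (!identical(sort(labs), sort(colnames(perturbed)))) {
    off <- union(setdiff(labs, colnames(perturbed)),
                 setdiff(colnames(perturbed), labs))
    stop("select_features: feature labels differ between conditions: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (nrow(balanced) < 4L || nrow(perturbed) < 4L)
    stop("select_features: need at least 4 strides per condition",
         call. = FALSE)
  sizes <- unique(c(nrow(balanced), nrow(perturbed)))
  tables <- stats::setNames(
    lapply(sizes, lilliefors_null_table, n_mc = n_mc, seed = seed),
    as.character(sizes))
  rows <- lapply(labs, function(lb) {
    res <- choose_and_run_test(balanced[, lb], perturbed[, lb],
                               alpha_norm = alpha_norm,
                               null_tables = tables)
    parts <- strsplit(lb, ".", fixed = TRUE)[[1L]]
    data.frame(feature = lb, metric = parts[1L],
               characteristic = parts[2L],
               p_norm_balanced = res$p_norm_x,
               p_norm_perturbed = res$p_norm_y,
               p_bartlett = res$p_bartlett,
               test = res$test, p = res$p.value,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  if (adjust == "BH") rep_df$p_adjusted <- stats::p.adjust(rep_df$p, "BH")
  crit <- if (adjust == "BH") rep_df$p_adjusted else rep_df$p
  rep_df$selected <- crit < alpha
  structure(rep_df, class = c("wbi_selection", "data.frame"),
            alpha = alpha, alpha_norm = alpha_norm,
            n_x = nrow(balanced), n_y = nrow(perturbed), adjust = adjust)
}

#' @export
print.wbi_selection <- function(x, ...) {
  cat(sprintf(paste0("<wbi_selection> %d of %d features selected at ",
                     "alpha = %g (n = %d vs %d strides)\n"),
              sum(x$selected), nrow(x), attr(x, "alpha"),
              attr(x, "n_x"), attr(x, "n_y")))
  tb <- table(x$test)
  cat("  tests used: ",
      paste(sprintf("%s:%d", names(tb), tb), collapse = ", "), "\n",
      sep = "")
  if (any(x$selected))
    cat("  selected: ",
        paste(utils::head(x$feature[x$selected], 10L), collapse = ", "),
        if (sum(x$selected) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write / read a selection report as JSON
#' @param selection A `wbi_selection`.
#' @param path File path.
#' @export
write_selection <- function(selection, path) {
  payload <- list(format = "wbi-selection", version = 1L,
                  alpha = attr(selection, "alpha"),
                  alpha_norm = attr(selection, "alpha_norm"),
                  n_x = attr(selection, "n_x"),
                  n_y = attr(selection, "n_y"),
                  adjust = attr(selection, "adjust"),
                  table = as.data.frame(selection))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "wbi-selection")
    stop("format error: not a wbi selection file: ", path, call. = FALSE)
  structure(p$table, class = c("wbi_selection", "data.frame"),
            alpha = p$alpha, alpha_norm = p$alpha_norm,
            n_x = p$n_x, n_y = p$n_y, adjust = p$adjust)
}
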