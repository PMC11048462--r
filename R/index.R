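#' Scale features to dimensionless form
#'
#' Removes anthropometric units so subjects of different stature are
#' comparable: position-like features (COP, COM, COP-CMP offset, MOS) are
#' divided by body height, velocities by `sqrt(g*height)`, linear
#' accelerations by `g` and the trunk angular acceleration by `g/height`.
#' Variance features are scaled by the square of the corresponding factor
#' (variance carries squared units); RMS and Range by the factor itself.
#' The operation is guarded by a `scaled` flag: scaling an already
#' dimensionless matrix is an error, since the factors are not idempotent.
#'
#' @param features A `wbi_features` matrix (unscaled).
#' @param height Subject height, m; defaults to the matrix's own attribute.
#' @param mass Subject mass, kg (carried for provenance; no kinematic
#'   feature carries mass units).
#' @param g Gravitational acceleration, m/s^2.
#' @return A dimensionless `wbi_features` matrix (`scaled` attribute set).
#' @export
scale_dimensionless <- function(features, height = attr(features, "height"),
                                mass = attr(features, "mass"), g = 9.81) {
  if (isTRUE(attr(features, "scaled")))
    stop("scale_dimensionless: features are already dimensionless ",
         "(scaling twice is not idempotent)", call. = FALSE)
  if (!is.finite(height) || height <= 0)
    stop("scale_dimensionless: `height` must be positive", call. = FALSE)
  out <- features
  for (lb in colnames(features)) {
    parts <- strsplit(lb, ".", fixed = TRUE)[[1L]]
    f <- unit_scale_factor(parts[1L], height, g)
    fac <- if (parts[2L] == "Var") f^2 else f
    out[, lb] <- features[, lb] * fac
  }
  attr(out, "scaled") <- TRUE
  attr(out, "height") <- height
  attr(out, "mass") <- mass
  out
}

# multiplicative factor taking one metric sample to dimensionless form
unit_scale_factor <- function(metric, height, g) {
  pos <- c("COPx", "COPy", "COMx", "COMy", "COMz", "COP_CMP", "MOS")
  vel <- c("VCOPx", "VCOPy")
  acc <- c("ACOMx", "ACOMy", "ACOMz", "ACOM")
  if (metric %in% pos) 1 / height
  else if (metric %in% vel) 1 / sqrt(g * height)
  else if (metric %in% acc) 1 / g
  else if (metric == "AANG") height / g
  else stop("unknown feature unit class for metric: ", metric,
            call. = FALSE)
}

#' Z-score feature columns
#'
#' Centers and scales every column to mean 0, sample sd 1, returning the
#' parameters so a fitted model can standardize new strides identically.
#'
#' @param features Numeric matrix with >= 2 rows.
#' @return List with `z` (standardized matrix), `center` and `scale`
#'   (named per-feature vectors).
#' @export
standardize_features <- function(features) {
  if (nrow(features) < 2L)
    stop("standardize_features: need at least 2 rows", call. = FALSE)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  dead <- colnames(features)[scl == 0 | !is.finite(scl)]
  if (length(dead))
    stop("standardize_features: zero-variance feature(s): ",
         paste(dead, collapse = ", "), call. = FALSE)
  z <- sweep(sweep(features, 2L, ctr, `-`), 2L, scl, `/`)
  list(z = z, center = ctr, scale = scl)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over the off-diagonal simple
#' correlations `r` and anti-image partial correlations `q`. Values near 1
#' mean the features share enough common variance for a PCA-based index;
#' for exactly two features the statistic is 0.5 by construction. A
#' near-singular correlation matrix is inverted with a small ridge (with a
#' warning).
#'
#' @param features Numeric matrix with >= 2 columns.
#' @return KMO statistic in \[0, 1\].
#' @export
kmo <- function(features) {
  if (ncol(features) < 2L)
    stop("kmo: need at least 2 features", call. = FALSE)
  r <- stats::cor(features)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(inv)) {
    warning("kmo: singular correlation matrix; using ridge fallback",
            call. = FALSE)
    inv <- solve(r + diag(1e-8, ncol(r)))
  }
  d <- 1 / sqrt(diag(inv))
  q <- -inv * outer(d, d)           # anti-image partial correlations
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' Principal components of a standardized feature matrix
#'
#' Eigendecomposition of the covariance matrix of the (already
#' standardized) features via singular value decomposition. Eigenvalues
#' are sorted descending; each component's sign is fixed so that its
#' largest-magnitude coefficient is positive, removing the sign
#' arbitrariness of PCA.
#'
#' @param z Standardized matrix (rows = strides).
#' @return List with `eigenvalues` (length = n features) and
#'   `coefficients` (components x features matrix, orthonormal rows).
#' @export
pca_components <- function(z) {
  if (!all(is.finite(z)))
    stop("pca_components: non-finite values in input", call. = FALSE)
  if (nrow(z) <= ncol(z))
    warning("pca_components: fewer strides than features + 1; ",
            "eigenstructure will be rank-deficient", call. = FALSE)
  zc <- sweep(z, 2L, colMeans(z), `-`)
  sv <- svd(zc)
  ev <- sv$d^2 / (nrow(z) - 1L)
  coef <- t(sv$v)
  for (i in seq_len(nrow(coef))) {
    j <- which.max(abs(coef[i, ]))
    if (coef[i, j] < 0) coef[i, ] <- -coef[i, ]
  }
  colnames(coef) <- colnames(z)
  list(eigenvalues = ev, coefficients = coef)
}

#' Number of components reaching a cumulative-contribution threshold
#'
#' Smallest `n` whose leading eigenvalues account for at least `threshold`
#' of the total variance.
#'
#' @param eigenvalues Non-negative, non-increasing eigenvalues.
#' @param threshold Required cumulative contribution, fraction in (0, 1].
#' @return Integer count.
#' @export
#' @examples
#' select_components(c(33.74, 24.36, 16.43, 8.14, 6.75, rep(10.58 / 17, 17)))
select_components <- function(eigenvalues, threshold = 0.85) {
  if (!length(eigenvalues) || all(eigenvalues <= 0))
    stop("select_components: eigenvalues are all zero", call. = FALSE)
  if (any(diff(eigenvalues) > 1e-9))
    stop("select_components: eigenvalues must be non-increasing",
         call. = FALSE)
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  as.integer(which(cum >= threshold - 1e-12)[1L])
}

#' Fit a Walking Balance Index model
#'
#' The full index-construction path between a balanced and a perturbed
#' feature matrix: restrict both to the selected features, scale them
#' dimensionless with the fitting subject's anthropometry, z-score on the
#' pooled strides, check sampling adequacy (KMO, advisory warning below
#' 0.5), eigendecompose the pooled covariance, retain the leading
#' components whose cumulative contribution reaches `threshold`, weight
#' them by their eigenvalues, and orient the index so that larger values
#' mean worse balance (mean WBI of the perturbed fitting strides at or
#' above the balanced mean).
#'
#' @param balanced,perturbed Unscaled `wbi_features` matrices sharing
#'   labels and anthropometry.
#' @param selection A `wbi_selection` from [select_features()].
#' @param threshold Cumulative-contribution retention threshold.
#' @param weight_norm `"sum"` (default): weights `lambda_i / sum(lambda)`,
#'   summing to 1; `"l2"`: `lambda_i / sqrt(sum(lambda^2))`.
#' @param g Gravitational acceleration used in the scaling, m/s^2.
#' @return Object of class `wbi_model`.
#' @export
fit_index <- function(balanced, perturbed, selection, threshold = 0.85,
                      weight_norm = c("sum", "l2"), g = 9.81) {
  weight_norm <- match.arg(weight_norm)
  sel <- selection$feature[selection$selected]
  if (!length(sel))
    stop("no effective metrics: the selection stage picked no feature",
         call. = FALSE)
  missing <- setdiff(sel, colnames(balanced))
  if (length(missing))
    stop("fit_index: features missing from the matrices: ",
         paste(missing, collapse = ", "), call. = FALSE)
  height <- attr(balanced, "height")
  mass <- attr(balanced, "mass")
  n_pool <- nrow(balanced) + nrow(perturbed)
  if (n_pool < length(sel) + 2L)
    warning("fit_index: only ", n_pool, " pooled strides for ",
            length(sel), " selected features", call. = FALSE)

  bal <- scale_dimensionless(balanced, height = height, mass = mass, g = g)
  per <- scale_dimensionless(perturbed, height = height, mass = mass, g = g)
  pooled <- rbind(bal[, sel, drop = FALSE], per[, sel, drop = FALSE])

  std <- standardize_features(pooled)
  kmo_val <- if (length(sel) >= 2L) kmo(std$z) else NA_real_
  if (is.finite(kmo_val) && kmo_val < 0.5)
    warning(sprintf("fit_index: KMO = %.3f < 0.5 - weak sampling adequacy",
                    kmo_val), call. = FALSE)

  pc <- pca_components(std$z)
  n_ret <- select_components(pc$eigenvalues, threshold)
  lam <- pc$eigenvalues[seq_len(n_ret)]
  w <- switch(weight_norm,
              sum = lam / sum(lam),
              l2 = lam / sqrt(sum(lam^2)))
  coef <- pc$coefficients[seq_len(n_ret), , drop = FALSE]

  model <- structure(list(
    features = sel, height = height, mass = mass, g = g,
    center = std$center, scale = std$scale,
    coefficients = coef, eigenvalues = pc$eigenvalues,
    n_retained = n_ret, weights = w, weight_norm = weight_norm,
    orientation = 1,
    cum_contribution = sum(lam) / sum(pc$eigenvalues),
    kmo = kmo_val, threshold = threshold,
    provenance = list(n_balanced = nrow(balanced),
                      n_perturbed = nrow(perturbed),
                      alpha = attr(selection, "alpha"))
  ), class = "wbi_model")

  # orientation: larger WBI = less balanced on the fitting data
  wb <- score_wbi(model, balanced)
  wp <- score_wbi(model, perturbed)
  if (mean(wp$wbi) < mean(wb$wbi)) model$orientation <- -1
  model
}

#' Score strides with a fitted index model
#'
#' Applies the model's own scaling (its anthropometry), standardization
#' parameters and component coefficients to new strides — a pure transfer,
#' so a model fitted on one subject scores another without refitting —
#' and returns the eigenvalue-weighted component combination per stride.
#' Extra feature columns are ignored; missing ones are an error.
#'
#' @param model A `wbi_model`.
#' @param features An unscaled `wbi_features` matrix (or an already
#'   dimensionless one, which is used as-is).
#' @return Object of class `wbi_series`: data frame with `stride` and
#'   `wbi`, plus a `condition` attribute.
#' @export
score_wbi <- function(model, features) {
  missing <- setdiff(model$features, colnames(features))
  if (length(missing))
    stop("score_wbi: features missing from input: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sc <- if (isTRUE(attr(features, "scaled"))) features
  else scale_dimensionless(features, height = model$height,
                           mass = model$mass, g = model$g)
  x <- sc[, model$features, drop = FALSE]
  z <- sweep(sweep(x, 2L, model$center, `-`), 2L, model$scale, `/`)
  y <- z %*% t(model$coefficients)      # strides x retained components
  wbi <- model$orientation * as.numeric(y %*% model$weights)
  structure(data.frame(stride = seq_len(nrow(x)), wbi = wbi),
            class = c("wbi_series", "data.frame"),
            condition = attr(features, "condition"))
}

#' @export
predict.wbi_model <- function(object, newdata, ...) {
  score_wbi(object, newdata)
}

#' @export
print.wbi_model <- function(x, ...) {
  cat("<wbi_model>\n")
  cat(sprintf("  %d effective features; %d of %d components retained ",
              length(x$features), x$n_retained, length(x$eigenvalues)))
  cat(sprintf("(%.1f%% cumulative contribution, threshold %.0f%%)\n",
              100 * x$cum_contribution, 100 * x$threshold))
  cat(sprintf("  weights (%s-normalized): %s\n", x$weight_norm,
              paste(sprintf("%.3f", x$weights), collapse = ", ")))
  if (is.finite(x$kmo)) cat(sprintf("  KMO = %.3f\n", x$kmo))
  cat(sprintf("  subject: %.2f m / %.1f kg; orientation %+d\n",
              x$height, x$mass, as.integer(x$orientation)))
  invisible(x)
}

#' Write a per-stride WBI series as TSV
#' @param series A `wbi_series`.
#' @param path Output path.
#' @export
write_wbi_series <- function(series, path) {
  writeLines(c(sprintf("# condition: %s", attr(series, "condition")),
               "stride\twbi",
               sprintf("%d\t%.17g", series$stride, series$wbi)), path)
  invisible(path)
}
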