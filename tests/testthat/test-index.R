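make_features <- function(mat, condition = "balanced", height = 1.75,
                          mass = 68, scaled = FALSE) {
  structure(mat, class = c("wbi_features", "matrix", "array"),
            condition = condition, height = height, mass = mass,
            scaled = scaled)
}

test_that("dimensionless scaling applies the unit-class factors", {
  m <- cbind("COPy.Range" = c(0.05, 0.06), "VCOPx.RMS" = c(1, 2),
             "ACOM.RMS" = c(9.81, 19.62), "AANG.Var" = c(4, 8),
             "COMz.Var" = c(0.01, 0.02))
  f <- make_features(m, height = 2)
  out <- scale_dimensionless(f, g = 9.81)
  expect_equal(out[1L, "COPy.Range"], c("COPy.Range" = 0.025))
  expect_equal(unname(out[, "VCOPx.RMS"]), c(1, 2) / sqrt(9.81 * 2))
  expect_equal(unname(out[, "ACOM.RMS"]), c(1, 2))
  expect_equal(unname(out[, "AANG.Var"]), c(4, 8) * (2 / 9.81)^2)
  expect_equal(unname(out[, "COMz.Var"]), c(0.01, 0.02) / 4)
  # height 1, g = 1: every factor is the identity
  ident <- scale_dimensionless(make_features(m, height = 1), g = 1)
  expect_equal(unclass(ident), unclass(m), ignore_attr = TRUE)
  # scaling twice is a guarded error
  expect_error(scale_dimensionless(out), "already dimensionless")
  bad <- make_features(cbind("XX.RMS" = c(1, 2)))
  expect_error(scale_dimensionless(bad), "unknown feature unit class")
})

test_that("standardization round-trips and rejects dead columns", {
  set.seed(2)
  m <- matrix(rnorm(60, 5, 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  std <- standardize_features(m)
  expect_lt(max(abs(colMeans(std$z))), 1e-9)
  expect_equal(unname(apply(std$z, 2L, sd)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(standardize_features(cbind(x = c(1, 3)))$z[, 1L]),
               c(-sqrt(0.5), sqrt(0.5)))
  redo <- sweep(sweep(m, 2L, std$center, `-`), 2L, std$scale, `/`)
  expect_equal(redo, std$z, tolerance = 0)
  m2 <- cbind(m, dead = 1)
  expect_error(standardize_features(m2), "dead")
})

test_that("KMO closed form, bounds and behaviour under shared variance", {
  set.seed(7)
  x <- rnorm(200)
  two <- cbind(a = x + rnorm(200, sd = 0.5), b = x + rnorm(200, sd = 0.5))
  expect_equal(kmo(two), 0.5, tolerance = 1e-12)
  # a correlated block raises adequacy above 0.5
  base <- rnorm(300)
  block <- sapply(1:4, function(i) base + rnorm(300, sd = 0.3))
  noise <- matrix(rnorm(600), 300, 2)
  k <- kmo(cbind(block, noise))
  expect_gt(k, 0.5)
  expect_lte(k, 1)
  ind <- matrix(rnorm(300 * 5), 300, 5)
  k2 <- kmo(ind)
  expect_gte(k2, 0)
  expect_lte(k2, 1)
})

test_that("PCA matches the two-variable closed form and conserves trace", {
  set.seed(11)
  n <- 20000L
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  z <- standardize_features(cbind(a = x, b = y))$z
  pc <- pca_components(z)
  expect_equal(pc$eigenvalues, c(1.6, 0.4), tolerance = 0.05)
  expect_equal(abs(pc$coefficients[1L, ]),
               c(a = 1, b = 1) / sqrt(2), tolerance = 0.05)
  # sign convention: largest coefficient positive
  expect_gt(max(pc$coefficients[1L, ]), 0)
  # uncorrelated unit-variance features: flat spectrum
  z2 <- standardize_features(matrix(rnorm(2 * n), n, 2,
                                    dimnames = list(NULL, c("u", "v"))))$z
  expect_equal(pca_components(z2)$eigenvalues, c(1, 1), tolerance = 0.05)
  # trace conservation and orthonormal rows on a generic matrix
  set.seed(12)
  m <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, letters[1:5])) %*%
    matrix(runif(25, -1, 1), 5, 5)
  colnames(m) <- letters[1:5]
  pc <- pca_components(m)
  expect_equal(sum(pc$eigenvalues), sum(diag(cov(m))), tolerance = 1e-9)
  expect_equal(pc$coefficients %*% t(pc$coefficients), diag(5),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
})

test_that("component retention honours the cumulative-contribution rule", {
  contributions <- c(33.74, 24.36, 16.43, 8.14, 6.75)
  expect_equal(sum(contributions), 89.42)
  spectrum <- c(contributions, rep((100 - sum(contributions)) / 17, 17))
  expect_identical(select_components(spectrum, 0.85), 5L)
  expect_identical(select_components(10), 1L)
  expect_identical(select_components(c(4, 2, 1, 0), threshold = 1), 3L)
  expect_error(select_components(c(0, 0)), "all zero")
  expect_error(select_components(c(1, 2)), "non-increasing")
})

test_that("fit_index builds a valid, deterministic, oriented model", {
  cfg <- gait_sim_config(n_strides = 40L, grf_rate = 500, perturbed = TRUE,
                         seed = 17L)
  pair <- simulate_condition_pair(cfg)
  fb <- trial_features(pair$balanced)
  fp <- trial_features(pair$perturbed)
  sel <- select_features(fb, fp, n_mc = 400L, seed = 2L)
  model <- fit_index(fb, fp, sel)
  expect_s3_class(model, "wbi_model")
  expect_gte(model$cum_contribution, 0.85)
  expect_true(all(diff(model$eigenvalues) <= 1e-9))
  expect_true(all(model$eigenvalues >= -1e-10))
  expect_equal(sum(model$weights), 1, tolerance = 1e-12)
  expect_true(all(model$weights >= 0))
  expect_equal(model$coefficients %*% t(model$coefficients),
               diag(model$n_retained), tolerance = 1e-8,
               ignore_attr = TRUE)
  # orientation: perturbed scores at or above balanced on the fitting data
  expect_gte(mean(score_wbi(model, fp)$wbi),
             mean(score_wbi(model, fb)$wbi))
  # refit is identical
  expect_equal(fit_index(fb, fp, sel), model, tolerance = 0)
  # l2 weighting normalizes by the eigenvalue 2-norm
  m2 <- fit_index(fb, fp, sel, weight_norm = "l2")
  lam <- m2$eigenvalues[seq_len(m2$n_retained)]
  expect_equal(m2$weights, lam / sqrt(sum(lam^2)), tolerance = 1e-12)
  # empty selection is a clear error
  none <- sel
  none$selected <- FALSE
  expect_error(fit_index(fb, fp, none), "no effective metrics")
})

test_that("perturbing lateral COP concentrates the top component on its features", {
  cfg <- gait_sim_config(n_strides = 50L, grf_rate = 500, perturbed = TRUE,
                         perturb_gain = 3,
                         perturb_targets = c("COPy", "VCOPy"), seed = 23L)
  pair <- simulate_condition_pair(cfg)
  fb <- trial_features(pair$balanced)
  fp <- trial_features(pair$perturbed)
  sel <- select_features(fb, fp, n_mc = 400L, seed = 4L)
  model <- fit_index(fb, fp, sel)
  top <- model$coefficients[1L, ]
  dominant <- names(sort(abs(top), decreasing = TRUE))[1:3]
  expect_true(all(grepl("^(COPy|VCOPy|MOS|COP_CMP)\\.", dominant)))
})

test_that("scoring: single component, centering, affinity and contracts", {
  set.seed(33)
  # rank-one structure forces a single retained component
  s <- rnorm(40)
  m <- cbind("COPy.RMS" = 0.1 + 0.01 * s,
             "COPy.Var" = 0.001 * (1 + 0.1 * s),
             "COPy.Range" = 0.2 + 0.02 * s)
  fb <- make_features(m[1:20, ], "balanced")
  fp <- make_features(m[21:40, ], "perturbed")
  sel <- structure(data.frame(feature = colnames(m), selected = TRUE),
                   class = c("wbi_selection", "data.frame"), alpha = 0.01)
  model <- suppressWarnings(fit_index(fb, fp, sel))
  expect_identical(model$n_retained, 1L)
  expect_equal(model$weights, 1)
  sc <- score_wbi(model, fb)
  z <- sweep(sweep(scale_dimensionless(fb)[, model$features], 2L,
                   model$center, `-`), 2L, model$scale, `/`)
  y1 <- as.numeric(z %*% model$coefficients[1L, ])
  expect_equal(sc$wbi, model$orientation * y1, tolerance = 1e-12)
  # pooled fitting scores are centered
  pooled <- c(score_wbi(model, fb)$wbi, score_wbi(model, fp)$wbi)
  expect_lt(abs(mean(pooled)), 1e-9)
  # affine in the standardized features: scoring a convex combination
  mix <- make_features((unclass(fb) + unclass(fp)) / 2, "mix")
  expect_equal(score_wbi(model, mix)$wbi,
               (score_wbi(model, fb)$wbi + score_wbi(model, fp)$wbi) / 2,
               tolerance = 1e-9)
  # missing feature errors by name
  short <- make_features(m[1:20, 1:2, drop = FALSE])
  expect_error(score_wbi(model, short), "COPy.Range")
})
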