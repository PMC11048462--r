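test_that("COP closed forms hold and swing samples are marked invalid", {
  expect_equal(compute_cop(0, 0, 700, 0, 0, h = 0)$COPx, 0)
  expect_equal(compute_cop(0, 0, 700, 0, 0, h = 0)$COPy, 0)
  expect_equal(compute_cop(0, 0, 700, 0, -70, h = 0)$COPx, 0.1)
  expect_equal(compute_cop(50, 0, 700, 0, 0, h = 0.02)$COPx, -1 / 700)
  # moment about x moves the lateral COP with opposite sign
  expect_equal(compute_cop(0, 0, 700, 70, 0, h = 0)$COPy, -0.1)
  low <- compute_cop(c(0, 0), c(0, 0), c(700, 10), c(0, 0), c(0, 0))
  expect_false(low$valid[2L])
  expect_true(is.na(low$COPx[2L]))
})

test_that("COP recovers an analytic trajectory from inverted forces and moments", {
  t <- (0:499) / 500
  copx <- 0.05 * sin(2 * pi * t)
  copy <- 0.02 * cos(2 * pi * t)
  fz <- 600 + 100 * sin(2 * pi * 3 * t)
  fx <- 40 * sin(2 * pi * t)
  fy <- 20 * cos(2 * pi * t)
  h <- 0.025
  my <- -h * fx - copx * fz
  mx <- h * fy - copy * fz
  out <- compute_cop(fx, fy, fz, mx, my, h = h)
  expect_lt(max(abs(out$COPx - copx)), 1e-9)
  expect_lt(max(abs(out$COPy - copy)), 1e-9)
})

test_that("finite differences match closed forms", {
  expect_equal(differentiate(rep(2, 10), 100, 1L), rep(0, 10))
  expect_equal(differentiate(rep(2, 10), 100, 2L), rep(0, 10))
  t <- (0:99) / 100
  ramp <- 3.5 * t
  expect_equal(differentiate(ramp, 100, 1L), rep(3.5, 100))
  expect_lt(max(abs(differentiate(ramp, 100, 2L)[2:99])), 1e-10)
  s <- sin(2 * pi * t)
  d <- differentiate(s, 100, 1L)
  expected <- 2 * pi * cos(2 * pi * t)
  expect_lt(max(abs(d[3:98] - expected[3:98])) / (2 * pi), 1e-3)
  expect_error(differentiate(c(1, 2), 100), "3 samples")
})

test_that("COM is the mass-weighted centroid mean", {
  one <- list(a = cbind(1:3, 4:6, 7:9))
  expect_equal(compute_com(one, c(a = 70))$COMz, 7:9)
  two <- list(a = cbind(0, 0, 0), b = cbind(0, 0, 1))
  expect_equal(compute_com(two, c(a = 1, b = 1))$COMz, 0.5)
  expect_equal(compute_com(two, c(a = 1, b = 3))$COMz, 0.75)
  expect_equal(compute_com(two, c(a = 3, b = 1))$COMz, 0.25)
  expect_error(compute_com(two, c(a = 1, b = 1), total_mass = 70),
               "body mass")
  expect_error(compute_com(two, c(a = -1, b = 1)), "positive")
})

test_that("COM acceleration norm identity and closed forms", {
  n <- 50
  com <- list(COMx = rep(1, n), COMy = rep(2, n), COMz = rep(0.9, n))
  acom <- compute_acom(com, 100)
  expect_true(all(unlist(acom) == 0))
  expect_equal(sqrt(3^2 + 4^2 + 0), 5)  # 3-4-5 via the norm used below
  t <- (0:99) / 100
  com <- list(COMx = 1.5 * t^2 / 2, COMy = 2 * t^2, COMz = rep(1, 100))
  acom <- compute_acom(com, 100)
  expect_lt(max(abs(acom$ACOMx[3:98] - 1.5)), 1e-8)
  expect_lt(max(abs(acom$ACOMy[3:98] - 4)), 1e-8)
  expect_equal(acom$ACOM^2,
               acom$ACOMx^2 + acom$ACOMy^2 + acom$ACOMz^2,
               tolerance = 1e-12)
  expect_true(all(acom$ACOM >= 0))
})

test_that("CMP and COP-CMP distance closed forms", {
  com <- list(COMx = 0.3, COMy = -0.1, COMz = 1)
  no_shear <- compute_cmp(com, 0, 0, 700)
  expect_equal(no_shear$CMPx, 0.3)
  expect_equal(no_shear$CMPy, -0.1)
  com0 <- list(COMx = 0, COMy = 0, COMz = 1)
  expect_equal(compute_cmp(com0, 70, 0, 700)$CMPx, -0.1)
  expect_equal(compute_cop_cmp(0.2, 0.1, 0.2, 0.1), 0)
  expect_equal(compute_cop_cmp(0, 3, 4, 0), 5)
  expect_true(is.na(compute_cmp(com0, 0, 0, 5)$CMPx))
})

test_that("margin of stability degenerates correctly", {
  expect_equal(compute_mos(0.1, 0, 0.04, 0, l = 1), 0.06)
  expect_equal(compute_mos(0.1, 0.3, 0.1, 0.3, l = 0.9), 0)
  # l = g makes w0 = 1 so velocities add straight in
  expect_equal(compute_mos(0.1, 0.2, 0.03, 0.05, l = 9.81, g = 9.81),
               (0.1 + 0.2) - (0.03 + 0.05))
  expect_error(compute_mos(0, 0, 0, 0, l = 0), "positive")
})

test_that("trunk angular acceleration from marker trajectories", {
  n <- 100
  pelvis <- cbind(rep(0, n), rep(0, n), rep(1, n))
  chest_up <- pelvis + cbind(0, 0, rep(0.5, n))
  expect_equal(compute_aang(pelvis, chest_up, 100)$AANG, rep(0, n))
  t <- (0:(n - 1)) / 100
  theta <- 0.3 + 2 * t^2 / 2        # angle ramps quadratically, offset > 0
  chest <- pelvis + 0.5 * cbind(sin(theta), 0, cos(theta))
  out <- compute_aang(pelvis, chest, 100)
  expect_lt(max(abs(out$AANG[5:95] - 2)), 1e-4)
  # unsigned angle: mirrored lateral sway gives the same magnitude
  sway <- 0.2 + 0.1 * sin(2 * pi * t)
  c1 <- pelvis + 0.5 * cbind(0, sin(sway), cos(sway))
  c2 <- pelvis + 0.5 * cbind(0, -sin(sway), cos(sway))
  expect_equal(compute_aang(pelvis, c1, 100)$AANG,
               compute_aang(pelvis, c2, 100)$AANG, tolerance = 1e-12)
  expect_error(compute_aang(pelvis, pelvis, 100), "coincide")
})

test_that("heel-strike detection finds the generator's stride period", {
  expect_identical(detect_heel_strikes(rep(0, 500), 100), numeric(0))
  cfg <- small_config(noise_sd = 0)
  tr <- simulate_trial(cfg)
  ev <- detect_heel_strikes(tr$grf$series$Fz, tr$grf$rate)
  expect_length(ev, cfg$n_strides)
  spacing <- diff(ev)
  expect_lt(max(abs(spacing - cfg$stride_period)), 1.5 / tr$grf$rate)
  high <- detect_heel_strikes(tr$grf$series$Fz, tr$grf$rate,
                              threshold = 2 * max(tr$grf$series$Fz))
  expect_identical(high, numeric(0))
})

test_that("stride segmentation covers consecutive event pairs", {
  times <- (0:200) / 100
  sl <- segment_strides(c(0, 1, 2), times)
  expect_length(sl, 2L)
  expect_equal(sl[[1L]], 1:100)
  expect_equal(sl[[2L]], 101:200)
  expect_length(segment_strides(c(0, 1), times), 1L)
  expect_error(segment_strides(1.5, times), "insufficient gait cycles")
  # property: n sorted events inside the grid give n-1 contiguous slices
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:8, 1L)
    ev <- 0.05 + cumsum(runif(k, 0.05, 1.9 / k))
    sl <- segment_strides(ev, times)
    expect_length(sl, length(ev) - 1L)
    idx <- unlist(sl)
    expect_identical(idx, seq(idx[1L], idx[length(idx)]))
  }
})

test_that("full metric computation matches generator ground truth", {
  cfg <- small_config()
  tr <- simulate_trial(cfg)
  met <- compute_metrics(tr)
  expect_named(met$channels, balance_metric_names())
  n <- length(met$time)
  expect_true(all(lengths(met$channels) == n))
  # Eq-6 norm identity on every sample
  expect_equal(met$channels$ACOM^2,
               met$channels$ACOMx^2 + met$channels$ACOMy^2 +
                 met$channels$ACOMz^2, tolerance = 1e-9)
  expect_true(all(met$channels$ACOM >= 0))
  expect_true(all(met$channels$COP_CMP >= 0, na.rm = TRUE))
  # COM height near the anthropometric expectation, lateral COP near zero
  expect_gt(met$aux$l, 0.4 * tr$height)
  expect_lt(met$aux$l, 0.7 * tr$height)
  # stride structure equals the generator's
  sl <- segment_strides(met$events, met$time)
  expect_length(sl, cfg$n_strides)
})
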