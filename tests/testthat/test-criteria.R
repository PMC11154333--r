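test_that("HIC handles degenerate and constant pulses in closed form", {
  t <- seq(0, 0.1, by = 1e-4)
  expect_equal(hic(rep(0, length(t)), t)$value, 0)
  # constant 10 g over 100 ms: maximised at the full 36 ms window,
  # HIC = 0.036 * 10^2.5
  h <- hic(rep(10, length(t)), t)
  expect_equal(h$value, 0.036 * 10^2.5, tolerance = 1e-9)
  expect_equal(h$t2 - h$t1, 0.036, tolerance = 1e-9)
})

test_that("accelerated HIC search equals the O(n^2) brute force bit-exactly", {
  set.seed(314)
  for (k in 1:20) {
    n <- 150 + sample(100, 1)
    t <- seq(0, by = 1e-3, length.out = n)
    # random piecewise-linear pulse
    knots <- sort(sample(n, 8))
    a <- approx(t[knots], runif(8, 0, 40), xout = t, rule = 2)$y
    fast <- hic(a, t)
    slow <- brute_force_hic(a, t)
    expect_identical(fast$value, slow$value)
    expect_identical(c(fast$t1, fast$t2), c(slow$t1, slow$t2))
  }
})

test_that("HIC is homogeneous of degree 2.5 and monotone in the window cap", {
  set.seed(99)
  t <- seq(0, 0.2, by = 1e-3)
  a <- abs(stats::filter(rnorm(length(t), 10, 5), rep(1, 5) / 5,
                         circular = TRUE))
  a <- as.numeric(a)
  h1 <- hic(a, t)$value
  for (lam in c(0.3, 2, 7.5)) {
    expect_equal(hic(lam * a, t)$value, lam^2.5 * h1, tolerance = 1e-9)
  }
  windows <- c(0.01, 0.02, 0.036, 0.05, 0.1)
  vals <- vapply(windows, function(w) hic(a, t, max_window = w)$value,
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("HIC rejects invalid inputs", {
  t <- seq(0, 0.1, by = 1e-3)
  expect_error(hic(rep(1, 50), t[1:50][c(1:49, 30)]), "uniform")
  expect_error(hic(c(rep(1, 100), -1), t), "non-negative")
  expect_error(hic(rep(1, length(t)), t, max_window = 1e-5), "sampling")
})

test_that("Nkm reproduces the normalization unit points of the printed constants", {
  n <- 50
  t <- seq(0, 0.049, by = 1e-3)
  z <- rep(0, n)
  r0 <- nkm(z, z, t)
  expect_equal(c(r0$nfa$value, r0$nfp$value, r0$nea$value, r0$nep$value),
               c(0, 0, 0, 0))
  r1 <- nkm(rep(845, n), z, t)
  expect_equal(r1$nfa$value, 1)
  expect_equal(r1$nea$value, 1)
  expect_equal(r1$nfp$value, 0)
  expect_equal(r1$nep$value, 0)
  r2 <- nkm(z, rep(88.1, n), t)
  expect_equal(r2$nfa$value, 1)
  expect_equal(r2$nfp$value, 1)
  expect_equal(r2$nea$value, 0)
  r3 <- nkm(z, rep(-47.5, n), t)
  expect_equal(r3$nep$value, 1)
  expect_equal(r3$nea$value, 1)
  expect_equal(r3$nfa$value, 0)
  # half-scale combination in the extension-posterior case
  r4 <- nkm(rep(-422.5, n), rep(-23.75, n), t)
  expect_equal(r4$nep$value, 1)
})

test_that("Nkm case maxima are gated by sign and scale with degree one", {
  set.seed(7)
  t <- seq(0, 0.3, by = 1e-3)
  Fx <- rnorm(length(t), 0, 300)
  My <- rnorm(length(t), 0, 20)
  r <- nkm(Fx, My, t)
  # invariant to appending samples where both channels vanish
  r_pad <- nkm(c(Fx, 0, 0, 0), c(My, 0, 0, 0),
               c(t, 0.301, 0.302, 0.303))
  for (cs in c("nfa", "nfp", "nea", "nep"))
    expect_equal(r_pad[[cs]]$value, r[[cs]]$value)
  # homogeneity of degree 1 under sign-preserving joint scaling
  r2 <- nkm(3 * Fx, 3 * My, t)
  for (cs in c("nfa", "nfp", "nea", "nep"))
    expect_equal(r2[[cs]]$value, 3 * r[[cs]]$value, tolerance = 1e-12)
  expect_error(nkm(Fx, My[-1]), "length")
})

test_that("HIC deviation reproduces the published headline comparison", {
  ref <- published_injury_criteria
  dev <- hic_deviation(ref$hic36[ref$model == "ENM-2D (identified)"],
                       ref$hic36[ref$model == "TNO-HBM (reference)"])
  expect_equal(round(dev, 1), 8.3)
  expect_equal(hic_deviation(42, 42), 0)
  expect_equal(hic_deviation(63.55, 127.1), -50)
  expect_error(hic_deviation(1, 0), "positive")
})

test_that("compute_criteria summarises a simulation consistently", {
  m <- build_model("V5B-final", "with_prismatic")
  motion <- pulse_to_motion(generate_pulse(12, 10 / 3.6), 0.15)
  s <- simulate_neck(m, motion, t_end = 0.15, output_rate = 2000)
  cr <- compute_criteria(s)
  expect_s3_class(cr, "criteria_result")
  expect_equal(cr$hic36, hic(s$head_acc_g, s$time)$value)
  nk <- nkm(s$oc_loads[, "Fx"], s$oc_loads[, "My"], s$time)
  expect_equal(cr$nfa, nk$nfa$value)
  expect_true(all(c(cr$hic36, cr$nfa, cr$nfp, cr$nea, cr$nep) >= 0))
  expect_lte(cr$hic_window["t2"] - cr$hic_window["t1"], 0.036 + 1e-9)
})
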