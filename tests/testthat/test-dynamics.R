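test_that("two-body chain matches the textbook double-pendulum closed form", {
  dp <- make_double_pendulum(m1 = 1.3, m2 = 0.7, l1 = 0.4, l2 = 0.25)
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    q <- runif(2, -2.5, 2.5)
    qd <- runif(2, -4, 4)
    a_impl <- assemble_eom(dp, q, qd)
    a_ref <- double_pendulum_qdd(1.3, 0.7, 0.4, 0.25, 9.81, q, qd)
    worst <- max(worst, max(abs(a_impl - a_ref) / pmax(abs(a_ref), 1)))
  }
  expect_lt(worst, 1e-9)
})

test_that("trivial chains do not accelerate", {
  # no springs, no gravity, stationary base, at rest
  dp <- make_double_pendulum(gravity = FALSE)
  expect_equal(assemble_eom(dp, c(0.3, -0.2), c(0, 0)), c(0, 0),
               tolerance = 1e-14)
  # gravity on with the build-time preload: the seated posture is equilibrium
  for (m in list(build_model("V1-initial", "baseline"),
                 build_model("V5B-final", "with_prismatic"))) {
    n <- nrow(m$joints)
    expect_lt(max(abs(assemble_eom(m, numeric(n), numeric(n)))), 1e-9)
  }
})

test_that("dimension mismatches in assemble_eom are rejected", {
  m <- build_model("V1-initial", "baseline")
  expect_error(assemble_eom(m, numeric(3), numeric(8)), "length 8")
})

test_that("zero prescribed motion leaves the posture unchanged for 300 ms", {
  m <- build_model("V1-initial", "baseline")
  s <- simulate_neck(m, motion = NULL, t_end = 0.3, output_rate = 1000)
  expect_lt(max(abs(s$q)), 1e-9)
  expect_lt(max(abs(s$qd)), 1e-7)
})

test_that("a single torsional joint oscillates at its linearized frequency", {
  # one body, inertia at the origin, symmetric small-angle stiffness
  # k = A2 B2 = A1 B1, no damping: f = sqrt(k / I) / (2 pi)
  A <- 0.6; B <- 0.4; I <- 0.002
  bodies <- data.frame(name = c("T1", "B1"), mass = c(0, 1), iyy = c(0, I),
                       sx = 0, sz = 0, gx = 0, gz = 0, theta0 = 0,
                       stringsAsFactors = FALSE)
  joints <- data.frame(body = "B1", joint = "J1", type = "revolute",
                       A1 = -A, B1 = -B, A2 = A, B2 = B, C = 0,
                       stringsAsFactors = FALSE)
  m <- make_chain_model(bodies, joints, gravity = FALSE)
  s <- simulate_neck(m, NULL, t_end = 2, output_rate = 10000, q0 = 1e-3)
  th <- s$q[, 1]
  crossings <- which(diff(sign(th)) != 0)
  period <- 2 * mean(diff(s$time[crossings]))
  f_expected <- sqrt(A * B / I) / (2 * pi)
  expect_equal(1 / period, f_expected, tolerance = 0.01)
})

test_that("total energy is conserved without damping under a stationary base", {
  m <- build_model("V1-initial", "baseline")
  m$joints$C <- 0
  m <- whipneck:::.compute_preload(m)
  q0 <- c(-0.3, 0.1, -0.05, 0.2, 0, -0.1, 0.05, 0.25)
  s <- simulate_neck(m, NULL, t_end = 0.3, output_rate = 1000, q0 = q0)
  tv <- s$energy[, "kinetic"] + s$energy[, "potential"]
  expect_lt(max(abs(tv - tv[1])) / max(abs(tv[1]), max(s$energy[, "kinetic"])),
            1e-6)
  # and nothing was dissipated or fed in
  expect_lt(max(abs(s$energy[, "dissipated"])), 1e-12)
  expect_lt(max(abs(s$energy[, "work"])), 1e-9)
})

test_that("the work-energy ledger balances for damped base-excited runs", {
  motion <- pulse_to_motion(generate_pulse(12, 10 / 3.6), 0.3)
  for (m in list(build_model("V1-initial", "baseline"),
                 build_model("V5B-final", "with_prismatic"))) {
    s <- simulate_neck(m, motion, t_end = 0.3, output_rate = 1000)
    expect_lt(energy_residual(s), 1e-5)
    expect_true(all(diff(s$energy[, "dissipated"]) >= 0))
  }
})

test_that("repeated runs are bit-identical", {
  m <- build_model("V5B-final", "with_prismatic")
  motion <- pulse_to_motion(generate_pulse(12, 10 / 3.6), 0.15)
  s1 <- simulate_neck(m, motion, t_end = 0.15, output_rate = 2000)
  s2 <- simulate_neck(m, motion, t_end = 0.15, output_rate = 2000)
  expect_identical(s1$q, s2$q)
  expect_identical(s1$qdd, s2$qdd)
  expect_identical(s1$oc_loads, s2$oc_loads)
})

test_that("the recovered T1 trajectory equals the prescribed motion exactly", {
  m <- build_model("V1-initial", "baseline")
  motion <- pulse_to_motion(generate_pulse(12, 10 / 3.6), 0.2, grid_dt = 1e-3)
  s <- simulate_neck(m, motion, t_end = 0.2, output_rate = 1000)
  # output times coincide with the motion knots: imposed, not integrated
  expect_equal(s$base[, "x"], m$base$origin[1] + motion$x, tolerance = 1e-14)
  expect_equal(s$base[, "z"], m$base$origin[2] + motion$z, tolerance = 1e-14)
})

test_that("relative-coordinate and absolute-coordinate formulations agree", {
  set.seed(202)
  for (variant in c("baseline", "with_prismatic")) {
    m <- build_model("V1-initial", variant)
    n <- nrow(m$joints)
    worst <- 0
    for (k in 1:25) {
      q <- rnorm(n, 0, 0.2)
      qd <- rnorm(n, 0, 2)
      if (variant == "with_prismatic") {
        q[8] <- rnorm(1, 0, 0.01); qd[8] <- rnorm(1, 0, 0.1)
      }
      base <- c(0, 0, 0, rnorm(2, 0, 50), rnorm(2, 0, 2))
      qdd <- whipneck:::.eom_qdd_cpp(whipneck:::.model_cpars(m), q, qd, base)
      orc <- lagrange_oracle(m, q, qd, base)
      worst <- max(worst, max(abs(qdd - orc$qdd) / pmax(abs(qdd), 1)))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("simulation validates its inputs", {
  m <- build_model("V1-initial", "baseline")
  motion <- pulse_to_motion(generate_pulse(12, 10 / 3.6), 0.1)
  expect_error(simulate_neck(m, motion, t_end = 0.3), "covers only")
  expect_error(simulate_neck(m, motion, t_end = -1), "positive")
  expect_error(simulate_neck(m, motion, t_end = 0.1, output_rate = 0),
               "positive")
})
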