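ref_cache <- new.env()
v1_reference <- function() {
  if (is.null(ref_cache$ref)) {
    truth <- build_model("V1-initial", "baseline")
    motion <- pulse_to_motion(generate_pulse(12, 10 / 3.6), 0.3)
    ref_cache$truth <- truth
    ref_cache$ref <- generate_reference(truth, motion, t_end = 0.3,
                                        output_rate = 1000)
  }
  list(truth = ref_cache$truth, ref = ref_cache$ref)
}

test_that("rms_deviation matches closed forms and resamples across grids", {
  x <- sin(seq(0, 1, by = 1e-3))
  expect_equal(rms_deviation(x, x), 0)
  expect_equal(rms_deviation(rep(0.02, 100), rep(0, 100)), 0.02)
  # full periods of a unit sinusoid: RMS = 1/sqrt(2)
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  expect_equal(rms_deviation(sin(2 * pi * 5 * t), rep(0, length(t))),
               1 / sqrt(2), tolerance = 1e-12)
  # linear resampling onto the reference grid
  ts <- seq(0, 1, by = 0.01); tr <- seq(0, 1, by = 0.0037)
  expect_equal(rms_deviation(2 * ts, 2 * tr, time_sim = ts, time_ref = tr),
               0, tolerance = 1e-12)
  expect_error(rms_deviation(1:5, 1:6), "length")
  expect_error(rms_deviation(1:5, 1:5, time_sim = 1:5, time_ref = 11:15),
               "overlap")
})

test_that("the design vector enumerates 40 (42 with prismatic) bounded parameters", {
  dv <- design_vector(build_model("V1-initial", "baseline"))
  expect_equal(nrow(dv), 40)
  dv2 <- design_vector(build_model("V5B-final", "with_prismatic"))
  expect_equal(nrow(dv2), 42)
  expect_true(all(c("prismatic.kv", "prismatic.cv") %in% dv2$id))
  expect_true(all(dv2$lower <= dv2$value & dv2$value <= dv2$upper))
  # the 25% box, oriented correctly for negative values
  neg <- dv2$value < 0
  expect_equal(dv2$lower[neg], dv2$value[neg] * 1.25)
  expect_equal(dv2$upper[!neg], dv2$value[!neg] * 1.25)
})

test_that("schedule presets transcribe the published step structure", {
  s3 <- schedule_preset("bottom-up")
  expect_length(s3$sequences, 4)
  for (sq in s3$sequences) {
    expect_length(sq, 8)
    expect_equal(vapply(sq, `[[`, character(1), "objective"),
                 c("C7", "C6", "C5", "C4", "C3", "C2", "C1", "C0"))
  }
  expect_equal(s3$sequences[[1]][[1]]$variables,
               c("C7/T1.A2", "C7/T1.B2", "C7/T1.C"))
  expect_equal(s3$sequences[[1]][[2]]$variables,
               c("C6/C7.A1", "C6/C7.B1", "C6/C7.C"))
  expect_equal(s3$sequences[[1]][[8]]$variables,
               c("C0/C1.A1", "C0/C1.B1", "C0/C1.B2", "C0/C1.C"))
  expect_equal(s3$sequences[[3]][[5]]$variables, c("C3/C4.A2", "C3/C4.B2"))
  s4 <- schedule_preset("modified")
  expect_length(s4$sequences, 1)
  steps <- s4$sequences[[1]]
  expect_equal(vapply(steps, `[[`, character(1), "objective"),
               c("OC", "OC", "OC", "C0"))
  expect_equal(lengths(lapply(steps, `[[`, "variables")), c(6, 8, 1, 2))
  expect_equal(steps[[3]]$variables, "kv")
})

test_that("an identification step started at the truth stays at the truth", {
  vr <- v1_reference()
  res <- identify_step(vr$truth, vr$ref, "C7",
                       c("C7/T1.A1", "C7/T1.B1", "C7/T1.C"))
  expect_lt(res$rms, 1e-8)
  expect_lte(res$rms, res$rms0 + 1e-12)
  truth_vals <- vapply(res$variables, whipneck:::.get_param, numeric(1),
                       model = vr$truth)
  expect_equal(unname(res$par), unname(truth_vals), tolerance = 1e-3)
})

test_that("each step is monotone in its own objective and respects the box", {
  vr <- v1_reference()
  start <- vr$truth
  for (v in c("C7/T1.A1", "C7/T1.C", "C6/C7.C"))
    start <- whipneck:::.set_param(start, v,
                                   whipneck:::.get_param(vr$truth, v) * 1.15)
  res <- identify_step(start, vr$ref, "C7",
                       c("C7/T1.A1", "C7/T1.B1", "C7/T1.C"))
  expect_lte(res$rms, res$rms0)
  start_vals <- vapply(res$variables, whipneck:::.get_param, numeric(1),
                       model = start)
  expect_true(all(res$par >= pmin(start_vals * 0.75, start_vals * 1.25) - 1e-12))
  expect_true(all(res$par <= pmax(start_vals * 0.75, start_vals * 1.25) + 1e-12))
})

test_that("damping and exercised-branch stiffness of the lowest joints are recoverable", {
  vr <- v1_reference()
  vars <- c("C7/T1.A1", "C7/T1.B1", "C7/T1.C", "C6/C7.C")
  fac <- c(0.9, 1.1, 0.9, 1.1)
  start <- vr$truth
  for (i in seq_along(vars))
    start <- whipneck:::.set_param(
      start, vars[i], whipneck:::.get_param(vr$truth, vars[i]) * fac[i])
  sched <- list(list(objective = "C7", variables = vars[1:3]),
                list(objective = "C6", variables = vars[4]))
  res <- sequential_identify(start, vr$ref, sched, max_sequences = 2)
  # the scheduled objectives improve (others may shift: the schedule only
  # touches the two lowest joints)
  expect_true(all(res$trace[2, c("C7", "C6")] <=
                    res$trace[1, c("C7", "C6")] + 1e-12))
  get <- function(m, v) whipneck:::.get_param(m, v)
  expect_equal(get(res$model, "C7/T1.C"), 1.8, tolerance = 0.05)
  expect_equal(get(res$model, "C6/C7.C"), 1.8, tolerance = 0.05)
  # individual A/B are sloppy along the product valley; the linearized
  # extension stiffness A1*B1 is the identifiable combination
  k_rec <- get(res$model, "C7/T1.A1") * get(res$model, "C7/T1.B1")
  k_true <- -0.3105 * -0.6489
  expect_equal(k_rec, k_true, tolerance = 0.05)
})

test_that("sequential identification converges immediately on a self-reference", {
  vr <- v1_reference()
  sched <- list(list(objective = "C7",
                     variables = c("C7/T1.A1", "C7/T1.B1", "C7/T1.C")),
                list(objective = "C0",
                     variables = c("C0/C1.A1", "C0/C1.C")))
  res <- sequential_identify(vr$truth, vr$ref, sched, max_sequences = 3)
  expect_equal(res$sequences_run, 1)
  expect_true(res$converged)
  expect_equal(nrow(res$trace), 2)
  expect_lt(max(res$trace[2, ]), 1e-6)
})

test_that("sensitivity analysis is local, deterministic and zero at zero perturbation", {
  vr <- v1_reference()
  start <- whipneck:::.set_param(vr$truth, "C7/T1.C", 1.8 * 1.1)
  vars <- c("C7/T1.C", "C4/C5.C", "C0/C1.C")
  s0 <- sensitivity_analysis(start, vr$ref, perturbation = 0,
                             variables = vars)
  expect_true(all(abs(as.matrix(s0[, 2:9])) < 1e-12))
  s1 <- sensitivity_analysis(start, vr$ref, variables = vars)
  s2 <- sensitivity_analysis(start, vr$ref, variables = vars)
  expect_identical(s1, s2)
  expect_false(any(s1$failed))
  # a joint's parameters influence the bodies above it far more than the
  # bodies below it
  mid <- abs(as.matrix(s1[s1$id == "C4/C5.C", 2:9]))
  expect_lt(mid[, "C7"], mid[, "C4"])
  expect_lt(mid[, "C7"], mid[, "C0"])
  top <- abs(as.matrix(s1[s1$id == "C0/C1.C", 2:9]))
  expect_lt(top[, "C7"], 0.1 * top[, "C0"])
})
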