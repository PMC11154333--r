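test_that("presets load with the published coefficients in SI units", {
  m <- build_model("V1-initial", "baseline")
  expect_equal(m$bodies$name,
               c("T1", "C7", "C6", "C5", "C4", "C3", "C2", "C1", "C0"))
  # hand-summed mass column (excluding any massless auxiliary body)
  expect_equal(sum(m$bodies$mass), 7.18, tolerance = 1e-12)
  j <- joint_params(m, "C7/T1")
  expect_equal(j$A2, 0.6084)
  expect_equal(j$B2, 0.3949)
  expect_equal(j$C, 1.8)
  expect_true(all(m$joints$C == 1.8))
  # mm -> m and deg -> rad conversion applied at build
  expect_equal(m$bodies$sz[m$bodies$name == "C0"], 0.021)
  expect_equal(m$bodies$theta0[1], -26 * pi / 180)
  # head CG vertical offset interpreted as 43 mm
  expect_equal(m$bodies$gz[m$bodies$name == "C0"], 0.043)

  v5 <- build_model("V5B-final", "with_prismatic")
  expect_equal(joint_params(v5, "C0/C1")$C, 2.954)
  expect_equal(v5$prismatic$kv, 1620)
  expect_equal(v5$prismatic$cv, 100)
  expect_equal(sum(v5$bodies$mass[v5$bodies$name != "Ca"]), 7.18,
               tolerance = 1e-12)
  expect_equal(v5$bodies$mass[v5$bodies$name == "Ca"], 0)
  expect_equal(v5$bodies$name,
               c("T1", "C7", "C6", "C5", "C4", "C3", "C2", "C1", "Ca", "C0"))
  expect_equal(sqrt(sum(v5$prismatic$axis^2)), 1, tolerance = 1e-12)
})

test_that("coefficient sign pattern holds for every joint in both presets", {
  for (m in list(build_model("V1-initial", "baseline"),
                 build_model("V5B-final", "with_prismatic"))) {
    j <- m$joints[m$joints$type == "revolute", ]
    expect_true(all(j$A1 < 0))
    expect_true(all(j$B1 < 0))
    expect_true(all(j$A2 > 0))
    expect_true(all(j$B2 > 0))
    expect_true(all(j$C >= 0))
  }
})

test_that("invalid preset/variant combinations are rejected", {
  expect_error(build_model("V5B-final", "baseline"), "with_prismatic")
  expect_error(build_model("nonsense"), "arg")
})

test_that("prismatic variant inserts Ca with the initial prismatic trial values", {
  m <- build_model("V1-initial", "with_prismatic")
  expect_equal(m$prismatic$kv, 10000)
  expect_equal(m$prismatic$cv, 100)
  i_ca <- which(m$bodies$name == "Ca")
  expect_equal(m$bodies$name[i_ca + 1L], "C0")
  expect_equal(m$joints$type[m$joints$body == "Ca"], "prismatic")
  # the relocated head revolute joint keeps its torsional parameters
  expect_equal(joint_params(m, "C0/C1")$A2, 0.0135)
  # Ca shares C1's orientation; the head origin coincides with Ca's
  expect_equal(m$bodies$theta0[i_ca],
               m$bodies$theta0[m$bodies$name == "C1"])
  fk <- forward_kinematics(m, numeric(9))
  fk0 <- forward_kinematics(build_model("V1-initial", "baseline"), numeric(8))
  expect_equal(fk[fk$name == "C0", -1], fk0[fk0$name == "C0", -1],
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unlist(fk[fk$name == "Ca", c("x_origin", "z_origin")]),
               unlist(fk[fk$name == "C0", c("x_origin", "z_origin")]),
               ignore_attr = TRUE)
})

test_that("forward kinematics reproduces the initial posture at q = 0", {
  m <- build_model("V1-initial", "baseline")
  fk <- forward_kinematics(m, numeric(8))
  expect_equal(fk$angle_rad[fk$name == "T1"], -26 * pi / 180)
  expect_equal(fk$angle_rad[fk$name == "C0"], -13 * pi / 180)
  expect_equal(fk$angle_rad[fk$name == "C6"], -23 * pi / 180)
  expect_equal(unlist(fk[fk$name == "T1", c("x_origin", "z_origin")]),
               c(x_origin = 0.004, z_origin = 0.019))
})

test_that("perturbing the lowest joint rotates every upper body by the same angle", {
  m <- build_model("V1-initial", "baseline")
  delta <- 0.137
  fk0 <- forward_kinematics(m, numeric(8))
  fk1 <- forward_kinematics(m, c(delta, numeric(7)))
  upper <- fk0$name != "T1"
  expect_equal(fk1$angle_rad[upper] - fk0$angle_rad[upper],
               rep(delta, sum(upper)))
  expect_equal(fk1$angle_rad[!upper], fk0$angle_rad[!upper])
})

test_that("forward kinematics is translation-equivariant", {
  m <- build_model("V5B-final", "with_prismatic")
  q <- seq(-0.2, 0.2, length.out = 9); q[8] <- 0.005
  shift <- c(0.37, -0.12)
  fk0 <- forward_kinematics(m, q)
  fk1 <- forward_kinematics(m, q, base_disp = shift)
  expect_equal(fk1$x_origin, fk0$x_origin + shift[1])
  expect_equal(fk1$z_origin, fk0$z_origin + shift[2])
  expect_equal(fk1$x_cg, fk0$x_cg + shift[1])
  expect_equal(fk1$angle_rad, fk0$angle_rad)
})

test_that("forward kinematics rejects a coordinate vector of the wrong length", {
  m <- build_model("V1-initial", "baseline")
  expect_error(forward_kinematics(m, numeric(5)), "length 8")
})

test_that("model config round-trips exactly through the config file", {
  for (m in list(build_model("V1-initial", "baseline"),
                 build_model("V5B-final", "with_prismatic"))) {
    f <- tempfile(fileext = ".yaml")
    write_model_config(m, f)
    m2 <- read_model_config(f)
    expect_identical(m2$bodies, m$bodies)
    expect_identical(m2$joints[c("A1", "B1", "A2", "B2", "C")],
                     m$joints[c("A1", "B1", "A2", "B2", "C")])
    expect_identical(m2$prismatic, m$prismatic)
    expect_identical(m2$preload, m$preload)
    unlink(f)
  }
})

test_that("the generalized mass matrix is positive definite despite massless Ca", {
  m <- build_model("V5B-final", "with_prismatic")
  M <- whipneck:::.mass_matrix_r(m, numeric(9))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(M, t(M), tolerance = 1e-12)
})
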