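# Forward dynamics: compiled equations of motion in relative joint
# coordinates, integrated with an adaptive Dormand-Prince Runge-Kutta 4(5)
# scheme (deSolve), plus occipital-condyle load recovery.

# Flatten a neck_model into the argument list consumed by the compiled core.
.model_cpars <- function(model) {
  b <- model$bodies[-1L, , drop = FALSE]   # moving bodies only
  j <- model$joints
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  p <- model$prismatic
  list(
    n = nrow(j),
    mass = b$mass, iyy = b$iyy,
    sx = b$sx, sz = b$sz, gx = b$gx, gz = b$gz,
    theta0 = b$theta0,
    A1 = zero_na(j$A1), B1 = zero_na(j$B1),
    A2 = zero_na(j$A2), B2 = zero_na(j$B2), C = zero_na(j$C),
    preload = model$preload,
    jtype = as.integer(j$type == "prismatic"),
    kv = if (is.null(p)) 0 else p$kv,
    cv = if (is.null(p)) 0 else p$cv,
    axx = if (is.null(p)) 0 else p$axis[1],
    axz = if (is.null(p)) 0 else p$axis[2],
    g = model$g,
    th_base0 = model$base$theta0
  )
}

#' Evaluate the equations of motion
#'
#' Solves `M(q) qdd = Q(q, qd, t)` for the joint accelerations at one state.
#' Generalized coordinates are the relative joint rotations (rad) measured
#' from the initial posture, plus the prismatic elongation (m) when present;
#' the prescribed T1 motion enters as support excitation.
#'
#' @param model a `neck_model`.
#' @param q,qd joint coordinates and velocities.
#' @param t time at which to evaluate the prescribed motion, s.
#' @param motion a [prescribed_motion()], or `NULL` for a stationary base.
#' @return Numeric vector of joint accelerations `qdd`.
#' @export
assemble_eom <- function(model, q, qd, t = 0, motion = NULL) {
  stopifnot(inherits(model, "neck_model"))
  n <- nrow(model$joints)
  if (length(q) != n || length(qd) != n)
    stop(sprintf("q and qd must have length %d", n))
  base <- if (is.null(motion)) numeric(7) else .motion_base(motion, t)
  .eom_qdd_cpp(.model_cpars(model), as.numeric(q), as.numeric(qd),
               as.numeric(base))
}

#' Simulate the chain under prescribed T1 motion
#'
#' Integrates the equations of motion over `[0, t_end]` from the initial
#' posture at rest, with dense output on a uniform grid.  Accelerations and
#' all derived channels (head kinematics, occipital-condyle loads, energy
#' ledger) are obtained by evaluating the equations of motion at the output
#' times, not by differencing.
#'
#' @param model a `neck_model`.
#' @param motion a [prescribed_motion()] covering at least `[0, t_end]`, or
#'   `NULL` for a stationary base.
#' @param t_end simulation end time, s.
#' @param output_rate output sampling rate, Hz (default 10 kHz).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @param q0,qd0 optional initial joint coordinates/velocities (default at
#'   rest in the initial posture).
#' @return An object of class `neck_sim`: a list with the output `time` grid,
#'   matrices `q`, `qd`, `qdd` (one column per joint), `body_angle` (absolute
#'   angles, one column per moving body), head CG position and acceleration
#'   channels (`head_acc_g` is the resultant in g), occipital-condyle
#'   position `oc_pos` and loads `oc_loads` (Fx, Fz in the head frame, N; My,
#'   Nm), the base trajectory, and the `energy` ledger (kinetic, potential,
#'   cumulative dissipation, cumulative support work, J).
#' @export
simulate_neck <- function(model, motion = NULL, t_end = 0.3,
                          output_rate = 10000, rtol = 1e-8, atol = 1e-10,
                          q0 = NULL, qd0 = NULL) {
  stopifnot(inherits(model, "neck_model"))
  if (t_end <= 0) stop("t_end must be positive")
  if (output_rate <= 0) stop("output_rate must be positive")
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "prescribed_motion"))
    if (motion$span[2] < t_end - 1e-12)
      stop(sprintf("motion covers only up to %g s but t_end = %g s",
                   motion$span[2], t_end))
  }
  n <- nrow(model$joints)
  if (is.null(q0)) q0 <- numeric(n)
  if (is.null(qd0)) qd0 <- numeric(n)
  stopifnot(length(q0) == n, length(qd0) == n)

  cp <- .model_cpars(model)
  times <- seq(0, t_end, by = 1 / output_rate)
  if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
  y0 <- c(q0, qd0, 0, 0)

  .eom_set_model_cpp(cp, .motion_cpp(motion))
  sol <- deSolve::ode(y = y0, times = times, func = "whipneck_rhs",
                      parms = NULL, dllname = "whipneck", initfunc = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop(sprintf("integration failed near t = %g s (step-size collapse)",
                 sol[nrow(sol), 1]))
  Y <- unname(sol[, -1L, drop = FALSE])

  if (is.null(motion)) {
    B <- matrix(0, length(times), 9)
  } else {
    B <- .motion_base_matrix(motion, times)
  }
  B[, 8] <- B[, 8] + model$base$origin[1]
  B[, 9] <- B[, 9] + model$base$origin[2]

  ch <- .eom_channels_cpp(cp, Y, B)
  k <- 2 * n
  moving <- model$bodies$name[-1L]
  qm <- Y[, seq_len(n), drop = FALSE]
  qdm <- Y[, n + seq_len(n), drop = FALSE]
  qddm <- ch[, seq_len(n), drop = FALSE]
  colnames(qm) <- colnames(qdm) <- colnames(qddm) <- moving
  ang <- ch[, n + seq_len(n), drop = FALSE]
  colnames(ang) <- moving

  structure(list(
    time = times,
    q = qm, qd = qdm, qdd = qddm,
    body_angle = ang,
    head_cg = cbind(x = ch[, k + 1], z = ch[, k + 2]),
    head_acc = cbind(ax = ch[, k + 3], az = ch[, k + 4], ares = ch[, k + 5]),
    head_acc_g = ch[, k + 5] / 9.81,
    oc_pos = cbind(x = ch[, k + 6], z = ch[, k + 7]),
    oc_loads = cbind(Fx = ch[, k + 8], Fz = ch[, k + 9], My = ch[, k + 10]),
    base = cbind(x = B[, 8], z = B[, 9], theta = model$base$theta0 + B[, 1]),
    energy = cbind(kinetic = ch[, k + 11], potential = ch[, k + 12],
                   dissipated = Y[, 2 * n + 1], work = Y[, 2 * n + 2]),
    model = model,
    settings = list(output_rate = output_rate, rtol = rtol, atol = atol)
  ), class = "neck_sim")
}

#' Occipital-condyle loads of a simulation
#'
#' Returns the joint reaction at the occipital condyles, recovered during
#' channel evaluation by inverse dynamics of the head body alone
#' (Newton--Euler on the head using its CG and angular accelerations):
#' anterior shear `Fx` and normal force `Fz` in the head local frame (N) and
#' the internal moment `My` (Nm, positive flexion) transmitted at the OC
#' joint.
#'
#' @param result a `neck_sim` from [simulate_neck()].
#' @return Data frame with columns `time_s`, `Fx_N`, `Fz_N`, `My_Nm`.
#' @export
oc_loads <- function(result) {
  stopifnot(inherits(result, "neck_sim"))
  if (is.null(result$oc_loads)) stop("missing acceleration channels")
  data.frame(time_s = result$time,
             Fx_N = result$oc_loads[, "Fx"],
             Fz_N = result$oc_loads[, "Fz"],
             My_Nm = result$oc_loads[, "My"])
}

#' Energy-balance residual of a simulation
#'
#' Work--energy check: `(T + V) - (T + V)(0)` must equal
#' `W_prescribed - D_damping` at every output time.  The residual is
#' normalised by the peak energy turnover of the run.
#'
#' @param result a `neck_sim`.
#' @return Maximum normalised residual (dimensionless).
#' @export
energy_residual <- function(result) {
  stopifnot(inherits(result, "neck_sim"))
  e <- result$energy
  tv <- e[, "kinetic"] + e[, "potential"]
  lhs <- tv - tv[1]
  rhs <- e[, "work"] - e[, "dissipated"]
  scale <- max(abs(lhs), abs(rhs), max(e[, "kinetic"]), 1e-12)
  max(abs(lhs - rhs)) / scale
}

#' @export
print.neck_sim <- function(x, ...) {
  cat(sprintf("<neck_sim> %s/%s, %d samples over [0, %g] s\n",
              x$model$preset, x$model$variant, length(x$time),
              x$time[length(x$time)]))
  cat(sprintf("  peak head acceleration %.2f g; peak |OC Fx| %.1f N; peak |OC My| %.2f Nm\n",
              max(x$head_acc_g), max(abs(x$oc_loads[, "Fx"])),
              max(abs(x$oc_loads[, "My"]))))
  cat(sprintf("  energy-balance residual %.2e\n", energy_residual(x)))
  invisible(x)
}

#' Simulation result as a channel table
#'
#' Flattens a `neck_sim` into the channel-CSV layout used by
#' [write_channels()]: `time_s` first, then one column per channel with the
#' unit in the name.
#'
#' @param x a `neck_sim`.
#' @param ... unused.
#' @export
as.data.frame.neck_sim <- function(x, ...) {
  moving <- colnames(x$body_angle)
  d <- data.frame(time_s = x$time)
  for (b in moving) d[[paste0(b, "_angle_rad")]] <- x$body_angle[, b]
  d$headCG_x_m <- x$head_cg[, "x"]
  d$headCG_z_m <- x$head_cg[, "z"]
  d$headCG_ax_mps2 <- x$head_acc[, "ax"]
  d$headCG_az_mps2 <- x$head_acc[, "az"]
  d$headCG_ares_g <- x$head_acc_g
  d$OC_x_m <- x$oc_pos[, "x"]
  d$OC_z_m <- x$oc_pos[, "z"]
  d$OC_Fx_N <- x$oc_loads[, "Fx"]
  d$OC_Fz_N <- x$oc_loads[, "Fz"]
  d$OC_My_Nm <- x$oc_loads[, "My"]
  d$T1_x_m <- x$base[, "x"]
  d$T1_z_m <- x$base[, "z"]
  d$energy_kin_J <- x$energy[, "kinetic"]
  d$energy_pot_J <- x$energy[, "potential"]
  d$energy_diss_J <- x$energy[, "dissipated"]
  d$energy_work_J <- x$energy[, "work"]
  d
}
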