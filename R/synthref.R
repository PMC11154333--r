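# Synthetic reference generation: parametric crash pulses, their double
# integration into a prescribed T1 motion, and reference kinematics produced
# by simulating a model with known ("true") parameters.  This stands in for
# the proprietary reference occupant simulation so the identification
# pipeline can be exercised end to end against ground truth.

#' Generate a parametric crash pulse
#'
#' Builds a sled acceleration pulse with a prescribed peak and velocity
#' change.  The haversine shape is `a(t) = peak * sin^2(pi (t - onset) / T)`
#' with the closed-form duration `T = 2 delta_v / (peak * 9.81)`; the
#' trapezoid shape uses symmetric ramps covering a fraction `ramp` of the
#' duration on each side.  The default scenario of interest is the LAB
#' rear-impact sled pulse, 12 g with delta-V = 10 km/h.
#'
#' @param peak peak acceleration, g.
#' @param delta_v velocity change, m/s.
#' @param shape `"haversine"` or `"trapezoid"`.
#' @param onset pulse onset time, s.
#' @param grid_dt time step of the stored series, s.
#' @param ramp trapezoid ramp fraction per side (ignored for haversine).
#' @return An object of class `crash_pulse`: time grid (starting at 0,
#'   extending one step past the pulse), acceleration series (m/s^2), and the
#'   shape parameters.
#' @export
generate_pulse <- function(peak, delta_v, shape = c("haversine", "trapezoid"),
                           onset = 0, grid_dt = 1e-4, ramp = 0.25) {
  shape <- match.arg(shape)
  if (delta_v < 0 || onset < 0 || grid_dt <= 0)
    stop("delta_v and onset must be non-negative, grid_dt positive")
  if (delta_v == 0) {
    time <- seq(0, max(onset, 10 * grid_dt), by = grid_dt)
    return(structure(list(shape = shape, peak = peak, delta_v = 0,
                          onset = onset, duration = 0, time = time,
                          acceleration = numeric(length(time))),
                     class = "crash_pulse"))
  }
  if (peak <= 0) stop("peak must be positive for a nonzero delta_v")
  a_peak <- peak * 9.81
  duration <- switch(shape,
    haversine = 2 * delta_v / a_peak,
    trapezoid = delta_v / (a_peak * (1 - ramp)))
  if (!is.finite(duration) || duration <= 0)
    stop("infeasible pulse: non-positive duration")
  t_end <- onset + duration
  time <- seq(0, t_end + grid_dt, by = grid_dt)
  tt <- time - onset
  acc <- switch(shape,
    haversine = ifelse(tt > 0 & tt < duration,
                       a_peak * sin(pi * tt / duration)^2, 0),
    trapezoid = {
      r <- ramp * duration
      ifelse(tt <= 0 | tt >= duration, 0,
        ifelse(tt < r, a_peak * tt / r,
          ifelse(tt > duration - r, a_peak * (duration - tt) / r, a_peak)))
    })
  structure(list(shape = shape, peak = peak, delta_v = delta_v,
                 onset = onset, duration = duration, time = time,
                 acceleration = acc, ramp = if (shape == "trapezoid") ramp),
            class = "crash_pulse")
}

#' @export
print.crash_pulse <- function(x, ...) {
  cat(sprintf("<crash_pulse> %s, peak %.3g g, delta-V %.4g m/s, duration %.4g s (onset %.3g s)\n",
              x$shape, x$peak, x$delta_v, x$duration, x$onset))
  invisible(x)
}

#' Integrate a crash pulse into a prescribed T1 motion
#'
#' Double-integrates the platform acceleration into the anterior displacement
#' of T1 (z displacement stays zero): `x(0) = xdot(0) = 0`, x monotone
#' nondecreasing, and after the pulse the velocity is constant at `delta_v`.
#' For the haversine shape the integrals are evaluated in closed form; other
#' shapes use cumulative trapezoidal quadrature on the pulse grid.
#'
#' @param pulse a [generate_pulse()] result.
#' @param t_end coverage required of the motion, s (extended past the pulse
#'   at constant velocity).
#' @param grid_dt sampling step of the motion record, s.
#' @return A [prescribed_motion()].
#' @export
pulse_to_motion <- function(pulse, t_end = 0.3, grid_dt = 1e-4) {
  stopifnot(inherits(pulse, "crash_pulse"))
  if (t_end < max(pulse$time)) stop("t_end must cover the pulse span")
  time <- seq(0, t_end, by = grid_dt)
  if (time[length(time)] < t_end - 1e-12) time <- c(time, t_end)
  if (pulse$delta_v == 0)
    return(prescribed_motion(time, numeric(length(time))))
  if (pulse$shape == "haversine") {
    ap <- pulse$peak * 9.81
    Td <- pulse$duration
    tt <- pmin(pmax(time - pulse$onset, 0), Td)
    # v(t) = ap/2 * (t - T/(2 pi) sin(2 pi t / T)); x = its integral
    x_in <- ap / 2 * (tt^2 / 2 + (Td / (2 * pi))^2 * (cos(2 * pi * tt / Td) - 1))
    v_end <- ap * Td / 2
    x <- x_in + v_end * pmax(time - pulse$onset - Td, 0)
  } else {
    # cumulative trapezoid twice on the pulse grid, then constant velocity
    pt <- pulse$time; pa <- pulse$acceleration
    dtp <- diff(pt)
    v <- c(0, cumsum((pa[-length(pa)] + pa[-1]) / 2 * dtp))
    xp <- c(0, cumsum((v[-length(v)] + v[-1]) / 2 * dtp))
    v_end <- v[length(v)]
    x <- ifelse(time <= max(pt),
                stats::approx(pt, xp, xout = pmin(time, max(pt)))$y,
                xp[length(xp)] + v_end * (time - max(pt)))
  }
  prescribed_motion(time, x)
}

#' Generate synthetic reference kinematics from a known model
#'
#' Simulates `true_model` under `motion` and extracts the identification
#' target channels: per-body absolute angles (rad) and the occipital-point
#' displacement relative to the moving T1 origin (m), optionally with
#' independent seeded Gaussian noise per channel.  The generating parameters
#' and seed are recorded as metadata.
#'
#' @param true_model a `neck_model` (the ground truth).
#' @param motion a [prescribed_motion()].
#' @param t_end simulated span, s.
#' @param output_rate reference sampling rate, Hz.
#' @param noise_sd either a single standard deviation applied to every
#'   channel, or a named list with `angle` (rad) and `oc` (m) entries.
#' @param seed integer seed for the noise generator.
#' @return An object of class `reference_kinematics`: `time`, matrix `angle`
#'   (one column per moving vertebra/head), matrix `oc` (columns x, z), and
#'   `meta` (true model, seed, noise levels).
#' @export
generate_reference <- function(true_model, motion, t_end = 0.3,
                               output_rate = 1000, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(true_model, "neck_model"))
  sim <- simulate_neck(true_model, motion, t_end = t_end,
                       output_rate = output_rate)
  keep <- setdiff(colnames(sim$body_angle), "Ca")
  ang <- sim$body_angle[, keep, drop = FALSE]
  oc <- cbind(x = sim$oc_pos[, "x"] - sim$base[, "x"],
              z = sim$oc_pos[, "z"] - sim$base[, "z"])
  if (is.numeric(noise_sd) && length(noise_sd) == 1L)
    noise_sd <- list(angle = noise_sd, oc = noise_sd)
  if (noise_sd$angle > 0 || noise_sd$oc > 0) {
    rng <- .seeded_rng(seed)
    if (noise_sd$angle > 0)
      ang <- ang + matrix(rng(length(ang)) * noise_sd$angle, nrow(ang))
    if (noise_sd$oc > 0)
      oc <- oc + matrix(rng(length(oc)) * noise_sd$oc, nrow(oc))
  }
  structure(list(
    time = sim$time, angle = ang, oc = oc,
    motion = motion,
    meta = list(preset = true_model$preset, variant = true_model$variant,
                seed = seed, noise_sd = noise_sd,
                true_joints = true_model$joints,
                true_prismatic = true_model$prismatic)
  ), class = "reference_kinematics")
}

# Local RNG stream: draws standard normals without touching the global
# .Random.seed state.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}

#' @export
print.reference_kinematics <- function(x, ...) {
  cat(sprintf("<reference_kinematics> %d samples, %d angle channels + OC x/z\n",
              length(x$time), ncol(x$angle)))
  cat(sprintf("  generated from %s/%s (seed %d, angle noise %g rad)\n",
              x$meta$preset, x$meta$variant, x$meta$seed,
              x$meta$noise_sd$angle))
  invisible(x)
}
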