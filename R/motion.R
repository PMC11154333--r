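# Prescribed T1 base motion: a time-gridded displacement record with a
# twice-differentiable interpolation contract.  Velocities and accelerations
# are taken from the cubic-spline interpolant, never from raw differencing.

#' Prescribed T1 base motion
#'
#' Packages a T1 displacement time history (the support excitation of the
#' chain) as natural cubic-spline interpolants.  Displacements must start at
#' zero at `t = 0`; velocity and acceleration are obtained from the spline.
#' The optional rotation channel holds the absolute T1 angle over time; by
#' default the T1 orientation is constant at its initial posture value.
#'
#' @param time strictly increasing time grid, s (must start at 0).
#' @param x anterior displacement of the T1 origin, m.
#' @param z superior displacement of the T1 origin, m (default all zero).
#' @param rotation optional absolute T1 angle channel, rad.
#' @return An object of class `prescribed_motion`.
#' @export
prescribed_motion <- function(time, x, z = NULL, rotation = NULL) {
  time <- as.numeric(time); x <- as.numeric(x)
  if (length(time) < 4L) stop("motion needs at least 4 samples")
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  if (length(x) != length(time)) stop("x and time lengths differ")
  if (is.null(z)) z <- numeric(length(time))
  if (length(z) != length(time)) stop("z and time lengths differ")
  if (abs(time[1]) > 1e-12) stop("motion must start at t = 0")
  if (abs(x[1]) > 1e-12 || abs(z[1]) > 1e-12)
    stop("displacements must start at 0 at t = 0")
  if (!is.null(rotation) && length(rotation) != length(time))
    stop("rotation and time lengths differ")
  structure(list(
    time = time, x = x, z = z, rotation = rotation,
    sx = .spline_rep(time, x),
    sz = .spline_rep(time, z),
    sr = if (is.null(rotation)) NULL else .spline_rep(time, rotation),
    span = range(time),
    interpolation = "natural cubic spline"
  ), class = "prescribed_motion")
}

# Natural-spline piecewise-polynomial representation (knots, values and the
# b/c/d coefficients of stats::splinefun), the single source of truth shared
# by the R-side evaluator below and the compiled right-hand side.
.spline_rep <- function(time, value) {
  z <- environment(stats::splinefun(time, value, method = "natural"))$z
  list(x = z$x, y = z$y, b = z$b, c = z$c, d = z$d)
}

# Evaluate a .spline_rep: the boundary cubic inside the knot span, linear
# extrapolation with the boundary slope outside (matching the compiled
# evaluator exactly).
.spline_eval <- function(s, t, deriv = 0L) {
  n <- length(s$x)
  i <- pmin(pmax(findInterval(t, s$x), 1L), n - 1L)
  dx <- t - s$x[i]
  out <- if (deriv == 0L) s$y[i] + dx * (s$b[i] + dx * (s$c[i] + dx * s$d[i]))
         else if (deriv == 1L) s$b[i] + dx * (2 * s$c[i] + 3 * s$d[i] * dx)
         else 2 * s$c[i] + 6 * s$d[i] * dx
  lo <- t < s$x[1]; hi <- t > s$x[n]
  if (any(lo)) out[lo] <- switch(deriv + 1L,
                                 s$y[1] + s$b[1] * (t[lo] - s$x[1]),
                                 rep(s$b[1], sum(lo)), rep(0, sum(lo)))
  if (any(hi)) out[hi] <- switch(deriv + 1L,
                                 s$y[n] + s$b[n] * (t[hi] - s$x[n]),
                                 rep(s$b[n], sum(hi)), rep(0, sum(hi)))
  out
}

# Base-motion state at scalar time t, as the 7-vector consumed by the
# compiled right-hand side: (th_off, w, al, ax, az, vx, vz).
.motion_base <- function(motion, t) {
  if (is.null(motion$sr)) {
    c(0, 0, 0,
      .spline_eval(motion$sx, t, 2L), .spline_eval(motion$sz, t, 2L),
      .spline_eval(motion$sx, t, 1L), .spline_eval(motion$sz, t, 1L))
  } else {
    r0 <- motion$rotation[1]
    c(.spline_eval(motion$sr, t) - r0,
      .spline_eval(motion$sr, t, 1L), .spline_eval(motion$sr, t, 2L),
      .spline_eval(motion$sx, t, 2L), .spline_eval(motion$sz, t, 2L),
      .spline_eval(motion$sx, t, 1L), .spline_eval(motion$sz, t, 1L))
  }
}

# Base-motion channel matrix over a time vector: columns
# th_off, w, al, ax, az, vx, vz, x_disp, z_disp.
.motion_base_matrix <- function(motion, times) {
  n <- length(times)
  if (is.null(motion$sr)) {
    th <- numeric(n); w <- numeric(n); al <- numeric(n)
  } else {
    th <- .spline_eval(motion$sr, times) - motion$rotation[1]
    w <- .spline_eval(motion$sr, times, 1L)
    al <- .spline_eval(motion$sr, times, 2L)
  }
  cbind(th, w, al,
        .spline_eval(motion$sx, times, 2L), .spline_eval(motion$sz, times, 2L),
        .spline_eval(motion$sx, times, 1L), .spline_eval(motion$sz, times, 1L),
        .spline_eval(motion$sx, times), .spline_eval(motion$sz, times))
}

# Spline representation bundle for the compiled integrator.
.motion_cpp <- function(motion) {
  if (is.null(motion)) return(NULL)
  list(x = motion$sx, z = motion$sz,
       rot = motion$sr,
       rot0 = if (is.null(motion$sr)) 0 else motion$rotation[1])
}

#' @export
print.prescribed_motion <- function(x, ...) {
  cat(sprintf("<prescribed_motion> %d samples over [%g, %g] s\n",
              length(x$time), x$span[1], x$span[2]))
  cat(sprintf("  peak |x| = %.4g m, peak |z| = %.4g m, rotation %s\n",
              max(abs(x$x)), max(abs(x$z)),
              if (is.null(x$rotation)) "constant" else "prescribed"))
  invisible(x)
}
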