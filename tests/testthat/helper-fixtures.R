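# Fixture model builders (bypass the anthropometric validation so that
# reduced chains and disabled springs can be constructed for oracle tests).

make_chain_model <- function(bodies, joints, prismatic = NULL,
                             base_origin = c(0, 0), base_theta0 = 0,
                             gravity = FALSE, g = 9.81, preload = TRUE) {
  m <- structure(list(
    preset = "fixture", variant = if (is.null(prismatic)) "baseline" else "with_prismatic",
    bodies = bodies, joints = joints, prismatic = prismatic,
    base = list(origin = base_origin, theta0 = base_theta0),
    gravity = gravity, g = if (gravity) g else 0,
    preload = numeric(nrow(joints))
  ), class = "neck_model")
  if (gravity && preload) m <- whipneck:::.compute_preload(m)
  m
}

# Planar double pendulum as a 2-body chain: point masses m1, m2 at rod
# lengths l1, l2, pivoted at the base origin, hanging along -z at q = 0.
make_double_pendulum <- function(m1 = 1.3, m2 = 0.7, l1 = 0.4, l2 = 0.25,
                                 gravity = TRUE) {
  bodies <- data.frame(
    name = c("T1", "B1", "B2"),
    mass = c(0, m1, m2), iyy = c(0, 0, 0),
    sx = c(0, 0, 0), sz = c(0, 0, -l1),
    gx = c(0, 0, 0), gz = c(0, -l1, -l2),
    theta0 = c(0, 0, 0), stringsAsFactors = FALSE)
  joints <- data.frame(
    body = c("B1", "B2"), joint = c("J1", "J2"),
    type = "revolute",
    A1 = 0, B1 = -1, A2 = 0, B2 = 1, C = 0, stringsAsFactors = FALSE)
  make_chain_model(bodies, joints, gravity = gravity, preload = FALSE)
}

# Closed-form double-pendulum joint accelerations (textbook absolute-angle
# form, angles measured from the downward vertical), mapped to the chain's
# relative coordinates.  Independent of the package's dynamics assembly.
double_pendulum_qdd <- function(m1, m2, l1, l2, g, q, qd) {
  th1 <- q[1]; th2 <- q[1] + q[2]
  w1 <- qd[1]; w2 <- qd[1] + qd[2]
  # pendulum angles from the downward vertical: phi = -theta_absolute
  p1 <- -th1; p2 <- -th2
  v1 <- -w1; v2 <- -w2
  A <- matrix(c((m1 + m2) * l1, m2 * l2 * cos(p1 - p2),
                m2 * l1 * cos(p1 - p2), m2 * l2), 2, 2, byrow = TRUE)
  b <- c(-m2 * l2 * v2^2 * sin(p1 - p2) - (m1 + m2) * g * sin(p1),
         m2 * l1 * v1^2 * sin(p1 - p2) - m2 * g * sin(p2))
  pa <- solve(A, b)
  a1 <- -pa[1]; a2 <- -pa[2]          # back to chain absolute angles
  c(a1, a2 - a1)                      # relative joint accelerations
}
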