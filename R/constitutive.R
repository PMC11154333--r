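# Constitutive laws of the joint elements.
#
# Each revolute joint carries a nonlinear torsional spring
#   M(theta) = A (exp(theta * B) - 1)
# with separate (A1, B1) extension (theta < 0) and (A2, B2) flexion
# (theta >= 0) branches, plus a linear torsional damper C.  The rotation
# theta is the relative joint rotation measured from the initial posture, so
# all spring moments vanish at the start of a run.  The prismatic C1--Ca
# element is a linear spring--damper along its axis.

#' Torsional spring moment of a joint
#'
#' Evaluates the exponential moment--rotation law on the branch selected by
#' the sign of the relative rotation: extension (`theta < 0`) uses `A1`/`B1`,
#' flexion (`theta >= 0`) uses `A2`/`B2`.  The law is continuous and zero at
#' `theta = 0` and monotonically increasing on each branch.
#'
#' @param params one joint row: a list or one-row data frame with fields
#'   `A1`, `B1` (Nm, dimensionless; both negative), `A2`, `B2` (positive).
#' @param theta_rel relative joint rotation from the initial posture, rad
#'   (vectorized).
#' @return Applied moment, Nm.
#' @examples
#' j <- joint_params(build_model("V1-initial", "baseline"), "C7/T1")
#' spring_moment(j, c(-0.1, 0, 0.1))
#' @export
spring_moment <- function(params, theta_rel) {
  stopifnot(is.finite(theta_rel))
  ifelse(theta_rel < 0,
         params$A1 * (exp(theta_rel * params$B1) - 1),
         params$A2 * (exp(theta_rel * params$B2) - 1))
}

#' Torsional damper moment magnitude
#'
#' Linear viscous law `C * theta_dot`: the magnitude of the resisting moment,
#' applied with sign opposing the relative rotation rate.
#'
#' @param params joint row with damping field `C` (Nms/rad).
#' @param theta_dot relative rotation rate, rad/s (vectorized).
#' @return Resisting moment magnitude, Nm.
#' @export
damper_moment <- function(params, theta_dot) {
  stopifnot(is.finite(theta_dot))
  abs(params$C * theta_dot)
}

#' Translational element restoring force
#'
#' Linear spring--damper force of the prismatic C1--Ca element,
#' `kv * e + cv * e_dot`, opposing the elongation `e` measured from the
#' initial O_C1 to O_Ca separation, directed along the prismatic axis.
#'
#' @param params list with `kv` (N/m) and `cv` (Ns/m), e.g.
#'   `model$prismatic`.
#' @param elongation elongation from the initial separation, m.
#' @param elongation_rate elongation rate, m/s.
#' @return Restoring force magnitude along the axis, N.
#' @export
translational_force <- function(params, elongation, elongation_rate = 0) {
  params$kv * elongation + params$cv * elongation_rate
}

#' Extract one joint's torsional parameters
#'
#' @param model a `neck_model`.
#' @param joint joint label, e.g. `"C7/T1"` or `"C0/C1"`.
#' @return One-row data frame with `A1`, `B1`, `A2`, `B2`, `C`.
#' @export
joint_params <- function(model, joint) {
  stopifnot(inherits(model, "neck_model"))
  i <- which(model$joints$joint == joint & model$joints$type == "revolute")
  if (length(i) != 1L)
    stop(sprintf("unknown revolute joint '%s'", joint))
  model$joints[i, c("A1", "B1", "A2", "B2", "C")]
}

# Torsional spring potential energy (integral of the moment from 0), J.
.spring_energy <- function(params, theta_rel) {
  A <- ifelse(theta_rel < 0, params$A1, params$A2)
  B <- ifelse(theta_rel < 0, params$B1, params$B2)
  ifelse(theta_rel == 0, 0, A * ((exp(B * theta_rel) - 1) / B - theta_rel))
}
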