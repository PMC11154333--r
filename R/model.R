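# Model assembly and kinematics for the planar head--neck chain.
#
# Conventions: global X anterior (direction of the sled acceleration),
# Z superior, rotation about +Y; flexion (forward rotation) is a positive
# relative joint rotation, extension negative.  The local-to-global planar
# rotation is v_g = R(theta) v_l with R(theta) = [cos, sin; -sin, cos] acting
# on (x, z).  Internally everything is SI (m, kg, s, rad).

.deg2rad <- function(x) x * pi / 180

# rotate local (x, z) into the global frame
.rotv <- function(th, v) {
  c(cos(th) * v[1] + sin(th) * v[2],
    -sin(th) * v[1] + cos(th) * v[2])
}

# d/dtheta of .rotv
.drotv <- function(th, v) {
  c(-sin(th) * v[1] + cos(th) * v[2],
    -cos(th) * v[1] - sin(th) * v[2])
}

.joint_of_body <- c(
  C7 = "C7/T1", C6 = "C6/C7", C5 = "C5/C6", C4 = "C4/C5",
  C3 = "C3/C4", C2 = "C2/C3", C1 = "C1/C2", C0 = "C0/C1"
)

#' Build a head--neck chain model from a named preset
#'
#' Assembles the planar multibody chain T1, C7..C1, (Ca,) C0 with its
#' torsional joint springs and dampers and, for the modified variant, the
#' prismatic spring--damper between C1 and the massless auxiliary body Ca.
#'
#' Two presets are available: `"V1-initial"`, the initial model carrying the
#' experimental moment--rotation coefficients and a constant joint damping of
#' 1.8 Nms/rad (with trial prismatic values kv = 10 kN/m, cv = 100 Ns/m when
#' `variant = "with_prismatic"`), and `"V5B-final"`, the identified modified
#' model (final coefficients, kv = 1620 N/m, cv = 100 Ns/m), which requires
#' the prismatic variant.
#'
#' When `gravity = TRUE` constant joint preload moments are computed at build
#' time so that the initial seated posture is a static equilibrium; disabling
#' gravity also disables the preload.
#'
#' @param preset `"V1-initial"` or `"V5B-final"`.
#' @param variant `"baseline"` (revolute joints only) or `"with_prismatic"`
#'   (massless body Ca and translational spring--damper between C1 and Ca,
#'   with the head revolute joint relocated onto Ca).
#' @param gravity logical; include gravity and the balancing joint preloads.
#' @param g gravitational acceleration magnitude in m/s^2.
#' @return An object of class `neck_model`.
#' @examples
#' m <- build_model("V1-initial", "baseline")
#' sum(m$bodies$mass)      # 7.18 kg
#' @export
build_model <- function(preset = c("V1-initial", "V5B-final"),
                        variant = c("baseline", "with_prismatic"),
                        gravity = TRUE, g = 9.81) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  if (preset == "V5B-final" && variant != "with_prismatic")
    stop("preset 'V5B-final' is a modified model: use variant = 'with_prismatic'")

  bt <- .body_table
  bodies <- data.frame(
    name = bt$name,
    mass = bt$mass_kg,
    iyy = bt$iyy_kgm2,
    sx = bt$sx_mm / 1000, sz = bt$sz_mm / 1000,
    gx = bt$gx_mm / 1000, gz = bt$gz_mm / 1000,
    theta0 = .deg2rad(bt$theta0_deg),
    stringsAsFactors = FALSE
  )

  jt <- if (preset == "V1-initial") .joint_table_initial else .joint_table_final
  joints <- data.frame(
    body = bodies$name[-1],
    joint = unname(.joint_of_body[bodies$name[-1]]),
    type = "revolute",
    stringsAsFactors = FALSE
  )
  joints <- cbind(joints, jt[match(joints$joint, jt$joint), c("A1", "B1", "A2", "B2", "C")])
  rownames(joints) <- NULL

  prismatic <- NULL
  if (variant == "with_prismatic") {
    # Massless auxiliary body Ca: same orientation as C1, origin initially
    # coincident with the head origin O_C0, so the relocated C0 revolute
    # joint keeps its initial position and the prismatic axis is the unit
    # direction from O_C1 to O_Ca in C1's local frame.
    i_c0 <- which(bodies$name == "C0")
    s_c0 <- c(bodies$sx[i_c0], bodies$sz[i_c0])
    axis <- s_c0 / sqrt(sum(s_c0^2))
    ca <- data.frame(name = "Ca", mass = 0, iyy = 0,
                     sx = s_c0[1], sz = s_c0[2], gx = 0, gz = 0,
                     theta0 = bodies$theta0[bodies$name == "C1"],
                     stringsAsFactors = FALSE)
    bodies <- rbind(bodies[seq_len(i_c0 - 1), ], ca, bodies[i_c0, ])
    bodies$sx[bodies$name == "C0"] <- 0
    bodies$sz[bodies$name == "C0"] <- 0
    rownames(bodies) <- NULL
    pj <- data.frame(body = "Ca", joint = "C1/Ca", type = "prismatic",
                     A1 = NA_real_, B1 = NA_real_, A2 = NA_real_,
                     B2 = NA_real_, C = NA_real_, stringsAsFactors = FALSE)
    i_j <- which(joints$body == "C0")
    joints <- rbind(joints[seq_len(i_j - 1), ], pj, joints[i_j, ])
    rownames(joints) <- NULL
    pv <- if (preset == "V1-initial") .prismatic_initial else .prismatic_final
    prismatic <- list(kv = pv$kv_N_per_m, cv = pv$cv_Ns_per_m, axis = axis)
  }

  model <- structure(list(
    preset = preset, variant = variant,
    bodies = bodies, joints = joints, prismatic = prismatic,
    base = list(origin = .base_origin_mm / 1000,
                theta0 = .deg2rad(bt$theta0_deg[bt$name == "T1"])),
    gravity = gravity, g = if (gravity) g else 0,
    preload = numeric(nrow(joints))
  ), class = "neck_model")

  model <- .compute_preload(model)
  .validate_model(model)
  model
}

# Constant generalized preload forces balancing gravity at the initial posture.
.compute_preload <- function(model) {
  n <- nrow(model$joints)
  if (!model$gravity || model$g == 0) {
    model$preload <- numeric(n)
    return(model)
  }
  kin <- .neck_kinematics(model, numeric(n))
  gvec <- c(0, -model$g)
  qg <- numeric(n)
  for (i in seq_len(n)) {
    mi <- model$bodies$mass[i + 1L]
    if (mi > 0) qg <- qg + mi * drop(gvec %*% kin$Jcg[[i]])
  }
  model$preload <- -qg
  model
}

.validate_model <- function(model) {
  b <- model$bodies
  stopifnot(b$name[1] == "T1", b$sx[1] == 0, b$sz[1] == 0)
  massless_ok <- b$mass > 0 | b$name == "Ca"
  if (!all(massless_ok)) stop("only Ca may be massless")
  core <- b$name != "Ca"
  if (abs(sum(b$mass[core]) - 7.18) > 5e-4)
    stop("total chain mass (excluding Ca) must be 7.18 kg")
  j <- model$joints[model$joints$type == "revolute", ]
  if (!all(j$A1 < 0 & j$B1 < 0 & j$A2 > 0 & j$B2 > 0 & j$C >= 0))
    stop("torsional coefficient sign pattern violated (need A1<0, B1<0, A2>0, B2>0, C>=0)")
  if (!is.null(model$prismatic)) {
    p <- model$prismatic
    stopifnot(p$kv > 0, p$cv >= 0)
    if (abs(sqrt(sum(p$axis^2)) - 1) > 1e-12) stop("prismatic axis must be a unit vector")
  }
  # generalized mass matrix must be nonsingular despite the massless body
  M <- .mass_matrix_r(model, numeric(nrow(model$joints)))
  if (rcond(M) < 1e-12) stop("singular generalized mass matrix: invalid massless configuration")
  invisible(model)
}

# Chain kinematics in R: absolute angles, origins, CGs and their Jacobians
# with respect to the joint coordinates.  Base displacement/rotation default
# to zero; positions are global (base origin included).  Used for preload
# computation, forward_kinematics() and as a cross-check of the compiled path.
.neck_kinematics <- function(model, q, base_disp = c(0, 0), base_rot = 0) {
  b <- model$bodies
  jn <- model$joints
  n <- nrow(jn)
  stopifnot(length(q) == n)
  rev_mask <- jn$type == "revolute"
  th_base <- model$base$theta0 + base_rot
  crot <- cumsum(ifelse(rev_mask, q, 0))

  theta <- numeric(n)
  O <- matrix(0, 2, n)
  CG <- matrix(0, 2, n)
  JO <- vector("list", n)
  Jcg <- vector("list", n)
  O_prev <- model$base$origin + base_disp
  J_prev <- matrix(0, 2, n)
  anc_prev <- rep(FALSE, n)   # revolute coords contributing to parent angle
  th_prev <- th_base

  for (i in seq_len(n)) {
    v <- c(b$sx[i + 1L], b$sz[i + 1L])
    Ji <- J_prev
    if (jn$type[i] == "prismatic") {
      ax <- model$prismatic$axis
      v <- v + q[i] * ax
      Ji[, i] <- Ji[, i] + .rotv(th_prev, ax)
    }
    if (any(anc_prev)) {
      dv <- .drotv(th_prev, v)
      Ji[, anc_prev] <- Ji[, anc_prev] + dv
    }
    Oi <- O_prev + .rotv(th_prev, v)
    anc_i <- anc_prev
    if (rev_mask[i]) anc_i[i] <- TRUE
    th_i <- b$theta0[i + 1L] + crot[i]
    gi <- c(b$gx[i + 1L], b$gz[i + 1L])
    Jcg_i <- Ji
    if (any(anc_i) && any(gi != 0)) {
      dg <- .drotv(th_i, gi)
      Jcg_i[, anc_i] <- Jcg_i[, anc_i] + dg
    }
    theta[i] <- th_i
    O[, i] <- Oi
    CG[, i] <- Oi + .rotv(th_i, gi)
    JO[[i]] <- Ji
    Jcg[[i]] <- Jcg_i

    O_prev <- Oi
    J_prev <- Ji
    anc_prev <- anc_i
    th_prev <- th_i
  }
  list(theta = theta, O = O, CG = CG, JO = JO, Jcg = Jcg,
       rev_mask = rev_mask, anc = NULL)
}

# Generalized mass matrix assembled from the R-side Jacobians.
.mass_matrix_r <- function(model, q) {
  kin <- .neck_kinematics(model, q)
  n <- nrow(model$joints)
  M <- matrix(0, n, n)
  anc <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (kin$rev_mask[i]) anc[i] <- TRUE
    mi <- model$bodies$mass[i + 1L]
    Ii <- model$bodies$iyy[i + 1L]
    if (mi > 0) M <- M + mi * crossprod(kin$Jcg[[i]])
    if (Ii > 0) M <- M + Ii * tcrossprod(as.numeric(anc))
  }
  M
}

#' Forward kinematics of the chain
#'
#' Computes the global pose (origin, CG position, absolute angle) of every
#' body for a given joint-coordinate vector.  Joint coordinates are relative
#' rotations (rad) measured from the initial posture, plus the prismatic
#' elongation (m) when the model carries the translational element; `q = 0`
#' reproduces the initial posture (absolute body angles equal to the preset's
#' initial-angle column).
#'
#' @param model a `neck_model`.
#' @param q numeric joint-coordinate vector (one entry per joint, chain order
#'   bottom-up).
#' @param base_disp translation of the T1 origin from its initial global
#'   position, m.
#' @param base_rot rotation of T1 from its initial absolute angle, rad.
#' @return A data frame with one row per body (T1 first) and columns `name`,
#'   `x_origin`, `z_origin`, `x_cg`, `z_cg`, `angle_rad` (SI units).
#' @export
forward_kinematics <- function(model, q, base_disp = c(0, 0), base_rot = 0) {
  stopifnot(inherits(model, "neck_model"))
  n <- nrow(model$joints)
  if (length(q) != n)
    stop(sprintf("q must have length %d (one coordinate per joint), got %d",
                 n, length(q)))
  kin <- .neck_kinematics(model, q, base_disp = base_disp, base_rot = base_rot)
  base_o <- model$base$origin + base_disp
  th_b <- model$base$theta0 + base_rot
  b <- model$bodies
  g_t1 <- .rotv(th_b, c(b$gx[1], b$gz[1]))
  data.frame(
    name = b$name,
    x_origin = c(base_o[1], kin$O[1, ]),
    z_origin = c(base_o[2], kin$O[2, ]),
    x_cg = c(base_o[1] + g_t1[1], kin$CG[1, ]),
    z_cg = c(base_o[2] + g_t1[2], kin$CG[2, ]),
    angle_rad = c(th_b, kin$theta),
    stringsAsFactors = FALSE
  )
}

#' @export
print.neck_model <- function(x, ...) {
  cat(sprintf("<neck_model> preset %s, variant %s\n", x$preset, x$variant))
  cat(sprintf("  %d bodies (chain: %s)\n", nrow(x$bodies),
              paste(x$bodies$name, collapse = " -> ")))
  cat(sprintf("  %d joint coordinates; gravity %s (g = %g m/s^2)\n",
              nrow(x$joints), if (x$gravity) "on" else "off", x$g))
  if (!is.null(x$prismatic))
    cat(sprintf("  prismatic C1-Ca: kv = %g N/m, cv = %g Ns/m\n",
                x$prismatic$kv, x$prismatic$cv))
  invisible(x)
}
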