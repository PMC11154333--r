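# Independent oracles used by the dynamics and criteria tests.

rot2 <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
drot2 <- function(th) matrix(c(-sin(th), -cos(th), cos(th), -sin(th)), 2, 2)
cross2y <- function(a, b) a[2] * b[1] - a[1] * b[2]

# Full-chain Lagrange-multiplier formulation in absolute body coordinates
# (x_cg, z_cg, theta per moving body): solves the saddle system
#   [ M  -Phi_q^T ] [ a      ]   [ F_applied ]
#   [ Phi_q   0   ] [ lambda ] = [ gamma_c   ]
# for the absolute accelerations and the joint constraint forces.  This is
# an independent route to the accelerations and to the occipital-condyle
# reaction (the constraint force of the head joint).  Supports prescribed
# base translation (base = output of whipneck:::.motion_base); base rotation
# must be constant.
lagrange_oracle <- function(model, q, qd, base = numeric(7)) {
  stopifnot(all(base[1:3] == 0))
  b <- model$bodies              # T1 first; body i of the chain is row i + 1
  jn <- model$joints
  n <- nrow(jn)
  kin <- whipneck:::.neck_kinematics(model, q)
  rev_mask <- jn$type == "revolute"
  thd <- cumsum(ifelse(rev_mask, qd, 0))          # absolute angular velocity
  vel <- matrix(base[6:7], 2, n)                  # CG velocities
  for (i in seq_len(n)) vel[, i] <- vel[, i] + kin$Jcg[[i]] %*% qd

  th0b <- model$base$theta0
  nb3 <- 3L * n
  idx <- function(i) (3L * (i - 1L) + 1L):(3L * i)  # (x, z, th) of body i

  Mdiag <- numeric(nb3)
  Fap <- numeric(nb3)
  for (i in seq_len(n)) {
    Mdiag[idx(i)] <- c(b$mass[i + 1L], b$mass[i + 1L], b$iyy[i + 1L])
    Fap[idx(i)[2]] <- -b$mass[i + 1L] * model$g
  }

  nc <- 2L * n
  Phi <- matrix(0, nc, nb3)
  gam <- numeric(nc)
  lam_rows <- vector("list", n)

  for (i in seq_len(n)) {
    rows <- (2L * (i - 1L) + 1L):(2L * i)
    lam_rows[[i]] <- rows
    p <- i - 1L
    if (jn$type[i] == "revolute") {
      u_i <- -c(b$gx[i + 1L], b$gz[i + 1L])       # CG -> own origin, local
      Ri <- rot2(kin$theta[i]); dRi <- drot2(kin$theta[i])
      Phi[rows, idx(i)[1:2]] <- -diag(2)
      Phi[rows, idx(i)[3]] <- -dRi %*% u_i
      if (p >= 1L) {
        a_p <- c(b$sx[i + 1L] - b$gx[p + 1L], b$sz[i + 1L] - b$gz[p + 1L])
        Rp <- rot2(kin$theta[p]); dRp <- drot2(kin$theta[p])
        Phi[rows, idx(p)[1:2]] <- diag(2)
        Phi[rows, idx(p)[3]] <- dRp %*% a_p
        gam[rows] <- thd[p]^2 * (Rp %*% a_p) - thd[i]^2 * (Ri %*% u_i)
      } else {
        gam[rows] <- -base[4:5] - thd[i]^2 * (Ri %*% u_i)
      }
    } else {
      # prismatic Ca: same orientation as the parent and the perpendicular
      # offset from the axis line fixed in the parent frame
      stopifnot(p >= 1L)
      u <- model$prismatic$axis
      nrm <- c(-u[2], u[1])
      G1 <- c(b$gx[p + 1L], b$gz[p + 1L])
      th1 <- kin$theta[p]; w1 <- thd[p]
      R1 <- rot2(th1); dR1 <- drot2(th1)
      # w = O_Ca - O_C1 with O_Ca = r_cg,Ca (G_Ca = 0), O_C1 = r_cg,C1 - R1 G1
      w_vec <- drop(kin$CG[, i] - (kin$CG[, p] - R1 %*% G1))
      wd <- drop(vel[, i] - vel[, p] + w1 * (dR1 %*% G1))
      # row A: equal orientation
      Phi[rows[1], idx(i)[3]] <- 1
      Phi[rows[1], idx(p)[3]] <- -1
      gam[rows[1]] <- 0
      # row B: n^T R1^T w = const
      Phi[rows[2], idx(i)[1:2]] <- drop(t(nrm) %*% t(R1))
      Phi[rows[2], idx(p)[1:2]] <- -drop(t(nrm) %*% t(R1))
      Phi[rows[2], idx(p)[3]] <- drop(t(nrm) %*% (t(dR1) %*% w_vec + t(R1) %*% dR1 %*% G1))
      gam[rows[2]] <- -drop(t(nrm) %*%
        (-t(R1) %*% w_vec * w1^2 + 2 * w1 * t(dR1) %*% wd -
           w1^2 * G1 * 1))       # R1^T R1 = I for the G1 term
    }
  }

  # applied joint moments and the prismatic spring force
  for (i in seq_len(n)) {
    p <- i - 1L
    if (jn$type[i] == "revolute") {
      Mint <- model$preload[i] -
        whipneck::spring_moment(jn[i, ], q[i]) - jn$C[i] * qd[i]
      Fap[idx(i)[3]] <- Fap[idx(i)[3]] + Mint
      if (p >= 1L) Fap[idx(p)[3]] <- Fap[idx(p)[3]] - Mint
    } else {
      f <- model$preload[i] - model$prismatic$kv * q[i] -
        model$prismatic$cv * qd[i]
      u_hat <- drop(rot2(kin$theta[p]) %*% model$prismatic$axis)
      O_ca <- kin$CG[, i]                          # G_Ca = 0
      Fap[idx(i)[1:2]] <- Fap[idx(i)[1:2]] + f * u_hat
      Fap[idx(p)[1:2]] <- Fap[idx(p)[1:2]] - f * u_hat
      Fap[idx(p)[3]] <- Fap[idx(p)[3]] +
        cross2y(O_ca - kin$CG[, p], -f * u_hat)
    }
  }

  K <- rbind(cbind(diag(Mdiag, nb3), -t(Phi)),
             cbind(Phi, matrix(0, nc, nc)))
  sol <- solve(K, c(Fap, gam))
  acc <- matrix(sol[seq_len(nb3)], 3L)
  lambda <- sol[-seq_len(nb3)]

  # relative joint accelerations back from the absolute ones
  alpha <- acc[3, ]
  qdd <- numeric(n)
  for (i in seq_len(n)) {
    p <- i - 1L
    if (jn$type[i] == "revolute") {
      qdd[i] <- alpha[i] - if (p >= 1L) alpha[p] else 0
    } else {
      # axial elongation acceleration: u^T d2/dt2 [R1^T w]
      u <- model$prismatic$axis
      G1 <- c(b$gx[p + 1L], b$gz[p + 1L])
      th1 <- kin$theta[p]; w1 <- thd[p]
      R1 <- rot2(th1); dR1 <- drot2(th1)
      w_vec <- drop(kin$CG[, i] - (kin$CG[, p] - R1 %*% G1))
      wd <- drop(vel[, i] - vel[, p] + w1 * (dR1 %*% G1))
      wdd <- drop(acc[1:2, i] - acc[1:2, p] + alpha[p] * (dR1 %*% G1) -
                    w1^2 * (R1 %*% G1))
      qdd[i] <- drop(t(u) %*% (-t(R1) %*% w_vec * w1^2 +
                                 t(dR1) %*% (alpha[p] * w_vec + 2 * w1 * wd) +
                                 t(R1) %*% wdd))
    }
  }

  head_rows <- lam_rows[[n]]
  list(acc = acc, qdd = qdd,
       F_oc_global = -lambda[head_rows])
}

# O(n^2) exhaustive HIC window search (trapezoidal integration), the brute
# force the accelerated implementation must match bit-exactly.
brute_force_hic <- function(a, time, max_window = 0.036) {
  n <- length(a)
  h <- time[2] - time[1]
  I <- c(0, cumsum((a[-n] + a[-1]) / 2 * h))
  best <- 0; bt <- c(time[1], time[2])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- time[j] - time[i]
      if (w > max_window + 1e-9) break
      v <- w * ((I[j] - I[i]) / w)^2.5
      if (v > best) { best <- v; bt <- c(time[i], time[j]) }
    }
  }
  list(value = best, t1 = bt[1], t2 = bt[2])
}
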