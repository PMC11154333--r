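# Built-in parameter presets for the ENM-2D head--neck chain.
#
# All preset tables are stored in the units they are conventionally reported
# in (mm, deg, Nm, Nms/rad); build_model() converts to SI at assembly time.

# Mass/inertia and initial posture of the bodies.  `sx`/`sz` locate a body's
# origin O_i in the local frame of the body below it; `gx`/`gz` locate the CG
# in the body's own frame; `theta0` is the initial absolute angle with the
# horizontal.  The head CG vertical offset is 43 mm (the source table typesets
# it in metres, 0.043).
.body_table <- data.frame(
  name   = c("T1", "C7", "C6", "C5", "C4", "C3", "C2", "C1", "C0"),
  mass_kg = c(0.86, 0.22, 0.24, 0.23, 0.23, 0.24, 0.25, 0.22, 4.69),
  ixx_kgm2 = c(0.010, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.018),
  iyy_kgm2 = c(0.010, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.024),
  izz_kgm2 = c(0.020, 0.002, 0.002, 0.002, 0.002, 0.002, 0.002, 0.002, 0.017),
  sx_mm  = c(0,  7,  6,  3,  2, -1, -2,  2, -2),
  sz_mm  = c(0, 17, 17, 17, 18, 18, 19, 16, 21),
  gx_mm  = c(0, -8.2, -8.3, -8.1, -7.9, -7.8, -7.7, -7.7, 27),
  gz_mm  = c(0,  0,    0,    0,    0,    0,    0,    0,   43),
  theta0_deg = c(-26, -26, -23, -17, -12, -7, -7, -7, -13),
  stringsAsFactors = FALSE
)

# Torsional joint coefficients, initial estimate (experimental moment-rotation
# curves; damping constant 1.8 Nms/rad at every joint).
.joint_table_initial <- data.frame(
  joint = c("C0/C1", "C1/C2", "C2/C3", "C3/C4",
            "C4/C5", "C5/C6", "C6/C7", "C7/T1"),
  A1 = c(-0.0095, -0.0095, -0.0037, -0.0068, -0.0027, -0.0126, -0.0125, -0.3105),
  B1 = c(-0.3937, -0.3937, -1.0137, -1.1416, -1.6410, -0.9581, -1.2366, -0.6489),
  A2 = c(0.0135, 0.0135, 0.1029, 0.0218, 0.1130, 0.0618, 0.1406, 0.6084),
  B2 = c(0.3052, 0.3052, 0.4714, 0.7503, 0.3929, 0.5587, 0.5607, 0.3949),
  C  = rep(1.8, 8),
  stringsAsFactors = FALSE
)

# Torsional joint coefficients of the identified modified model (V5B).
.joint_table_final <- data.frame(
  joint = c("C0/C1", "C1/C2", "C2/C3", "C3/C4",
            "C4/C5", "C5/C6", "C6/C7", "C7/T1"),
  A1 = c(-0.0071, -0.0095, -0.0037, -0.0068, -0.0027, -0.01225, -0.0125, -0.3105),
  B1 = c(-0.2215, -0.3937, -1.014, -1.142, -1.641, -0.9581, -1.237, -0.6489),
  A2 = c(0.0159, 0.0330, 0.2512, 0.0433, 0.2335, 0.1037, 0.2057, 1.322),
  B2 = c(0.4131, 0.7029, 0.8907, 1.173, 0.7685, 1.027, 0.8521, 1.240),
  C  = c(2.954, 4.395, 1.582, 1.758, 3.516, 4.395, 3.279, 3.516),
  stringsAsFactors = FALSE
)

# Prismatic C1--Ca spring/damper values: trial starting values and the
# identified final values.
.prismatic_initial <- list(kv_N_per_m = 10000, cv_Ns_per_m = 100)
.prismatic_final   <- list(kv_N_per_m = 1620,  cv_Ns_per_m = 100)

# T1 local-frame origin in the global frame (mm), initial posture.
.base_origin_mm <- c(4, 19)

#' Published injury-criteria benchmark for the LAB sled scenario
#'
#' Injury criteria reported for a 300 ms rear-impact LAB sled simulation
#' (12 g, delta-V = 10 km/h, rigid seat, no head restraint): the TNO-HBM
#' reference occupant model versus the identified planar ENM-2D model.
#' These published values are inputs for deviation arithmetic (see
#' [hic_deviation()]); they are not recomputable from this package because
#' the reference T1 trajectory that produced them is not publicly available.
#'
#' @format A data frame with two rows (reference and identified model) and
#'   columns `model`, `hic36`, `nep`, `nfp`, `nea`, `nfa`.
#' @export
published_injury_criteria <- data.frame(
  model = c("TNO-HBM (reference)", "ENM-2D (identified)"),
  hic36 = c(127.1, 137.7),
  nep   = c(0.0291, 0.0509),
  nfp   = c(0, 0),
  nea   = c(0.1596, 0.1403),
  nfa   = c(0.3284, 0.3159),
  stringsAsFactors = FALSE
)
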