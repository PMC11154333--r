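# Model config serialization: a YAML document with sections options/bodies/
# joints/prismatic; numeric keys carry SI unit suffixes.  Numbers are written
# with 17 significant digits so a write/read round trip is value-exact.

.fmt_num <- function(x) {
  if (is.na(x)) return("~")
  sprintf("%.17g", x)
}

#' Write a model to a config file
#'
#' Serializes a `neck_model` to a YAML document (sections `options`, `bodies`,
#' `joints`, `prismatic`).  All numeric fields are SI with the unit in the key
#' name and are written at full double precision, so
#' `read_model_config(write_model_config(m, f))` reproduces the parameters
#' exactly.
#'
#' @param model a `neck_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "neck_model"))
  ln <- c(
    "options:",
    sprintf("  preset: %s", model$preset),
    sprintf("  variant: %s", model$variant),
    sprintf("  gravity: %s", if (model$gravity) "true" else "false"),
    sprintf("  g_m_per_s2: %s", .fmt_num(if (model$gravity) model$g else 9.81)),
    sprintf("  base_origin_x_m: %s", .fmt_num(model$base$origin[1])),
    sprintf("  base_origin_z_m: %s", .fmt_num(model$base$origin[2])),
    sprintf("  base_theta0_rad: %s", .fmt_num(model$base$theta0)),
    "bodies:"
  )
  b <- model$bodies
  for (i in seq_len(nrow(b))) {
    ln <- c(ln,
      sprintf("  - name: %s", b$name[i]),
      sprintf("    mass_kg: %s", .fmt_num(b$mass[i])),
      sprintf("    iyy_kgm2: %s", .fmt_num(b$iyy[i])),
      sprintf("    sx_m: %s", .fmt_num(b$sx[i])),
      sprintf("    sz_m: %s", .fmt_num(b$sz[i])),
      sprintf("    gx_m: %s", .fmt_num(b$gx[i])),
      sprintf("    gz_m: %s", .fmt_num(b$gz[i])),
      sprintf("    theta0_rad: %s", .fmt_num(b$theta0[i])))
  }
  ln <- c(ln, "joints:")
  j <- model$joints
  for (i in seq_len(nrow(j))) {
    ln <- c(ln,
      sprintf("  - body: %s", j$body[i]),
      sprintf("    joint: %s", j$joint[i]),
      sprintf("    type: %s", j$type[i]),
      sprintf("    A1_Nm: %s", .fmt_num(j$A1[i])),
      sprintf("    B1: %s", .fmt_num(j$B1[i])),
      sprintf("    A2_Nm: %s", .fmt_num(j$A2[i])),
      sprintf("    B2: %s", .fmt_num(j$B2[i])),
      sprintf("    C_Nms_per_rad: %s", .fmt_num(j$C[i])))
  }
  if (!is.null(model$prismatic)) {
    p <- model$prismatic
    ln <- c(ln,
      "prismatic:",
      sprintf("  kv_N_per_m: %s", .fmt_num(p$kv)),
      sprintf("  cv_Ns_per_m: %s", .fmt_num(p$cv)),
      sprintf("  axis_x: %s", .fmt_num(p$axis[1])),
      sprintf("  axis_z: %s", .fmt_num(p$axis[2])))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a model from a config file
#'
#' @param path path to a config written by [write_model_config()].
#' @return A `neck_model`.
#' @export
read_model_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$options) || is.null(doc$bodies) || is.null(doc$joints))
    stop("model config must contain 'options', 'bodies' and 'joints' sections")
  opt <- doc$options
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  bodies <- do.call(rbind, lapply(doc$bodies, function(x) data.frame(
    name = x$name, mass = num(x$mass_kg), iyy = num(x$iyy_kgm2),
    sx = num(x$sx_m), sz = num(x$sz_m), gx = num(x$gx_m), gz = num(x$gz_m),
    theta0 = num(x$theta0_rad), stringsAsFactors = FALSE)))
  joints <- do.call(rbind, lapply(doc$joints, function(x) data.frame(
    body = x$body, joint = x$joint, type = x$type,
    A1 = num(x$A1_Nm), B1 = num(x$B1), A2 = num(x$A2_Nm), B2 = num(x$B2),
    C = num(x$C_Nms_per_rad), stringsAsFactors = FALSE)))
  prismatic <- NULL
  if (!is.null(doc$prismatic)) {
    p <- doc$prismatic
    prismatic <- list(kv = num(p$kv_N_per_m), cv = num(p$cv_Ns_per_m),
                      axis = c(num(p$axis_x), num(p$axis_z)))
  }
  model <- structure(list(
    preset = opt$preset, variant = opt$variant,
    bodies = bodies, joints = joints, prismatic = prismatic,
    base = list(origin = c(opt$base_origin_x_m, opt$base_origin_z_m),
                theta0 = opt$base_theta0_rad),
    gravity = isTRUE(opt$gravity),
    g = if (isTRUE(opt$gravity)) opt$g_m_per_s2 else 0,
    preload = numeric(nrow(joints))
  ), class = "neck_model")
  model <- .compute_preload(model)
  .validate_model(model)
  model
}
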