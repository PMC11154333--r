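# Channel-table CSV input/output and run reports.
#
# Channel CSV dialect: comma separator, '.' decimal, UTF-8, mandatory header;
# first column `time_s` strictly increasing, remaining columns named
# `<channel>_<unit>` (e.g. C0_angle_rad, headCG_ares_g, OC_Fx_N).

#' Write a channel table to CSV
#'
#' Numbers are written with 17 significant digits so a write/read round trip
#' is value-exact.
#'
#' @param table data frame whose first column is `time_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channels <- function(table, path) {
  .validate_channels(table)
  tab <- as.data.frame(lapply(table, function(col) sprintf("%.17g", col)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a channel table from CSV
#'
#' Validates the channel-table invariants: a `time_s` first column, strictly
#' increasing time, unit-suffixed column names and no missing values, each
#' with a distinct error.
#'
#' @param path CSV path.
#' @return Data frame of channels.
#' @export
read_channels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  .validate_channels(tab)
  tab
}

.validate_channels <- function(tab) {
  if (ncol(tab) < 1L || names(tab)[1] != "time_s")
    stop("missing time column: first column must be 'time_s'")
  bad <- names(tab)[-1][!grepl("_[A-Za-z0-9]+$", names(tab)[-1])]
  if (length(bad))
    stop(sprintf("malformed header: column(s) without unit suffix: %s",
                 paste(bad, collapse = ", ")))
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("malformed header: non-numeric channel data")
  if (anyNA(tab)) stop("channel table contains NaN or missing values")
  if (any(diff(tab$time_s) <= 0)) stop("non-monotone time column")
  invisible(tab)
}

#' Reference kinematics as a channel table
#'
#' @param x a `reference_kinematics`.
#' @param ... unused.
#' @export
as.data.frame.reference_kinematics <- function(x, ...) {
  d <- data.frame(time_s = x$time)
  for (b in colnames(x$angle)) d[[paste0(b, "_angle_rad")]] <- x$angle[, b]
  d$OC_x_m <- x$oc[, "x"]
  d$OC_z_m <- x$oc[, "z"]
  d
}

#' Write a run report
#'
#' Writes a key-value summary of a run (injury criteria, peak head
#' acceleration, peak occipital-condyle loads, energy-balance residual)
#' followed by the full channel table of the simulation.  Regenerating the
#' report from identical inputs is byte-identical apart from the
#' `generated` timestamp line.
#'
#' @param result a `neck_sim`.
#' @param criteria a `criteria_result` for the same run (default: computed
#'   from `result`).
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
run_report <- function(result, criteria = compute_criteria(result), out_path) {
  stopifnot(inherits(result, "neck_sim"))
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "# whipneck run report",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("model_preset: %s", result$model$preset),
    sprintf("model_variant: %s", result$model$variant),
    sprintf("t_end_s: %s", num(result$time[length(result$time)])),
    sprintf("output_rate_hz: %s", num(result$settings$output_rate)),
    sprintf("hic36: %s", num(criteria$hic36)),
    sprintf("hic_window_t1_s: %s", num(criteria$hic_window[1])),
    sprintf("hic_window_t2_s: %s", num(criteria$hic_window[2])),
    sprintf("nfa: %s", num(criteria$nfa)),
    sprintf("nfp: %s", num(criteria$nfp)),
    sprintf("nea: %s", num(criteria$nea)),
    sprintf("nep: %s", num(criteria$nep)),
    sprintf("peak_head_acc_g: %s", num(max(result$head_acc_g))),
    sprintf("peak_oc_fx_N: %s", num(max(abs(result$oc_loads[, "Fx"])))),
    sprintf("peak_oc_fz_N: %s", num(max(abs(result$oc_loads[, "Fz"])))),
    sprintf("peak_oc_my_Nm: %s", num(max(abs(result$oc_loads[, "My"])))),
    sprintf("energy_balance_residual: %s", num(energy_residual(result))),
    ""
  )
  con <- file(out_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- as.data.frame(result)
  tabf <- as.data.frame(lapply(tab, function(col) sprintf("%.17g", col)),
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tabf, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out_path)
}
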