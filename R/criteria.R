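# Injury criteria: HIC (sliding-window 2.5-power functional of the resultant
# head acceleration) and the four-case Nkm neck criterion.

# Normalization constants of the Nkm criterion: intercept shear force
# (anterior/posterior) and intercept moments (flexion/extension).
.nkm_fint <- 845     # N, either sign
.nkm_mint_flex <- 88.1   # Nm, flexion (My > 0)
.nkm_mint_ext <- 47.5    # Nm, magnitude for extension (My < 0)

#' Head Injury Criterion
#'
#' Maximises `(t2 - t1) * [ (1/(t2 - t1)) * integral of a dt ]^2.5` over all
#' grid-point window pairs with `0 < t2 - t1 <= max_window`, using
#' trapezoidal integration on the uniform sampling grid.  The default 36 ms
#' window cap is the convention for impacts without direct head contact
#' (HIC36).  A cumulative-sum accelerated search over window lengths is used;
#' it is exactly equivalent to the exhaustive pair search.
#'
#' @param a_resultant resultant head CG acceleration, in g (non-negative).
#' @param time uniform time grid, s.
#' @param max_window maximum window length, s (default 0.036).
#' @return List with `value` (dimensionless), `t1`, `t2` (s).
#' @export
hic <- function(a_resultant, time, max_window = 0.036) {
  a <- as.numeric(a_resultant); time <- as.numeric(time)
  n <- length(a)
  if (length(time) != n) stop("acceleration and time lengths differ")
  if (n < 2L) stop("need at least two samples")
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * max(dt, 1e-300))
    stop("time grid must be uniform and increasing")
  if (any(a < 0)) stop("resultant acceleration must be non-negative")
  h <- dt[1]
  # cumulative trapezoid: I[k] = integral from time[1] to time[k]
  I <- c(0, cumsum((a[-n] + a[-1]) / 2 * h))
  kmax <- min(n - 1L, floor(max_window / h + 1e-9))
  if (kmax < 1L) stop("max_window shorter than the sampling interval")
  best <- 0; bi <- 1L; bk <- 1L
  for (k in seq_len(kmax)) {
    w <- time[(1L + k):n] - time[1L:(n - k)]
    avg <- (I[(1L + k):n] - I[1L:(n - k)]) / w
    v <- w * avg^2.5
    j <- which.max(v)
    if (v[j] > best) { best <- v[j]; bi <- j; bk <- k }
  }
  list(value = best, t1 = time[bi], t2 = time[bi + bk])
}

#' Nkm neck injury criterion (four load cases)
#'
#' Combines normalized occipital-condyle shear force and sagittal bending
#' moment.  At each instant each of the four cases sums only the
#' sign-matching contributions (Fx > 0 anterior, My > 0 flexion):
#' `Nfa = max(Fx,0)/845 + max(My,0)/88.1`,
#' `Nfp = max(-Fx,0)/845 + max(My,0)/88.1`,
#' `Nea = max(Fx,0)/845 + max(-My,0)/47.5`,
#' `Nep = max(-Fx,0)/845 + max(-My,0)/47.5`;
#' the time-maximum of each case is returned with its argmax time.
#'
#' @param Fx occipital-condyle shear force, N (positive anterior).
#' @param My occipital-condyle sagittal moment, Nm (positive flexion).
#' @param time optional time grid (for argmax times), s.
#' @return List with `nfa`, `nfp`, `nea`, `nep` (each `value` and `t_max`)
#'   and the constants record.
#' @export
nkm <- function(Fx, My, time = seq_along(Fx)) {
  Fx <- as.numeric(Fx); My <- as.numeric(My)
  if (length(Fx) != length(My)) stop("Fx and My grids differ in length")
  if (length(time) != length(Fx)) stop("time grid mismatch")
  fa <- pmax(Fx, 0) / .nkm_fint
  fp <- pmax(-Fx, 0) / .nkm_fint
  mf <- pmax(My, 0) / .nkm_mint_flex
  me <- pmax(-My, 0) / .nkm_mint_ext
  case <- function(x) {
    j <- which.max(x)
    list(value = x[j], t_max = time[j])
  }
  list(nfa = case(fa + mf), nfp = case(fp + mf),
       nea = case(fa + me), nep = case(fp + me),
       constants = list(Fint = c(-.nkm_fint, .nkm_fint),
                        Mint = c(-.nkm_mint_ext, .nkm_mint_flex)))
}

#' Relative deviation of a HIC value from a reference
#'
#' Signed percent deviation `100 * (hic_model - hic_reference) /
#' hic_reference`, the headline comparison statistic between an efficient
#' model and its reference occupant model.
#'
#' @param hic_model HIC of the model under assessment.
#' @param hic_reference HIC of the reference (must be positive).
#' @return Signed percent deviation.
#' @examples
#' hic_deviation(137.7, 127.1)   # about 8.3
#' @export
hic_deviation <- function(hic_model, hic_reference) {
  if (any(hic_reference <= 0)) stop("reference HIC must be positive")
  100 * (hic_model - hic_reference) / hic_reference
}

#' Injury criteria of a simulation
#'
#' Computes HIC (windowed on the resultant head CG acceleration in g) and
#' the four Nkm cases from the occipital-condyle loads of a run.
#'
#' @param result a `neck_sim` from [simulate_neck()], or any list providing
#'   `time`, `head_acc_g` and `oc_loads`.
#' @param max_window HIC window cap, s.
#' @return An object of class `criteria_result`.
#' @export
compute_criteria <- function(result, max_window = 0.036) {
  h <- hic(result$head_acc_g, result$time, max_window = max_window)
  nk <- nkm(result$oc_loads[, "Fx"], result$oc_loads[, "My"], result$time)
  structure(list(
    hic36 = h$value, hic_window = c(t1 = h$t1, t2 = h$t2),
    nfa = nk$nfa$value, nfp = nk$nfp$value,
    nea = nk$nea$value, nep = nk$nep$value,
    nkm_times = c(nfa = nk$nfa$t_max, nfp = nk$nfp$t_max,
                  nea = nk$nea$t_max, nep = nk$nep$t_max),
    constants = nk$constants,
    max_window = max_window
  ), class = "criteria_result")
}

#' @export
print.criteria_result <- function(x, ...) {
  cat(sprintf("<criteria_result> HIC%2.0f = %.4g (window [%.4g, %.4g] s)\n",
              x$max_window * 1000, x$hic36, x$hic_window[1], x$hic_window[2]))
  cat(sprintf("  Nfa = %.4g  Nfp = %.4g  Nea = %.4g  Nep = %.4g\n",
              x$nfa, x$nfp, x$nea, x$nep))
  invisible(x)
}
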