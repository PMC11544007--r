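# Variable-flip-angle T1 mapping and SPGR signal <-> concentration
# conversion.  TE decay is neglected throughout (TE ~ 1 ms).

#' Spoiled gradient-echo signal equation
#'
#' `S = m0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-tr/t1)`.
#' All arguments are vectorized.
#'
#' @param m0 equilibrium signal (proton density x gain).
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @param tr repetition time, ms.
#' @param alpha flip angle, degrees.
#' @return Signal in arbitrary units.
#' @export
spgr_signal <- function(m0, t1, tr, alpha) {
  if (any(t1 <= 0)) stop_invalid("t1 must be > 0")
  e1 <- exp(-tr / t1)
  a <- alpha * pi / 180
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable-flip-angle T1 and M0 fit (linearized DESPOT1)
#'
#' Per voxel, regresses `S/sin(a)` on `S/tan(a)`; the slope is
#' `E1 = exp(-tr/t1)` and the intercept `m0 (1 - E1)`.  Exact on noiseless
#' SPGR data for any T1.  Voxels whose slope falls outside (0, 1), or with
#' non-finite/all-zero signals, are flagged `fit_ok = FALSE` rather than
#' raising an error.
#'
#' @param signals data frame with columns `voxel`, `flip_angle` (degrees)
#'   and `signal`, or a numeric matrix (voxels x angles).
#' @param flip_angles flip angles (degrees) for the matrix interface;
#'   ignored for the data-frame interface.
#' @param tr repetition time, ms.
#' @return A tibble with columns `voxel`, `t1` (ms), `m0`, `fit_ok`.
#' @export
fit_t1_vfa <- function(signals, flip_angles = NULL, tr = 3.03) {
  if (is.data.frame(signals)) {
    need <- c("voxel", "flip_angle", "signal")
    if (!all(need %in% names(signals))) {
      stop_invalid("data-frame interface needs columns voxel, flip_angle, signal")
    }
    wide <- tidyr::pivot_wider(signals[need], names_from = "flip_angle",
                               values_from = "signal")
    flip_angles <- as.numeric(names(wide)[-1])
    voxel_ids <- wide$voxel
    S <- as.matrix(wide[-1])
  } else {
    S <- as.matrix(signals)
    if (is.null(flip_angles)) stop_invalid("flip_angles required for matrix input")
    voxel_ids <- seq_len(nrow(S))
  }
  if (length(unique(flip_angles)) < 2L) stop_invalid("need >= 2 distinct flip angles")
  if (any(flip_angles <= 0 | flip_angles > 90)) stop_invalid("flip angles must be in (0, 90]")
  a <- flip_angles * pi / 180
  y <- sweep(S, 2, sin(a), "/")
  x <- sweep(S, 2, tan(a), "/")
  xbar <- rowMeans(x); ybar <- rowMeans(y)
  sxx <- rowSums((x - xbar)^2)
  sxy <- rowSums((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  ok <- is.finite(slope) & slope > 0 & slope < 1 & intercept > 0 &
    apply(is.finite(S), 1, all) & rowSums(abs(S)) > 0
  t1 <- ifelse(ok, -tr / log(slope), NA_real_)
  m0 <- ifelse(ok, intercept / (1 - slope), NA_real_)
  tibble::tibble(voxel = voxel_ids, t1 = t1, m0 = m0, fit_ok = ok)
}

#' Convert a dynamic SPGR signal series to contrast-agent concentration
#'
#' The baseline signal `S0` (mean of the first `n_baseline` frames) pins the
#' scanner gain: `m0` from the VFA fit is rescaled so the pre-contrast
#' signal maps exactly to `t10`.  Each frame's SPGR equation is then
#' inverted for `T1(t)` and
#' \deqn{C(t) = \frac{1000}{r_1}\Big(\frac{1}{T_1(t)} - \frac{1}{T_{10}}\Big)
#'   \ \mathrm{mM}} (with T1 in ms and `r1` in L mmol^-1 s^-1).
#' Concentrations are floored at 0; the largest sub-floor magnitude is
#' returned as attribute `subfloor`.  Frames whose signal implies
#' `E1` outside (0, 1) are flagged invalid (`NA` concentration).
#'
#' @param signal numeric vector of dynamic signal for one voxel.
#' @param t10 pre-contrast T1, ms.
#' @param m0 equilibrium signal from the VFA fit.
#' @param r1 longitudinal relaxivity, L mmol^-1 s^-1.
#' @param tr repetition time, ms.
#' @param alpha dynamic flip angle, degrees.
#' @param n_baseline number of pre-contrast frames (>= 1).
#' @return A tibble with columns `frame`, `conc` (mM, `NA` when invalid)
#'   and `valid`; attribute `subfloor` carries the largest clipped
#'   magnitude.
#' @export
signal_to_concentration <- function(signal, t10, m0, r1 = 3.6, tr = 3.03,
                                    alpha = 9, n_baseline = 10) {
  if (n_baseline < 1 || n_baseline > length(signal)) {
    stop_invalid("n_baseline must be in [1, length(signal)]")
  }
  if (t10 <= 0 || !is.finite(t10)) stop_invalid("t10 must be > 0")
  s0 <- mean(signal[seq_len(n_baseline)])
  m0_eff <- s0 / spgr_signal(1, t10, tr, alpha)
  a <- alpha * pi / 180
  e1 <- (m0_eff * sin(a) - signal) / (m0_eff * sin(a) - signal * cos(a))
  valid <- is.finite(e1) & e1 > 0 & e1 < 1
  t1 <- ifelse(valid, -tr / log(e1), NA_real_)
  conc <- (1000 / r1) * (1 / t1 - 1 / t10)
  subfloor <- max(0, -min(conc[valid], 0))
  conc <- ifelse(valid, pmax(conc, 0), NA_real_)
  out <- tibble::tibble(frame = seq_along(signal), conc = conc, valid = valid)
  attr(out, "subfloor") <- subfloor
  out
}

#' Convert a tissue concentration series to dynamic SPGR signal
#'
#' Exact forward counterpart of [signal_to_concentration()]:
#' `1/T1(t) = 1/t10 + r1 C(t) / 1000`, then the SPGR equation at `m0`.
#'
#' @param conc concentration series, mM (>= 0).
#' @inheritParams signal_to_concentration
#' @return Numeric signal vector.
#' @export
concentration_to_signal <- function(conc, t10, m0, r1 = 3.6, tr = 3.03,
                                    alpha = 9) {
  if (t10 <= 0) stop_invalid("t10 must be > 0")
  if (any(conc < 0)) stop_invalid("concentration must be >= 0")
  t1 <- 1 / (1 / t10 + r1 * conc / 1000)
  spgr_signal(m0, t1, tr, alpha)
}
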