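#' Parker population arterial input function
#'
#' Evaluates the Parker mixture-of-Gaussians-plus-sigmoidal-exponential
#' population AIF (plasma gadolinium concentration after a standard-dose
#' bolus) on an arbitrary time grid, time-shifted so the bolus arrives at
#' `bolus_arrival` and scaled linearly by `dose_scale`.  The curve is exactly
#' zero before the bolus arrival.
#'
#' The population curve is defined directly in plasma units, so no
#' hematocrit correction applies (contrast [read_aif()] for measured
#' whole-blood curves).
#'
#' @param times numeric vector of sample times in minutes (strictly
#'   increasing, starting at >= 0).
#' @param bolus_arrival bolus arrival time in minutes; must lie within the
#'   span of `times`.
#' @param dose_scale linear scaling of the standard-dose curve.
#' @return A tibble with columns `time` (min) and `cp` (mM plasma).
#' @examples
#' aif <- aif_parker(seq(0, 5, by = 1 / 30), bolus_arrival = 0.5)
#' @export
aif_parker <- function(times, bolus_arrival = 0.5, dose_scale = 1) {
  check_time_grid(times)
  if (!is.numeric(bolus_arrival) || length(bolus_arrival) != 1L ||
      bolus_arrival < times[1] || bolus_arrival > times[length(times)]) {
    stop_invalid("bolus_arrival must lie within the time grid span")
  }
  if (!is.numeric(dose_scale) || length(dose_scale) != 1L || dose_scale < 0) {
    stop_invalid("dose_scale must be a nonnegative scalar")
  }
  cp <- ifelse(times < bolus_arrival, 0,
               dose_scale * parker_cb(times - bolus_arrival))
  tibble::tibble(time = as.numeric(times), cp = as.numeric(cp))
}

# Parker et al. population parameters (concentration in mM, time in minutes).
parker_cb <- function(t) {
  A1 <- 0.809; A2 <- 0.330          # mmol.min
  T1 <- 0.17046; T2 <- 0.365        # min
  s1 <- 0.0563; s2 <- 0.132         # min
  alpha <- 1.050; beta <- 0.1685    # mM, 1/min
  s <- 38.078; tau <- 0.483         # 1/min, min
  A1 / (s1 * sqrt(2 * pi)) * exp(-(t - T1)^2 / (2 * s1^2)) +
    A2 / (s2 * sqrt(2 * pi)) * exp(-(t - T2)^2 / (2 * s2^2)) +
    alpha * exp(-beta * t) / (1 + exp(-s * (t - tau)))
}

#' Read a measured arterial input function from CSV
#'
#' Expects a two-column CSV with header `time_s, concentration_mM`.  A
#' measured in-vivo curve is usually whole-blood; setting `blood = TRUE`
#' converts it to plasma concentration by dividing by `1 - hematocrit`.
#'
#' @param path CSV file path.
#' @param blood logical; is the curve whole-blood concentration?
#' @param hematocrit hematocrit fraction used for the blood-to-plasma
#'   conversion (only used when `blood = TRUE`).
#' @return A tibble with columns `time` (min) and `cp` (mM plasma).
#' @export
read_aif <- function(path, blood = FALSE, hematocrit = 0.45) {
  if (!file.exists(path)) stop_invalid(sprintf("AIF file not found: %s", path))
  d <- read.csv(path)
  if (!all(c("time_s", "concentration_mM") %in% names(d))) {
    stop_invalid("AIF CSV must have columns 'time_s' and 'concentration_mM'")
  }
  cp <- d$concentration_mM
  if (blood) {
    if (hematocrit <= 0 || hematocrit >= 1) stop_invalid("hematocrit must be in (0, 1)")
    cp <- cp / (1 - hematocrit)
  }
  out <- tibble::tibble(time = d$time_s / 60, cp = cp)
  check_aif(out)
  out
}
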