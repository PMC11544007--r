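# Forward tracer-kinetic models.
#
# Internal units throughout: fractional volumes (mL per mL tissue), rate
# constants and flow in 1/min (flow: mL blood per min per mL tissue), time
# in minutes, concentration in mM.  Reported units (mL/100 mL,
# mL/min/100 mL, percent) are produced only at aggregation time.

check_tofts_params <- function(ktrans, ve, vp) {
  if (ktrans < 0) stop_invalid("ktrans must be >= 0")
  if (ve < 0 || ve > 1) stop_invalid("ve must be in [0, 1]")
  if (vp < 0 || vp > 1) stop_invalid("vp must be in [0, 1]")
  if (ve + vp > 1 + 1e-12) stop_invalid("ve + vp must be <= 1")
  if (ktrans > 0 && ve == 0) {
    stop_degenerate("ve = 0 with ktrans > 0: efflux rate undefined")
  }
  invisible(NULL)
}

check_dp_params <- function(f, ps, vp, ve) {
  if (f <= 0) stop_degenerate("blood flow f must be > 0")
  if (ps < 0) stop_invalid("ps must be >= 0")
  if (vp <= 0 || vp > 1) stop_degenerate("vp must be in (0, 1]")
  if (ve < 0 || ve > 1) stop_invalid("ve must be in [0, 1]")
  if (ve + vp > 1 + 1e-12) stop_invalid("ve + vp must be <= 1")
  if (ps > 0 && ve == 0) stop_degenerate("ve = 0 with ps > 0: exchange into zero volume")
  invisible(NULL)
}

#' Extended Tofts forward model
#'
#' Tissue concentration of the extended Tofts model,
#' \deqn{C_t(t) = v_p c_p(t) + K^{trans} \int_0^t c_p(s)\,
#'   e^{-(K^{trans}/v_e)(t-s)}\, ds,}
#' evaluated on the AIF's time grid.  The convolution is computed on a finer
#' internal uniform grid (trapezoid rule) and sampled back.
#'
#' @param aif data frame with columns `time` (min) and `cp` (mM plasma).
#' @param ktrans volume transfer constant, 1/min.
#' @param ve interstitial (EES) volume fraction in \[0, 1\].
#' @param vp plasma volume fraction in \[0, 1\]; `ve + vp <= 1`.
#' @param dt_internal internal convolution step in minutes (default 0.5 s).
#' @return A tibble with columns `time` and `ct` (mM).
#' @export
tofts_forward <- function(aif, ktrans, ve, vp, dt_internal = 1 / 120) {
  a <- check_aif(aif)
  check_tofts_params(ktrans, ve, vp)
  ctx <- conv_context(a$time, a$value, dt = dt_internal)
  ct <- tofts_ct(ctx, ktrans, ve, vp)
  tibble::tibble(time = a$time, ct = ct)
}

# fast path on a prebuilt context; cp contribution uses the *acquisition*
# samples so the ktrans = 0 limit is exact.
tofts_ct <- function(ctx, ktrans, ve, vp) {
  cp_acq <- approx(ctx$s, ctx$cpi, xout = ctx$time - ctx$t0, rule = 2)$y
  if (ktrans == 0) return(vp * cp_acq)
  kep <- ktrans / ve
  kernel <- ktrans * exp(-kep * ctx$s)
  leak <- conv_trapz(ctx$cpi, kernel, ctx$dt)
  pmax(vp * cp_acq + sample_back(ctx, leak), 0)
}

#' Distributed-parameter (Sangren-Sheppard) residue function
#'
#' Fraction of an instantaneous intravascular bolus still in tissue at time
#' `t` under the two-region distributed-parameter model: a plug-flow
#' capillary (transit time `Tc = vp / f`) exchanging bidirectionally with
#' the interstitium at rate `ps`.  For `0 <= t < Tc` the residue is 1; at
#' the capillary outflow time it drops to the first-pass extraction
#' fraction `E = 1 - exp(-ps/f)` and then decays monotonically to 0 as
#' back-exchanged tracer washes out:
#' \deqn{R(t) = 1 - e^{-PS/F}\Big[1 + \int_0^{t-T_c}
#'   e^{-(PS/v_e)\tau}\sqrt{\tfrac{(PS/v_e)(PS/F)}{\tau}}\,
#'   I_1\big(2\sqrt{(PS/v_e)(PS/F)\,\tau}\big)\, d\tau\Big], \quad t \ge T_c.}
#' The integrable \eqn{1/\sqrt\tau} endpoint singularity is removed by the
#' substitution \eqn{\tau = u^2} and the integral evaluated by adaptive
#' quadrature (absolute and relative tolerance `tol`); the product
#' \eqn{e^{-(PS/v_e)\tau} I_1(\cdot)} is computed through the exponentially
#' scaled Bessel function so large arguments cannot overflow.
#'
#' @param t time(s) since bolus arrival, minutes, `>= 0`.
#' @param f blood flow, mL/min per mL tissue (> 0).
#' @param ps permeability-surface product, mL/min per mL tissue (>= 0).
#' @param vp plasma volume fraction in (0, 1\].
#' @param ve interstitial volume fraction in \[0, 1\].
#' @param tol quadrature tolerance.
#' @return Residue values in \[0, 1\], same length as `t`.
#' @export
dp_residue <- function(t, f, ps, vp, ve, tol = 1e-8) {
  check_dp_params(f, ps, vp, ve)
  if (any(t < 0)) stop_invalid("t must be >= 0")
  tc <- vp / f
  vapply(t, function(ti) {
    if (ti < tc) return(1)
    if (ps == 0) return(0)
    b <- ps / f
    k <- ps / ve
    1 - exp(-b) - dp_exchange_integral(ti - tc, k, b, tol = tol)
  }, numeric(1))
}

# H(tau_max) = e^{-b} * Int_0^{tau_max} e^{-k tau} sqrt(k b / tau)
#              I1(2 sqrt(k b tau)) dtau, via tau = u^2.  The e^{-b} factor is
# folded into the integrand so the bracketed series never overflows:
#   integrand(u) = 2 sqrt(k b) exp(-(sqrt(k) u - sqrt(b))^2) I1scaled(z),
#   z = 2 sqrt(k b) u.
dp_exchange_integrand <- function(u, k, b) {
  z <- 2 * sqrt(k * b) * u
  2 * sqrt(k * b) * exp(-(sqrt(k) * u - sqrt(b))^2) *
    besselI(z, nu = 1, expon.scaled = TRUE)
}

dp_exchange_integral <- function(tau_max, k, b, tol = 1e-8) {
  if (tau_max <= 0) return(0)
  res <- tryCatch(
    integrate(dp_exchange_integrand, 0, sqrt(tau_max), k = k, b = b,
              rel.tol = tol, abs.tol = tol, subdivisions = 400L),
    error = function(e) {
      stop_numerical(sprintf(
        "residue quadrature failed (tau_max=%.4g, k=%.4g, b=%.4g): %s",
        tau_max, k, b, conditionMessage(e)))
    })
  res$value
}

#' Distributed-parameter forward model
#'
#' Tissue concentration `ct = f * (cp (x) R)` with the residue of
#' [dp_residue()].  The convolution is evaluated on an internal uniform
#' grid; the residue's discontinuity at the capillary transit time `Tc` is
#' handled exactly by splitting it into a plug-flow boxcar (cumulative
#' integral differences) plus a continuous exchange tail shifted to
#' `t - Tc`, so no grid node needs to coincide with `Tc`.
#'
#' A transit time shorter than one internal step is clamped to one step
#' with a warning of class `dpdce_tc_clamped`.
#'
#' @inheritParams dp_residue
#' @inheritParams tofts_forward
#' @return A tibble with columns `time` and `ct` (mM).
#' @export
dp_forward <- function(aif, f, ps, vp, ve, dt_internal = 1 / 120) {
  a <- check_aif(aif)
  check_dp_params(f, ps, vp, ve)
  ctx <- conv_context(a$time, a$value, dt = dt_internal)
  tibble::tibble(time = a$time, ct = dp_ct(ctx, f, ps, vp, ve))
}

dp_ct <- function(ctx, f, ps, vp, ve) {
  tc <- vp / f
  if (tc < ctx$dt) {
    warn(sprintf("capillary transit time %.4g min < internal step %.4g min; clamped",
                 tc, ctx$dt), class = "dpdce_tc_clamped")
    tc <- ctx$dt
  }
  s <- ctx$s
  # cubic interpolation of a smooth cumulative series at the shifted times
  # t - Tc (negative arguments -> 0); linear interpolation here dominates
  # the grid-refinement error near the bolus peak
  shift_interp <- function(v) {
    sf <- stats::splinefun(s, v, method = "natural")
    out <- sf(pmax(s - tc, 0))
    out[s - tc < 0] <- 0
    out
  }
  # plug-flow boxcar: f * (P(t) - P(t - Tc)), P = cumulative integral of cp
  P <- cumtrapz_uniform(ctx$cpi, ctx$dt)
  ct_box <- f * (P - shift_interp(P))
  if (ps > 0 && ve > 0) {
    b <- ps / f
    k <- ps / ve
    rex <- dp_exchange_tail(s, k, b)
    h <- conv_trapz(ctx$cpi, rex, ctx$dt)
    ct_ex <- f * shift_interp(h)
  } else {
    ct_ex <- 0
  }
  ct <- sample_back(ctx, ct_box + ct_ex)
  pmax(ct, 0)
}

# Continuous exchange tail Rex(tau) = R(Tc + tau) for tau >= 0, evaluated on
# a (possibly long) tau grid via one cumulative quadrature in u = sqrt(tau).
dp_exchange_tail <- function(tau, k, b) {
  u_max <- sqrt(max(tau))
  n_u <- max(1024L, 2L * length(tau))
  u <- seq(0, u_max, length.out = n_u)
  g <- dp_exchange_integrand(u, k, b)
  H <- cumtrapz_uniform(g, u[2] - u[1])
  Hi <- approx(u, H, xout = sqrt(tau), rule = 2)$y
  pmax(1 - exp(-b) - Hi, 0)
}

#' First-pass extraction fraction
#'
#' `E = 100 * (1 - exp(-ps/f))`, in percent.  Accepts the paper's reported
#' units (mL/min/100 mL) or internal fractional units interchangeably: only
#' the ratio `ps/f` enters.
#'
#' @param f blood flow (> 0).
#' @param ps permeability-surface product (>= 0), same units as `f`.
#' @return Extraction fraction in percent, in \[0, 100).
#' @export
extraction_fraction <- function(f, ps) {
  if (any(f <= 0)) stop_degenerate("f must be > 0")
  if (any(ps < 0)) stop_invalid("ps must be >= 0")
  100 * (1 - exp(-ps / f))
}

#' Efflux rate constant
#'
#' `kep = ktrans / ve` (1/min).
#'
#' @param ktrans volume transfer constant, 1/min (>= 0).
#' @param ve interstitial volume fraction (> 0).
#' @return Efflux rate constant in 1/min.
#' @export
kep_from <- function(ktrans, ve) {
  if (any(ktrans < 0)) stop_invalid("ktrans must be >= 0")
  if (any(ve <= 0)) stop_degenerate("ve must be > 0")
  ktrans / ve
}
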