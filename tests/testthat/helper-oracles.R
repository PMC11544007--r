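# Independent oracles used across the suite.  None of these share code with
# the package's own computational paths.

# Brute-force numerical solution of the two-region axially distributed
# capillary-tissue exchange system (plug-flow capillary discretised into
# n_seg axial segments, explicit upwind time stepping):
#   vp dc_b/dt + F dc_b/dx = PS (c_e - c_b),   ve dc_e/dt = PS (c_b - c_e)
# with inlet concentration cp(t); tissue concentration is the
# volume-weighted mean of both compartments.
pde_dp_oracle <- function(time, cp, f, ps, vp, ve, n_seg = 200) {
  dx <- 1 / n_seg
  rate <- f / (vp * dx) + ps / vp
  if (ve > 0) rate <- max(rate, ps / ve)
  dt <- 0.4 / rate
  tmax <- max(time)
  nt <- ceiling(tmax / dt)
  dt <- tmax / nt
  cb <- numeric(n_seg)
  ce <- numeric(n_seg)
  out <- numeric(length(time))
  ti <- 1
  tcur <- 0
  prev_val <- 0
  cp_fun <- stats::approxfun(time, cp, rule = 2)
  adv <- f / (vp * dx)
  for (step in seq_len(nt)) {
    cin <- cp_fun(tcur)
    upstream <- c(cin, cb[-n_seg])
    cb_new <- cb + dt * (adv * (upstream - cb) + ps * (ce - cb) / vp)
    if (ve > 0) ce <- ce + dt * ps * (cb - ce) / ve
    cb <- cb_new
    tcur <- tcur + dt
    cur_val <- vp * mean(cb) + ve * mean(ce)
    # linear interpolation between steps: the vascular spike can be
    # narrower than one output frame, so snapping to step times aliases
    while (ti <= length(time) && time[ti] <= tcur + 1e-12) {
      w <- (tcur - time[ti]) / dt
      out[ti] <- w * prev_val + (1 - w) * cur_val
      ti <- ti + 1
    }
    prev_val <- cur_val
  }
  # rounding in tcur accumulation can leave the final frame unfilled
  while (ti <= length(time)) {
    out[ti] <- prev_val
    ti <- ti + 1
  }
  out
}

# High-resolution trapezoid convolution oracle for the extended Tofts model.
tofts_conv_oracle <- function(time, cp, ktrans, ve, vp, upsample = 100) {
  dtf <- min(diff(time)) / upsample
  tf <- seq(time[1], max(time), by = dtf)
  cpf <- stats::approx(time, cp, xout = tf, rule = 2)$y
  kern <- ktrans * exp(-(ktrans / ve) * (tf - tf[1]))
  n <- length(cpf)
  full <- stats::convolve(cpf, rev(kern), type = "open")[seq_len(n)]
  leak <- (full - 0.5 * (cpf[1] * kern + cpf * kern[1])) * dtf
  vp * cp + stats::approx(tf, leak, xout = time, rule = 2)$y
}

# standard acquisition grid: 10 baseline + 180 dynamic frames at 2 s
acq_times <- function() seq(0, by = 2 / 60, length.out = 190)

std_aif <- function() aif_parker(acq_times(), bolus_arrival = 24 / 60)

# 3^4 DP parameter grid spanning the reported glioma ranges
# (fractional units: f, ps in 1/min; vp, ve fractions)
dp_param_grid <- function() {
  expand.grid(f = c(0.05, 0.085, 0.14),
              ps = c(0.003, 0.012, 0.035),
              vp = c(0.002, 0.006, 0.015),
              ve = c(0.004, 0.04, 0.12))
}

# random DP / Tofts parameters across the reported ranges
random_dp_params <- function(n) {
  data.frame(f = exp(runif(n, log(0.05), log(0.14))),
             ps = exp(runif(n, log(0.003), log(0.035))),
             vp = exp(runif(n, log(0.0015), log(0.015))),
             ve = exp(runif(n, log(0.002), log(0.12))))
}

random_tofts_params <- function(n) {
  data.frame(ktrans = exp(runif(n, log(0.005), log(0.06))),
             ve = exp(runif(n, log(0.002), log(0.15))),
             vp = exp(runif(n, log(0.0005), log(0.01))))
}

# trapezoid area under the DP residue: exact plateau (= Tc) plus a
# two-piece grid over the tail — dense where the post-plateau drop is fast,
# coarse over the slow washout, whose timescale is ve/ps when exchange is
# weak (a fixed multiple of the mean transit time truncates visibly there)
residue_area <- function(f, ps, vp, ve) {
  tc <- vp / f
  mtt <- (vp + ve) / f
  slow <- if (ps > 0) ve / ps else 0
  h1 <- tc + 3 * mtt
  h2 <- tc + 25 * max(mtt, slow)
  t_dense <- seq(tc, h1, length.out = 20000)
  t_coarse <- seq(h1, h2, length.out = 20000)
  trap <- function(tt) {
    r <- dp_residue(tt, f, ps, vp, ve)
    sum((r[-1] + r[-length(r)]) / 2) * diff(tt)[1]
  }
  f * (tc + trap(t_dense) + trap(t_coarse))
}

# independent permutation generator (iterative insertion; different
# algorithm from the package's recursive one)
perms_insertion <- function(n) {
  m <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(m) * k, k)
    r <- 0L
    for (i in seq_len(nrow(m))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        out[r, ] <- append(m[i, ], k, after = pos - 1L)
      }
    }
    m <- out
  }
  m
}
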