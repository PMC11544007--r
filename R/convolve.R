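# Internal uniform-grid convolution engine shared by both forward models.
#
# Acquisition grids are 2 s nominal but may be non-uniform; model kernels
# (in particular the distributed-parameter residue with its plateau edge at
# the capillary transit time) alias badly at that resolution, so every
# convolution is carried out on a finer uniform grid and sampled back.

check_time_grid <- function(time) {
  if (!is.numeric(time) || length(time) < 2L || anyNA(time) || any(!is.finite(time))) {
    stop_invalid("time grid must be finite numeric of length >= 2")
  }
  if (time[1] < 0) stop_invalid("time grid must start at t >= 0")
  if (any(diff(time) <= 0)) stop_invalid("time grid must be strictly increasing")
  invisible(time)
}

as_curve <- function(x, value_col) {
  if (!is.data.frame(x) || !all(c("time", value_col) %in% names(x))) {
    stop_invalid(sprintf("expected a data frame with columns 'time' and '%s'", value_col))
  }
  check_time_grid(x$time)
  v <- x[[value_col]]
  if (anyNA(v) || any(!is.finite(v))) stop_invalid(sprintf("'%s' must be finite", value_col))
  list(time = as.numeric(x$time), value = as.numeric(v))
}

check_aif <- function(aif) {
  a <- as_curve(aif, "cp")
  if (any(a$value < 0)) stop_invalid("AIF concentrations must be nonnegative")
  a
}

# Context caching the internal uniform grid and the resampled AIF so that
# repeated forward evaluations during fitting share the interpolation work.
# dt is in minutes (default 0.5 s).
conv_context <- function(time, cp, dt = 1 / 120) {
  span <- time[length(time)] - time[1]
  n <- max(2L, ceiling(span / dt) + 1L)
  s <- dt * (0:(n - 1L))                      # elapsed time since first sample
  cpi <- approx(time - time[1], cp, xout = s, rule = 2)$y
  list(time = time, t0 = time[1], s = s, cpi = cpi, dt = dt, n = n)
}

# Trapezoid convolution of two series sampled on the same uniform grid:
# out_i = dt * [ sum_{j<=i} f_j g_{i-j} - (f_1 g_i + f_i g_1)/2 ]
conv_trapz <- function(f, g, dt) {
  n <- length(f)
  full <- convolve(f, rev(g), type = "open")[seq_len(n)]
  (full - 0.5 * (f[1] * g + f * g[1])) * dt
}

# Cumulative trapezoid on a uniform grid.
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

# Sample a series defined on the internal elapsed-time grid back onto the
# acquisition grid.
sample_back <- function(ctx, y) {
  approx(ctx$s, y, xout = ctx$time - ctx$t0, rule = 2)$y
}
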