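aif <- std_aif()

test_that("Tofts limits: ktrans = 0 gives pure plasma term; impulse gives kep decay", {
  ct <- tofts_forward(aif, ktrans = 0, ve = 0.05, vp = 0.01)
  expect_equal(ct$ct, 0.01 * aif$cp)

  # unit-area narrow bolus at t = 0.5 min on a fine grid; vp = 0
  tg <- seq(0, 4, by = 1 / 600)
  w <- 1 / 300
  bolus <- tibble::tibble(time = tg, cp = ifelse(abs(tg - 0.5) <= w / 2, 1 / w, 0))
  ct <- tofts_forward(bolus, ktrans = 0.1, ve = 0.2, vp = 0, dt_internal = 1 / 1200)
  post <- tg > 0.6
  kep_hat <- -coef(lm(log(ct$ct[post]) ~ tg[post]))[[2]]
  expect_equal(kep_hat, 0.1 / 0.2, tolerance = 1e-3)
})

test_that("Tofts forward matches 100x-upsampled trapezoid convolution oracle", {
  set.seed(11)
  pars <- random_tofts_params(5)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    ct <- tofts_forward(aif, p$ktrans, p$ve, p$vp)$ct
    oracle <- tofts_conv_oracle(aif$time, aif$cp, p$ktrans, p$ve, p$vp)
    expect_lt(max(abs(ct - oracle)) / max(oracle), 0.01)
  }
})

test_that("Tofts rejects ve = 0 with ktrans > 0", {
  expect_error(tofts_forward(aif, 0.1, 0, 0.01), class = "dpdce_degenerate_parameter")
})

test_that("DP residue: plug-flow limit, entry value E, Stewart-Hamilton area", {
  f <- 0.09; vp <- 0.006; tc <- vp / f
  # ps = 0: boxcar
  expect_equal(dp_residue(c(0, tc / 2), f, 0, vp, 0.07), c(1, 1))
  expect_equal(dp_residue(c(tc, tc * 2, 1), f, 0, vp, 0.07), c(0, 0, 0))
  # R(Tc+) = E = 1 - exp(-ps/f); ps = f gives 1 - 1/e
  expect_equal(dp_residue(tc + 1e-12, f, f, vp, 0.07), 1 - exp(-1), tolerance = 1e-7)
  for (ps in c(0.005, 0.02)) {
    expect_equal(dp_residue(tc + 1e-12, f, ps, vp, 0.07),
                 1 - exp(-ps / f), tolerance = 1e-7)
  }
  # f * int_0^inf R dt = vp + ve, several random parameter sets
  set.seed(21)
  pars <- random_dp_params(4)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    area <- residue_area(p$f, p$ps, p$vp, p$ve)
    expect_lt(abs(area - (p$vp + p$ve)) / (p$vp + p$ve), 0.005)
  }
})

test_that("DP residue is monotone non-increasing after the plateau", {
  tt <- seq(0, 10, length.out = 400)
  r <- dp_residue(tt, 0.08, 0.02, 0.005, 0.06)
  expect_true(all(diff(r) <= 1e-10))
  expect_equal(r[1], 1)
})

test_that("DP forward reduces to boxcar convolution when ps = 0 (area ratio vp)", {
  ct <- dp_forward(aif, f = 0.09, ps = 0, vp = 0.006, ve = 0)
  dt <- diff(aif$time)[1]
  area_ratio <- sum(ct$ct) / sum(aif$cp)
  expect_equal(area_ratio, 0.006, tolerance = 0.01)
})

test_that("DP forward of a narrow bolus reproduces f * R(t - t_bolus)", {
  tg <- seq(0, 3, by = 1 / 600)
  w <- 1 / 300
  bolus <- tibble::tibble(time = tg, cp = ifelse(abs(tg - 0.3) <= w / 2, 1 / w, 0))
  p <- list(f = 0.09, ps = 0.02, vp = 0.009, ve = 0.07)
  ct <- dp_forward(bolus, p$f, p$ps, p$vp, p$ve, dt_internal = 1 / 2400)$ct
  # exclude the bolus itself and a bolus-width window around the residue's
  # jump at t_bolus + Tc, where the finite-width bolus smooths the edge
  tc <- p$vp / p$f
  tpost <- tg >= 0.32 & tg <= 2.5 & abs(tg - (0.3 + tc)) > 0.01
  expect_lt(max(abs(ct[tpost] - p$f * dp_residue(tg[tpost] - 0.3, p$f, p$ps, p$vp, p$ve))) /
              (p$f), 0.02)
})

test_that("both forward models are linear in the AIF and preserve nonnegativity", {
  aif3 <- tibble::tibble(time = aif$time, cp = 3 * aif$cp)
  expect_equal(tofts_forward(aif3, 0.02, 0.07, 0.005)$ct,
               3 * tofts_forward(aif, 0.02, 0.07, 0.005)$ct, tolerance = 1e-12)
  expect_equal(dp_forward(aif3, 0.09, 0.02, 0.006, 0.07)$ct,
               3 * dp_forward(aif, 0.09, 0.02, 0.006, 0.07)$ct, tolerance = 1e-12)
  expect_true(all(tofts_forward(aif, 0.02, 0.07, 0.005)$ct >= 0))
  expect_true(all(dp_forward(aif, 0.09, 0.02, 0.006, 0.07)$ct >= 0))
})

test_that("Stewart-Hamilton holds for the Tofts impulse response (vp + ve)", {
  # integral of the Eq-1 impulse response: vp + ktrans/kep = vp + ve
  p <- list(ktrans = 0.03, ve = 0.08, vp = 0.004)
  expect_equal(p$vp + p$ktrans / kep_from(p$ktrans, p$ve), p$vp + p$ve)
})

test_that("halving the internal convolution step changes ct by < 0.1%", {
  for (p in list(list(f = 0.09, ps = 0.02, vp = 0.006, ve = 0.07),
                 list(f = 0.14, ps = 0.005, vp = 0.002, ve = 0.01))) {
    c1 <- dp_forward(aif, p$f, p$ps, p$vp, p$ve, dt_internal = 1 / 120)$ct
    c2 <- dp_forward(aif, p$f, p$ps, p$vp, p$ve, dt_internal = 1 / 240)$ct
    expect_lt(max(abs(c1 - c2)) / max(c2), 0.001)
  }
  c1 <- tofts_forward(aif, 0.02, 0.07, 0.005, dt_internal = 1 / 120)$ct
  c2 <- tofts_forward(aif, 0.02, 0.07, 0.005, dt_internal = 1 / 240)$ct
  expect_lt(max(abs(c1 - c2)) / max(c2), 0.001)
})

test_that("DP forward agrees with the two-region PDE oracle (spot check)", {
  p <- list(f = 0.085, ps = 0.012, vp = 0.006, ve = 0.04)
  ct <- dp_forward(aif, p$f, p$ps, p$vp, p$ve)$ct
  oracle <- pde_dp_oracle(aif$time, aif$cp, p$f, p$ps, p$vp, p$ve)
  expect_lt(max(abs(ct - oracle)) / max(oracle), 0.02)
})

test_that("short transit times are clamped with a classed warning", {
  expect_warning(dp_forward(aif, f = 2, ps = 0.01, vp = 0.002, ve = 0.05),
                 class = "dpdce_tc_clamped")
})

test_that("derived quantities: extraction fraction and kep", {
  expect_equal(extraction_fraction(0.09, 0), 0)
  expect_gt(extraction_fraction(0.01, 2), 99.99)       # ps/f -> inf
  expect_true(all(diff(extraction_fraction(0.09, seq(0, 0.1, by = 0.01))) > 0))
  # direct evaluation at the reported wild-type-like medians (per-100-mL units)
  expect_equal(extraction_fraction(8.532, 0.896), 9.96905, tolerance = 1e-4)
  expect_error(extraction_fraction(0, 0.1), class = "dpdce_degenerate_parameter")
  expect_equal(kep_from(0, 0.5), 0)
  expect_equal(kep_from(0.3, 1), 0.3)
  expect_equal(kep_from(0.022, 0.068), 0.3235294, tolerance = 1e-6)
  expect_error(kep_from(0.1, 0), class = "dpdce_degenerate_parameter")
})
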