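aif <- std_aif()

test_that("noiseless Tofts curves are recovered to < 0.5% relative error", {
  p <- list(ktrans = 0.02, ve = 0.07, vp = 0.005)
  ct <- tofts_forward(aif, p$ktrans, p$ve, p$vp)
  fit <- fit_curve(ct, aif, "tofts")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params - unlist(p)) / unlist(p)), 0.005)
  expect_equal(glance(fit)$model, "tofts")
  expect_equal(tidy(fit)$term, c("ktrans", "ve", "vp"))
})

test_that("noiseless DP curves are recovered to < 2% relative error", {
  p <- list(f = 0.09, ps = 0.02, vp = 0.006, ve = 0.07)
  ct <- dp_forward(aif, p$f, p$ps, p$vp, p$ve)
  fit <- fit_curve(ct, aif, "dp")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params - unlist(p)) / unlist(p)), 0.02)
})

test_that("returned rss never exceeds the best multi-start initial point and beats random search", {
  set.seed(33)
  cfg <- fit_config()
  ctx <- dpdce:::conv_context(aif$time, aif$cp, dt = cfg$dt_internal)
  lattice <- dpdce:::start_lattice("tofts", cfg)
  pars <- random_tofts_params(8)
  n_rand <- 1e4
  rand <- cbind(runif(n_rand, 0, 2), runif(n_rand, 1e-4, 1), runif(n_rand, 0, 0.5))
  for (i in seq_len(nrow(pars))) {
    p <- unlist(pars[i, ])
    y <- dpdce:::tofts_ct(ctx, p[1], p[2], p[3]) + rnorm(length(aif$time), 0, 0.002)
    fit <- dpdce:::fit_curve_ctx(y, ctx, "tofts", cfg)
    lattice_rss <- apply(lattice, 1, function(q) sum((y - dpdce:::tofts_ct(ctx, q[1], q[2], q[3]))^2))
    expect_lte(fit$rss, min(lattice_rss) + 1e-12)
    # random-search oracle over the same bounds
    rand_rss <- min(apply(rand[sample.int(n_rand, 1250), , drop = FALSE], 1, function(q) {
      sum((y - dpdce:::tofts_ct(ctx, q[1], q[2], q[3]))^2)
    }))
    expect_lte(fit$rss, rand_rss)
  }
})

test_that("fit_curve validates grids and sample counts", {
  ct <- tofts_forward(aif, 0.02, 0.07, 0.005)
  expect_error(fit_curve(ct[1:30, ], aif, "tofts"), class = "dpdce_invalid_input")
  short <- aif[1:25, ]
  ct_s <- tofts_forward(short, 0.02, 0.07, 0.005)
  # 25 samples but bolus at 24 s leaves < 20 post-bolus points
  expect_error(fit_curve(ct_s[1:20, ], short[1:20, ], "tofts"),
               class = "dpdce_invalid_input")
})

test_that("fit_roi fits all good voxels and excludes degenerate ones", {
  set.seed(5)
  pars <- random_tofts_params(6)
  Y <- t(apply(pars, 1, function(p) tofts_forward(aif, p[1], p[2], p[3])$ct))
  roi <- fit_roi(Y, rep(TRUE, 6), aif, "tofts")
  expect_equal(roi$n_excluded, 0)
  expect_true(all(roi$fits$converged))
  # inject an all-zero voxel: excluded, others unaffected
  Y2 <- rbind(Y, 0)
  roi2 <- fit_roi(Y2, rep(TRUE, 7), aif, "tofts")
  expect_equal(roi2$n_excluded, 1)
  expect_equal(roi2$fits$reason[7], "degenerate-signal")
  expect_equal(roi2$fits$ktrans[1:6], roi$fits$ktrans)
})

test_that("ROI medians: order statistics, permutation invariance, reported units", {
  fits <- tibble::tibble(voxel = 1:5,
                         ktrans = c(0.05, 0.01, 0.03, 0.02, 0.04),
                         ve = c(0.05, 0.01, 0.03, 0.02, 0.04),
                         vp = c(0.005, 0.001, 0.003, 0.002, 0.004),
                         rss = 0, converged = TRUE, excluded = FALSE,
                         reason = NA_character_)
  med <- aggregate_roi_median(fits)
  expect_equal(med$tofts_ktrans, 0.03)          # middle order statistic
  expect_equal(med$tofts_ve, 3)                 # x100 reported units
  expect_equal(med$tofts_kep, 1)                # per-voxel kep all equal 1
  expect_equal(med$n_voxels_used, 5)
  perm <- fits[sample.int(5), ]
  expect_equal(aggregate_roi_median(perm), med)
  # single voxel
  one <- aggregate_roi_median(fits[2, ])
  expect_equal(one$tofts_ktrans, 0.01)
  # exclusion placement does not change the answer
  fits2 <- dplyr::bind_rows(fits, dplyr::mutate(fits[1, ], ktrans = 99, excluded = TRUE))
  expect_equal(aggregate_roi_median(fits2)$tofts_ktrans, 0.03)
  expect_error(aggregate_roi_median(dplyr::mutate(fits, excluded = TRUE)),
               class = "dpdce_invalid_input")
})

test_that("DP medians derive E per voxel before aggregation", {
  fits <- tibble::tibble(voxel = 1:3,
                         f = c(0.05, 0.09, 0.13), ps = c(0.002, 0.03, 0.01),
                         vp = c(0.004, 0.006, 0.008), ve = c(0.02, 0.05, 0.08),
                         rss = 0, converged = TRUE, excluded = FALSE,
                         reason = NA_character_)
  med <- aggregate_roi_median(structure(list(model = "dp", fits = fits,
                                             n_excluded = 0, n_voxels = 3),
                                        class = "dce_roi_fit"))
  e_vox <- 100 * (1 - exp(-fits$ps / fits$f))
  expect_equal(med$dp_e, median(e_vox))
  # median of voxelwise E differs from E of the median F, PS here
  expect_false(isTRUE(all.equal(med$dp_e, 100 * (1 - exp(-median(fits$ps) / median(fits$f))))))
})

test_that("map medians over a synthetic ROI track the generating distribution", {
  set.seed(77)
  n <- 60
  truth <- list(f = 0.085, ps = 0.015, vp = 0.006, ve = 0.05)
  vox <- lapply(truth, function(m) m * exp(rnorm(n, 0, 0.15)))
  ctx <- dpdce:::conv_context(aif$time, aif$cp, dt = 1 / 120)
  Y <- t(vapply(seq_len(n), function(i) {
    suppressWarnings(dpdce:::dp_ct(ctx, vox$f[i], vox$ps[i], vox$vp[i], vox$ve[i]))
  }, numeric(length(aif$time))))
  roi <- fit_roi(Y, rep(TRUE, n), aif, "dp")
  med <- aggregate_roi_median(roi)
  expect_lt(abs(med$dp_ve - 100 * median(vox$ve)) / (100 * median(vox$ve)), 0.05)
  expect_lt(abs(med$dp_f - 100 * median(vox$f)) / (100 * median(vox$f)), 0.05)
})
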