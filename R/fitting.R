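# Voxelwise nonlinear estimation of kinetic parameters and ROI-median
# aggregation.

#' Fitting configuration
#'
#' Bounds (fractional units, 1/min) generously cover the kinetic-parameter
#' ranges reported for gliomas; the multi-start lattice places 3 values per
#' parameter across the bounds, geometrically for the rate/flow parameters
#' and linearly for the volume fractions, because the distributed-parameter
#' objective is multimodal in (f, ps).
#'
#' @param ktrans_bounds,ve_bounds,vp_bounds,f_bounds,ps_bounds length-2
#'   numeric bounds (fractional units).
#' @param n_refine how many best-RSS lattice starts are polished with
#'   bounded Levenberg-Marquardt.
#' @param dt_internal internal convolution step, minutes.
#' @param rss_exclude voxels whose fitted RSS exceeds this (mM^2) are
#'   excluded from aggregation.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A list of class `dce_fit_config`.
#' @export
fit_config <- function(ktrans_bounds = c(0, 2), ve_bounds = c(1e-4, 1),
                       vp_bounds = c(0, 0.5), f_bounds = c(1e-3, 4),
                       ps_bounds = c(0, 2), n_refine = 6L,
                       dt_internal = 1 / 120, rss_exclude = Inf,
                       maxiter = 50L) {
  structure(list(ktrans_bounds = ktrans_bounds, ve_bounds = ve_bounds,
                 vp_bounds = vp_bounds, f_bounds = f_bounds,
                 ps_bounds = ps_bounds, n_refine = as.integer(n_refine),
                 dt_internal = dt_internal, rss_exclude = rss_exclude,
                 maxiter = as.integer(maxiter)),
            class = "dce_fit_config")
}

# 3-point geometric spans per parameter (lower bound floored at a small
# positive value).  Kinetic parameters vary over orders of magnitude across
# tissue, so geometric spacing puts a lattice point near the physiological
# decade for every parameter; a linear span for the volume fractions leaves
# no start near brain-tissue vp (~0.005) and funnels the optimizer into a
# degenerate short-transit ridge.
lattice_geom <- function(b, floor = 1e-3) exp(seq(log(max(b[1], floor)), log(b[2]), length.out = 3))

start_lattice <- function(model, cfg) {
  if (model == "tofts") {
    g <- expand.grid(ktrans = lattice_geom(cfg$ktrans_bounds),
                     ve = lattice_geom(cfg$ve_bounds, floor = 1e-3),
                     vp = lattice_geom(cfg$vp_bounds, floor = 1e-4))
  } else {
    g <- expand.grid(f = lattice_geom(cfg$f_bounds),
                     ps = lattice_geom(cfg$ps_bounds, floor = 1e-4),
                     vp = lattice_geom(cfg$vp_bounds, floor = 1e-4),
                     ve = lattice_geom(cfg$ve_bounds, floor = 1e-3))
  }
  as.matrix(g)
}

model_bounds <- function(model, cfg) {
  if (model == "tofts") {
    list(lower = c(cfg$ktrans_bounds[1], max(cfg$ve_bounds[1], 1e-4), cfg$vp_bounds[1]),
         upper = c(cfg$ktrans_bounds[2], cfg$ve_bounds[2], cfg$vp_bounds[2]),
         names = c("ktrans", "ve", "vp"))
  } else {
    list(lower = c(cfg$f_bounds[1], cfg$ps_bounds[1], max(cfg$vp_bounds[1], 1e-4),
                   max(cfg$ve_bounds[1], 1e-4)),
         upper = c(cfg$f_bounds[2], cfg$ps_bounds[2], cfg$vp_bounds[2], cfg$ve_bounds[2]),
         names = c("f", "ps", "vp", "ve"))
  }
}

model_eval <- function(model, ctx, par) {
  if (model == "tofts") {
    tofts_ct(ctx, par[1], par[2], par[3])
  } else {
    dp_ct(ctx, par[1], par[2], par[3], par[4])
  }
}

#' Fit one concentration curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, numeric Jacobian)
#' minimizing the sum of squared concentration residuals.  The RSS is first
#' evaluated at every point of a fixed multi-start lattice; the `n_refine`
#' best starts are polished and the lowest final RSS wins (ties broken by
#' lattice order).  If no start converges the best-effort parameters are
#' returned with `converged = FALSE`.
#'
#' @param ct tissue curve: data frame with columns `time` (min) and `ct`
#'   (mM), on the same grid as `aif`.
#' @param aif data frame with columns `time`, `cp`.
#' @param model `"tofts"` or `"dp"`.
#' @param config a [fit_config()].
#' @return An object of class `dce_fit` with elements `model`, `params`
#'   (named, fractional units), `rss`, `n_iter`, `converged`, `init_used`,
#'   `physical` (volume fractions sum to <= 1), and the observed/fitted
#'   curves.  Has [tidy()] and [glance()] methods.
#' @export
fit_curve <- function(ct, aif, model = c("tofts", "dp"), config = fit_config()) {
  model <- match.arg(model)
  a <- check_aif(aif)
  cc <- as_curve(ct, "ct")
  if (length(cc$time) != length(a$time) || max(abs(cc$time - a$time)) > 1e-9) {
    stop_invalid("ct and aif must share the same time grid")
  }
  post_bolus <- sum(cc$time >= a$time[which(a$value > 0)[1]])
  if (is.na(post_bolus) || post_bolus < 20L) {
    stop_invalid("need >= 20 post-bolus samples to fit")
  }
  ctx <- conv_context(a$time, a$value, dt = config$dt_internal)
  fit_curve_ctx(cc$value, ctx, model, config, time = a$time)
}

# fast path used by fit_roi: context prebuilt, clamp warnings muffled.
fit_curve_ctx <- function(y, ctx, model, config, time = ctx$time) {
  b <- model_bounds(model, config)
  lattice <- start_lattice(model, config)
  n_clamped <- 0L
  quiet <- function(expr) {
    withCallingHandlers(expr, dpdce_tc_clamped = function(w) {
      n_clamped <<- n_clamped + 1L
      invokeRestart("muffleWarning")
    })
  }
  rss_of <- function(par) {
    r <- y - quiet(model_eval(model, ctx, par))
    sum(r * r)
  }
  lattice_rss <- apply(lattice, 1, rss_of)
  ord <- order(lattice_rss)
  best <- list(par = lattice[ord[1], ], rss = lattice_rss[ord[1]],
               n_iter = 0L, converged = FALSE, init = lattice[ord[1], ])
  # refine the best-RSS starts, but skip starts whose initial RSS is nearly
  # identical to one already refined: those sit on the same objective
  # plateau and would waste the refinement budget on duplicate basins
  refined_rss0 <- numeric(0)
  n_refined <- 0L
  for (i in seq_len(nrow(lattice))) {
    if (n_refined >= config$n_refine) break
    rss0 <- lattice_rss[ord[i]]
    if (length(refined_rss0) &&
        any(abs(rss0 - refined_rss0) <= 0.05 * pmax(refined_rss0, 1e-300))) {
      next
    }
    refined_rss0 <- c(refined_rss0, rss0)
    n_refined <- n_refined + 1L
    start <- pmin(pmax(lattice[ord[i], ], b$lower), b$upper)
    # minpack's iteration-cap warning is routine here: a capped start simply
    # loses the rss comparison
    muffle_lm <- function(expr) {
      withCallingHandlers(expr, warning = function(w) {
        if (grepl("lmdif|lmder|maxiter", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    }
    fit <- tryCatch(
      muffle_lm(quiet(minpack.lm::nls.lm(
        par = start,
        fn = function(par) y - model_eval(model, ctx, par),
        lower = b$lower, upper = b$upper,
        control = minpack.lm::nls.lm.control(maxiter = config$maxiter)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best$rss - 1e-15) {
      best <- list(par = fit$par, rss = rss, n_iter = fit$niter,
                   converged = fit$info %in% 1:4, init = lattice[ord[i], ])
    } else if (!best$converged && fit$info %in% 1:4 && rss <= best$rss * (1 + 1e-9)) {
      best$converged <- TRUE
      best$n_iter <- fit$niter
    }
    if (best$converged && best$rss < 1e-12 * max(1e-6, sum(y^2))) break
  }
  par <- setNames(as.numeric(best$par), b$names)
  fitted <- quiet(model_eval(model, ctx, best$par))
  vol_sum <- if (model == "tofts") par["ve"] + par["vp"] else par["ve"] + par["vp"]
  structure(list(model = model, params = par, rss = best$rss,
                 n_iter = best$n_iter, converged = best$converged,
                 init_used = setNames(as.numeric(best$init), b$names),
                 physical = as.logical(vol_sum <= 1),
                 n_clamped = n_clamped,
                 data = tibble::tibble(time = time, observed = y, fitted = fitted)),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("<dce_fit: %s model, rss = %.4g, converged = %s>\n",
              x$model, x$rss, x$converged))
  print(round(x$params, 5))
  invisible(x)
}

#' @rdname fit_curve
#' @param x a `dce_fit`.
#' @param ... unused.
#' @export
tidy.dce_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = as.numeric(x$params))
}

#' @rdname fit_curve
#' @export
glance.dce_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, n_iter = x$n_iter,
                 converged = x$converged, physical = x$physical)
}

#' Fit every voxel of an ROI
#'
#' @param conc either a matrix (voxels x frames) of concentration curves or
#'   a 4D array `[x, y, z, t]`.
#' @param mask logical vector (matrix interface) or 3D logical array
#'   aligned to `conc`; at least one voxel must be `TRUE`.
#' @inheritParams fit_curve
#' @return An object of class `dce_roi_fit`: a list with `fits` (tibble of
#'   per-voxel parameter estimates in fractional units plus `rss`,
#'   `converged`, `excluded`, `reason`), `model`, and counts of excluded
#'   voxels.
#' @export
fit_roi <- function(conc, mask, aif, model = c("tofts", "dp"),
                    config = fit_config()) {
  model <- match.arg(model)
  a <- check_aif(aif)
  if (length(dim(conc)) == 4L) {
    dm <- dim(conc)
    if (is.null(dim(mask)) || any(dim(mask) != dm[1:3])) {
      stop_invalid("mask dimensions must match the spatial grid of conc")
    }
    vox <- which(as.logical(mask))
    Y <- array(conc, c(prod(dm[1:3]), dm[4]))[vox, , drop = FALSE]
  } else {
    Y <- as.matrix(conc)
    vox <- which(as.logical(mask))
    if (length(mask) != nrow(Y)) stop_invalid("mask length must match rows of conc")
    Y <- Y[vox, , drop = FALSE]
  }
  if (length(vox) < 1L) stop_invalid("mask selects no voxels")
  if (ncol(Y) != length(a$time)) stop_invalid("conc frames must match aif grid")
  ctx <- conv_context(a$time, a$value, dt = config$dt_internal)
  rows <- purrr::map(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]
    if (!all(is.finite(y)) || all(y == 0)) {
      return(tibble::tibble(voxel = vox[i], rss = NA_real_, converged = FALSE,
                            excluded = TRUE, reason = "degenerate-signal"))
    }
    f <- fit_curve_ctx(y, ctx, model, config)
    excl <- !f$converged || !f$physical || f$rss > config$rss_exclude
    reason <- if (!excl) NA_character_
              else if (!f$converged) "non-converged"
              else if (!f$physical) "nonphysical" else "rss-threshold"
    dplyr::bind_cols(tibble::tibble(voxel = vox[i]),
                     tibble::as_tibble(as.list(f$params)),
                     tibble::tibble(rss = f$rss, converged = f$converged,
                                    excluded = excl, reason = reason))
  })
  fits <- dplyr::bind_rows(rows)
  structure(list(model = model, fits = fits,
                 n_excluded = sum(fits$excluded),
                 n_voxels = nrow(fits)),
            class = "dce_roi_fit")
}

#' Write per-voxel parameter maps as NIfTI volumes
#'
#' One single-precision volume per fitted parameter (plus `rss`), with
#' excluded voxels and everything outside the ROI set to `NA`.
#'
#' @param roi_fit a `dce_roi_fit` from [fit_roi()].
#' @param dim3 spatial dimensions of the original volume.
#' @param dir output directory.
#' @param prefix filename prefix (default the model name).
#' @return Invisibly, the paths written.
#' @export
write_param_maps <- function(roi_fit, dim3, dir, prefix = roi_fit$model) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fits <- roi_fit$fits
  par_cols <- intersect(c("ktrans", "ve", "vp", "f", "ps", "rss"), names(fits))
  ok <- !fits$excluded
  paths <- vapply(par_cols, function(pc) {
    vol <- array(NA_real_, dim3)
    vol[fits$voxel[ok]] <- fits[[pc]][ok]
    p <- file.path(dir, sprintf("%s_%s.nii", prefix, pc))
    RNifti::writeNifti(vol, p, datatype = "float")
    p
  }, character(1))
  invisible(paths)
}

#' ROI-median kinetic parameters, in reported units
#'
#' Medians are taken over valid (non-excluded) in-mask voxels; the derived
#' quantities `kep = ktrans/ve` and `E = 100 (1 - exp(-ps/f))` are computed
#' per voxel *before* the median, so the reported median E is a median of
#' voxelwise extraction fractions.  Volume fractions and flows are reported
#' x100 (mL/100 mL, mL/min/100 mL); rate constants stay in 1/min; E in
#' percent.
#'
#' @param roi_fit a `dce_roi_fit` from [fit_roi()], or its `fits` tibble.
#' @return A one-row tibble of medians in reported units plus
#'   `n_voxels_used`.
#' @export
aggregate_roi_median <- function(roi_fit) {
  fits <- if (inherits(roi_fit, "dce_roi_fit")) roi_fit$fits else roi_fit
  model <- if (inherits(roi_fit, "dce_roi_fit")) roi_fit$model
           else if ("f" %in% names(fits)) "dp" else "tofts"
  ok <- fits[!fits$excluded, , drop = FALSE]
  if (nrow(ok) == 0L) stop_invalid("no valid voxels to aggregate")
  if (model == "tofts") {
    tibble::tibble(
      model = "tofts",
      tofts_ktrans = median(ok$ktrans),
      tofts_ve = 100 * median(ok$ve),
      tofts_vp = 100 * median(ok$vp),
      tofts_kep = median(ok$ktrans / ok$ve),
      n_voxels_used = nrow(ok))
  } else {
    tibble::tibble(
      model = "dp",
      dp_f = 100 * median(ok$f),
      dp_ps = 100 * median(ok$ps),
      dp_vp = 100 * median(ok$vp),
      dp_ve = 100 * median(ok$ve),
      dp_e = median(extraction_fraction(ok$f, ok$ps)),
      n_voxels_used = nrow(ok))
  }
}
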