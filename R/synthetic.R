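# Calibrated synthetic glioma cohort: ground-truth kinetic parameters per
# molecular subtype, Ki-67 indices coupled to interstitial volume, and
# rendered VFA + 4D dynamic volumes.

#' Log-normal distribution matched to a printed median and IQR
#'
#' `meanlog = log(median)` and `sdlog = log(q75/q25) / (2 z_0.75)` with
#' `z_0.75 = qnorm(0.75)`.  The returned distribution reproduces the median
#' and the interquartile *ratio* exactly; when the printed quartiles are
#' asymmetric on the log scale around the median the individual quartiles
#' are matched only approximately.
#'
#' @param median,q25,q75 target median and quartiles, `0 < q25 < median < q75`.
#' @return A list with `meanlog`, `sdlog`.
#' @export
lognormal_from_median_iqr <- function(median, q25, q75) {
  if (!(is.finite(median) && is.finite(q25) && is.finite(q75)) ||
      !(0 < q25 && q25 < median && median < q75)) {
    stop_invalid("need 0 < q25 < median < q75")
  }
  list(meanlog = log(median), sdlog = log(q75 / q25) / (2 * qnorm(0.75)))
}

#' Default per-group calibration of the distributed-parameter truth
#'
#' Median and quartiles (reported units: mL/min/100 mL for `f` and `ps`,
#' mL/100 mL for `vp` and `ve`) of the generative DP parameters for the
#' three molecular subtypes, taken from the glioma cohort this package
#' models.  Extended Tofts truth is *derived* from these (`ktrans = E f`,
#' shared `ve`, `vp`), so only these four parameters are calibrated.
#'
#' @return A tibble with columns `group`, `param`, `median`, `q25`, `q75`.
#' @export
default_calibration <- function() {
  tibble::tribble(
    ~group,       ~param, ~median, ~q25,   ~q75,
    "wild-type",  "f",     7.454,  6.308, 13.777,
    "wild-type",  "ps",    2.445,  1.769,  3.527,
    "wild-type",  "vp",    0.897,  0.600,  1.508,
    "wild-type",  "ve",    6.739,  3.558, 11.505,
    "intact",     "f",     6.607,  5.196,  6.997,
    "intact",     "ps",    1.437,  0.281,  2.257,
    "intact",     "vp",    0.380,  0.149,  0.542,
    "intact",     "ve",    0.276,  0.182,  4.969,
    "codeleted",  "f",     8.963,  8.320, 12.418,
    "codeleted",  "ps",    0.872,  0.457,  1.245,
    "codeleted",  "vp",    0.283,  0.215,  0.679,
    "codeleted",  "ve",    0.415,  0.247,  3.201)
}

#' Synthetic cohort configuration
#'
#' Group sizes default to the modelled study (24 IDH wild-type, 9 mutant
#' with intact 1p/19q, 15 mutant codeleted = 48 patients).  Acquisition
#' constants default to the modelled protocol: 10 pre-contrast baseline
#' frames plus 180 dynamic frames at 2 s, SPGR TR 3.03 ms, pre-contrast
#' flip angles 3/6/9 degrees, dynamic angle 9 degrees.
#'
#' @param n_wildtype,n_intact,n_codeleted group sizes.
#' @param calibration per-group DP parameter targets, see
#'   [default_calibration()].
#' @param vp_f_rho Spearman correlation between `vp` and `f` within a
#'   patient group (Gaussian copula); the modelled study reports 0.56.
#' @param ki67_rho target Spearman correlation between Ki-67 and true DP
#'   `ve` across the cohort.
#' @param jitter_sd log-scale SD of the multiplicative within-ROI voxel
#'   heterogeneity.
#' @param roi_dim,vol_dim ROI and volume dimensions (voxels).
#' @param n_baseline,n_dynamic,dt_s frame counts and temporal resolution.
#' @param flip_pre,flip_dyn,tr_ms flip angles (degrees) and TR.
#' @param r1 relaxivity, L mmol^-1 s^-1.
#' @param t10_tumor_ms,t10_bg_ms,m0 pre-contrast T1 (tumour, background) and
#'   equilibrium signal used when rendering volumes.
#' @param snr baseline-signal-to-noise ratio of rendered volumes.
#' @param noise `"rician"` (on signal) or `"gaussian"`.
#' @param bolus_arrival_s bolus arrival time, seconds.
#' @param ki67_meanlog,ki67_sdlog marginal of the Ki-67 labelling index
#'   (percent), truncated to \[1, 90\].
#' @return A list of class `dce_cohort_config`.
#' @export
cohort_config <- function(n_wildtype = 24, n_intact = 9, n_codeleted = 15,
                          calibration = default_calibration(),
                          vp_f_rho = 0.56, ki67_rho = 0.62,
                          jitter_sd = 0.15,
                          roi_dim = c(6, 6, 3), vol_dim = c(10, 10, 5),
                          n_baseline = 10, n_dynamic = 180, dt_s = 2,
                          flip_pre = c(3, 6, 9), flip_dyn = 9, tr_ms = 3.03,
                          r1 = 3.6, t10_tumor_ms = 1400, t10_bg_ms = 1000,
                          m0 = 500, snr = 20,
                          noise = c("rician", "gaussian"),
                          bolus_arrival_s = 24,
                          ki67_meanlog = log(15), ki67_sdlog = 0.9) {
  noise <- match.arg(noise)
  if (any(c(n_wildtype, n_intact, n_codeleted) < 1)) stop_invalid("group sizes must be >= 1")
  if (snr <= 0) stop_invalid("snr must be > 0")
  if (any(!(calibration$q25 < calibration$median & calibration$median < calibration$q75))) {
    stop_invalid("calibration medians must lie inside their IQRs")
  }
  structure(list(n_wildtype = n_wildtype, n_intact = n_intact,
                 n_codeleted = n_codeleted, calibration = calibration,
                 vp_f_rho = vp_f_rho, ki67_rho = ki67_rho,
                 jitter_sd = jitter_sd, roi_dim = roi_dim, vol_dim = vol_dim,
                 n_baseline = n_baseline, n_dynamic = n_dynamic, dt_s = dt_s,
                 flip_pre = flip_pre, flip_dyn = flip_dyn, tr_ms = tr_ms,
                 r1 = r1, t10_tumor_ms = t10_tumor_ms, t10_bg_ms = t10_bg_ms,
                 m0 = m0, snr = snr, noise = noise,
                 bolus_arrival_s = bolus_arrival_s,
                 ki67_meanlog = ki67_meanlog, ki67_sdlog = ki67_sdlog),
            class = "dce_cohort_config")
}

cohort_times <- function(config) {
  ((seq_len(config$n_baseline + config$n_dynamic) - 1) * config$dt_s) / 60
}

# Spearman -> Pearson correlation of the latent Gaussian copula.
copula_r <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Sample ground-truth cohort parameters
#'
#' Per patient the four generative DP parameters (`f`, `ps`, `vp`, `ve`,
#' fractional internal units) are drawn from the group's calibrated
#' log-normal marginals, coupled by a Gaussian copula with rank correlation
#' `vp_f_rho` between `vp` and `f` (other pairs independent).  Derived
#' truth: `E = 1 - exp(-ps/f)`, `ktrans = E f`, `kep = ktrans/ve`; `ve` and
#' `vp` are shared between models.  Ki-67 is attached by [sample_ki67()].
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed; identical `(config, seed)` reproduce
#'   the cohort exactly.
#' @return A tibble (one row per patient) with labels (`idh`,
#'   `codeletion`, `group`), Ki-67, and the 9 kinetic parameters in
#'   reported units (`dp_f` ... `tofts_kep`).
#' @export
sample_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  groups <- c(rep("wild-type", config$n_wildtype),
              rep("intact", config$n_intact),
              rep("codeleted", config$n_codeleted))
  n <- length(groups)
  cal <- config$calibration
  spec_of <- function(group, param) {
    row <- cal[cal$group == group & cal$param == param, ]
    if (nrow(row) != 1L) stop_invalid(sprintf("calibration missing %s/%s", group, param))
    lognormal_from_median_iqr(row$median, row$q25, row$q75)
  }
  r <- copula_r(config$vp_f_rho)
  draws <- purrr::map(seq_len(n), function(i) {
    g <- groups[i]
    z <- rnorm(4)                      # order: f, ps, vp, ve
    z[3] <- r * z[1] + sqrt(1 - r^2) * z[3]   # couple vp to f
    vals <- purrr::map2_dbl(c("f", "ps", "vp", "ve"), z, function(pn, zi) {
      s <- spec_of(g, pn)
      exp(s$meanlog + s$sdlog * zi) / 100     # reported -> fractional
    })
    names(vals) <- c("f", "ps", "vp", "ve")
    # keep volume fractions physical (heavy upper lognormal tail)
    tot <- vals["ve"] + vals["vp"]
    if (tot > 0.95) vals[c("ve", "vp")] <- vals[c("ve", "vp")] * 0.95 / tot
    vals
  })
  m <- do.call(rbind, draws)
  e_frac <- 1 - exp(-m[, "ps"] / m[, "f"])
  ktrans <- e_frac * m[, "f"]
  truth <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    group = groups,
    idh = ifelse(groups == "wild-type", "wild-type", "mutation"),
    codeletion = dplyr::case_when(groups == "intact" ~ "intact",
                                  groups == "codeleted" ~ "codeleted",
                                  TRUE ~ NA_character_),
    dp_f = 100 * m[, "f"], dp_ps = 100 * m[, "ps"],
    dp_vp = 100 * m[, "vp"], dp_ve = 100 * m[, "ve"],
    dp_e = 100 * e_frac,
    tofts_ktrans = ktrans,
    tofts_ve = 100 * m[, "ve"], tofts_vp = 100 * m[, "vp"],
    tofts_kep = ktrans / m[, "ve"])
  truth$ki67 <- sample_ki67(truth, target_rho = config$ki67_rho,
                            seed = seed + 1L,
                            meanlog = config$ki67_meanlog,
                            sdlog = config$ki67_sdlog)
  truth
}

#' Sample Ki-67 indices rank-coupled to interstitial volume
#'
#' Gaussian copula linking the Ki-67 rank to the rank of the true DP `ve`
#' with target Spearman correlation `target_rho`; the marginal is
#' log-normal, truncated to \[1, 90\] percent.
#'
#' @param truth a cohort truth tibble with column `dp_ve` (any monotone
#'   transform of the true ve works).
#' @param target_rho target Spearman correlation.
#' @param seed integer seed.
#' @param meanlog,sdlog Ki-67 marginal parameters.
#' @return Numeric vector of Ki-67 labelling indices (percent).
#' @export
sample_ki67 <- function(truth, target_rho = 0.62, seed = 1,
                        meanlog = log(15), sdlog = 0.9) {
  if (abs(target_rho) > 1) stop_invalid("target_rho must be in [-1, 1]")
  set.seed(seed)
  n <- nrow(truth)
  z_ve <- qnorm((rank(truth$dp_ve) - 0.5) / n)
  r <- copula_r(target_rho)
  z <- r * z_ve + sqrt(max(0, 1 - r^2)) * rnorm(n)
  ki <- exp(meanlog + sdlog * qnorm(pnorm(z)))
  pmin(90, pmax(1, ki))
}

# multiplicative voxel heterogeneity around the patient value
jitter_voxels <- function(patient, n_vox, jitter_sd) {
  par_names <- c("f", "ps", "vp", "ve")
  base <- c(patient$dp_f, patient$dp_ps, patient$dp_vp, patient$dp_ve) / 100
  m <- vapply(seq_along(par_names), function(j) {
    base[j] * exp(rnorm(n_vox, 0, jitter_sd))
  }, numeric(n_vox))
  colnames(m) <- par_names
  tot <- m[, "ve"] + m[, "vp"]
  over <- tot > 0.95
  m[over, c("ve", "vp")] <- m[over, c("ve", "vp")] * 0.95 / tot[over]
  m
}

#' Render one synthetic patient acquisition
#'
#' Builds a small rectangular ROI (default 6 x 6 x 3 voxels) centred in a
#' slightly larger volume, jitters the patient's ground-truth DP parameters
#' voxelwise (multiplicative log-normal), generates tissue curves with the
#' distributed-parameter forward model driven by the population AIF,
#' converts them to SPGR signal, adds Rician or Gaussian noise at the
#' configured baseline SNR, and (optionally) writes NIfTI volumes plus the
#' AIF CSV.
#'
#' @param patient one row of a [sample_cohort()] truth tibble.
#' @param config a [cohort_config()].
#' @param seed integer seed for jitter and noise.
#' @param dir output directory; `NULL` keeps everything in memory.
#' @return A list with `vfa` (list of 3D arrays per flip angle), `dynamic`
#'   (4D array), `mask` (3D logical), `aif` (tibble), `voxel_truth`
#'   (tibble), `times` (minutes), and the paths written (if any).
#' @export
render_patient <- function(patient, config = cohort_config(), seed = 1,
                           dir = NULL) {
  set.seed(seed)
  vd <- config$vol_dim; rd <- config$roi_dim
  if (any(rd > vd)) stop_invalid("roi_dim must fit inside vol_dim")
  times <- cohort_times(config)
  aif <- aif_parker(times, bolus_arrival = config$bolus_arrival_s / 60)
  mask <- array(FALSE, vd)
  lo <- floor((vd - rd) / 2) + 1L
  mask[lo[1]:(lo[1] + rd[1] - 1L), lo[2]:(lo[2] + rd[2] - 1L),
       lo[3]:(lo[3] + rd[3] - 1L)] <- TRUE
  n_vox <- sum(mask)
  vox <- jitter_voxels(patient, n_vox, config$jitter_sd)
  ctx <- conv_context(aif$time, aif$cp)
  ct_mat <- t(vapply(seq_len(n_vox), function(i) {
    suppressWarnings(dp_ct(ctx, vox[i, "f"], vox[i, "ps"], vox[i, "vp"], vox[i, "ve"]))
  }, numeric(length(times))))
  t10 <- array(config$t10_bg_ms, vd); t10[mask] <- config$t10_tumor_ms
  # noiseless signals
  nt <- length(times)
  dyn <- array(0, c(vd, nt))
  flat <- array(dyn, c(prod(vd), nt))
  idx_mask <- which(mask)
  base_sig_bg <- spgr_signal(config$m0, config$t10_bg_ms, config$tr_ms, config$flip_dyn)
  flat[, ] <- base_sig_bg
  for (i in seq_len(n_vox)) {
    flat[idx_mask[i], ] <- concentration_to_signal(
      ct_mat[i, ], t10 = config$t10_tumor_ms, m0 = config$m0,
      r1 = config$r1, tr = config$tr_ms, alpha = config$flip_dyn)
  }
  base_sig_tumor <- spgr_signal(config$m0, config$t10_tumor_ms, config$tr_ms, config$flip_dyn)
  sigma <- base_sig_tumor / config$snr
  add_noise <- function(s) {
    if (config$snr == Inf) return(s)
    if (config$noise == "rician") {
      sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
    } else {
      s + rnorm(length(s), 0, sigma)
    }
  }
  flat <- array(add_noise(flat), dim(flat))
  dyn <- array(flat, c(vd, nt))
  vfa <- lapply(config$flip_pre, function(ang) {
    s <- spgr_signal(config$m0, t10, config$tr_ms, ang)
    array(add_noise(s), vd)
  })
  names(vfa) <- sprintf("deg%02d", config$flip_pre)
  voxel_truth <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient$patient_id, voxel = idx_mask),
    tibble::as_tibble(vox))
  out <- list(vfa = vfa, dynamic = dyn, mask = mask, aif = aif,
              voxel_truth = voxel_truth, times = times, paths = character())
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    for (j in seq_along(vfa)) {
      p <- file.path(dir, sprintf("vfa_%s.nii", names(vfa)[j]))
      RNifti::writeNifti(vfa[[j]], p); paths <- c(paths, p)
    }
    p <- file.path(dir, "dynamic.nii"); RNifti::writeNifti(dyn, p); paths <- c(paths, p)
    p <- file.path(dir, "mask.nii")
    RNifti::writeNifti(array(as.integer(mask), vd), p); paths <- c(paths, p)
    p <- file.path(dir, "aif.csv")
    write.csv(data.frame(time_s = aif$time * 60, concentration_mM = aif$cp),
              p, row.names = FALSE); paths <- c(paths, p)
    out$paths <- paths
  }
  out
}
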