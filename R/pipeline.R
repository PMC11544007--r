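# Reproducible multi-stage workflow: simulate -> fit -> stats, each stage
# writing a manifest sufficient to reproduce its outputs.

config_hash <- function(x) rlang::hash(x)

write_manifest <- function(dir, stage, seed, config, extra = list()) {
  manifest <- c(list(stage = stage, seed = seed,
                     config_hash = config_hash(config),
                     package_version = as.character(utils::packageVersion("dpdce")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic cohort run directory
#'
#' Samples cohort ground truth with [sample_cohort()], renders every
#' patient's acquisition with [render_patient()] into per-patient
#' subdirectories, and writes `truth.csv`, `labels.csv`, `aif.csv` and a
#' manifest.
#'
#' @param out_dir run directory (created; must be creatable).
#' @param config a [cohort_config()].
#' @param seed integer master seed; every patient derives its own
#'   sub-seed from it.
#' @return Invisibly, the truth tibble.
#' @export
run_simulate <- function(out_dir, config = cohort_config(), seed = 1) {
  if (is.null(out_dir) || !nzchar(out_dir)) stop_invalid("out_dir must be a valid path")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_invalid(sprintf("cannot create output path: %s", out_dir))
  truth <- sample_cohort(config, seed)
  for (i in seq_len(nrow(truth))) {
    render_patient(truth[i, ], config, seed = seed + 1000L + i,
                   dir = file.path(out_dir, truth$patient_id[i]))
  }
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write.csv(truth[, c("patient_id", "group", "idh", "codeletion", "ki67")],
            file.path(out_dir, "labels.csv"), row.names = FALSE)
  times <- cohort_times(config)
  aif <- aif_parker(times, bolus_arrival = config$bolus_arrival_s / 60)
  write.csv(data.frame(time_s = aif$time * 60, concentration_mM = aif$cp),
            file.path(out_dir, "aif.csv"), row.names = FALSE)
  write_manifest(out_dir, "simulate", seed, config,
                 extra = list(n_patients = nrow(truth)))
  invisible(truth)
}

fit_one_patient <- function(pdir, aif, config, fit_cfg, model) {
  vfa_paths <- sort(list.files(pdir, pattern = "^vfa_.*\\.nii$", full.names = TRUE))
  dyn <- RNifti::readNifti(file.path(pdir, "dynamic.nii"))
  mask <- array(as.logical(RNifti::readNifti(file.path(pdir, "mask.nii"))),
                dim(RNifti::readNifti(file.path(pdir, "mask.nii"))))
  vd <- dim(dyn)[1:3]
  if (any(dim(mask) != vd)) stop_invalid("mask grid does not match dynamic volume")
  angles <- as.numeric(sub(".*deg(\\d+)\\.nii$", "\\1", vfa_paths))
  idx <- which(mask)
  vfa_sig <- vapply(vfa_paths, function(p) {
    v <- RNifti::readNifti(p)
    if (any(dim(v) != vd)) stop_invalid("VFA grid does not match dynamic volume")
    as.numeric(v)[idx]
  }, numeric(length(idx)))
  t1fit <- fit_t1_vfa(vfa_sig, flip_angles = angles, tr = config$tr_ms)
  flat_dyn <- array(dyn, c(prod(vd), dim(dyn)[4]))[idx, , drop = FALSE]
  nt <- ncol(flat_dyn)
  conc <- matrix(NA_real_, length(idx), nt)
  usable <- t1fit$fit_ok
  for (i in which(usable)) {
    s2c <- signal_to_concentration(flat_dyn[i, ], t10 = t1fit$t1[i],
                                   m0 = t1fit$m0[i], r1 = config$r1,
                                   tr = config$tr_ms, alpha = config$flip_dyn,
                                   n_baseline = config$n_baseline)
    ci <- s2c$conc
    bad <- which(!s2c$valid)
    # isolated failed frames are interpolated; longer runs disqualify voxel
    if (length(bad)) {
      runs <- rle(!s2c$valid)
      if (any(runs$lengths[runs$values] > 2)) { usable[i] <- FALSE; next }
      ci[bad] <- approx(which(s2c$valid), ci[s2c$valid], xout = bad, rule = 2)$y
    }
    conc[i, ] <- ci
  }
  fits <- fit_roi(conc[usable, , drop = FALSE], rep(TRUE, sum(usable)), aif,
                  model = model, config = fit_cfg)
  # remap row indices back to volume voxel indices and write parameter maps
  fits$fits$voxel <- idx[usable][fits$fits$voxel]
  write_param_maps(fits, vd, file.path(pdir, "maps"))
  med <- aggregate_roi_median(fits)
  med$model <- NULL
  names(med)[names(med) == "n_voxels_used"] <- paste0("n_voxels_used_", model)
  med[[paste0("n_voxels_t1_failed_", model)]] <- sum(!usable)
  med
}

#' Fit a simulated (or real) run directory into a cohort parameter table
#'
#' Per patient: VFA T1/M0 fit over in-mask voxels, dynamic SPGR signal to
#' concentration, voxelwise kinetic fitting for the requested model(s), and
#' ROI-median aggregation.  Patients whose inputs cannot be read are
#' skipped with a warning and recorded in the manifest; the attribute
#' `status` on the returned tibble is 0 (all fitted) or 2 (partial).
#'
#' @param run_dir directory produced by [run_simulate()] (per-patient
#'   subdirectories plus `aif.csv` and `labels.csv`).
#' @param model `"tofts"`, `"dp"` or `"both"`.
#' @param config the [cohort_config()] describing the acquisition.
#' @param fit_cfg a [fit_config()].
#' @return A cohort tibble (one row per patient) with labels and the
#'   fitted ROI-median parameters in reported units; also written to
#'   `cohort_params.csv` in `run_dir`.
#' @export
run_fit <- function(run_dir, model = c("both", "tofts", "dp"),
                    config = cohort_config(), fit_cfg = fit_config()) {
  model <- match.arg(model)
  labels <- tibble::as_tibble(read.csv(file.path(run_dir, "labels.csv")))
  aif <- read_aif(file.path(run_dir, "aif.csv"))
  models <- if (model == "both") c("tofts", "dp") else model
  skipped <- character()
  rows <- purrr::map(labels$patient_id, function(pid) {
    pdir <- file.path(run_dir, pid)
    meds <- tryCatch({
      purrr::map(models, function(mm) fit_one_patient(pdir, aif, config, fit_cfg, mm))
    }, error = function(e) {
      warn(sprintf("patient %s skipped: %s", pid, conditionMessage(e)),
           class = "dpdce_patient_skipped")
      skipped <<- c(skipped, pid)
      NULL
    })
    if (is.null(meds)) return(NULL)
    dplyr::bind_cols(tibble::tibble(patient_id = pid), dplyr::bind_cols(meds))
  })
  out <- dplyr::left_join(labels, dplyr::bind_rows(rows), by = "patient_id")
  path <- file.path(run_dir, "cohort_params.csv")
  write.csv(out, path, row.names = FALSE)
  write_manifest(run_dir, "fit", seed = NA, config = list(config, fit_cfg, model),
                 extra = list(skipped = skipped))
  attr(out, "status") <- if (length(skipped)) 2L else 0L
  out
}

#' Run the statistical battery on a cohort table
#'
#' @param cohort a cohort tibble or the path of a cohort CSV (schema of
#'   [run_fit()] / [sample_cohort()]).
#' @param out_dir directory for the report CSVs and manifest.
#' @param config a [report_config()].
#' @param seed recorded in the manifest (the battery itself is
#'   deterministic).
#' @return The [build_report()] object, invisibly.
#' @export
run_stats <- function(cohort, out_dir, config = report_config(), seed = NA) {
  if (is.character(cohort)) cohort <- tibble::as_tibble(read.csv(cohort))
  report <- build_report(cohort, config)
  write_report(report, out_dir)
  write_manifest(out_dir, "stats", seed, config,
                 extra = list(n_patients = nrow(cohort)))
  invisible(report)
}

#' Miniature three-patient fixture cohort
#'
#' One patient per molecular subtype with a reduced ROI, used by the test
#' suite and examples; small enough to simulate and fit in seconds.
#'
#' @param out_dir run directory.
#' @param seed integer seed.
#' @param snr baseline SNR of the rendered volumes (`Inf` for noiseless).
#' @return Invisibly, the truth tibble.
#' @export
run_fixtures <- function(out_dir, seed = 1, snr = 50) {
  cfg <- cohort_config(n_wildtype = 1, n_intact = 1, n_codeleted = 1,
                       roi_dim = c(3, 3, 1), vol_dim = c(5, 5, 3), snr = snr)
  run_simulate(out_dir, cfg, seed)
}
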