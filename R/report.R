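# Cohort report: group comparisons, ROC battery, model comparison, Ki-67
# correlations, mirroring the layout of a glioma DCE genotyping study.

dce_param_names <- c("tofts_ktrans", "tofts_ve", "tofts_vp", "tofts_kep",
                     "dp_f", "dp_vp", "dp_ve", "dp_ps", "dp_e")

# A-priori ROC orientations.  Values name the class that the parameter is
# expected to be elevated in; that class plays "positive" with
# direction = "higher".  Kep is elevated in IDH-mutant tumours (tighter
# blood-brain barrier -> small ve -> fast efflux) and blood flow in
# 1p/19q-codeleted oligodendrogliomas; every other parameter tracks
# barrier leakiness and is elevated on the wild-type / astrocytic side.
roc_directions <- function() {
  list(
    idh = c(tofts_ktrans = "wild-type", tofts_ve = "wild-type",
            tofts_vp = "wild-type", tofts_kep = "mutation",
            dp_f = "mutation", dp_vp = "wild-type", dp_ve = "wild-type",
            dp_ps = "wild-type", dp_e = "wild-type"),
    codeletion = c(tofts_ktrans = "codeleted", tofts_ve = "codeleted",
                   tofts_vp = "codeleted", tofts_kep = "intact",
                   dp_f = "codeleted", dp_vp = "intact", dp_ve = "codeleted",
                   dp_ps = "intact", dp_e = "intact"))
}

#' Report configuration
#'
#' @param alpha two-sided significance level.
#' @param directions a-priori ROC orientations per comparison (see
#'   [build_report()]); each entry names, per parameter, the class in which
#'   the parameter is expected elevated.
#' @return A list of class `dce_report_config`.
#' @export
report_config <- function(alpha = 0.05, directions = roc_directions()) {
  structure(list(alpha = alpha, directions = directions),
            class = "dce_report_config")
}

check_cohort <- function(cohort) {
  need <- c("patient_id", "idh", "codeletion", dce_param_names)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_invalid(paste("cohort is missing columns:",
                                       paste(miss, collapse = ", ")))
  bad <- !cohort$idh %in% c("mutation", "wild-type")
  if (any(bad)) stop_invalid("idh must be 'mutation' or 'wild-type'")
  mut <- cohort$idh == "mutation"
  if (any(!cohort$codeletion[mut] %in% c("intact", "codeleted"))) {
    stop_invalid("codeletion must be 'intact' or 'codeleted' for IDH-mutant patients")
  }
  invisible(cohort)
}

median_iqr <- function(v) {
  sprintf("%.3f (%.3f, %.3f)", median(v), quantile(v, 0.25), quantile(v, 0.75))
}

comparison_table <- function(cohort, comparison, grp_hi, grp_lo, group_col) {
  rows <- purrr::map(dce_param_names, function(pn) {
    x <- cohort[[pn]][cohort[[group_col]] == grp_hi]
    y <- cohort[[pn]][cohort[[group_col]] == grp_lo]
    mw <- mann_whitney_u(x, y)
    tibble::tibble(comparison = comparison, parameter = pn,
                   !!paste0("median_iqr_", gsub("-", "_", grp_hi)) := median_iqr(x),
                   !!paste0("median_iqr_", gsub("-", "_", grp_lo)) := median_iqr(y),
                   u = mw$u, p_raw = mw$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out
}

roc_table <- function(cohort, comparison, group_col, directions) {
  rows <- purrr::map(dce_param_names, function(pn) {
    pos <- directions[[pn]]
    r <- roc_auc(cohort[[pn]], cohort[[group_col]], positive = pos)
    yj <- youden_cutoff(cohort[[pn]], cohort[[group_col]], positive = pos)
    dplyr::bind_cols(tibble::tibble(comparison = comparison, parameter = pn,
                                    positive_class = pos), r, yj)
  })
  dplyr::bind_rows(rows)
}

#' Run the full cohort statistical battery
#'
#' Given a per-patient table of ROI-median kinetic parameters plus
#' molecular labels, runs (1) Mann-Whitney comparisons of all 9 parameters
#' between IDH-mutant and wild-type patients, and between 1p/19q-codeleted
#' and -intact patients *within* the IDH-mutant subgroup, each family
#' BH-adjusted across its 9 parameters; (2) ROC analysis of every parameter
#' in both comparisons under fixed a-priori orientations (AUC < 0.5 is
#' possible); (3) a paired DeLong comparison of the best-AUC parameter of
#' each model per comparison; (4) Spearman correlation of every parameter
#' with the Ki-67 labelling index.  Nonparametric tests are used throughout
#' (glioma kinetic parameters are heavily right-skewed and fail normality).
#'
#' @param cohort data frame with columns `patient_id`, `idh`
#'   (`"mutation"`/`"wild-type"`), `codeletion` (`"intact"`/`"codeleted"`,
#'   `NA` for wild-type), optionally `ki67` (percent), and the 9 parameter
#'   columns `tofts_ktrans`, `tofts_ve`, `tofts_vp`, `tofts_kep`, `dp_f`,
#'   `dp_vp`, `dp_ve`, `dp_ps`, `dp_e` (reported units).
#' @param config a [report_config()].
#' @return An object of class `dce_report`: list of tibbles `comparison`,
#'   `roc`, `delong`, `correlation` (`NULL` if `ki67` absent), and `meta`.
#' @export
build_report <- function(cohort, config = report_config()) {
  cohort <- check_cohort(tibble::as_tibble(cohort))
  mutant <- dplyr::filter(cohort, .data$idh == "mutation")
  for (stratum in list(c("idh", "mutation"), c("idh", "wild-type"))) {
    if (!any(cohort[[stratum[1]]] == stratum[2])) {
      stop_invalid(sprintf("empty stratum: %s = '%s'", stratum[1], stratum[2]))
    }
  }
  for (lev in c("intact", "codeleted")) {
    if (!any(mutant$codeletion == lev)) {
      stop_invalid(sprintf("empty stratum: codeletion = '%s' within IDH-mutant patients", lev))
    }
  }
  comparison <- dplyr::bind_rows(
    comparison_table(cohort, "idh", "mutation", "wild-type", "idh"),
    comparison_table(mutant, "codeletion", "codeleted", "intact", "codeletion"))
  roc <- dplyr::bind_rows(
    roc_table(cohort, "idh", "idh", config$directions$idh),
    roc_table(mutant, "codeletion", "codeletion", config$directions$codeletion))
  delong <- dplyr::bind_rows(purrr::map(c("idh", "codeletion"), function(cmp) {
    sub <- dplyr::filter(roc, .data$comparison == cmp)
    dat <- if (cmp == "idh") cohort else mutant
    best_tofts <- sub$parameter[sub$parameter %in% dce_param_names[1:4]][
      which.max(sub$auc[sub$parameter %in% dce_param_names[1:4]])]
    best_dp <- sub$parameter[sub$parameter %in% dce_param_names[5:9]][
      which.max(sub$auc[sub$parameter %in% dce_param_names[5:9]])]
    pos <- config$directions[[cmp]][[best_tofts]]
    # both scores oriented toward the *same* positive class for pairing
    ori_a <- "higher"
    ori_b <- if (config$directions[[cmp]][[best_dp]] == pos) "higher" else "lower"
    grp_col <- if (cmp == "idh") "idh" else "codeletion"
    dl <- delong_paired_test(dat[[best_tofts]], dat[[best_dp]], dat[[grp_col]],
                             positive = pos, direction_a = ori_a, direction_b = ori_b)
    dplyr::bind_cols(tibble::tibble(comparison = cmp, tofts_parameter = best_tofts,
                                    dp_parameter = best_dp), dl)
  }))
  correlation <- NULL
  if ("ki67" %in% names(cohort) && any(is.finite(cohort$ki67))) {
    correlation <- dplyr::bind_rows(purrr::map(dce_param_names, function(pn) {
      sc <- spearman_corr(cohort[[pn]], cohort$ki67)
      dplyr::bind_cols(tibble::tibble(parameter = pn), sc)
    }))
  } else {
    warn("cohort has no usable ki67 column; correlation table skipped",
         class = "dpdce_no_ki67")
  }
  structure(list(comparison = comparison, roc = roc, delong = delong,
                 correlation = correlation,
                 meta = list(alpha = config$alpha,
                             n = nrow(cohort),
                             n_by_group = table(cohort$idh, useNA = "no"),
                             directions = config$directions,
                             u_convention = "U counts pairs with the mutation/codeleted-group value higher (ties 0.5)"),
                 cohort = cohort),
            class = "dce_report")
}

#' @export
print.dce_report <- function(x, ...) {
  cat(sprintf("<dce_report: %d patients>\n", x$meta$n))
  cat("\nGroup comparisons (Mann-Whitney U, BH-adjusted):\n")
  print(as.data.frame(x$comparison[, c("comparison", "parameter", "u", "p_raw", "p_adj")]),
        digits = 3)
  cat("\nROC (fixed orientation):\n")
  print(as.data.frame(x$roc[, c("comparison", "parameter", "auc", "ci_lo", "ci_hi",
                                "cutoff", "sens", "spec", "acc")]), digits = 3)
  invisible(x)
}

#' @rdname build_report
#' @param x a `dce_report`.
#' @param ... unused.
#' @export
tidy.dce_report <- function(x, ...) {
  dplyr::left_join(x$comparison[, c("comparison", "parameter", "u", "p_raw", "p_adj")],
                   x$roc[, c("comparison", "parameter", "auc", "ci_lo", "ci_hi",
                             "p", "cutoff", "sens", "spec", "acc")],
                   by = c("comparison", "parameter"))
}

#' @rdname build_report
#' @export
glance.dce_report <- function(x, ...) {
  tibble::tibble(
    n = x$meta$n,
    n_significant_idh = sum(x$comparison$p_adj[x$comparison$comparison == "idh"] < x$meta$alpha),
    n_significant_codeletion = sum(x$comparison$p_adj[x$comparison$comparison == "codeletion"] < x$meta$alpha),
    best_auc_idh = max(x$roc$auc[x$roc$comparison == "idh"]),
    best_auc_codeletion = max(x$roc$auc[x$roc$comparison == "codeletion"]))
}

#' Write the report tables to CSV
#'
#' Emits `tables_2_3.csv` (group comparisons), `tables_4_5.csv` (ROC) and,
#' when available, `fig4_correlations.csv` (Ki-67 Spearman correlations).
#'
#' @param report a `dce_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "tables_2_3.csv"), file.path(dir, "tables_4_5.csv"))
  write.csv(report$comparison, paths[1], row.names = FALSE)
  write.csv(report$roc, paths[2], row.names = FALSE)
  if (!is.null(report$correlation)) {
    p3 <- file.path(dir, "fig4_correlations.csv")
    write.csv(report$correlation, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Classify a glioma case from its ROI-median parameters
#'
#' Two-stage rule using fixed thresholds: an interstitial volume fraction
#' (extended Tofts `Ve`, mL/100 mL) above `ve_cutoff` calls the case IDH
#' wild-type; otherwise the case is IDH-mutant, and a distributed-parameter
#' blood flow (mL/min/100 mL) above `f_cutoff` calls 1p/19q codeletion.
#' The default thresholds are the Youden-optimal cut-offs of the glioma
#' study this package models (Ex-Tofts Ve = 1.670, DP F = 7.154).
#'
#' @param tofts_ve extended Tofts interstitial volume fraction, mL/100 mL.
#' @param dp_f distributed-parameter blood flow, mL/min/100 mL.
#' @param ve_cutoff,f_cutoff decision thresholds.
#' @return Character vector with values `"wild-type"`,
#'   `"mutation-intact"`, `"mutation-codeleted"`.
#' @export
classify_subtype <- function(tofts_ve, dp_f, ve_cutoff = 1.670, f_cutoff = 7.154) {
  ifelse(tofts_ve > ve_cutoff, "wild-type",
         ifelse(dp_f > f_cutoff, "mutation-codeleted", "mutation-intact"))
}

#' Worked-example cases
#'
#' Three cases (one per molecular subtype) with histologically confirmed
#' labels and their published ROI-median `tofts_ve` and `dp_f` values, used
#' to demonstrate [classify_subtype()].
#'
#' @return A tibble with columns `case`, `subtype`, `tofts_ve`, `dp_f`.
#' @export
example_cases <- function() {
  path <- system.file("extdata", "example_cases.csv", package = "dpdce")
  tibble::as_tibble(read.csv(path))
}
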