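# Cohort-level statistical battery: Mann-Whitney U with BH correction,
# ROC/AUC with DeLong variance and Youden cut-offs, Spearman correlation.

#' Mann-Whitney U test
#'
#' Returns `u` = number of (x, y) pairs with `x > y` (ties counted 0.5), so
#' a large U means the `x` sample tends to score higher.  The two-sided p
#' value is exact (full null distribution of U) when `n1 + n2 <= 12` and
#' there are no ties, and a tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y numeric samples (each length >= 1).
#' @return A one-row tibble with `u`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop_invalid("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_invalid("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 + n2 <= 12L) {
    lo <- pwilcox(floor(u + 1e-9), n1, n2)
    hi <- 1 - pwilcox(ceiling(u - 1e-9) - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    n <- n1 + n2
    tab <- table(c(x, y))
    tiecorr <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tiecorr))
    mu <- n1 * n2 / 2
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-tie-corrected"
  }
  tibble::tibble(u = u, p = p, n1 = n1, n2 = n2, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction over one family of p values
#' (delegates to [stats::p.adjust()]); output is clipped at 1 and preserves
#' the input order.
#'
#' @param p numeric vector of raw p values.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_invalid("p values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

# structural components: per positive case, the fraction of negatives it
# outscores (ties 0.5); and the column-wise complement for negatives.
delong_components <- function(pos, neg) {
  v10 <- vapply(pos, function(xi) mean((xi > neg) + 0.5 * (xi == neg)), numeric(1))
  v01 <- vapply(neg, function(yj) mean((pos > yj) + 0.5 * (pos == yj)), numeric(1))
  # the components variance needs >= 2 cases per class; below that the
  # AUC is still defined but its uncertainty is not
  v <- if (length(pos) < 2L || length(neg) < 2L) NA_real_
       else stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  list(auc = mean(v10), v10 = v10, v01 = v01, var = v)
}

#' Empirical AUC with DeLong variance
#'
#' The AUC is the probability that a positive-class score exceeds a
#' negative-class score (ties credited 0.5), computed under a *fixed*
#' orientation: `direction = "higher"` means higher scores indicate the
#' positive class.  Because the orientation is set a priori per parameter
#' (not flipped to whichever side wins), AUC values below 0.5 are possible
#' and meaningful.  The variance is DeLong's structural-components
#' estimator; the 95% CI is Wald, truncated to \[0, 1\]; `p` tests
#' AUC = 0.5.
#'
#' @param scores numeric scores.
#' @param labels class labels (any type with two distinct values).
#' @param positive the label of the positive class.
#' @param direction `"higher"` (default) if larger scores indicate the
#'   positive class, `"lower"` otherwise.
#' @return A one-row tibble: `auc`, `var_auc`, `ci_lo`, `ci_hi`, `p`.
#' @export
roc_auc <- function(scores, labels, positive, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(scores) != length(labels)) stop_invalid("scores and labels lengths differ")
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop_invalid("both classes must be present")
  s <- if (direction == "higher") scores else -scores
  d <- delong_components(s[is_pos], s[!is_pos])
  if (is.na(d$var)) {
    return(tibble::tibble(auc = d$auc, var_auc = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, p = NA_real_))
  }
  se <- sqrt(max(d$var, 0))
  z <- if (se > 0) (d$auc - 0.5) / se else sign(d$auc - 0.5) * Inf
  tibble::tibble(auc = d$auc, var_auc = d$var,
                 ci_lo = max(0, d$auc - qnorm(0.975) * se),
                 ci_hi = min(1, d$auc + qnorm(0.975) * se),
                 p = if (d$auc == 0.5) 1 else 2 * pnorm(-abs(z)))
}

#' Youden-index optimal cut-off
#'
#' Maximizes sensitivity + specificity - 1 over candidate thresholds placed
#' at midpoints between adjacent distinct scores; ties are broken toward
#' the smaller cut-off.  A case is called positive when its (oriented)
#' score exceeds the cut-off.  If all scores are equal the cut-off is
#' degenerate (`NA`) with a Youden index of 0.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `cutoff`, `sens`, `spec`, `acc`, `youden`,
#'   `degenerate`.  The cut-off is on the original score scale regardless
#'   of `direction`.
#' @export
youden_cutoff <- function(scores, labels, positive, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop_invalid("both classes must be present")
  s <- if (direction == "higher") scores else -scores
  d <- sort(unique(s))
  if (length(d) < 2L) {
    return(tibble::tibble(cutoff = NA_real_, sens = NA_real_, spec = NA_real_,
                          acc = NA_real_, youden = 0, degenerate = TRUE))
  }
  cand <- (d[-1] + d[-length(d)]) / 2
  stats_at <- function(thr) {
    call_pos <- s > thr
    sens <- mean(call_pos[is_pos])
    spec <- mean(!call_pos[!is_pos])
    c(sens = sens, spec = spec, acc = mean(call_pos == is_pos))
  }
  m <- vapply(cand, stats_at, numeric(3))
  youden <- m["sens", ] + m["spec", ] - 1
  best <- which(youden >= max(youden) - 1e-12)[1]   # smallest cut-off among ties
  cutoff <- cand[best]
  tibble::tibble(cutoff = unname(if (direction == "higher") cutoff else -cutoff),
                 sens = unname(m["sens", best]), spec = unname(m["spec", best]),
                 acc = unname(m["acc", best]), youden = unname(youden[best]),
                 degenerate = FALSE)
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects via
#' the structural-components covariance; `z = (auc_a - auc_b) / se` with a
#' two-sided normal p value.  Identical scores give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b paired score vectors (same subjects, same order).
#' @inheritParams roc_auc
#' @param direction_a,direction_b orientation of each score vector.
#' @return A one-row tibble: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, positive,
                               direction_a = "higher", direction_b = "higher") {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop_invalid("scores_a, scores_b, labels must have equal length")
  }
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop_invalid("both classes must be present")
  sa <- if (direction_a == "higher") scores_a else -scores_a
  sb <- if (direction_b == "higher") scores_b else -scores_b
  da <- delong_components(sa[is_pos], sa[!is_pos])
  db <- delong_components(sb[is_pos], sb[!is_pos])
  m <- sum(is_pos); n <- sum(!is_pos)
  if (is.na(da$var) || is.na(db$var)) {
    return(tibble::tibble(auc_a = da$auc, auc_b = db$auc, z = NA_real_,
                          p = NA_real_))
  }
  covar <- stats::cov(da$v10, db$v10) / m + stats::cov(da$v01, db$v01) / n
  s2 <- da$var + db$var - 2 * covar
  diff <- da$auc - db$auc
  z <- if (s2 <= 0) { if (abs(diff) < 1e-12) 0 else sign(diff) * Inf } else diff / sqrt(s2)
  tibble::tibble(auc_a = da$auc, auc_b = db$auc, z = z,
                 p = if (z == 0) 1 else 2 * pnorm(-abs(z)))
}

# all permutations of 1..n as an (n! x n) matrix, built recursively.
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks.  For `n <= 10` the p value
#' is exact, from full enumeration of the `n!` rank permutations (for
#' n = 9, 10 the enumeration is chunked over the first rank to bound
#' memory); for larger n the t approximation with `n - 2` degrees of
#' freedom is used.
#'
#' @param x,y paired numeric vectors.
#' @return A one-row tibble: `rho`, `p`, `n`, `method`.
#' @export
spearman_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop_degenerate("constant ranks: rho undefined")
  rho <- cor(rx, ry)
  if (n <= 10L) {
    # |rho| is monotone in |sum rx*ry - n*mean^2|; enumerate that statistic
    obs <- abs(sum(rx * ry) - n * mean(rx) * mean(ry))
    count <- 0L; total <- 0L
    chunks <- if (n <= 8L) list(seq_len(n)) else as.list(seq_len(n))
    for (ch in chunks) {
      if (n <= 8L) {
        pm <- perms_all(n)
        ry_perm <- matrix(ry[pm], nrow(pm), n)
      } else {
        sub <- perms_all(n - 1L)
        rest <- seq_len(n)[-ch]
        pm <- cbind(ch, matrix(rest[sub], nrow(sub), n - 1L))
        ry_perm <- matrix(ry[pm], nrow(pm), n)
      }
      stat <- abs(as.numeric(ry_perm %*% rx) - n * mean(rx) * mean(ry))
      count <- count + sum(stat >= obs - 1e-9)
      total <- total + nrow(ry_perm)
    }
    p <- count / total
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, p = p, n = n, method = method)
}
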