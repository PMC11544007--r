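test_that("Mann-Whitney U: worked example, symmetry, exact enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p, 1 / 3)
  # identical multisets: U = n1 n2 / 2
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$u, 4.5)
  # full-enumeration oracle at n1 = n2 = 6 on random tie-free samples
  set.seed(14)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6, 0.8)
    r <- mann_whitney_u(x, y)
    pooled <- c(x, y)
    u_of <- function(idx) {
      xs <- pooled[idx]; ys <- pooled[-idx]
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    all_u <- apply(combn(12, 6), 2, u_of)
    obs_dev <- abs(r$u - 18)
    expect_equal(r$p, mean(abs(all_u - 18) >= obs_dev - 1e-9))
    expect_equal(r$method, "exact")
    # orientation: swapping samples mirrors U
    expect_equal(mann_whitney_u(y, x)$u, 36 - r$u)
  }
  # larger samples with ties: tie-corrected normal approximation against
  # base wilcox.test (identical convention and correction)
  set.seed(15)
  x <- round(rlnorm(20), 1); y <- round(rlnorm(25, 0.5), 1)
  r <- mann_whitney_u(x, y)
  w <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(r$u, unname(w$statistic))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg: hand-computed step-up, monotonicity, permutation invariance", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed: p (0.005, 0.04, 0.04, 0.8), m = 4
  # ranks 1:4 -> 0.005*4/1 = 0.02; 0.04*4/2 = 0.08; 0.04*4/3 = 0.0533 ->
  # cummin from the top: 0.02, 0.0533, 0.0533, 0.8
  expect_equal(bh_adjust(c(0.005, 0.04, 0.04, 0.8)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
  set.seed(4)
  p <- runif(9)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone-consistent with ranks
  perm <- sample.int(9)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("AUC: perfect separation, label flip, U identity, pROC cross-check", {
  lab <- rep(c("neg", "pos"), each = 5)
  r <- roc_auc(c(1:5, 6:10), lab, positive = "pos")
  expect_equal(r$auc, 1)
  set.seed(8)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  scores <- c(x, y); labels <- rep(c("a", "b"), c(12, 15))
  r <- roc_auc(scores, labels, positive = "b")
  # identity: auc = U / (n1 n2) with U counting pairs where the positive
  # class scores higher
  expect_equal(r$auc, mann_whitney_u(y, x)$u / (12 * 15))
  # flipping the positive class mirrors the AUC
  expect_equal(roc_auc(scores, labels, positive = "a")$auc, 1 - r$auc)
  # direction = "lower" mirrors too
  expect_equal(roc_auc(scores, labels, positive = "b", direction = "lower")$auc,
               1 - r$auc)
  # DeLong variance/CI against pROC
  pr <- pROC::roc(labels, scores, levels = c("a", "b"), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_equal(c(r$ci_lo, r$ci_hi), ci[c(1, 3)], tolerance = 1e-9)
})

test_that("DeLong CI width shrinks as n grows", {
  set.seed(19)
  widths <- vapply(c(20, 80, 320), function(n) {
    s <- c(rnorm(n), rnorm(n, 0.7))
    l <- rep(c("a", "b"), each = n)
    r <- roc_auc(s, l, positive = "b")
    expect_gte(r$var_auc, 0)
    r$ci_hi - r$ci_lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Youden cut-off: perfect separation, exhaustive-threshold oracle, degenerate input", {
  lab <- rep(c("neg", "pos"), each = 4)
  r <- youden_cutoff(c(1, 2, 3, 4, 10, 11, 12, 13), lab, positive = "pos")
  expect_equal(c(r$sens, r$spec, r$acc), c(1, 1, 1))
  expect_gt(r$cutoff, 4); expect_lt(r$cutoff, 10)
  set.seed(23)
  for (rep in 1:5) {
    s <- round(rnorm(20), 1)
    l <- sample(rep(c("a", "b"), 10))
    r <- youden_cutoff(s, l, positive = "b")
    # brute force over a fine sweep of thresholds
    thr <- seq(min(s) - 1, max(s) + 1, by = 0.01)
    j <- vapply(thr, function(th) {
      mean(s[l == "b"] > th) + mean(s[l == "a"] <= th) - 1
    }, numeric(1))
    expect_equal(r$youden, max(j), tolerance = 1e-9)
  }
  d <- youden_cutoff(rep(2, 8), rep(c("a", "b"), 4), positive = "b")
  expect_true(d$degenerate)
  expect_equal(d$youden, 0)
})

test_that("paired DeLong: identical scores, antisymmetry, pROC cross-check", {
  set.seed(31)
  lab <- rep(c("a", "b"), each = 15)
  s1 <- c(rnorm(15), rnorm(15, 1))
  r0 <- delong_paired_test(s1, s1, lab, positive = "b")
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  s2 <- s1 + rnorm(30, 0, 0.8)
  r <- delong_paired_test(s1, s2, lab, positive = "b")
  rsw <- delong_paired_test(s2, s1, lab, positive = "b")
  expect_equal(rsw$z, -r$z)
  expect_equal(rsw$p, r$p)
  pr <- pROC::roc.test(pROC::roc(lab, s1, levels = c("a", "b"), direction = "<", quiet = TRUE),
                       pROC::roc(lab, s2, levels = c("a", "b"), direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(r$z, unname(pr$statistic), tolerance = 1e-9)
  expect_equal(r$p, pr$p.value, tolerance = 1e-9)
})

test_that("paired DeLong p sits inside the Monte-Carlo band of a bootstrap oracle", {
  set.seed(57)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  base <- c(rnorm(n / 2), rnorm(n / 2, 0.9))
  s1 <- base + rnorm(n, 0, 0.6)
  s2 <- base + rnorm(n, 0, 0.9)
  r <- delong_paired_test(s1, s2, lab, positive = "b")
  auc_of <- function(s, l) {
    pos <- s[l == "b"]; neg <- s[l == "a"]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }
  B <- 2e4
  obs <- auc_of(s1, lab) - auc_of(s2, lab)
  boot <- vapply(seq_len(B), function(b) {
    i <- c(sample(which(lab == "a"), replace = TRUE),
           sample(which(lab == "b"), replace = TRUE))
    auc_of(s1[i], lab[i]) - auc_of(s2[i], lab[i])
  }, numeric(1))
  # normal-theory bootstrap p for the difference
  p_boot <- 2 * pnorm(-abs(obs) / sd(boot))
  mc_tol <- 4 * p_boot / sqrt(B) + 0.05
  expect_lt(abs(r$p - p_boot), mc_tol)
})

test_that("Spearman: monotone transforms, reversal, exact enumeration at n = 8", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 5.0, 6.6, 7.1)
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  expect_equal(spearman_corr(x, -x^3)$rho, -1)
  set.seed(61)
  for (rep in 1:3) {
    xs <- rnorm(8); ys <- rnorm(8)
    r <- spearman_corr(xs, ys)
    expect_equal(r$method, "exact-permutation")
    # independent enumeration oracle (insertion-order permutation generator)
    rx <- rank(xs); ry <- rank(ys)
    pm <- perms_insertion(8)
    rhos <- apply(pm, 1, function(idx) cor(rx, ry[idx]))
    expect_equal(r$p, mean(abs(rhos) >= abs(r$rho) - 1e-9))
    # cross-check against base cor.test's exact path
    ct <- cor.test(xs, ys, method = "spearman", exact = TRUE)
    expect_equal(r$rho, unname(ct$estimate))
  }
  # t approximation for larger n against cor.test
  set.seed(62)
  xl <- rnorm(25); yl <- 0.5 * xl + rnorm(25)
  r <- spearman_corr(xl, yl)
  expect_equal(r$method, "t-approximation")
  expect_equal(r$p, cor.test(xl, yl, method = "spearman", exact = FALSE)$p.value,
               tolerance = 0.02)
})

test_that("chunked exact permutation (n = 9) matches the direct path", {
  set.seed(63)
  xs <- rnorm(9); ys <- rnorm(9)
  r9 <- spearman_corr(xs, ys)
  expect_equal(r9$method, "exact-permutation")
  ct <- cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(r9$rho, unname(ct$estimate))
  expect_equal(r9$p, ct$p.value, tolerance = 1e-9)
})
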