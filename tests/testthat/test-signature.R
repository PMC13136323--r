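make_groups <- function(n_met = 20, n_case = 6, n_ctrl = 4, seed = 101,
                        effect = 0.8) {
  set.seed(seed)
  row_sd <- exp(rnorm(n_met, -0.7, 0.6))  # heterogeneous metabolite variances
  vals <- matrix(rnorm(n_met * (n_case + n_ctrl)), n_met,
                 dimnames = list(sprintf("m%02d", seq_len(n_met)),
                                 sprintf("s%02d", seq_len(n_case + n_ctrl)))) *
    row_sd
  vals[1:5, seq_len(n_case)] <- vals[1:5, seq_len(n_case)] + effect
  list(x = norm_matrix(vals),
       ann = case_control_annotation(sprintf("s%02d", seq_len(n_case)),
                                     sprintf("s%02d", n_case + seq_len(n_ctrl))))
}

test_that("shrinkage limits recover the ordinary t and the fully pooled variance", {
  g <- make_groups()
  n_case <- 6; n_ctrl <- 4
  sig0 <- estimate_signature(g$x, g$ann, shrinkage = "moderated", prior_df = 0)
  # ordinary pooled-variance two-sample t, straight-line implementation
  cs <- g$x$log2_values[, 1:n_case]; ct <- g$x$log2_values[, n_case + 1:n_ctrl]
  fc <- rowMeans(cs) - rowMeans(ct)
  sp2 <- ((n_case - 1) * apply(cs, 1, var) + (n_ctrl - 1) * apply(ct, 1, var)) /
    (n_case + n_ctrl - 2)
  t_ord <- fc / sqrt(sp2 * (1 / n_case + 1 / n_ctrl))
  expect_equal(sig0$t, unname(t_ord), tolerance = 1e-10)
  expect_equal(sig0$log2FC, unname(fc), tolerance = 1e-12)

  sig_inf <- estimate_signature(g$x, g$ann, shrinkage = "moderated",
                                prior_df = Inf)
  s02 <- attr(sig_inf, "prior_var")
  expect_equal(sig_inf$t, unname(fc / sqrt(s02 * (1 / n_case + 1 / n_ctrl))),
               tolerance = 1e-10)
})

test_that("a metabolite with identical group means has zero fold change and t", {
  g <- make_groups()
  v <- g$x$log2_values
  v["m01", ] <- c(rep(c(1, 2), 3), rep(1.5, 4))  # both group means 1.5
  sig <- estimate_signature(norm_matrix(v), g$ann)
  expect_equal(sig$log2FC[sig$metabolite == "m01"], 0, tolerance = 1e-12)
  expect_equal(sig$t[sig$metabolite == "m01"], 0, tolerance = 1e-12)
})

test_that("moderated t matches an independent moment-matched shrinkage implementation", {
  g <- make_groups(seed = 202)
  sig <- estimate_signature(g$x, g$ann, shrinkage = "moderated")
  # straight-line re-derivation: F-moment matching of s^2, posterior variance
  cs <- g$x$log2_values[, 1:6]; ct <- g$x$log2_values[, 7:10]
  n1 <- 6; n2 <- 4; d <- n1 + n2 - 2
  fc <- rowMeans(cs) - rowMeans(ct)
  s2 <- ((n1 - 1) * apply(cs, 1, var) + (n2 - 1) * apply(ct, 1, var)) / d
  m <- mean(s2); R <- var(s2) / m^2
  if (R * d <= 2) { d0 <- Inf; s02 <- m } else {
    d0 <- (4 * R * d + 2 * d - 4) / (R * d - 2)
    if (d0 <= 4) d0 <- 4.001
    s02 <- m * (d0 - 2) / d0
  }
  expect_true(is.finite(d0))  # fixture must exercise real shrinkage
  s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  t_mod <- fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p_mod <- 2 * pt(abs(t_mod), df = d + d0, lower.tail = FALSE)
  expect_equal(sig$t, unname(t_mod), tolerance = 1e-8)
  expect_equal(sig$p, unname(p_mod), tolerance = 1e-8)
  expect_true(all(sig$fdr >= sig$p - 1e-12))
})

test_that("swapping group labels negates every fold change exactly", {
  g <- make_groups(seed = 303)
  swapped <- g$ann
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  swapped$visit_week <- ifelse(swapped$group == "case", 0, NA)
  s1 <- estimate_signature(g$x, g$ann)
  s2 <- estimate_signature(g$x, swapped)
  expect_equal(s1$log2FC, -s2$log2FC, tolerance = 1e-12)
})

test_that("fold changes agree with limma's linear-model estimates", {
  skip_if_not_installed("limma")
  g <- make_groups(seed = 404)
  sig <- estimate_signature(g$x, g$ann)
  design <- cbind(1, c(rep(1, 6), rep(0, 4)))
  fit <- limma::eBayes(limma::lmFit(g$x$log2_values, design))
  expect_equal(sig$log2FC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # different prior estimators (F-moment vs log-variance matching), so the
  # moderated statistics agree closely but not identically
  expect_gt(cor(sig$t, fit$t[, 2]), 0.99)
})

test_that("BH adjustment reproduces the hand step-up and its edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.42), 0.42)
  set.seed(11)
  for (i in 1:5) {
    p <- runif(20)
    o <- order(p)
    m <- length(p)
    q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))  # q_i = min_{j>=i} p_(j) m/j
    expect_equal(bh_fdr(p)[o], pmin(q_sorted, 1), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Fisher combination matches the chi-square closed form", {
  one <- fisher_combine(matrix(c(1, 1), 1))
  expect_equal(one$fisher_stat, 0)
  expect_equal(one$p_combined, 1)

  two <- fisher_combine(matrix(c(0.05, 0.05), 1))
  expect_equal(two$fisher_stat, -2 * (log(0.05) + log(0.05)), tolerance = 1e-12)
  expect_equal(two$p_combined,
               pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # single comparison: identity
  set.seed(3)
  p <- runif(8)
  expect_equal(fisher_combine(matrix(p, ncol = 1))$p_combined, p,
               tolerance = 1e-12)

  # order of the comparisons is irrelevant
  pm <- matrix(runif(12), ncol = 3)
  expect_equal(fisher_combine(pm)$p_combined,
               fisher_combine(pm[, 3:1])$p_combined, tolerance = 1e-14)

  expect_warning(z <- fisher_combine(matrix(c(0, 0.5), 1)), "clamped")
  expect_true(is.finite(z$fisher_stat))
})

test_that("PC1 separation: equal-variance groups give F = 1, and p follows the F distribution", {
  set.seed(21)
  block <- matrix(rnorm(10 * 4), 10, 4)
  vals <- cbind(block, block)  # case samples duplicate the controls exactly
  dimnames(vals) <- list(sprintf("m%d", 1:10), sprintf("s%d", 1:8))
  ann <- case_control_annotation(sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  res <- pc1_separation(norm_matrix(vals), ann)
  expect_equal(res$F, 1, tolerance = 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-9)

  set.seed(22)
  vals2 <- matrix(rnorm(30 * 20), 30, 20,
                  dimnames = list(sprintf("m%d", 1:30), sprintf("s%d", 1:20)))
  vals2[1:10, 1:15] <- vals2[1:10, 1:15] + rep(rnorm(15, 0, 2), each = 10)
  ann2 <- case_control_annotation(sprintf("s%d", 1:15), sprintf("s%d", 16:20))
  res2 <- pc1_separation(norm_matrix(vals2), ann2)
  v_case <- var(res2$pc1_scores[1:15]); v_ctrl <- var(res2$pc1_scores[16:20])
  expect_equal(res2$F, v_case / v_ctrl, tolerance = 1e-12)
  expect_equal(res2$p,
               min(1, 2 * min(pf(res2$F, 14, 4), pf(res2$F, 14, 4, lower.tail = FALSE))),
               tolerance = 1e-12)

  # sample order only flips the score sign at most
  perm <- sample(20)
  res3 <- pc1_separation(norm_matrix(vals2[, perm]), ann2)
  agree <- res3$pc1_scores[names(res2$pc1_scores)]
  expect_true(max(abs(agree - res2$pc1_scores)) < 1e-8 ||
                max(abs(agree + res2$pc1_scores)) < 1e-8)
  expect_equal(res3$F, res2$F, tolerance = 1e-9)

  res4 <- pc1_separation(norm_matrix(vals2), ann2, method = "anova")
  expect_true(res4$p > 0 && res4$p <= 1)
})
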