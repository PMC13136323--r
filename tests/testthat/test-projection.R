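test_that("patient deltas subtract phase endpoints and omit incomplete subjects", {
  mets <- sprintf("m%02d", 1:12)
  ann <- longitudinal_annotation(c("P1", "P2"))
  vals <- matrix(0, 12, nrow(ann), dimnames = list(mets, ann$sample_id))
  vals[, "P1_W00"] <- 2; vals[, "P1_W16"] <- 2; vals[, "P1_W32"] <- 6
  vals[1, c("P2_W00", "P2_W16", "P2_W32")] <- c(2, 5, 4)
  d <- patient_deltas(norm_matrix(vals), ann)
  get <- function(s, p) Filter(function(e) e$subject_id == s && e$phase == p,
                               d$deltas)[[1]]
  expect_true(all(get("P1", "lead_in")$delta == 0))
  expect_equal(unname(get("P2", "lead_in")$delta[1]), 3)
  expect_equal(unname(get("P2", "treatment")$delta[1]), -1)

  # missing endpoint: drop P2's week-32 sample
  ann2 <- ann[ann$sample_id != "P2_W32", ]
  d2 <- patient_deltas(norm_matrix(vals[, ann2$sample_id]), ann2)
  expect_length(d2$deltas, 3L)
  expect_match(d2$audit, "P2", all = FALSE)

  # duplicate subject-visit is an error
  ann3 <- rbind(ann, data.frame(sample_id = "P1_dup", subject_id = "P1",
                                group = "case", visit_week = 16,
                                quality_flag = "ok"))
  vals3 <- cbind(vals, P1_dup = 0)
  expect_error(patient_deltas(norm_matrix(vals3), ann3), "duplicate")
})

test_that("lead-in and treatment deltas telescope to the baseline-to-week-32 delta", {
  tr <- generate_trial(synthetic_config(seed = 15, n_cases = 6,
                                        n_metabolites = 60))
  x <- normalize_intensities(tr$muscle)
  d <- patient_deltas(x, tr$annotation)
  for (subj in unique(vapply(d$deltas, `[[`, "", "subject_id"))) {
    li <- Filter(function(e) e$subject_id == subj && e$phase == "lead_in",
                 d$deltas)[[1]]
    tr_ <- Filter(function(e) e$subject_id == subj && e$phase == "treatment",
                  d$deltas)[[1]]
    common <- intersect(names(li$delta), names(tr_$delta))
    direct <- x$log2_values[common, sprintf("MU_%s_W32", subj)] -
      x$log2_values[common, sprintf("MU_%s_W00", subj)]
    expect_equal(li$delta[common] + tr_$delta[common], direct,
                 tolerance = 1e-9)
  }
})

test_that("Spearman rho matches the brute-force average-rank computation", {
  a <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(a, a), 1)
  expect_equal(spearman_rho(a, -a), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # ties resolved by average ranks
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 4)
  expect_equal(spearman_rho(x, y), spearman_by_hand(x, y), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:5) {
    x <- sample(1:6, 15, replace = TRUE); y <- sample(1:6, 15, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_by_hand(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  # rank statistic: invariant under strictly monotone transforms
  set.seed(10)
  u <- rnorm(30); v <- 0.5 * u + rnorm(30)
  expect_equal(spearman_rho(exp(u), v^3 + 2 * v), spearman_rho(u, v),
               tolerance = 1e-12)
})

test_that("jackknife CI equals an independently coded delete-one loop", {
  set.seed(33)
  a <- rnorm(12); b <- 0.6 * a + rnorm(12)
  got <- jackknife_ci(a, b, level = 0.95)
  # independent loop on first principles
  z <- function(r) 0.5 * log((1 + r) / (1 - r))
  rho_full <- spearman_by_hand(a, b)
  z_i <- vapply(1:12, function(i) z(spearman_by_hand(a[-i], b[-i])), numeric(1))
  vj <- (12 - 1) / 12 * sum((z_i - mean(z_i))^2)
  lo <- tanh(z(rho_full) - qnorm(0.975) * sqrt(vj))
  hi <- tanh(z(rho_full) + qnorm(0.975) * sqrt(vj))
  expect_equal(got$rho, rho_full, tolerance = 1e-10)
  expect_equal(got$low, lo, tolerance = 1e-10)
  expect_equal(got$high, hi, tolerance = 1e-10)

  # perfectly monotone data: rho 1, upper bound clamped
  m <- sort(rnorm(15))
  res <- jackknife_ci(m, m^3)
  expect_equal(res$rho, 1)
  expect_equal(res$high, 1)
  expect_error(jackknife_ci(rnorm(5), rnorm(5)), "10")
})

test_that("projection recovers perfect alignment and flags thin overlap", {
  sig <- data.frame(metabolite = sprintf("m%02d", 1:30),
                    log2FC = rnorm(30), fdr = rep(c(0.01, 0.5), 15))
  class(sig) <- c("disease_signature", "data.frame")
  delta <- list(subject_id = "P1", phase = "lead_in",
                delta = setNames(sig$log2FC, sig$metabolite),
                n_metabolites = 30)
  up <- project_patient(delta, sig)
  expect_equal(up$rho, 1)
  expect_true(up$usable)
  down <- project_patient(list(subject_id = "P1", phase = "lead_in",
                               delta = setNames(-sig$log2FC, sig$metabolite)),
                          sig)
  expect_equal(down$rho, -1)

  few <- project_patient(list(subject_id = "P1", phase = "lead_in",
                              delta = setNames(rnorm(4), sig$metabolite[1:4])),
                         sig)
  expect_false(few$usable)
  expect_true(is.na(few$rho))

  # FDR filter restricts the common set
  filt <- project_patient(delta, sig, fdr_filter = 0.05)
  expect_equal(filt$n_used, 15L)
})

test_that("a subject planted at rho 0.49 is recovered within 0.1 under low noise", {
  hits <- 0L; total <- 0L
  for (s in 1:14) {
    tr <- generate_trial(synthetic_config(
      seed = 800 + s, n_metabolites = 200, n_shared_serum = 100,
      leadin_drift = 0.49, rho_target_sd = 0, responder_shift = 0,
      noise_sd = 0.05))
    x <- normalize_intensities(tr$muscle)
    d <- patient_deltas(x, tr$annotation)
    rt <- rho_score_table(d, tr$truth$true_signature, ci = FALSE)
    lead <- rt$rho[rt$phase == "lead_in"]
    hits <- hits + sum(abs(lead - 0.49) <= 0.1)
    total <- total + length(lead)
  }
  expect_gte(hits / total, 0.9)
})

test_that("responder calls require disjoint intervals and respect directionality", {
  rs <- function(id, lo, hi, rho = (lo + hi) / 2, phase = "lead_in")
    structure(list(subject_id = id, phase = phase, rho = rho, ci_low = lo,
                   ci_high = hi, n_used = 100, usable = TRUE,
                   method = "jackknife"), class = "rho_score")
  same <- classify_responder(rs("a", 0.2, 0.5), rs("a", 0.2, 0.5))
  expect_false(same$responder)
  expect_equal(same$direction, "none")

  hit <- classify_responder(rs("a", 0.2, 0.5), rs("a", -0.6, -0.1))
  expect_true(hit$responder)
  expect_equal(hit$direction, "toward_control")

  worse <- classify_responder(rs("a", -0.5, -0.2), rs("a", 0.1, 0.4))
  expect_false(worse$responder)  # directional rule: shift toward disease
  expect_equal(worse$direction, "toward_disease")
  worse2 <- classify_responder(rs("a", -0.5, -0.2), rs("a", 0.1, 0.4),
                               directional = FALSE)
  expect_true(worse2$responder)

  # unusable score propagates to a none call
  bad <- rs("a", NA, NA); bad$usable <- FALSE
  nn <- classify_responder(rs("a", 0.2, 0.5), bad)
  expect_false(nn$responder)
  expect_false(nn$usable)

  # monotone in interval separation: widening both CIs by the same amount
  # can only turn a responder into a non-responder, never the reverse
  widen <- function(x, w) { x$ci_low <- x$ci_low - w; x$ci_high <- x$ci_high + w; x }
  for (w in c(0.05, 0.2, 0.4)) {
    call_w <- classify_responder(widen(rs("a", 0.2, 0.5), w),
                                 widen(rs("a", -0.6, -0.1), w))
    if (!call_w$responder) expect_gte(w, 0.15)  # gap/2 between 0.2 and -0.1
  }
})

test_that("cohort fold-change correlation uses the intersection and labels quadrants", {
  fc_a <- setNames(c(1, -2, 0.5, 3), c("A", "B", "C", "D"))
  self <- correlate_signatures(fc_a, fc_a)
  expect_equal(self$rho, 1)
  fc_b <- setNames(c(2, -1, -0.5, 9), c("B", "C", "D", "Z"))
  res <- correlate_signatures(fc_a, fc_b)
  expect_equal(res$n, 3L)
  expect_setequal(res$table$metabolite, c("B", "C", "D"))
  expect_equal(res$table$quadrant[res$table$metabolite == "B"], "opposite")
  expect_error(correlate_signatures(fc_a, setNames(1:3, c("X", "Y", "Z"))),
               "shared|3")
  # with per-comparison p-values the combined significance is attached
  res2 <- correlate_signatures(fc_a, fc_b,
                               p_a = setNames(rep(0.04, 4), names(fc_a)),
                               p_b = setNames(rep(0.03, 4), names(fc_b)))
  expect_true(all(c("p_combined", "fdr_combined") %in% names(res2$table)))
})

test_that("projection has no hidden randomness", {
  set.seed(77)
  delta <- list(subject_id = "P1", phase = "lead_in",
                delta = setNames(rnorm(50), sprintf("m%d", 1:50)))
  sig <- setNames(rnorm(50), sprintf("m%d", 1:50))
  a <- project_patient(delta, sig)
  b <- project_patient(delta, sig)
  expect_identical(a, b)
})
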