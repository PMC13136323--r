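# shared fixtures: wrap plain matrices as module inputs, independent rank
# helpers used as oracles

norm_matrix <- function(values, tissue = "muscle") {
  structure(list(log2_values = values, tissue = tissue, audit = character()),
            class = "normalized_matrix")
}

case_control_annotation <- function(case_ids, control_ids) {
  data.frame(
    sample_id = c(case_ids, control_ids),
    subject_id = c(paste0("S_", case_ids), paste0("S_", control_ids)),
    group = rep(c("case", "control"), c(length(case_ids), length(control_ids))),
    visit_week = c(rep(0, length(case_ids)), rep(NA, length(control_ids))),
    quality_flag = "ok", stringsAsFactors = FALSE)
}

# average ranks computed from first principles (independent of base rank())
avg_ranks <- function(v) {
  vapply(seq_along(v), function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2,
         numeric(1))
}

# Pearson correlation from the definition (sums formula)
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

spearman_by_hand <- function(a, b) pearson_by_hand(avg_ranks(a), avg_ranks(b))

# longitudinal case annotation with visits 0/16/32 for given subjects
longitudinal_annotation <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s)
    data.frame(sample_id = sprintf("%s_W%02d", s, c(0, 16, 32)),
               subject_id = s, group = "case", visit_week = c(0, 16, 32),
               quality_flag = "ok", stringsAsFactors = FALSE)))
}
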