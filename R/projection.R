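#' Per-patient phase-wise log2 fold-change vectors
#'
#' For each case subject with both endpoint biopsies of a phase, computes the
#' metabolite-wise difference of centered log2 values: lead-in is week 16
#' minus baseline, treatment is week 32 minus week 16. Only metabolites
#' observed at both endpoints enter a delta. Subjects missing an endpoint
#' sample (e.g. excluded for poor tissue quality) are omitted with an audit
#' entry.
#'
#' @param x a `normalized_matrix`.
#' @param ann sample annotation data.frame (`sample_id`, `subject_id`,
#'   `group`, `visit_week`, optional `quality_flag`).
#' @return list of class `patient_deltas`: `deltas` — a list with one entry
#'   per subject x phase (`subject_id`, `phase`, `delta` named numeric,
#'   `n_metabolites`) — and `audit`.
#' @export
patient_deltas <- function(x, ann) {
  stopifnot(inherits(x, "normalized_matrix"))
  ann <- ann[ann$sample_id %in% colnames(x$log2_values) &
               ann$group == "case", , drop = FALSE]
  if ("quality_flag" %in% names(ann))
    ann <- ann[is.na(ann$quality_flag) | ann$quality_flag != "excluded", ,
               drop = FALSE]
  dup <- duplicated(ann[, c("subject_id", "visit_week")])
  if (any(dup))
    stop_named("duplicate sample for subject-visit: %s",
               paste(unique(sprintf("%s/week %s", ann$subject_id[dup],
                                    ann$visit_week[dup])), collapse = ", "))
  phases <- list(lead_in = c(0, 16), treatment = c(16, 32))
  deltas <- list(); audit <- character()
  for (subj in unique(ann$subject_id)) {
    rows <- ann[ann$subject_id == subj, ]
    for (ph in names(phases)) {
      wk <- phases[[ph]]
      s_from <- rows$sample_id[rows$visit_week == wk[1]]
      s_to <- rows$sample_id[rows$visit_week == wk[2]]
      if (length(s_from) != 1L || length(s_to) != 1L) {
        audit <- c(audit, sprintf("subject %s: missing endpoint for %s phase, omitted",
                                  subj, ph))
        next
      }
      a <- x$log2_values[, s_from]; b <- x$log2_values[, s_to]
      keep <- !is.na(a) & !is.na(b)
      deltas[[length(deltas) + 1L]] <- list(
        subject_id = subj, phase = ph,
        delta = (b - a)[keep], n_metabolites = sum(keep))
    }
  }
  structure(list(deltas = deltas, audit = audit), class = "patient_deltas")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and pairwise-complete
#' deletion of missing values.
#'
#' @param a,b paired numeric vectors.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop_named("vectors must be paired (same length)")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop_named("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0)
    stop_named("constant vector: Spearman correlation undefined")
  cor(a, b, method = "spearman")
}

#' Delete-one jackknife confidence interval for Spearman's rho
#'
#' Leave-one-pair-out jackknife on the Fisher z scale: for each pair i the
#' correlation of the remaining n-1 pairs is z-transformed; the jackknife
#' variance of z is `(n-1)/n * sum((z_i - mean(z_i))^2)`; a normal-theory
#' interval around the full-sample z is back-transformed with tanh and
#' clamped to \[-1, 1\]. Leave-one-out subsets in which either vector is
#' constant are skipped with a warning; if fewer than 80% of pseudovalues are
#' usable the interval is refused.
#'
#' @param a,b paired numeric vectors (n >= 10 complete pairs).
#' @param level confidence level, default 0.95.
#' @return list `rho`, `low`, `high`, `n_used`, `level`.
#' @export
jackknife_ci <- function(a, b, level = 0.95) {
  stopifnot(is_prob(level), level > 0, level < 1)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 10L) stop_named("need at least 10 complete pairs (got %d)", n)
  rho <- spearman_rho(a, b)
  z_full <- fisher_z(rho)
  if (!anyDuplicated(a) && !anyDuplicated(b)) {
    z_loo <- fisher_z(loo_spearman_noties(a, b))
  } else {
    z_loo <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ai <- a[-i]; bi <- b[-i]
      if (sd(ai) == 0 || sd(bi) == 0) next
      z_loo[i] <- fisher_z(cor(ai, bi, method = "spearman"))
    }
  }
  usable <- is.finite(z_loo)
  if (any(!usable))
    warn_named("%d leave-one-out pseudovalue(s) skipped (constant subset)",
               sum(!usable))
  if (mean(usable) < 0.8)
    stop_named("fewer than 80%% of jackknife pseudovalues usable")
  m <- sum(usable)
  z_bar <- mean(z_loo[usable])
  var_jack <- (m - 1) / m * sum((z_loo[usable] - z_bar)^2)
  half <- qnorm((1 + level) / 2) * sqrt(var_jack)
  list(rho = rho,
       low = clamp(tanh(z_full - half), -1, 1),
       high = clamp(tanh(z_full + half), -1, 1),
       n_used = n, level = level)
}

# all delete-one Spearman correlations at once for tie-free vectors.
# Removing pair i shifts every remaining rank above rank_i down by one, so
# the leave-one-out ranks are a permutation of 1..(n-1) and only the rank
# cross-product varies with i; the dominance count supplies the correction.
loo_spearman_noties <- function(a, b) {
  n <- length(a)
  ra <- rank(a); rb <- rank(b)
  T_all <- sum(ra * rb)
  w_ab <- numeric(n); w_ab[rb] <- ra      # ra listed in rb-rank order
  w_ba <- numeric(n); w_ba[ra] <- rb
  suf_ab <- rev(cumsum(rev(w_ab)))        # sum of ra over rb-rank >= k
  suf_ba <- rev(cumsum(rev(w_ba)))
  sum_rav <- c(suf_ab[-1L], 0)[rb]        # ra_j over rb_j > rb_i
  sum_rbu <- c(suf_ba[-1L], 0)[ra]
  cnt <- colSums(outer(ra, ra, ">") & outer(rb, rb, ">"))
  S_ab <- T_all - ra * rb - sum_rav - sum_rbu + cnt
  m <- n - 1
  mu <- m * (m + 1)^2 / 4                 # (sum of 1..m)^2 / m
  ss <- m * (m + 1) * (2 * m + 1) / 6 - mu
  (S_ab - mu) / ss
}

#' Project a patient's phase delta onto the disease signature
#'
#' The signature-shift score: Spearman correlation of the patient's
#' phase-wise log2 fold changes against the cohort disease signature over
#' their common metabolites, with a delete-one jackknife confidence
#' interval. Positive rho means the patient's metabolome moved in the
#' direction of the disease signature during that phase; negative rho means
#' it moved toward the control profile.
#'
#' @param delta one element of [patient_deltas()]`$deltas` (list with
#'   `subject_id`, `phase`, `delta`).
#' @param sig a `disease_signature` data.frame, or a named numeric log2FC
#'   vector (e.g. an external transcriptomic signature).
#' @param min_common minimum common features for a usable score (default 10).
#' @param level confidence level for the jackknife interval.
#' @param fdr_filter optional FDR threshold: restrict the projection to
#'   signature metabolites with `fdr <=` this value (requires a
#'   `disease_signature` input). Default uses all common metabolites.
#' @param ci compute the jackknife interval (default TRUE); `FALSE` returns
#'   the point score only (e.g. inside simulations that do not use the CI).
#' @return `rho_score`: list `subject_id`, `phase`, `rho`, `ci_low`,
#'   `ci_high`, `n_used`, `usable`, `method = "jackknife"`.
#' @export
project_patient <- function(delta, sig, min_common = 10L, level = 0.95,
                            fdr_filter = NULL, ci = TRUE) {
  fc <- signature_vector(sig, fdr_filter)
  common <- intersect(names(delta$delta), names(fc))
  if (length(common) < min_common) {
    return(structure(list(subject_id = delta$subject_id, phase = delta$phase,
                          rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          n_used = length(common), usable = FALSE,
                          method = "jackknife"), class = "rho_score"))
  }
  if (ci) {
    jk <- jackknife_ci(delta$delta[common], fc[common], level = level)
    structure(list(subject_id = delta$subject_id, phase = delta$phase,
                   rho = jk$rho, ci_low = jk$low, ci_high = jk$high,
                   n_used = jk$n_used, usable = TRUE, method = "jackknife"),
              class = "rho_score")
  } else {
    structure(list(subject_id = delta$subject_id, phase = delta$phase,
                   rho = spearman_rho(delta$delta[common], fc[common]),
                   ci_low = NA_real_, ci_high = NA_real_,
                   n_used = length(common), usable = TRUE,
                   method = "jackknife"), class = "rho_score")
  }
}

signature_vector <- function(sig, fdr_filter = NULL) {
  if (inherits(sig, "disease_signature") ||
      (is.data.frame(sig) && all(c("metabolite", "log2FC") %in% names(sig)))) {
    keep <- !is.na(sig$log2FC)
    if (!is.null(fdr_filter)) keep <- keep & !is.na(sig$fdr) & sig$fdr <= fdr_filter
    setNames(sig$log2FC[keep], sig$metabolite[keep])
  } else if (is.numeric(sig) && !is.null(names(sig))) {
    if (!is.null(fdr_filter))
      stop_named("fdr_filter requires a disease_signature with an fdr column")
    sig[!is.na(sig)]
  } else stop_named("sig must be a disease_signature or a named log2FC vector")
}

#' Project every patient delta and tabulate rho scores
#'
#' @param deltas a [patient_deltas()] result.
#' @param sig signature (see [project_patient()]).
#' @inheritParams project_patient
#' @return data.frame with columns `subject_id`, `phase`, `rho`, `ci_low`,
#'   `ci_high`, `n_used`, `usable`.
#' @export
rho_score_table <- function(deltas, sig, min_common = 10L, level = 0.95,
                            fdr_filter = NULL, ci = TRUE) {
  rows <- lapply(deltas$deltas, project_patient, sig = sig,
                 min_common = min_common, level = level,
                 fdr_filter = fdr_filter, ci = ci)
  do.call(rbind, lapply(rows, function(r)
    data.frame(subject_id = r$subject_id, phase = r$phase, rho = r$rho,
               ci_low = r$ci_low, ci_high = r$ci_high, n_used = r$n_used,
               usable = r$usable, stringsAsFactors = FALSE)))
}

#' Classify a patient as a metabolic responder
#'
#' A patient is a responder when the jackknife confidence intervals of the
#' lead-in and treatment rho scores do not overlap — a significant
#' within-patient change in signature alignment between the two phases. By
#' default the call additionally requires the treatment interval to lie
#' entirely below the lead-in interval (a shift away from the disease
#' signature, toward the control profile); set `directional = FALSE` to call
#' any disjoint pair a responder.
#'
#' @param leadin,treatment `rho_score` objects for the same subject.
#' @param directional require the shift to be toward the control profile.
#' @return `responder_call`: list `subject_id`, `responder`, `direction`
#'   (`"toward_control"`, `"toward_disease"` or `"none"`), `usable`.
#' @export
classify_responder <- function(leadin, treatment, directional = TRUE) {
  if (!identical(leadin$subject_id, treatment$subject_id))
    stop_named("lead-in and treatment scores belong to different subjects")
  if (!isTRUE(leadin$usable) || !isTRUE(treatment$usable)) {
    return(structure(list(subject_id = leadin$subject_id, responder = FALSE,
                          direction = "none", usable = FALSE),
                     class = "responder_call"))
  }
  below <- treatment$ci_high < leadin$ci_low
  above <- treatment$ci_low > leadin$ci_high
  disjoint <- below || above
  direction <- if (!disjoint) "none" else if (below) "toward_control" else "toward_disease"
  responder <- disjoint && (!directional || below)
  structure(list(subject_id = leadin$subject_id, responder = responder,
                 direction = direction, usable = TRUE),
            class = "responder_call")
}

#' Responder calls for a whole rho table
#'
#' @param rho_table data.frame from [rho_score_table()].
#' @param directional see [classify_responder()].
#' @return data.frame `subject_id`, `responder`, `direction`, `usable`.
#' @export
responder_table <- function(rho_table, directional = TRUE) {
  subjects <- unique(rho_table$subject_id)
  rows <- lapply(subjects, function(s) {
    li <- rho_table[rho_table$subject_id == s & rho_table$phase == "lead_in", ]
    tr <- rho_table[rho_table$subject_id == s & rho_table$phase == "treatment", ]
    if (nrow(li) != 1L || nrow(tr) != 1L)
      return(data.frame(subject_id = s, responder = FALSE, direction = "none",
                        usable = FALSE, stringsAsFactors = FALSE))
    call <- classify_responder(as_rho_score(li), as_rho_score(tr),
                               directional = directional)
    data.frame(subject_id = s, responder = call$responder,
               direction = call$direction, usable = call$usable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_rho_score <- function(row) {
  structure(list(subject_id = row$subject_id, phase = row$phase,
                 rho = row$rho, ci_low = row$ci_low, ci_high = row$ci_high,
                 n_used = row$n_used, usable = isTRUE(row$usable),
                 method = "jackknife"), class = "rho_score")
}

#' Cohort-level correlation of two fold-change vectors
#'
#' Spearman correlation (asymptotic p-value) of two log2FC vectors over their
#' common identifiers, e.g. disease signature vs severe-vs-mild fold changes,
#' muscle vs serum signatures, or signature vs mean phase change. The
#' per-metabolite table labels each metabolite's quadrant (same-direction vs
#' opposite); when per-comparison p-values are supplied, Fisher-combined and
#' BH-adjusted significance is attached.
#'
#' @param fc_a,fc_b named numeric log2FC vectors.
#' @param p_a,p_b optional named per-comparison p-value vectors matching
#'   `fc_a` / `fc_b`.
#' @return list `rho`, `p`, `n`, `table` (metabolite, fc_a, fc_b, quadrant,
#'   and combined significance columns when p-values were given).
#' @export
correlate_signatures <- function(fc_a, fc_b, p_a = NULL, p_b = NULL) {
  common <- intersect(names(fc_a)[!is.na(fc_a)], names(fc_b)[!is.na(fc_b)])
  if (length(common) < 3L)
    stop_named("need at least 3 shared identifiers (got %d)", length(common))
  a <- fc_a[common]; b <- fc_b[common]
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  tab <- data.frame(metabolite = common, fc_a = unname(a), fc_b = unname(b),
                    quadrant = ifelse(sign(a) * sign(b) >= 0, "same_direction",
                                      "opposite"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(p_a) && !is.null(p_b)) {
    pm <- cbind(p_a[common], p_b[common])
    rownames(pm) <- common
    comb <- fisher_combine(pm)
    tab$p_combined <- comb$p_combined
    tab$fdr_combined <- comb$fdr_combined
  }
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common),
       table = tab)
}
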