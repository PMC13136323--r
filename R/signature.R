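#' Estimate the disease metabolic signature
#'
#' Per-metabolite case-vs-control log2 fold change on the centered log2
#' scale (difference of group means), with either an ordinary pooled-variance
#' two-sample t-test or a moderated t-test in which per-metabolite variances
#' are shrunk toward an empirical-Bayes prior. The prior is a scaled
#' inverse-chi-square with prior degrees of freedom `d0` and prior variance
#' `s0^2` estimated from the marginal distribution of the per-metabolite
#' sample variances by moment matching (under the prior, `s^2 / s0^2` follows
#' an F(d, d0) distribution; its first two moments identify `d0` and `s0^2`).
#' The moderated statistic uses the posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` and a t reference with `d + d0` degrees of
#' freedom. Benjamini-Hochberg FDR is computed across all metabolites with a
#' defined p-value.
#'
#' Cases contribute their baseline (week 0) sample only; samples flagged
#' `excluded` in the annotation are dropped.
#'
#' @param x a `normalized_matrix` (see [normalize_intensities()]).
#' @param ann sample annotation data.frame with columns `sample_id`,
#'   `subject_id`, `group`, `visit_week`, `quality_flag` (visit/quality
#'   columns are optional; when present they select baseline, non-excluded
#'   samples).
#' @param shrinkage `"moderated"` (default) or `"ordinary"`.
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom `d0` (0 recovers the ordinary t, `Inf` fully shrinks every
#'   variance to `s0^2`).
#' @return `disease_signature`: a data.frame with one row per metabolite and
#'   columns `metabolite`, `log2FC`, `t`, `p`, `fdr`, `n_case`, `n_control`,
#'   plus attributes `prior_df`, `prior_var`, `shrinkage` and `audit`.
#' @export
estimate_signature <- function(x, ann,
                               shrinkage = c("moderated", "ordinary"),
                               prior_df = NULL) {
  shrinkage <- match.arg(shrinkage)
  stopifnot(inherits(x, "normalized_matrix"))
  sel <- signature_samples(x, ann)
  case_m <- x$log2_values[, sel$case, drop = FALSE]
  ctrl_m <- x$log2_values[, sel$control, drop = FALSE]
  if (ncol(case_m) < 2L || ncol(ctrl_m) < 2L)
    stop_named("need at least 2 samples per group (got %d case, %d control)",
               ncol(case_m), ncol(ctrl_m))

  n1 <- rowSums(!is.na(case_m))
  n2 <- rowSums(!is.na(ctrl_m))
  m1 <- rowMeans(case_m, na.rm = TRUE)
  m2 <- rowMeans(ctrl_m, na.rm = TRUE)
  v1 <- apply(case_m, 1, var, na.rm = TRUE)
  v2 <- apply(ctrl_m, 1, var, na.rm = TRUE)
  ok <- n1 >= 2L & n2 >= 2L
  fc <- ifelse(n1 >= 1L & n2 >= 1L, m1 - m2, NA_real_)

  d <- n1 + n2 - 2
  s2 <- (ifelse(n1 > 1, (n1 - 1) * v1, 0) + ifelse(n2 > 1, (n2 - 1) * v2, 0)) / d
  s2[!ok] <- NA_real_

  if (shrinkage == "moderated") {
    prior <- moment_match_prior(s2[ok], d[ok])
    d0 <- prior_df %||% prior$d0
    s02 <- prior$s02
    if (is.infinite(d0)) {
      s2_post <- rep(s02, length(s2))
      df_post <- rep(Inf, length(s2))
    } else {
      s2_post <- (d0 * s02 + d * s2) / (d0 + d)
      df_post <- d + d0
    }
  } else {
    d0 <- 0; s02 <- NA_real_
    s2_post <- s2
    df_post <- d
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- fc / se
  tstat[!ok] <- NA_real_
  p <- 2 * pt(abs(tstat), df = df_post, lower.tail = FALSE)
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- bh_fdr(p[!is.na(p)])

  res <- data.frame(metabolite = rownames(x$log2_values),
                    log2FC = fc, t = tstat, p = p, fdr = fdr,
                    n_case = n1, n_control = n2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "shrinkage") <- shrinkage
  attr(res, "prior_df") <- if (shrinkage == "moderated") d0 else 0
  attr(res, "prior_var") <- s02
  attr(res, "audit") <- c(x$audit,
    sprintf("signature: %d case vs %d control samples, %s test; %d metabolite(s) with <2 values in a group",
            ncol(case_m), ncol(ctrl_m), shrinkage, sum(!ok)))
  class(res) <- c("disease_signature", "data.frame")
  res
}

# select baseline case and control sample ids from an annotation
signature_samples <- function(x, ann) {
  ann <- ann[ann$sample_id %in% colnames(x$log2_values), , drop = FALSE]
  if ("quality_flag" %in% names(ann))
    ann <- ann[is.na(ann$quality_flag) | ann$quality_flag != "excluded", ,
               drop = FALSE]
  is_case <- ann$group == "case"
  if ("visit_week" %in% names(ann)) {
    vb <- ann$visit_week
    is_case <- is_case & (is.na(vb) | vb == 0)
  }
  list(case = ann$sample_id[is_case],
       control = ann$sample_id[ann$group == "control"])
}

# moment-matched scaled-inverse-chi-square prior for per-metabolite variances:
# marginally s2/s02 ~ F(d, d0); matching mean and variance of s2 gives
#   d0 = (4 R d + 2 d - 4) / (R d - 2),  R = var(s2)/mean(s2)^2
# and s02 = mean(s2) (d0 - 2)/d0. Underdispersion (R d <= 2) means no finite
# d0 fits: the prior is degenerate at s02 = mean(s2) (d0 = Inf).
moment_match_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 3L)
    stop_named("too few per-metabolite variances to estimate a prior")
  d_use <- median(d[is.finite(d)])
  m <- mean(s2)
  R <- var(s2) / m^2
  if (R * d_use <= 2) return(list(d0 = Inf, s02 = m))
  d0 <- (4 * R * d_use + 2 * d_use - 4) / (R * d_use - 2)
  if (d0 <= 4) d0 <- 4.001  # variance moment at the edge of existence
  list(d0 = d0, s02 = m * (d0 - 2) / d0)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone in the ranking of the input and capped
#' at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_named("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's combined probability test across comparisons
#'
#' Combines k per-comparison p-values per metabolite as
#' `X = -2 sum(log p)` referred to a chi-square distribution with 2k degrees
#' of freedom, then applies Benjamini-Hochberg FDR across metabolites to the
#' combined p-values. Used to label metabolites jointly significant in two
#' fold-change comparisons (e.g. case-vs-control and severe-vs-mild).
#'
#' @param p_lists numeric matrix (metabolites x comparisons) or data.frame;
#'   rownames identify metabolites. All p in (0, 1]; zeros are clamped to the
#'   smallest positive double with a warning.
#' @return `combined_significance` data.frame: `metabolite`, per-comparison
#'   p columns, `fisher_stat`, `p_combined`, `fdr_combined`.
#' @export
fisher_combine <- function(p_lists) {
  pm <- as.matrix(p_lists)
  storage.mode(pm) <- "double"
  if (any(is.na(pm)))
    stop_named("missing p-values cannot be combined")
  if (any(pm < 0 | pm > 1))
    stop_named("p-values must lie in (0, 1]")
  if (any(pm == 0)) {
    warn_named("p-value(s) equal to 0 clamped to smallest positive double")
    pm[pm == 0] <- .Machine$double.xmin
  }
  k <- ncol(pm)
  stat <- -2 * rowSums(log(pm))
  p_comb <- pchisq(stat, df = 2 * k, lower.tail = FALSE)
  res <- data.frame(metabolite = rownames(pm) %||% as.character(seq_len(nrow(pm))),
                    pm, fisher_stat = stat, p_combined = p_comb,
                    fdr_combined = bh_fdr(p_comb),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(res)[seq_len(k) + 1L] <- paste0("p_", seq_len(k))
  class(res) <- c("combined_significance", "data.frame")
  res
}

#' Group separation on the first principal component
#'
#' PCA of samples (metabolites as features, per-metabolite centering, no
#' scaling — inputs are already median-centered log2 values), followed by a
#' test of group difference on PC1 scores. The default construction is the
#' variance-ratio F-test (case PC1 variance over control PC1 variance,
#' two-sided); `method = "anova"` instead runs a one-way ANOVA of PC1 scores
#' on group.
#'
#' Only metabolites observed in every selected sample enter the PCA.
#'
#' @param x a `normalized_matrix`.
#' @param ann sample annotation (see [estimate_signature()]).
#' @param method `"var_ratio"` (default) or `"anova"`.
#' @return list with `pc1_scores` (named by sample), `F`, `df`, `p`,
#'   `var_explained` (PC1 proportion of variance) and `method`.
#' @export
pc1_separation <- function(x, ann, method = c("var_ratio", "anova")) {
  method <- match.arg(method)
  sel <- signature_samples(x, ann)
  samples <- c(sel$case, sel$control)
  if (length(sel$case) < 3L || length(sel$control) < 3L)
    stop_named("need at least 3 samples per group for PC1 separation")
  mat <- x$log2_values[, samples, drop = FALSE]
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2L)
    stop_named("fewer than 2 metabolites observed in all samples")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  scores <- setNames(pc$x[, 1L], samples)
  g_case <- scores[sel$case]; g_ctrl <- scores[sel$control]
  v1 <- var(g_case); v2 <- var(g_ctrl)
  if (v1 <= 0 || v2 <= 0)
    stop_named("degenerate (zero-variance) PC1 scores in a group")
  if (method == "var_ratio") {
    Fstat <- v1 / v2
    df <- c(length(g_case) - 1L, length(g_ctrl) - 1L)
    p <- min(1, 2 * min(pf(Fstat, df[1], df[2]),
                        pf(Fstat, df[1], df[2], lower.tail = FALSE)))
  } else {
    grp <- factor(rep(c("case", "control"), c(length(g_case), length(g_ctrl))))
    a <- anova(stats::lm(c(g_case, g_ctrl) ~ grp))
    Fstat <- a$`F value`[1L]
    df <- c(a$Df[1L], a$Df[2L])
    p <- a$`Pr(>F)`[1L]
  }
  list(pc1_scores = scores, F = Fstat, df = df, p = p,
       var_explained = unname(pc$sdev[1L]^2 / sum(pc$sdev^2)), method = method)
}

#' Write a disease signature to TSV
#'
#' Hand-off format to the projection stage: columns metabolite, log2FC, t,
#' p, fdr.
#'
#' @param sig a `disease_signature`.
#' @param path output path.
#' @export
write_signature_tsv <- function(sig, path) {
  out <- sig[, c("metabolite", "log2FC", "t", "p", "fdr")]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a signature TSV (metabolite + log2FC, e.g. an external gene signature)
#'
#' @param path path to a TSV with at least an identifier column and a
#'   `log2FC` column.
#' @return named numeric vector of log2 fold changes.
#' @export
read_signature_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"log2FC" %in% names(tab))
    stop_named("%s: no log2FC column", path)
  setNames(tab$log2FC, as.character(tab[[1L]]))
}
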