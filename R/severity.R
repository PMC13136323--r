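#' Ultrasound sum score and severity class
#'
#' Heckmatt echointensity grades (1-4) are collected bilaterally for three
#' muscles — flexor digitorum profundus (FDP), vastus lateralis (VL) and
#' rectus femoris (RF). The higher grade of the two sides is taken per
#' muscle and the three maxima are summed (range 3-12). Severe disease is a
#' sum score above the cutoff (default 10) together with atrophy in at least
#' one muscle; `require_atrophy = FALSE` drops the atrophy condition.
#'
#' @param assessment data.frame for one subject with columns `muscle`
#'   (FDP/VL/RF), `side` (left/right), `grade` (integer 1-4), `atrophy`
#'   (logical).
#' @param cutoff severity cutoff on the sum score (default 10, exceeded
#'   strictly).
#' @param require_atrophy logical, default TRUE.
#' @return list `sum_score` (integer), `severity` (`"severe"` or
#'   `"mild_moderate"`), `per_muscle` (named bilateral maxima).
#' @export
sum_score <- function(assessment, cutoff = 10L, require_atrophy = TRUE) {
  muscles <- c("FDP", "VL", "RF")
  sides <- c("left", "right")
  per_muscle <- setNames(integer(3), muscles)
  for (mus in muscles) {
    for (sd_ in sides) {
      g <- assessment$grade[assessment$muscle == mus & assessment$side == sd_]
      if (length(g) != 1L || is.na(g))
        stop_named("missing Heckmatt grade for %s %s", mus, sd_)
      if (!g %in% 1:4)
        stop_named("Heckmatt grade for %s %s out of range 1-4 (got %s)",
                   mus, sd_, g)
    }
    per_muscle[mus] <- max(assessment$grade[assessment$muscle == mus])
  }
  total <- sum(per_muscle)
  atrophy <- any(as.logical(assessment$atrophy), na.rm = TRUE)
  severe <- total > cutoff && (!require_atrophy || atrophy)
  list(sum_score = as.integer(total),
       severity = if (severe) "severe" else "mild_moderate",
       per_muscle = per_muscle)
}

#' Severity classes for an ultrasound table of many subjects
#'
#' @param ultrasound data.frame with columns `subject_id`, `muscle`, `side`,
#'   `grade`, `atrophy`.
#' @inheritParams sum_score
#' @return data.frame `subject_id`, `sum_score`, `severity`.
#' @export
severity_classes <- function(ultrasound, cutoff = 10L, require_atrophy = TRUE) {
  subjects <- unique(ultrasound$subject_id)
  rows <- lapply(subjects, function(s) {
    sc <- sum_score(ultrasound[ultrasound$subject_id == s, , drop = FALSE],
                    cutoff = cutoff, require_atrophy = require_atrophy)
    data.frame(subject_id = s, sum_score = sc$sum_score,
               severity = sc$severity, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way mixed ANOVA of rho by phase and severity
#'
#' Tests whether the metabolic response differs by ultrasound severity:
#' within-subject factor phase (lead-in vs treatment), between-subject factor
#' severity (severe vs mild-moderate), classical univariate decomposition via
#' `aov` with a subject error stratum. With only two within-subject levels
#' sphericity holds trivially, so no correction is applied. Tukey HSD over
#' the four phase x severity cell means is computed with \pkg{emmeans}.
#' `response = "change"` instead tests the severity effect on the per-subject
#' rho change (treatment minus lead-in) with a one-way ANOVA, which is the
#' equivalent contrast on difference scores.
#'
#' @param rho_table data.frame from [rho_score_table()] (columns
#'   `subject_id`, `phase`, `rho`; unusable scores are dropped).
#' @param severity data.frame `subject_id`, `severity` (or a named character
#'   vector).
#' @param response `"per_phase"` (default) or `"change"`.
#' @return list `interaction_F`, `interaction_p`, `anova_table` (data.frame
#'   of the within stratum, or the one-way table), `tukey` (data.frame of
#'   pairwise cell comparisons; NULL for `"change"`), `n_per_class`,
#'   `response`.
#' @export
severity_anova <- function(rho_table, severity,
                           response = c("per_phase", "change")) {
  response <- match.arg(response)
  if (!is.data.frame(severity))
    severity <- data.frame(subject_id = names(severity),
                           severity = unname(severity),
                           stringsAsFactors = FALSE)
  d <- rho_table
  if ("usable" %in% names(d)) d <- d[d$usable, , drop = FALSE]
  d <- merge(d, severity, by = "subject_id")
  complete <- names(which(table(d$subject_id) == 2L))
  d <- d[d$subject_id %in% complete, , drop = FALSE]
  if (!nrow(d)) stop_named("no subject has rho for both phases")
  d$subject_id <- factor(d$subject_id)
  d$phase <- factor(d$phase, levels = c("lead_in", "treatment"))
  d$severity <- factor(d$severity, levels = c("mild_moderate", "severe"))
  n_per_class <- table(d$severity[d$phase == "lead_in"])
  if (any(n_per_class < 2L))
    stop_named("severity class with fewer than 2 subjects: %s",
               paste(names(n_per_class)[n_per_class < 2L], collapse = ", "))

  if (response == "change") {
    wide <- merge(d[d$phase == "lead_in", c("subject_id", "rho", "severity")],
                  d[d$phase == "treatment", c("subject_id", "rho")],
                  by = "subject_id", suffixes = c("_lead", "_treat"))
    wide$change <- wide$rho_treat - wide$rho_lead
    a <- anova(stats::lm(change ~ severity, data = wide))
    return(list(interaction_F = a$`F value`[1L], interaction_p = a$`Pr(>F)`[1L],
                anova_table = as.data.frame(a), tukey = NULL,
                n_per_class = as.vector(n_per_class), response = response))
  }

  # do.call embeds the data in the stored call so emmeans can recover it
  fit <- do.call(aov, list(rho ~ severity * phase + Error(subject_id),
                           data = d))
  within <- as.data.frame(summary(fit)[["Error: Within"]][[1L]])
  within$term <- trimws(rownames(within))
  ia <- within[within$term == "severity:phase", ]
  if (var(d$rho) < 1e-14) {
    # all responses identical: no variance anywhere, interaction is null
    ia_F <- 0; ia_p <- 1
  } else {
    ia_F <- ia$`F value`; ia_p <- ia$`Pr(>F)`
  }
  em <- suppressMessages(emmeans::emmeans(fit, ~ severity * phase))
  tk <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  list(interaction_F = ia_F, interaction_p = ia_p,
       anova_table = within, tukey = tk,
       n_per_class = as.vector(n_per_class), response = response)
}

#' Leave-one-out sensitivity analysis of the severity interaction
#'
#' Repeats [severity_anova()] with each subject removed in turn. A subject is
#' flagged influential when their removal moves the phase x severity
#' interaction p-value across the 0.05 boundary (in either direction)
#' relative to the full-data analysis.
#'
#' @inheritParams severity_anova
#' @param alpha decision boundary, default 0.05.
#' @return list `full_p`, `table` (data.frame `subject_left_out`, `p`,
#'   `influential`, `skipped`), `audit`.
#' @export
leave_one_out <- function(rho_table, severity, response = "per_phase",
                          alpha = 0.05) {
  full <- severity_anova(rho_table, severity, response = response)
  subjects <- sort(unique(rho_table$subject_id))
  audit <- character()
  rows <- lapply(subjects, function(s) {
    sub <- rho_table[rho_table$subject_id != s, , drop = FALSE]
    res <- tryCatch(severity_anova(sub, severity, response = response),
                    error = function(e) e)
    if (inherits(res, "error")) {
      audit <<- c(audit, sprintf("subject %s: re-run skipped (%s)",
                                 s, conditionMessage(res)))
      return(data.frame(subject_left_out = s, p = NA_real_,
                        influential = NA, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    crossed <- (full$interaction_p < alpha) != (res$interaction_p < alpha)
    data.frame(subject_left_out = s, p = res$interaction_p,
               influential = crossed, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  list(full_p = full$interaction_p, table = do.call(rbind, rows),
       audit = audit)
}
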