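# Longitudinal clinical outcome models.
#
# Time is coded as visit index in 16-week units (weeks 0/16/32/48 -> 0/1/2/3)
# and Treatment as an indicator that is 1 at the on-drug visits (weeks 32 and
# 48). Both codings are recorded in every result.

TIME_CODING <- "time = visit_week / 16 (0..3); treatment = 1 at weeks 32, 48"

#' Fit the treatment-effect mixed model for one clinical outcome
#'
#' `outcome ~ 1 + Treatment * Time + (1 + Time | subject)`, REML, with Wald
#' z p-values for the fixed effects. If the random intercept-and-slope fit is
#' singular or fails to converge, the model is automatically refit with a
#' random intercept only and the fallback is recorded; if that fit is also
#' degenerate the result is marked non-converged and carries no p-values.
#'
#' @param records clinical long data.frame: `subject_id`, `visit_week`
#'   (0/16/32/48), `outcome_name`, `value`.
#' @param outcome_name which outcome to model.
#' @param random_structure `"intercept_and_slope"` (default) or
#'   `"intercept_only"` to skip the slope from the start.
#' @return `mixed_model_result`: list with `outcome_name`, `model_type`,
#'   `fixed_effects` (data.frame term/estimate/se/p), `vcov_fixed`,
#'   `random_structure`, `converged`, `n_obs`, `n_subjects`, `time_coding`,
#'   `audit`.
#' @export
fit_treatment_model <- function(records, outcome_name,
                                random_structure = c("intercept_and_slope",
                                                     "intercept_only")) {
  random_structure <- match.arg(random_structure)
  d <- outcome_frame(records, outcome_name)
  d$treatment <- as.numeric(d$visit_week >= 32)
  fit_mixed(d, value ~ treatment * time + (1 + time | subject_id),
            value ~ treatment * time + (1 | subject_id),
            outcome_name, "treatment", random_structure, audit = character())
}

#' Fit the rho-by-time mixed model for one clinical outcome
#'
#' Relates each patient's signature-shift score to their outcome trajectory:
#' the time-varying covariate rho(t) equals the subject's lead-in rho at
#' weeks 0 and 16 and their treatment rho at weeks 32 and 48. Model:
#' `outcome ~ 1 + rho(t) * Time + (1 + Time | subject)`; the rho x Time
#' coefficient is the headline estimate (a negative value for a
#' higher-is-better outcome means that staying disease-like predicts faster
#' decline). Subjects lacking either phase rho are dropped with an audit
#' entry.
#'
#' @inheritParams fit_treatment_model
#' @param rho_table data.frame from [rho_score_table()].
#' @return `mixed_model_result` (see [fit_treatment_model()]); the rho x time
#'   term is named `rho_t:time`.
#' @export
fit_rho_model <- function(records, outcome_name, rho_table,
                          random_structure = c("intercept_and_slope",
                                               "intercept_only")) {
  random_structure <- match.arg(random_structure)
  d <- outcome_frame(records, outcome_name)
  if ("usable" %in% names(rho_table))
    rho_table <- rho_table[rho_table$usable, , drop = FALSE]
  li <- rho_table[rho_table$phase == "lead_in", c("subject_id", "rho")]
  tr <- rho_table[rho_table$phase == "treatment", c("subject_id", "rho")]
  both <- merge(li, tr, by = "subject_id", suffixes = c("_lead", "_treat"))
  dropped <- setdiff(unique(d$subject_id), both$subject_id)
  audit <- if (length(dropped))
    sprintf("subject(s) without both phase rho scores dropped: %s",
            paste(dropped, collapse = ", ")) else character()
  d <- d[d$subject_id %in% both$subject_id, , drop = FALSE]
  if (!nrow(d)) stop_named("no modelled subject has both phase rho scores")
  idx <- match(d$subject_id, both$subject_id)
  d$rho_t <- ifelse(d$visit_week <= 16, both$rho_lead[idx], both$rho_treat[idx])
  if (var(both$rho_lead) < 1e-12 && var(both$rho_treat) < 1e-12)
    stop_named("rho covariate is constant across subjects: rho x time is collinear with time")
  fit_mixed(d, value ~ rho_t * time + (1 + time | subject_id),
            value ~ rho_t * time + (1 | subject_id),
            outcome_name, "rho", random_structure, audit = audit)
}

outcome_frame <- function(records, outcome_name) {
  d <- records[records$outcome_name == outcome_name, , drop = FALSE]
  if (!nrow(d)) stop_named("no records for outcome %s", outcome_name)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (length(unique(d$subject_id)) < 3L)
    stop_named("need at least 3 subjects with data for %s", outcome_name)
  d$time <- d$visit_week / 16
  d$subject_id <- factor(d$subject_id)
  d
}

fit_mixed <- function(d, full_formula, fallback_formula, outcome_name,
                      model_type, random_structure, audit) {
  try_fit <- function(formula) {
    warn <- character()
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(formula, data = d, REML = TRUE),
               error = function(e) e),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(fit, "error"))
      return(list(ok = FALSE, fit = NULL, singular = TRUE, failed = TRUE,
                  warn = warn))
    singular <- lme4::isSingular(fit, tol = 1e-5)
    # gradient-check warnings trigger the fallback refit; hard optimizer
    # failure is the nonzero convergence code
    failed <- !is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0
    suspect <- any(grepl("failed to converge", warn))
    list(ok = !singular && !failed && !suspect, fit = fit,
         singular = singular, failed = failed, warn = warn)
  }
  structure_used <- random_structure
  res <- if (random_structure == "intercept_and_slope") try_fit(full_formula)
         else try_fit(fallback_formula)
  if (!res$ok && random_structure == "intercept_and_slope") {
    fb <- try_fit(fallback_formula)
    if (!is.null(fb$fit)) {
      audit <- c(audit, "random slope for time removed (singular or non-converged fit)")
      structure_used <- "intercept_only"
      res <- fb
    }
  }
  if (is.null(res$fit)) stop_named("mixed model could not be fitted for %s",
                                   outcome_name)
  # optimizer failure invalidates the fit; a boundary (singular) fit after
  # the fallback keeps its estimates but carries no p-values
  converged <- !isTRUE(res$failed)
  report_p <- converged && !res$singular
  if (res$singular)
    audit <- c(audit, "variance estimate on the boundary after fallback; p-values withheld")
  co <- as.data.frame(coef(summary(res$fit)))
  fe <- data.frame(term = rownames(co), estimate = co$Estimate,
                   se = co$`Std. Error`,
                   p = if (report_p) 2 * pnorm(-abs(co$`t value`)) else NA_real_,
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome_name = outcome_name, model_type = model_type,
                 fixed_effects = fe,
                 vcov_fixed = as.matrix(stats::vcov(res$fit)),
                 random_structure = structure_used, converged = converged,
                 n_obs = nrow(d),
                 n_subjects = length(unique(d$subject_id)),
                 time_coding = TIME_CODING, audit = audit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("mixed_model_result: %s (%s model, %s, %s)\n", x$outcome_name,
              x$model_type, x$random_structure,
              if (x$converged) "converged" else "NOT converged"))
  print(x$fixed_effects)
  invisible(x)
}

#' Predict an outcome trajectory for a hypothetical rho profile
#'
#' Population-level prediction (random effects at zero) of a rho model at
#' the four study visits for a specified rho profile, e.g. a patient who
#' stays at the study's highest observed rho versus one who shifts to the
#' lowest after week 16. 95% bands come from the fixed-effect covariance by
#' the delta method.
#'
#' @param model a converged `mixed_model_result` of type `"rho"`.
#' @param rho_profile either `list(lead_in =, treatment =)` (values applied
#'   at weeks 0/16 and 32/48 respectively) or a numeric vector of length 4,
#'   one rho per visit. Values must lie in \[-1, 1\].
#' @param level band level, default 0.95.
#' @return data.frame `visit_week`, `rho`, `predicted`, `lower`, `upper`.
#' @export
predict_trajectory <- function(model, rho_profile, level = 0.95) {
  stopifnot(inherits(model, "mixed_model_result"))
  if (model$model_type != "rho")
    stop_named("predict_trajectory requires a rho model")
  if (!model$converged) stop_named("model did not converge")
  weeks <- c(0, 16, 32, 48)
  if (is.list(rho_profile))
    rho <- c(rho_profile$lead_in, rho_profile$lead_in,
             rho_profile$treatment, rho_profile$treatment)
  else rho <- rep_len(as.numeric(rho_profile), 4L)
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop_named("rho profile values must lie in [-1, 1]")
  time <- weeks / 16
  X <- cbind(`(Intercept)` = 1, rho_t = rho, time = time, `rho_t:time` = rho * time)
  X <- X[, model$fixed_effects$term, drop = FALSE]
  beta <- model$fixed_effects$estimate
  pred <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% model$vcov_fixed) * X))
  zq <- qnorm((1 + level) / 2)
  data.frame(visit_week = weeks, rho = rho, predicted = pred,
             lower = pred - zq * se, upper = pred + zq * se)
}

#' Paired t-test of lead-in versus treatment phase changes
#'
#' For a per-subject variable measured as a change over each phase, tests
#' whether the treatment-phase change differs from the lead-in change with a
#' two-sided paired t-test. If every difference is zero, the statistic is
#' undefined and the result reports p = 1 with a zero-width interval and a
#' degeneracy flag.
#'
#' @param changes data.frame with columns `subject_id`, `leadin_change`,
#'   `treatment_change` (at least 3 complete subjects).
#' @param variable_name label carried into the result.
#' @return `phase_comparison`: list `variable_name`, `n`, `mean_difference`
#'   (mean of treatment minus lead-in), `ci` (length 2), `t`, `p`,
#'   `degenerate`, `per_subject`.
#' @export
paired_phase_test <- function(changes, variable_name = "variable") {
  d <- changes[stats::complete.cases(changes[, c("leadin_change",
                                                 "treatment_change")]), ,
               drop = FALSE]
  if (nrow(d) < 3L) stop_named("need at least 3 subjects with both changes")
  diffs <- d$treatment_change - d$leadin_change
  if (sd(diffs) == 0) {
    degenerate <- TRUE
    md <- mean(diffs)
    out <- list(mean_difference = md, ci = c(md, md),
                t = if (md == 0) 0 else NA_real_, p = 1)
  } else {
    tt <- t.test(d$treatment_change, d$leadin_change, paired = TRUE)
    degenerate <- FALSE
    out <- list(mean_difference = unname(tt$estimate),
                ci = as.numeric(tt$conf.int), t = unname(tt$statistic),
                p = tt$p.value)
  }
  structure(c(list(variable_name = variable_name, n = nrow(d)), out,
              list(degenerate = degenerate, per_subject = d)),
            class = "phase_comparison")
}

#' Read a clinical outcomes long TSV
#'
#' Columns: subject_id, visit_week, outcome_name, value.
#'
#' @param path path to TSV.
#' @return data.frame; out-of-range IBM_FRS values (outside 0-40) raise a
#'   warning.
#' @export
read_clinical_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit_week", "outcome_name", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_named("%s: missing clinical column(s): %s", path,
               paste(miss, collapse = ", "))
  key <- paste(d$subject_id, d$visit_week, d$outcome_name)
  if (anyDuplicated(key))
    stop_named("%s: duplicate subject/visit/outcome record", path)
  frs <- d$value[d$outcome_name == "IBM_FRS"]
  if (any(!is.na(frs) & (frs < 0 | frs > 40)))
    warn_named("%s: IBM_FRS value(s) outside the 0-40 scale range", path)
  d
}
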