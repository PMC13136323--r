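#' Configuration for a synthetic signature-shift trial
#'
#' Defaults emulate the structure of a single-arm lead-in/crossover IBM
#' trial: 15 cases with muscle biopsies at baseline, week 16 (end of the
#' no-treatment lead-in) and week 32 (end of treatment); 5 healthy muscle
#' controls and 10 healthy serum controls measured once; 211 muscle
#' metabolites of which 124 are shared with serum; roughly a third of cases
#' respond to treatment, with response concentrated in mild-moderate
#' disease; clinical outcomes at weeks 0/16/32/48 generated from a linear
#' mixed model whose rho-by-time coefficient is planted truth.
#'
#' @param seed integer RNG seed; the same seed reproduces the trial
#'   byte-identically.
#' @param n_cases,n_controls_muscle,n_controls_serum cohort sizes (>= 2).
#' @param n_metabolites muscle metabolite count.
#' @param n_shared_serum number of serum metabolites shared with muscle
#'   (<= `n_metabolites`); default 124, reduced to `n_metabolites` when a
#'   smaller muscle panel is configured.
#' @param n_serum_only additional serum-only metabolites.
#' @param frac_dysregulated fraction of muscle metabolites with large
#'   disease effects.
#' @param signature_effect_sd SD (log2 units) of the planted disease
#'   log2 fold changes for dysregulated metabolites.
#' @param background_effect_ratio non-dysregulated metabolites receive small
#'   effects with SD `background_effect_ratio * signature_effect_sd`, so the
#'   planted signature has no exact ties (real metabolomes are dense in
#'   small effects); 0 plants exact nulls.
#' @param noise_sd i.i.d. measurement noise SD per cell, log2 units.
#' @param leadin_drift target Spearman rho of the lead-in change against the
#'   signature (cohort mean; per-subject targets scatter around it). The
#'   default 0.03 encodes a stable lead-in.
#' @param rho_target_sd between-subject SD of the lead-in rho targets.
#' @param responder_fraction fraction of cases planted as responders.
#' @param responder_shift added to a responder's lead-in target to give
#'   their treatment-phase target (negative = shift toward controls). Must
#'   be negative when `responder_fraction > 0`; with 0 no subject is flagged.
#' @param severe_fraction fraction of cases classed severe (deterministic
#'   split; the last subjects in id order are severe, and responders are
#'   assigned mild-first, mirroring the observation that treatment response
#'   concentrates in milder disease).
#' @param severity_amplification multiplicative factor >= 1 on signature
#'   effects for severe subjects.
#' @param delta_scale SD (log2 units) of a subject's observed phase-change
#'   vector; raised automatically per subject when an extreme rho target
#'   needs more headroom over the measurement noise.
#' @param dropout_rate fraction of raw intensity cells zeroed (missing).
#' @param outcome_coefs named list of outcomes; each a list with `intercept`,
#'   `time` (slope per 16 weeks), `rho` (main effect), `rho_time`
#'   (rho-by-time coefficient), `resid_sd`, `re_int_sd`, `re_slope_sd`.
#' @param protein_conc_range mg/mL interval for per-sample protein
#'   concentrations.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_cases = 15L,
                             n_controls_muscle = 5L,
                             n_controls_serum = 10L,
                             n_metabolites = 211L,
                             n_shared_serum = NULL,
                             n_serum_only = 76L,
                             frac_dysregulated = 0.3,
                             signature_effect_sd = 2,
                             background_effect_ratio = 0.05,
                             noise_sd = 0.25,
                             leadin_drift = 0.03,
                             rho_target_sd = 0.25,
                             responder_fraction = 1 / 3,
                             responder_shift = -0.8,
                             severe_fraction = 0.5,
                             severity_amplification = 1.5,
                             delta_scale = 1,
                             dropout_rate = 0,
                             outcome_coefs = default_outcome_coefs(),
                             protein_conc_range = c(0.5, 5)) {
  if (is.null(n_shared_serum))
    n_shared_serum <- min(124L, as.integer(n_metabolites))
  cfg <- list(seed = as.integer(seed), n_cases = n_cases,
              n_controls_muscle = n_controls_muscle,
              n_controls_serum = n_controls_serum,
              n_metabolites = n_metabolites, n_shared_serum = n_shared_serum,
              n_serum_only = n_serum_only,
              frac_dysregulated = frac_dysregulated,
              signature_effect_sd = signature_effect_sd,
              background_effect_ratio = background_effect_ratio,
              noise_sd = noise_sd, leadin_drift = leadin_drift,
              rho_target_sd = rho_target_sd,
              responder_fraction = responder_fraction,
              responder_shift = responder_shift,
              severe_fraction = severe_fraction,
              severity_amplification = severity_amplification,
              delta_scale = delta_scale, dropout_rate = dropout_rate,
              outcome_coefs = outcome_coefs,
              protein_conc_range = protein_conc_range)
  for (nm in c("n_cases", "n_controls_muscle", "n_controls_serum",
               "n_metabolites", "n_shared_serum")) {
    if (!is_count(cfg[[nm]]) || cfg[[nm]] < 2)
      stop_named("%s must be an integer count >= 2", nm)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (!is_count(cfg$n_serum_only)) stop_named("n_serum_only must be a count")
  cfg$n_serum_only <- as.integer(cfg$n_serum_only)
  for (nm in c("frac_dysregulated", "responder_fraction", "severe_fraction",
               "dropout_rate"))
    if (!is_prob(cfg[[nm]])) stop_named("%s must be a proportion in [0, 1]", nm)
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop_named("noise_sd must be > 0")
  if (cfg$n_shared_serum > cfg$n_metabolites)
    stop_named("n_shared_serum must not exceed n_metabolites")
  if (abs(cfg$leadin_drift) > 1)
    stop_named("leadin_drift must lie in [-1, 1]")
  if (cfg$severity_amplification < 1)
    stop_named("severity_amplification must be >= 1")
  if (cfg$signature_effect_sd < 0)
    stop_named("signature_effect_sd must be >= 0")
  if (cfg$responder_fraction > 0 && cfg$responder_shift >= 0 &&
      cfg$responder_shift != 0)
    stop_named("responder_shift must be negative (or 0 to plant no responders)")
  if (length(cfg$protein_conc_range) != 2L ||
      any(cfg$protein_conc_range <= 0) ||
      diff(cfg$protein_conc_range) < 0)
    stop_named("protein_conc_range must be a positive increasing interval")
  structure(cfg, class = "synthetic_config")
}

default_outcome_coefs <- function() {
  list(
    IBM_FRS = list(intercept = 29, time = -0.3, rho = 0, rho_time = -3.32,
                   resid_sd = 1, re_int_sd = 4, re_slope_sd = 0.5),
    mTUG = list(intercept = 10.5, time = 0.2, rho = 0, rho_time = 1.95,
                resid_sd = 0.8, re_int_sd = 2.5, re_slope_sd = 0.3))
}

#' Generate a complete synthetic trial with planted ground truth
#'
#' Log-scale intensities are built as per-metabolite baseline abundance
#' (Normal mean 10, SD 2) plus a group/severity-scaled disease signature
#' effect, plus cumulative phase-wise change vectors, plus i.i.d. noise;
#' they are then exponentiated and multiplied by a per-sample protein
#' concentration so that preprocessing must undo both transformations.
#'
#' Each subject's phase-change vector is constructed on the Gaussian-score
#' scale: the signature is rank-transformed to normal scores and mixed with
#' an independent Gaussian vector so that the *observed* change (including
#' the measurement noise of the two endpoint samples) has population
#' Spearman correlation with the planted signature equal to the subject's
#' phase target (Pearson mixing weight `2*sin(pi*rho/6)`, the Gaussian-copula
#' inverse of the Spearman value).
#'
#' Clinical outcomes at weeks 0/16/32/48 follow the planted linear mixed
#' model with subject-level random intercepts and slopes, using each
#' subject's phase rho targets as the time-varying covariate.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_trial`: `muscle` and `serum`
#'   [metabolite_matrix()] objects, `annotation` (sample metadata
#'   data.frame), `ultrasound`, `clinical`, `truth` (planted ground truth:
#'   `true_signature`, `true_signature_serum`, `dysregulated`,
#'   `responder_flags`, `severity_class`, `phase_rho_targets`,
#'   `outcome_coefs`, `prefactor_intensities`), and `config`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  M <- config$n_metabolites
  met_ids <- sprintf("MET%03d", seq_len(M))
  shared_ids <- met_ids[seq_len(config$n_shared_serum)]
  serum_only <- if (config$n_serum_only > 0)
    sprintf("SER%03d", seq_len(config$n_serum_only)) else character()
  serum_ids <- c(shared_ids, serum_only)
  cases <- sprintf("P%02d", seq_len(config$n_cases))

  # severity: deterministic split, last subjects severe
  n_severe <- round(config$severe_fraction * config$n_cases)
  severity <- setNames(rep("mild_moderate", config$n_cases), cases)
  if (n_severe > 0)
    severity[seq(config$n_cases - n_severe + 1L, config$n_cases)] <- "severe"

  # responders: mild-first assignment
  n_resp <- if (config$responder_shift < 0)
    round(config$responder_fraction * config$n_cases) else 0L
  mild_first <- c(names(severity)[severity == "mild_moderate"],
                  names(severity)[severity == "severe"])
  responder <- setNames(rep(FALSE, config$n_cases), cases)
  if (n_resp > 0) responder[mild_first[seq_len(n_resp)]] <- TRUE

  # planted signatures (dense: large effects for the dysregulated fraction,
  # small background effects elsewhere so ranks are tie-free)
  base_mu <- rnorm(M, mean = 10, sd = 2)
  n_dys <- round(config$frac_dysregulated * M)
  dys <- sort(sample.int(M, n_dys))
  sig <- rnorm(M, 0, config$background_effect_ratio * config$signature_effect_sd)
  sig[dys] <- rnorm(n_dys, 0, config$signature_effect_sd)
  names(sig) <- met_ids

  n_serum_met <- length(serum_ids)
  base_mu_serum <- rnorm(n_serum_met, mean = 10, sd = 2)
  n_dys_serum <- round(config$frac_dysregulated * n_serum_met)
  dys_serum <- sort(sample.int(n_serum_met, n_dys_serum))
  sig_serum <- rnorm(n_serum_met, 0,
                     config$background_effect_ratio * config$signature_effect_sd)
  sig_serum[dys_serum] <- rnorm(n_dys_serum, 0, config$signature_effect_sd)
  names(sig_serum) <- serum_ids

  # per-subject phase rho targets
  leadin_t <- clamp(rnorm(config$n_cases, config$leadin_drift,
                          config$rho_target_sd), -0.9, 0.9)
  names(leadin_t) <- cases
  treat_t <- clamp(leadin_t + ifelse(responder, config$responder_shift, 0),
                   -0.95, 0.95)
  targets <- data.frame(
    subject_id = rep(cases, each = 2L),
    phase = rep(c("lead_in", "treatment"), config$n_cases),
    target = as.vector(rbind(leadin_t, treat_t)),
    stringsAsFactors = FALSE)

  # Gaussian scores of the signature ranks (degenerate signature -> no
  # achievable rank target; change vectors are then pure noise)
  degenerate <- sd(sig) == 0
  z_s <- if (degenerate) rep(0, M)
         else qnorm((rank(sig, ties.method = "average") - 0.5) / M)

  make_delta <- function(target) {
    eps <- rnorm(M)  # always drawn, keeps the stream aligned
    if (degenerate) target <- 0
    rho_p <- 2 * sin(pi * clamp(target, -0.99, 0.99) / 6)
    amp <- config$delta_scale
    need <- sqrt(2) * config$noise_sd / sqrt(max(1 - rho_p^2, 1e-8))
    if (amp < need * 1.05) amp <- need * 1.05
    b2 <- amp^2 * (1 - rho_p^2) - 2 * config$noise_sd^2
    amp * rho_p * z_s + sqrt(max(b2, 0)) * eps
  }

  amp_subject <- ifelse(severity == "severe", config$severity_amplification, 1)

  # muscle case samples at weeks 0/16/32, controls once
  visits <- c(0, 16, 32)
  muscle_samples <- c(
    as.vector(t(outer(cases, visits, function(s, w) sprintf("MU_%s_W%02d", s, w)))),
    sprintf("MU_HC%02d", seq_len(config$n_controls_muscle)))
  latent <- matrix(NA_real_, M, length(muscle_samples),
                   dimnames = list(met_ids, muscle_samples))
  truth_targets <- list()
  for (i in seq_along(cases)) {
    subj <- cases[i]
    d_lead <- make_delta(leadin_t[subj])
    d_treat <- make_delta(treat_t[subj])
    profile0 <- base_mu + amp_subject[i] * sig
    latent[, sprintf("MU_%s_W00", subj)] <- profile0
    latent[, sprintf("MU_%s_W16", subj)] <- profile0 + d_lead
    latent[, sprintf("MU_%s_W32", subj)] <- profile0 + d_lead + d_treat
  }
  for (j in seq_len(config$n_controls_muscle))
    latent[, sprintf("MU_HC%02d", j)] <- base_mu
  log2_muscle <- latent + matrix(rnorm(length(latent), 0, config$noise_sd),
                                 nrow(latent))

  # serum: cases at baseline plus serum controls
  serum_samples <- c(sprintf("SE_%s_W00", cases),
                     sprintf("SE_HC%02d", seq_len(config$n_controls_serum)))
  latent_serum <- matrix(NA_real_, n_serum_met, length(serum_samples),
                         dimnames = list(serum_ids, serum_samples))
  for (i in seq_along(cases))
    latent_serum[, i] <- base_mu_serum + amp_subject[i] * sig_serum
  for (j in seq_len(config$n_controls_serum))
    latent_serum[, config$n_cases + j] <- base_mu_serum
  log2_serum <- latent_serum +
    matrix(rnorm(length(latent_serum), 0, config$noise_sd), nrow(latent_serum))

  # protein factors and raw intensities (preprocessing must undo both)
  pc_muscle <- setNames(runif(length(muscle_samples),
                              config$protein_conc_range[1],
                              config$protein_conc_range[2]), muscle_samples)
  pc_serum <- setNames(runif(length(serum_samples),
                             config$protein_conc_range[1],
                             config$protein_conc_range[2]), serum_samples)
  pre_muscle <- 2^log2_muscle
  pre_serum <- 2^log2_serum
  raw_muscle <- sweep(pre_muscle, 2, pc_muscle, "*")
  raw_serum <- sweep(pre_serum, 2, pc_serum, "*")
  if (config$dropout_rate > 0) {
    drop_m <- runif(length(raw_muscle)) < config$dropout_rate
    drop_s <- runif(length(raw_serum)) < config$dropout_rate
    raw_muscle[drop_m] <- 0
    raw_serum[drop_s] <- 0
  }

  annotation <- rbind(
    data.frame(sample_id = as.vector(t(outer(cases, visits, function(s, w)
                 sprintf("MU_%s_W%02d", s, w)))),
               subject_id = rep(cases, each = 3L), group = "case",
               tissue = "muscle", visit_week = rep(visits, config$n_cases),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("MU_HC%02d", seq_len(config$n_controls_muscle)),
               subject_id = sprintf("HCM%02d", seq_len(config$n_controls_muscle)),
               group = "control", tissue = "muscle", visit_week = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("SE_%s_W00", cases), subject_id = cases,
               group = "case", tissue = "serum", visit_week = 0,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("SE_HC%02d", seq_len(config$n_controls_serum)),
               subject_id = sprintf("HCS%02d", seq_len(config$n_controls_serum)),
               group = "control", tissue = "serum", visit_week = NA_real_,
               stringsAsFactors = FALSE))
  annotation$protein_conc <- unname(c(pc_muscle, pc_serum)[annotation$sample_id])
  annotation$quality_flag <- "ok"

  ultrasound <- generate_ultrasound(cases, severity)
  clinical <- generate_clinical(cases, leadin_t, treat_t, config$outcome_coefs)

  truth <- list(
    true_signature = amp_mean(sig, amp_subject),
    planted_signature_unit = sig,
    true_signature_serum = amp_mean(sig_serum, amp_subject),
    dysregulated = met_ids[dys],
    responder_flags = responder,
    severity_class = severity,
    phase_rho_targets = targets,
    outcome_coefs = config$outcome_coefs,
    prefactor_intensities = list(muscle = pre_muscle, serum = pre_serum))

  structure(list(
    muscle = metabolite_matrix(raw_muscle, pc_muscle, "muscle"),
    serum = metabolite_matrix(raw_serum, pc_serum, "serum"),
    annotation = annotation, ultrasound = ultrasound, clinical = clinical,
    truth = truth, config = config), class = "synthetic_trial")
}

# population case-vs-control log2FC: signature scaled by the mean severity
# amplification across cases
amp_mean <- function(sig, amp_subject) sig * mean(amp_subject)

generate_ultrasound <- function(cases, severity) {
  muscles <- c("FDP", "VL", "RF")
  rows <- list()
  for (subj in cases) {
    severe <- severity[subj] == "severe"
    maxes <- if (severe) c(4L, 4L, sample(3:4, 1L))
             else sample(1:3, 3L, replace = TRUE)
    for (k in seq_along(muscles)) {
      hi_side <- sample(c("left", "right"), 1L)
      lo <- sample.int(maxes[k], 1L)
      for (sd_ in c("left", "right")) {
        g <- if (sd_ == hi_side) maxes[k] else lo
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj, muscle = muscles[k], side = sd_,
          grade = as.integer(g), atrophy = severe && maxes[k] == 4L,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

generate_clinical <- function(cases, leadin_t, treat_t, outcome_coefs) {
  weeks <- c(0, 16, 32, 48)
  tt <- weeks / 16
  rows <- list()
  for (nm in names(outcome_coefs)) {
    co <- outcome_coefs[[nm]]
    for (subj in cases) {
      b0 <- rnorm(1, 0, co$re_int_sd)
      b1 <- rnorm(1, 0, co$re_slope_sd)
      rho_t <- c(leadin_t[subj], leadin_t[subj], treat_t[subj], treat_t[subj])
      mu <- co$intercept + co$time * tt + (co$rho %||% 0) * rho_t +
        co$rho_time * rho_t * tt + b0 + b1 * tt
      y <- mu + rnorm(4, 0, co$resid_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, visit_week = weeks, outcome_name = nm, value = y,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(paste0("synthetic_trial: %d cases, %d muscle / %d serum controls, ",
                     "%d muscle metabolites (%d shared with serum), seed %d\n"),
              x$config$n_cases, x$config$n_controls_muscle,
              x$config$n_controls_serum, x$config$n_metabolites,
              x$config$n_shared_serum, x$config$seed))
  invisible(x)
}
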