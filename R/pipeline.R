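# End-to-end pipeline wiring: file-based inputs -> preprocess -> signature ->
# projection -> severity -> outcomes, with a JSON run report.

#' Pipeline run configuration
#'
#' @param muscle_tsv,serum_tsv intensity TSV paths (first column metabolite
#'   id, one column per sample); `serum_tsv` may be NULL.
#' @param metadata_tsv sample metadata TSV (see [read_sample_metadata()]).
#' @param clinical_tsv clinical long TSV (optional).
#' @param ultrasound_tsv ultrasound grades TSV (optional).
#' @param external_signature_tsv optional external log2FC table (e.g. a
#'   transcriptomic signature) to project patient deltas onto as well.
#' @param exclusion_list metabolite identifiers removed before normalization
#'   (default `"epinephrine"`, the anaesthetic carry-over).
#' @param min_common minimum common metabolites for a usable rho score.
#' @param fdr_level FDR level used for labeling (in (0,1)).
#' @param ci_level jackknife confidence level (in (0,1)).
#' @param severity_cutoff ultrasound sum-score cutoff (positive integer).
#' @param directional_responder require responder shifts to point toward the
#'   control profile.
#' @param shrinkage `"moderated"` or `"ordinary"` signature test.
#' @param anova_response `"per_phase"` or `"change"`.
#' @param require_atrophy atrophy condition in the severity rule.
#' @param outcomes character vector of outcome names to model (default: all
#'   present in the clinical file).
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(muscle_tsv, metadata_tsv, serum_tsv = NULL,
                       clinical_tsv = NULL, ultrasound_tsv = NULL,
                       external_signature_tsv = NULL,
                       exclusion_list = "epinephrine",
                       min_common = 10L, fdr_level = 0.05, ci_level = 0.95,
                       severity_cutoff = 10L, directional_responder = TRUE,
                       shrinkage = "moderated",
                       anova_response = "per_phase", require_atrophy = TRUE,
                       outcomes = NULL, out_dir = "sigshift_out") {
  if (!is_prob(fdr_level) || fdr_level <= 0 || fdr_level >= 1)
    stop_named("fdr_level must lie in (0, 1)")
  if (!is_prob(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop_named("ci_level must lie in (0, 1)")
  if (!is_count(severity_cutoff) || severity_cutoff < 1)
    stop_named("severity_cutoff must be a positive integer")
  structure(list(muscle_tsv = muscle_tsv, serum_tsv = serum_tsv,
                 metadata_tsv = metadata_tsv, clinical_tsv = clinical_tsv,
                 ultrasound_tsv = ultrasound_tsv,
                 external_signature_tsv = external_signature_tsv,
                 exclusion_list = exclusion_list, min_common = min_common,
                 fdr_level = fdr_level, ci_level = ci_level,
                 severity_cutoff = severity_cutoff,
                 directional_responder = directional_responder,
                 shrinkage = shrinkage, anova_response = anova_response,
                 require_atrophy = require_atrophy, outcomes = outcomes,
                 out_dir = out_dir), class = "run_config")
}

#' Run the full signature-shift pipeline on file inputs
#'
#' Executes preprocess -> signature -> projection -> severity -> outcomes,
#' writing every stage's tables under `config$out_dir` and a JSON run report
#' (`report.json`) with a config echo, per-stage audits, warnings, and an
#' MD5-checksummed file manifest. The pipeline is deterministic given its
#' inputs: no stage draws random numbers.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  note_warning <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  audits <- list()
  outputs <- character()
  emit <- function(name) outputs <<- c(outputs, file.path(config$out_dir, name))

  withCallingHandlers({
    meta <- read_sample_metadata(config$metadata_tsv)

    # ---- preprocess ----
    muscle_raw <- read_intensity_tsv(config$muscle_tsv, meta)
    check_subjects(muscle_raw, meta)
    muscle_raw <- exclude_metabolites(muscle_raw, config$exclusion_list)
    muscle <- normalize_intensities(muscle_raw)
    write_normalized_tsv(muscle, file.path(config$out_dir, "muscle_normalized.tsv"))
    emit("muscle_normalized.tsv")
    audits$preprocess_muscle <- muscle$audit
    serum <- NULL
    if (!is.null(config$serum_tsv)) {
      serum_raw <- read_intensity_tsv(config$serum_tsv, meta)
      serum_raw <- exclude_metabolites(serum_raw, config$exclusion_list)
      serum <- normalize_intensities(serum_raw)
      write_normalized_tsv(serum, file.path(config$out_dir, "serum_normalized.tsv"))
      emit("serum_normalized.tsv")
      audits$preprocess_serum <- serum$audit
    }

    # ---- signature ----
    sig <- estimate_signature(muscle, meta, shrinkage = config$shrinkage)
    write_signature_tsv(sig, file.path(config$out_dir, "muscle_signature.tsv"))
    emit("muscle_signature.tsv")
    audits$signature_muscle <- attr(sig, "audit")
    pc1 <- pc1_separation(muscle, meta)
    audits$pc1_muscle <- sprintf("F = %.4g on df (%d, %d), p = %.4g",
                                 pc1$F, pc1$df[1], pc1$df[2], pc1$p)
    sig_serum <- NULL
    if (!is.null(serum)) {
      sig_serum <- estimate_signature(serum, meta, shrinkage = config$shrinkage)
      write_signature_tsv(sig_serum,
                          file.path(config$out_dir, "serum_signature.tsv"))
      emit("serum_signature.tsv")
      cross <- correlate_signatures(
        signature_vector(sig), signature_vector(sig_serum),
        p_a = setNames(sig$p, sig$metabolite),
        p_b = setNames(sig_serum$p, sig_serum$metabolite))
      write_tsv(cross$table, file.path(config$out_dir, "muscle_serum_fc.tsv"))
      emit("muscle_serum_fc.tsv")
      audits$cross_tissue <- sprintf(
        "muscle vs serum signature over %d shared metabolites: rho = %.3f, p = %.3g",
        cross$n, cross$rho, cross$p)
    }

    # ---- projection ----
    deltas <- patient_deltas(muscle, meta)
    audits$deltas <- deltas$audit
    rho_tab <- rho_score_table(deltas, sig, min_common = config$min_common,
                               level = config$ci_level)
    write_tsv(rho_tab, file.path(config$out_dir, "rho_scores.tsv"))
    emit("rho_scores.tsv")
    calls <- responder_table(rho_tab,
                             directional = config$directional_responder)
    write_tsv(calls, file.path(config$out_dir, "responder_calls.tsv"))
    emit("responder_calls.tsv")
    if (!is.null(config$external_signature_tsv)) {
      ext <- read_signature_tsv(config$external_signature_tsv)
      ext_tab <- rho_score_table(deltas, ext, min_common = config$min_common,
                                 level = config$ci_level)
      write_tsv(ext_tab, file.path(config$out_dir, "rho_scores_external.tsv"))
      emit("rho_scores_external.tsv")
    }

    # ---- severity ----
    severity_out <- NULL
    if (!is.null(config$ultrasound_tsv)) {
      us <- read.delim(config$ultrasound_tsv, stringsAsFactors = FALSE)
      sev <- severity_classes(us, cutoff = config$severity_cutoff,
                              require_atrophy = config$require_atrophy)
      write_tsv(sev, file.path(config$out_dir, "severity_classes.tsv"))
      emit("severity_classes.tsv")
      an <- severity_anova(rho_tab, sev, response = config$anova_response)
      loo <- leave_one_out(rho_tab, sev, response = config$anova_response)
      write_tsv(loo$table, file.path(config$out_dir, "leave_one_out.tsv"))
      emit("leave_one_out.tsv")
      severity_out <- list(interaction_F = an$interaction_F,
                           interaction_p = an$interaction_p,
                           leave_one_out_full_p = loo$full_p)
      audits$severity <- c(
        sprintf("phase x severity interaction: F = %.4g, p = %.4g",
                an$interaction_F, an$interaction_p), loo$audit)
    }

    # ---- outcomes ----
    outcome_models <- list()
    if (!is.null(config$clinical_tsv)) {
      clin <- read_clinical_tsv(config$clinical_tsv)
      outs <- config$outcomes %||% unique(clin$outcome_name)
      for (nm in outs) {
        tm <- fit_treatment_model(clin, nm)
        rm_ <- fit_rho_model(clin, nm, rho_tab)
        outcome_models[[nm]] <- list(
          treatment = model_summary(tm), rho = model_summary(rm_))
        audits[[paste0("outcome_", nm)]] <- c(tm$audit, rm_$audit)
      }
      jsonlite::write_json(outcome_models,
                           file.path(config$out_dir, "outcome_models.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit("outcome_models.json")
    }
  }, warning = note_warning)

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("sigshift")),
                 config = config[!vapply(config, is.null, logical(1))],
                 audits = audits, warnings = unique(warnings_seen),
                 severity = severity_out, manifest = manifest)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

check_subjects <- function(m, meta) {
  missing <- setdiff(colnames(m$intensities), meta$sample_id)
  if (length(missing))
    stop_named("metadata missing for sample(s): %s",
               paste(missing, collapse = ", "))
  invisible(TRUE)
}

model_summary <- function(m) {
  list(outcome = m$outcome_name, model_type = m$model_type,
       random_structure = m$random_structure, converged = m$converged,
       n_obs = m$n_obs, n_subjects = m$n_subjects,
       time_coding = m$time_coding,
       fixed_effects = m$fixed_effects)
}

write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], signif, digits = 6)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic trial to pipeline input files
#'
#' Writes the same TSV formats [run_pipeline()] reads — intensity tables per
#' tissue, sample metadata, clinical outcomes, ultrasound grades — plus the
#' planted ground truth as JSON.
#'
#' @param trial a [generate_trial()] result (or a [synthetic_config()],
#'   which is generated first).
#' @param out_dir output directory, created if needed.
#' @return named character vector of the files written (a manifest).
#' @export
simulate_trial <- function(trial, out_dir) {
  if (inherits(trial, "synthetic_config")) trial <- generate_trial(trial)
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    muscle_tsv = file.path(out_dir, "muscle_intensities.tsv"),
    serum_tsv = file.path(out_dir, "serum_intensities.tsv"),
    metadata_tsv = file.path(out_dir, "sample_metadata.tsv"),
    clinical_tsv = file.path(out_dir, "clinical.tsv"),
    ultrasound_tsv = file.path(out_dir, "ultrasound.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.json"))
  write_intensity_tsv(trial$muscle, paths[["muscle_tsv"]])
  write_intensity_tsv(trial$serum, paths[["serum_tsv"]])
  write_tsv(trial$annotation, paths[["metadata_tsv"]])
  write_tsv(trial$clinical, paths[["clinical_tsv"]])
  write_tsv(trial$ultrasound, paths[["ultrasound_tsv"]])
  truth <- trial$truth
  jsonlite::write_json(
    list(true_signature = as.list(truth$true_signature),
         true_signature_serum = as.list(truth$true_signature_serum),
         dysregulated = truth$dysregulated,
         responder_flags = as.list(truth$responder_flags),
         severity_class = as.list(truth$severity_class),
         phase_rho_targets = truth$phase_rho_targets,
         outcome_coefs = truth$outcome_coefs,
         seed = trial$config$seed),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}

write_intensity_tsv <- function(m, path) {
  stopifnot(inherits(m, "metabolite_matrix"))
  tab <- data.frame(metabolite = rownames(m$intensities),
                    signif(m$intensities, 8), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
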