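#' Construct a raw metabolite intensity matrix
#'
#' Container for untargeted metabolomics intensities prior to normalization.
#' Rows are metabolites, columns are samples. Each sample carries the protein
#' concentration of its source material (BCA assay, mg/mL) used for the first
#' normalization step.
#'
#' @param intensities numeric matrix, metabolites x samples, with rownames
#'   (metabolite identifiers) and colnames (sample identifiers). Nonnegative;
#'   zeros are allowed and treated as missing during normalization.
#' @param protein_conc numeric vector of per-sample protein concentrations
#'   (mg/mL), named by sample or in column order. All values must be > 0.
#' @param tissue `"muscle"` or `"serum"`.
#' @return An object of class `metabolite_matrix`: a list with elements
#'   `intensities`, `protein_conc`, `tissue` and an `audit` character vector
#'   recording provenance.
#' @export
metabolite_matrix <- function(intensities, protein_conc, tissue = c("muscle", "serum")) {
  tissue <- match.arg(tissue)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_named("intensities must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop_named("intensities must have metabolite rownames and sample colnames")
  if (anyDuplicated(rownames(intensities)))
    stop_named("duplicate metabolite identifiers")
  if (anyDuplicated(colnames(intensities)))
    stop_named("duplicate sample identifiers")
  if (any(intensities < 0, na.rm = TRUE))
    stop_named("negative intensities are not allowed")
  if (!is.null(names(protein_conc))) {
    missing_pc <- setdiff(colnames(intensities), names(protein_conc))
    if (length(missing_pc))
      stop_named("protein_conc missing for sample(s): %s",
                 paste(missing_pc, collapse = ", "))
    protein_conc <- protein_conc[colnames(intensities)]
  } else if (length(protein_conc) != ncol(intensities)) {
    stop_named("protein_conc length does not match number of samples")
  } else {
    names(protein_conc) <- colnames(intensities)
  }
  if (any(!is.finite(protein_conc)) || any(protein_conc <= 0))
    stop_named("protein_conc must be positive for every sample")
  structure(
    list(intensities = intensities, protein_conc = protein_conc,
         tissue = tissue,
         audit = sprintf("created %s matrix: %d metabolites x %d samples",
                         tissue, nrow(intensities), ncol(intensities))),
    class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix (%s): %d metabolites x %d samples\n",
              x$tissue, nrow(x$intensities), ncol(x$intensities)))
  invisible(x)
}

#' Remove metabolites from a matrix by identifier
#'
#' Drops listed metabolites (e.g. epinephrine introduced by the biopsy
#' anaesthetic, whose abundance is non-physiological) before normalization.
#' Exclusion is idempotent: identifiers absent from the matrix raise a
#' warning, not an error.
#'
#' @param m a [metabolite_matrix()].
#' @param exclusion_list character vector of metabolite identifiers.
#' @return The matrix without the listed metabolites; the audit trail records
#'   the removal and count.
#' @export
exclude_metabolites <- function(m, exclusion_list) {
  stopifnot(inherits(m, "metabolite_matrix"))
  exclusion_list <- as.character(exclusion_list)
  if (!length(exclusion_list)) return(m)
  present <- intersect(exclusion_list, rownames(m$intensities))
  absent <- setdiff(exclusion_list, present)
  if (length(absent))
    warn_named("exclusion list entries not present: %s",
               paste(absent, collapse = ", "))
  if (length(present)) {
    keep <- setdiff(rownames(m$intensities), present)
    m$intensities <- m$intensities[keep, , drop = FALSE]
  }
  m$audit <- c(m$audit,
               sprintf("excluded %d metabolite(s): %s", length(present),
                       paste(present, collapse = ", ")))
  m
}

#' Normalize raw intensities to centered log2 values
#'
#' Applies the three normalization steps in fixed order:
#' \enumerate{
#'   \item divide each sample's intensities by its protein concentration;
#'   \item log2-transform, with zero (and any nonpositive) intensities set to
#'     missing first — no pseudocount is added;
#'   \item center each sample at its median log2 value (per-sample median of
#'     the returned values is 0).
#' }
#' Per-sample multiplicative scale (protein loading, injection amount) is a
#' constant shift on the log2 scale and is absorbed exactly by the median
#' centering, so downstream fold changes and rank correlations are invariant
#' to it.
#'
#' @param m a [metabolite_matrix()].
#' @return An object of class `normalized_matrix`: list with `log2_values`
#'   (metabolites x samples, NA where intensity was missing/zero), `tissue`
#'   and `audit` (ordered record of the applied steps).
#' @export
normalize_intensities <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  v <- sweep(m$intensities, 2, m$protein_conc, "/")
  v[!is.finite(v) | v <= 0] <- NA_real_
  l <- log2(v)
  n_missing <- sum(is.na(l))
  meds <- apply(l, 2, median, na.rm = TRUE)
  bad <- colnames(l)[!is.finite(meds)]
  if (length(bad))
    stop_named("sample(s) with no usable intensities (median undefined): %s",
               paste(bad, collapse = ", "))
  centered <- sweep(l, 2, meds, "-")
  structure(
    list(log2_values = centered, tissue = m$tissue,
         audit = c(m$audit,
                   "divided intensities by per-sample protein concentration",
                   sprintf("log2 transform (%d nonpositive cells set missing)",
                           n_missing),
                   "centered each sample at its median log2 value")),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d metabolites x %d samples\n",
              x$tissue, nrow(x$log2_values), ncol(x$log2_values)))
  invisible(x)
}

#' Shared metabolite identifiers of two normalized matrices
#'
#' Cross-tissue comparisons (e.g. muscle vs serum fold-change correlation)
#' are computed over exactly this set.
#'
#' @param a,b `normalized_matrix` objects (or anything with rownames on
#'   `log2_values`, or plain character vectors of identifiers).
#' @return Sorted character vector of common identifiers.
#' @export
intersect_features <- function(a, b) {
  ids <- function(x) {
    if (inherits(x, "normalized_matrix")) rownames(x$log2_values)
    else if (inherits(x, "metabolite_matrix")) rownames(x$intensities)
    else as.character(x)
  }
  common <- sort(intersect(ids(a), ids(b)))
  if (!length(common))
    stop_named("no shared metabolite identifiers between the two matrices")
  common
}

# ---- file interfaces --------------------------------------------------------

#' Read an intensity TSV (first column metabolite id, one column per sample)
#'
#' @param path path to a tab-separated file.
#' @param metadata sample metadata data frame as returned by
#'   [read_sample_metadata()]; supplies `protein_conc` and `tissue` for the
#'   samples in the file.
#' @return A [metabolite_matrix()].
#' @export
read_intensity_tsv <- function(path, metadata) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  missing_meta <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing_meta))
    stop_named("%s: sample(s) absent from metadata: %s", path,
               paste(missing_meta, collapse = ", "))
  meta <- metadata[match(colnames(mat), metadata$sample_id), ]
  tissue <- unique(meta$tissue)
  if (length(tissue) != 1L)
    stop_named("%s: samples span multiple tissues (%s)", path,
               paste(tissue, collapse = ", "))
  metabolite_matrix(mat, setNames(meta$protein_conc, meta$sample_id), tissue)
}

#' Read the sample metadata TSV
#'
#' Expected columns: sample_id, subject_id, group (case/control), tissue
#' (muscle/serum), visit_week (0/16/32/48, empty for controls), protein_conc,
#' quality_flag (ok/excluded).
#'
#' @param path path to a tab-separated file with header.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group", "tissue", "visit_week",
            "protein_conc", "quality_flag")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop_named("%s: missing metadata column(s): %s", path,
               paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop_named("%s: duplicate sample_id", path)
  bad_group <- setdiff(unique(meta$group), c("case", "control"))
  if (length(bad_group))
    stop_named("%s: unknown group value(s): %s", path,
               paste(bad_group, collapse = ", "))
  meta$visit_week <- suppressWarnings(as.numeric(meta$visit_week))
  meta
}

#' Write a normalized matrix as TSV plus a JSON audit
#'
#' @param x a `normalized_matrix`.
#' @param path output TSV path; the audit is written next to it as
#'   `<path>.audit.json`.
#' @return invisibly, the paths written.
#' @export
write_normalized_tsv <- function(x, path) {
  stopifnot(inherits(x, "normalized_matrix"))
  tab <- data.frame(metabolite = rownames(x$log2_values),
                    signif(x$log2_values, 6), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  audit_path <- paste0(path, ".audit.json")
  jsonlite::write_json(list(tissue = x$tissue, steps = x$audit), audit_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, audit_path))
}
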