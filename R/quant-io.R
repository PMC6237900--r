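#' Read and write the long-format quant table
#'
#' The quant CSV dialect has one row per measured transition per run:
#' `sample_id, batch_id, is_qc, replicate_index, protein_id, peptide_id,
#' transition_id, raw_peak_area, panel`.
#'
#' @param path file path.
#' @return `read_quant()` returns the validated quant data.frame.
#' @export
read_quant <- function(path) {
  q <- utils::read.csv(path, stringsAsFactors = FALSE)
  q$is_qc <- as.logical(q$is_qc)
  validate_quant(q)
}

#' @rdname read_quant
#' @param quant a quant table.
#' @export
write_quant <- function(quant, path) {
  validate_quant(quant)
  utils::write.csv(quant, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_quant
#' @export
validate_quant <- function(quant) {
  need <- c("sample_id", "batch_id", "is_qc", "replicate_index",
            "protein_id", "peptide_id", "transition_id", "raw_peak_area",
            "panel")
  miss <- setdiff(need, names(quant))
  if (length(miss)) {
    stop("quant table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(quant$raw_peak_area < 0, na.rm = TRUE)) {
    stop("raw_peak_area must be nonnegative", call. = FALSE)
  }
  key <- paste(quant$sample_id, quant$peptide_id, quant$transition_id,
               quant$replicate_index)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, peptide, transition, replicate) records",
         call. = FALSE)
  }
  quant
}

#' Read and write the clinical table
#'
#' Tab-separated with columns `patient_id, stage, arm, dfs_months, event`;
#' `stage` is coerced to the ordered factor `1b < 2 < 3 < 4`.
#'
#' @param path file path.
#' @return `read_clinical()` returns the clinical data.frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "stage", "arm", "dfs_months", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss)) {
    stop("clinical table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cl$stage <- factor(as.character(cl$stage),
                     levels = c("1b", "2", "3", "4"), ordered = TRUE)
  if (anyNA(cl$stage)) stop("stage must be one of 1b, 2, 3, 4", call. = FALSE)
  cl
}

#' @rdname read_clinical
#' @param clinical a clinical table.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes the quant table as CSV, the clinical table as TSV, and the ground
#' truth (protein effects, per-run NSF, per-peptide beta) as a plain-text
#' key-value sidecar.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    quant = file.path(dir, "quant.csv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.yml")
  )
  write_quant(cohort$quant, paths["quant"])
  write_clinical(cohort$clinical, paths["clinical"])
  tr <- cohort$truth
  kv <- c(
    "# ground truth of synthetic cohort",
    paste0("seed: ", cohort$config$seed),
    paste0("spike_protein: ", tr$spike_protein),
    paste0("np_candidates: ", paste(tr$np_candidates, collapse = ",")),
    paste0("np_unstable: ", paste(tr$np_unstable, collapse = ",")),
    paste0("true_proteins: ", paste(tr$true_proteins, collapse = ",")),
    "effects:",
    sprintf("  %s: %.10g", names(tr$effects)[tr$effects != 0],
            tr$effects[tr$effects != 0]),
    "beta:",
    sprintf("  %s: %.10g", names(tr$beta), tr$beta),
    "nsf:",
    sprintf("  %s_r%d: %.10g", tr$nsf$sample_id, tr$nsf$replicate_index,
            tr$nsf$nsf)
  )
  writeLines(kv, paths["truth"])
  invisible(paths)
}
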