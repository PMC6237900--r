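#' Replicate-based coefficient of variation per peptide
#'
#' For every (peptide, sample) with triplicate runs, computes the CV of the
#' raw peak areas across replicates (sample sd over mean, n - 1
#' denominator), and summarises per peptide how many samples violate the CV
#' threshold. Peptides measured in no triplicated sample are flagged as not
#' assessable rather than excluded.
#'
#' @param quant a quant table (see [read_quant()]).
#' @param cv_threshold per-sample CV above which a sample counts as a
#'   violation; default 0.25.
#' @return a list with `per_sample` (peptide_id, sample_id, cv, n_reps) and
#'   `report` (peptide_id, n_samples, n_violations, median_cv, assessable).
#' @export
compute_replicate_cv <- function(quant, cv_threshold = 0.25) {
  validate_quant(quant)
  rep_q <- quant[!quant$is_qc & quant$replicate_index > 0L, , drop = FALSE]
  peptides <- unique(quant$peptide_id)
  if (nrow(rep_q)) {
    key <- interaction(rep_q$peptide_id, rep_q$sample_id, drop = TRUE)
    cv_tab <- do.call(rbind, lapply(split(rep_q, key), function(d) {
      data.frame(peptide_id = d$peptide_id[1], sample_id = d$sample_id[1],
                 n_reps = nrow(d),
                 cv = if (nrow(d) >= 2L) sd(d$raw_peak_area) /
                   mean(d$raw_peak_area) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(cv_tab) <- NULL
  } else {
    cv_tab <- data.frame(peptide_id = character(), sample_id = character(),
                         n_reps = integer(), cv = numeric())
  }
  report <- do.call(rbind, lapply(peptides, function(p) {
    d <- cv_tab[cv_tab$peptide_id == p & !is.na(cv_tab$cv), , drop = FALSE]
    data.frame(peptide_id = p, n_samples = nrow(d),
               n_violations = sum(d$cv > cv_threshold),
               median_cv = if (nrow(d)) median(d$cv) else NA_real_,
               assessable = nrow(d) > 0L, stringsAsFactors = FALSE)
  }))
  list(per_sample = cv_tab, report = report, cv_threshold = cv_threshold)
}

#' Exclude irreproducible peptides
#'
#' A peptide is excluded when its replicate CV exceeds the threshold in
#' strictly more than `max_violations` samples. Peptides with no
#' triplicated measurement are retained (not assessable).
#'
#' @param qc result of [compute_replicate_cv()].
#' @param max_violations violation count above which a peptide is excluded;
#'   default 5.
#' @return the QC report with an `excluded` flag added.
#' @export
filter_peptides <- function(qc, max_violations = 5L) {
  report <- qc$report
  report$excluded <- report$assessable & report$n_violations > max_violations
  report
}

#' Choose one representative peptide per protein
#'
#' Ordering criteria, applied lexicographically: (1) smallest interference
#' score if supplied, (2) lowest median replicate CV over the triplicated
#' samples, (3) highest median peak area; remaining ties go to the
#' alphabetically smallest peptide id for determinism.
#'
#' @param quant a quant table.
#' @param qc_report report from [filter_peptides()]; excluded peptides are
#'   ineligible.
#' @param interference optional named numeric vector (peptide_id ->
#'   interference score, lower is better).
#' @return a list with `representative` (data.frame protein_id, peptide_id)
#'   and `dropped_proteins` (proteins whose peptides were all excluded).
#' @export
select_representative_peptide <- function(quant, qc_report = NULL,
                                          interference = NULL) {
  validate_quant(quant)
  excluded <- if (!is.null(qc_report)) {
    qc_report$peptide_id[qc_report$excluded]
  } else character()
  med_cv <- if (!is.null(qc_report)) {
    stats::setNames(qc_report$median_cv, qc_report$peptide_id)
  } else NULL
  pep_info <- unique(quant[, c("protein_id", "peptide_id")])
  med_area <- tapply(quant$raw_peak_area, quant$peptide_id, median)
  rows <- lapply(split(pep_info, pep_info$protein_id), function(d) {
    ok <- !(d$peptide_id %in% excluded)
    if (!any(ok)) return(NULL)
    d <- d[ok, , drop = FALSE]
    intf <- if (is.null(interference)) rep(0, nrow(d)) else {
      v <- interference[d$peptide_id]
      v[is.na(v)] <- 0
      v
    }
    cv <- if (is.null(med_cv)) rep(0, nrow(d)) else {
      v <- med_cv[d$peptide_id]
      v[is.na(v)] <- Inf   # no triplicate data ranks after measured CVs
      v
    }
    area <- as.numeric(med_area[d$peptide_id])
    pick <- order(intf, cv, -area, d$peptide_id)[1]
    d[pick, , drop = FALSE]
  })
  keep <- !vapply(rows, is.null, logical(1))
  representative <- do.call(rbind, rows[keep])
  rownames(representative) <- NULL
  list(representative = representative,
       dropped_proteins = names(rows)[!keep])
}
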