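# Iterated cross-validated Cox feature selection with the binomial
# selection-probability Z stopping rule.

#' Null probability of a feature being selected in >= 4 of 8 folds
#'
#' If a rank-s feature were drawn at random from n features in each of 8
#' folds, the chance it appears at least four times is
#' `p_s = sum_{i=4..8} C(8, i) (s/n)^i ((n-s)/n)^(8-i)`.
#'
#' @param s feature rank (1..n); vectorised.
#' @param n panel size (number of candidate features).
#' @return the probability `p_s`.
#' @export
binomial_selection_prob <- function(s, n) {
  stopifnot(n >= 1)
  if (any(s < 1 | s > n)) stop("rank s must satisfy 1 <= s <= n",
                               call. = FALSE)
  q <- s / n
  vapply(q, function(qi) {
    i <- 4:8
    sum(choose(8, i) * qi^i * (1 - qi)^(8 - i))
  }, numeric(1))
}

#' Normal-approximation Z statistic of the observation count
#'
#' Compares the observed number of iterations in which a feature reached
#' the fold-hit criterion against its binomial null:
#' `Z = (N.O. - R p_s) / sqrt(R p_s (1 - p_s))` with R iterations. The
#' selection rule keeps features with `Z >= 1.96` (97.5% confidence).
#'
#' @param observed observation count N.O. (0..n_iterations).
#' @param p_s null probability from [binomial_selection_prob()].
#' @param n_iterations number of repeated cross-validations, default 500.
#' @return the Z statistic.
#' @export
z_statistic <- function(observed, p_s, n_iterations = 500) {
  if (any(p_s <= 0 | p_s >= 1)) {
    stop("p_s must lie strictly between 0 and 1", call. = FALSE)
  }
  (observed - n_iterations * p_s) /
    sqrt(n_iterations * p_s * (1 - p_s))
}

#' Configuration for cross-validated stability selection
#'
#' @param n_folds folds per cross-validation, default 8.
#' @param n_iterations repeated cross-validations, default 500.
#' @param alpha backward-elimination Wald p cutoff, default 0.05.
#' @param min_fold_hits folds a feature must be retained in for the
#'   iteration to count as an observation, default 4.
#' @param z_threshold Z cutoff of the stopping rule, default 1.96.
#' @param force_stage whether clinical stage is a forced covariate in every
#'   fold fit (prognosis modules), default TRUE.
#' @param seed root seed; each iteration reseeds deterministically from it.
#' @return a validated `selection_config` list.
#' @export
selection_config <- function(n_folds = 8L, n_iterations = 500L,
                             alpha = 0.05, min_fold_hits = 4L,
                             z_threshold = 1.96, force_stage = TRUE,
                             seed = 1L) {
  cfg <- list(n_folds = as.integer(n_folds),
              n_iterations = as.integer(n_iterations), alpha = alpha,
              min_fold_hits = as.integer(min_fold_hits),
              z_threshold = z_threshold, force_stage = isTRUE(force_stage),
              seed = as.integer(seed))
  stopifnot(cfg$min_fold_hits <= cfg$n_folds, cfg$z_threshold > 0,
            cfg$n_folds >= 2L, cfg$n_iterations >= 1L)
  class(cfg) <- "selection_config"
  cfg
}

# Random fold assignment stratified by the event indicator
stratified_folds <- function(event, n_folds) {
  fold <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated Cox stability selection
#'
#' Repeats `n_iterations` times: draw a random `n_folds`-fold partition
#' (stratified by the event indicator); on each training split (all folds
#' but one) run Cox backward elimination over the protein covariates, with
#' stage forced when configured; a protein scores a fold-hit when it is
#' retained in that fold's converged model. An iteration counts as an
#' observation for a protein when its fold-hits reach `min_fold_hits`.
#' Proteins are then ranked by descending observation count (N.O.,
#' alphabetical tie-break) and the selected set is the longest prefix whose
#' every rank satisfies `Z >= z_threshold` against the binomial null.
#'
#' @param time,event derived survival endpoint (months, indicator).
#' @param x protein covariate matrix (columns = proteins); a column named
#'   `stage` is treated as the forced stage covariate when
#'   `config$force_stage` and never enters the protein ranking.
#' @param config a [selection_config()].
#' @return object of class `selection_result`: `ranking` (data.frame
#'   protein, n_obs, rank, p_s, z, selected), `selected` (protein ids),
#'   `n_panel`, `n_failed_fits`, `config`.
#' @export
run_selection <- function(time, event, x, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  x <- as.matrix(x)
  forced <- intersect("stage", colnames(x))
  if (!config$force_stage) forced <- character()
  proteins <- sort(setdiff(colnames(x), "stage"))
  xx <- x[, c(forced, proteins), drop = FALSE]
  n_obs <- stats::setNames(integer(length(proteins)), proteins)
  n_failed <- 0L
  for (it in seq_len(config$n_iterations)) {
    hits <- with_seed(config$seed + it, {
      fold <- stratified_folds(event, config$n_folds)
      h <- stats::setNames(integer(length(proteins)), proteins)
      for (f in seq_len(config$n_folds)) {
        train <- fold != f
        be <- tryCatch(
          backward_eliminate(time[train], event[train],
                             xx[train, , drop = FALSE],
                             forced = forced, alpha = config$alpha),
          error = function(e) NULL)
        if (is.null(be) || !be$converged) {
          n_failed <- n_failed + 1L
          next   # non-convergent fold: nothing selected here
        }
        h[be$retained] <- h[be$retained] + 1L
      }
      h
    })
    n_obs <- n_obs + as.integer(hits >= config$min_fold_hits)
  }
  ord <- order(-n_obs, proteins)
  n_panel <- length(proteins)
  ranking <- data.frame(
    protein = proteins[ord],
    n_obs = as.integer(n_obs[ord]),
    rank = seq_len(n_panel),
    stringsAsFactors = FALSE
  )
  ranking$p_s <- binomial_selection_prob(ranking$rank, n_panel)
  ranking$z <- ifelse(
    ranking$p_s > 0 & ranking$p_s < 1,
    z_statistic(ranking$n_obs, pmin(pmax(ranking$p_s, 1e-300), 1 - 1e-16),
                config$n_iterations),
    NA_real_)
  pass <- !is.na(ranking$z) & ranking$z >= config$z_threshold
  n_sel <- if (all(pass)) n_panel else which(!pass)[1] - 1L
  ranking$selected <- ranking$rank <= n_sel
  structure(list(ranking = ranking,
                 selected = ranking$protein[ranking$selected],
                 n_panel = n_panel, n_failed_fits = n_failed,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Stability selection over", x$n_panel, "proteins,",
      x$config$n_iterations, "iterations of",
      x$config$n_folds, "-fold CV\n")
  cat("Selected", length(x$selected), "protein(s):",
      paste(x$selected, collapse = ", "), "\n")
  if (x$n_failed_fits > 0)
    cat(x$n_failed_fits, "fold fit(s) failed to converge\n")
  invisible(x)
}
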