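# Mann-Whitney / midrank AUC: fraction of correctly ordered
# (positive, negative) pairs, ties counted 0.5.
auc_midrank <- function(scores, is_pos) {
  npos <- sum(is_pos)
  nneg <- sum(!is_pos)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Deterministic ranking of a protein's candidates: decreasing score,
# lexicographic term id on ties.
candidate_order <- function(scores) {
  names(scores)[order(-scores, names(scores), method = "radix")]
}

#' Evaluate a prediction against masked ground truth
#'
#' Computes the six multi-label accuracy metrics over candidate terms only
#' (terms still annotated to a protein after masking are not candidates
#' for it):
#' \describe{
#'   \item{AvgROC}{mean per-term midrank AUC over terms with at least one
#'     positive and one negative candidate protein, as a percentage.}
#'   \item{1-RankLoss}{per protein, the fraction of correctly ordered
#'     (masked, non-masked) candidate pairs (ties 0.5), averaged over
#'     proteins with both kinds, as a percentage.}
#'   \item{Coverage}{per protein, the depth in its candidate ranking needed
#'     to retrieve every masked term, minus 1, averaged over masked
#'     proteins; unnormalized, lower is better.}
#'   \item{Fmax}{protein-centric maximum F-measure over score thresholds:
#'     precision averaged over proteins making at least one call, recall
#'     averaged over all masked proteins.}
#'   \item{MacroF1}{per-term F1 after calling each protein's top-r
#'     candidates positive (r = that protein's masked count), averaged
#'     over terms with at least one positive, as a percentage.}
#'   \item{RAccuracy}{fraction of masked pairs recovered by the same top-r
#'     calls, as a percentage.}
#' }
#'
#' @param scores a `score_matrix` computed on the masked table.
#' @param masked a `masked_dataset` from [mask_annotations()] (or any list
#'   with a `truth_pairs` data.frame of `protein`/`term` columns).
#' @param strata optional named term-to-stratum vector
#'   ([sparsity_strata()]); when given, mean per-term AUC per stratum is
#'   reported.
#' @param fmax_thresholds maximum number of score thresholds swept for
#'   Fmax; the unique candidate scores are used when fewer.
#' @return a `metric_report` list: `macro_f1`, `avg_roc`,
#'   `one_minus_rankloss`, `r_accuracy`, `fmax`, `coverage`,
#'   `per_term_auc` (named, `NA` where undefined), `strata_auc`,
#'   `n_terms_skipped` (terms without positives, excluded from averages).
#' @export
evaluate_predictions <- function(scores, masked, strata = NULL,
                                 fmax_thresholds = 512L) {
  stopifnot(inherits(scores, "score_matrix"))
  truth <- masked$truth_pairs
  stopifnot(is.data.frame(truth), all(c("protein", "term") %in% names(truth)))
  proteins <- rownames(scores)
  terms <- colnames(scores)
  truth <- truth[truth$protein %in% proteins & truth$term %in% terms, ,
                 drop = FALSE]
  pos <- matrix(FALSE, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  pos[cbind(truth$protein, truth$term)] <- TRUE
  cand <- !is.na(scores)
  pos <- pos & cand

  # --- term-centric: per-term AUC ---
  per_term_auc <- vapply(terms, function(v) {
    sel <- cand[, v]
    if (!any(sel)) return(NA_real_)
    auc_midrank(scores[sel, v], pos[sel, v])
  }, 0)
  defined <- !is.na(per_term_auc)
  avg_roc <- 100 * mean(per_term_auc[defined])

  # --- protein-centric rankings ---
  n_pos_i <- rowSums(pos)
  rl <- numeric(); cov <- numeric()
  topcalls <- matrix(FALSE, nrow(scores), ncol(scores),
                     dimnames = dimnames(scores))
  for (i in seq_along(proteins)) {
    sel <- cand[i, ]
    if (!any(sel)) next
    sc <- scores[i, sel]
    pv <- pos[i, sel]
    if (any(pv) && any(!pv)) rl <- c(rl, auc_midrank(sc, pv))
    if (any(pv)) {
      ord <- candidate_order(sc)
      cov <- c(cov, max(match(names(sc)[pv], ord)) - 1)
      topcalls[i, utils::head(ord, sum(pv))] <- TRUE
    }
  }
  one_minus_rankloss <- if (length(rl)) 100 * mean(rl) else NA_real_
  coverage <- if (length(cov)) mean(cov) else NA_real_

  # --- rank-r binarization: MacroF1 and RAccuracy ---
  tp_t <- colSums(topcalls & pos)
  fp_t <- colSums(topcalls & !pos)
  fn_t <- colSums(pos & !topcalls)
  has_pos <- colSums(pos) > 0L
  f1_t <- ifelse(2 * tp_t + fp_t + fn_t > 0,
                 2 * tp_t / (2 * tp_t + fp_t + fn_t), 0)
  macro_f1 <- if (any(has_pos)) 100 * mean(f1_t[has_pos]) else NA_real_
  r_accuracy <- if (sum(pos) > 0L) 100 * sum(tp_t) / sum(pos) else NA_real_

  # --- Fmax over a threshold sweep ---
  fmax <- fmax_sweep(scores, pos, cand, fmax_thresholds)

  structure(list(
    macro_f1 = macro_f1, avg_roc = avg_roc,
    one_minus_rankloss = one_minus_rankloss, r_accuracy = r_accuracy,
    fmax = fmax, coverage = coverage,
    per_term_auc = 100 * per_term_auc,
    strata_auc = if (!is.null(strata)) {
      tapply(100 * per_term_auc[defined], strata[terms[defined]], mean)
    },
    n_terms_skipped = sum(!defined)
  ), class = "metric_report")
}

fmax_sweep <- function(scores, pos, cand, max_thresholds) {
  masked_prots <- which(rowSums(pos) > 0L)
  if (length(masked_prots) == 0L) return(NA_real_)
  all_scores <- scores[cand]
  taus <- sort(unique(all_scores), decreasing = TRUE)
  if (length(taus) > max_thresholds) {
    taus <- unique(stats::quantile(all_scores,
                                   probs = seq(0, 1, length.out = max_thresholds),
                                   names = FALSE, type = 1L))
    taus <- sort(taus, decreasing = TRUE)
  }
  # per protein: sorted candidate scores (all and positive-only), so
  # counts at any threshold come from a binary search
  sc_all <- lapply(seq_len(nrow(scores)), function(i) sort(scores[i, cand[i, ]]))
  sc_pos <- lapply(seq_len(nrow(scores)), function(i) sort(scores[i, pos[i, ]]))
  n_all <- lengths(sc_all)
  best <- 0
  for (tau in taus) {
    npred <- vapply(seq_along(sc_all), function(i) {
      n_all[[i]] - findInterval(tau, sc_all[[i]], left.open = TRUE)
    }, 1L)
    ntp <- vapply(masked_prots, function(i) {
      length(sc_pos[[i]]) - findInterval(tau, sc_pos[[i]], left.open = TRUE)
    }, 1L)
    calling <- npred > 0L
    if (!any(calling)) next
    prec <- mean((ntp_full <- replace(numeric(length(sc_all)), masked_prots, ntp))[calling] /
                   npred[calling])
    rec <- mean(ntp / vapply(masked_prots, function(i) length(sc_pos[[i]]), 1L))
    if (prec + rec > 0) best <- max(best, 2 * prec * rec / (prec + rec))
  }
  100 * best
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_report>\n  MacroF1      %8.2f\n  AvgROC       %8.2f\n",
    "  1-RankLoss   %8.2f\n  RAccuracy    %8.2f\n  Fmax         %8.2f\n",
    "  Coverage     %8.2f\n"),
    x$macro_f1, x$avg_roc, x$one_minus_rankloss, x$r_accuracy, x$fmax,
    x$coverage))
  invisible(x)
}

#' Per-term AUC difference between two reports, by sparsity stratum
#'
#' @param report_a,report_b `metric_report`s computed over the same term
#'   universe (e.g. dRW-kNN vs ITSS).
#' @param strata named term-to-stratum mapping from [sparsity_strata()].
#' @return named list (stratum -> numeric vector of per-term
#'   `AUC(a) - AUC(b)`, in percentage points), for terms where both AUCs
#'   are defined.
#' @export
auc_delta_by_stratum <- function(report_a, report_b, strata) {
  common <- intersect(names(report_a$per_term_auc), names(report_b$per_term_auc))
  delta <- report_a$per_term_auc[common] - report_b$per_term_auc[common]
  ok <- !is.na(delta)
  split(delta[ok], strata[common[ok]])
}

#' Write a metric report as a flat key-value text block
#'
#' @param report a `metric_report`.
#' @param path output file path.
#' @param header optional `# key=value` comment lines.
#' @export
write_metric_report <- function(report, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  for (key in c("macro_f1", "avg_roc", "one_minus_rankloss", "r_accuracy",
                "fmax", "coverage")) {
    writeLines(sprintf("%s\t%.17g", key, report[[key]]), con)
  }
  invisible(path)
}
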