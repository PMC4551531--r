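new_score_matrix <- function(scores, method) {
  structure(scores, class = c("score_matrix", class(scores)), method = method)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> method=%s, %d proteins x %d terms (%d annotated entries)\n",
              attr(x, "method"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

scoring_universe <- function(dag, table, include_root = FALSE) {
  u <- intersect(table$universe, dag$terms)
  if (!include_root) u <- setdiff(u, dag$roots)
  sort(u)
}

#' Predict missing annotations with downward random walks (dRW)
#'
#' For each protein, walks downward from every annotated term and scores
#' each unannotated candidate term by the thresholded sum of arrival
#' probabilities ([drw_likelihood()]). Because the walk runs on the
#' ontology rather than the annotation corpus, terms currently annotated
#' to no protein at all ("second kind" missing functions) can still
#' receive positive scores.
#'
#' @param dag an [ontology_dag].
#' @param table a propagated [annotation_table].
#' @param sim_variant edge-weighting scheme: `"structure"` (Lin similarity
#'   under structure IC, the default), `"corpus"` (Lin under
#'   annotation-frequency IC, the dRW-Corpus variant), or `"equal"`
#'   (uniform over parents, the dRW-E variant).
#' @param eta,iterations walk parameters, see [downward_rwr()].
#' @param include_root keep the sub-ontology root(s) in the candidate set
#'   (needed by rollback experiments); dropped by default.
#' @return a `score_matrix`: N x |T| numeric matrix, `NA` marking already
#'   annotated (protein, term) pairs, non-negative scores elsewhere. Rows
#'   of unannotated proteins are all zero.
#' @export
drw_predict <- function(dag, table,
                        sim_variant = c("structure", "corpus", "equal"),
                        eta = 0.5, iterations = 10L, include_root = FALSE) {
  sim_variant <- match.arg(sim_variant)
  sim <- switch(sim_variant,
    structure = make_term_sim(dag, structure_ic(dag)),
    corpus = make_term_sim(dag, corpus_ic(table)),
    equal = function(t1, t2) 1
  )
  W <- transition_matrix(dag, sim)
  universe <- scoring_universe(dag, table, include_root)
  starts <- sort(unique(intersect(unlist(table$term_sets, use.names = FALSE),
                                  dag$terms)))
  profiles <- stationary_profiles(W, dag, starts, eta, iterations)
  S <- matrix(0, length(table$proteins), length(universe),
              dimnames = list(table$proteins, universe))
  for (i in seq_along(table$proteins)) {
    T_i <- table$term_sets[[i]]
    if (length(T_i) > 0L) {
      row <- drw_likelihood(profiles, intersect(T_i, dag$terms), universe)
      S[i, names(row$scores)] <- row$scores
    }
    S[i, intersect(T_i, universe)] <- NA_real_
  }
  new_score_matrix(S, paste0("drw-", sim_variant))
}

knn_neighbourhood <- function(psim, i, k) {
  # self always included; remaining k-1 slots by decreasing psim, ties to
  # the smaller protein index
  others <- setdiff(seq_len(nrow(psim)), i)
  ord <- others[order(-psim[i, others], others)]
  c(i, utils::head(ord, k - 1L))
}

knn_fuse <- function(L, table, psim, k, method) {
  N <- length(table$proteins)
  if (k < 1L) stop("k must be >= 1")
  if (k > N) stop(sprintf("k = %d exceeds the number of proteins (%d)", k, N))
  terms <- colnames(L)
  # neighbour belief: 1 for a neighbour's own annotations, estimated
  # likelihood elsewhere
  Lfull <- L
  Lfull[is.na(Lfull)] <- 1
  S <- matrix(NA_real_, N, ncol(L), dimnames = dimnames(L))
  for (i in seq_len(N)) {
    nk <- knn_neighbourhood(psim, i, k)
    cand <- !is.na(L[i, ])
    if (!any(cand)) next
    w <- psim[i, nk]
    block <- Lfull[nk, cand, drop = FALSE]
    S[i, cand] <- as.numeric(w %*% block) / k
  }
  new_score_matrix(S, method)
}

#' Predict with dRW-kNN
#'
#' Fuses dRW scores across a protein's k nearest neighbours under
#' annotation-derived semantic similarity: for a candidate v of protein i,
#' score = (1/k) * sum over j in N_k(i) of psim(i, j) * L(j, v), where
#' L(j, v) = 1 when v is annotated to j and the dRW score otherwise.
#' N_k(i) always contains i itself, so k = 1 reproduces dRW exactly
#' (psim(i, i) = 1).
#'
#' @param drw_scores a `score_matrix` from [drw_predict()].
#' @param table the same propagated [annotation_table].
#' @param psim symmetric N x N protein-similarity matrix, see
#'   [protein_similarity_matrix()].
#' @param k neighbourhood size (>= 1, <= N). Default 10.
#' @return a `score_matrix`.
#' @export
drw_knn_predict <- function(drw_scores, table, psim, k = 10L) {
  stopifnot(inherits(drw_scores, "score_matrix"),
            nrow(psim) == length(table$proteins))
  knn_fuse(drw_scores, table, psim, k, sprintf("drw-knn(k=%d)", k))
}

#' ITSS-style kNN baseline
#'
#' The same kNN fusion as [drw_knn_predict()] but with neighbour belief
#' restricted to observed annotations: L(j, v) = 1 if v is annotated to j,
#' else 0. No walk pre-estimation, so a term annotated to no protein can
#' never score above zero (only "first kind" missing functions are
#' recoverable).
#'
#' @inheritParams drw_knn_predict
#' @param dag an [ontology_dag] (defines the candidate universe).
#' @param include_root see [drw_predict()].
#' @return a `score_matrix`.
#' @export
itss_baseline <- function(dag, table, psim, k = 10L, include_root = FALSE) {
  universe <- scoring_universe(dag, table, include_root)
  N <- length(table$proteins)
  B <- matrix(0, N, length(universe), dimnames = list(table$proteins, universe))
  for (i in seq_len(N)) {
    B[i, intersect(table$term_sets[[i]], universe)] <- NA_real_
  }
  knn_fuse(B, table, psim, k, sprintf("itss(k=%d)", k))
}

#' Naive frequency baseline
#'
#' Scores every candidate term by its annotation frequency, freq(v)/N,
#' identically for all proteins: the more proteins carry a function, the
#' more likely any protein is to carry it. Unannotated terms score 0.
#'
#' @param dag an [ontology_dag].
#' @param table a propagated [annotation_table].
#' @param include_root see [drw_predict()].
#' @return a `score_matrix`.
#' @export
naive_predict <- function(dag, table, include_root = FALSE) {
  universe <- scoring_universe(dag, table, include_root)
  N <- length(table$proteins)
  freq <- term_frequency(table)[universe] / max(N, 1L)
  S <- matrix(rep(freq, each = N), N, length(universe),
              dimnames = list(table$proteins, universe))
  for (i in seq_len(N)) {
    S[i, intersect(table$term_sets[[i]], universe)] <- NA_real_
  }
  new_score_matrix(S, "naive")
}

#' Write a score matrix as long-form TSV
#'
#' One row per (protein, term) with the score (17 significant digits) and
#' a flag distinguishing already-annotated pairs from scored candidates.
#'
#' @param scores a `score_matrix`.
#' @param path output file path.
#' @param header optional character vector of `# key=value` comment lines.
#' @export
write_score_tsv <- function(scores, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines("protein\tterm\tscore\tflag", con)
  for (i in seq_len(nrow(scores))) {
    row <- scores[i, ]
    flag <- ifelse(is.na(row), "annotated", "candidate")
    val <- ifelse(is.na(row), "NA", sprintf("%.17g", row))
    writeLines(paste(rownames(scores)[[i]], colnames(scores), val, flag,
                     sep = "\t"), con)
  }
  invisible(path)
}
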