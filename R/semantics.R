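#' Structure-based information content
#'
#' IC(t) = 1 - log(1 + |desc(t)|) / log |T|, where desc(t) is the set of
#' descendants of t and |T| the number of terms in the hierarchy. Leaves
#' get IC = 1, a term whose descendants cover the rest of the hierarchy
#' gets IC = 0. Unlike corpus IC this depends only on the ontology
#' structure, so it is unbiased by incomplete or research-interest-skewed
#' annotation corpora.
#'
#' @param dag an [ontology_dag] with at least 2 terms.
#' @return named numeric vector in `[0, 1]` over `dag$terms`.
#' @export
structure_ic <- function(dag) {
  nT <- length(dag$terms)
  if (nT <= 1L) stop("structure IC undefined for a universe of size <= 1")
  ndesc <- vapply(dag$terms, function(t) length(descendants(dag, t)), 1L)
  ic <- 1 - log1p(ndesc) / log(nT)
  pmax(ic, 0)
}

#' Corpus-based (frequency) information content
#'
#' IC(t) = log(freq(t)/N) / log(1/N), the annotation-frequency analogue of
#' [structure_ic()] normalized to `[0, 1]`: a term annotated to every
#' protein gets 0, a term annotated to exactly one protein gets 1. Terms
#' with zero frequency get IC = 0, which forces their Lin similarity with
#' any other term to 0 — the known failure mode of corpus IC that
#' structure IC avoids.
#'
#' @param table a propagated [annotation_table] with at least one protein.
#' @return named numeric vector in `[0, 1]` over the universe.
#' @export
corpus_ic <- function(table) {
  N <- length(table$proteins)
  if (N == 0L) stop("corpus IC undefined for an empty protein set")
  freq <- term_frequency(table)
  ic <- ifelse(freq == 0L, 0,
               if (N == 1L) 1 else log(freq / N) / log(1 / N))
  ic <- pmin(pmax(ic, 0), 1)
  names(ic) <- names(freq)
  ic
}

self_and_ancestors <- function(dag, t) c(t, ancestors(dag, t))

#' Most informative common ancestor
#'
#' The common ancestor of `t1` and `t2` (each term counts as its own
#' ancestor here) with maximal information content. If one term subsumes
#' the other, the subsumer is returned. Ties break to the
#' lexicographically smallest identifier for determinism.
#'
#' @param dag an [ontology_dag].
#' @param ic named numeric IC vector (see [structure_ic()], [corpus_ic()]).
#' @param t1,t2 term identifiers.
#' @return a term identifier, or `NULL` when the terms share no ancestor
#'   (e.g. different sub-ontologies).
#' @export
mica <- function(dag, ic, t1, t2) {
  check_terms(dag, c(t1, t2))
  common <- intersect(self_and_ancestors(dag, t1), self_and_ancestors(dag, t2))
  if (length(common) == 0L) return(NULL)
  vals <- ic[common]
  vals[is.na(vals)] <- 0
  best <- sort(common[vals == max(vals)])[[1L]]
  best
}

#' Lin similarity between two terms
#'
#' sim(t1, t2) = 2 IC(t*) / (IC(t1) + IC(t2)) with t* the most informative
#' common ancestor. Zero when no common ancestor exists or when both IC
#' values are zero. Identical terms have similarity 1 by convention, even
#' when their IC is exactly 0 (the 0/0 case arises for the sub-ontology
#' root under structure IC); this keeps self-similarity maximal, so a
#' shared term is always its own reciprocal match in
#' [protein_similarity()].
#'
#' @inheritParams mica
#' @return a value in `[0, 1]`.
#' @export
lin_similarity <- function(ic, dag, t1, t2) {
  check_terms(dag, c(t1, t2))
  if (t1 == t2) return(1)
  m <- mica(dag, ic, t1, t2)
  if (is.null(m)) return(0)
  denom <- ic[[t1]] + ic[[t2]]
  if (denom <= 0) return(0)
  2 * ic[[m]] / denom
}

#' Memoised term-pair similarity function
#'
#' Wraps [lin_similarity()] (or any `(t1, t2) -> value` function) with a
#' symmetric cache, for use where many repeated pairs are evaluated
#' (protein similarity, transition matrices).
#'
#' @param dag an [ontology_dag].
#' @param ic named numeric IC vector.
#' @return a function `(t1, t2) -> numeric`.
#' @export
make_term_sim <- function(dag, ic) {
  cache <- new.env(parent = emptyenv())
  function(t1, t2) {
    key <- if (t1 <= t2) paste(t1, t2, sep = "\r") else paste(t2, t1, sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- lin_similarity(ic, dag, t1, t2)
    cache[[key]] <- val
    val
  }
}

#' Semantic similarity between two proteins
#'
#' psim(i, j) = 2 * sum over reciprocal pairs of sim(t1, t2) divided by
#' (|T_i| + |T_j|). A pair (t1 in T_i, t2 in T_j) is reciprocal when t2 is
#' t1's best match in T_j and t1 is t2's best match in T_i (mutual best
#' match; argmax ties break to the lexicographically smallest term, and a
#' term may serve as the mutual best of several partners). Zero when
#' either set is empty. With IC such that sim(t, t) = 1 > sim(t, u) for
#' u != t, psim(i, i) = 1.
#'
#' @param T_i,T_j character vectors of (propagated) annotation terms.
#' @param sim a term-pair similarity function, e.g. from [make_term_sim()].
#' @return a value in `[0, 1]`.
#' @export
protein_similarity <- function(T_i, T_j, sim) {
  T_i <- sort(unique(T_i)); T_j <- sort(unique(T_j))
  if (length(T_i) == 0L || length(T_j) == 0L) return(0)
  S <- matrix(0, length(T_i), length(T_j), dimnames = list(T_i, T_j))
  for (a in seq_along(T_i)) {
    for (b in seq_along(T_j)) S[a, b] <- sim(T_i[[a]], T_j[[b]])
  }
  # rows/cols are sorted, so which.max's first-hit rule is the lexicographic
  # tie-break
  best_j <- apply(S, 1L, which.max)
  best_i <- apply(S, 2L, which.max)
  total <- 0
  for (a in seq_along(T_i)) {
    b <- best_j[[a]]
    if (best_i[[b]] == a) total <- total + S[a, b]
  }
  2 * total / (length(T_i) + length(T_j))
}

#' All-pairs protein similarity matrix
#'
#' @param table a propagated [annotation_table].
#' @param sim a term-pair similarity function.
#' @return symmetric N x N numeric matrix with protein dimnames.
#' @export
protein_similarity_matrix <- function(table, sim) {
  N <- length(table$proteins)
  M <- matrix(0, N, N, dimnames = list(table$proteins, table$proteins))
  for (i in seq_len(N)) {
    for (j in i:N) {
      v <- protein_similarity(table$term_sets[[i]], table$term_sets[[j]], sim)
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  M
}
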