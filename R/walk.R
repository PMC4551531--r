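#' Filtered term-pair similarity
#'
#' fsim(t1, t2) = sim(t1, t2) when t1 is a direct parent of t2, else 0:
#' the walker may only step along parent->child edges, never skip a
#' generation.
#'
#' @param dag an [ontology_dag].
#' @param sim a term-pair similarity function.
#' @param t1,t2 term identifiers.
#' @return a value in `[0, 1]`.
#' @export
filtered_similarity <- function(dag, sim, t1, t2) {
  check_terms(dag, c(t1, t2))
  if (!(t1 %in% dag$parents[[t2]])) return(0)
  sim(t1, t2)
}

#' Downward transition matrix over the ontology
#'
#' W(t1, t2) = fsim(t1, t2) / sum over parents t of fsim(t, t2): each
#' non-root column is the similarity-weighted distribution over the
#' term's incoming parent edges and sums to 1; root columns are zero.
#' When every parent similarity of a term is 0 (possible under corpus IC)
#' the column falls back to uniform over parents, with a warning.
#'
#' @param dag an [ontology_dag].
#' @param sim a term-pair similarity function; pass `function(a, b) 1` for
#'   the equal-weight (dRW-E) variant.
#' @return a sparse `Matrix::dgCMatrix` with rows and columns indexed by
#'   `dag$terms` (class `transition_matrix` added).
#' @export
transition_matrix <- function(dag, sim) {
  terms <- dag$terms
  idx <- seq_along(terms)
  names(idx) <- terms
  ii <- integer(); jj <- integer(); xx <- numeric()
  fallbacks <- character()
  for (v in terms) {
    ps <- dag$parents[[v]]
    if (length(ps) == 0L) next
    w <- vapply(ps, function(p) sim(p, v), 0)
    tot <- sum(w)
    if (tot <= 0) {
      fallbacks <- c(fallbacks, v)
      w <- rep(1, length(ps))
      tot <- length(ps)
    }
    ii <- c(ii, idx[ps]); jj <- c(jj, rep(idx[[v]], length(ps)))
    xx <- c(xx, w / tot)
  }
  if (length(fallbacks) > 0L) {
    warning(length(fallbacks),
            " term(s) with all-zero parent similarity; using uniform parents: ",
            paste(utils::head(fallbacks, 5L), collapse = ", "))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(terms), length(terms)),
                            dimnames = list(terms, terms))
  class(W) <- class(Matrix::drop0(W))
  structure(W, walk_terms = terms)
}

#' Downward random walk with restart from one term
#'
#' Iterates R_{s+1}(t, v) = eta * sum_u R_s(t, u) W(u, v) + (1 - eta) e_t
#' restricted to t and its descendants, starting from R_0 = e_t. The
#' restart mass keeps 1 - eta at the start term from the first step
#' onward (no term is its own descendant), and probability decays with
#' depth, so direct children outrank deeper descendants.
#'
#' @param W transition matrix from [transition_matrix()].
#' @param dag an [ontology_dag].
#' @param t start term.
#' @param eta restart complement in `[0, 1]`: the probability of following
#'   an edge at each step; `1 - eta` is the probability of staying at `t`.
#'   Default 0.5.
#' @param iterations number of iterations (>= 1); the hierarchy depth is
#'   small (max GO depth is 15), so 10 iterations reach a near-stationary
#'   profile. Default 10.
#' @return a `walk_profile`: list with `start`, `probs` (named numeric over
#'   `t` and its descendants), `eta`, `iterations`.
#' @export
downward_rwr <- function(W, dag, t, eta = 0.5, iterations = 10L) {
  check_terms(dag, t)
  stopifnot(eta >= 0, eta <= 1, iterations >= 1L)
  support <- c(t, descendants(dag, t))
  Wt <- Matrix::t(W[support, support, drop = FALSE])
  e <- numeric(length(support))
  names(e) <- support
  e[[t]] <- 1
  r <- e
  for (s in seq_len(iterations)) {
    r <- as.numeric(eta * (Wt %*% r)) + (1 - eta) * e
  }
  names(r) <- support
  structure(list(start = t, probs = r, eta = eta, iterations = iterations),
            class = "walk_profile")
}

#' Batch walk profiles
#'
#' One [downward_rwr()] profile per requested start term; results are
#' independent of request order.
#'
#' @inheritParams downward_rwr
#' @param starts character vector of start terms.
#' @return named list of `walk_profile`s.
#' @export
stationary_profiles <- function(W, dag, starts, eta = 0.5, iterations = 10L) {
  starts <- sort(unique(starts))
  out <- lapply(starts, function(t) downward_rwr(W, dag, t, eta, iterations))
  names(out) <- starts
  out
}

#' dRW likelihood scores for one protein
#'
#' L(i, v) = sum over t in T_i of R(t, v) subject to R(t, v) > theta, for
#' candidate terms v outside T_i. The adaptive threshold theta is the mean
#' of all nonzero off-start entries pooled over the profiles of T_i (the
#' constant start entries R(t, t) = 1 - eta are never candidates and are
#' excluded); it prunes the long tail of weak deep-descendant estimates.
#'
#' @param profiles named list of `walk_profile`s covering every term of
#'   `T_i` (e.g. from [stationary_profiles()]).
#' @param T_i the protein's (propagated) term set.
#' @param universe candidate term universe.
#' @return list with `scores` (named numeric over `universe \\ T_i`,
#'   zeros where nothing was propagated) and `theta`.
#' @export
drw_likelihood <- function(profiles, T_i, universe) {
  candidates <- setdiff(universe, T_i)
  scores <- numeric(length(candidates))
  names(scores) <- candidates
  T_i <- intersect(T_i, names(profiles))
  pooled <- numeric()
  for (t in T_i) {
    p <- profiles[[t]]$probs
    off <- p[names(p) != t]
    pooled <- c(pooled, off[off > 0])
  }
  theta <- if (length(pooled) > 0L) mean(pooled) else 0
  for (t in T_i) {
    p <- profiles[[t]]$probs
    hit <- intersect(names(p)[p > theta], candidates)
    hit <- setdiff(hit, t)
    if (length(hit) > 0L) scores[hit] <- scores[hit] + p[hit]
  }
  list(scores = scores, theta = theta)
}
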