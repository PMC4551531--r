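# Independent brute-force oracles; these deliberately avoid the package's
# sparse/restricted code paths.

# Dense full-universe iteration of the restart recursion; no support
# restriction (mass cannot leave the start term's cone anyway).
dense_walk_oracle <- function(W, dag, t, eta, iterations) {
  Wd <- as.matrix(W)
  n <- length(dag$terms)
  e <- numeric(n)
  names(e) <- dag$terms
  e[[t]] <- 1
  r <- e
  for (s in seq_len(iterations)) {
    r <- eta * drop(r %*% Wd) + (1 - eta) * e
  }
  names(r) <- dag$terms
  r
}

# Exhaustive reachability by path enumeration over all simple paths.
reach_oracle <- function(adj, from) {
  out <- character()
  stack <- list(from)
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    for (w in adj[[v]]) {
      if (!(w %in% out)) {
        out <- c(out, w)
        stack <- c(stack, w)
      }
    }
  }
  sort(out)
}

# Mutual-best reciprocal-pair protein similarity, written from the
# definition with explicit loops and explicit lexicographic tie-breaks.
psim_oracle <- function(T_i, T_j, sim) {
  T_i <- sort(unique(T_i)); T_j <- sort(unique(T_j))
  if (length(T_i) == 0L || length(T_j) == 0L) return(0)
  best_match <- function(t, pool, fixed_first) {
    vals <- vapply(pool, function(u) {
      if (fixed_first) sim(t, u) else sim(u, t)
    }, 0)
    pool[[which(vals == max(vals))[[1L]]]]  # pool sorted => lexicographic
  }
  total <- 0
  for (t1 in T_i) {
    t2 <- best_match(t1, T_j, fixed_first = TRUE)
    if (identical(best_match(t2, T_i, fixed_first = FALSE), t1)) {
      total <- total + sim(t1, t2)
    }
  }
  2 * total / (length(T_i) + length(T_j))
}

# Pairwise rank-loss complement counted pair by pair (ties 0.5).
rankloss_complement_oracle <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
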