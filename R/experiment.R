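# Evaluate `code` under a temporary RNG state; the caller's stream is
# untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Mask protein-specific leaf annotations
#'
#' Simulates missing functions: for every protein annotated with at least
#' two terms, iteratively removes `m` uniformly drawn protein-specific
#' leaf terms (recomputing the leaf frontier after each removal — a
#' non-leaf term becomes maskable once its in-set children are gone).
#' A protein always retains at least one term; unannotated proteins are
#' skipped. Masked sets stay upward-closed throughout. Terms whose every
#' annotation is masked become "second kind" missing functions: present
#' in the hierarchy, annotated to nobody.
#'
#' @param dag an [ontology_dag].
#' @param table a propagated [annotation_table].
#' @param m number of terms to mask per protein (>= 1).
#' @param seed RNG seed making the draw reproducible.
#' @return a `masked_dataset`: list with `masked_table`, `truth_pairs`
#'   (data.frame of masked `protein`/`term` pairs), `second_kind_terms`,
#'   `m`, `N_m` (total masked count), `seed`.
#' @export
mask_annotations <- function(dag, table, m, seed = 1L) {
  stopifnot(inherits(table, "annotation_table"))
  if (m < 1L) stop("m must be >= 1 (masking nothing is a protocol bug)")
  orig_freq <- term_frequency(table)
  res <- with_seed(seed, {
    sets <- table$term_sets
    mp <- character(); mt <- character()
    for (p in table$proteins) {
      cur <- sets[[p]]
      if (length(cur) < 2L) next
      for (r in seq_len(m)) {
        if (length(cur) <= 1L) break
        leaves <- protein_leaf_terms(dag, cur)
        drawn <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
        cur <- setdiff(cur, drawn)
        mp <- c(mp, p); mt <- c(mt, drawn)
      }
      sets[[p]] <- cur
    }
    list(sets = sets, mp = mp, mt = mt)
  })
  masked_table <- annotation_table(table$proteins, res$sets,
                                   universe = table$universe)
  new_freq <- term_frequency(masked_table)
  structure(list(
    masked_table = masked_table,
    truth_pairs = data.frame(protein = res$mp, term = res$mt,
                             stringsAsFactors = FALSE),
    second_kind_terms = names(new_freq)[new_freq == 0L & orig_freq > 0L],
    m = m, N_m = length(res$mp), seed = seed
  ), class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("<masked_dataset> m=%d, N_m=%d masked pairs, |T_m^0|=%d second-kind terms (seed %d)\n",
              x$m, x$N_m, length(x$second_kind_terms), x$seed))
  invisible(x)
}

run_method <- function(method, dag, table, eta, iterations, k, sim_variant,
                       psim = NULL) {
  need_psim <- method %in% c("drw-knn", "itss")
  if (need_psim && is.null(psim)) {
    psim <- protein_similarity_matrix(table, make_term_sim(dag, structure_ic(dag)))
  }
  switch(method,
    "drw" = drw_predict(dag, table, sim_variant, eta, iterations),
    "drw-knn" = drw_knn_predict(
      drw_predict(dag, table, sim_variant, eta, iterations), table, psim, k),
    "itss" = itss_baseline(dag, table, psim, k),
    "naive" = naive_predict(dag, table),
    stop("unknown method: ", method)
  )
}

#' Repeated mask-and-evaluate experiment
#'
#' For each mask depth `m` and each repeat, masks the table with sub-seed
#' `seed + repeat`, runs every requested method on the masked table
#' (second-kind terms stay in the candidate universe), evaluates against
#' the masked pairs, and summarizes each metric as mean and standard
#' deviation across repeats.
#'
#' @param dag an [ontology_dag].
#' @param table a propagated (and usually support-filtered)
#'   [annotation_table].
#' @param methods subset of `"drw"`, `"drw-knn"`, `"itss"`, `"naive"`.
#' @param m_values mask depths; default `c(1, 3, 5)`.
#' @param repeats rounds per `m`; default 10.
#' @param seed base seed; repeat `r` uses `seed + r`.
#' @param eta,iterations,k,sim_variant method parameters.
#' @return a `masking_summary`: list with `summary` (data.frame of
#'   method/m/metric/mean/sd) and `details` (data.frame with one row per
#'   method, m, repeat, including `N_m` and `n_second_kind`).
#' @export
run_masking_experiment <- function(dag, table,
                                   methods = c("drw", "drw-knn", "itss", "naive"),
                                   m_values = c(1L, 3L, 5L), repeats = 10L,
                                   seed = 1L, eta = 0.5, iterations = 10L,
                                   k = 10L, sim_variant = "structure") {
  stopifnot(repeats >= 1L)
  metric_keys <- c("macro_f1", "avg_roc", "one_minus_rankloss", "r_accuracy",
                   "fmax", "coverage")
  rows <- list()
  for (m in m_values) {
    for (r in seq_len(repeats)) {
      masked <- mask_annotations(dag, table, m, seed = seed + r)
      psim <- if (any(methods %in% c("drw-knn", "itss"))) {
        protein_similarity_matrix(masked$masked_table,
                                  make_term_sim(dag, structure_ic(dag)))
      }
      for (method in methods) {
        scores <- run_method(method, dag, masked$masked_table, eta, iterations,
                             k, sim_variant, psim)
        rep_ <- evaluate_predictions(scores, masked)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, m = m, repeat_ = r, N_m = masked$N_m,
          n_second_kind = length(masked$second_kind_terms),
          as.data.frame(rep_[metric_keys]), stringsAsFactors = FALSE)
      }
    }
  }
  details <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(details, list(details$method, details$m),
                                      drop = TRUE), function(d) {
    do.call(rbind, lapply(metric_keys, function(key) data.frame(
      method = d$method[[1L]], m = d$m[[1L]], metric = key,
      mean = mean(d[[key]]),
      sd = if (nrow(d) > 1L) stats::sd(d[[key]]) else 0,
      stringsAsFactors = FALSE)))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, details = details), class = "masking_summary")
}

#' @export
print.masking_summary <- function(x, ...) {
  cat("<masking_summary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Historical rollback comparison
#'
#' Scores computed from an older annotation release are checked against a
#' newer one: the `top_n` highest-scoring candidate (protein, term) pairs
#' are called positive, and a call is a true positive when the pair is
#' annotated in the new release but not the old. With `apply_tpr`, every
#' called pair is first expanded with its ancestor pairs (the true path
#' rule applied to the predictions) and the counts recomputed over the
#' expanded set.
#'
#' @param old_table,new_table propagated [annotation_table]s over `dag`.
#' @param scores a `score_matrix` computed from `old_table` (use
#'   `include_root = TRUE` in the predictor to mirror rollback protocols
#'   that retain the sub-ontology root).
#' @param dag an [ontology_dag].
#' @param top_n number of global top predictions to call; default 100.
#' @param apply_tpr also report the ancestor-augmented counts.
#' @return a `rollback_report`: list with `predictions` (data.frame:
#'   protein, term, score, true_positive), `n_true_positive`, `rate`, and
#'   when `apply_tpr` the `augmented` counterpart, plus `n_unverifiable`
#'   (predictions for proteins absent from the new release).
#' @export
rollback_compare <- function(old_table, new_table, scores, dag,
                             top_n = 100L, apply_tpr = FALSE) {
  stopifnot(inherits(scores, "score_matrix"))
  cand <- which(!is.na(scores), arr.ind = TRUE)
  df <- data.frame(protein = rownames(scores)[cand[, 1L]],
                   term = colnames(scores)[cand[, 2L]],
                   score = scores[cand], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$protein, df$term, method = "radix"), ,
           drop = FALSE]
  df <- utils::head(df, top_n)
  pair_in <- function(tab, prot, term) {
    mapply(function(p, t) p %in% tab$proteins && t %in% tab$term_sets[[p]],
           prot, term, USE.NAMES = FALSE)
  }
  unver <- !(df$protein %in% new_table$proteins)
  if (any(unver)) {
    message(sum(unver), " prediction(s) for protein(s) absent from the new table")
  }
  df$true_positive <- pair_in(new_table, df$protein, df$term) &
    !pair_in(old_table, df$protein, df$term)
  out <- list(predictions = df,
              n_true_positive = sum(df$true_positive),
              rate = if (nrow(df)) mean(df$true_positive) else NA_real_,
              n_unverifiable = sum(unver))
  if (apply_tpr) {
    aug <- unique(do.call(rbind, lapply(seq_len(nrow(df)), function(r) {
      terms <- c(df$term[[r]], ancestors(dag, df$term[[r]]))
      data.frame(protein = df$protein[[r]], term = terms,
                 stringsAsFactors = FALSE)
    })))
    aug$true_positive <- pair_in(new_table, aug$protein, aug$term) &
      !pair_in(old_table, aug$protein, aug$term)
    out$augmented <- list(pairs = aug,
                          n_true_positive = sum(aug$true_positive),
                          rate = if (nrow(aug)) mean(aug$true_positive) else NA_real_)
  }
  structure(out, class = "rollback_report")
}

#' @export
print.rollback_report <- function(x, ...) {
  cat(sprintf("<rollback_report> %d/%d true positives (rate %.3f)\n",
              x$n_true_positive, nrow(x$predictions), x$rate))
  if (!is.null(x$augmented)) {
    cat(sprintf("  with true-path augmentation: %d/%d (rate %.3f)\n",
                x$augmented$n_true_positive, nrow(x$augmented$pairs),
                x$augmented$rate))
  }
  invisible(x)
}
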