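#' Configuration for the synthetic ontology/annotation generator
#'
#' The generator emulates the shape of a GO sub-ontology and its GOA
#' annotations at desk scale: a single root, multiple inheritance, bounded
#' depth (real GO tops out at depth 15), and a leaf-first annotation
#' process in which most terms end up sparse and some proteins end up
#' unannotated.
#'
#' @param n_terms number of terms including the root (>= 2).
#' @param max_depth maximum depth of any term (>= 1); default 6.
#' @param max_parents maximum parents per non-root term (>= 1); default 3.
#' @param n_proteins number of proteins; default 50.
#' @param mean_leaf_annotations Poisson mean of the number of leaf terms
#'   drawn per protein before upward closure; default 3 (keeps the bulk of
#'   terms in the sparse strata at these scales while leaving a tail of
#'   unannotated proteins, as in real GOA snapshots).
#' @param seed RNG seed; every generator output is bit-reproducible
#'   under it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_terms, max_depth = 6L, max_parents = 3L,
                         n_proteins = 50L, mean_leaf_annotations = 3,
                         seed = 1L) {
  stopifnot(n_terms >= 2L, max_depth >= 1L, max_parents >= 1L,
            n_proteins >= 0L, mean_leaf_annotations >= 0)
  structure(list(n_terms = as.integer(n_terms),
                 max_depth = as.integer(max_depth),
                 max_parents = as.integer(max_parents),
                 n_proteins = as.integer(n_proteins),
                 mean_leaf_annotations = mean_leaf_annotations,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_term_ids <- function(n) sprintf("ST:%06d", seq_len(n))

#' Generate a synthetic rooted DAG
#'
#' Terms are created in order; each non-root term draws a level in
#' `1..max_depth` and 1 to `max_parents` parents uniformly from strictly
#' shallower terms, which guarantees acyclicity, a single root, and depth
#' at most `max_depth`. `max_parents = 1` yields a tree.
#'
#' @param cfg a [synth_config].
#' @return an [ontology_dag] with namespace `"synthetic"`.
#' @export
generate_dag <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    ids <- synth_term_ids(cfg$n_terms)
    level <- integer(cfg$n_terms)
    level[[1L]] <- 0L
    edges <- list()
    for (i in seq_len(cfg$n_terms)[-1L]) {
      level[[i]] <- sample.int(cfg$max_depth, 1L)
      shallower <- which(level[seq_len(i - 1L)] < level[[i]])
      np <- min(sample.int(cfg$max_parents, 1L), length(shallower))
      ps <- if (length(shallower) == 1L) shallower else sample(shallower, np)
      edges[[i]] <- cbind(ids[ps], ids[[i]])
    }
    ontology_dag(ids, do.call(rbind, edges))
  })
}

dag_leaves <- function(dag) {
  dag$terms[vapply(dag$children, length, 1L) == 0L]
}

#' Generate true-path-consistent synthetic annotations
#'
#' Each protein draws a Poisson number of distinct DAG leaves (possibly
#' zero, so some proteins stay unannotated) and the set is closed upward,
#' mirroring how GOA records the most detailed terms and the true path
#' rule supplies the ancestors. The output equals its own propagation by
#' construction.
#'
#' @param dag an [ontology_dag].
#' @param cfg a [synth_config] (uses `n_proteins`,
#'   `mean_leaf_annotations`, and `seed + 1` so the annotation draw is
#'   independent of the DAG draw).
#' @return an [annotation_table] with universe `dag$terms`.
#' @export
generate_annotations <- function(dag, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  leaves <- dag_leaves(dag)
  with_seed(cfg$seed + 1L, {
    proteins <- sprintf("P%05d", seq_len(cfg$n_proteins))
    sets <- lapply(proteins, function(p) {
      n <- min(stats::rpois(1L, cfg$mean_leaf_annotations), length(leaves))
      if (n == 0L) return(character())
      drawn <- if (length(leaves) == 1L) leaves else sample(leaves, n)
      sort(unique(c(drawn, unlist(lapply(drawn, ancestors, dag = dag),
                                  use.names = FALSE))))
    })
    annotation_table(proteins, sets, universe = dag$terms)
  })
}

#' Write an ontology as an OBO file
#'
#' @param dag an [ontology_dag].
#' @param path output file path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    ps <- dag$parents[[t]]
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", dag$name[[t]]),
                 paste0("namespace: ", dag$namespace[[t]]),
                 if (length(ps) > 0L) paste0("is_a: ", ps),
                 ""), con)
  }
  invisible(path)
}

#' Write an annotation table as a GAF 2.1 file
#'
#' Only the most detailed terms need be written for a propagated table
#' (set `leaves_only = TRUE`); parsing followed by
#' [propagate_true_path()] then restores the full table. Records carry a
#' non-excluded evidence code by default; `iea_fraction` injects IEA
#' records to exercise the evidence filter.
#'
#' @param table an [annotation_table].
#' @param path output file path.
#' @param dag an [ontology_dag], required for `leaves_only`.
#' @param leaves_only write only protein-specific leaf terms.
#' @param evidence evidence code for the records; default `"IDA"`.
#' @param iea_fraction fraction of extra duplicate records written with
#'   evidence `"IEA"`; default 0.
#' @export
write_gaf <- function(table, path, dag = NULL, leaves_only = FALSE,
                      evidence = "IDA", iea_fraction = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  gaf_line <- function(p, t, ev) {
    paste("SYNTH", p, p, "", t, "SYNTH_REF:0000001", ev, "", "P",
          "", "", "protein", "taxon:0", "20260101", "SYNTH", "", "",
          sep = "\t")
  }
  for (p in table$proteins) {
    ts <- table$term_sets[[p]]
    if (leaves_only && length(ts) > 0L) ts <- protein_leaf_terms(dag, ts)
    for (t in ts) {
      writeLines(gaf_line(p, t, evidence), con)
      if (iea_fraction > 0 && stats::runif(1L) < iea_fraction) {
        writeLines(gaf_line(p, t, "IEA"), con)
      }
    }
  }
  invisible(path)
}

#' Write a matched OBO/GAF fixture pair
#'
#' Emits `ontology.obo` and `annotations.gaf` into `directory`; the pair
#' round-trips through [parse_obo()] and [parse_gaf()] to structures equal
#' to the inputs.
#'
#' @param dag an [ontology_dag].
#' @param table an [annotation_table] over `dag`.
#' @param directory output directory (created if missing).
#' @return named character vector of the two paths.
#' @export
write_fixture <- function(dag, table, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  obo <- file.path(directory, "ontology.obo")
  gaf <- file.path(directory, "annotations.gaf")
  write_obo(dag, obo)
  write_gaf(table, gaf)
  c(obo = obo, gaf = gaf)
}
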