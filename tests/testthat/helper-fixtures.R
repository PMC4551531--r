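# Shared toy fixtures, built in code.

# t -> a -> b
chain_dag <- function() {
  ontology_dag(c("t", "a", "b"), rbind(c("t", "a"), c("a", "b")))
}

# t -> {a, b}, a -> c, b -> c
diamond_dag <- function() {
  ontology_dag(c("t", "a", "b", "c"),
               rbind(c("t", "a"), c("t", "b"), c("a", "c"), c("b", "c")))
}

# deterministic random DAG + annotations at a given size
random_fixture <- function(n_terms, n_proteins, seed,
                           mean_leaf_annotations = 3, max_depth = 6L,
                           max_parents = 3L) {
  cfg <- synth_config(n_terms = n_terms, n_proteins = n_proteins,
                      seed = seed, mean_leaf_annotations = mean_leaf_annotations,
                      max_depth = max_depth, max_parents = max_parents)
  dag <- generate_dag(cfg)
  list(cfg = cfg, dag = dag, table = generate_annotations(dag, cfg))
}

manual_scores <- function(m, method = "manual") {
  structure(m, class = c("score_matrix", class(m)), method = method)
}

obo_lines <- function(...) unlist(list("format-version: 1.2", "", ...))

gaf_record <- function(protein, term, evidence = "IDA", qualifier = "") {
  paste("DB", protein, protein, qualifier, term, "REF:1", evidence, "", "P",
        "", "", "protein", "taxon:0", "20200101", "DB", "", "", sep = "\t")
}
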