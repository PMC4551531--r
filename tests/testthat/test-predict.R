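test_that("drw_predict composes walk likelihood rows", {
  dag <- chain_dag()
  tab <- annotation_table(c("P1", "P2"), list("t", character()),
                          universe = dag$terms)
  S <- drw_predict(dag, tab, include_root = TRUE)
  expect_equal(S["P1", ], c(a = 0.25, b = 0, t = NA_real_))
  expect_equal(unname(S["P2", ]), c(0, 0, 0))     # unannotated -> zero row
  # root excluded from candidates by default
  Sdef <- drw_predict(dag, tab)
  expect_equal(colnames(Sdef), c("a", "b"))
  # fully annotated protein -> all-sentinel row
  full <- annotation_table("P1", list(dag$terms))
  expect_true(all(is.na(drw_predict(dag, full, include_root = TRUE))))
})

test_that("equal-weight variant coincides with structure on single-parent DAGs", {
  fx <- random_fixture(25, 10, 31, max_parents = 1L)   # a tree
  Ss <- drw_predict(fx$dag, fx$table, "structure")
  Se <- drw_predict(fx$dag, fx$table, "equal")
  expect_equal(unclass(Ss), unclass(Se), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("drw_knn_predict with k = 1 reproduces dRW entry-wise", {
  fx <- random_fixture(30, 12, 37)
  sim <- make_term_sim(fx$dag, structure_ic(fx$dag))
  psim <- protein_similarity_matrix(fx$table, sim)
  L <- drw_predict(fx$dag, fx$table)
  L1 <- drw_knn_predict(L, fx$table, psim, k = 1L)
  expect_equal(unclass(L1), unclass(L), ignore_attr = TRUE)
  expect_error(drw_knn_predict(L, fx$table, psim, k = 1000L), "exceeds")
})

test_that("drw_knn_predict matches hand evaluation of the fusion rule", {
  dag <- chain_dag()
  tab <- annotation_table(c("P1", "P2"), list(c("t", "a"), c("t", "a", "b")),
                          universe = dag$terms)
  L <- drw_predict(dag, tab)
  psim <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
                 dimnames = list(tab$proteins, tab$proteins))
  S <- drw_knn_predict(L, tab, psim, k = 2L)
  # P1's only candidate is b: (1 * L(P1,b) + 0.5 * 1) / 2
  expect_equal(S["P1", "b"], (L["P1", "b"] + 0.5 * 1) / 2)
  expect_true(is.na(S["P2", "b"]))
  # zero neighbour similarity: ranking identical to dRW, scaled by 1/k
  psim0 <- diag(2); dimnames(psim0) <- dimnames(psim)
  S0 <- drw_knn_predict(L, tab, psim0, k = 2L)
  expect_equal(S0["P1", "b"], L["P1", "b"] / 2)
})

test_that("itss_baseline only transfers observed neighbour annotations", {
  dag <- chain_dag()
  tab <- annotation_table(c("P1", "P2", "P3"),
                          list(c("t", "a"), c("t", "a", "b"), c("t", "a")),
                          universe = dag$terms)
  sim <- make_term_sim(dag, structure_ic(dag))
  psim <- protein_similarity_matrix(tab, sim)
  S <- itss_baseline(dag, tab, psim, k = 3L)
  # brute-force Eq with binary neighbour belief
  expect_equal(S["P1", "b"],
               (psim["P1", "P1"] * 0 + psim["P1", "P2"] * 1 + psim["P1", "P3"] * 0) / 3)
  # k = 1: only self in the neighbourhood, candidates all 0
  S1 <- itss_baseline(dag, tab, psim, k = 1L)
  expect_true(all(S1[!is.na(S1)] == 0))
  # second-kind term (annotated to nobody) scores 0 for everyone
  tab2 <- annotation_table(c("P1", "P2"), list(c("t", "a"), c("t", "a")),
                           universe = dag$terms)
  psim2 <- protein_similarity_matrix(tab2, sim)
  S2 <- itss_baseline(dag, tab2, psim2, k = 2L)
  expect_true(all(S2[, "b"] == 0))
})

test_that("naive_predict ranks by frequency, identically across proteins", {
  dag <- chain_dag()
  tab <- annotation_table(c("P1", "P2", "P3"),
                          list(c("t", "a"), "t", c("t", "a", "b")),
                          universe = dag$terms)
  S <- naive_predict(dag, tab, include_root = TRUE)
  expect_equal(S["P2", c("t", "a", "b")], c(t = NA_real_, a = 2 / 3, b = 1 / 3))
  expect_equal(S["P1", "b"], 1 / 3)
  # frequency 0 (second kind) scores 0
  tab2 <- annotation_table("P1", list("t"), universe = dag$terms)
  expect_equal(naive_predict(dag, tab2, include_root = TRUE)["P1", "b"], 0)
})

test_that("scores are permutation-equivariant in protein order", {
  fx <- random_fixture(25, 8, 41)
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 7L, 6L)
  tab_p <- annotation_table(fx$table$proteins[perm],
                            fx$table$term_sets[perm],
                            universe = fx$table$universe)
  S <- drw_predict(fx$dag, fx$table)
  Sp <- drw_predict(fx$dag, tab_p)
  expect_equal(unclass(Sp), unclass(S)[fx$table$proteins[perm], ],
               ignore_attr = TRUE)
})

test_that("score TSV export is stable and complete", {
  fx <- random_fixture(15, 5, 43)
  S <- drw_predict(fx$dag, fx$table)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_tsv(S, path, header = c("method=drw"))
  lines <- readLines(path)
  expect_equal(lines[[1L]], "# method=drw")
  expect_equal(length(lines), 2L + nrow(S) * ncol(S))
})
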