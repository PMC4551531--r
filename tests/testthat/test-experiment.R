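test_that("mask_annotations masks protein leaves with the >=1-term guard", {
  dag <- chain_dag()
  tab <- annotation_table(c("P1", "P2", "P3"),
                          list(c("t", "a", "b"), "t", character()),
                          universe = dag$terms)
  m1 <- mask_annotations(dag, tab, m = 1, seed = 1)
  expect_equal(m1$truth_pairs, data.frame(protein = "P1", term = "b"))
  expect_equal(m1$masked_table$term_sets[["P1"]], c("a", "t"))
  # deep mask stops at one retained term; single-term and empty proteins
  # untouched
  m5 <- mask_annotations(dag, tab, m = 5, seed = 1)
  expect_setequal(m5$truth_pairs$term, c("a", "b"))
  expect_equal(m5$masked_table$term_sets[["P1"]], "t")
  expect_equal(m5$masked_table$term_sets[["P2"]], "t")
  expect_equal(m5$N_m, 2L)
  expect_error(mask_annotations(dag, tab, m = 0), "m must be")
})

test_that("masking preserves closure and is exactly reversible", {
  fx <- random_fixture(40, 25, 61)
  for (m in c(1, 3)) {
    md <- mask_annotations(fx$dag, fx$table, m, seed = 17)
    # masked sets stay upward-closed
    prop <- propagate_true_path(fx$dag, md$masked_table)
    expect_equal(prop$term_sets, md$masked_table$term_sets)
    # truth pairs are disjoint from the masked table
    for (r in seq_len(nrow(md$truth_pairs))) {
      expect_false(md$truth_pairs$term[[r]] %in%
                     md$masked_table$term_sets[[md$truth_pairs$protein[[r]]]])
    }
    # re-adding the masked pairs restores the original exactly
    restored <- md$masked_table$term_sets
    for (r in seq_len(nrow(md$truth_pairs))) {
      p <- md$truth_pairs$protein[[r]]
      restored[[p]] <- sort(c(restored[[p]], md$truth_pairs$term[[r]]))
    }
    expect_equal(restored, fx$table$term_sets)
    # every originally annotated protein retains at least one term
    had <- lengths(fx$table$term_sets) > 0L
    expect_true(all(lengths(md$masked_table$term_sets)[had] >= 1L))
    # second-kind bookkeeping
    f0 <- term_frequency(md$masked_table)
    f1 <- term_frequency(fx$table)
    expect_setequal(md$second_kind_terms, names(f0)[f0 == 0L & f1 > 0L])
    # determinism
    md2 <- mask_annotations(fx$dag, fx$table, m, seed = 17)
    expect_equal(md, md2)
  }
})

test_that("run_masking_experiment summarizes repeats deterministically", {
  fx <- random_fixture(30, 20, 67)
  res <- run_masking_experiment(fx$dag, fx$table, methods = c("drw", "naive"),
                                m_values = 1L, repeats = 2L, seed = 5)
  expect_s3_class(res, "masking_summary")
  expect_setequal(unique(res$summary$method), c("drw", "naive"))
  expect_equal(nrow(res$details), 4L)
  expect_true(all(c("N_m", "n_second_kind") %in% names(res$details)))
  res2 <- run_masking_experiment(fx$dag, fx$table, methods = c("drw", "naive"),
                                 m_values = 1L, repeats = 2L, seed = 5)
  expect_equal(res, res2)
  # single repeat: sd reported as 0
  one <- run_masking_experiment(fx$dag, fx$table, methods = "naive",
                                m_values = 1L, repeats = 1L, seed = 5)
  expect_true(all(one$summary$sd == 0))
})

test_that("rollback_compare counts new-release true positives", {
  dag <- chain_dag()
  old <- annotation_table(c("P1", "P2"), list("t", c("t", "a")),
                          universe = dag$terms)
  new <- annotation_table(c("P1", "P2"), list(c("a", "t"), c("t", "a", "b")),
                          universe = dag$terms)
  S <- drw_predict(dag, old, include_root = TRUE)
  rb <- rollback_compare(old, new, S, dag, top_n = 2)
  # P1 gains a, P2 gains b; both are the top dRW candidates
  expect_equal(rb$n_true_positive, 2L)
  expect_equal(rb$rate, 1)
  # new == old: zero true positives
  rb0 <- rollback_compare(old, old, S, dag, top_n = 2)
  expect_equal(rb0$n_true_positive, 0L)
  # top_n beyond the candidate count evaluates everything
  rb_all <- rollback_compare(old, new, S, dag, top_n = 1000)
  expect_equal(nrow(rb_all$predictions), sum(!is.na(S)))
})

test_that("true-path augmentation expands predictions before counting", {
  dag <- chain_dag()
  old <- annotation_table("P1", list("t"), universe = dag$terms)
  new <- annotation_table("P1", list(c("t", "a", "b")), universe = dag$terms)
  # predict only the deep term b; its ancestor a is also newly annotated
  S <- manual_scores(matrix(c(NA, 0, 0.9), 1, 3,
                            dimnames = list("P1", c("t", "a", "b"))))
  rb <- rollback_compare(old, new, S, dag, top_n = 1, apply_tpr = TRUE)
  expect_equal(rb$n_true_positive, 1L)
  expect_equal(rb$augmented$n_true_positive, 2L)   # b plus ancestor a; t is old
  # protein missing from the new table is flagged unverifiable
  new2 <- annotation_table("PX", list("t"), universe = dag$terms)
  expect_message(rb2 <- rollback_compare(old, new2, S, dag, top_n = 1),
                 "absent")
  expect_equal(rb2$n_unverifiable, 1L)
})
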