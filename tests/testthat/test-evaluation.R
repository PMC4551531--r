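make_masked <- function(truth_df) {
  structure(list(truth_pairs = truth_df), class = "masked_dataset")
}

test_that("hand-enumerated single-protein example matches pairwise counting", {
  S <- manual_scores(matrix(c(0.9, 0.4, 0.8, 0.1), 1, 4,
                            dimnames = list("P1", c("c1", "c2", "c3", "c4"))))
  masked <- make_masked(data.frame(protein = "P1", term = c("c1", "c3")))
  rep_ <- evaluate_predictions(S, masked)
  expect_equal(rep_$one_minus_rankloss, 100)   # 4/4 ordered pairs correct
  expect_equal(rep_$coverage, 1)               # positives at ranks 1 and 2
  expect_equal(rep_$r_accuracy, 100)
  expect_equal(rep_$fmax, 100)
  # oracle agreement on the ordering fraction
  expect_equal(rep_$one_minus_rankloss / 100,
               rankloss_complement_oracle(S[1, ], c(TRUE, FALSE, TRUE, FALSE)))

  # degrade: swap scores so c3 drops below c2
  S2 <- manual_scores(matrix(c(0.9, 0.4, 0.3, 0.1), 1, 4,
                             dimnames = dimnames(S)))
  rep2 <- evaluate_predictions(S2, masked)
  expect_equal(rep2$one_minus_rankloss / 100,
               rankloss_complement_oracle(S2[1, ], c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(rep2$coverage, 2)
  expect_lt(rep2$r_accuracy, 100)
})

test_that("perfect rankings score 100 and constant scores give AUC 50", {
  fx <- random_fixture(40, 30, 47)
  masked <- mask_annotations(fx$dag, fx$table, m = 2, seed = 3)
  universe <- setdiff(fx$dag$terms, fx$dag$roots)
  N <- length(fx$table$proteins)
  base <- matrix(0, N, length(universe),
                 dimnames = list(fx$table$proteins, universe))
  for (i in seq_len(N)) {
    base[i, intersect(masked$masked_table$term_sets[[i]], universe)] <- NA_real_
  }
  perfect <- base
  perfect[cbind(masked$truth_pairs$protein, masked$truth_pairs$term)] <- 1
  repp <- evaluate_predictions(manual_scores(perfect), masked)
  expect_equal(repp$avg_roc, 100)
  expect_equal(repp$one_minus_rankloss, 100)
  expect_equal(repp$r_accuracy, 100)
  expect_equal(repp$macro_f1, 100)
  expect_equal(repp$fmax, 100)
  # minimal possible coverage: m_i - 1 averaged over masked proteins
  per_prot <- table(masked$truth_pairs$protein)
  expect_equal(repp$coverage, mean(per_prot - 1))

  flat <- base
  repf <- evaluate_predictions(manual_scores(flat), masked)
  auc <- repf$per_term_auc
  expect_true(all(abs(auc[!is.na(auc)] - 50) < 1e-12))

  # negation flips per-term AUC around 50
  neg <- -perfect
  repn <- evaluate_predictions(manual_scores(neg), masked)
  both <- !is.na(repp$per_term_auc) & !is.na(repn$per_term_auc)
  expect_true(all(abs(repp$per_term_auc[both] + repn$per_term_auc[both] - 100) < 1e-9))
})

test_that("metrics are invariant under strictly monotone score transforms", {
  fx <- random_fixture(30, 20, 53)
  masked <- mask_annotations(fx$dag, fx$table, m = 1, seed = 5)
  S <- drw_predict(fx$dag, masked$masked_table)
  a <- evaluate_predictions(S, masked)
  S2 <- manual_scores(exp(3 * unclass(S)))   # strictly increasing
  b <- evaluate_predictions(S2, masked)
  for (key in c("macro_f1", "avg_roc", "one_minus_rankloss", "r_accuracy",
                "coverage")) {
    expect_equal(a[[key]], b[[key]], info = key)
  }
})

test_that("strata summaries and AUC deltas recompute correctly", {
  fx <- random_fixture(40, 30, 59)
  strata <- sparsity_strata(fx$table)
  masked <- mask_annotations(fx$dag, fx$table, m = 2, seed = 7)
  Sa <- drw_predict(fx$dag, masked$masked_table)
  Sb <- naive_predict(fx$dag, masked$masked_table)
  ra <- evaluate_predictions(Sa, masked, strata = strata)
  rb <- evaluate_predictions(Sb, masked, strata = strata)
  expect_true(!is.null(ra$strata_auc))
  d_same <- auc_delta_by_stratum(ra, ra, strata)
  expect_true(all(unlist(d_same) == 0))
  d <- auc_delta_by_stratum(ra, rb, strata)
  # deltas match direct recomputation from the per-term AUCs
  manual <- ra$per_term_auc - rb$per_term_auc
  manual <- manual[!is.na(manual)]
  expect_equal(sort(unlist(d, use.names = FALSE)), sort(unname(manual)))
})

test_that("metric report writes a parseable key-value block", {
  S <- manual_scores(matrix(c(0.9, 0.4, 0.8, 0.1), 1, 4,
                            dimnames = list("P1", c("c1", "c2", "c3", "c4"))))
  rep_ <- evaluate_predictions(S, make_masked(
    data.frame(protein = "P1", term = "c1")))
  path <- withr::local_tempfile()
  write_metric_report(rep_, path, header = "m=1")
  lines <- readLines(path)
  expect_equal(lines[[1L]], "# m=1")
  expect_length(grep("^[a-z_0-9]+\t", lines), 6L)
})
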