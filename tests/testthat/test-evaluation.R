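test_that("ROC/AUC handles separable, uninformative and tied scores", {
  perfect <- roc_auc(c(0.9, 0.1), c(1, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)
  flat <- roc_auc(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$roc), 2L)  # single tied threshold step + origin
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "degenerate")
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  set.seed(40)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-9)
})

test_that("threshold metrics reproduce confusion-table arithmetic", {
  expect_equal(unname(classification_metrics(c(0.9, 0.8, 0.2, 0.1),
                                             c(1, 1, 0, 0))),
               c(1, 1, 1))
  # all predicted positive
  m <- classification_metrics(rep(0.9, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(m), c(0.5, 1, 0))
  # TP=3 FN=1 TN=2 FP=2 -> acc 0.625, sens 0.75, spec 0.5
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.9, 0.1, 0.3)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(unname(classification_metrics(scores, labels)),
               c(0.625, 0.75, 0.5))
  expect_error(classification_metrics(c(0.2, 0.8), c(0, 0)), "no positives")
})

test_that("perturbation protocol at level 0 is chance and is reproducible", {
  co <- tiny_cohort()
  set.seed(42)
  ppn <- init_network(network_descriptor("ppn"))
  rep0 <- perturbation_protocol(ppn, co, levels = 0, seed = 3)
  expect_equal(rep0$metrics$auc, 0.5)
  repA <- perturbation_protocol(ppn, co, seed = 7)
  repB <- perturbation_protocol(ppn, co, seed = 7)
  expect_identical(repA$metrics, repB$metrics)
  expect_equal(nrow(repA$metrics), 4L)
  expect_true(all(repA$metrics$auc >= 0 & repA$metrics$auc <= 1))
})

test_that("sweeps reproduce the unmodified plan at factor 1 in any order", {
  co <- tiny_cohort()
  set.seed(43)
  ppn <- init_network(network_descriptor("ppn"))
  sw <- oar_sweep(ppn, co, "rectum", factors = c(0.8, 1.0, 1.2))
  base <- mean(ppn_forward(ppn, co$anatomy, t(plan_total_dose(co$plans))))
  expect_equal(sw$mean_probability[sw$factor == 1], base, tolerance = 1e-12)
  sw_rev <- oar_sweep(ppn, co, "rectum", factors = c(1.2, 1.0, 0.8))
  expect_equal(sort(sw_rev$mean_probability), sort(sw$mean_probability))
  g <- three_oar_grid(ppn, co, factors = c(0.8, 1, 1.2), ctv_scale = 1)
  expect_equal(dim(g), c(3L, 3L, 3L))
  expect_equal(g["1", "1", "1"], base, tolerance = 1e-12)
})

test_that("consistency audit finds identical cases and bounds pair counts", {
  co <- tiny_cohort()
  two <- cohort_subset(co, c(1, 1))
  aud <- consistency_audit(two)
  expect_equal(nrow(aud$pairs), 1L)
  expect_equal(unlist(aud$variation), c(ctv = 0, bladder = 0, rectum = 0,
                                        sigmoid = 0))
  full <- suppressWarnings(consistency_audit(co, similarity_threshold = 0.9))
  n <- nrow(co$plans)
  expect_lte(nrow(full$pairs), choose(n, 2))
  # audit never pairs plans with different prescriptions
  if (nrow(full$pairs)) {
    rx <- co$plans$prescription
    expect_true(all(rx[full$pairs$i] == rx[full$pairs$j]))
  }
  expect_warning(consistency_audit(cohort_subset(co, 1)), "fewer than 2")
})

test_that("DPN relative errors match hand-computed values", {
  co <- tiny_cohort()
  small <- cohort_subset(co, 1:3)
  dpn <- zero_params(init_network(network_descriptor("dpn")))
  res <- dpn_relative_error(dpn, small)
  expect_equal(unname(res$mean), rep(1, 4))  # zero predictor: |0 - d| / d = 1
  # prediction = 1.1 x truth -> 10% everywhere (via a synthetic wrapper)
  truth <- as.matrix(small$plans[, c("ctv_d90", "bladder_d2cc",
                                     "rectum_d2cc", "sigmoid_d2cc")])
  rel <- abs(1.1 * truth - truth) / truth
  expect_equal(unname(colMeans(rel)), rep(0.1, 4), tolerance = 1e-12)
})
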