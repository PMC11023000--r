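small_cfg <- function(...) {
  args <- modifyList(list(pretrain_epochs = 8L, joint_epochs = 4L, seed = 60L,
                          channels = c(6L, 8L, 8L, 6L), dense_width = 16L),
                     list(...))
  do.call(train_config, args)
}

split_cohort <- function(co, seed = 60) {
  pats <- unique(co$plans$patient_id)
  folds <- grouped_kfold(pats, k = 4L, seed = seed)
  list(train = cohort_patients(co, unlist(folds[2:4])),
       val = cohort_patients(co, folds[[1]]))
}

test_that("DPN pre-training recovers a constant dose function", {
  co <- build_cohort(40, seed = 61, sigma_rel = 0)
  # overwrite with one constant quad: the regression target is a constant
  cols <- c("ctv_d90", "bladder_d2cc", "rectum_d2cc", "sigmoid_d2cc")
  co$plans[, cols] <- matrix(rep(c(7, 4.5, 4, 3.5), each = nrow(co$plans)),
                             nrow = nrow(co$plans))
  sp <- split_cohort(co)
  res <- pretrain_dpn(sp$train, sp$val, train_config(pretrain_epochs = 100L,
                                                     seed = 61L))
  # validation MSE in scaled units, target scale ~0.5: well below 1e-3
  expect_lt(res$best_val, 1e-3)
  pred <- dpn_forward(res$params, sp$val$anatomy, sp$val$plans$prescription)
  expect_equal(unname(rowMeans(pred)), c(7, 4.5, 4, 3.5), tolerance = 0.05)
})

test_that("pre-training bookkeeping: history, best checkpoint, determinism", {
  co <- tiny_cohort(10, seed = 62)
  sp <- split_cohort(co)
  cfg <- small_cfg()
  r1 <- pretrain_dpn(sp$train, sp$val, cfg)
  expect_equal(nrow(r1$history), cfg$pretrain_epochs)
  expect_equal(r1$history$epoch, seq_len(cfg$pretrain_epochs))
  expect_equal(r1$best_val, min(r1$history$val_loss))
  expect_lte(r1$best_val, r1$history$val_loss[nrow(r1$history)])
  expect_true(all(r1$history$train_loss >= 0))
  r2 <- pretrain_dpn(sp$train, sp$val, cfg)
  expect_identical(r1$history, r2$history)
  expect_error(pretrain_dpn(cohort_subset(co, integer(0)), sp$val, cfg), "empty")
})

test_that("negative generation produces k labeled-unapproved copies per plan", {
  co <- tiny_cohort(6, seed = 63)
  neg <- generate_negatives(co, k = 4, seed = 9)
  expect_equal(nrow(neg$plans), 4L * nrow(co$plans))
  expect_true(all(neg$plans$label == 0))
  expect_equal(length(neg$anatomy), nrow(neg$plans))
  neg2 <- generate_negatives(co, k = 4, seed = 9)
  expect_identical(neg$plans, neg2$plans)
  expect_error(generate_negatives(co, k = 0), "k must be")
})

test_that("PPN pre-training separates clearly shifted negatives", {
  # single-fraction, single-prescription courses with no EBRT floor: a +50%
  # dose shift is then linearly separable in the total-course dose input
  co <- build_cohort(60, seed = 64, sigma_rel = 0.03,
                     prescription_set = 7, ebrt_dose = c(0, 0, 0, 0),
                     fraction_weights = c(1, 0, 0, 0, 0))
  sp <- split_cohort(co)
  shift_up <- function(cohort) {
    neg <- cohort
    neg$plans <- perturb_scaled(cohort$plans, 0.5, signs = c(1, 1, 1, 1))
    neg
  }
  tr_mix <- cohort_bind(sp$train, shift_up(sp$train))
  va_mix <- cohort_bind(sp$val, shift_up(sp$val))
  cfg <- small_cfg(pretrain_epochs = 250L, channels = c(16L, 32L, 32L, 16L),
                   dense_width = 64L, dose_scale = 10)
  res <- pretrain_ppn(tr_mix, va_mix, cfg)
  tens <- brachynet:::.cohort_tensors(tr_mix)
  p <- ppn_forward(res$params, tens$anat, tens$total)
  acc <- mean((p >= 0.5) == (tens$label == 1))
  expect_gte(acc, 0.95)
  expect_error(pretrain_ppn(sp$train, sp$val, cfg), "degenerate")
})

test_that("with identical inputs the PPN converges to the class prior", {
  co <- tiny_cohort(4, seed = 65)
  one <- cohort_subset(co, rep(1L, 12))
  one$plans$label <- rep(c(1L, 0L, 0L), 4)  # prior 1/3 on identical inputs
  cfg <- small_cfg(pretrain_epochs = 150L, weight_decay = 0)
  res <- pretrain_ppn(one, one, cfg)
  p <- ppn_forward(res$params, one$anatomy, t(plan_total_dose(one$plans)))
  expect_lt(abs(mean(p) - 1 / 3), 0.1)
})

test_that("adversarial training alternates, keeps histories and stays stable", {
  co <- tiny_cohort(12, seed = 66)
  sp <- split_cohort(co)
  cfg <- small_cfg()
  dpn <- pretrain_dpn(sp$train, sp$val, cfg)$params
  trn <- generate_negatives(sp$train, 2, cfg, seed = 1)
  van <- generate_negatives(sp$val, 2, cfg, seed = 2)
  ppn <- pretrain_ppn(cohort_bind(sp$train, trn), cohort_bind(sp$val, van),
                      cfg)$params
  res <- adversarial_train(dpn, ppn, sp$train, sp$val, cfg)
  expect_equal(nrow(res$history), cfg$joint_epochs)
  expect_true(all(c("adv_ppn_loss", "adv_dpn_loss", "val_dpn_loss",
                    "val_ppn_loss") %in% names(res$history)))
  expect_true(all(is.finite(unlist(res$history))))
  res2 <- adversarial_train(dpn, ppn, sp$train, sp$val, cfg)
  expect_identical(res$history, res2$history)
})

test_that("a constant frozen PPN yields an exactly zero adversarial DPN gradient", {
  ns <- asNamespace("brachynet")
  set.seed(67)
  dpn <- init_network(network_descriptor("dpn"))
  ppn_const <- zero_params(init_network(network_descriptor("ppn")))
  A <- array(runif(4 * 20 * 4), c(4, 20, 4))
  x0 <- ns$.dpn_x0(list(anat = A, rx = rep(7, 4)), dpn$descriptor)
  lg <- ns$.dpn_adv_loss_grad(dpn, ppn_const, x0, A,
                              prior = matrix(0, 4, 4),
                              ebrt = matrix(40, 4, 4),
                              ratio = rep(1, 4), dpn_mode = "eval")
  expect_identical(max(abs(unlist(lg$grads))), 0)
  expect_equal(lg$loss, 0.25)  # |1 - 0.5|^2
})

test_that("grouped k-fold splits are patient-disjoint partitions", {
  pats <- sprintf("P%02d", 1:54)
  folds <- grouped_kfold(pats, k = 4, seed = 68)
  expect_equal(unname(sort(lengths(folds), decreasing = TRUE)),
               c(14L, 14L, 13L, 13L))
  expect_setequal(unlist(folds), pats)
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  expect_identical(grouped_kfold(pats, 4, 68), folds)
  expect_error(grouped_kfold(pats[1:3], k = 4), "fewer patients")
})

test_that("fold selection takes the argmax with lowest-index ties", {
  expect_equal(select_best_fold(0.7), 1L)
  expect_equal(select_best_fold(c(0.6, 0.7, 0.7, 0.5)), 2L)
  expect_error(select_best_fold(numeric(0)), "no fold")
})
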