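# Shared end-to-end fixture: one full three-stage training run at study
# scale (200 fast-mode patients, sigma_rel = 5%), built lazily and reused by
# every acceptance check that needs a trained model.
.trained_cache <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (is.null(.trained_cache$fit)) {
    co <- build_cohort(200, seed = 11, sigma_rel = 0.05)
    folds <- grouped_kfold(unique(co$plans$patient_id), k = 5L, seed = 11)
    test_co <- cohort_patients(co, folds[[1]])
    val_co <- cohort_patients(co, folds[[2]])
    train_co <- cohort_patients(co, unlist(folds[3:5]))
    fit <- brachynet(train_co, val_co, train_config(seed = 11))
    .trained_cache$fit <- fit
    .trained_cache$test <- test_co
    .trained_cache$val <- val_co
  }
  list(fit = .trained_cache$fit, test = .trained_cache$test,
       val = .trained_cache$val)
}
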