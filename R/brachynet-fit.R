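#' Fit the adversarial DPN/PPN model
#'
#' The main fitting function. Runs the three-stage scheme on a cohort of
#' approved plans:
#' \enumerate{
#'   \item DPN pre-training: dose regression
#'     `min E || DPN(R, A) - D ||^2` ([pretrain_dpn()]);
#'   \item PPN pre-training on approved plans plus unfavorably perturbed
#'     negatives: `min E | PPN(F(D), A) - Y |^2` ([pretrain_ppn()]);
#'   \item alternating least-squares adversarial training, PPN pushing
#'     approved plans toward probability 1 and DPN-generated plans toward 0
#'     while DPN learns to fool it ([adversarial_train()]).
#' }
#'
#' @param train_cohort `plan_cohort` of approved plans (label 1).
#' @param val_cohort `plan_cohort` of approved validation plans, patient-
#'   disjoint from `train_cohort`. If `NULL`, a patient-grouped 80/20 split of
#'   `train_cohort` is made.
#' @param config a [train_config()].
#' @param stages which stages to run: `"all"` (default) or `"pretrain"`
#'   (skip the adversarial stage).
#' @return object of class `brachynet` with components `dpn`, `ppn`
#'   (final parameters), `dpn_pretrained`, `ppn_pretrained`, `history`
#'   (per-stage loss histories), `config`, and the training/validation
#'   cohorts.
#' @seealso [predict.brachynet()], [perturbation_protocol()], [oar_sweep()],
#'   [dpn_relative_error()]
#' @examples
#' \donttest{
#' co <- build_cohort(24, seed = 7)
#' cfg <- train_config(pretrain_epochs = 5, joint_epochs = 3, seed = 7)
#' fit <- brachynet(co, config = cfg)
#' print(fit)
#' }
#' @export
brachynet <- function(train_cohort, val_cohort = NULL, config = train_config(),
                      stages = c("all", "pretrain")) {
  stages <- match.arg(stages)
  if (is.null(val_cohort)) {
    pats <- unique(train_cohort$plans$patient_id)
    folds <- grouped_kfold(pats, k = 5L, seed = config$seed)
    val_cohort <- cohort_patients(train_cohort, folds[[1]])
    train_cohort <- cohort_patients(train_cohort, unlist(folds[-1]))
  }
  if (any(train_cohort$plans$label != 1) || any(val_cohort$plans$label != 1)) {
    stop("brachynet() expects cohorts of approved plans (label 1)", call. = FALSE)
  }
  dpn_pre <- pretrain_dpn(train_cohort, val_cohort, config)
  tr_neg <- generate_negatives(train_cohort, config$negatives_per_plan,
                               config, seed = config$seed + 100L)
  va_neg <- generate_negatives(val_cohort, config$negatives_per_plan,
                               config, seed = config$seed + 101L)
  ppn_pre <- pretrain_ppn(cohort_bind(train_cohort, tr_neg),
                          cohort_bind(val_cohort, va_neg), config)
  history <- list(dpn_pretrain = dpn_pre$history, ppn_pretrain = ppn_pre$history)
  dpn <- dpn_pre$params
  ppn <- ppn_pre$params
  if (stages == "all") {
    joint <- adversarial_train(dpn, ppn, train_cohort, val_cohort, config)
    dpn <- joint$dpn
    ppn <- joint$ppn
    history$joint <- joint$history
  }
  structure(list(dpn = dpn, ppn = ppn,
                 dpn_pretrained = dpn_pre$params,
                 ppn_pretrained = ppn_pre$params,
                 history = history, config = config,
                 train_cohort = train_cohort, val_cohort = val_cohort),
            class = "brachynet")
}

#' @export
print.brachynet <- function(x, ...) {
  cat("Adversarial DPN/PPN plan-approval model\n")
  cat(sprintf("  training plans: %d (%d patients); validation plans: %d (%d patients)\n",
              nrow(x$train_cohort$plans),
              length(unique(x$train_cohort$plans$patient_id)),
              nrow(x$val_cohort$plans),
              length(unique(x$val_cohort$plans$patient_id))))
  cat(sprintf("  DPN parameters: %d; PPN parameters: %d\n",
              count_parameters(x$dpn), count_parameters(x$ppn)))
  cat(sprintf("  stages run: %s\n",
              paste(names(x$history), collapse = ", ")))
  invisible(x)
}

#' @export
summary.brachynet <- function(object, ...) {
  err <- dpn_relative_error(object, object$val_cohort)
  rep <- perturbation_protocol(object, object$val_cohort,
                               seed = object$config$seed + 900L)
  out <- list(dpn_val_error = err$mean, ppn_val_metrics = rep$metrics,
              fit = object)
  class(out) <- "summary.brachynet"
  out
}

#' @export
print.summary.brachynet <- function(x, ...) {
  print(x$fit)
  cat("\nDPN validation relative error (mean):\n")
  print(round(100 * x$dpn_val_error, 2))
  cat("\nPPN validation discrimination vs +/- perturbed plans:\n")
  print(x$ppn_val_metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict from a fitted brachynet model
#'
#' @param object `brachynet` fit.
#' @param cohort `plan_cohort` of new plans.
#' @param type `"approval"` for PPN approval probabilities of the recorded
#'   plans (via the total-course extrapolation), `"dose"` for DPN-predicted
#'   per-fraction EQD2 quadruples.
#' @param ... unused.
#' @return numeric vector of probabilities, or an `n x 4` matrix of doses
#'   (Gy).
#' @export
predict.brachynet <- function(object, cohort, type = c("approval", "dose"),
                              ...) {
  type <- match.arg(type)
  if (type == "approval") {
    .score_plans(object$ppn, cohort)
  } else {
    t(dpn_forward(object$dpn, cohort$anatomy, cohort$plans$prescription))
  }
}

#' Residuals of the dose prediction network
#'
#' @param object `brachynet` fit.
#' @param cohort cohort to evaluate on (default: the training cohort).
#' @param ... unused.
#' @return `n x 4` matrix of predicted minus approved per-fraction EQD2 (Gy).
#' @export
residuals.brachynet <- function(object, cohort = object$train_cohort, ...) {
  pred <- predict(object, cohort, type = "dose")
  res <- pred - .plan_dose_matrix(cohort$plans)
  colnames(res) <- STRUCTURES
  res
}

#' Plot training histories of a fitted model
#'
#' Draws the train/validation loss curves of the two pre-training stages and,
#' when present, the adversarial stage.
#'
#' @param x `brachynet` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.brachynet <- function(x, ...) {
  h <- x$history
  n <- length(h)
  old <- graphics::par(mfrow = c(1, n), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(h)) {
    hh <- h[[nm]]
    cols <- setdiff(names(hh), c("epoch", "lr", "lr_dpn", "lr_ppn"))
    graphics::matplot(hh$epoch, hh[, cols, drop = FALSE], type = "l", lty = 1,
                      xlab = "epoch", ylab = "loss", main = nm, log = "y", ...)
    graphics::legend("topright", legend = cols, col = seq_along(cols),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
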