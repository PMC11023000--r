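# Evaluation battery: ROC/AUC, threshold metrics, perturbation-level
# protocol, OAR scaling sweeps/grids, anatomy consistency audit, DPN errors.

#' ROC curve and AUC by tie-grouped threshold sweep
#'
#' Sweeps thresholds over the unique score values (equal scores form a single
#' threshold step), returning the ROC point list from (0,0) to (1,1) and the
#' trapezoidal area under the curve. With ties this equals the concordance
#' estimator `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `roc` (data.frame fpr/tpr/threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: ROC needs both classes", call. = FALSE)
  }
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Accuracy, sensitivity and specificity at a threshold
#'
#' Predicts approval when `score >= threshold` (default 0.5).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold.
#' @return named vector (accuracy, sensitivity, specificity).
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1L)) stop("sensitivity undefined: no positives", call. = FALSE)
  if (!any(labels == 0L)) stop("specificity undefined: no negatives", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L); fp <- sum(pred == 1L & labels == 0L)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

# internal: PPN approval scores for the rows of a plan table
.score_plans <- function(ppn, cohort, plans = cohort$plans,
                         anatomy = cohort$anatomy) {
  total <- t(total_course_dose(.plan_dose_matrix(plans),
                               list(n_fractions = plans$n_fractions,
                                    fraction_index = plans$fraction_index,
                                    prior_hdr_dose = .plan_prior_matrix(plans),
                                    ebrt_dose = .plan_ebrt_matrix(plans))))
  total[total < 0] <- 0
  ppn_forward(ppn, anatomy, total, mode = "eval")
}

#' Perturbation-level evaluation protocol
#'
#' For each perturbation level, builds one (or `k_negatives`) unapproved
#' plan(s) per approved plan by [perturb_scaled()] (independent random +/-
#' sign per structure on the per-fraction HDRBT EQD2), scores approved and
#' perturbed plans through the total-course extrapolation and the PPN, and
#' reports accuracy/sensitivity/specificity/AUC plus the ROC points.
#'
#' @param ppn PPN `network_params` (or a `brachynet` fit).
#' @param cohort `plan_cohort` of approved plans.
#' @param levels perturbation magnitudes (default `c(0.05, 0.10, 0.15, 0.20)`).
#' @param k_negatives perturbed negatives per plan and level (default 1).
#' @param seed RNG seed for the perturbation signs.
#' @param threshold decision threshold for the counting metrics.
#' @return list of class `classification_report`: `metrics` data.frame (one
#'   row per level) and `roc` (list of ROC point data.frames).
#' @export
perturbation_protocol <- function(ppn, cohort,
                                  levels = c(0.05, 0.10, 0.15, 0.20),
                                  k_negatives = 1L, seed = 1L,
                                  threshold = 0.5) {
  ppn <- .as_ppn(ppn)
  set.seed(seed)
  pos_scores <- .score_plans(ppn, cohort)
  metrics <- vector("list", length(levels))
  rocs <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    neg_scores <- unlist(lapply(seq_len(k_negatives), function(k) {
      neg <- perturb_scaled(cohort$plans, levels[li])
      .score_plans(ppn, cohort, plans = neg)
    }))
    scores <- c(pos_scores, neg_scores)
    labels <- c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores)))
    ra <- roc_auc(scores, labels)
    cm <- classification_metrics(scores, labels, threshold)
    metrics[[li]] <- data.frame(level = levels[li], accuracy = cm["accuracy"],
                                sensitivity = cm["sensitivity"],
                                specificity = cm["specificity"], auc = ra$auc)
    rocs[[li]] <- ra$roc
  }
  out <- list(metrics = do.call(rbind, metrics), roc = rocs)
  rownames(out$metrics) <- NULL
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Perturbation-level classification report\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' OAR dose-scaling sweep of the approval probability
#'
#' Holds CTV D90% fixed, scales one OAR's per-fraction HDRBT EQD2 by each
#' factor, recomputes the total-course dose and reports the mean PPN approval
#' probability across the cohort. Mirrors the behavioral check that approval
#' probability should peak near the clinically approved dose (factor 1).
#'
#' @param ppn PPN `network_params` or `brachynet` fit.
#' @param cohort `plan_cohort`.
#' @param structure one of `"bladder"`, `"rectum"`, `"sigmoid"` (or `"ctv"`).
#' @param factors scaling factors (default 0.60 to 1.40 in steps of 0.05).
#' @return data.frame of class `sweep_curve` with columns `factor`,
#'   `mean_probability`.
#' @export
oar_sweep <- function(ppn, cohort, structure = "bladder",
                      factors = seq(0.6, 1.4, by = 0.05)) {
  ppn <- .as_ppn(ppn)
  structure <- match.arg(structure, STRUCTURES)
  col <- .dose_cols[match(structure, STRUCTURES)]
  probs <- vapply(factors, function(f) {
    plans <- cohort$plans
    plans[[col]] <- plans[[col]] * f
    mean(.score_plans(ppn, cohort, plans = plans))
  }, 0)
  out <- data.frame(factor = factors, mean_probability = probs)
  class(out) <- c("sweep_curve", "data.frame")
  attr(out, "structure") <- structure
  out
}

#' Three-OAR scaling grid of the approval probability
#'
#' Cartesian sweep over scaling factors of the three OAR per-fraction doses
#' at a fixed CTV scale, averaged over the plans of the cohort.
#'
#' @param ppn PPN `network_params` or `brachynet` fit.
#' @param cohort `plan_cohort` (use a single-plan cohort for a per-case grid).
#' @param factors factor vector applied to each OAR (default 0.6-1.4 step 0.2).
#' @param ctv_scale scale applied to the CTV per-fraction dose (1.0 or 1.1).
#' @return 3-D array of mean approval probabilities, dims
#'   bladder x rectum x sigmoid factors.
#' @export
three_oar_grid <- function(ppn, cohort, factors = seq(0.6, 1.4, by = 0.2),
                           ctv_scale = 1.0) {
  ppn <- .as_ppn(ppn)
  grid <- expand.grid(bladder = factors, rectum = factors, sigmoid = factors)
  base <- cohort$plans
  base$ctv_d90 <- base$ctv_d90 * ctv_scale
  probs <- vapply(seq_len(nrow(grid)), function(g) {
    plans <- base
    plans$bladder_d2cc <- plans$bladder_d2cc * grid$bladder[g]
    plans$rectum_d2cc <- plans$rectum_d2cc * grid$rectum[g]
    plans$sigmoid_d2cc <- plans$sigmoid_d2cc * grid$sigmoid[g]
    mean(.score_plans(ppn, cohort, plans = plans))
  }, 0)
  array(probs, dim = rep(length(factors), 3L),
        dimnames = list(bladder = factors, rectum = factors, sigmoid = factors))
}

#' Anatomy consistency audit
#'
#' Identifies all pairs of plans with equal prescriptions whose anatomy
#' representations are similar (relative Frobenius distance below
#' `similarity_threshold`), and summarizes the relative differences of the
#' four dosimetric measures across those pairs. Reproduces the data-quality
#' audit that bounds what any data-driven dose model can achieve.
#'
#' @param cohort `plan_cohort`.
#' @param similarity_threshold similar-pair cutoff (default 0.10).
#' @return list of class `consistency_audit`: `pairs` (data.frame i/j/
#'   similarity), `variation` (per-structure relative differences, one row
#'   per pair) and `summary` (per-structure quartiles), or an empty audit
#'   with a warning when fewer than 2 cases exist.
#' @export
consistency_audit <- function(cohort, similarity_threshold = 0.10) {
  n <- nrow(cohort$plans)
  empty <- list(pairs = data.frame(), variation = data.frame(),
                summary = data.frame())
  class(empty) <- "consistency_audit"
  if (n < 2L) {
    warning("fewer than 2 cases: empty audit")
    return(empty)
  }
  flat <- t(vapply(cohort$anatomy, function(a) as.vector(as.matrix(a)),
                   numeric(length(cohort$anatomy[[1]]))))
  norms <- sqrt(rowSums(flat^2))
  rx <- cohort$plans$prescription
  pair_list <- list()
  for (g in split(seq_len(n), rx)) {
    if (length(g) < 2L) next
    d <- as.matrix(stats::dist(flat[g, , drop = FALSE]))
    rel <- d / outer(norms[g], norms[g], `+`)
    hits <- which(upper.tri(rel) & rel < similarity_threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      pair_list[[length(pair_list) + 1L]] <-
        data.frame(i = g[hits[, 1]], j = g[hits[, 2]],
                   similarity = rel[hits])
    }
  }
  if (!length(pair_list)) {
    warning("no similar pairs under the threshold: empty audit")
    return(empty)
  }
  pairs <- do.call(rbind, pair_list)
  D <- .plan_dose_matrix(cohort$plans)
  di <- D[pairs$i, , drop = FALSE]; dj <- D[pairs$j, , drop = FALSE]
  variation <- abs(di - dj) / ((di + dj) / 2)
  colnames(variation) <- STRUCTURES
  summ <- apply(variation, 2, quantile, probs = c(0.25, 0.5, 0.75))
  out <- list(pairs = pairs, variation = as.data.frame(variation),
              summary = as.data.frame(summ))
  class(out) <- "consistency_audit"
  out
}

#' @export
print.consistency_audit <- function(x, ...) {
  cat(sprintf("Consistency audit: %d similar pairs\n", nrow(x$pairs)))
  if (nrow(x$pairs)) {
    cat("Per-structure relative dose variation (quartiles):\n")
    print(round(x$summary, 4))
  }
  invisible(x)
}

#' DPN relative prediction errors
#'
#' Per-structure relative errors `|predicted - approved| / approved` of the
#' dose prediction network on a cohort of approved plans.
#'
#' @param dpn DPN `network_params` or `brachynet` fit.
#' @param cohort `plan_cohort`.
#' @return list: `errors` (n x 4 data.frame), `mean`, `sd`, `quartiles`.
#' @export
dpn_relative_error <- function(dpn, cohort) {
  dpn <- .as_dpn(dpn)
  pred <- t(dpn_forward(dpn, cohort$anatomy, cohort$plans$prescription))
  truth <- .plan_dose_matrix(cohort$plans)
  rel <- abs(pred - truth) / truth
  colnames(rel) <- STRUCTURES
  list(errors = as.data.frame(rel),
       mean = colMeans(rel),
       sd = apply(rel, 2, sd),
       quartiles = apply(rel, 2, quantile, probs = c(0.25, 0.5, 0.75)))
}

.as_ppn <- function(x) {
  if (inherits(x, "brachynet")) x$ppn
  else if (inherits(x, "network_params")) x
  else stop("expected a PPN checkpoint or brachynet fit", call. = FALSE)
}

.as_dpn <- function(x) {
  if (inherits(x, "brachynet")) x$dpn
  else if (inherits(x, "network_params")) x
  else stop("expected a DPN checkpoint or brachynet fit", call. = FALSE)
}
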