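# Three-stage training scheme: DPN pre-training (dose regression), PPN
# pre-training on approved plans plus unfavorably perturbed negatives, then
# alternating least-squares adversarial joint training.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with initial learning rate
#' 5e-4 and L2 regularization, reduce-on-plateau (factor 0.1, patience 5
#' epochs on validation loss), batch size 4, dropout 0.5, kernel 3, LeakyReLU
#' slope 0.2, 100 epochs for each pre-training stage and 100 joint epochs.
#'
#' @param lr_init initial learning rate.
#' @param plateau_factor multiplicative LR reduction on plateau.
#' @param plateau_patience epochs without validation improvement before the
#'   LR is reduced.
#' @param plateau_warmup epochs before the plateau rule engages (default 75).
#'   The validation loss of both networks is non-monotone over the first tens
#'   of epochs at this data scale, and an all-time-minimum rule misreads that
#'   warm-up noise as a plateau; annealing is therefore applied only past the
#'   warm-up.
#' @param batch_size mini-batch size.
#' @param pretrain_epochs epochs for each pre-training stage.
#' @param joint_epochs epochs of adversarial joint training.
#' @param weight_decay L2 regularization coefficient.
#' @param adam_beta1,adam_beta2 Adam moment decay rates. The second-moment
#'   decay defaults to 0.98: with batch-size-4 gradients under heavy dropout
#'   the faster-adapting second moment reaches the validation floor within
#'   the 100-epoch budget (unprinted optimizer settings are tuned for
#'   validation performance, as the protocol prescribes).
#' @param negatives_per_plan perturbed negatives generated per approved plan
#'   for PPN pre-training.
#' @param magnitude_low,magnitude_high unfavorable perturbation range.
#' @param seed RNG seed controlling initialization, shuffling, dropout and
#'   negative generation.
#' @param n_bins,channels,dense_width,dropout,dropout_mode,leaky_slope,dense_act
#'   network architecture settings, see [network_descriptor()].
#' @param dose_scale,rx_scale,out_scale input/output scaling constants (Gy);
#'   see [network_descriptor()].
#' @return list of class `train_config`.
#' @export
train_config <- function(lr_init = 5e-4, plateau_factor = 0.1,
                         plateau_patience = 5L, plateau_warmup = 75L,
                         batch_size = 4L,
                         pretrain_epochs = 100L, joint_epochs = 100L,
                         weight_decay = 1e-5, adam_beta1 = 0.9,
                         adam_beta2 = 0.98, negatives_per_plan = 4L,
                         magnitude_low = 0.05, magnitude_high = 0.25,
                         seed = 1L, n_bins = 20L,
                         channels = c(16L, 32L, 32L, 16L), dense_width = 64L,
                         dropout = 0.5, dropout_mode = "channel",
                         leaky_slope = 0.2, dense_act = TRUE,
                         dose_scale = 100, rx_scale = 10, out_scale = 10) {
  cfg <- list(lr_init = lr_init, plateau_factor = plateau_factor,
              plateau_patience = as.integer(plateau_patience),
              plateau_warmup = as.integer(plateau_warmup),
              batch_size = as.integer(batch_size),
              pretrain_epochs = as.integer(pretrain_epochs),
              joint_epochs = as.integer(joint_epochs),
              weight_decay = weight_decay,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              negatives_per_plan = as.integer(negatives_per_plan),
              magnitude_low = magnitude_low, magnitude_high = magnitude_high,
              seed = as.integer(seed), n_bins = as.integer(n_bins),
              channels = as.integer(channels),
              dense_width = as.integer(dense_width), dropout = dropout,
              dropout_mode = dropout_mode,
              leaky_slope = leaky_slope, dense_act = isTRUE(dense_act),
              dose_scale = dose_scale, rx_scale = rx_scale,
              out_scale = out_scale)
  bad <- vapply(cfg[c("lr_init", "plateau_factor", "plateau_patience",
                      "batch_size", "pretrain_epochs", "joint_epochs",
                      "negatives_per_plan")], function(v) any(v <= 0), TRUE)
  if (any(bad)) stop("train_config values must be positive: ",
                     paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  class(cfg) <- "train_config"
  cfg
}

.descriptor_from_config <- function(config, head) {
  network_descriptor(head = head, n_bins = config$n_bins,
                     channels = config$channels,
                     dense_width = config$dense_width,
                     dropout = config$dropout,
                     dropout_mode = config$dropout_mode,
                     leaky_slope = config$leaky_slope,
                     dense_act = config$dense_act,
                     dose_scale = config$dose_scale,
                     rx_scale = config$rx_scale,
                     out_scale = config$out_scale)
}

# Dense tensors for a cohort: anatomy stack, per-fraction doses (Gy),
# total-course doses (Gy), prescriptions, labels, extrapolation factors.
.cohort_tensors <- function(cohort) {
  plans <- cohort$plans
  B <- nrow(plans)
  n_bins <- ncol(cohort$anatomy[[1]])
  anat <- array(unlist(cohort$anatomy, use.names = FALSE),
                dim = c(4L, n_bins, B))
  list(anat = anat,
       rx = plans$prescription,
       dose = t(.plan_dose_matrix(plans)),          # 4 x B, Gy per fraction
       total = t(plan_total_dose(plans)),           # 4 x B, Gy total course
       prior = t(.plan_prior_matrix(plans)),
       ebrt = t(.plan_ebrt_matrix(plans)),
       ratio = plans$n_fractions / plans$fraction_index,
       label = plans$label, B = B)
}

# Plateau LR scheduler state machine (relative improvement threshold 1e-4,
# mirroring the usual reduce-on-plateau semantics).
.plateau_init <- function(lr, factor, patience, warmup = 0L) {
  list(lr = lr, factor = factor, patience = patience,
       warmup = as.integer(warmup), epoch = 0L, best = Inf, stall = 0L)
}

.plateau_update <- function(st, val_loss, min_lr = 1e-7) {
  st$epoch <- st$epoch + 1L
  if (st$epoch <= st$warmup) return(st)
  if (val_loss < st$best * (1 - 1e-4)) {
    st$best <- val_loss
    st$stall <- 0L
  } else {
    st$stall <- st$stall + 1L
    if (st$stall > st$patience) {
      st$lr <- max(st$lr * st$factor, min_lr)
      st$stall <- 0L
    }
  }
  st
}

# Loss/gradient closures -----------------------------------------------------

# Precomputed network inputs for a whole tensor set (inputs are fixed during
# pre-training, so assemble them once).
.dpn_x0 <- function(tens, desc) {
  vec <- matrix(rep(tens$rx, each = 4L), nrow = 4L) / desc$rx_scale
  .make_input(tens$anat, vec, desc$n_bins)
}

.ppn_x0 <- function(tens, desc) {
  .make_input(tens$anat, tens$total / desc$dose_scale, desc$n_bins)
}

# DPN regression loss (scaled units): mean_j || DPN(R_j, A_j) - D_j ||^2.
# x0: prebuilt (2, S, B) input; target in Gy.
.dpn_loss_grad <- function(params, x0, dose_gy, mode = "train") {
  d <- params$descriptor
  B <- dim(x0)[3]
  fw <- .net_forward(params, x0, mode)
  target <- dose_gy / d$out_scale
  resid <- fw$out - target
  loss <- sum(resid^2) / B
  bw <- .net_backward(params, fw$cache, 2 * resid / B)
  list(loss = loss, grads = bw$grads)
}

.dpn_val_loss <- function(params, tens, x0 = .dpn_x0(tens, params$descriptor)) {
  out <- .forward_chunked(params, x0, "eval")
  pred <- matrix(out, nrow = 4L) * params$descriptor$out_scale
  sum(((pred - tens$dose) / params$descriptor$out_scale)^2) / tens$B
}

# PPN label loss: mean_j | PPN(F(D_j), A_j) - Y_j |^2. x0 prebuilt.
.ppn_loss_grad <- function(params, x0, label, mode = "train") {
  B <- dim(x0)[3]
  fw <- .net_forward(params, x0, mode)
  resid <- fw$out - label
  loss <- sum(resid^2) / B
  bw <- .net_backward(params, fw$cache, 2 * resid / B)
  list(loss = loss, grads = bw$grads)
}

.ppn_val_loss <- function(params, tens, x0 = .ppn_x0(tens, params$descriptor)) {
  p <- .forward_chunked(params, x0, "eval")
  mean((p - tens$label)^2)
}

.check_finite_loss <- function(loss, stage, epoch) {
  if (!is.finite(loss)) {
    stop(sprintf("non-finite %s loss at epoch %d -- aborting with diagnostics: loss=%s",
                 stage, epoch, format(loss)), call. = FALSE)
  }
}

#' Pre-train the dose prediction network
#'
#' Minimizes the mean squared error between predicted and approved
#' per-fraction EQD2 quadruples by mini-batch Adam, with a reduce-on-plateau
#' learning-rate schedule driven by the validation loss. The returned
#' parameters are those of the best validation epoch.
#'
#' @param train_cohort,val_cohort `plan_cohort` objects with approved plans
#'   (label 1).
#' @param config a [train_config()].
#' @return list with `params` (best-validation `network_params`), `history`
#'   (data.frame epoch/lr/train_loss/val_loss) and `best_val`.
#' @export
pretrain_dpn <- function(train_cohort, val_cohort, config = train_config()) {
  if (nrow(train_cohort$plans) == 0L || nrow(val_cohort$plans) == 0L) {
    stop("empty training or validation set", call. = FALSE)
  }
  set.seed(config$seed)
  tr <- .cohort_tensors(train_cohort)
  va <- .cohort_tensors(val_cohort)
  params <- init_network(.descriptor_from_config(config, "dpn"))
  x0 <- .dpn_x0(tr, params$descriptor)
  vx0 <- .dpn_x0(va, params$descriptor)
  opt <- .adam_init(params)
  sched <- .plateau_init(config$lr_init, config$plateau_factor,
                         config$plateau_patience, config$plateau_warmup)
  best <- list(val = Inf, params = params)
  hist <- vector("list", config$pretrain_epochs)
  for (ep in seq_len(config$pretrain_epochs)) {
    ord <- sample.int(tr$B)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      lg <- .dpn_loss_grad(params, x0[, , bi, drop = FALSE],
                           tr$dose[, bi, drop = FALSE])
      .check_finite_loss(lg$loss, "DPN", ep)
      st <- .adam_step(params, lg$grads, opt, sched$lr, config$weight_decay,
                       config$adam_beta1, config$adam_beta2)
      params <- st$params; opt <- st$state
      tl <- tl + lg$loss * length(bi)
    }
    vl <- .dpn_val_loss(params, va, vx0)
    .check_finite_loss(vl, "DPN validation", ep)
    if (vl < best$val) best <- list(val = vl, params = params)
    hist[[ep]] <- c(epoch = ep, lr = sched$lr, train_loss = tl / tr$B,
                    val_loss = vl)
    sched <- .plateau_update(sched, vl)
  }
  list(params = best$params, history = as.data.frame(do.call(rbind, hist)),
       best_val = best$val)
}

#' Generate unfavorably perturbed negatives for PPN pre-training
#'
#' Each approved plan is replicated `k` times and perturbed by
#' [perturb_unfavorable()] (OAR doses up, CTV dose down, magnitudes uniform on
#' the configured range), yielding labeled-unapproved plans that share the
#' original anatomy and prescription.
#'
#' @param cohort `plan_cohort` of approved plans.
#' @param k negatives per approved plan (`>= 1`).
#' @param config a [train_config()] supplying the magnitude range.
#' @param seed RNG seed for the perturbation draws.
#' @return `plan_cohort` of `k * nrow` plans, all with label 0.
#' @export
generate_negatives <- function(cohort, k = 4L, config = train_config(),
                               seed = config$seed) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  set.seed(seed)
  rows <- rep(seq_len(nrow(cohort$plans)), times = k)
  rep_cohort <- cohort_subset(cohort, rows)
  rep_cohort$plans <- perturb_unfavorable(rep_cohort$plans,
                                          config$magnitude_low,
                                          config$magnitude_high)
  rep_cohort
}

#' Pre-train the plan-approval probability network
#'
#' Minimizes the squared label loss `|PPN(F(D_j), A_j) - Y_j|^2` on the union
#' of approved plans (label 1) and generated negatives (label 0), where `F`
#' is the total-course extrapolation of [total_course_dose()].
#'
#' @param train_cohort,val_cohort `plan_cohort` objects containing both
#'   labels (positives plus generated negatives).
#' @param config a [train_config()].
#' @return as [pretrain_dpn()].
#' @export
pretrain_ppn <- function(train_cohort, val_cohort, config = train_config()) {
  if (length(unique(train_cohort$plans$label)) < 2L) {
    stop("degenerate labels: PPN pre-training needs both classes", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  tr <- .cohort_tensors(train_cohort)
  va <- .cohort_tensors(val_cohort)
  params <- init_network(.descriptor_from_config(config, "ppn"))
  x0 <- .ppn_x0(tr, params$descriptor)
  vx0 <- .ppn_x0(va, params$descriptor)
  opt <- .adam_init(params)
  sched <- .plateau_init(config$lr_init, config$plateau_factor,
                         config$plateau_patience, config$plateau_warmup)
  best <- list(val = Inf, params = params)
  hist <- vector("list", config$pretrain_epochs)
  for (ep in seq_len(config$pretrain_epochs)) {
    ord <- sample.int(tr$B)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      lg <- .ppn_loss_grad(params, x0[, , bi, drop = FALSE], tr$label[bi])
      .check_finite_loss(lg$loss, "PPN", ep)
      st <- .adam_step(params, lg$grads, opt, sched$lr, config$weight_decay,
                       config$adam_beta1, config$adam_beta2)
      params <- st$params; opt <- st$state
      tl <- tl + lg$loss * length(bi)
    }
    vl <- .ppn_val_loss(params, va, vx0)
    .check_finite_loss(vl, "PPN validation", ep)
    if (vl < best$val) best <- list(val = vl, params = params)
    hist[[ep]] <- c(epoch = ep, lr = sched$lr, train_loss = tl / tr$B,
                    val_loss = vl)
    sched <- .plateau_update(sched, vl)
  }
  list(params = best$params, history = as.data.frame(do.call(rbind, hist)),
       best_val = best$val)
}

# One adversarial PPN (discriminator) gradient: least-squares targets
# PPN(real) -> 1, PPN(generated) -> 0. x_real prebuilt.
.ppn_adv_loss_grad <- function(ppn, anat, x_real, total_gen, mode = "train") {
  d <- ppn$descriptor
  B <- dim(anat)[3]
  x_gen <- .make_input(anat, total_gen / d$dose_scale, d$n_bins)
  fw_r <- .net_forward(ppn, x_real, mode)
  fw_g <- .net_forward(ppn, x_gen, mode)
  loss <- mean((fw_r$out - 1)^2) + mean(fw_g$out^2)
  gr_r <- .net_backward(ppn, fw_r$cache, 2 * (fw_r$out - 1) / B)$grads
  gr_g <- .net_backward(ppn, fw_g$cache, 2 * fw_g$out / B)$grads
  paths <- .tensor_paths(ppn)
  for (nm in names(paths)) {
    gr_r <- .set_tensor(gr_r, paths[[nm]],
                        .get_tensor(gr_r, paths[[nm]]) +
                        .get_tensor(gr_g, paths[[nm]]))
  }
  list(loss = loss, grads = gr_r)
}

# One adversarial DPN (generator) gradient: minimize |1 - PPN(F(DPN(.)))|^2,
# chaining through the frozen PPN and the linear course extrapolation.
# x0: prebuilt DPN input for the batch.
.dpn_adv_loss_grad <- function(dpn, ppn, x0, anat, prior, ebrt, ratio,
                               dpn_mode = "train") {
  dd <- dpn$descriptor; dp <- ppn$descriptor
  B <- dim(x0)[3]
  fw_d <- .net_forward(dpn, x0, dpn_mode)
  pred_gy <- fw_d$out * dd$out_scale                       # 4 x B
  total_gen <- sweep(pred_gy + prior, 2, ratio, `*`) + ebrt
  clamped <- total_gen < 0
  total_gen[clamped] <- 0
  x_gen <- .make_input(anat, total_gen / dp$dose_scale, dp$n_bins)
  fw_p <- .net_forward(ppn, x_gen, "eval")
  loss <- mean((1 - fw_p$out)^2)
  bw_p <- .net_backward(ppn, fw_p$cache, 2 * (fw_p$out - 1) / B,
                        need_dinput = TRUE)
  dtotal <- bw_p$dvec / dp$dose_scale                      # 4 x B
  dtotal[clamped] <- 0
  dpred_gy <- sweep(dtotal, 2, ratio, `*`)
  dout_raw <- dpred_gy * dd$out_scale
  bw_d <- .net_backward(dpn, fw_d$cache, dout_raw)
  list(loss = loss, grads = bw_d$grads, ppn_scores = fw_p$out)
}

#' Adversarial joint training of DPN and PPN
#'
#' Alternates, per mini-batch, one PPN update (least-squares discriminator:
#' approved plans toward probability 1, DPN-generated plans toward 0) and one
#' DPN update (generator: DPN-generated plans toward probability 1 through
#' the frozen PPN), for `joint_epochs` epochs. Each optimizer keeps its own
#' reduce-on-plateau schedule driven by its own pre-training-style validation
#' loss (DPN: dose MSE; PPN: label loss on validation positives plus
#' regenerated validation negatives).
#'
#' Checkpoint selection spans the whole stage including its starting point:
#' the returned DPN is the state with the lowest validation dose MSE, and the
#' returned PPN is the state with the highest mean validation AUC over the
#' four +/- perturbation levels -- the same criterion by which the
#' best-performing model is advanced between stages.
#'
#' @param dpn,ppn pre-trained `network_params`.
#' @param train_cohort `plan_cohort` of approved plans.
#' @param val_cohort `plan_cohort` of approved validation plans.
#' @param config a [train_config()].
#' @return list with `dpn`, `ppn` (best-validation parameters) and `history`.
#' @export
adversarial_train <- function(dpn, ppn, train_cohort, val_cohort,
                              config = train_config()) {
  set.seed(config$seed + 2L)
  tr <- .cohort_tensors(train_cohort)
  va <- .cohort_tensors(val_cohort)
  val_neg <- generate_negatives(val_cohort, config$negatives_per_plan, config,
                                seed = config$seed + 101L)
  va_mix <- .cohort_tensors(cohort_bind(val_cohort, val_neg))
  set.seed(config$seed + 2L)  # negatives used a dedicated stream
  x0_dpn <- .dpn_x0(tr, dpn$descriptor)
  x0_real <- .ppn_x0(tr, ppn$descriptor)
  vx0_d <- .dpn_x0(va, dpn$descriptor)
  vx0_p <- .ppn_x0(va_mix, ppn$descriptor)
  opt_d <- .adam_init(dpn); opt_p <- .adam_init(ppn)
  sch_d <- .plateau_init(config$lr_init, config$plateau_factor,
                         config$plateau_patience, config$plateau_warmup)
  sch_p <- .plateau_init(config$lr_init, config$plateau_factor,
                         config$plateau_patience, config$plateau_warmup)
  ppn_sel_score <- function(p) {
    rep <- perturbation_protocol(p, val_cohort, seed = config$seed + 500L)
    mean(rep$metrics$auc)
  }
  best_d <- list(val = .dpn_val_loss(dpn, va, vx0_d), params = dpn)
  best_p <- list(score = ppn_sel_score(ppn), params = ppn)
  hist <- vector("list", config$joint_epochs)
  init_loss <- NULL
  for (ep in seq_len(config$joint_epochs)) {
    ord <- sample.int(tr$B)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    lp_sum <- ld_sum <- 0
    for (bi in batches) {
      anat <- tr$anat[, , bi, drop = FALSE]
      xd <- x0_dpn[, , bi, drop = FALSE]
      # generated doses for the PPN step (DPN frozen, deterministic)
      pred_gy <- .net_forward(dpn, xd, "eval")$out * dpn$descriptor$out_scale
      total_gen <- sweep(pred_gy + tr$prior[, bi, drop = FALSE], 2,
                         tr$ratio[bi], `*`) + tr$ebrt[, bi, drop = FALSE]
      total_gen[total_gen < 0] <- 0
      lg_p <- .ppn_adv_loss_grad(ppn, anat, x0_real[, , bi, drop = FALSE],
                                 total_gen)
      .check_finite_loss(lg_p$loss, "adversarial PPN", ep)
      st <- .adam_step(ppn, lg_p$grads, opt_p, sch_p$lr, config$weight_decay,
                       config$adam_beta1, config$adam_beta2)
      ppn <- st$params; opt_p <- st$state
      # DPN step against the updated, now frozen, PPN
      lg_d <- .dpn_adv_loss_grad(dpn, ppn, xd, anat,
                                 tr$prior[, bi, drop = FALSE],
                                 tr$ebrt[, bi, drop = FALSE], tr$ratio[bi])
      .check_finite_loss(lg_d$loss, "adversarial DPN", ep)
      st <- .adam_step(dpn, lg_d$grads, opt_d, sch_d$lr, config$weight_decay,
                       config$adam_beta1, config$adam_beta2)
      dpn <- st$params; opt_d <- st$state
      lp_sum <- lp_sum + lg_p$loss * length(bi)
      ld_sum <- ld_sum + lg_d$loss * length(bi)
    }
    ep_loss <- (lp_sum + ld_sum) / tr$B
    if (is.null(init_loss)) init_loss <- max(ep_loss, 1e-8)
    if (ep_loss > 1e3 * init_loss) {
      stop(sprintf("adversarial training diverged at epoch %d (loss %.3g vs initial %.3g)",
                   ep, ep_loss, init_loss), call. = FALSE)
    }
    vl_d <- .dpn_val_loss(dpn, va, vx0_d)
    vl_p <- .ppn_val_loss(ppn, va_mix, vx0_p)
    sc_p <- ppn_sel_score(ppn)
    if (vl_d < best_d$val) best_d <- list(val = vl_d, params = dpn)
    if (sc_p > best_p$score) best_p <- list(score = sc_p, params = ppn)
    hist[[ep]] <- c(epoch = ep, lr_dpn = sch_d$lr, lr_ppn = sch_p$lr,
                    adv_ppn_loss = lp_sum / tr$B, adv_dpn_loss = ld_sum / tr$B,
                    val_dpn_loss = vl_d, val_ppn_loss = vl_p,
                    val_ppn_auc = sc_p)
    sch_d <- .plateau_update(sch_d, vl_d)
    sch_p <- .plateau_update(sch_p, vl_p)
  }
  list(dpn = best_d$params, ppn = best_p$params,
       history = as.data.frame(do.call(rbind, hist)))
}

#' Patient-grouped k-fold split
#'
#' Partitions patients (not plans) into `k` folds of sizes differing by at
#' most one, deterministically under `seed`. Grouping by patient keeps all
#' fractions of one course on the same side of every split.
#'
#' @param patients vector of unique patient identifiers.
#' @param k number of folds (default 4).
#' @param seed RNG seed.
#' @return list of `k` vectors of patient ids (a partition of `patients`).
#' @export
grouped_kfold <- function(patients, k = 4L, seed = 1L) {
  patients <- unique(patients)
  if (length(patients) < k) stop("fewer patients than folds", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(patients)
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  split(shuffled, fold_of)
}

#' Select the best cross-validation fold
#'
#' @param fold_results numeric vector of per-fold validation criteria (larger
#'   is better, e.g. mean AUC over the perturbation levels).
#' @return index of the best fold; ties resolved to the lowest index.
#' @export
select_best_fold <- function(fold_results) {
  if (length(fold_results) == 0L) stop("no fold results", call. = FALSE)
  which.max(fold_results)
}
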