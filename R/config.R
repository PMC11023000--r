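# Experiment configuration, validation and the end-to-end runner.

.default_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    n_patients = 54L,
    sigma_rel = 0.10,
    mode = "fast",
    max_fractions = 5L,
    allow_long_courses = FALSE,
    prescription_set = c(5.5, 6, 7, 7.5, 8),
    ebrt_dose = c(45, 40, 40, 40),
    train = list(lr_init = 5e-4, plateau_factor = 0.1, plateau_patience = 5L,
                 plateau_warmup = 75L,
                 batch_size = 4L, pretrain_epochs = 100L, joint_epochs = 100L,
                 weight_decay = 1e-5, adam_beta1 = 0.9, adam_beta2 = 0.98,
                 negatives_per_plan = 4L,
                 magnitude_low = 0.05, magnitude_high = 0.25, n_bins = 20L,
                 channels = c(16L, 32L, 32L, 16L), dense_width = 64L,
                 dropout = 0.5, dropout_mode = "channel",
                 leaky_slope = 0.2, dense_act = TRUE,
                 dose_scale = 100, rx_scale = 10, out_scale = 10),
    eval = list(levels = c(0.05, 0.10, 0.15, 0.20), k_negatives = 1L,
                threshold = 0.5, sweep_from = 0.6, sweep_to = 1.4,
                sweep_by = 0.05, audit_threshold = 0.10)
  )
}

#' Default experiment configuration
#'
#' The full runnable configuration with every default: study conditions for
#' the synthetic cohort, the training hyperparameters and the evaluation
#' settings. Override fields via `modifyList()` or a YAML file.
#' @return nested configuration list.
#' @export
default_run_config <- function() .default_config()

#' Validate an experiment configuration
#'
#' Checks the configuration (a list or a YAML file path) against the schema:
#' unknown keys are rejected, types and ranges are checked, and courses
#' longer than 5 fractions require the explicit `allow_long_courses` flag.
#'
#' @param config list or path to a YAML file.
#' @return invisible `TRUE` when valid; otherwise an error listing every
#'   violation. Use [config_violations()] to obtain the list without error.
#' @export
validate_config <- function(config) {
  v <- config_violations(config)
  if (length(v)) {
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname validate_config
#' @export
config_violations <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  v <- character()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    v <- c(v, paste("unknown keys:", paste(unknown, collapse = ", ")))
  }
  for (blk in c("train", "eval")) {
    if (!is.null(config[[blk]])) {
      u <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(u)) v <- c(v, paste0("unknown ", blk, " keys: ",
                                      paste(u, collapse = ", ")))
    }
  }
  cfg <- modifyList(def, config[intersect(names(config), names(def))])
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed must be an integer")
  chk(cfg$n_patients >= 2, "n_patients must be >= 2")
  chk(cfg$sigma_rel >= 0 && cfg$sigma_rel <= 0.3, "sigma_rel must be in [0, 0.3]")
  chk(cfg$mode %in% c("fast", "masks"), "mode must be 'fast' or 'masks'")
  chk(all(cfg$prescription_set >= 5.5 - 1e-9) && all(cfg$prescription_set <= 8 + 1e-9),
      "prescriptions must lie in 5.5-8 Gy per fraction")
  chk(length(cfg$ebrt_dose) == 4 && all(cfg$ebrt_dose >= 0),
      "ebrt_dose must be four non-negative values")
  if (cfg$max_fractions > 5L && !isTRUE(cfg$allow_long_courses)) {
    v <- c(v, "max_fractions > 5 requires allow_long_courses: true")
  }
  chk(cfg$train$lr_init > 0, "train.lr_init must be positive")
  chk(cfg$train$batch_size >= 1, "train.batch_size must be >= 1")
  chk(cfg$train$pretrain_epochs >= 1, "train.pretrain_epochs must be >= 1")
  chk(cfg$train$dropout >= 0 && cfg$train$dropout < 1, "train.dropout must be in [0, 1)")
  chk(cfg$train$magnitude_low > 0 &&
        cfg$train$magnitude_low <= cfg$train$magnitude_high &&
        cfg$train$magnitude_high < 1,
      "train perturbation magnitudes must satisfy 0 < low <= high < 1")
  chk(all(cfg$eval$levels > 0 & cfg$eval$levels < 1),
      "eval.levels must be fractions in (0, 1)")
  chk(cfg$eval$sweep_from < cfg$eval$sweep_to, "eval sweep range must increase")
  v
}

# FNV-1a hash of the canonical JSON form of a config (artifact provenance).
config_hash <- function(config) {
  .fnv1a(as.character(jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE)))
}

.train_config_from <- function(cfg) {
  do.call(train_config, c(cfg$train, list(seed = cfg$seed + 1000L)))
}

#' Run a full experiment: simulate, split, train, evaluate
#'
#' Orchestrates the pipeline under a single configuration: generates the
#' synthetic cohort, makes a patient-grouped split (validation and held-out
#' test patients never seen in training), runs the two pre-training stages
#' and the adversarial stage, evaluates the result, and writes all artifacts
#' (cohort, checkpoints, loss histories, metrics JSON) to `out_dir` with a
#' manifest recording the configuration hash. Identical configuration and
#' seed reproduce byte-identical metrics.
#'
#' @param config configuration list (see [default_run_config()]) or YAML path.
#' @param out_dir artifact directory.
#' @return the metrics list, invisibly; artifacts on disk.
#' @export
run_experiment <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  cfg <- modifyList(.default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  log_path <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("resolved config: ",
      as.character(jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE)),
      "\n", sep = "", file = log_path)

  cohort <- build_cohort(cfg$n_patients, seed = cfg$seed,
                         sigma_rel = cfg$sigma_rel, mode = cfg$mode,
                         prescription_set = cfg$prescription_set,
                         ebrt_dose = cfg$ebrt_dose,
                         n_bins = cfg$train$n_bins)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  t1 <- proc.time()[3]; logline("stage simulate: %.1fs", t1 - t0)

  pats <- unique(cohort$plans$patient_id)
  folds <- grouped_kfold(pats, k = 5L, seed = cfg$seed)
  test_cohort <- cohort_patients(cohort, folds[[1]])
  val_cohort <- cohort_patients(cohort, folds[[2]])
  train_cohort <- cohort_patients(cohort, unlist(folds[3:5]))

  tc <- .train_config_from(cfg)
  fit <- brachynet(train_cohort, val_cohort, tc)
  save_checkpoint(fit$dpn, file.path(out_dir, "dpn.json"))
  save_checkpoint(fit$ppn, file.path(out_dir, "ppn.json"))
  save_checkpoint(fit$dpn_pretrained, file.path(out_dir, "dpn_pretrained.json"))
  save_checkpoint(fit$ppn_pretrained, file.path(out_dir, "ppn_pretrained.json"))
  for (nm in names(fit$history)) {
    write.csv(fit$history[[nm]],
              file.path(out_dir, paste0("history_", nm, ".csv")),
              row.names = FALSE)
  }
  t2 <- proc.time()[3]; logline("stage train: %.1fs", t2 - t1)

  rep <- perturbation_protocol(fit, test_cohort, levels = cfg$eval$levels,
                               k_negatives = cfg$eval$k_negatives,
                               seed = cfg$seed + 2000L,
                               threshold = cfg$eval$threshold)
  err <- dpn_relative_error(fit, test_cohort)
  sweep <- oar_sweep(fit, test_cohort, "bladder",
                     seq(cfg$eval$sweep_from, cfg$eval$sweep_to,
                         by = cfg$eval$sweep_by))
  audit <- consistency_audit(cohort, cfg$eval$audit_threshold)
  metrics <- list(
    config_hash = config_hash(cfg),
    dpn_test_relative_error = as.list(err$mean),
    ppn_test_metrics = rep$metrics,
    sweep_bladder = sweep,
    audit_median_variation = if (nrow(audit$pairs)) {
      as.list(apply(audit$variation, 2, median))
    } else NULL,
    n_similar_pairs = nrow(audit$pairs))
  writeLines(jsonlite::toJSON(metrics, digits = NA, auto_unbox = TRUE,
                              dataframe = "columns"),
             file.path(out_dir, "metrics.json"))
  t3 <- proc.time()[3]; logline("stage evaluate: %.1fs", t3 - t2)

  files <- c("cohort/plans.csv", "dpn.json", "ppn.json",
             "dpn_pretrained.json", "ppn_pretrained.json",
             paste0("history_", names(fit$history), ".csv"), "metrics.json")
  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   files = files)
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(metrics)
}

#' Load artifacts of a previous experiment
#'
#' @param dir artifact directory written by [run_experiment()].
#' @return list with `dpn`, `ppn` checkpoints and the `cohort`.
#' @export
load_experiment <- function(dir) {
  for (f in c("dpn.json", "ppn.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("missing artifact %s: run the 'train' stage first", f),
           call. = FALSE)
    }
  }
  if (!file.exists(file.path(dir, "cohort", "plans.csv"))) {
    stop("missing cohort artifacts: run the 'simulate' stage first",
         call. = FALSE)
  }
  list(dpn = load_checkpoint(file.path(dir, "dpn.json")),
       ppn = load_checkpoint(file.path(dir, "ppn.json")),
       cohort = read_cohort(file.path(dir, "cohort")))
}
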