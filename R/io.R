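# Plain-text round-tripping of plan tables, anatomy features, dwell
# positions and structure masks.

#' Write a plan table to CSV
#'
#' Columns follow the exchange schema: `patient_id`, `fraction_index`,
#' `n_fractions`, `prescription_cGy`, the four per-fraction dose columns, the
#' `prior_*` and `ebrt_*` course columns (all doses in Gy), `dose_kind`,
#' `scale` and `label`. Prescription is written in cGy per the clinical
#' convention; all other doses stay in Gy.
#'
#' @param plans plan `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plans_csv <- function(plans, path) {
  out <- plans
  out$prescription_cGy <- round(plans$prescription * 100, 6)
  out$prescription <- NULL
  out$dose_kind <- "EQD2"
  out$scale <- "fraction"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a plan table from CSV
#'
#' Inverse of [write_plans_csv()]: converts `prescription_cGy` back to Gy and
#' validates the schema.
#'
#' @param path CSV path.
#' @return plan `data.frame` in package-internal units (Gy).
#' @export
read_plans_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"prescription_cGy" %in% names(df)) {
    stop("plan CSV missing prescription_cGy column", call. = FALSE)
  }
  df$prescription <- df$prescription_cGy / 100
  df$prescription_cGy <- NULL
  df$dose_kind <- NULL
  df$scale <- NULL
  df$patient_id <- as.character(df$patient_id)
  df$label <- as.integer(df$label)
  need <- c(.dose_cols, .prior_cols, .ebrt_cols)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("plan CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write anatomy features as CSV plus a JSON sidecar
#'
#' The CSV holds the 4 x n histogram matrix (rows CTV, bladder, rectum,
#' sigmoid); the sidecar (`<path>.json`) records bin edges and normalization.
#'
#' @param anatomy `anatomy_features`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_anatomy_csv <- function(anatomy, path) {
  A <- as.matrix(anatomy)
  write.csv(data.frame(structure = rownames(A), A, check.names = FALSE),
            path, row.names = FALSE)
  meta <- list(bin_edges = attr(anatomy, "bin_edges"),
               normalization = attr(anatomy, "normalization"))
  writeLines(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' Read anatomy features written by [write_anatomy_csv()]
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @return `anatomy_features`.
#' @export
read_anatomy_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  dimnames(A) <- list(df$structure, NULL)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    as_anatomy_features(A, meta$bin_edges, meta$normalization)
  } else {
    as_anatomy_features(A)
  }
}

#' Write / read dwell positions (3-column mm CSV)
#' @param dwells m x 3 matrix of dwell coordinates (mm).
#' @param path CSV path.
#' @return `path` invisibly / the dwell matrix.
#' @export
write_dwells_csv <- function(dwells, path) {
  dwells <- as.matrix(dwells)
  colnames(dwells) <- c("x_mm", "y_mm", "z_mm")
  write.csv(as.data.frame(dwells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwells_csv
#' @export
read_dwells_csv <- function(path) {
  m <- as.matrix(read.csv(path))
  if (ncol(m) != 3L || any(!is.finite(m))) {
    stop("dwell CSV must have three finite numeric columns", call. = FALSE)
  }
  colnames(m) <- c("x_mm", "y_mm", "z_mm")
  m
}

#' Write / read a structure mask set as NIfTI volumes
#'
#' One `<name>.nii.gz` file per structure, sharing grid and a diagonal
#' affine built from the voxel size and origin.
#'
#' @param masks a [structure_mask_set()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly / a `structure_mask_set`.
#' @export
write_masks_nifti <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(masks$masks)) {
    img <- RNifti::asNifti(array(as.integer(masks$masks[[s]]),
                                 dim = dim(masks$masks[[s]])),
                           pixdim = masks$voxel_size)
    RNifti::writeNifti(img, file.path(dir, paste0(s, ".nii.gz")))
  }
  meta <- list(voxel_size = masks$voxel_size, origin = masks$origin)
  writeLines(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE),
             file.path(dir, "grid.json"))
  invisible(dir)
}

#' @rdname write_masks_nifti
#' @export
read_masks_nifti <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "grid.json"))
  m <- lapply(setNames(STRUCTURES, STRUCTURES), function(s) {
    img <- RNifti::readNifti(file.path(dir, paste0(s, ".nii.gz")))
    array(as.logical(img > 0), dim = dim(img))
  })
  structure_mask_set(m$ctv, m$bladder, m$rectum, m$sigmoid,
                     meta$voxel_size, meta$origin)
}

#' Write / read a cohort (plan CSV plus per-plan anatomy CSVs)
#'
#' `plans.csv` holds the plan table; `anatomy/plan_<i>.csv` the per-row
#' histograms; `policy.json` (when the cohort carries a hidden synthetic
#' policy) the ground-truth policy; `manifest.json` the inventory.
#'
#' @param cohort `plan_cohort`.
#' @param dir output directory.
#' @return `dir` invisibly / a `plan_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "anatomy"), showWarnings = FALSE, recursive = TRUE)
  write_plans_csv(cohort$plans, file.path(dir, "plans.csv"))
  for (i in seq_along(cohort$anatomy)) {
    write_anatomy_csv(cohort$anatomy[[i]],
                      file.path(dir, "anatomy", sprintf("plan_%05d.csv", i)))
  }
  if (!is.null(cohort$policy)) {
    pol <- cohort$policy
    pol$coef <- list(structure = rownames(pol$coef),
                     c0 = pol$coef[, "c0"], c1 = pol$coef[, "c1"])
    writeLines(jsonlite::toJSON(unclass(pol), digits = NA, auto_unbox = TRUE),
               file.path(dir, "policy.json"))
  }
  manifest <- list(n_plans = nrow(cohort$plans),
                   n_patients = length(unique(cohort$plans$patient_id)),
                   files = c("plans.csv",
                             sprintf("anatomy/plan_%05d.csv",
                                     seq_along(cohort$anatomy))))
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  plans <- read_plans_csv(file.path(dir, "plans.csv"))
  anatomy <- lapply(seq_len(nrow(plans)), function(i) {
    read_anatomy_csv(file.path(dir, "anatomy", sprintf("plan_%05d.csv", i)))
  })
  policy <- NULL
  pj <- file.path(dir, "policy.json")
  if (file.exists(pj)) {
    raw <- jsonlite::fromJSON(pj)
    coef <- cbind(c0 = raw$coef$c0, c1 = raw$coef$c1)
    rownames(coef) <- raw$coef$structure
    policy <- structure(list(coef = coef, sigma_rel = raw$sigma_rel,
                             ctv_sd = raw$ctv_sd, cap = raw$cap),
                        class = "synthetic_policy")
  }
  a1 <- anatomy[[1]]
  plan_cohort(plans, anatomy, attr(a1, "bin_edges"),
              attr(a1, "normalization"), policy)
}
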