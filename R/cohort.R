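# Plan cohort container: a flat plan table plus one anatomy matrix per row.

#' Construct a plan cohort
#'
#' A `plan_cohort` couples a plan table (one row per HDRBT fraction) with the
#' 4 x n distance-histogram anatomy of each row. The plan table carries, in
#' Gy: the per-fraction EQD2 quadruple (`ctv_d90`, `bladder_d2cc`,
#' `rectum_d2cc`, `sigmoid_d2cc`), the summed EQD2 of previously delivered
#' fractions (`prior_*`), the total-course EBRT EQD2 (`ebrt_*`), the
#' prescription per fraction, the course bookkeeping (`n_fractions`,
#' `fraction_index`) and the approval `label`.
#'
#' @param plans plan `data.frame` (schema above).
#' @param anatomy list of 4 x n anatomy matrices, one per plan row.
#' @param bin_edges histogram bin edges (mm).
#' @param normalization `"fraction"` or `"counts"`.
#' @param policy optional hidden `synthetic_policy` used to generate the
#'   cohort (kept for recovery checks).
#' @return list of class `plan_cohort`.
#' @export
plan_cohort <- function(plans, anatomy, bin_edges = default_bin_edges(),
                        normalization = "fraction", policy = NULL) {
  required <- c("patient_id", "fraction_index", "n_fractions", "prescription",
                .dose_cols, .prior_cols, .ebrt_cols, "label")
  missing <- setdiff(required, names(plans))
  if (length(missing)) {
    stop("plan table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(plans) != length(anatomy)) {
    stop("one anatomy matrix is required per plan row", call. = FALSE)
  }
  if (any(plans$fraction_index < 1 | plans$fraction_index > plans$n_fractions)) {
    stop("invalid course context: need 1 <= fraction_index <= n_fractions",
         call. = FALSE)
  }
  structure(list(plans = plans, anatomy = anatomy, bin_edges = bin_edges,
                 normalization = normalization, policy = policy),
            class = "plan_cohort")
}

#' @export
print.plan_cohort <- function(x, ...) {
  cat(sprintf("<plan_cohort: %d plans, %d patients, %d labeled approved>\n",
              nrow(x$plans), length(unique(x$plans$patient_id)),
              sum(x$plans$label == 1)))
  invisible(x)
}

#' Subset a cohort by plan rows
#' @param cohort `plan_cohort`.
#' @param rows integer or logical row index into the plan table.
#' @return `plan_cohort` restricted to `rows` (anatomy kept in step).
#' @export
cohort_subset <- function(cohort, rows) {
  if (is.logical(rows)) rows <- which(rows)
  out <- cohort
  out$plans <- cohort$plans[rows, , drop = FALSE]
  rownames(out$plans) <- NULL
  out$anatomy <- cohort$anatomy[rows]
  out
}

#' Subset a cohort by patient ids
#' @param cohort `plan_cohort`.
#' @param patient_ids patients to keep.
#' @export
cohort_patients <- function(cohort, patient_ids) {
  cohort_subset(cohort, cohort$plans$patient_id %in% patient_ids)
}

#' Concatenate two cohorts sharing binning and normalization
#' @param a,b `plan_cohort` objects.
#' @export
cohort_bind <- function(a, b) {
  stopifnot(identical(a$bin_edges, b$bin_edges),
            identical(a$normalization, b$normalization))
  plan_cohort(rbind(a$plans, b$plans), c(a$anatomy, b$anatomy),
              a$bin_edges, a$normalization, a$policy)
}
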