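#' @useDynLib brachynet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm predict coef quantile median sd setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

#' Structure order used throughout the package
#'
#' All four-element dose quantities are ordered (CTV, bladder, rectum, sigmoid).
#' @export
STRUCTURES <- c("ctv", "bladder", "rectum", "sigmoid")

.oar_idx <- 2:4
.ctv_idx <- 1L

#' Construct a dosimetric quadruple
#'
#' A `dose_quad` holds the four dosimetric measures a physician reviews for an
#' HDR brachytherapy plan: CTV D90% and the D2cc of bladder, rectum and
#' sigmoid, in that fixed order, in Gy. The `scale` flag records whether the
#' values are per-fraction or total-course quantities; `kind` records whether
#' they are physical doses or EQD2.
#'
#' @param ctv,bladder,rectum,sigmoid doses in Gy, all `>= 0`.
#' @param scale `"fraction"` or `"course"`.
#' @param kind `"eqd2"` or `"physical"`.
#' @return a named numeric vector of length 4 with class `dose_quad`.
#' @examples
#' dose_quad(7, 4.5, 3.8, 3.2)
#' @export
dose_quad <- function(ctv, bladder, rectum, sigmoid,
                      scale = c("fraction", "course"),
                      kind = c("eqd2", "physical")) {
  scale <- match.arg(scale)
  kind <- match.arg(kind)
  x <- c(ctv = ctv, bladder = bladder, rectum = rectum, sigmoid = sigmoid)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("dose_quad values must be finite and >= 0", call. = FALSE)
  }
  structure(x, scale = scale, kind = kind, class = "dose_quad")
}

#' @export
print.dose_quad <- function(x, ...) {
  cat(sprintf("<dose_quad: %s %s> ", attr(x, "kind"), attr(x, "scale")))
  cat(paste(sprintf("%s=%.3f", names(x), unclass(x)), collapse = " "), "Gy\n")
  invisible(x)
}

#' Equivalent dose in 2-Gy fractions (linear-quadratic model)
#'
#' Converts a physical dose delivered at `dose_per_fraction` Gy per fraction
#' into the equivalent dose in 2-Gy fractions,
#' `EQD2 = D * (d + alpha_beta) / (2 + alpha_beta)`. The conventional
#' alpha/beta ratios here are 10 Gy for the CTV and 3 Gy for organs at risk.
#'
#' @param total_physical_dose total physical dose D in Gy (`>= 0`); vectorised.
#' @param dose_per_fraction dose per fraction d in Gy (`> 0`).
#' @param alpha_beta tissue alpha/beta ratio in Gy (`> 0`).
#' @return EQD2 in Gy. Equals the input when `dose_per_fraction = 2`.
#' @examples
#' eqd2_from_physical(7, 7, 10)   # single 7 Gy HDR fraction, CTV
#' eqd2_from_physical(2, 2, 3)    # 2 Gy/fx is the EQD2 fixed point
#' @export
eqd2_from_physical <- function(total_physical_dose, dose_per_fraction, alpha_beta) {
  if (any(!is.finite(alpha_beta)) || any(alpha_beta <= 0)) {
    stop("alpha_beta must be positive", call. = FALSE)
  }
  if (any(!is.finite(dose_per_fraction)) || any(dose_per_fraction <= 0)) {
    stop("dose_per_fraction must be positive", call. = FALSE)
  }
  if (any(!is.finite(total_physical_dose)) || any(total_physical_dose < 0)) {
    stop("total_physical_dose must be >= 0", call. = FALSE)
  }
  total_physical_dose * (dose_per_fraction + alpha_beta) / (2 + alpha_beta)
}

#' Course bookkeeping for one HDRBT fraction
#'
#' Records where fraction `i` sits in a course of `N` HDRBT fractions, the
#' summed EQD2 of fractions `1..i-1` and the total-course EQD2 contribution of
#' external-beam radiotherapy.
#'
#' @param n_fractions total number N of HDRBT fractions (1..`max_fractions`).
#' @param fraction_index current fraction index i, `1 <= i <= N`.
#' @param prior_hdr_dose `dose_quad`: sum of per-fraction EQD2 over fractions
#'   `1..i-1` (zero quad when `i = 1`).
#' @param ebrt_dose `dose_quad`: total-course EBRT EQD2.
#' @param max_fractions configurable upper bound on N (default 5).
#' @return list of class `course_context`.
#' @export
course_context <- function(n_fractions, fraction_index,
                           prior_hdr_dose = dose_quad(0, 0, 0, 0, scale = "course"),
                           ebrt_dose = dose_quad(0, 0, 0, 0, scale = "course"),
                           max_fractions = 5L) {
  N <- as.integer(n_fractions); i <- as.integer(fraction_index)
  if (is.na(N) || is.na(i) || i < 1L || i > N || N > max_fractions) {
    stop(sprintf("invalid course context: need 1 <= i <= N <= %d, got i=%s N=%s",
                 max_fractions, fraction_index, n_fractions), call. = FALSE)
  }
  if (i == 1L && any(unclass(prior_hdr_dose) != 0)) {
    stop("prior_hdr_dose must be the zero quad for fraction 1", call. = FALSE)
  }
  structure(list(n_fractions = N, fraction_index = i,
                 prior_hdr_dose = prior_hdr_dose, ebrt_dose = ebrt_dose),
            class = "course_context")
}

#' Total-course EQD2 extrapolation
#'
#' Extrapolates the mean HDRBT dose delivered up to (and including) the
#' current fraction to the whole course and adds the EBRT contribution:
#' `D_total = (N/i) * D_i + (N/i) * D_prior + D_ebrt`, component-wise over the
#' four structures. This is the total-course dose a physician reviews when
#' approving fraction `i` of `N`.
#'
#' @param current `dose_quad` of the current fraction (per-fraction EQD2), or
#'   an `n x 4` matrix of such quads for the vectorised form.
#' @param ctx a [course_context()], or (matrix form) a list with numeric
#'   vectors `n_fractions`, `fraction_index` and `n x 4` matrices
#'   `prior_hdr_dose`, `ebrt_dose`.
#' @return total-course EQD2 as a `dose_quad` (or `n x 4` matrix).
#' @examples
#' ctx <- course_context(1, 1, ebrt_dose = dose_quad(45, 40, 40, 40, scale = "course"))
#' total_course_dose(dose_quad(9, 6, 5, 4), ctx)
#' @export
total_course_dose <- function(current, ctx) {
  if (is.matrix(current)) {
    N <- ctx$n_fractions; i <- ctx$fraction_index
    if (any(i < 1) || any(i > N)) stop("invalid course context: i outside 1..N", call. = FALSE)
    f <- N / i
    out <- f * current + f * ctx$prior_hdr_dose + ctx$ebrt_dose
    colnames(out) <- STRUCTURES
    return(out)
  }
  stopifnot(inherits(ctx, "course_context"))
  if (!is.null(attr(current, "kind")) && attr(current, "kind") != "eqd2") {
    stop("current dose must be EQD2", call. = FALSE)
  }
  if (!is.null(attr(current, "scale")) && attr(current, "scale") != "fraction") {
    stop("current dose must be per-fraction scale", call. = FALSE)
  }
  f <- ctx$n_fractions / ctx$fraction_index
  vals <- f * unclass(current) + f * unclass(ctx$prior_hdr_dose) + unclass(ctx$ebrt_dose)
  structure(setNames(vals, STRUCTURES), scale = "course", kind = "eqd2",
            class = "dose_quad")
}

# internal: pull the n x 4 per-fraction dose matrix out of a plans data.frame
.dose_cols  <- c("ctv_d90", "bladder_d2cc", "rectum_d2cc", "sigmoid_d2cc")
.prior_cols <- paste0("prior_", STRUCTURES)
.ebrt_cols  <- paste0("ebrt_", STRUCTURES)

.plan_dose_matrix  <- function(plans) as.matrix(plans[, .dose_cols,  drop = FALSE])
.plan_prior_matrix <- function(plans) as.matrix(plans[, .prior_cols, drop = FALSE])
.plan_ebrt_matrix  <- function(plans) as.matrix(plans[, .ebrt_cols,  drop = FALSE])

#' Total-course EQD2 for each row of a plan table
#'
#' Applies [total_course_dose()] row-wise to a plan table carrying the
#' per-fraction dose quadruple and its course bookkeeping columns.
#'
#' @param plans a plan `data.frame` (see [read_plans_csv()] for the schema).
#' @return an `n x 4` matrix of total-course EQD2 in Gy, columns
#'   `r paste(STRUCTURES, collapse = ", ")`.
#' @export
plan_total_dose <- function(plans) {
  total_course_dose(.plan_dose_matrix(plans),
                    list(n_fractions = plans$n_fractions,
                         fraction_index = plans$fraction_index,
                         prior_hdr_dose = .plan_prior_matrix(plans),
                         ebrt_dose = .plan_ebrt_matrix(plans)))
}

#' Unfavorable plan perturbation (training negatives)
#'
#' Turns approved plans into synthetic unapproved ones by perturbing each
#' structure's per-fraction EQD2 in the unfavorable direction: organs at risk
#' are scaled up by `(1 + m)`, the CTV down by `(1 - m)`, with `m` drawn
#' independently per structure, uniform on `[magnitude_low, magnitude_high]`.
#' Anatomy, prescription and course bookkeeping are unchanged; the label is
#' set to 0.
#'
#' @param plans plan `data.frame`, all rows with `label == 1`.
#' @param magnitude_low,magnitude_high perturbation range as fractions;
#'   defaults 0.05 and 0.25.
#' @return the perturbed plan `data.frame`, `label` set to 0.
#' @export
perturb_unfavorable <- function(plans, magnitude_low = 0.05, magnitude_high = 0.25) {
  if (!(magnitude_low > 0 && magnitude_low <= magnitude_high && magnitude_high < 1)) {
    stop("need 0 < magnitude_low <= magnitude_high < 1", call. = FALSE)
  }
  if (any(plans$label != 1)) stop("perturb_unfavorable expects approved plans (label 1)", call. = FALSE)
  n <- nrow(plans)
  m <- matrix(runif(4L * n, magnitude_low, magnitude_high), nrow = n)
  fac <- cbind(1 - m[, 1L, drop = FALSE], 1 + m[, 2:4, drop = FALSE])
  out <- plans
  out[, .dose_cols] <- .plan_dose_matrix(plans) * fac
  out$label <- 0L
  out
}

#' Signed scaling perturbation (evaluation negatives)
#'
#' Perturbs the per-fraction HDRBT EQD2 of each structure by
#' `(1 + s * factor)` with sign `s` drawn uniformly from {-1, +1} per
#' structure (or fixed via `signs`). The EBRT and previously delivered parts
#' of the course are unchanged. Used to build the +/-5/10/15/20% unapproved
#' plans of the evaluation protocol.
#'
#' @param plans plan `data.frame`.
#' @param factor_magnitude perturbation magnitude as a fraction in `[0, 1)`;
#'   conventionally 0.05, 0.10, 0.15 or 0.20.
#' @param signs optional fixed sign vector of length 4 (values -1/+1) applied
#'   to every row.
#' @return the perturbed plan `data.frame` with `label = 0`.
#' @export
perturb_scaled <- function(plans, factor_magnitude, signs = NULL) {
  if (!is.finite(factor_magnitude) || factor_magnitude < 0 || factor_magnitude >= 1) {
    stop("factor_magnitude must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(plans)
  s <- if (is.null(signs)) {
    matrix(sample(c(-1, 1), 4L * n, replace = TRUE), nrow = n)
  } else {
    stopifnot(length(signs) == 4L, all(signs %in% c(-1, 1)))
    matrix(signs, nrow = n, ncol = 4L, byrow = TRUE)
  }
  out <- plans
  out[, .dose_cols] <- .plan_dose_matrix(plans) * (1 + s * factor_magnitude)
  out$label <- 0L
  out
}
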