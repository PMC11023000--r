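# Synthetic cohort generator.
#
# Clinical HDRBT plan data are not publicly available, so every stage of the
# pipeline is exercised on simulated cohorts with the statistical structure
# the framework assumes: tandem-and-ovoid-like geometry, approved doses that
# depend smoothly on anatomy through a hidden "physician policy", and ~10%
# case-to-case dosimetric variation among similar anatomies.

#' Geometry configuration for the voxel-mask simulator
#'
#' @param grid_dim voxel grid dimensions (default `c(90, 90, 90)`, 1 mm
#'   voxels; must not exceed 128 per axis).
#' @param voxel_size mm per voxel.
#' @param ctv_semiaxes ranges (mm) for the CTV ellipsoid semi-axes
#'   (`list(x=, y=, z=)`), chosen so CTV volumes fall in roughly 20-130 cm^3.
#' @param gap_range range (mm) of the sampled OAR-to-CTV-boundary gap.
#' @param dwell_spacing spacing of tandem dwell positions (mm).
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(grid_dim = c(90L, 90L, 90L), voxel_size = c(1, 1, 1),
                            ctv_semiaxes = list(x = c(16, 25), y = c(16, 25),
                                                z = c(20, 30)),
                            gap_range = c(2, 25), dwell_spacing = 5) {
  if (any(grid_dim > 128L)) {
    stop("infeasible geometry config: grid_dim exceeds 128 voxels per axis",
         call. = FALSE)
  }
  if (gap_range[1] < 0 || gap_range[2] <= gap_range[1]) {
    stop("infeasible geometry config: bad gap_range", call. = FALSE)
  }
  structure(list(grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
                 ctv_semiaxes = ctv_semiaxes, gap_range = gap_range,
                 dwell_spacing = dwell_spacing),
            class = "geometry_config")
}

.ellipsoid_mask <- function(dims, voxel_size, origin, center, semi) {
  cx <- origin[1] + (seq_len(dims[1]) - 1) * voxel_size[1]
  cy <- origin[2] + (seq_len(dims[2]) - 1) * voxel_size[2]
  cz <- origin[3] + (seq_len(dims[3]) - 1) * voxel_size[3]
  ux <- ((cx - center[1]) / semi[1])^2
  uy <- ((cy - center[2]) / semi[2])^2
  uz <- ((cz - center[3]) / semi[3])^2
  q <- outer(outer(ux, uy, `+`), uz, `+`)
  q <= 1
}

#' Simulate a tandem-and-ovoid anatomy as voxel masks plus dwell positions
#'
#' Draws a randomized ellipsoidal CTV around a straight tandem dwell line
#' (dwells every `dwell_spacing` mm, plus two ovoid dwell clusters at the
#' inferior end), then places bladder (anterior), rectum (posterior) and
#' sigmoid (superior) as deformed ellipsoids offset from the CTV boundary by
#' a random gap sampled from `gap_range`; the OAR masks are carved so that
#' their minimum distance to the CTV boundary equals the sampled gap (within
#' one voxel). Uses the current RNG state.
#'
#' @param config a [geometry_config()].
#' @return list with `masks` (a [structure_mask_set()]), `dwells` (m x 3
#'   matrix, mm) and `gaps` (named sampled gaps, mm).
#' @export
simulate_anatomy <- function(config = geometry_config()) {
  dims <- config$grid_dim; vs <- config$voxel_size
  origin <- -(dims - 1) * vs / 2
  ax <- runif(1, config$ctv_semiaxes$x[1], config$ctv_semiaxes$x[2])
  ay <- runif(1, config$ctv_semiaxes$y[1], config$ctv_semiaxes$y[2])
  az <- runif(1, config$ctv_semiaxes$z[1], config$ctv_semiaxes$z[2])
  ctv <- .ellipsoid_mask(dims, vs, origin, c(0, 0, 0), c(ax, ay, az))

  # tandem dwell line along z through the CTV, ovoid clusters at inferior end
  zmin <- -az * 0.9; zmax <- az * 0.7
  tz <- seq(zmin, zmax, by = config$dwell_spacing)
  dwells <- cbind(0, 0, tz)
  for (sx in c(-12, 12)) {
    dwells <- rbind(dwells, cbind(sx, c(-4, 0, 4), zmin))
  }
  colnames(dwells) <- c("x_mm", "y_mm", "z_mm")

  bmap <- ctv_boundary_distance_map(ctv, vs)
  half_extent <- (dims - 1) * vs / 2
  place_oar <- function(direction, semi_ranges, gap) {
    semi <- vapply(semi_ranges, function(r) runif(1, r[1], r[2]), 0)
    # start with the inner edge just inside the gap shell, back off if empty
    reach <- sum(abs(direction) * c(ax, ay, az))
    for (step in seq(0, 18, by = 3)) {
      center <- direction * (reach + gap + 0.55 * sum(abs(direction) * semi) - step)
      cand <- .ellipsoid_mask(dims, vs, origin, center, semi) &
        bmap >= gap & !ctv
      if (sum(cand) >= 50) return(cand)
    }
    stop("infeasible geometry: OAR placement failed (gap too large for grid)",
         call. = FALSE)
  }
  gaps <- runif(3, config$gap_range[1], config$gap_range[2])
  names(gaps) <- c("bladder", "rectum", "sigmoid")
  # clamp each gap to what the grid can accommodate beyond the CTV surface
  feas <- function(direction, gap) {
    room <- sum(abs(direction) * half_extent) -
      sum(abs(direction) * c(ax, ay, az)) - 6
    if (room < 0.5) {
      stop("infeasible geometry: grid too small for the CTV and gap range",
           call. = FALSE)
    }
    min(gap, room)
  }
  gaps["bladder"] <- feas(c(0, -1, 0), gaps["bladder"])
  gaps["rectum"] <- feas(c(0, 1, 0), gaps["rectum"])
  gaps["sigmoid"] <- feas(c(0, 0, 1), gaps["sigmoid"])
  bladder <- place_oar(c(0, -1, 0),
                       list(c(15, 24), c(10, 18), c(15, 24)), gaps["bladder"])
  rectum <- place_oar(c(0, 1, 0),
                      list(c(10, 16), c(8, 14), c(15, 24)), gaps["rectum"])
  sigmoid <- place_oar(c(0, 0, 1),
                       list(c(10, 18), c(10, 18), c(8, 16)), gaps["sigmoid"])
  masks <- structure_mask_set(ctv, bladder, rectum, sigmoid, vs, origin)
  list(masks = masks, dwells = dwells, gaps = gaps)
}

# Fast mode: draw a parametric (Beta-shaped) distance histogram family for
# one patient; per-fraction anatomies jitter the base parameters slightly.
.sample_patient_geometry <- function(gap_range = c(2, 25)) {
  list(ctv = list(d_max = runif(1, 25, 45), a = runif(1, 1.2, 2.5),
                  b = runif(1, 1.5, 3.0)),
       oar = lapply(setNames(1:3, STRUCTURES[2:4]), function(i) {
         list(gap = runif(1, gap_range[1], gap_range[2]),
              width = runif(1, 15, 40),
              a = runif(1, 1.2, 3.0), b = runif(1, 1.2, 3.0))
       }))
}

.beta_row <- function(lo, width, a, b, edges) {
  u <- pmin(pmax((edges - lo) / width, 0), 1)
  cum <- stats::pbeta(u, a, b)
  cum[length(cum)] <- 1   # clamp out-of-range mass into the last bin
  diff(cum)
}

.features_from_geometry <- function(geom, edges, jitter = TRUE) {
  jit <- function(x, s) if (jitter) x * exp(rnorm(1, 0, s)) else x
  g <- geom$ctv
  rows <- matrix(0, nrow = 4L, ncol = length(edges) - 1L,
                 dimnames = list(STRUCTURES, NULL))
  rows[1, ] <- .beta_row(0, jit(g$d_max, 0.05), jit(g$a, 0.08), jit(g$b, 0.08),
                         edges)
  for (i in 2:4) {
    o <- geom$oar[[STRUCTURES[i]]]
    gap <- if (jitter) max(0.5, o$gap + rnorm(1, 0, 1.5)) else o$gap
    rows[i, ] <- .beta_row(gap, jit(o$width, 0.08), jit(o$a, 0.08),
                           jit(o$b, 0.08), edges)
  }
  as_anatomy_features(rows, edges, "fraction")
}

#' Proximity score of each OAR row
#'
#' Fraction of an OAR's histogram mass within the first four bins (0-20 mm
#' with default binning) -- the anatomy summary the hidden physician policy
#' acts on: organs closer to the CTV receive higher approved D2cc.
#'
#' @param anatomy `anatomy_features` matrix (fraction-normalized rows).
#' @param n_close number of leading bins counted (default 4).
#' @return named numeric vector (bladder, rectum, sigmoid) in `[0, 1]`.
#' @export
proximity_score <- function(anatomy, n_close = 4L) {
  A <- as.matrix(anatomy)
  rs <- rowSums(A)
  p <- rowSums(A[, seq_len(n_close), drop = FALSE]) / rs
  p[2:4]
}

#' Sample a hidden physician policy
#'
#' The policy maps (anatomy proximity, prescription) to the mean approved
#' per-fraction EQD2: for each OAR, `mean = R * min(cap, c0 + c1 * prox)`;
#' for the CTV, `mean = R * (1 + eps)` with per-fraction preference jitter
#' `eps ~ N(0, ctv_sd)`. Per-fraction doses then receive multiplicative
#' lognormal noise with relative spread `sigma_rel` on every structure,
#' emulating the ~10% case-to-case variation observed among similar clinical
#' anatomies. Uses the current RNG state.
#'
#' @param sigma_rel relative dose noise (default 0.10, must be in [0, 0.3]).
#' @param ctv_sd sd of the CTV preference jitter (default 0.03).
#' @param cap upper bound on the OAR mean dose as a fraction of the
#'   prescription (default 0.95).
#' @param intercept_range,slope_range ranges for the per-OAR coefficients
#'   `c0`, `c1`.
#' @return list of class `synthetic_policy` with `coef` (3 x 2 matrix).
#' @export
sample_policy <- function(sigma_rel = 0.10, ctv_sd = 0.03, cap = 0.95,
                          intercept_range = c(0.35, 0.55),
                          slope_range = c(0.35, 0.60)) {
  if (sigma_rel < 0 || sigma_rel > 0.3) {
    stop("sigma_rel must be in [0, 0.3]", call. = FALSE)
  }
  coef <- cbind(c0 = runif(3, intercept_range[1], intercept_range[2]),
                c1 = runif(3, slope_range[1], slope_range[2]))
  rownames(coef) <- STRUCTURES[2:4]
  structure(list(coef = coef, sigma_rel = sigma_rel, ctv_sd = ctv_sd,
                 cap = cap),
            class = "synthetic_policy")
}

#' Mean approved dose quadruple under a policy (no noise)
#' @param policy `synthetic_policy`.
#' @param proximity OAR proximity scores (from [proximity_score()]).
#' @param prescription Gy per fraction.
#' @param eps_ctv CTV preference jitter (default 0: the deterministic mean).
#' @return named 4-vector, Gy per fraction (EQD2).
#' @export
policy_mean_dose <- function(policy, proximity, prescription, eps_ctv = 0) {
  oar <- prescription * pmin(policy$cap,
                             policy$coef[, "c0"] + policy$coef[, "c1"] * proximity)
  setNames(c(prescription * (1 + eps_ctv), oar), STRUCTURES)
}

#' Simulate one approved treatment course
#'
#' Applies the hidden policy fraction by fraction: the approved dose is the
#' policy mean times per-structure lognormal noise (`sigma_rel`); course
#' bookkeeping (`prior_*` running sums, shared EBRT quadruple) is filled in.
#' Uses the current RNG state.
#'
#' @param policy `synthetic_policy`.
#' @param anatomies list of `anatomy_features`, one per fraction.
#' @param prescription Gy per fraction.
#' @param ebrt_dose length-4 total-course EBRT EQD2 (Gy).
#' @param patient_id identifier stamped on the rows.
#' @return plan `data.frame` with `length(anatomies)` approved rows.
#' @export
simulate_course <- function(policy, anatomies, prescription,
                            ebrt_dose = c(45, 40, 40, 40),
                            patient_id = "p1") {
  N <- length(anatomies)
  s <- policy$sigma_rel
  sdlog <- sqrt(log(1 + s^2))
  prior <- numeric(4L)
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    prox <- proximity_score(anatomies[[i]])
    eps <- rnorm(1, 0, policy$ctv_sd)
    mu <- policy_mean_dose(policy, prox, prescription, eps)
    noise <- if (s > 0) rlnorm(4L, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, 4L)
    dose <- mu * noise
    rows[[i]] <- data.frame(patient_id = patient_id, fraction_index = i,
                            n_fractions = N, prescription = prescription,
                            ctv_d90 = dose[1], bladder_d2cc = dose[2],
                            rectum_d2cc = dose[3], sigmoid_d2cc = dose[4],
                            prior_ctv = prior[1], prior_bladder = prior[2],
                            prior_rectum = prior[3], prior_sigmoid = prior[4],
                            ebrt_ctv = ebrt_dose[1], ebrt_bladder = ebrt_dose[2],
                            ebrt_rectum = ebrt_dose[3], ebrt_sigmoid = ebrt_dose[4],
                            label = 1L, stringsAsFactors = FALSE)
    prior <- prior + dose
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort
#'
#' End to end: per patient draws a fraction count (1-5, weighted toward 4-5
#' as in multi-fraction T&O courses), a prescription from a discrete clinical
#' set within 5.5-8 Gy per fraction, per-fraction anatomies, and approved
#' doses from one shared hidden policy. In `"fast"` mode anatomies come from
#' the parametric histogram family; in `"masks"` mode voxel masks and dwell
#' positions are simulated and featurized through the full distance-transform
#' path (one mask set per patient, reused across its fractions).
#'
#' @param n_patients number of patients.
#' @param seed RNG seed (all draws are deterministic given the seed).
#' @param sigma_rel per-structure relative dose noise (default 0.10).
#' @param mode `"fast"` or `"masks"`.
#' @param prescription_set discrete prescriptions to sample from (Gy/fx).
#' @param ebrt_dose shared total-course EBRT EQD2 quadruple (Gy).
#' @param policy optional fixed `synthetic_policy`; drawn if `NULL`.
#' @param geometry a [geometry_config()] (masks mode).
#' @param n_bins histogram bins.
#' @param fraction_weights sampling weights for N = 1..5.
#' @return `plan_cohort` with the hidden `policy` attached.
#' @export
build_cohort <- function(n_patients, seed = 1L, sigma_rel = 0.10,
                         mode = c("fast", "masks"),
                         prescription_set = c(5.5, 6, 7, 7.5, 8),
                         ebrt_dose = c(45, 40, 40, 40), policy = NULL,
                         geometry = geometry_config(), n_bins = 20L,
                         fraction_weights = c(0.05, 0.10, 0.20, 0.35, 0.30)) {
  mode <- match.arg(mode)
  set.seed(seed)
  edges <- default_bin_edges(n_bins)
  if (is.null(policy)) policy <- sample_policy(sigma_rel = sigma_rel)
  policy$sigma_rel <- sigma_rel
  all_plans <- vector("list", n_patients)
  all_anat <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    N <- sample(1:5, 1, prob = fraction_weights)
    rx <- prescription_set[sample.int(length(prescription_set), 1L)]
    if (mode == "fast") {
      geom <- .sample_patient_geometry(geometry$gap_range)
      anat <- lapply(seq_len(N), function(i) {
        .features_from_geometry(geom, edges, jitter = TRUE)
      })
    } else {
      sim <- simulate_anatomy(geometry)
      A <- build_anatomy(sim$masks, sim$dwells, "fraction", edges)
      anat <- rep(list(A), N)
    }
    all_plans[[p]] <- simulate_course(policy, anat, rx, ebrt_dose, pid)
    all_anat <- c(all_anat, anat)
  }
  plan_cohort(do.call(rbind, all_plans), all_anat, edges, "fraction", policy)
}
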