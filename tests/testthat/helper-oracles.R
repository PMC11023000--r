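# Independent brute-force oracles used to pin down the fast implementations.

# O(V * F) exhaustive distance map: distance of every voxel to the nearest
# feature voxel (mm), anisotropic voxel sizes supported.
oracle_distance_map <- function(feature, voxel_size = c(1, 1, 1)) {
  d <- dim(feature)
  fidx <- which(feature, arr.ind = TRUE)
  out <- array(Inf, dim = d)
  all_idx <- which(array(TRUE, dim = d), arr.ind = TRUE)
  fx <- sweep(fidx - 1, 2, voxel_size, `*`)
  ax <- sweep(all_idx - 1, 2, voxel_size, `*`)
  for (k in seq_len(nrow(fx))) {
    dk <- sqrt((ax[, 1] - fx[k, 1])^2 + (ax[, 2] - fx[k, 2])^2 +
               (ax[, 3] - fx[k, 3])^2)
    out[all_idx] <- pmin(out[all_idx], dk)
  }
  out
}

# O(n^2) pairwise concordance AUC: P(score+ > score-) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random small binary mask guaranteed non-empty and non-full.
random_mask <- function(dims, p = 0.3) {
  m <- array(runif(prod(dims)) < p, dim = dims)
  if (!any(m)) m[ceiling(prod(dims) / 2)] <- TRUE
  if (all(m)) m[1] <- FALSE
  m
}

# Tiny deterministic cohort for training plumbing tests.
tiny_cohort <- function(n_patients = 8, seed = 5, sigma_rel = 0.05) {
  build_cohort(n_patients, seed = seed, sigma_rel = sigma_rel)
}
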