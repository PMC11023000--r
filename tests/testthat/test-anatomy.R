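test_that("CTV distance histogram bins nearest-dwell distances correctly", {
  m <- array(FALSE, c(10, 10, 10))
  m[2, 2, 2] <- TRUE
  # voxel center (origin 0): world (1, 1, 1) mm -> dwell exactly there
  h <- ctv_distance_histogram(m, matrix(c(1, 1, 1), 1))
  expect_equal(h[1], 1L)
  expect_equal(sum(h), 1L)
  # three voxels at hand-computed distances 2.5, 7.5, 55.5 -> bins 1, 2, 12
  m2 <- array(FALSE, c(60, 5, 5))
  m2[1, 1, 1] <- TRUE; m2[6, 1, 1] <- TRUE; m2[54, 1, 1] <- TRUE
  dw <- matrix(c(-2.5, 0, 0), 1)  # voxels at x = 0, 5, 53
  h2 <- ctv_distance_histogram(m2, dw)
  expect_equal(which(h2 > 0), c(1L, 2L, 12L))
  expect_equal(sum(h2), 3L)
  # clamp: voxel 250 mm away lands in bin 20
  m3 <- array(FALSE, c(2, 2, 2)); m3[1, 1, 1] <- TRUE
  h3 <- ctv_distance_histogram(m3, matrix(c(250, 0, 0), 1))
  expect_equal(h3[20], 1L)
  expect_error(ctv_distance_histogram(array(FALSE, c(2, 2, 2)), matrix(0, 1, 3)),
               "empty")
})

test_that("CTV distance histogram equals a brute-force oracle on random scenes", {
  set.seed(10)
  for (rep in 1:20) {
    dims <- sample(4:9, 3, replace = TRUE)
    m <- random_mask(dims)
    dw <- matrix(runif(9, -5, max(dims) + 5), ncol = 3)
    h <- ctv_distance_histogram(m, dw)
    xyz <- which(m, arr.ind = TRUE) - 1
    dmin <- apply(xyz, 1, function(v) min(sqrt(colSums((t(dw) - v)^2))))
    edges <- default_bin_edges()
    b <- pmin(pmax(findInterval(dmin, edges), 1L), 20L)
    expect_equal(h, tabulate(b, 20L))
  }
})

test_that("boundary distance map is exact against the all-pairs oracle", {
  set.seed(11)
  m0 <- array(FALSE, c(9, 9, 9)); m0[3:6, 3:6, 3:6] <- TRUE
  bm0 <- ctv_boundary_distance_map(m0)
  b0 <- boundary_voxels(m0)
  expect_true(all(bm0[b0] == 0))
  # single-voxel CTV: the voxel is its own boundary; 3-4-5 triangle
  m1 <- array(FALSE, c(8, 8, 8)); m1[1, 1, 1] <- TRUE
  bm1 <- ctv_boundary_distance_map(m1)
  expect_equal(bm1[4, 5, 1], 5)
  for (rep in 1:50) {
    dims <- sample(3:12, 3, replace = TRUE)
    m <- random_mask(dims)
    bm <- ctv_boundary_distance_map(m)
    oracle <- oracle_distance_map(boundary_voxels(m))
    expect_equal(bm, oracle, tolerance = 1e-9)
  }
  # anisotropic voxels
  m <- random_mask(c(7, 6, 5))
  expect_equal(ctv_boundary_distance_map(m, c(1, 2, 3.5)),
               oracle_distance_map(boundary_voxels(m), c(1, 2, 3.5)),
               tolerance = 1e-9)
  expect_error(ctv_boundary_distance_map(array(TRUE, c(3, 3, 3)) & FALSE), "empty")
})

test_that("OAR histogram restricts the boundary map to organ voxels", {
  m <- array(FALSE, c(20, 20, 20)); m[8:12, 8:12, 8:12] <- TRUE
  bm <- ctv_boundary_distance_map(m)
  # OAR voxels on the CTV boundary -> all mass in bin 1
  oar1 <- boundary_voxels(m)
  h1 <- oar_distance_histogram(oar1, bm)
  expect_equal(h1[1], sum(oar1))
  expect_equal(sum(h1), sum(oar1))
  # toy map values {1, 6, 12, 101} -> bins 1, 2, 3, 20
  fake_map <- array(0, c(2, 2, 2))
  fake_map[1:4] <- c(1, 6, 12, 101)
  oar <- array(FALSE, c(2, 2, 2)); oar[1:4] <- TRUE
  h2 <- oar_distance_histogram(oar, fake_map)
  expect_equal(which(h2 > 0), c(1L, 2L, 3L, 20L))
  expect_error(oar_distance_histogram(array(FALSE, c(2, 2, 2)), fake_map), "empty")
  expect_error(oar_distance_histogram(oar, array(0, c(3, 3, 3))), "grids differ")
})

test_that("build_anatomy stacks normalized rows invariant to dwell order and translation", {
  set.seed(12)
  dims <- c(24, 24, 24)
  ctv <- array(FALSE, dims); ctv[10:15, 10:15, 10:15] <- TRUE
  bl <- array(FALSE, dims); bl[10:14, 4:8, 10:14] <- TRUE
  re <- array(FALSE, dims); re[10:14, 17:21, 10:14] <- TRUE
  si <- array(FALSE, dims); si[10:14, 10:14, 18:22] <- TRUE
  ms <- structure_mask_set(ctv, bl, re, si)
  dw <- cbind(runif(5, 10, 14), runif(5, 10, 14), runif(5, 10, 14))
  A <- build_anatomy(ms, dw)
  expect_equal(dim(A), c(4L, 20L))
  expect_equal(unname(rowSums(A)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(A >= 0))
  # counts mode conserves voxel counts
  Ac <- build_anatomy(ms, dw, "counts")
  expect_equal(unname(rowSums(Ac)),
               as.numeric(c(sum(ctv), sum(bl), sum(re), sum(si))))
  # dwell permutation invariance
  expect_equal(unclass(build_anatomy(ms, dw[sample(5), ])), unclass(A))
  # rigid translation of the whole scene (shift masks by one voxel + dwells by 1 mm)
  shift <- function(m) { s <- array(FALSE, dim(m)); s[-1, , ] <- m[-dims[1], , ]; s }
  ms2 <- structure_mask_set(shift(ctv), shift(bl), shift(re), shift(si))
  A2 <- build_anatomy(ms2, dw + matrix(c(1, 0, 0), nrow(dw), 3, byrow = TRUE))
  expect_equal(unclass(A2), unclass(A), tolerance = 1e-12)
})

test_that("histogram similarity is the scaled Frobenius distance", {
  set.seed(13)
  A <- matrix(runif(80), 4)
  expect_equal(histogram_similarity(A, A), 0)
  expect_equal(histogram_similarity(A, 2 * A), 1 / 3, tolerance = 1e-12)
  B <- matrix(runif(80), 4)
  manual <- sqrt(sum((A - B)^2)) / (sqrt(sum(A^2)) + sqrt(sum(B^2)))
  expect_equal(histogram_similarity(A, B), manual, tolerance = 1e-12)
  expect_equal(histogram_similarity(A, B), histogram_similarity(B, A))
  expect_error(histogram_similarity(0 * A, 0 * A), "undefined")
})
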