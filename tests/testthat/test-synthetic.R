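test_that("fast cohorts are reproducible with plausible structure", {
  a <- build_cohort(10, seed = 50)
  b <- build_cohort(10, seed = 50)
  expect_identical(a$plans, b$plans)
  expect_identical(a$anatomy, b$anatomy)
  c2 <- build_cohort(10, seed = 51)
  expect_false(identical(a$plans, c2$plans))
  n <- nrow(a$plans)
  expect_gte(n, 10); expect_lte(n, 50)
  expect_true(all(a$plans$label == 1))
  expect_true(all(a$plans$prescription >= 5.5 & a$plans$prescription <= 8))
  expect_true(all(a$plans$fraction_index <= a$plans$n_fractions))
  expect_true(all(a$plans$n_fractions <= 5))
  # anatomy rows are fraction-normalized
  expect_equal(unname(rowSums(a$anatomy[[1]])), rep(1, 4), tolerance = 1e-9)
})

test_that("zero-noise courses equal the policy means and bookkeeping sums up", {
  set.seed(52)
  pol <- sample_policy(sigma_rel = 0)
  pol$ctv_sd <- 0
  geom <- brachynet:::.sample_patient_geometry()
  anat <- replicate(3, brachynet:::.features_from_geometry(
    geom, default_bin_edges(), jitter = FALSE), simplify = FALSE)
  course <- simulate_course(pol, anat, prescription = 7,
                            ebrt_dose = c(45, 40, 40, 40), patient_id = "X")
  prox <- proximity_score(anat[[1]])
  mu <- policy_mean_dose(pol, prox, 7)
  expect_equal(course$ctv_d90, rep(mu[["ctv"]], 3), tolerance = 1e-12)
  expect_equal(course$bladder_d2cc, rep(mu[["bladder"]], 3), tolerance = 1e-12)
  # prior columns are running sums of delivered fractions
  expect_equal(course$prior_ctv, c(0, mu[["ctv"]], 2 * mu[["ctv"]]),
               tolerance = 1e-12)
  # Eq-style identity: total at i = N equals sum of fractions + EBRT
  tot <- plan_total_dose(course)
  expect_equal(unname(tot[3, "ctv"]), 3 * mu[["ctv"]] + 45, tolerance = 1e-12)
})

test_that("dose noise reproduces the configured coefficient of variation", {
  co <- build_cohort(150, seed = 53, sigma_rel = 0.10)
  # CV of the OAR dose around the policy mean: regress out proximity first
  pol <- co$policy
  prox <- t(vapply(co$anatomy, proximity_score, numeric(3)))
  mu <- co$plans$prescription *
    pmin(pol$cap, pol$coef["bladder", "c0"] + pol$coef["bladder", "c1"] * prox[, 1])
  ratio <- co$plans$bladder_d2cc / mu
  cv <- sd(ratio) / mean(ratio)
  expect_gt(cv, 0.10 * 0.8)
  expect_lt(cv, 0.10 * 1.2)
})

test_that("hidden policy coefficients are recoverable by regression", {
  co <- build_cohort(170, seed = 54, sigma_rel = 0.05)
  pol <- co$policy
  prox <- t(vapply(co$anatomy, proximity_score, numeric(3)))
  for (k in 1:3) {
    oar <- c("bladder_d2cc", "rectum_d2cc", "sigmoid_d2cc")[k]
    y <- co$plans[[oar]] / co$plans$prescription
    fitk <- lm(y ~ prox[, k])
    est <- unname(coef(fitk))
    expect_equal(est[1], pol$coef[k, "c0"], tolerance = 0.08)
    expect_equal(est[2], pol$coef[k, "c1"], tolerance = 0.15)
  }
  # zero proximity coefficient -> dose independent of anatomy
  pol0 <- pol; pol0$coef[, "c1"] <- 0
  m1 <- policy_mean_dose(pol0, c(0.1, 0.1, 0.1), 7)
  m2 <- policy_mean_dose(pol0, c(0.9, 0.9, 0.9), 7)
  expect_equal(m1[2:4], m2[2:4])
  # monotonicity: closer OAR (higher proximity) -> higher mean dose
  m3 <- policy_mean_dose(pol, c(0.2, 0.2, 0.2), 7)
  m4 <- policy_mean_dose(pol, c(0.6, 0.6, 0.6), 7)
  expect_true(all(m4[2:4] >= m3[2:4]))
})

test_that("mask-mode anatomy meets its geometric contract", {
  cfgeo <- geometry_config(grid_dim = c(80L, 80L, 80L))
  set.seed(55)
  vols <- numeric(8)
  for (i in 1:8) {
    sim <- simulate_anatomy(cfgeo)
    vols[i] <- sum(sim$masks$masks$ctv) / 1000  # cm^3 at 1 mm voxels
    bmap <- ctv_boundary_distance_map(sim$masks$masks$ctv)
    for (s in c("bladder", "rectum", "sigmoid")) {
      gap <- sim$gaps[[s]]
      dmin <- min(bmap[sim$masks$masks[[s]]])
      expect_gte(dmin, gap - 1e-9)
      expect_lte(dmin, gap + 1.8)  # within one voxel diagonal of the shell
    }
    expect_true(nrow(sim$dwells) > 5)
  }
  expect_true(all(vols > 20 & vols < 130))
  # deterministic under seed
  set.seed(56); s1 <- simulate_anatomy(cfgeo)
  set.seed(56); s2 <- simulate_anatomy(cfgeo)
  expect_identical(s1$masks$masks$ctv, s2$masks$masks$ctv)
  expect_error(geometry_config(grid_dim = c(200L, 80L, 80L)), "infeasible")
})

test_that("masks-mode cohorts flow through the distance-transform path", {
  co <- build_cohort(2, seed = 57, mode = "masks",
                     geometry = geometry_config(grid_dim = c(96L, 96L, 96L)))
  expect_true(all(vapply(co$anatomy, function(a) all(rowSums(a) > 0.999), TRUE)))
  expect_equal(dim(co$anatomy[[1]]), c(4L, 20L))
})
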