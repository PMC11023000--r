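test_that("EQD2 conversion matches the linear-quadratic closed form", {
  # hand-evaluated: 7 * (7 + 10) / (2 + 10)
  expect_equal(eqd2_from_physical(7, 7, 10), 7 * 17 / 12, tolerance = 1e-12)
  expect_equal(eqd2_from_physical(0, 5, 3), 0)
  # 2 Gy/fraction is the fixed point for any alpha/beta
  for (ab in c(0.5, 3, 10, 25)) {
    expect_equal(eqd2_from_physical(2, 2, ab), 2, tolerance = 1e-12)
    expect_equal(eqd2_from_physical(37.5, 2, ab), 37.5, tolerance = 1e-12)
  }
  set.seed(1)
  for (i in 1:100) {
    D <- runif(1, 0, 100); d <- runif(1, 0.5, 10); ab <- runif(1, 0.5, 20)
    expect_equal(eqd2_from_physical(D, d, ab), D * (d + ab) / (2 + ab),
                 tolerance = 1e-12)
  }
})

test_that("EQD2 is monotone in dose per fraction and rejects bad input", {
  d <- seq(0.5, 10, by = 0.5)
  v <- eqd2_from_physical(30, d, 3)
  expect_true(all(diff(v) > 0))
  expect_error(eqd2_from_physical(10, 2, -3), "alpha_beta")
  expect_error(eqd2_from_physical(-1, 2, 3), "total_physical_dose")
  expect_error(eqd2_from_physical(10, 0, 3), "dose_per_fraction")
})

test_that("total-course extrapolation reproduces hand-computed examples", {
  ebrt <- dose_quad(45, 40, 40, 40, scale = "course")
  ctx1 <- course_context(1, 1, ebrt_dose = ebrt)
  expect_equal(unclass(total_course_dose(dose_quad(9, 6, 5, 4), ctx1)),
               c(ctv = 54, bladder = 46, rectum = 45, sigmoid = 44),
               ignore_attr = TRUE)
  ctx2 <- course_context(5, 2, prior_hdr_dose = dose_quad(9, 6, 5, 4, scale = "course"),
                         ebrt_dose = ebrt)
  expect_equal(unclass(total_course_dose(dose_quad(9, 6, 5, 4), ctx2)),
               c(ctv = 90, bladder = 70, rectum = 65, sigmoid = 60),
               ignore_attr = TRUE)
})

test_that("total-course dose is linear and fraction-index invariant for equal fractions", {
  set.seed(2)
  for (rep in 1:20) {
    N <- sample(1:5, 1); i <- sample(seq_len(N), 1)
    mk <- function() matrix(runif(4, 0, 10), 1)
    a <- mk(); b <- mk(); prior <- mk(); ebrt <- mk()
    ctx <- list(n_fractions = N, fraction_index = i,
                prior_hdr_dose = prior, ebrt_dose = ebrt)
    lhs <- total_course_dose(a + b, ctx)
    rhs <- total_course_dose(a, ctx) +
      total_course_dose(b, list(n_fractions = N, fraction_index = i,
                                prior_hdr_dose = 0 * prior, ebrt_dose = 0 * ebrt))
    expect_equal(as.vector(lhs), as.vector(rhs), tolerance = 1e-12)
    # identical fraction dose d: total is N*d + EBRT independent of i
    d <- runif(4, 2, 9)
    ctx_i <- list(n_fractions = N, fraction_index = i,
                  prior_hdr_dose = matrix((i - 1) * d, 1), ebrt_dose = ebrt)
    expect_equal(as.vector(total_course_dose(matrix(d, 1), ctx_i)),
                 N * d + as.vector(ebrt), tolerance = 1e-12)
  }
})

test_that("course context enforces 1 <= i <= N <= cap", {
  expect_error(course_context(6, 1), "invalid course context")
  expect_error(course_context(3, 4), "invalid course context")
  expect_error(course_context(3, 0), "invalid course context")
  expect_silent(course_context(6, 6, max_fractions = 8))
  expect_silent(course_context(2, 2,
                               prior_hdr_dose = dose_quad(1, 1, 1, 1, scale = "course")))
  expect_error(course_context(2, 1,
                              prior_hdr_dose = dose_quad(1, 1, 1, 1, scale = "course")),
               "zero quad")
})

test_that("unfavorable perturbation moves OARs up and CTV down within range", {
  co <- tiny_cohort()
  plans <- co$plans
  set.seed(3)
  out <- perturb_unfavorable(plans)
  expect_true(all(out$label == 0))
  orig <- as.matrix(plans[, c("ctv_d90", "bladder_d2cc", "rectum_d2cc", "sigmoid_d2cc")])
  pert <- as.matrix(out[, c("ctv_d90", "bladder_d2cc", "rectum_d2cc", "sigmoid_d2cc")])
  ratio <- pert / orig
  expect_true(all(ratio[, 1] >= 0.75 - 1e-12 & ratio[, 1] <= 0.95 + 1e-12))
  expect_true(all(ratio[, 2:4] >= 1.05 - 1e-12 & ratio[, 2:4] <= 1.25 + 1e-12))
  # anatomy, prescription, bookkeeping untouched
  expect_identical(out$prescription, plans$prescription)
  expect_identical(out$prior_ctv, plans$prior_ctv)
  # forced magnitude via degenerate range
  one <- plans[1, ]
  f <- perturb_unfavorable(one, 0.25, 0.2500000001)
  expect_equal(f$bladder_d2cc, one$bladder_d2cc * 1.25, tolerance = 1e-6)
  expect_equal(f$ctv_d90, one$ctv_d90 * 0.75, tolerance = 1e-6)
  expect_error(perturb_unfavorable(out), "approved")
  expect_error(perturb_unfavorable(plans, 0.3, 0.2), "magnitude")
})

test_that("signed scaling perturbation hits the exact factors", {
  co <- tiny_cohort()
  one <- co$plans[3, ]
  up <- perturb_scaled(one, 0.20, signs = c(1, 1, 1, 1))
  expect_equal(up$ctv_d90, one$ctv_d90 * 1.2)
  expect_equal(up$sigmoid_d2cc, one$sigmoid_d2cc * 1.2)
  same <- perturb_scaled(one, 0)
  expect_equal(same$bladder_d2cc, one$bladder_d2cc)
  expect_equal(same$label, 0L)
  # EBRT/prior components of the course untouched
  expect_equal(up$ebrt_ctv, one$ebrt_ctv)
  expect_equal(up$prior_bladder, one$prior_bladder)
  expect_error(perturb_scaled(one, 1.2), "factor_magnitude")
  # mean absolute relative change equals the factor exactly (sign = +/-1)
  set.seed(4)
  many <- do.call(rbind, replicate(300, perturb_scaled(co$plans, 0.15),
                                   simplify = FALSE))
  base <- do.call(rbind, replicate(300, co$plans, simplify = FALSE))
  relch <- abs(many$rectum_d2cc - base$rectum_d2cc) / base$rectum_d2cc
  expect_equal(mean(relch), 0.15, tolerance = 1e-9)
})

test_that("perturbation magnitudes are uniform on the configured range", {
  co <- tiny_cohort()
  plans <- co$plans[rep(1, 2500), ]
  plans$label <- 1L
  set.seed(6)
  out <- perturb_unfavorable(plans)
  m <- out$bladder_d2cc / plans$bladder_d2cc - 1
  ks <- suppressWarnings(stats::ks.test(m, "punif", 0.05, 0.25))
  expect_gt(ks$p.value, 0.01)
})
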