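test_that("squared distance is the usual CRM criterion, tied across gamma", {
  expect_identical(squared_distance(0.3, 0.3), 0)
  expect_equal(squared_distance(0.2, 0.3), 0.01)
  # the motivating tie: equidistant estimates score identically
  expect_equal(squared_distance(0.2, 0.3), squared_distance(0.4, 0.3))
})

test_that("CIBP divergence matches its closed form and breaks the tie", {
  # symmetric case a = 1: exact rational values
  expect_equal(cibp_divergence(0.2, 0.3, a = 1), 1 / 16)
  expect_equal(cibp_divergence(0.4, 0.3, a = 1), 1 / 24)
  # at a = 1 the more toxic of two equidistant estimates wins (more variance)
  expect_lt(cibp_divergence(0.4, 0.3, 1), cibp_divergence(0.2, 0.3, 1))
  # at a = 0.5 the ordering flips: overly toxic doses penalized more
  expect_identical(cibp_divergence(0.3, 0.3, 0.5), 0)
  expect_equal(cibp_divergence(0.2, 0.3, 0.5), 0.01 / 0.32)
  expect_equal(cibp_divergence(0.4, 0.3, 0.5),
               0.01 / (0.4^0.5 * 0.6^1.5), tolerance = 1e-12)
  expect_lt(cibp_divergence(0.2, 0.3, 0.5), cibp_divergence(0.4, 0.3, 0.5))
  expect_error(cibp_divergence(0.2, 0.3, a = 2), "asymmetry")
  expect_error(cibp_divergence(0.2, 0.3, a = 0), "asymmetry")
})

test_that("CIBP divergence blows up at the boundaries", {
  expect_identical(cibp_divergence(0, 0.3, 1), Inf)
  expect_identical(cibp_divergence(1, 0.3, 1), Inf)
  expect_identical(cibp_abs_divergence(0, 0.3, 0.5), Inf)
  # and monotonically so near the boundaries (beyond any interior
  # stationary point)
  for (a in c(0.3, 1, 1.5)) {
    p_lo <- c(1e-6, 1e-4, 1e-3)
    expect_true(all(diff(cibp_divergence(p_lo, 0.3, a)) < 0))
    p_hi <- c(0.999, 0.9999, 0.999999)
    expect_true(all(diff(cibp_divergence(p_hi, 0.3, a)) > 0))
  }
})

test_that("CIBP divergence is unimodal with its zero at the target", {
  p <- seq(0.001, 0.999, by = 1e-3)
  for (a in c(0.1, 0.3, 0.5, 1.0, 1.5)) {
    v <- cibp_divergence(p, 0.3, a)
    expect_true(all(v >= 0))
    left <- v[p <= 0.3]
    right <- v[p >= 0.3]
    expect_true(all(diff(left) <= 0))
    expect_true(all(diff(right) >= 0))
  }
})

test_that("a = 1 gives logit symmetry of the divergence", {
  set.seed(421)
  for (i in seq_len(1000)) {
    gamma <- runif(1, 0.05, 0.45)
    t <- runif(1, 0, 2)
    p1 <- plogis(qlogis(gamma) - t)
    p2 <- plogis(qlogis(gamma) + t)
    expect_equal(cibp_divergence(p1, gamma, 1), cibp_divergence(p2, gamma, 1),
                 tolerance = 1e-10)
  }
})

test_that("absolute-distance variant matches its closed form", {
  expect_identical(cibp_abs_divergence(0.3, 0.3, 1), 0)
  expect_equal(cibp_abs_divergence(0.2, 0.3, 1), 0.625)
  expect_equal(cibp_abs_divergence(0.4, 0.3, 1), 0.1 / 0.24)
})

test_that("Aitchison distance is the squared logit difference", {
  expect_identical(aitchison_distance(0.3, 0.3), 0)
  expect_identical(aitchison_distance(0.5, 0.5), 0)
  # frozen from (log(0.25) - log(3/7))^2 evaluated independently
  expect_equal(aitchison_distance(0.2, 0.3), 0.2905172, tolerance = 1e-6)
  expect_error(aitchison_distance(0, 0.3), "\\(0, 1\\)")
  expect_error(aitchison_distance(0.2, 1), "\\(0, 1\\)")
})

test_that("asymmetry calibration equalizes the interval ends and has the
           squared-distance limit", {
  # theta -> 0 limit is 2 * gamma
  for (gamma in c(0.20, 0.25, 0.30))
    expect_equal(asymmetry_from_interval(gamma, 1e-8), 2 * gamma,
                 tolerance = 1e-6)
  # closed form at a wide interval, frozen from direct evaluation
  expect_equal(asymmetry_from_interval(0.25, 0.245), 0.2572142,
               tolerance = 1e-6)
  # round trip: the calibrated a equalizes the divergence at gamma +/- theta
  set.seed(99)
  for (i in seq_len(200)) {
    gamma <- runif(1, 0.1, 0.45)
    theta <- runif(1, 0.01, 0.95 * min(gamma, 1 - gamma))
    a <- asymmetry_from_interval(gamma, theta)
    expect_gt(a, 0); expect_lt(a, 2)
    expect_equal(cibp_divergence(gamma - theta, gamma, a),
                 cibp_divergence(gamma + theta, gamma, a),
                 tolerance = 1e-10)
  }
  expect_error(asymmetry_from_interval(0.3, 0.3), "theta")
  expect_error(asymmetry_from_interval(0.3, 0), "theta")
})

test_that("smaller a than the calibrated value prefers the safer dose", {
  set.seed(7)
  for (i in seq_len(200)) {
    gamma <- runif(1, 0.1, 0.45)
    eps <- runif(1, 0.02, 0.9 * min(gamma, 1 - gamma))
    a_star <- asymmetry_from_interval(gamma, eps)
    a_lo <- a_star * runif(1, 0.2, 0.9)
    a_hi <- a_star + (2 - a_star) * runif(1, 0.1, 0.8)
    expect_lt(cibp_divergence(gamma - eps, gamma, a_lo),
              cibp_divergence(gamma + eps, gamma, a_lo))
    expect_gt(cibp_divergence(gamma - eps, gamma, a_hi),
              cibp_divergence(gamma + eps, gamma, a_hi))
  }
})

test_that("EWOC loss is piecewise linear with asymmetric weights", {
  expect_identical(ewoc_loss(0.33, 0.33, 0.25), 0)
  expect_equal(ewoc_loss(0.43, 0.33, 0.25), 0.075)
  expect_equal(ewoc_loss(0.23, 0.33, 0.25), 0.025)
  # overdosing costs (1 - alpha)/alpha times underdosing at equal distance
  expect_equal(ewoc_loss(0.43, 0.33, 0.25) / ewoc_loss(0.23, 0.33, 0.25), 3)
})

test_that("BLRM interval loss follows the loss table", {
  expect_identical(blrm_loss(0.30), 0)
  expect_identical(blrm_loss(0.10), 1)
  expect_identical(blrm_loss(0.70), 2)
  expect_identical(blrm_loss(0.50), 1)
  # right-open convention with p = 1 in the last interval
  expect_identical(blrm_loss(0.26), 0)
  expect_identical(blrm_loss(1), 2)
  expect_identical(blrm_loss(0), 1)
  expect_error(blrm_loss_table(lower = c(0, 0.3), upper = c(0.2, 1),
                               loss = c(1, 0)), "partition")
})

test_that("beta-interval motivation: the wider posterior near the target
           holds more mass in the indifference window", {
  # P{Beta(4,6) in (0.25, 0.35)} > P{Beta(2,8) in (0.25, 0.35)}: equal means
  # squared distance, but the distribution centred at 0.4 is more likely to
  # be near the 0.3 target than the one centred at 0.2
  mass <- function(a, b) pbeta(0.35, a, b) - pbeta(0.25, a, b)
  expect_gt(mass(4, 6), mass(2, 8))
})

test_that("criterion_spec validates and dispatches", {
  expect_warning(criterion_spec("squared", gamma = 0.6), "unusual")
  expect_error(criterion_spec("cibp", gamma = 0.3), "asymmetry")
  spec <- criterion_spec("cibp", gamma = 0.3, a = 1)
  expect_equal(criterion_value(spec, c(0.2, 0.4)), c(1 / 16, 1 / 24))
  ew <- criterion_spec("ewoc", gamma = 0.33, alpha = 0.25)
  expect_equal(criterion_value(ew, 0.43), 0.075)
  expect_equal(criterion_value(ew, 0.43, alpha = 0.5), 0.05)
})
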