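test_that("TR schedule plateaus then climbs to its cap", {
  expect_equal(tr_alpha(5), 0.25)
  expect_equal(tr_alpha(9), 0.25)
  expect_equal(tr_alpha(10), 0.30)
  expect_equal(tr_alpha(14), 0.50)
  expect_equal(tr_alpha(20), 0.50)
  expect_error(tr_alpha(1), "at least 2")
})

test_that("TDFB bound grows with the DLT-free count", {
  expect_equal(tdfb_alpha(1, 0, 0.25, S = 10), 0.25)
  expect_equal(tdfb_alpha(11, 5, 0.25, S = 10), 0.375)
  expect_equal(tdfb_alpha(21, 0, 0.25, S = 10), 0.50)   # cap
  # nondecreasing in the number of DLT-free patients
  a <- sapply(0:10, function(d) tdfb_alpha(11, 10 - d, 0.25, S = 10))
  expect_true(all(diff(a) >= 0))
  expect_error(tdfb_alpha(5, 6, 0.25, S = 10), "exceed")
  expect_error(tdfb_alpha(5, 1, 0.25, S = 0), "positive")
})

test_that("no-skipping clips to one above the highest dose tried", {
  h <- trial_history(doses_given = 1L, n_enrolled = 3L)
  expect_identical(apply_no_skip(3L, h), 2L)
  expect_identical(apply_no_skip(1L, h), 1L)
  h2 <- trial_history(doses_given = c(1L, 2L), n_enrolled = 6L)
  expect_identical(apply_no_skip(2L, h2), 2L)
  expect_identical(apply_no_skip(1L, trial_history()), 1L)
})

test_that("final MTD selection is the squared-distance argmin with low ties", {
  expect_identical(select_mtd(point_mass_state(c(0.10, 0.24, 0.41)), 0.25), 2L)
  expect_identical(select_mtd(point_mass_state(c(0.2, 0.4)), 0.3), 1L)
  expect_identical(select_mtd(point_mass_state(c(0.1, 0.3, 0.5)), 0.3), 2L)
})

test_that("every design picks an exact-target dose on a point-mass
           posterior", {
  gamma <- 0.25
  st <- point_mass_state(c(0.1, gamma, 0.6))
  h <- trial_history(doses_given = c(1L, 2L, 3L), n_enrolled = 9L)
  model <- power_model(c(0.1, 0.25, 0.6))
  lmod <- logistic2_model(qlogis(c(0.1, 0.25, 0.6)))
  designs <- list(
    crm_design(model, gamma),
    cibp_design(model, gamma, a = 0.5),
    cibp_design(model, gamma, a = 0.5, use_plugin = TRUE),
    ewoc_design(lmod, gamma),
    tr_design(lmod, gamma),
    tdfb_design(lmod, gamma),
    blrm_design(lmod, gamma,
                blrm_loss_table(c(0, 0.2, 0.31, 0.6), c(0.2, 0.31, 0.6, 1),
                                c(1, 0, 1, 2)))
  )
  for (d in designs)
    expect_identical(next_dose(d, st, h), 2L)
  # CRM(M) demands toxicity strictly below the target, so it steps off an
  # exact-target dose; just below the target it selects it like the others
  expect_identical(next_dose(crm_m_design(model, gamma), st, h), 1L)
  st_below <- point_mass_state(c(0.1, gamma - 1e-3, 0.6))
  expect_identical(next_dose(crm_m_design(model, gamma), st_below, h), 2L)
})

test_that("design/criterion consistency is enforced", {
  model <- power_model(c(0.2, 0.3, 0.4))
  expect_error(design_spec("CRM", model, criterion_spec("cibp", 0.3, a = 1)),
               "requires a criterion")
  expect_error(design_spec("CIBP", model, criterion_spec("squared", 0.3)),
               "requires a criterion")
})

test_that("plug-in CIBP at a = 2*gamma allocates like the CRM almost
           always", {
  # the equivalence is approximate: the divergence denominator peaks at the
  # target but is not symmetric about it, so near-ties (and toxicity
  # estimates close to the boundaries, where the denominator collapses) can
  # flip the argmin; agreement away from those configurations is the claim
  set.seed(2026)
  gamma <- 0.25
  n_checked <- 0; n_agree <- 0
  while (n_checked < 1000) {
    m <- sample(3:6, 1)
    probs <- sort(runif(m, 0.01, 0.8))
    if (any(diff(probs) <= 0)) next
    sq <- squared_distance(probs, gamma)
    best2 <- sort(sq)[1:2]
    if (diff(best2) <= 1e-3) next    # exact ties excluded outright
    n_checked <- n_checked + 1
    st <- point_mass_state(probs)
    h <- trial_history(doses_given = seq_len(m), n_enrolled = 3L * m)
    model <- power_model(sort(runif(m, 0.05, 0.95)))
    crm <- next_dose(crm_design(model, gamma), st, h)
    cibp <- next_dose(cibp_design(model, gamma, a = 2 * gamma,
                                  use_plugin = TRUE), st, h)
    n_agree <- n_agree + (cibp == crm)
  }
  expect_gte(n_agree / n_checked, 0.97)
})

test_that("the CIBP-selected dose is nondecreasing in a on a fixed
           posterior", {
  st <- update_posterior(everolimus_cohort1_state(n_nodes = 1001),
                         observations(rep(2L, 3L), c(1L, 0L, 0L)))
  h <- trial_history(doses_given = c(1L, 2L), n_enrolled = 6L, n_dlt = 1L,
                     last_cohort_dlt = 0L)  # isolate the criterion ordering
  model <- everolimus_model()
  picks <- sapply(c(0.1, 0.25, 0.3, 0.4, 0.5, 0.65), function(a)
    next_dose(cibp_design(model, 0.3, a = a), st, h))
  expect_true(all(diff(picks) >= 0))
})

test_that("EWOC at alpha = 0.5 allocates like the absolute distance", {
  set.seed(11)
  gamma <- 0.3
  lmod <- logistic2_model(1:4)
  for (i in seq_len(200)) {
    probs <- sort(runif(4, 0.02, 0.9))
    if (any(diff(probs) <= 0)) next
    st <- point_mass_state(probs)
    h <- trial_history(doses_given = 1:4, n_enrolled = 12L)
    ew <- next_dose(ewoc_design(lmod, gamma, alpha = 0.5), st, h)
    expect_identical(ew, which.min(abs(probs - gamma)))
    # and the loss itself is half the absolute distance
    expect_equal(ewoc_loss(probs, gamma, 0.5), abs(probs - gamma) / 2)
  }
})

test_that("CRM(M) only allocates below the estimated target, falling back
           to the lowest dose", {
  model <- power_model(c(0.1, 0.2, 0.3, 0.45))
  d <- crm_m_design(model, 0.25)
  h <- trial_history(doses_given = 1:4, n_enrolled = 12L)
  st <- point_mass_state(c(0.05, 0.18, 0.26, 0.5))
  # dose 3 is the unrestricted argmin but sits above target: dose 2 wins
  expect_identical(next_dose(crm_design(model, 0.25), st, h), 3L)
  expect_identical(next_dose(d, st, h), 2L)
  # all doses above target: fall back to the lowest dose
  st_tox <- point_mass_state(c(0.3, 0.4, 0.5, 0.6))
  expect_identical(next_dose(d, st_tox, h), 1L)
})

test_that("constraints: start lowest, never skip, coherent after toxicity", {
  model <- everolimus_model()
  d <- crm_design(model, 0.3)
  st <- point_mass_state(c(0.05, 0.1, 0.31))
  # empty history: dose 1 regardless of the scores
  expect_identical(next_dose(d, st, trial_history()), 1L)
  # dose 3 is the argmin but only dose 1 was tried: clipped to 2
  h1 <- trial_history(doses_given = 1L, n_enrolled = 3L)
  expect_identical(next_dose(d, st, h1), 2L)
  # coherent: a DLT in the last cohort blocks escalation from dose 2
  h2 <- trial_history(doses_given = c(1L, 2L), n_enrolled = 6L, n_dlt = 1L,
                      last_cohort_dlt = 1L)
  expect_identical(next_dose(d, st, h2), 2L)
  # without coherence the same state escalates
  d_free <- crm_design(model, 0.3,
                       constraints = escalation_constraint(coherent = FALSE))
  expect_identical(next_dose(d_free, st, h2), 3L)
})
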