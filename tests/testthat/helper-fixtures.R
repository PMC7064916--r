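# shared fixtures for the test suite

everolimus_model <- function() {
  fx <- everolimus_fixture()
  power_model(fx$skeleton, fx$prior_mean, fx$prior_var)
}

# posterior after the first Everolimus cohort (3 non-DLTs at dose 1)
everolimus_cohort1_state <- function(n_nodes = NULL, range_sd = 8) {
  st <- init_posterior(everolimus_model(), n_nodes = n_nodes,
                       range_sd = range_sd)
  update_posterior(st, observations(rep(1L, 3L), c(0L, 0L, 0L)))
}

# independent skeleton oracle: solve each indifference-interval step with
# uniroot on beta instead of the closed-form recursion
skeleton_oracle <- function(m, idx, gamma, h) {
  s <- numeric(m); s[idx] <- gamma
  if (idx < m) for (k in idx:(m - 1)) {
    b <- uniroot(function(b) s[k]^exp(b) - (gamma - h), c(-20, 20),
                 tol = 1e-14)$root
    s[k + 1] <- uniroot(function(x) x^exp(b) - (gamma + h),
                        c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  if (idx > 1) for (k in idx:2) {
    b <- uniroot(function(b) s[k]^exp(b) - (gamma + h), c(-20, 20),
                 tol = 1e-14)$root
    s[k - 1] <- uniroot(function(x) x^exp(b) - (gamma - h),
                        c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  s
}
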