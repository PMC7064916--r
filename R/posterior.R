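#' Grid-quadrature posteriors
#'
#' The posterior over the model parameter(s) is represented by a fixed grid
#' of nodes with log-weights, updated by multiplying in Bernoulli likelihood
#' terms and renormalizing (all in log space with max-subtraction). For the
#' 1-D power model the default is 2001 nodes spanning the prior mean plus or
#' minus 8 prior standard deviations; for the 2-D logistic model, a 201x201
#' product grid. Deterministic quadrature makes every design decision exactly
#' reproducible and lets tests compare against brute-force refinements.
#'
#' @name posterior
NULL

#' Observation set
#'
#' Per-patient dose assignments and binary DLT outcomes, in administration
#' order.
#'
#' @param dose Integer vector of dose indices.
#' @param tox Binary vector (0/1 or logical) of DLT outcomes.
#' @return A `data.frame` of class `observations` with columns `dose`, `tox`.
#' @export
observations <- function(dose = integer(0), tox = integer(0)) {
  dose <- as.integer(dose)
  tox <- as.integer(tox)
  if (length(dose) != length(tox))
    stop("`dose` and `tox` must have equal length", call. = FALSE)
  if (length(tox) && (any(is.na(tox)) || any(!tox %in% c(0L, 1L))))
    stop("`tox` must be binary (0/1)", call. = FALSE)
  if (length(dose) && (any(is.na(dose)) || any(dose < 1L)))
    stop("`dose` must contain positive dose indices", call. = FALSE)
  structure(data.frame(dose = dose, tox = tox),
            class = c("observations", "data.frame"))
}

#' Initialize a posterior state from a model prior
#'
#' @param model A [power_model()] or [logistic2_model()].
#' @param n_nodes Number of quadrature nodes (per dimension for the 2-D
#'   logistic model). Defaults: 2001 (1-D), 201 (per dimension, 2-D).
#' @param range_sd Half-range of the grid in prior standard deviations
#'   (marginal standard deviations for the 2-D model).
#' @return An object of class `posterior_state` holding the nodes, normalized
#'   log-weights, and precomputed log toxicity probabilities per dose.
#' @export
init_posterior <- function(model, n_nodes = NULL, range_sd = 8) {
  if (inherits(model, "power_model")) {
    if (is.null(n_nodes)) n_nodes <- 2001L
    if (n_nodes < 2L) stop("`n_nodes` must be at least 2", call. = FALSE)
    sd <- sqrt(model$prior_var)
    nodes <- seq(model$prior_mean - range_sd * sd,
                 model$prior_mean + range_sd * sd, length.out = n_nodes)
    log_prior <- stats::dnorm(nodes, model$prior_mean, sd, log = TRUE)
    # log psi_i(beta) = exp(beta) * log(s_i); exact even where psi under- or
    # overflows on the probability scale
    log_psi <- outer(log(model$skeleton), exp(nodes))
    log_1m_psi <- log_minus_expm1(log_psi)
  } else if (inherits(model, "logistic2_model")) {
    if (is.null(n_nodes)) n_nodes <- 201L
    if (n_nodes < 2L) stop("`n_nodes` must be at least 2", call. = FALSE)
    sds <- sqrt(diag(model$prior_cov))
    g1 <- seq(model$prior_mean[1] - range_sd * sds[1],
              model$prior_mean[1] + range_sd * sds[1], length.out = n_nodes)
    g2 <- seq(model$prior_mean[2] - range_sd * sds[2],
              model$prior_mean[2] + range_sd * sds[2], length.out = n_nodes)
    nodes <- as.matrix(expand.grid(beta1 = g1, beta2 = g2))
    log_prior <- dmvnorm2_log(nodes, model$prior_mean, model$prior_cov)
    eta <- outer(model$dose_values, nodes[, 2]) +
      matrix(nodes[, 1], nrow = length(model$dose_values),
             ncol = nrow(nodes), byrow = TRUE)
    log_psi <- stats::plogis(eta, log.p = TRUE)
    log_1m_psi <- stats::plogis(-eta, log.p = TRUE)
  } else {
    stop("`model` must be a power_model or logistic2_model", call. = FALSE)
  }
  lw <- log_prior - log_sum_exp(log_prior)
  structure(list(model = model, nodes = nodes, log_weights = lw,
                 log_psi = log_psi, log_1m_psi = log_1m_psi),
            class = "posterior_state")
}

#' Degenerate (point-mass) posterior at given toxicity probabilities
#'
#' A one-node `posterior_state` whose per-dose toxicity probabilities are
#' given directly. Useful for exploring allocation rules deterministically
#' and for unit tests; it bypasses any parametric model.
#'
#' @param probs Vector of toxicity probabilities (one per dose), strictly
#'   inside (0, 1).
#' @return A `posterior_state`.
#' @export
point_mass_state <- function(probs) {
  check_prob(probs, "probs")
  structure(list(model = NULL, nodes = 0,
                 log_weights = 0,
                 log_psi = matrix(log(probs), ncol = 1),
                 log_1m_psi = matrix(log1p(-probs), ncol = 1)),
            class = "posterior_state")
}

#' Update a posterior state with observed outcomes
#'
#' Multiplies the node weights by the Bernoulli likelihood of all
#' observations and renormalizes; the result does not depend on the order of
#' observations, and updating with two batches equals one joint update.
#'
#' @param state A `posterior_state`.
#' @param obs An [observations()] set (may be empty: the state is returned
#'   unchanged).
#' @return The updated `posterior_state`.
#' @export
update_posterior <- function(state, obs) {
  stopifnot(inherits(state, "posterior_state"))
  if (!inherits(obs, "observations")) obs <- do.call(observations, as.list(obs))
  if (nrow(obs) == 0L) return(state)
  m <- nrow(state$log_psi)
  if (any(obs$dose > m))
    stop("observation dose index exceeds the number of doses", call. = FALSE)
  n_i <- tabulate(obs$dose, nbins = m)
  t_i <- tabulate(obs$dose[obs$tox == 1L], nbins = m)
  ll <- 0
  for (i in which(n_i > 0L))
    ll <- ll + t_i[i] * state$log_psi[i, ] +
      (n_i[i] - t_i[i]) * state$log_1m_psi[i, ]
  lw <- state$log_weights + ll
  norm <- log_sum_exp(lw)
  if (!is.finite(norm))
    stop("posterior mass underflowed to zero: the data are impossible under ",
         "every grid node; widen the grid or check the observations",
         call. = FALSE)
  state$log_weights <- lw - norm
  state
}

#' Posterior mean toxicity probability
#'
#' \eqn{\hat p_i = E[\psi(d_i, \beta) \mid \mathrm{data}]} by quadrature.
#'
#' @param state A `posterior_state`.
#' @param dose Dose index, or `NULL` for all doses.
#' @return Probability (vector if `dose` is `NULL`).
#' @export
posterior_mean_prob <- function(state, dose = NULL) {
  stopifnot(inherits(state, "posterior_state"))
  w <- exp(state$log_weights)
  out <- as.vector(exp(state$log_psi) %*% w)
  if (is.null(dose)) out else out[dose]
}

#' Posterior expectation of a function of the toxicity probability
#'
#' \eqn{E[g(\psi(d_i, \beta)) \mid \mathrm{data}]} by quadrature. Nodes with
#' zero posterior weight are ignored; if `g` returns a non-finite value on a
#' node with positive weight the non-finite value propagates, with a
#' diagnostic attribute.
#'
#' @param state A `posterior_state`.
#' @param dose Dose index.
#' @param g Vectorized function of a probability.
#' @return A single numeric value (possibly `Inf`).
#' @export
posterior_expected <- function(state, dose, g) {
  stopifnot(inherits(state, "posterior_state"))
  w <- exp(state$log_weights)
  keep <- w > 0
  gv <- g(exp(state$log_psi[dose, keep]))
  if (any(!is.finite(gv))) {
    out <- Inf
    attr(out, "n_nonfinite") <- sum(!is.finite(gv))
    return(out)
  }
  sum(w[keep] * gv)
}

# log of the posterior-expected CIBP divergence for every dose, computed
# entirely in log space: the expectation can exceed double-precision range
# (and diverges outright under an untruncated prior before the first DLT is
# observed), but its logarithm is finite on the grid and preserves the
# ordering that the argmin needs.
cibp_log_scores <- function(state, gamma, a, squared = TRUE) {
  lw <- state$log_weights
  m <- nrow(state$log_psi)
  vapply(seq_len(m), function(i) {
    lad <- log(abs(exp(state$log_psi[i, ]) - gamma))
    lg <- log_cibp_kernel(lad, state$log_psi[i, ], state$log_1m_psi[i, ],
                          a, squared = squared)
    log_sum_exp(lw + lg)
  }, numeric(1))
}

#' Export a posterior snapshot to JSON
#'
#' Writes nodes, weights and posterior mean probabilities for audit.
#'
#' @param state A `posterior_state`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
posterior_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "posterior_state"))
  obj <- list(
    n_nodes = if (is.matrix(state$nodes)) nrow(state$nodes) else length(state$nodes),
    posterior_mean_prob = posterior_mean_prob(state),
    log_weight_range = range(state$log_weights)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.posterior_state <- function(x, ...) {
  nn <- if (is.matrix(x$nodes)) nrow(x$nodes) else length(x$nodes)
  cat("<posterior_state>", nrow(x$log_psi), "doses,", nn, "nodes\n")
  cat("  posterior mean prob:",
      paste(sprintf("%.3f", posterior_mean_prob(x)), collapse = " "), "\n")
  invisible(x)
}

# --- numeric helpers -------------------------------------------------------

log_sum_exp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log(1 - exp(lp)) for lp <= 0, stable at both ends
log_minus_expm1 <- function(lp) {
  out <- lp
  small <- lp < -0.6931472  # exp(lp) < 1/2: log1p is accurate
  out[small] <- log1p(-exp(lp[small]))
  out[!small] <- log(-expm1(lp[!small]))
  out
}

# bivariate normal log density on rows of x
dmvnorm2_log <- function(x, mean, cov) {
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(x) - mean)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}
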