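#' Dose-toxicity working models
#'
#' Two standard working models for binary dose-limiting toxicity (DLT):
#' the one-parameter power model \eqn{\psi(d, \beta) = d^{\exp(\beta)}} on
#' standardized doses (the skeleton values), and the two-parameter logistic
#' model \eqn{\psi(d, \beta_1, \beta_2) = \mathrm{expit}(\beta_1 + \beta_2 d)}.
#'
#' @name dose_models
NULL

#' One-parameter power model toxicity probability
#'
#' \eqn{d^{\exp(\beta)}}: strictly increasing in the standardized dose `d`,
#' decreasing in `beta`.
#'
#' @param d Standardized dose in (0, 1) (a skeleton value).
#' @param beta Model parameter.
#' @return Toxicity probability in (0, 1).
#' @examples
#' power_prob(0.3, log(2))  # 0.09
#' @export
power_prob <- function(d, beta) {
  check_prob(d, "d")
  d^exp(beta)
}

#' Two-parameter logistic model toxicity probability
#'
#' @param d Dose covariate (any real).
#' @param beta1,beta2 Intercept and slope.
#' @return Toxicity probability.
#' @export
logistic2_prob <- function(d, beta1, beta2) {
  stats::plogis(beta1 + beta2 * d)
}

#' Power model specification
#'
#' A skeleton of prior DLT probabilities (doubling as standardized doses)
#' with a normal prior on the parameter `beta`.
#'
#' @param skeleton Strictly increasing vector of prior DLT probabilities
#'   in (0, 1).
#' @param prior_mean,prior_var Mean and variance of the normal prior on
#'   `beta`; the default N(0, 1.34) is the usual operational prior for this
#'   model.
#' @return An object of class `power_model`.
#' @export
power_model <- function(skeleton, prior_mean = 0, prior_var = 1.34) {
  if (!is.numeric(skeleton) || length(skeleton) < 2L)
    stop("`skeleton` must be a numeric vector of length >= 2", call. = FALSE)
  check_prob(skeleton, "skeleton")
  if (any(diff(skeleton) <= 0))
    stop("`skeleton` must be strictly increasing", call. = FALSE)
  if (!is.numeric(prior_var) || prior_var <= 0)
    stop("`prior_var` must be positive", call. = FALSE)
  structure(list(skeleton = as.numeric(skeleton),
                 prior_mean = prior_mean, prior_var = prior_var),
            class = "power_model")
}

#' Two-parameter logistic model specification
#'
#' @param dose_values Ordered dose covariate values, one per dose level.
#'   A common choice (and the package default elsewhere) is the logit of a
#'   skeleton.
#' @param prior_mean Length-2 prior mean of (beta1, beta2).
#' @param prior_cov 2x2 symmetric positive-definite prior covariance.
#' @return An object of class `logistic2_model`.
#' @export
logistic2_model <- function(dose_values,
                            prior_mean = c(0, 1),
                            prior_cov = diag(c(4, 1))) {
  if (!is.numeric(dose_values) || length(dose_values) < 2L ||
      any(diff(dose_values) <= 0))
    stop("`dose_values` must be a strictly increasing numeric vector",
         call. = FALSE)
  if (length(prior_mean) != 2L) stop("`prior_mean` must have length 2",
                                     call. = FALSE)
  prior_cov <- as.matrix(prior_cov)
  if (!all(dim(prior_cov) == c(2L, 2L)) ||
      max(abs(prior_cov - t(prior_cov))) > 1e-12 ||
      any(eigen(prior_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("`prior_cov` must be 2x2 symmetric positive definite", call. = FALSE)
  structure(list(dose_values = as.numeric(dose_values),
                 prior_mean = as.numeric(prior_mean), prior_cov = prior_cov),
            class = "logistic2_model")
}

n_doses <- function(model) {
  if (inherits(model, "power_model")) length(model$skeleton)
  else length(model$dose_values)
}

#' Indifference-interval skeleton for the power model
#'
#' Constructs the skeleton iteratively from an anchor: the prior MTD gets
#' skeleton value `gamma`, and each neighbor is chosen so that when the
#' parameter `beta` maps one dose to the edge of the indifference interval
#' \eqn{\gamma \mp h}, the adjacent dose sits at the opposite edge
#' \eqn{\gamma \pm h}. For the power model this gives the recursion
#' \deqn{s_{k+1} = \exp\{\log(\gamma+h)\,\log s_k / \log(\gamma-h)\}, \quad
#'       s_{k-1} = \exp\{\log(\gamma-h)\,\log s_k / \log(\gamma+h)\}.}
#'
#' @param m Number of dose levels.
#' @param prior_mtd_index Index of the anticipated MTD (anchored at `gamma`).
#' @param gamma Target toxicity probability.
#' @param halfwidth Indifference half-width `h`, in (0, gamma); must also
#'   satisfy `gamma + halfwidth < 1`.
#' @return Strictly increasing numeric skeleton of length `m`.
#' @examples
#' make_skeleton(3, 2, 0.3, 0.05)   # close to c(0.20, 0.30, 0.40)
#' @export
make_skeleton <- function(m, prior_mtd_index, gamma, halfwidth) {
  stopifnot(m >= 1, prior_mtd_index >= 1, prior_mtd_index <= m)
  check_prob(gamma, "gamma")
  if (!is.numeric(halfwidth) || halfwidth <= 0 || halfwidth >= gamma ||
      gamma + halfwidth >= 1)
    stop("`halfwidth` must satisfy 0 < halfwidth < gamma and gamma + halfwidth < 1",
         call. = FALSE)
  s <- numeric(m)
  s[prior_mtd_index] <- gamma
  if (prior_mtd_index < m)
    for (k in prior_mtd_index:(m - 1L))
      s[k + 1L] <- exp(log(gamma + halfwidth) * log(s[k]) /
                         log(gamma - halfwidth))
  if (prior_mtd_index > 1L)
    for (k in prior_mtd_index:2L)
      s[k - 1L] <- exp(log(gamma - halfwidth) * log(s[k]) /
                         log(gamma + halfwidth))
  if (any(s <= 0) || any(s >= 1) || any(diff(s) <= 0))
    stop("skeleton construction left (0, 1); reduce `m` or `halfwidth`",
         call. = FALSE)
  s
}
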