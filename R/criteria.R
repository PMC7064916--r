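#' Allocation criteria for dose-escalation designs
#'
#' Pure functions measuring how far a toxicity probability `p` is from the
#' target toxicity `gamma`, used to pick the next dose in a model-based
#' phase I trial. The workhorse is the convex infinite bounds penalization
#' (CIBP) divergence
#' \deqn{\delta(p, \gamma) = \frac{(p - \gamma)^2}{p^a (1 - p)^{2 - a}},}
#' which is zero at \eqn{p = \gamma}, blows up at the boundaries of the unit
#' interval, and penalizes overly toxic doses more severely than overly safe
#' ones when \eqn{a < 1}. At \eqn{a = 1} it is symmetric on the logit scale;
#' at \eqn{a = 2\gamma} its plug-in argmin approximately coincides with the
#' squared-distance rule.
#'
#' @name criteria
NULL

#' Squared distance criterion
#'
#' The conventional CRM allocation criterion \eqn{(p - \gamma)^2}.
#'
#' @param p Toxicity probability (vectorized), in \[0, 1\].
#' @param gamma Target toxicity probability.
#' @return Nonnegative numeric, zero iff `p == gamma`.
#' @examples
#' squared_distance(c(0.2, 0.4), 0.3)  # both 0.01: the tie CIBP breaks
#' @export
squared_distance <- function(p, gamma) {
  check_prob(p, "p", closed = TRUE)
  check_prob(gamma, "gamma", closed = TRUE)
  (p - gamma)^2
}

#' CIBP divergence
#'
#' Asymmetric convex divergence \eqn{(p-\gamma)^2 / (p^a (1-p)^{2-a})} on the
#' unit interval. Returns `Inf` at `p = 0` or `p = 1` (for interior `gamma`):
#' boundary probabilities must never win an argmin. Exponent `a` in (0, 2)
#' sets the asymmetry: values below 1 penalize overly toxic doses more than
#' overly safe ones; `a = 1` recovers the symmetric divergence
#' \eqn{(p-\gamma)^2 / (p(1-p))}.
#'
#' @inheritParams squared_distance
#' @param a Asymmetry parameter, strictly inside (0, 2).
#' @return Nonnegative numeric (possibly `Inf` at the boundaries).
#' @examples
#' cibp_divergence(0.2, 0.3, a = 1)  # 1/16
#' cibp_divergence(0.4, 0.3, a = 1)  # 1/24: the more toxic dose wins at a = 1
#' cibp_divergence(0.4, 0.3, a = 0.5) > cibp_divergence(0.2, 0.3, a = 0.5)
#' @export
cibp_divergence <- function(p, gamma, a) {
  check_prob(p, "p", closed = TRUE)
  check_prob(gamma, "gamma", closed = TRUE)
  check_a(a)
  out <- ifelse(p <= 0 | p >= 1, Inf,
                (p - gamma)^2 / (p^a * (1 - p)^(2 - a)))
  # the divergence is 0 (not Inf) if the target itself sits on the boundary
  out[p == gamma] <- 0
  out
}

#' Absolute-distance CIBP variant
#'
#' \eqn{|p-\gamma| / (p^a (1-p)^{2-a})}: same denominator as
#' [cibp_divergence()], absolute instead of squared distance in the
#' numerator, so small deviations are penalized relatively more.
#'
#' @inheritParams cibp_divergence
#' @return Nonnegative numeric (possibly `Inf` at the boundaries).
#' @export
cibp_abs_divergence <- function(p, gamma, a) {
  check_prob(p, "p", closed = TRUE)
  check_prob(gamma, "gamma", closed = TRUE)
  check_a(a)
  out <- ifelse(p <= 0 | p >= 1, Inf,
                abs(p - gamma) / (p^a * (1 - p)^(2 - a)))
  out[p == gamma] <- 0
  out
}

#' Aitchison distance on the unit interval
#'
#' Squared distance after the logit transformation,
#' \eqn{(\mathrm{logit}\, p - \mathrm{logit}\, \gamma)^2} (natural log).
#' Defined only for interior probabilities.
#'
#' @inheritParams squared_distance
#' @return Nonnegative numeric.
#' @export
aitchison_distance <- function(p, gamma) {
  check_prob(p, "p")
  check_prob(gamma, "gamma")
  (stats::qlogis(p) - stats::qlogis(gamma))^2
}

#' EWOC asymmetric linear loss
#'
#' \eqn{\alpha (\gamma - p)_+ + (1-\alpha)(p - \gamma)_+}: underdosing is
#' weighted by the feasibility bound `alpha`, overdosing by `1 - alpha`, so
#' small `alpha` is overdose-averse.
#'
#' @inheritParams squared_distance
#' @param alpha Feasibility bound in (0, 1).
#' @return Nonnegative numeric, zero at `p == gamma`.
#' @export
ewoc_loss <- function(p, gamma, alpha) {
  check_prob(p, "p", closed = TRUE)
  check_prob(gamma, "gamma", closed = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  alpha * pmax(0, gamma - p) + (1 - alpha) * pmax(0, p - gamma)
}

#' Interval loss table for the BLRM design
#'
#' Default table adapted for target toxicity 0.33: loss 1 on (0, 0.26)
#' (underdosing), 0 on the target interval (0.26, 0.41), 1 on (0.41, 0.66)
#' (excessive), 2 on (0.66, 1) (unacceptable). Intervals are taken right-open
#' `[lo, hi)` with `p = 1` assigned to the last interval; the boundary
#' convention is measure-zero and fixed for determinism.
#'
#' @param lower,upper,loss Parallel vectors defining a partition of \[0, 1\]
#'   and the loss on each interval.
#' @return A `data.frame` with columns `lower`, `upper`, `loss`.
#' @export
blrm_loss_table <- function(lower = c(0, 0.26, 0.41, 0.66),
                            upper = c(0.26, 0.41, 0.66, 1),
                            loss = c(1, 0, 1, 2)) {
  stopifnot(length(lower) == length(upper), length(lower) == length(loss))
  if (lower[1] != 0 || upper[length(upper)] != 1 ||
      any(lower[-1] != upper[-length(upper)]) || any(upper <= lower))
    stop("loss intervals must partition [0, 1]", call. = FALSE)
  if (any(!is.finite(loss)))
    stop("interval losses must be finite", call. = FALSE)
  data.frame(lower = lower, upper = upper, loss = loss)
}

#' BLRM interval loss
#'
#' Loss of the interval containing `p`, given a partition of \[0, 1\].
#'
#' @inheritParams squared_distance
#' @param table Loss table as returned by [blrm_loss_table()].
#' @return Numeric loss values.
#' @export
blrm_loss <- function(p, table = blrm_loss_table()) {
  check_prob(p, "p", closed = TRUE)
  breaks <- c(table$lower, 1)
  idx <- findInterval(p, breaks, rightmost.closed = TRUE)
  table$loss[idx]
}

#' Calibrate the CIBP asymmetry parameter from an indifference interval
#'
#' Finds the `a` for which the CIBP divergence takes equal values at the two
#' ends of the interval \eqn{(\gamma - \theta, \gamma + \theta)}: inside the
#' interval the safer of two equidistant estimates is preferred, outside it
#' the more uncertain one. Closed form \eqn{a = 2 / (1 + A)} with
#' \deqn{A = \log\frac{\gamma-\theta}{\gamma+\theta} \Big/
#'          \log\frac{1-\gamma-\theta}{1-\gamma+\theta}.}
#' As \eqn{\theta \to 0} the calibrated `a` tends to \eqn{2\gamma}, the
#' squared-distance-like regime; larger \eqn{\theta} gives smaller, more
#' conservative `a`.
#'
#' @param gamma Target toxicity probability.
#' @param theta Interval half-width, in (0, min(gamma, 1 - gamma)).
#' @return The calibrated asymmetry parameter, in (0, 2).
#' @examples
#' asymmetry_from_interval(0.25, 1e-8)  # ~ 2 * 0.25
#' @export
asymmetry_from_interval <- function(gamma, theta) {
  check_prob(gamma, "gamma")
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 ||
      theta >= min(gamma, 1 - gamma))
    stop("`theta` must lie strictly inside (0, min(gamma, 1 - gamma))",
         call. = FALSE)
  A <- log((gamma - theta) / (gamma + theta)) /
    log((1 - gamma - theta) / (1 - gamma + theta))
  2 / (1 + A)
}

#' Criterion specification
#'
#' Bundles a criterion kind with its parameters, for use in a
#' [design_spec()] and in configuration files.
#'
#' @param kind One of `"squared"`, `"cibp"`, `"cibp_abs"`, `"aitchison"`,
#'   `"ewoc"`, `"blrm"`.
#' @param gamma Target toxicity probability; phase I convention is
#'   `gamma < 0.5` (a warning is issued otherwise, not an error).
#' @param a Asymmetry parameter, required for the cibp kinds.
#' @param alpha Feasibility bound, required for `"ewoc"` (may be superseded
#'   by an alpha schedule at the design level).
#' @param loss_table Loss table for `"blrm"`; defaults to [blrm_loss_table()].
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(kind = c("squared", "cibp", "cibp_abs",
                                    "aitchison", "ewoc", "blrm"),
                           gamma, a = NULL, alpha = NULL, loss_table = NULL) {
  kind <- match.arg(kind)
  check_prob(gamma, "gamma")
  if (gamma >= 0.5)
    warning("target toxicity gamma >= 0.5 is unusual for phase I trials",
            call. = FALSE)
  if (kind %in% c("cibp", "cibp_abs")) {
    if (is.null(a)) stop("CIBP criteria require the asymmetry parameter `a`",
                         call. = FALSE)
    check_a(a)
  }
  if (kind == "ewoc") {
    if (is.null(alpha)) alpha <- 0.25
    if (alpha <= 0 || alpha >= 1)
      stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (kind == "blrm" && is.null(loss_table)) loss_table <- blrm_loss_table()
  structure(list(kind = kind, gamma = gamma, a = a, alpha = alpha,
                 loss_table = loss_table),
            class = "criterion_spec")
}

#' Evaluate a criterion specification at given probabilities
#'
#' @param spec A [criterion_spec()].
#' @param p Vector of probabilities.
#' @param alpha Optional override of the EWOC feasibility bound (used by
#'   alpha schedules).
#' @return Numeric vector of criterion values.
#' @export
criterion_value <- function(spec, p, alpha = NULL) {
  stopifnot(inherits(spec, "criterion_spec"))
  switch(spec$kind,
    squared   = squared_distance(p, spec$gamma),
    cibp      = cibp_divergence(p, spec$gamma, spec$a),
    cibp_abs  = cibp_abs_divergence(p, spec$gamma, spec$a),
    aitchison = aitchison_distance(p, spec$gamma),
    ewoc      = ewoc_loss(p, spec$gamma, if (is.null(alpha)) spec$alpha else alpha),
    blrm      = blrm_loss(p, spec$loss_table)
  )
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat("<criterion_spec> kind:", x$kind, " gamma:", x$gamma)
  if (!is.null(x$a)) cat("  a:", x$a)
  if (!is.null(x$alpha)) cat("  alpha:", x$alpha)
  cat("\n")
  invisible(x)
}

# --- internal validators ---------------------------------------------------

check_prob <- function(x, name, closed = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("`%s` must be numeric and non-missing", name), call. = FALSE)
  ok <- if (closed) all(x >= 0 & x <= 1) else all(x > 0 & x < 1)
  if (!ok)
    stop(sprintf("`%s` must lie in %s", name,
                 if (closed) "[0, 1]" else "(0, 1)"), call. = FALSE)
  invisible(x)
}

check_a <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 2)
    stop("asymmetry parameter `a` must lie strictly inside (0, 2)",
         call. = FALSE)
  invisible(a)
}

# log CIBP divergence from log p and log(1-p); stable where p under/overflows.
# numerator log|p - gamma| is passed in by the caller (it is well conditioned
# on the quadrature grid).
log_cibp_kernel <- function(log_abs_diff, log_p, log_1mp, a, squared = TRUE) {
  (if (squared) 2 else 1) * log_abs_diff - a * log_p - (2 - a) * log_1mp
}
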