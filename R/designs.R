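#' Dose-escalation designs
#'
#' A design maps the current posterior and trial history to the next dose:
#' CRM minimizes the squared distance of the posterior mean toxicity from
#' the target; CIBP minimizes the posterior expectation of the CIBP
#' divergence; the EWOC family minimizes posterior expected asymmetric
#' linear loss under a (possibly adaptive) feasibility bound; BLRM minimizes
#' posterior expected interval loss; CRM(M) is the CRM restricted to doses
#' with estimated toxicity strictly below the target. Escalation constraints
#' (start at the lowest dose, no skipping, coherence) clip the candidate.
#'
#' @name designs
NULL

#' Escalation constraints
#'
#' @param no_skip Candidate may not exceed the highest dose previously
#'   administered plus one.
#' @param start_lowest First cohort is always allocated to dose 1.
#' @param coherent No escalation immediately after a cohort that contained
#'   at least one DLT (the candidate is clipped to the current dose).
#' @param restrict_below_target CRM(M) restriction: only doses with
#'   estimated toxicity strictly below the target are admissible, falling
#'   back to the lowest dose when none qualifies.
#' @return An object of class `escalation_constraint`.
#' @export
escalation_constraint <- function(no_skip = TRUE, start_lowest = TRUE,
                                  coherent = TRUE,
                                  restrict_below_target = FALSE) {
  structure(list(no_skip = isTRUE(no_skip), start_lowest = isTRUE(start_lowest),
                 coherent = isTRUE(coherent),
                 restrict_below_target = isTRUE(restrict_below_target)),
            class = "escalation_constraint")
}

#' Feasibility-bound schedules for the EWOC family
#'
#' `fixed` keeps alpha constant; `TR` raises it by a fixed increment per
#' patient after an initial plateau; `TDFB` raises it with the number of
#' DLT-free patients.
#'
#' @param kind One of `"fixed"`, `"TR"`, `"TDFB"`.
#' @param alpha0 Fixed value (kind `"fixed"`), or plateau value (`"TR"`).
#' @param alpha_min TDFB baseline.
#' @param increment Per-patient increment for `"TR"`.
#' @param cap Upper bound for the schedule.
#' @param plateau_end Last patient index of the TR plateau.
#' @param S TDFB scale: the bound reaches `cap` once `S` DLT-free patients
#'   have accrued.
#' @return An object of class `alpha_schedule`.
#' @export
alpha_schedule <- function(kind = c("fixed", "TR", "TDFB"),
                           alpha0 = 0.25, alpha_min = 0.25,
                           increment = 0.05, cap = 0.5,
                           plateau_end = 9, S = NULL) {
  kind <- match.arg(kind)
  if (kind == "TDFB") {
    if (is.null(S)) stop("the TDFB schedule requires `S`", call. = FALSE)
    if (S <= 0) stop("`S` must be positive", call. = FALSE)
  }
  if (cap < alpha_min) stop("`cap` must be at least `alpha_min`", call. = FALSE)
  structure(list(kind = kind, alpha0 = alpha0, alpha_min = alpha_min,
                 increment = increment, cap = cap,
                 plateau_end = plateau_end, S = S),
            class = "alpha_schedule")
}

#' TR feasibility bound
#'
#' Constant `alpha0` through patient `plateau_end`, then increasing by
#' `increment` per patient up to `cap`: with the defaults, 0.25 for patients
#' 2 to 9, then 0.30, 0.35, ... capped at 0.50.
#'
#' @param n Patient index (at least 2; the first patient is allocated by
#'   `start_lowest`, not by the loss).
#' @param alpha0,increment,cap,plateau_end Schedule parameters.
#' @return The feasibility bound for patient `n`.
#' @export
tr_alpha <- function(n, alpha0 = 0.25, increment = 0.05, cap = 0.5,
                     plateau_end = 9) {
  if (any(n < 2)) stop("`n` must be at least 2", call. = FALSE)
  pmin(cap, alpha0 + increment * pmax(0, n - plateau_end))
}

#' Toxicity-dependent feasibility bound (TDFB)
#'
#' \eqn{\alpha_{n+1} = \min\{cap,\ \alpha_{min} + (cap - \alpha_{min})
#' (n - 1 - \sum y_i)/S\}}: the bound grows with the number of DLT-free
#' patients among the `n` treated so far.
#'
#' @param n Number of patients treated so far.
#' @param total_dlts Number of DLTs among them.
#' @param alpha_min Baseline bound.
#' @param S Scale (positive): DLT-free patients needed to reach the cap.
#' @param cap Upper bound.
#' @return The feasibility bound for the next allocation.
#' @export
tdfb_alpha <- function(n, total_dlts, alpha_min = 0.25, S, cap = 0.5) {
  if (S <= 0) stop("`S` must be positive", call. = FALSE)
  if (any(total_dlts > n)) stop("`total_dlts` cannot exceed `n`", call. = FALSE)
  pmin(cap, alpha_min + (cap - alpha_min) * pmax(0, n - 1 - total_dlts) / S)
}

#' Design specification
#'
#' @param name One of `"CRM"`, `"CRM_M"`, `"CIBP"`, `"EWOC"`, `"TR"`,
#'   `"TDFB"`, `"BLRM"`.
#' @param model A [power_model()] or [logistic2_model()].
#' @param criterion A [criterion_spec()] consistent with `name`.
#' @param alpha_sched An [alpha_schedule()] (EWOC family only).
#' @param constraints An [escalation_constraint()].
#' @param use_plugin If `TRUE`, CIBP allocates by the plug-in divergence at
#'   the posterior mean probability instead of the posterior expectation of
#'   the divergence (used to study the `a = 2*gamma` equivalence with CRM).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(name = c("CRM", "CRM_M", "CIBP", "EWOC", "TR",
                                 "TDFB", "BLRM"),
                        model, criterion,
                        alpha_sched = NULL,
                        constraints = escalation_constraint(),
                        use_plugin = FALSE) {
  name <- match.arg(name)
  stopifnot(inherits(criterion, "criterion_spec"),
            inherits(constraints, "escalation_constraint"))
  needed <- switch(name,
    CRM = "squared", CRM_M = "squared",
    CIBP = c("cibp", "cibp_abs"),
    EWOC = "ewoc", TR = "ewoc", TDFB = "ewoc",
    BLRM = "blrm")
  if (!criterion$kind %in% needed)
    stop(sprintf("design %s requires a criterion of kind %s", name,
                 paste(needed, collapse = "/")), call. = FALSE)
  if (name %in% c("EWOC", "TR", "TDFB")) {
    if (is.null(alpha_sched))
      alpha_sched <- switch(name,
        EWOC = alpha_schedule("fixed", alpha0 = criterion$alpha),
        TR = alpha_schedule("TR"),
        TDFB = alpha_schedule("TDFB", S = 12))
    stopifnot(inherits(alpha_sched, "alpha_schedule"))
  }
  if (name == "CRM_M") constraints$restrict_below_target <- TRUE
  structure(list(name = name, model = model, criterion = criterion,
                 alpha_sched = alpha_sched, constraints = constraints,
                 use_plugin = isTRUE(use_plugin)),
            class = "design_spec")
}

#' Trial history summary used by allocation rules
#'
#' @param doses_given Vector of doses administered so far (one entry per
#'   cohort is enough; only the maximum and the last entry matter).
#' @param n_enrolled Patients treated so far.
#' @param n_dlt DLTs observed so far.
#' @param last_cohort_dlt DLT count in the most recent cohort.
#' @return An object of class `trial_history`.
#' @export
trial_history <- function(doses_given = integer(0), n_enrolled = 0L,
                          n_dlt = 0L, last_cohort_dlt = 0L) {
  structure(list(doses_given = as.integer(doses_given),
                 n_enrolled = as.integer(n_enrolled),
                 n_dlt = as.integer(n_dlt),
                 last_cohort_dlt = as.integer(last_cohort_dlt)),
            class = "trial_history")
}

#' Clip a candidate dose by the no-skipping rule
#'
#' The candidate may not exceed the highest dose previously administered
#' plus one; de-escalation is never blocked. With an empty history the
#' lowest dose is returned (the `start_lowest` convention).
#'
#' @param candidate Candidate dose index.
#' @param history A [trial_history()] (or anything with `$doses_given`).
#' @return The clipped dose index.
#' @export
apply_no_skip <- function(candidate, history) {
  if (length(history$doses_given) == 0L) return(1L)
  min(candidate, max(history$doses_given) + 1L)
}

#' Next dose under a design
#'
#' Scores every dose with the design's criterion (posterior-expected for
#' CIBP/EWOC/BLRM, posterior-mean plug-in for the squared-distance rules),
#' takes the argmin (ties to the lowest dose), and clips by the escalation
#' constraints.
#'
#' @param design A [design_spec()].
#' @param state The current `posterior_state` (already updated with all of
#'   the history's outcomes).
#' @param history A [trial_history()].
#' @return The next dose index.
#' @export
next_dose <- function(design, state, history = trial_history()) {
  stopifnot(inherits(design, "design_spec"),
            inherits(state, "posterior_state"))
  con <- design$constraints
  if (con$start_lowest && history$n_enrolled == 0L) return(1L)
  m <- nrow(state$log_psi)
  crit <- design$criterion
  gamma <- crit$gamma

  scores <- switch(design$name,
    CRM = , CRM_M = squared_distance(posterior_mean_prob(state), gamma),
    CIBP = {
      if (design$use_plugin) {
        criterion_value(crit, posterior_mean_prob(state))
      } else {
        cibp_log_scores(state, gamma, crit$a,
                        squared = crit$kind == "cibp")
      }
    },
    EWOC = , TR = , TDFB = {
      alpha <- current_alpha(design$alpha_sched, history)
      vapply(seq_len(m), function(i)
        posterior_expected(state, i, function(p) ewoc_loss(p, gamma, alpha)),
        numeric(1))
    },
    BLRM = vapply(seq_len(m), function(i)
      posterior_expected(state, i, function(p) blrm_loss(p, crit$loss_table)),
      numeric(1))
  )

  if (con$restrict_below_target) {
    admissible <- which(posterior_mean_prob(state) < gamma)
    candidate <- if (length(admissible)) admissible[which.min(scores[admissible])]
                 else 1L
  } else {
    candidate <- which.min(scores)
    if (length(candidate) == 0L) candidate <- 1L  # all scores NA/empty guard
  }
  if (con$no_skip) candidate <- apply_no_skip(candidate, history)
  if (con$coherent && history$last_cohort_dlt >= 1L &&
      length(history$doses_given))
    candidate <- min(candidate, history$doses_given[length(history$doses_given)])
  as.integer(candidate)
}

current_alpha <- function(sched, history) {
  switch(sched$kind,
    fixed = sched$alpha0,
    # the schedule is indexed by patient number; the incoming patient is
    # n_enrolled + 1, with the plateau covering the early patients
    TR = if (history$n_enrolled + 1L <= 1L) sched$alpha0
         else tr_alpha(history$n_enrolled + 1L, sched$alpha0,
                       sched$increment, sched$cap, sched$plateau_end),
    TDFB = tdfb_alpha(history$n_enrolled, history$n_dlt,
                      sched$alpha_min, sched$S, sched$cap)
  )
}

#' Final MTD selection
#'
#' The squared distance of the posterior mean toxicity from the target is
#' used for the final recommendation, unconstrained by escalation history
#' (uncertainty and conservatism matter during allocation only). Ties go to
#' the lower dose.
#'
#' @param state Final `posterior_state`.
#' @param gamma Target toxicity probability.
#' @return The selected dose index.
#' @export
select_mtd <- function(state, gamma) {
  which.min(squared_distance(posterior_mean_prob(state), gamma))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", x$name, " criterion:", x$criterion$kind,
      " gamma:", x$criterion$gamma)
  if (!is.null(x$criterion$a)) cat("  a:", x$criterion$a)
  cat("\n")
  invisible(x)
}

# --- factory settings replicating the standard comparative setups ----------

#' Design factories
#'
#' Convenience constructors wiring model, criterion and constraints for the
#' designs compared in the package: the power-model CRM and CIBP designs and
#' the two-parameter-logistic EWOC/TR/TDFB/BLRM designs. The logistic prior
#' (bivariate normal, mean (0, 1), covariance diag(4, 1), covariate = logit
#' skeleton) is a package default, required because published comparisons
#' leave it to the original works.
#'
#' @param model A dose-toxicity model specification.
#' @param gamma Target toxicity probability.
#' @param a CIBP asymmetry parameter.
#' @param alpha EWOC feasibility bound.
#' @param S TDFB scale parameter.
#' @param constraints An [escalation_constraint()].
#' @param use_plugin See [design_spec()].
#' @param loss_table See [blrm_loss_table()].
#' @name design_factories
NULL

#' @rdname design_factories
#' @export
crm_design <- function(model, gamma, constraints = escalation_constraint()) {
  design_spec("CRM", model, criterion_spec("squared", gamma),
              constraints = constraints)
}

#' @rdname design_factories
#' @export
crm_m_design <- function(model, gamma, constraints = escalation_constraint()) {
  design_spec("CRM_M", model, criterion_spec("squared", gamma),
              constraints = constraints)
}

#' @rdname design_factories
#' @export
cibp_design <- function(model, gamma, a,
                        constraints = escalation_constraint(),
                        use_plugin = FALSE) {
  design_spec("CIBP", model, criterion_spec("cibp", gamma, a = a),
              constraints = constraints, use_plugin = use_plugin)
}

#' @rdname design_factories
#' @export
ewoc_design <- function(model, gamma, alpha = 0.25,
                        constraints = escalation_constraint()) {
  design_spec("EWOC", model, criterion_spec("ewoc", gamma, alpha = alpha),
              constraints = constraints)
}

#' @rdname design_factories
#' @export
tr_design <- function(model, gamma, constraints = escalation_constraint()) {
  design_spec("TR", model, criterion_spec("ewoc", gamma, alpha = 0.25),
              alpha_sched = alpha_schedule("TR"), constraints = constraints)
}

#' @rdname design_factories
#' @export
tdfb_design <- function(model, gamma, S = 12,
                        constraints = escalation_constraint()) {
  design_spec("TDFB", model, criterion_spec("ewoc", gamma, alpha = 0.25),
              alpha_sched = alpha_schedule("TDFB", S = S),
              constraints = constraints)
}

#' @rdname design_factories
#' @export
blrm_design <- function(model, gamma, loss_table = blrm_loss_table(),
                        constraints = escalation_constraint()) {
  design_spec("BLRM", model,
              criterion_spec("blrm", gamma, loss_table = loss_table),
              constraints = constraints)
}
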