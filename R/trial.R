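#' Sequential trial execution
#'
#' Runs a dose-escalation trial cohort by cohort: allocate, observe, update
#' the posterior, repeat until a stopping rule fires, then select the MTD.
#' Outcomes come either from a scenario (true DLT probabilities, Bernoulli
#' draws) or from fixed per-dose outcome streams consumed in assignment
#' order (deterministic replay).
#'
#' @name trial_engine
NULL

#' Outcome sources
#'
#' @param probs Vector of true DLT probabilities per dose (scenario kind).
#' @param seed Optional integer seed set at the start of the run
#'   (scenario kind); with a seed the trial is exactly replayable.
#' @param streams List of per-dose binary outcome vectors, consumed in
#'   assignment order (fixed kind).
#' @return An object of class `outcome_source`.
#' @name outcome_sources
NULL

#' @rdname outcome_sources
#' @export
scenario_source <- function(probs, seed = NULL) {
  check_prob(probs, "probs", closed = TRUE)
  structure(list(kind = "scenario", probs = as.numeric(probs), seed = seed),
            class = "outcome_source")
}

#' @rdname outcome_sources
#' @export
fixed_streams_source <- function(streams) {
  streams <- lapply(streams, as.integer)
  if (any(vapply(streams, function(s) any(!s %in% c(0L, 1L)), logical(1))))
    stop("streams must be binary (0/1)", call. = FALSE)
  structure(list(kind = "fixed_streams", streams = streams),
            class = "outcome_source")
}

#' Stopping rule
#'
#' @param max_patients Maximum number of patients (should be a multiple of
#'   the cohort size; a warning is issued at run time otherwise).
#' @param stop_if_lowest_all_tox Stop for safety when a full cohort at the
#'   lowest dose all experience DLTs; such trials make no MTD selection.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(max_patients = 30L, stop_if_lowest_all_tox = TRUE) {
  stopifnot(max_patients >= 1L)
  structure(list(max_patients = as.integer(max_patients),
                 stop_if_lowest_all_tox = isTRUE(stop_if_lowest_all_tox)),
            class = "stopping_rule")
}

#' Run one dose-escalation trial
#'
#' @param design A [design_spec()].
#' @param source An outcome source ([scenario_source()] or
#'   [fixed_streams_source()]) with as many doses as the design's model.
#' @param cohort_size Patients per cohort.
#' @param stopping A [stopping_rule()].
#' @param prior_state Optional precomputed prior `posterior_state` for the
#'   design's model (a performance shortcut for repeated simulation); it is
#'   never mutated.
#' @param n_nodes,range_sd Passed to [init_posterior()] when `prior_state`
#'   is not supplied.
#' @return A `trial_record`: per-cohort allocations, outcomes, posterior
#'   mean toxicities and recommendations, totals, the stop reason
#'   (`max_n`, `lowest_dose_all_tox` or `stream_exhausted`), and the final
#'   MTD (`NA` after a safety stop).
#' @export
run_trial <- function(design, source, cohort_size = 3L,
                      stopping = stopping_rule(),
                      prior_state = NULL, n_nodes = NULL, range_sd = 8) {
  stopifnot(inherits(design, "design_spec"),
            inherits(source, "outcome_source"),
            inherits(stopping, "stopping_rule"))
  m <- n_doses(design$model)
  if (source$kind == "scenario" && length(source$probs) != m)
    stop("scenario and model disagree on the number of doses", call. = FALSE)
  if (source$kind == "fixed_streams" && length(source$streams) != m)
    stop("streams and model disagree on the number of doses", call. = FALSE)
  if (stopping$max_patients %% cohort_size != 0L)
    warning("`max_patients` is not a multiple of the cohort size",
            call. = FALSE)
  if (source$kind == "scenario" && !is.null(source$seed))
    set.seed(source$seed)

  state <- if (is.null(prior_state))
    init_posterior(design$model, n_nodes = n_nodes, range_sd = range_sd)
  else prior_state
  gamma <- design$criterion$gamma

  used <- integer(m)                 # stream cursor per dose
  doses <- integer(0); dlts <- integer(0); recommended <- integer(0)
  outcomes <- list(); phat <- NULL
  hist <- trial_history()
  stop_reason <- NA_character_

  dose <- next_dose(design, state, hist)   # start_lowest gives dose 1
  repeat {
    if (source$kind == "fixed_streams" &&
        used[dose] + cohort_size > length(source$streams[[dose]])) {
      stop_reason <- "stream_exhausted"
      break
    }
    y <- if (source$kind == "scenario") {
      stats::rbinom(cohort_size, 1L, source$probs[dose])
    } else {
      out <- source$streams[[dose]][used[dose] + seq_len(cohort_size)]
      used[dose] <- used[dose] + cohort_size
      out
    }
    state <- update_posterior(state, observations(rep(dose, cohort_size), y))
    doses <- c(doses, dose)
    dlts <- c(dlts, sum(y))
    outcomes[[length(outcomes) + 1L]] <- as.integer(y)
    phat <- rbind(phat, posterior_mean_prob(state))
    hist <- trial_history(doses_given = doses,
                          n_enrolled = cohort_size * length(doses),
                          n_dlt = sum(dlts),
                          last_cohort_dlt = sum(y))
    if (stopping$stop_if_lowest_all_tox && dose == 1L &&
        sum(y) == cohort_size) {
      stop_reason <- "lowest_dose_all_tox"
      recommended <- c(recommended, NA_integer_)
      break
    }
    nxt <- next_dose(design, state, hist)
    recommended <- c(recommended, nxt)
    if (hist$n_enrolled >= stopping$max_patients) {
      stop_reason <- "max_n"
      break
    }
    dose <- nxt
  }

  final_mtd <- if (identical(stop_reason, "lowest_dose_all_tox"))
    NA_integer_ else select_mtd(state, gamma)
  structure(list(
    design = design$name,
    gamma = gamma,
    cohorts = data.frame(cohort = seq_along(doses), dose = doses,
                         n = rep(cohort_size, length(doses)), dlt = dlts),
    outcomes = outcomes,
    phat = phat,
    recommended = recommended,
    n_enrolled = cohort_size * length(doses),
    n_dlt = sum(dlts),
    stop_reason = stop_reason,
    final_mtd = final_mtd,
    final_state = state
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record>", x$design, " target gamma =", x$gamma, "\n")
  cat("  doses:", paste(x$cohorts$dose, collapse = " "),
      " (", x$n_enrolled, "patients,", x$n_dlt, "DLTs )\n")
  cat("  stop:", x$stop_reason, " final MTD:",
      if (is.na(x$final_mtd)) "none (safety)" else x$final_mtd, "\n")
  invisible(x)
}

#' @export
as.data.frame.trial_record <- function(x, ...) {
  df <- x$cohorts
  df$recommended_next <- c(x$recommended, rep(NA_integer_,
                                              nrow(df) - length(x$recommended)))
  df
}

#' Serialize a trial record to JSON
#'
#' @param record A `trial_record`.
#' @param path File path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
trial_to_json <- function(record, path = NULL) {
  stopifnot(inherits(record, "trial_record"))
  obj <- record[c("design", "gamma", "n_enrolled", "n_dlt",
                  "stop_reason", "final_mtd")]
  obj$schema <- "cibpcrm/trial_record/v1"
  obj$doses <- record$cohorts$dose
  obj$dlt_per_cohort <- record$cohorts$dlt
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' The Everolimus trial fixture
#'
#' Design inputs and reconstructed outcome streams for the individual-trial
#' illustration: three Everolimus regimens given with Paclitaxel and
#' Trastuzumab, target toxicity 0.3, skeleton (0.20, 0.30, 0.40), prior
#' N(0, 1.34), cohorts of three. The aggregated trial data are 6, 17 and 10
#' patients at the three regimens with 3, 6 and 7 DLTs. The per-dose streams
#' fix one order of those outcomes: the dose-2 stream's cohort-level DLT
#' counts (1, 0, 1, 2) are a reconstruction consistent with the aggregated
#' counts (only cohort totals matter to the designs, and the trial totals
#' are invariant to the within-dose split).
#'
#' @return A list with elements `skeleton`, `gamma`, `prior_mean`,
#'   `prior_var`, `cohort_size`, `counts` (aggregated patients/DLTs per
#'   dose) and `streams`.
#' @export
everolimus_fixture <- function() {
  list(
    skeleton = c(0.20, 0.30, 0.40),
    gamma = 0.3,
    prior_mean = 0,
    prior_var = 1.34,
    cohort_size = 3L,
    counts = data.frame(dose = 1:3, n = c(6L, 17L, 10L),
                        dlt = c(3L, 6L, 7L)),
    streams = list(
      d1 = c(0L, 0L, 0L, 1L, 1L, 1L),
      d2 = c(1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 0L),
      d3 = c(1L, 1L, 1L)
    )
  )
}

#' Replay the Everolimus illustration
#'
#' Runs the CRM or the CIBP design on the fixture outcome streams with the
#' illustration's settings (no skipping, start at the lowest dose, coherent
#' escalation, safety stop when a full lowest-dose cohort is all-DLT).
#'
#' @param design `"CRM"` or `"CIBP"`.
#' @param a CIBP asymmetry parameter.
#' @param n_nodes,range_sd Quadrature settings, see [init_posterior()].
#' @return A `trial_record`.
#' @export
replay_everolimus <- function(design = c("CRM", "CIBP"), a = 0.3,
                              n_nodes = NULL, range_sd = 8) {
  design <- match.arg(design)
  fx <- everolimus_fixture()
  model <- power_model(fx$skeleton, fx$prior_mean, fx$prior_var)
  spec <- if (design == "CRM") crm_design(model, fx$gamma)
          else cibp_design(model, fx$gamma, a = a)
  run_trial(spec, fixed_streams_source(fx$streams),
            cohort_size = fx$cohort_size,
            stopping = stopping_rule(max_patients = 33L,
                                     stop_if_lowest_all_tox = TRUE),
            n_nodes = n_nodes, range_sd = range_sd)
}
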