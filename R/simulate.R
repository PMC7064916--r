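#' Operating-characteristics simulation
#'
#' Repeats trials under known dose-toxicity scenarios and summarizes
#' selection quality and safety: per-dose selection probabilities, the
#' proportion of correct selections (PCS), the accuracy index, and DLT
#' counts, with Monte-Carlo standard errors; aggregates across scenarios
#' use geometric means for the accuracy measures and arithmetic means for
#' DLT counts.
#'
#' @name simulation
NULL

#' Scenario: true dose-toxicity curve
#'
#' @param probs Monotone nondecreasing vector of true DLT probabilities.
#' @param gamma Target toxicity probability.
#' @param name Optional label.
#' @return An object of class `scenario` with the MTD index (the dose whose
#'   probability is closest to `gamma`).
#' @export
scenario <- function(probs, gamma, name = NULL) {
  check_prob(probs, "probs", closed = TRUE)
  if (any(diff(probs) < 0))
    stop("`probs` must be monotone nondecreasing", call. = FALSE)
  check_prob(gamma, "gamma")
  mtd <- which.min((probs - gamma)^2)
  structure(list(name = if (is.null(name)) sprintf("mtd%d", mtd) else name,
                 probs = as.numeric(probs), gamma = gamma, mtd_index = mtd),
            class = "scenario")
}

#' Generate monotone toxicity scenarios with designated MTD positions
#'
#' Logistic-shaped curves on the logit scale: the anchor dose sits exactly
#' at `gamma`, and neighbors move away by jittered multiples of `steepness`
#' logits, guaranteeing strict monotonicity and one scenario per requested
#' MTD position.
#'
#' @param m Number of dose levels.
#' @param gamma Target toxicity probability.
#' @param mtd_positions Dose indices to anchor at `gamma`, one scenario each.
#' @param steepness Mean logit step between adjacent doses (positive).
#' @param seed Optional integer seed for the step jitter.
#' @return A list of [scenario()] objects.
#' @export
generate_scenarios <- function(m, gamma, mtd_positions, steepness = 1,
                               seed = NULL) {
  stopifnot(m >= 2, all(mtd_positions >= 1), all(mtd_positions <= m))
  if (!is.numeric(steepness) || steepness <= 0)
    stop("`steepness` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(mtd_positions, function(pos) {
    steps <- steepness * stats::runif(m - 1L, 0.6, 1.4)
    x <- c(-rev(cumsum(rev(steps[seq_len(pos - 1L)]))), 0,
           cumsum(steps[seq_len(m - pos) + (pos - 1L)]))
    scenario(stats::plogis(stats::qlogis(gamma) + x), gamma,
             name = sprintf("mtd%d", pos))
  })
}

#' Accuracy index of a selection distribution
#'
#' \deqn{\mathcal{A} = 1 - m \frac{\sum_i (p_i-\gamma)^2 \pi_i}
#'                              {\sum_i (p_i-\gamma)^2},}
#' where \eqn{\pi_i} is the probability of selecting dose i. Equals 1 when
#' all selection mass sits at doses with true toxicity `gamma`, 0 for a
#' uniform selection, and can be negative when mass concentrates on the
#' worst doses. Mass not in `pi` (e.g. trials stopped without a selection)
#' simply contributes nothing to the numerator.
#'
#' @param pi Per-dose selection probabilities (sum at most 1).
#' @param probs True DLT probabilities.
#' @param gamma Target toxicity probability.
#' @return The accuracy index (at most 1).
#' @export
accuracy_index <- function(pi, probs, gamma) {
  stopifnot(length(pi) == length(probs), length(probs) >= 2)
  if (any(pi < 0) || sum(pi) > 1 + 1e-12)
    stop("`pi` must be nonnegative with sum at most 1", call. = FALSE)
  d2 <- (probs - gamma)^2
  if (all(d2 == 0))
    stop("accuracy index undefined when every dose sits at the target",
         call. = FALSE)
  1 - length(probs) * sum(d2 * pi) / sum(d2)
}

#' Proportion of correct selections
#'
#' @param selections Vector of selected dose indices (`NA` for trials that
#'   made no selection; these count as incorrect).
#' @param mtd_index True MTD index.
#' @return Fraction of selections equal to `mtd_index`.
#' @export
pcs <- function(selections, mtd_index) {
  if (!length(selections)) stop("`selections` is empty", call. = FALSE)
  mean(!is.na(selections) & selections == mtd_index)
}

geometric_mean <- function(x) {
  if (any(x < 0))
    stop("geometric aggregation is undefined for negative values; ",
         "inspect the per-scenario results", call. = FALSE)
  exp(mean(log(x)))
}

#' Simulate operating characteristics
#'
#' Runs `n_reps` trials for every (design, scenario) cell with
#' deterministically derived per-replicate seeds (results are independent of
#' execution order), then summarizes selections and safety.
#'
#' @param designs Named list of [design_spec()] objects.
#' @param scenarios List of [scenario()] objects.
#' @param n_reps Replicates per cell.
#' @param cohort_size Patients per cohort.
#' @param max_patients Sample size per trial.
#' @param base_seed Integer master seed.
#' @param stop_if_lowest_all_tox Safety stopping, see [stopping_rule()];
#'   safety-stopped replicates contribute no selection (reducing PCS).
#' @param n_nodes,range_sd Quadrature settings shared by all cells.
#' @return An `oc_result`: `summary` (one row per cell with PCS, accuracy
#'   index, DLT and patient summaries and Monte-Carlo standard errors),
#'   `selection` (per-cell selection probabilities including "none"), and
#'   `aggregate` (per-design cross-scenario means: geometric for accuracy
#'   and PCS, arithmetic for DLTs).
#' @export
simulate_oc <- function(designs, scenarios, n_reps = 2000L,
                        cohort_size = 3L, max_patients = 30L,
                        base_seed = 1L, stop_if_lowest_all_tox = TRUE,
                        n_nodes = NULL, range_sd = 8) {
  stopifnot(n_reps >= 1L, length(designs) >= 1L, length(scenarios) >= 1L)
  if (is.null(names(designs)))
    names(designs) <- vapply(designs, `[[`, character(1), "name")
  stopping <- stopping_rule(max_patients, stop_if_lowest_all_tox)
  summary_rows <- list(); selection <- list()
  for (di in seq_along(designs)) {
    design <- designs[[di]]
    prior_state <- init_posterior(design$model, n_nodes = n_nodes,
                                  range_sd = range_sd)
    m <- n_doses(design$model)
    for (si in seq_along(scenarios)) {
      sc <- scenarios[[si]]
      stopifnot(length(sc$probs) == m)
      sel <- integer(n_reps); dlt <- integer(n_reps)
      pat <- matrix(0L, n_reps, m)
      for (r in seq_len(n_reps)) {
        set.seed(derive_seed(base_seed, di, si, r))
        tr <- run_trial(design, scenario_source(sc$probs),
                        cohort_size = cohort_size, stopping = stopping,
                        prior_state = prior_state)
        sel[r] <- if (is.na(tr$final_mtd)) NA_integer_ else tr$final_mtd
        dlt[r] <- tr$n_dlt
        tab <- tapply(tr$cohorts$n, factor(tr$cohorts$dose, levels = 1:m), sum)
        pat[r, ] <- ifelse(is.na(tab), 0L, tab)
      }
      pi_hat <- vapply(seq_len(m), function(i)
        mean(!is.na(sel) & sel == i), numeric(1))
      p_correct <- pcs(sel, sc$mtd_index)
      key <- sprintf("%s|%s", names(designs)[di], sc$name)
      selection[[key]] <- c(pi_hat, none = 1 - sum(pi_hat))
      summary_rows[[key]] <- data.frame(
        design = names(designs)[di], scenario = sc$name,
        mtd_index = sc$mtd_index,
        pcs = p_correct,
        pcs_se = sqrt(p_correct * (1 - p_correct) / n_reps),
        accuracy = accuracy_index(pi_hat, sc$probs, sc$gamma),
        mean_dlt = mean(dlt),
        dlt_se = stats::sd(dlt) / sqrt(n_reps),
        mean_patients = mean(rowSums(pat)),
        prop_no_selection = mean(is.na(sel)),
        n_reps = n_reps,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, c(summary_rows, make.row.names = FALSE))
  aggregate <- do.call(rbind, lapply(split(summary, summary$design),
    function(d) data.frame(
      design = d$design[1],
      geo_mean_accuracy = geometric_mean(d$accuracy),
      geo_mean_pcs = geometric_mean(d$pcs),
      mean_dlt = mean(d$mean_dlt),
      stringsAsFactors = FALSE)))
  rownames(aggregate) <- NULL
  structure(list(summary = summary, selection = selection,
                 aggregate = aggregate, base_seed = base_seed,
                 n_reps = n_reps),
            class = "oc_result")
}

# per-replicate seed, deterministic in (base, design, scenario, replicate)
# and independent of worker layout; kept within 32-bit integer range
derive_seed <- function(base_seed, di, si, r) {
  v <- (as.double(base_seed) * 48271 + di * 1299721 + si * 104729 + r)
  as.integer(v %% 2147483587 + 1)
}

#' @export
print.oc_result <- function(x, ...) {
  cat("<oc_result>", x$n_reps, "replicates per cell, base seed",
      x$base_seed, "\n\n")
  df <- x$summary
  df$pcs <- sprintf("%.3f (%.3f)", df$pcs, df$pcs_se)
  df$mean_dlt <- sprintf("%.2f (%.2f)", df$mean_dlt, df$dlt_se)
  print(df[, c("design", "scenario", "pcs", "accuracy", "mean_dlt",
               "prop_no_selection")], row.names = FALSE)
  cat("\nAggregates across scenarios:\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write OC results to CSV
#'
#' @param x An `oc_result`.
#' @param summary_path,aggregate_path Output CSV paths (`NULL` to skip).
#' @return `x`, invisibly.
#' @export
oc_to_csv <- function(x, summary_path = NULL, aggregate_path = NULL) {
  stopifnot(inherits(x, "oc_result"))
  if (!is.null(summary_path))
    utils::write.csv(x$summary, summary_path, row.names = FALSE)
  if (!is.null(aggregate_path))
    utils::write.csv(x$aggregate, aggregate_path, row.names = FALSE)
  invisible(x)
}
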