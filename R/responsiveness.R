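# Event responsiveness: paired permutation test of baseline-vs-stimulus
# spike counts per unit and trial type, and cohort summary percentages.

# Trial types analyzed per phase (pooled emotion types first, then the
# emotion x memory cells).
trial_types_for_phase <- function(phase) {
  if (phase == "encoding") {
    c("e", "n", "eR", "nR", "eF", "nF")
  } else {
    c("eRHit", "nRHit", "eMiss", "nMiss", "eCR", "nCR")
  }
}

trials_of_type <- function(trials, type) {
  if (type %in% c("e", "n")) {
    keep <- !trials$excluded_primary &
      (substring(trials$outcome, 1, 1) == type)
  } else {
    keep <- trials$outcome == type
  }
  trials[keep, , drop = FALSE]
}

#' Permutation test of event responsiveness
#'
#' Tests whether a unit's spike count differs between the baseline
#' (`[-1.5, -0.2)` s) and post-stimulus (`[0.2, 1.5)` s) windows on trials
#' of one type. The statistic is `mean(stimulus counts) - mean(baseline
#' counts)`; the null is built by independently swapping the
#' baseline/stimulus labels within each trial (paired sign-flip of the
#' per-trial differences), and the two-sided p-value uses the add-one rule
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`
#' and never exactly 0. With `exact = TRUE` all `2^n` sign assignments are
#' enumerated instead and the exact proportion is returned (no add-one).
#'
#' @param unit A [unit_spikes] object.
#' @param trials Labeled trial table of the unit's phase.
#' @param trial_type One of the per-phase types (e.g. `"e"`, `"nF"`,
#'   `"eRHit"`); see Details.
#' @param n_perm Number of random sign-flip draws (default 1000).
#' @param seed Integer seed.
#' @param baseline,stimulus Count windows (s).
#' @param exact Enumerate all sign assignments (requires few trials).
#' @param pooled Use an unpaired pooled shuffle of the 2n counts instead of
#'   the paired sign-flip (sensitivity option; default `FALSE`).
#' @return Data frame row: `unit_id`, `trial_type`, `n_trials`,
#'   `statistic` (mean count difference), `p`, `n_perm`, `direction`.
#' @export
permutation_response_test <- function(unit, trials, trial_type,
                                      n_perm = 1000, seed = NULL,
                                      baseline = default_windows()$baseline,
                                      stimulus = default_windows()$stimulus,
                                      exact = FALSE, pooled = FALSE) {
  tt <- trials_of_type(trials, trial_type)
  tt <- tt[tt$trial_id %in% names(unit$spikes), , drop = FALSE]
  n <- nrow(tt)
  if (n < 2L) stop("need >= 2 trials of type ", trial_type, call. = FALSE)
  sub <- unit
  sub$spikes <- unit$spikes[tt$trial_id]
  b <- window_spike_count(sub, window = baseline)
  s <- window_spike_count(sub, window = stimulus)
  d <- s - b
  t_obs <- mean(d)
  if (all(b == 0) && all(s == 0)) {
    p <- 1
  } else if (exact) {
    if (n > 20L) stop("exact enumeration limited to <= 20 trials",
                      call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_null <- as.vector(signs %*% d) / n
    p <- mean(abs(t_null) >= abs(t_obs) - 1e-12)
  } else {
    t_null <- with_seed(seed, {
      if (pooled) {
        pool <- c(b, s)
        vapply(seq_len(n_perm), function(i) {
          idx <- sample.int(2L * n, n)
          mean(pool[idx]) - mean(pool[-idx])
        }, numeric(1))
      } else {
        flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                        nrow = n_perm)
        as.vector(flips %*% d) / n
      }
    })
    p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  }
  data.frame(unit_id = unit$unit_id, trial_type = trial_type, n_trials = n,
             statistic = t_obs, p = p, n_perm = if (exact) 2L^n else n_perm,
             direction = if (t_obs >= 0) "increase" else "decrease",
             stringsAsFactors = FALSE)
}

#' Event responsiveness across a cohort
#'
#' Runs [permutation_response_test()] for every unit and trial type of a
#' phase, skipping (with a log entry) unit/type combinations with fewer
#' than 2 trials.
#'
#' @param units List of [unit_spikes] (one phase).
#' @param trials_by_patient Named list of labeled trial tables.
#' @param phase `"encoding"` or `"recognition"`.
#' @param trial_types Types to test (default: all of the phase).
#' @param n_perm,seed,... Passed to [permutation_response_test()].
#' @return Data frame of per-(unit, type) results; attribute `"skipped"`
#'   lists combinations without enough trials.
#' @export
responsiveness_scan <- function(units, trials_by_patient,
                                phase = c("encoding", "recognition"),
                                trial_types = NULL, n_perm = 1000,
                                seed = NULL, ...) {
  phase <- match.arg(phase)
  if (is.null(trial_types)) trial_types <- trial_types_for_phase(phase)
  skipped <- character()
  rows <- list()
  for (u in units) {
    tr <- trials_by_patient[[u$patient_id]]
    for (ty in trial_types) {
      nt <- nrow(trials_of_type(tr, ty))
      if (nt < 2L) {
        skipped <- c(skipped, paste(u$unit_id, ty))
        next
      }
      rows[[length(rows) + 1L]] <- permutation_response_test(
        u, tr, ty, n_perm = n_perm,
        seed = if (is.null(seed)) NULL else child_seed(seed, u$unit_id, ty),
        ...)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Percentage of event-responsive neurons per trial type
#'
#' @param results Data frame from [responsiveness_scan()].
#' @param alpha Significance threshold (default 0.05).
#' @param by_region Optional region vector (named by unit_id) to stratify.
#' @return Data frame with `trial_type` (and `region` when stratified),
#'   `n_units`, `n_significant`, `pct_significant`.
#' @export
responsiveness_summary <- function(results, alpha = 0.05,
                                   by_region = NULL) {
  if (is.null(results) || nrow(results) == 0L) {
    return(data.frame(trial_type = character(), n_units = integer(),
                      n_significant = integer(),
                      pct_significant = numeric()))
  }
  grp <- results$trial_type
  if (!is.null(by_region)) {
    grp <- paste(by_region[results$unit_id], grp, sep = ":")
  }
  agg <- lapply(split(results, grp), function(df) {
    data.frame(trial_type = df$trial_type[1],
               region = if (is.null(by_region)) NA_character_ else
                 by_region[df$unit_id[1]],
               n_units = nrow(df), n_significant = sum(df$p < alpha),
               pct_significant = 100 * mean(df$p < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  if (is.null(by_region)) out$region <- NULL
  out
}
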