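# Firing-rate features: Gaussian-smoothed PSTHs (sigma = 50 ms, 10 ms
# bins), window spike counts, per-trial abs(z) scores, and the
# unit x emotion x memory x time population tensor fed to dPCA.

#' Gaussian-smoothed peri-stimulus rate vectors
#'
#' Each spike contributes a unit-area Gaussian kernel (default sigma =
#' 50 ms) evaluated at bin centers spaced every 10 ms, yielding per-trial
#' firing-rate vectors in Hz. Kernel mass falling outside the window is
#' truncated (not renormalized), so the integral of the rate over the
#' window equals the spike count up to edge losses.
#'
#' @param unit A [unit_spikes] object.
#' @param window Analysis window `c(lo, hi)` in seconds.
#' @param sigma Kernel SD (s, default 0.05).
#' @param bin Bin spacing (s, default 0.01).
#' @return List of class `psth_matrix`: `rates` (trials x bins, Hz),
#'   `bin_centers` (s), `sigma`, `bin`, `unit_id`, `trial_ids`.
#' @export
compute_psth <- function(unit, window = default_windows()$psth,
                         sigma = 0.05, bin = 0.01) {
  assert_window(window)
  if (bin > diff(window)) stop("bin wider than the window", call. = FALSE)
  centers <- seq(window[1] + bin / 2, window[2], by = bin)
  rates <- t(vapply(unit$spikes, function(s) {
    s <- s[s >= window[1] - 4 * sigma & s < window[2] + 4 * sigma]
    if (!length(s)) return(numeric(length(centers)))
    colSums(matrix(stats::dnorm(rep(centers, each = length(s)) - s,
                                sd = sigma),
                   nrow = length(s)))
  }, numeric(length(centers))))
  structure(list(rates = rates, bin_centers = centers, sigma = sigma,
                 bin = bin, unit_id = unit$unit_id,
                 trial_ids = names(unit$spikes)),
            class = "psth_matrix")
}

#' Count spikes in a half-open window
#'
#' @param unit A [unit_spikes] object.
#' @param trial_id Trial identifier (or `NULL` for all trials).
#' @param window `c(lo, hi)`; spikes with `lo <= t < hi` are counted.
#' @return Integer count (vector over trials when `trial_id` is `NULL`).
#' @export
window_spike_count <- function(unit, trial_id = NULL,
                               window = default_windows()$stimulus) {
  assert_window(window)
  count1 <- function(s) sum(s >= window[1] & s < window[2])
  if (is.null(trial_id)) {
    vapply(unit$spikes, count1, integer(1))
  } else {
    s <- unit$spikes[[as.character(trial_id)]]
    if (is.null(s)) stop("unknown trial_id: ", trial_id, call. = FALSE)
    count1(s)
  }
}

#' Per-trial abs(z) firing-rate scores
#'
#' For each trial, `x` is that trial's mean stimulus-window firing rate;
#' `mu` and `sigma` are the mean and SD of the per-trial baseline-window
#' rates pooled over all trials; `z = (x - mu) / sigma`. If the mean z over
#' trials is negative the whole vector is multiplied by -1, so units that
#' suppress firing contribute positive modulation scores (abs(z)).
#' Rates are taken from the smoothed PSTH by default (`smoothed = TRUE`),
#' or from raw window counts divided by window length.
#'
#' @param unit A [unit_spikes] object.
#' @param trials Labeled trial table of the unit's phase.
#' @param baseline,stimulus Windows (s).
#' @param smoothed Use Gaussian-smoothed rates (default) or raw counts.
#' @param sigma,bin PSTH parameters when `smoothed`.
#' @return Data frame with one row per non-excluded trial: `patient_id`,
#'   `unit_id`, `trial_id`, `emotion`, `memory`, `abs_z`. When the baseline
#'   SD is zero the frame is empty and carries an `"excluded"` attribute;
#'   such units are dropped from the mixed model rather than zero-filled.
#' @export
compute_abs_z <- function(unit, trials,
                          baseline = default_windows()$baseline,
                          stimulus = default_windows()$stimulus,
                          smoothed = TRUE, sigma = 0.05, bin = 0.01) {
  trials <- trials[!trials$excluded_primary, , drop = FALSE]
  trials <- trials[trials$trial_id %in% names(unit$spikes), , drop = FALSE]
  if (smoothed) {
    span <- range(c(baseline, stimulus))
    p <- compute_psth(unit, window = span, sigma = sigma, bin = bin)
    idx <- match(trials$trial_id, p$trial_ids)
    in_b <- p$bin_centers >= baseline[1] & p$bin_centers < baseline[2]
    in_s <- p$bin_centers >= stimulus[1] & p$bin_centers < stimulus[2]
    b <- rowMeans(p$rates[idx, in_b, drop = FALSE])
    x <- rowMeans(p$rates[idx, in_s, drop = FALSE])
  } else {
    sub <- unit
    sub$spikes <- unit$spikes[trials$trial_id]
    b <- window_spike_count(sub, window = baseline) / diff(baseline)
    x <- window_spike_count(sub, window = stimulus) / diff(stimulus)
  }
  mu <- mean(b)
  sd_b <- stats::sd(b)
  if (!is.finite(sd_b) || sd_b == 0) {
    out <- data.frame(patient_id = character(), unit_id = character(),
                      trial_id = character(), emotion = character(),
                      memory = character(), abs_z = numeric())
    attr(out, "excluded") <- sprintf(
      "unit %s: baseline SD is zero, excluded from abs(z) analysis",
      unit$unit_id)
    return(out)
  }
  z <- (x - mu) / sd_b
  if (mean(z) < 0) z <- -z
  data.frame(patient_id = unit$patient_id, unit_id = unit$unit_id,
             trial_id = trials$trial_id,
             emotion = ifelse(trials$emotion == "emotional", "e", "n"),
             memory = memory_level(trials$outcome),
             abs_z = z, stringsAsFactors = FALSE)
}

# Memory factor level from an outcome label: R/F at encoding,
# RHit/Miss/CR (plus KHit/FA, normally pre-filtered) at recognition.
memory_level <- function(outcome) substring(outcome, 2)

#' Build the abs(z) table for a whole cohort phase
#'
#' Applies [compute_abs_z()] to every unit and stacks the rows; units with
#' zero baseline SD are dropped and listed in the `"excluded"` attribute.
#'
#' @param units List of [unit_spikes] (one phase).
#' @param trials_by_patient Named list (by patient) of labeled trial tables
#'   for that phase.
#' @param ... Passed to [compute_abs_z()].
#' @return Data frame (the z-score table); attribute `"excluded"` holds
#'   exclusion messages.
#' @export
build_ztable <- function(units, trials_by_patient, ...) {
  excluded <- character()
  rows <- lapply(units, function(u) {
    zt <- compute_abs_z(u, trials_by_patient[[u$patient_id]], ...)
    if (nrow(zt) == 0L) excluded <<- c(excluded, attr(zt, "excluded"))
    zt
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Trial-averaged population tensor for dPCA
#'
#' Stacks per-unit smoothed PSTHs into a 4-d array over
#' unit x emotion(2) x memory(K) x time, together with the retained single
#' trials (needed for noise estimation, regularization CV and decoding).
#' The memory factor has K = 2 levels at encoding (R/F) and K = 3 at
#' recognition (RHit/Miss/CR). Units lacking at least `min_trials` trials
#' in any condition cell are dropped and listed in the `"dropped"`
#' attribute.
#'
#' @param units List of [unit_spikes] (one phase).
#' @param trials_by_patient Named list of labeled trial tables.
#' @param phase `"encoding"` or `"recognition"`.
#' @param window,sigma,bin PSTH parameters (time axis common to all units).
#' @param min_trials Minimum trials per condition cell (default 1).
#' @param max_trials Cap on stored single trials per cell (memory bound;
#'   cells are truncated to the first `max_trials` trials).
#' @return Object of class `population_tensor`: `avg` (array
#'   `[unit, emotion, memory, time]`), `single` (array
#'   `[unit, emotion, memory, trial, time]`, NA-padded), `counts`
#'   (`[unit, emotion, memory]`), `time`, `emotions`, `memories`, `units`
#'   (metadata data frame).
#' @export
build_population_tensor <- function(units, trials_by_patient,
                                    phase = c("encoding", "recognition"),
                                    window = default_windows()$psth,
                                    sigma = 0.05, bin = 0.01,
                                    min_trials = 1L, max_trials = 40L) {
  phase <- match.arg(phase)
  emotions <- c("e", "n")
  memories <- if (phase == "encoding") c("R", "F") else
    c("RHit", "Miss", "CR")
  centers <- seq(window[1] + bin / 2, window[2], by = bin)
  TT <- length(centers)
  keep_units <- list()
  dropped <- character()
  slices <- list()
  for (u in units) {
    tr <- trials_by_patient[[u$patient_id]]
    tr <- tr[!tr$excluded_primary, , drop = FALSE]
    emo <- ifelse(tr$emotion == "emotional", "e", "n")
    mem <- memory_level(tr$outcome)
    cnt <- table(factor(emo, emotions), factor(mem, memories))
    if (any(cnt < min_trials)) {
      dropped <- c(dropped, sprintf(
        "unit %s: empty/underfilled condition cell (min count %d)",
        u$unit_id, min(cnt)))
      next
    }
    p <- compute_psth(u, window = window, sigma = sigma, bin = bin)
    idx <- match(tr$trial_id, p$trial_ids)
    single <- array(NA_real_, c(2, length(memories), max_trials, TT))
    counts <- matrix(0L, 2, length(memories))
    for (ei in seq_along(emotions)) {
      for (mi in seq_along(memories)) {
        rows <- which(emo == emotions[ei] & mem == memories[mi])
        rows <- rows[seq_len(min(length(rows), max_trials))]
        counts[ei, mi] <- length(rows)
        single[ei, mi, seq_along(rows), ] <- p$rates[idx[rows], , drop = FALSE]
      }
    }
    slices[[length(slices) + 1L]] <- list(single = single, counts = counts)
    keep_units[[length(keep_units) + 1L]] <- u
  }
  U <- length(keep_units)
  if (U == 0L) stop("no units left after condition-cell filtering",
                    call. = FALSE)
  single <- array(NA_real_, c(U, 2, length(memories), max_trials, TT))
  counts <- array(0L, c(U, 2, length(memories)))
  for (i in seq_len(U)) {
    single[i, , , , ] <- slices[[i]]$single
    counts[i, , ] <- slices[[i]]$counts
  }
  avg <- apply(single, c(1, 2, 3, 5), mean, na.rm = TRUE)
  meta <- data.frame(
    unit_id = vapply(keep_units, `[[`, "", "unit_id"),
    patient_id = vapply(keep_units, `[[`, "", "patient_id"),
    region = vapply(keep_units, `[[`, "", "region"),
    stringsAsFactors = FALSE)
  structure(list(avg = avg, single = single, counts = counts,
                 time = centers, emotions = emotions, memories = memories,
                 units = meta, phase = phase),
            class = "population_tensor",
            dropped = dropped)
}

#' @export
print.population_tensor <- function(x, ...) {
  d <- dim(x$avg)
  cat(sprintf(
    "<population_tensor> %s: %d units x %d emotions x %d memory x %d bins\n",
    x$phase, d[1], d[2], d[3], d[4]))
  invisible(x)
}
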