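#' @keywords internal
"_PACKAGE"

# Time conventions used throughout the package:
#   * all times are seconds relative to stimulus onset (t = 0);
#   * stimulus offset is at t = 0.5 s;
#   * analysis windows are half-open [lo, hi), EXCEPT the artifact windows
#     around stimulus onset/offset, which are closed [lo, hi];
#   * default baseline window [-1.5, -0.2), stimulus window [0.2, 1.5).

#' Default analysis windows
#'
#' Returns the default peri-stimulus analysis windows: baseline
#' `[-1.5, -0.2)` s and stimulus `[0.2, 1.5)` s relative to stimulus onset,
#' plus the full recorded peri-stimulus window and the PSTH/dPCA window.
#'
#' @return Named list of 2-vectors `c(lo, hi)` in seconds:
#'   `baseline`, `stimulus`, `peri` (recorded span), `psth` (dPCA time axis).
#' @export
default_windows <- function() {
  list(
    baseline = c(-1.5, -0.2),
    stimulus = c(0.2, 1.5),
    peri     = c(-1.5, 2.5),
    psth     = c(-0.5, 2.5)
  )
}

assert_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || !all(is.finite(window)) ||
      window[2] <= window[1]) {
    stop(sprintf("%s must be c(lo, hi) with hi > lo", what), call. = FALSE)
  }
  invisible(window)
}

REGIONS <- c("HIP", "AMY", "EC")
PHASES <- c("encoding", "recognition")
ENC_OUTCOMES <- c("eR", "nR", "eF", "nF", "eK", "nK")
REC_OUTCOMES <- c("eRHit", "nRHit", "eKHit", "nKHit", "eMiss", "nMiss",
                  "eCR", "nCR", "eFA", "nFA")

#' Construct a single-unit spike container
#'
#' A `unit_spikes` object holds one putative neuron's trial-aligned spike
#' times: a list with one sorted numeric vector per trial, indexed by trial
#' id, plus identity metadata (patient, region, task phase) and an optional
#' mean waveform.
#'
#' @param unit_id,patient_id Character identifiers.
#' @param region One of `"HIP"`, `"AMY"`, `"EC"`.
#' @param phase One of `"encoding"`, `"recognition"`.
#' @param spikes Named list of numeric vectors; names are trial ids, each
#'   vector holds spike times in seconds relative to stimulus onset, sorted
#'   ascending.
#' @param window Peri-stimulus window `c(lo, hi)` the spikes were recorded
#'   in; spikes outside it are an error.
#' @param waveform Optional list with `samples` (numeric, microvolts) and
#'   `fs` (sampling rate, Hz).
#' @return An object of class `unit_spikes`.
#' @export
unit_spikes <- function(unit_id, patient_id, region, phase, spikes,
                        window = default_windows()$peri, waveform = NULL) {
  region <- match.arg(region, REGIONS)
  phase <- match.arg(phase, PHASES)
  assert_window(window)
  if (is.null(names(spikes)) || anyDuplicated(names(spikes))) {
    stop("'spikes' must be a list uniquely named by trial id", call. = FALSE)
  }
  spikes <- lapply(spikes, function(s) {
    s <- as.numeric(s)
    if (is.unsorted(s)) {
      stop("per-trial spike times must be sorted ascending", call. = FALSE)
    }
    if (length(s) && (min(s) < window[1] || max(s) > window[2])) {
      stop("spike times outside the peri-stimulus window", call. = FALSE)
    }
    s
  })
  structure(
    list(unit_id = as.character(unit_id), patient_id = as.character(patient_id),
         region = region, phase = phase, spikes = spikes, window = window,
         waveform = waveform),
    class = "unit_spikes"
  )
}

#' @export
print.unit_spikes <- function(x, ...) {
  cat(sprintf("<unit_spikes> %s  patient %s  %s  %s\n", x$unit_id,
              x$patient_id, x$region, x$phase))
  cat(sprintf("  %d trials, %d spikes, window [%g, %g] s\n",
              length(x$spikes), sum(lengths(x$spikes)),
              x$window[1], x$window[2]))
  invisible(x)
}

n_spikes <- function(unit) sum(lengths(unit$spikes))

#' Derive trial outcome labels from encoding and recognition responses
#'
#' Matches every encoding item to its recognition re-presentation (by
#' `stimulus_id`) and assigns subsequent-memory outcomes. Encoding trials
#' become `eR`/`nR` (old item later given a Remember response), `eF`/`nF`
#' (later judged New, i.e. forgotten), or `eK`/`nK` (later judged Know;
#' flagged `excluded_primary` because Know trials are excluded from the
#' primary analyses). Recognition old items become `RHit`/`KHit`/`Miss` by
#' response R/K/N and new items `CR`/`FA` by response N versus R-or-K, each
#' prefixed by emotion (`e`/`n`). Know hits and false alarms are also
#' flagged `excluded_primary`.
#'
#' @param encoding Data frame with columns `trial_id`, `stimulus_id`,
#'   `emotion` ("emotional"/"neutral"), `response` (encoding judgment,
#'   e.g. "indoor"/"outdoor"; not used for labeling), optionally
#'   `reaction_time`.
#' @param recognition Data frame with columns `trial_id`, `stimulus_id`,
#'   `emotion`, `old_new` ("old"/"new"), `response` ("R"/"K"/"N"),
#'   optionally `reaction_time`.
#' @return List with labeled data frames `encoding` and `recognition`, each
#'   gaining `outcome` and logical `excluded_primary` columns; encoding also
#'   gains `old_new = "n/a"`.
#' @export
label_trials <- function(encoding, recognition) {
  need_enc <- c("trial_id", "stimulus_id", "emotion")
  need_rec <- c("trial_id", "stimulus_id", "emotion", "old_new", "response")
  miss <- setdiff(need_enc, names(encoding))
  if (length(miss)) stop("encoding table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_rec, names(recognition))
  if (length(miss)) stop("recognition table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(recognition$old_new %in% c("old", "new"))) {
    stop("recognition old_new must be 'old' or 'new'", call. = FALSE)
  }
  if (!all(recognition$response %in% c("R", "K", "N"))) {
    bad <- setdiff(unique(recognition$response), c("R", "K", "N"))
    stop("unknown recognition response code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  old <- recognition[recognition$old_new == "old", ]
  if (anyDuplicated(old$stimulus_id)) {
    stop("stimulus presented as old more than once at recognition",
         call. = FALSE)
  }
  idx <- match(encoding$stimulus_id, old$stimulus_id)
  if (anyNA(idx)) {
    bad <- encoding$trial_id[is.na(idx)][1]
    stop(sprintf(
      "encoding trial %s: stimulus has no matching old recognition trial",
      bad), call. = FALSE)
  }
  emo_pfx <- function(emotion) ifelse(emotion == "emotional", "e", "n")

  later <- old$response[idx]
  enc_suffix <- c(R = "R", N = "F", K = "K")[later]
  encoding$old_new <- "n/a"
  encoding$outcome <- paste0(emo_pfx(encoding$emotion), enc_suffix)
  encoding$excluded_primary <- enc_suffix == "K"

  rec_map_old <- c(R = "RHit", K = "KHit", N = "Miss")
  is_old <- recognition$old_new == "old"
  suffix <- character(nrow(recognition))
  suffix[is_old] <- rec_map_old[recognition$response[is_old]]
  suffix[!is_old] <- ifelse(recognition$response[!is_old] == "N", "CR", "FA")
  recognition$outcome <- paste0(emo_pfx(recognition$emotion), suffix)
  recognition$excluded_primary <- suffix %in% c("KHit", "FA")

  list(encoding = encoding, recognition = recognition)
}

#' Remove artifact spikes around stimulus onset and offset
#'
#' Mechanical/electrical artifacts can masquerade as spikes time-locked to
#' the stimulus transitions. Spikes within 3 ms of stimulus appearance
#' (t = 0) or disappearance (t = 0.5 s) are deleted; the windows are treated
#' as closed intervals `[-0.003, 0.003]` and `[0.497, 0.503]`.
#'
#' @param unit A [unit_spikes] object.
#' @param onset,offset Stimulus onset/offset times (s).
#' @param halfwidth Half-width of the deletion window (s, default 0.003).
#' @return The unit with artifact spikes removed; attribute
#'   `"n_removed"` records the per-trial count of deleted spikes.
#' @export
remove_artifact_spikes <- function(unit, onset = 0, offset = 0.5,
                                   halfwidth = 0.003) {
  stopifnot(inherits(unit, "unit_spikes"))
  removed <- integer(length(unit$spikes))
  for (i in seq_along(unit$spikes)) {
    s <- unit$spikes[[i]]
    keep <- !((s >= onset - halfwidth & s <= onset + halfwidth) |
                (s >= offset - halfwidth & s <= offset + halfwidth))
    removed[i] <- sum(!keep)
    unit$spikes[[i]] <- s[keep]
  }
  attr(unit, "n_removed") <- stats::setNames(removed, names(unit$spikes))
  unit
}

#' Unit inclusion quality control
#'
#' Applies the standard spike-sorting quality rules: a unit is retained iff
#' (i) fewer than 3% of its interspike intervals are under 3 ms, (ii) its
#' mean firing rate exceeds 0.25 Hz, and (iii) it fired at least one spike
#' on at least 50 (encoding) or 100 (recognition) trials. ISIs are computed
#' on spike times concatenated in trial order; intervals spanning trial
#' boundaries are excluded (the inter-trial gap makes them uninformative).
#' Mean rate is total spikes / (number of trials x peri-stimulus window
#' length).
#'
#' @param units List of [unit_spikes] objects (one phase).
#' @param phase `"encoding"` or `"recognition"`; determines the minimum
#'   number of trials with a spike (50 / 100).
#' @param isi_threshold_s ISIs shorter than this count as refractory-period
#'   violations (default 0.003 s).
#' @param max_pct_short_isi Exclusion threshold on the percentage of short
#'   ISIs (default 3).
#' @param min_rate_hz Minimum mean firing rate (default 0.25 Hz, strict).
#' @return List with `units` (the retained units) and `report`, a data frame
#'   with one row per input unit: `unit_id`, `pct_isi_under_3ms`,
#'   `mean_rate`, `n_trials_with_spike`, `included`, `exclusion_reasons`.
#' @export
quality_filter <- function(units, phase = c("encoding", "recognition"),
                           isi_threshold_s = 0.003, max_pct_short_isi = 3,
                           min_rate_hz = 0.25) {
  phase <- match.arg(phase)
  min_trials <- if (phase == "encoding") 50L else 100L
  rows <- lapply(units, function(u) {
    stopifnot(inherits(u, "unit_spikes"))
    nsp <- n_spikes(u)
    ntr <- length(u$spikes)
    win_len <- diff(u$window)
    isis <- unlist(lapply(u$spikes, function(s) if (length(s) > 1) diff(s)),
                   use.names = FALSE)
    pct_short <- if (length(isis)) 100 * mean(isis < isi_threshold_s) else 0
    rate <- nsp / (ntr * win_len)
    n_with <- sum(lengths(u$spikes) > 0L)
    reasons <- character()
    if (nsp == 0L) reasons <- c(reasons, "no spikes")
    if (pct_short >= max_pct_short_isi) {
      reasons <- c(reasons, sprintf("%.2f%% ISIs < %g ms", pct_short,
                                    1000 * isi_threshold_s))
    }
    if (rate <= min_rate_hz) {
      reasons <- c(reasons, sprintf("mean rate %.3f Hz <= %g Hz", rate,
                                    min_rate_hz))
    }
    if (n_with < min_trials) {
      reasons <- c(reasons, sprintf("spikes on only %d/%d trials (min %d)",
                                    n_with, ntr, min_trials))
    }
    data.frame(unit_id = u$unit_id, patient_id = u$patient_id,
               region = u$region,
               pct_isi_under_3ms = pct_short, mean_rate = rate,
               n_trials_with_spike = n_with,
               included = length(reasons) == 0L,
               exclusion_reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(units = units[report$included], report = report)
}

#' Spike width from a mean waveform
#'
#' Spike width is the peak-to-trough separation of the mean waveform in
#' milliseconds: the time from the global extremum of the leading sign to
#' the subsequent opposite-sign extremum.
#'
#' @param waveform List with `samples` (numeric vector, microvolts) and
#'   `fs` (sampling rate, Hz).
#' @param leading `"trough"` (default; negative-first convention typical of
#'   extracellular waveforms) or `"peak"`.
#' @return Spike width in ms.
#' @export
spike_width <- function(waveform, leading = c("trough", "peak")) {
  leading <- match.arg(leading)
  s <- waveform$samples
  fs <- waveform$fs
  if (length(s) < 3L || is.null(fs) || fs <= 0) {
    stop("waveform needs >= 3 samples and a positive sampling rate",
         call. = FALSE)
  }
  if (diff(range(s)) == 0 || all(diff(s) >= 0) || all(diff(s) <= 0)) {
    stop("waveform is flat or monotone: spike width undefined", call. = FALSE)
  }
  i1 <- if (leading == "trough") which.min(s) else which.max(s)
  after <- s[seq(i1, length(s))]
  i2 <- i1 - 1L + if (leading == "trough") which.max(after) else
    which.min(after)
  if (i2 <= i1) {
    stop("no opposite-sign extremum after the leading extremum",
         call. = FALSE)
  }
  1000 * (i2 - i1) / fs
}

# ---- interchange formats -------------------------------------------------

#' Write / read a dataset in the CSV interchange format
#'
#' The interchange format is two delimited text tables: a spike table with
#' one row per spike (`patient_id`, `unit_id`, `region`, `phase`,
#' `trial_id`, `spike_time_s`) and a trial table with the labeled
#' `TrialRecord` fields. `write_dataset()` serializes a dataset list;
#' `read_dataset()` validates the schema and reassembles [unit_spikes]
#' objects and trial tables. Units present in the spike table get one spike
#' vector per trial of their phase, including empty trials.
#'
#' @param dataset List with `units` (list of [unit_spikes]) and `trials`
#'   (list with labeled `encoding` / `recognition` data frames).
#' @param dir Directory to write `spikes.csv` and `trials.csv` into.
#' @return `write_dataset()` returns the paths invisibly; `read_dataset()`
#'   returns a dataset list.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- spike_table(dataset$units)
  tr <- trial_table(dataset$trials)
  sp_path <- file.path(dir, "spikes.csv")
  tr_path <- file.path(dir, "trials.csv")
  utils::write.csv(sp, sp_path, row.names = FALSE)
  utils::write.csv(tr, tr_path, row.names = FALSE)
  invisible(c(spikes = sp_path, trials = tr_path))
}

#' Flatten units to a one-row-per-spike table
#' @param units List of [unit_spikes].
#' @return Data frame with columns `patient_id`, `unit_id`, `region`,
#'   `phase`, `trial_id`, `spike_time_s`.
#' @export
spike_table <- function(units) {
  rows <- lapply(units, function(u) {
    n <- lengths(u$spikes)
    data.frame(patient_id = u$patient_id, unit_id = u$unit_id,
               region = u$region, phase = u$phase,
               trial_id = rep(names(u$spikes), n),
               spike_time_s = unlist(u$spikes, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), unit_id = character(),
                      region = character(), phase = character(),
                      trial_id = character(), spike_time_s = numeric())
  }
  out
}

trial_table <- function(trials) {
  cols <- c("trial_id", "phase", "stimulus_id", "emotion", "old_new",
            "response", "outcome", "excluded_primary", "reaction_time")
  fix <- function(df, phase) {
    df$phase <- phase
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[cols]
  }
  rbind(fix(trials$encoding, "encoding"),
        fix(trials$recognition, "recognition"))
}

#' @rdname write_dataset
#' @param path Directory containing `spikes.csv` and `trials.csv`, written
#'   by [write_dataset()].
#' @param window Peri-stimulus window to attach to the reassembled units.
#' @export
read_dataset <- function(path, window = default_windows()$peri) {
  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        colClasses = c(trial_id = "character"))
  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        colClasses = c(trial_id = "character"))
  need_sp <- c("patient_id", "unit_id", "region", "phase", "trial_id",
               "spike_time_s")
  miss <- setdiff(need_sp, names(sp))
  if (length(miss)) stop("spike table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  need_tr <- c("trial_id", "phase", "emotion", "outcome")
  miss <- setdiff(need_tr, names(tr))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  trials <- list(
    encoding = tr[tr$phase == "encoding", , drop = FALSE],
    recognition = tr[tr$phase == "recognition", , drop = FALSE]
  )
  units <- list()
  if (nrow(sp)) {
    key <- paste(sp$unit_id, sp$phase, sep = "\r")
    for (k in unique(key)) {
      rows <- sp[key == k, , drop = FALSE]
      phase <- rows$phase[1]
      tids <- trials[[phase]]$trial_id
      spikes <- lapply(stats::setNames(tids, tids), function(tid) {
        sort(rows$spike_time_s[rows$trial_id == tid])
      })
      units[[length(units) + 1L]] <- unit_spikes(
        unit_id = rows$unit_id[1], patient_id = rows$patient_id[1],
        region = rows$region[1], phase = phase, spikes = spikes,
        window = window)
    }
  }
  list(units = units, trials = trials)
}
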