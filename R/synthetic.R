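# Synthetic cohorts: inhomogeneous-Poisson spike trains with planted
# emotion / subsequent-memory effects, on a task design mirroring the
# emotional memory paradigm (40 emotional / 80 neutral encoding scenes,
# 0.5 s presentation, 3.5 s ISI, 240-trial recognition session, no two
# emotional items adjacent).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a bounded child seed from a master seed, stable across platforms.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Generate a pseudo-random task design
#'
#' Builds encoding and recognition trial tables for one synthetic session:
#' by default 120 encoding trials (40 emotional, 80 neutral) and 240
#' recognition trials (every encoding item re-presented as old, plus an
#' equal number of new items), with stimulus order constrained so that no
#' two emotional items are adjacent, mirroring the presentation constraint
#' of the task (0.5 s presentation, 3.5 s interstimulus interval).
#'
#' Non-adjacency is enforced constructively: emotional items are placed
#' into distinct gaps between neutral items, which requires
#' `n_emotional <= n_neutral + 1`.
#'
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param n_emotional,n_neutral Encoding counts per emotion (defaults 40/80).
#' @param n_new_emotional,n_new_neutral New items added at recognition
#'   (defaults equal to the encoding counts).
#' @return List of data frames `encoding` and `recognition` (unlabeled:
#'   outcomes are assigned by [assign_behavior()]).
#' @export
build_task_design <- function(seed = NULL, n_emotional = 40, n_neutral = 80,
                              n_new_emotional = n_emotional,
                              n_new_neutral = n_neutral) {
  with_seed(seed, {
    enc <- interleave_emotions(
      paste0("stim_e", seq_len(n_emotional)),
      paste0("stim_n", seq_len(n_neutral)))
    encoding <- data.frame(
      trial_id = sprintf("enc_%03d", seq_along(enc$id)),
      stimulus_id = enc$id, emotion = enc$emotion,
      response = sample(c("indoor", "outdoor"), length(enc$id),
                        replace = TRUE),
      stringsAsFactors = FALSE)
    old_e <- paste0("stim_e", seq_len(n_emotional))
    old_n <- paste0("stim_n", seq_len(n_neutral))
    new_e <- paste0("new_e", seq_len(n_new_emotional))
    new_n <- paste0("new_n", seq_len(n_new_neutral))
    rec <- interleave_emotions(c(old_e, new_e), c(old_n, new_n))
    recognition <- data.frame(
      trial_id = sprintf("rec_%03d", seq_along(rec$id)),
      stimulus_id = rec$id, emotion = rec$emotion,
      old_new = ifelse(startsWith(rec$id, "stim_"), "old", "new"),
      stringsAsFactors = FALSE)
    list(encoding = encoding, recognition = recognition)
  })
}

# Random order of emotional/neutral stimulus ids with no two emotional
# items adjacent: shuffle each pool, then drop the shuffled emotional items
# into distinct gaps between the neutral sequence.
interleave_emotions <- function(emotional_ids, neutral_ids) {
  ne <- length(emotional_ids)
  nn <- length(neutral_ids)
  if (ne > nn + 1) {
    stop(sprintf(paste0("cannot order %d emotional among %d neutral items ",
                        "without adjacent emotional pairs"), ne, nn),
         call. = FALSE)
  }
  e <- sample(emotional_ids)
  n <- sample(neutral_ids)
  gaps <- sort(sample.int(nn + 1, ne))   # gap g precedes neutral item g
  id <- character(ne + nn)
  emo <- character(ne + nn)
  pos <- 1L
  ei <- 1L
  for (g in seq_len(nn + 1)) {
    if (ei <= ne && gaps[ei] == g) {
      id[pos] <- e[ei]; emo[pos] <- "emotional"; pos <- pos + 1L; ei <- ei + 1L
    }
    if (g <= nn) {
      id[pos] <- n[g]; emo[pos] <- "neutral"; pos <- pos + 1L
    }
  }
  list(id = id, emotion = emo)
}

#' Default behavioral response probabilities
#'
#' Per-emotion probabilities of Remember / Know / New responses to old
#' items, and the false-alarm probability for new items. Defaults give a
#' clearly above-chance recognizer (hit rates well above the false-alarm
#' rate) with few Know responses, mirroring the task's low Know / false
#' alarm counts.
#'
#' @return List with matrix `old` (rows emotional/neutral, cols R/K/N) and
#'   scalar `p_fa`.
#' @export
default_behavior_rates <- function() {
  old <- rbind(emotional = c(R = 0.55, K = 0.10, N = 0.35),
               neutral   = c(R = 0.50, K = 0.10, N = 0.40))
  list(old = old, p_fa = 0.10)
}

#' Draw behavioral outcomes for a task design
#'
#' Samples a Remember/Know/New response for every old recognition item from
#' the per-emotion response probabilities, a New-vs-false-alarm response for
#' every new item, then derives encoding subsequent-memory labels through
#' [label_trials()].
#'
#' @param design Output of [build_task_design()].
#' @param rates As returned by [default_behavior_rates()]; each row of
#'   `rates$old` must sum to 1.
#' @param seed Integer seed.
#' @return Labeled trial tables (list `encoding`, `recognition`).
#' @export
assign_behavior <- function(design, rates = default_behavior_rates(),
                            seed = NULL) {
  old <- rates$old
  if (any(abs(rowSums(old) - 1) > 1e-8) || any(old < 0)) {
    stop("rates$old rows must be probabilities summing to 1", call. = FALSE)
  }
  if (rates$p_fa < 0 || rates$p_fa > 1) {
    stop("rates$p_fa must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    rec <- design$recognition
    resp <- character(nrow(rec))
    for (i in seq_len(nrow(rec))) {
      if (rec$old_new[i] == "old") {
        p <- old[ifelse(rec$emotion[i] == "emotional", "emotional",
                        "neutral"), ]
        resp[i] <- sample(colnames(old), 1L, prob = p)
      } else {
        resp[i] <- if (stats::runif(1) < rates$p_fa) {
          sample(c("R", "K"), 1L)
        } else "N"
      }
    }
    rec$response <- resp
    label_trials(design$encoding, rec)
  })
}

#' Construct a synthetic unit response profile
#'
#' Parameterizes one simulated neuron's inhomogeneous-Poisson intensity:
#' `lambda(t | trial) = baseline * (1 + bump(t) * G)` with a Gaussian bump
#' `exp(-(t - latency)^2 / (2 width^2))` and condition-dependent gain
#' `G = event_gain + emotion_gain * 1[emotional] + memory_gain *
#' 1[remembered] + interaction_gain * 1[emotional & remembered]`, clipped at
#' zero. Gains are dimensionless multiples of the baseline rate.
#' "Remembered" means outcome R (encoding) or RHit (recognition).
#'
#' @param baseline_rate Baseline rate (Hz, > 0).
#' @param event_gain Condition-independent response amplitude (>= 0).
#' @param emotion_gain,memory_gain,interaction_gain Signed condition gains.
#' @param response_latency,response_width Bump center and SD (s).
#' @param refractory Dead time (s); spikes closer than this are deleted.
#' @return Object of class `unit_profile`.
#' @export
unit_profile <- function(baseline_rate = 2, event_gain = 0,
                         emotion_gain = 0, memory_gain = 0,
                         interaction_gain = 0, response_latency = 0.3,
                         response_width = 0.2, refractory = 0.002) {
  stopifnot(baseline_rate > 0, event_gain >= 0, response_width > 0,
            refractory >= 0)
  structure(list(baseline_rate = baseline_rate, event_gain = event_gain,
                 emotion_gain = emotion_gain, memory_gain = memory_gain,
                 interaction_gain = interaction_gain,
                 response_latency = response_latency,
                 response_width = response_width, refractory = refractory),
            class = "unit_profile")
}

profile_gain <- function(profile, emotional, remembered) {
  profile$event_gain +
    profile$emotion_gain * emotional +
    profile$memory_gain * remembered +
    profile$interaction_gain * emotional * remembered
}

is_remembered_outcome <- function(outcome) {
  substring(outcome, 2) %in% c("R", "RHit")
}

#' Simulate one unit's spike trains for a labeled design
#'
#' Draws per-trial spike trains from the profile's intensity function by
#' thinning a homogeneous Poisson process at the per-trial intensity
#' ceiling, then enforces refractoriness by deleting any spike closer than
#' `refractory` to its predecessor.
#'
#' @param profile A [unit_profile].
#' @param trials Labeled trial table for one phase (needs `trial_id`,
#'   `emotion`, `outcome`).
#' @param phase `"encoding"` or `"recognition"`.
#' @param seed Integer seed.
#' @param unit_id,patient_id,region Metadata for the returned unit.
#' @param window Peri-stimulus simulation window (s).
#' @return A [unit_spikes] object.
#' @export
simulate_unit <- function(profile, trials, phase = "encoding", seed = NULL,
                          unit_id = "u1", patient_id = "p1", region = "HIP",
                          window = default_windows()$peri) {
  assert_window(window)
  with_seed(seed, {
    emotional <- as.numeric(trials$emotion == "emotional")
    remembered <- as.numeric(is_remembered_outcome(trials$outcome))
    span <- diff(window)
    spikes <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      g <- profile_gain(profile, emotional[i], remembered[i])
      lambda_max <- profile$baseline_rate * (1 + max(0, g))
      n_cand <- stats::rpois(1, lambda_max * span)
      t_cand <- sort(stats::runif(n_cand, window[1], window[2]))
      bump <- exp(-(t_cand - profile$response_latency)^2 /
                    (2 * profile$response_width^2))
      lam <- pmax(0, profile$baseline_rate * (1 + bump * g))
      keep <- stats::runif(n_cand) < lam / lambda_max
      s <- t_cand[keep]
      if (profile$refractory > 0 && length(s) > 1) {
        ok <- logical(length(s))
        ok[1] <- TRUE
        last <- s[1]
        for (j in seq_along(s)[-1]) {
          if (s[j] - last >= profile$refractory) {
            ok[j] <- TRUE
            last <- s[j]
          }
        }
        s <- s[ok]
      }
      spikes[[i]] <- s
    }
    names(spikes) <- trials$trial_id
    unit_spikes(unit_id, patient_id, region, phase, spikes, window = window)
  })
}

#' Default cohort configuration
#'
#' The defaults emulate the recorded cohort's structure: 5 patients with
#' ~52 units each spread over hippocampus, amygdala and entorhinal cortex
#' (~260 units, the scale of the 258/284 analyzable units per phase);
#' log-normal baseline rates with median 2 Hz (so a few units straddle the
#' 0.25 Hz inclusion boundary); ~10% emotion-selective, ~7%
#' memory-selective and ~6% interaction units, the remainder split between
#' event-only responders and unmodulated units.
#'
#' @param n_patients,units_per_patient Cohort size.
#' @param prop_emotion,prop_memory,prop_interaction,prop_event Fractions of
#'   units per planted effect class (must sum to <= 1; the rest are
#'   unmodulated).
#' @param gain Magnitude of planted condition gains (multiples of baseline).
#' @param event_gain Event gain of event-only responders; selective units
#'   also receive it so condition effects ride on a stimulus response.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @return Named list of configuration values.
#' @export
cohort_config <- function(n_patients = 5, units_per_patient = 52,
                          prop_emotion = 0.10, prop_memory = 0.07,
                          prop_interaction = 0.06, prop_event = 0.30,
                          gain = 1.5, event_gain = 1.0,
                          baseline_meanlog = log(2), baseline_sdlog = 0.8) {
  props <- c(prop_emotion, prop_memory, prop_interaction, prop_event)
  if (any(props < 0) || sum(props) > 1) {
    stop("effect-class fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  list(n_patients = n_patients, units_per_patient = units_per_patient,
       prop_emotion = prop_emotion, prop_memory = prop_memory,
       prop_interaction = prop_interaction, prop_event = prop_event,
       gain = gain, event_gain = event_gain,
       baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog)
}

#' Simulate a full multi-patient cohort with ground truth
#'
#' Generates one task design + behavioral outcomes per patient and a
#' population of simulated units with planted effect classes. Units are
#' assigned to classes `emotion`, `memory`, `interaction`, `event` or
#' `none` at the configured fractions; condition gains take magnitude
#' `config$gain` with random sign for emotion/memory units (effects can be
#' increases or decreases) and positive sign for interaction units.
#'
#' @param config From [cohort_config()].
#' @param seed Integer master seed; all per-patient and per-unit streams are
#'   derived from it, so a fixed seed reproduces the cohort exactly.
#' @param phases Phases to simulate (default both).
#' @return List with `units` (list of [unit_spikes] across phases),
#'   `trials` (per patient: labeled encoding/recognition tables),
#'   `ground_truth` (data frame: unit_id, patient_id, region, class, gains,
#'   baseline) and `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            phases = c("encoding", "recognition")) {
  n_units <- config$n_patients * config$units_per_patient
  classes <- with_seed(child_seed(seed, "classes"), {
    n_each <- round(n_units * c(config$prop_emotion, config$prop_memory,
                                config$prop_interaction, config$prop_event))
    cls <- rep("none", n_units)
    cls[seq_len(sum(n_each))] <- rep(c("emotion", "memory", "interaction",
                                       "event"), n_each)
    sample(cls)
  })
  units <- list()
  trials <- list()
  gt <- vector("list", n_units)
  k <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("p%02d", p)
    design <- build_task_design(seed = child_seed(seed, pid, "design"))
    labeled <- assign_behavior(design, seed = child_seed(seed, pid, "beh"))
    trials[[pid]] <- labeled
    for (u in seq_len(config$units_per_patient)) {
      k <- k + 1L
      uid <- sprintf("%s_u%03d", pid, u)
      region <- REGIONS[1L + (u %% 3L)]
      pars <- with_seed(child_seed(seed, uid, "pars"), {
        base <- stats::rlnorm(1, config$baseline_meanlog,
                              config$baseline_sdlog)
        sgn <- sample(c(-1, 1), 1)
        g <- config$gain
        list(base = base,
             emotion = if (classes[k] == "emotion") sgn * g else 0,
             memory = if (classes[k] == "memory") sgn * g else 0,
             interaction = if (classes[k] == "interaction") g else 0,
             event = if (classes[k] %in% c("none")) 0 else
               config$event_gain)
      })
      prof <- unit_profile(
        baseline_rate = pars$base, event_gain = pars$event,
        emotion_gain = pars$emotion, memory_gain = pars$memory,
        interaction_gain = pars$interaction)
      for (ph in phases) {
        units[[length(units) + 1L]] <- simulate_unit(
          prof, labeled[[ph]], phase = ph,
          seed = child_seed(seed, uid, ph),
          unit_id = uid, patient_id = pid, region = region)
      }
      gt[[k]] <- data.frame(
        unit_id = uid, patient_id = pid, region = region,
        class = classes[k], baseline_rate = pars$base,
        event_gain = pars$event, emotion_gain = pars$emotion,
        memory_gain = pars$memory, interaction_gain = pars$interaction,
        stringsAsFactors = FALSE)
    }
  }
  list(units = units, trials = trials,
       ground_truth = do.call(rbind, gt), seed = seed)
}

#' Extract one patient's labeled trials for a phase from a cohort
#' @param cohort Output of [simulate_cohort()].
#' @param patient_id Patient identifier.
#' @param phase `"encoding"` or `"recognition"`.
#' @return Labeled trial data frame.
#' @export
cohort_trials <- function(cohort, patient_id, phase) {
  cohort$trials[[patient_id]][[phase]]
}

#' Subset cohort units by phase (and optionally region)
#' @param cohort Output of [simulate_cohort()].
#' @param phase Phase to keep.
#' @param region Optional region filter.
#' @return List of [unit_spikes].
#' @export
cohort_units <- function(cohort, phase, region = NULL) {
  keep <- vapply(cohort$units, function(u) {
    u$phase == phase && (is.null(region) || u$region %in% region)
  }, logical(1))
  cohort$units[keep]
}
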