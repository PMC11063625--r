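# Shared fixtures: hand-built units/trials and synthetic tensors.

# A unit from an explicit list of per-trial spike vectors.
make_unit <- function(spikes, unit_id = "u1", patient_id = "p1",
                      region = "HIP", phase = "encoding",
                      window = c(-1.5, 2.5)) {
  names(spikes) <- sprintf("t%03d", seq_along(spikes))
  unit_spikes(unit_id, patient_id, region, phase, spikes, window = window)
}

# Minimal labeled encoding trial table matching make_unit() trial ids.
make_enc_trials <- function(n, emotion = NULL, outcome = NULL) {
  if (is.null(emotion)) emotion <- rep(c("emotional", "neutral"),
                                       length.out = n)
  if (is.null(outcome)) {
    outcome <- paste0(ifelse(emotion == "emotional", "e", "n"),
                      rep(c("R", "F"), each = 2, length.out = n))
  }
  data.frame(trial_id = sprintf("t%03d", seq_len(n)), phase = "encoding",
             emotion = emotion, old_new = "n/a", outcome = outcome,
             excluded_primary = substring(outcome, 2) == "K",
             stringsAsFactors = FALSE)
}

# Simulate a small labeled cohort for one phase (defaults: null cohort).
quick_cohort <- function(seed, n_patients = 2, units_per_patient = 6,
                         phases = "encoding", ...) {
  simulate_cohort(cohort_config(n_patients = n_patients,
                                units_per_patient = units_per_patient, ...),
                  seed = seed, phases = phases)
}

trials_for <- function(cohort, phase) lapply(cohort$trials, `[[`, phase)

# Hand-built population tensor: avg[u,e,m,t] from a function f(u,e,m,t),
# single trials = avg + iid Gaussian noise, n trials per cell.
make_tensor <- function(U, n_m = 2, TT = 30, n_trials = 5, noise_sd = 0,
                        f = function(u, e, m, t) 0, seed = 1,
                        time = seq(0.005, by = 0.01, length.out = TT),
                        regions = NULL, phase = "encoding") {
  set.seed(seed)
  avg <- array(0, c(U, 2, n_m, TT))
  for (u in seq_len(U)) for (e in 1:2) for (m in seq_len(n_m)) {
    avg[u, e, m, ] <- f(u, e, m, time)
  }
  single <- array(NA_real_, c(U, 2, n_m, n_trials, TT))
  for (j in seq_len(n_trials)) {
    single[, , , j, ] <- avg +
      array(stats::rnorm(U * 2 * n_m * TT, sd = noise_sd),
            c(U, 2, n_m, TT))
  }
  avg2 <- apply(single, c(1, 2, 3, 5), mean)
  if (is.null(regions)) {
    regions <- rep(c("HIP", "AMY", "EC"), length.out = U)
  }
  structure(list(
    avg = avg2, single = single,
    counts = array(n_trials, c(U, 2, n_m)),
    time = time, emotions = c("e", "n"),
    memories = if (n_m == 2) c("R", "F") else c("RHit", "Miss", "CR"),
    units = data.frame(unit_id = sprintf("u%03d", seq_len(U)),
                       patient_id = "p01", region = regions,
                       stringsAsFactors = FALSE),
    phase = phase), class = "population_tensor")
}

# Gaussian generative model for abs(z) tables (mixed-model tests): random
# patient and unit intercepts plus fixed condition effects.
make_ztable <- function(n_patients = 5, n_units = 40, n_trials = 120,
                        b_emotion = 0, b_memory = 0, b_interaction = 0,
                        sd_patient = 0.2, sd_unit = 0.3, sd_noise = 1,
                        seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_patients * n_units)
  k <- 0L
  for (p in seq_len(n_patients)) {
    a_p <- rnorm(1, 0, sd_patient)
    for (u in seq_len(n_units)) {
      k <- k + 1L
      a_u <- rnorm(1, 0, sd_unit)
      n_e <- round(n_trials / 3)
      emotion <- sample(rep(c("e", "n"), c(n_e, n_trials - n_e)))
      memory <- sample(rep(c("R", "F"), length.out = n_trials))
      mu <- 1 + a_p + a_u + b_emotion * (emotion == "e") +
        b_memory * (memory == "R") +
        b_interaction * (emotion == "e") * (memory == "R")
      rows[[k]] <- data.frame(
        patient_id = sprintf("p%02d", p),
        unit_id = sprintf("p%02d_u%03d", p, u),
        trial_id = sprintf("t%03d", seq_len(n_trials)),
        emotion = emotion, memory = memory,
        abs_z = mu + rnorm(n_trials, 0, sd_noise),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
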