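test_that("trial labeling maps responses to subsequent-memory outcomes", {
  enc <- data.frame(trial_id = c("e1", "e2", "e3"),
                    stimulus_id = c("s1", "s2", "s3"),
                    emotion = c("emotional", "neutral", "emotional"),
                    response = "indoor", stringsAsFactors = FALSE)
  rec <- data.frame(
    trial_id = c("r1", "r2", "r3", "r4"),
    stimulus_id = c("s1", "s2", "s3", "x1"),
    emotion = c("emotional", "neutral", "emotional", "neutral"),
    old_new = c("old", "old", "old", "new"),
    response = c("N", "R", "K", "N"), stringsAsFactors = FALSE)
  lab <- label_trials(enc, rec)
  # old emotional item answered New -> forgotten at encoding, Miss at rec
  expect_equal(lab$encoding$outcome, c("eF", "nR", "eK"))
  expect_equal(lab$recognition$outcome, c("eMiss", "nRHit", "eKHit", "nCR"))
  expect_equal(lab$encoding$excluded_primary, c(FALSE, FALSE, TRUE))
  expect_equal(lab$recognition$excluded_primary,
               c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(lab$encoding$old_new == "n/a"))
})

test_that("exhaustive labeling: all old answered R, all new answered N", {
  n <- 120
  enc <- data.frame(trial_id = paste0("e", 1:n),
                    stimulus_id = paste0("s", 1:n),
                    emotion = rep(c("emotional", "neutral"), c(40, 80)),
                    response = "outdoor", stringsAsFactors = FALSE)
  rec <- data.frame(trial_id = paste0("r", 1:(2 * n)),
                    stimulus_id = c(paste0("s", 1:n), paste0("x", 1:n)),
                    emotion = "neutral",
                    old_new = rep(c("old", "new"), each = n),
                    response = rep(c("R", "N"), each = n),
                    stringsAsFactors = FALSE)
  rec$emotion[1:40] <- "emotional"
  lab <- label_trials(enc, rec)
  suff <- substring(lab$recognition$outcome, 2)
  expect_equal(sum(suff == "RHit"), 120)
  expect_equal(sum(suff == "CR"), 120)
  expect_equal(sum(suff %in% c("Miss", "FA")), 0)
  expect_equal(sum(substring(lab$encoding$outcome, 2) == "R"), 120)
})

test_that("labeling errors name the offending trial / response", {
  enc <- data.frame(trial_id = "e1", stimulus_id = "s1",
                    emotion = "neutral", response = "indoor")
  rec <- data.frame(trial_id = "r1", stimulus_id = "OTHER",
                    emotion = "neutral", old_new = "old", response = "R")
  expect_error(label_trials(enc, rec), "e1")
  rec$stimulus_id <- "s1"
  rec$response <- "Z"
  expect_error(label_trials(enc, rec), "Z")
})

test_that("artifact removal deletes closed 3 ms windows at on/offset", {
  u <- make_unit(list(c(-0.002, 0.1, 0.499), numeric(0),
                      c(0.0031, 0.4969), c(-0.003, 0.003, 0.497, 0.503)))
  out <- remove_artifact_spikes(u)
  expect_equal(out$spikes[[1]], 0.1)
  expect_equal(out$spikes[[2]], numeric(0))
  # boundary convention: closed interval, so 0.0031 and 0.4969 survive
  expect_equal(out$spikes[[3]], c(0.0031, 0.4969))
  expect_equal(out$spikes[[4]], numeric(0))
  expect_equal(unname(attr(out, "n_removed")), c(2L, 0L, 0L, 4L))
  # idempotence
  twice <- remove_artifact_spikes(out)
  expect_equal(twice$spikes, out$spikes)
})

test_that("quality filter applies ISI, rate and trial-coverage rules", {
  # 3.5% of ISIs under 3 ms -> excluded
  n_short <- 7; n_long <- 193
  spk <- cumsum(c(0.01, rep(c(0.002, 0.018), c(n_short, n_long)))) - 1.4
  u_isi <- make_unit(c(list(spk), replicate(119, 0.1, simplify = FALSE)))
  # mean rate 0.20 Hz over 120 trials x 4 s window -> excluded
  u_slow <- make_unit(replicate(120, numeric(0), simplify = FALSE))
  for (i in 1:96) u_slow$spikes[[i]] <- runif(1, -1, 1)
  # healthy unit: 1 Hz, no short ISIs, spikes on 110/120 trials
  u_ok <- make_unit(c(replicate(110, seq(-1.4, 2.4, length.out = 4),
                                simplify = FALSE),
                      replicate(10, numeric(0), simplify = FALSE)),
                    unit_id = "ok")
  qf <- quality_filter(list(u_isi, u_slow, u_ok), "encoding")
  expect_equal(qf$report$included, c(FALSE, FALSE, TRUE))
  expect_gt(qf$report$pct_isi_under_3ms[1], 3)
  expect_lt(qf$report$mean_rate[2], 0.25)
  expect_match(qf$report$exclusion_reasons[2], "mean rate")
  expect_equal(length(qf$units), 1L)
  expect_equal(qf$units[[1]]$unit_id, "ok")
})

test_that("zero-spike unit is excluded with a reason, not an error", {
  u0 <- make_unit(replicate(120, numeric(0), simplify = FALSE))
  qf <- quality_filter(list(u0), "encoding")
  expect_false(qf$report$included)
  expect_match(qf$report$exclusion_reasons, "no spikes")
})

test_that("quality decisions depend only on the unit's own spikes", {
  set.seed(3)
  mk <- function(id) make_unit(replicate(120, sort(runif(rpois(1, 5),
                                                         -1.4, 2.4)),
                                         simplify = FALSE), unit_id = id)
  us <- lapply(c("a", "b", "c"), mk)
  r1 <- quality_filter(us, "encoding")$report
  r2 <- quality_filter(rev(us), "encoding")$report
  expect_equal(r1[order(r1$unit_id), ], r2[order(r2$unit_id), ],
               ignore_attr = TRUE)
})

test_that("spike width is the peak-trough separation in ms", {
  w <- numeric(60)
  w[20] <- -80; w[35] <- 40          # trough then peak, 30 kHz
  expect_equal(spike_width(list(samples = w, fs = 30000)), 0.5)
  # constructed biphasic template with 0.8 ms separation at 20 kHz
  t <- seq(0, 3, by = 1 / 20)        # ms
  biph <- -exp(-(t - 1)^2 / 0.05) + 0.6 * exp(-(t - 1.8)^2 / 0.1)
  expect_equal(spike_width(list(samples = biph, fs = 20000)), 0.8)
  expect_error(spike_width(list(samples = rep(1, 10), fs = 30000)),
               "undefined")
  expect_error(spike_width(list(samples = 1:10, fs = 30000)))
})

test_that("dataset round trip preserves spikes and labels exactly", {
  coh <- quick_cohort(seed = 21, n_patients = 1, units_per_patient = 2,
                      phases = c("encoding", "recognition"))
  ds <- list(units = coh$units,
             trials = coh$trials[["p01"]])
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(length(back$units), length(ds$units))
  # spike-count conservation and per-trial identity
  tot0 <- sum(vapply(ds$units, function(u) sum(lengths(u$spikes)), 0))
  tot1 <- sum(vapply(back$units, function(u) sum(lengths(u$spikes)), 0))
  expect_equal(tot1, tot0)
  u0 <- ds$units[[1]]
  u1 <- Filter(function(u) u$unit_id == u0$unit_id &&
                 u$phase == u0$phase, back$units)[[1]]
  expect_equal(u1$spikes[names(u0$spikes)], u0$spikes, tolerance = 1e-12)
  expect_equal(sort(back$trials$encoding$outcome),
               sort(ds$trials$encoding$outcome))
})

test_that("schema violations are reported by column name", {
  dir <- withr::local_tempdir()
  coh <- quick_cohort(seed = 22, n_patients = 1, units_per_patient = 1)
  write_dataset(list(units = coh$units, trials = coh$trials[["p01"]]), dir)
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  sp$region <- NULL
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "region")
})
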