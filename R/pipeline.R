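# Orchestration: behavioral summaries, run configuration, and the full
# QC -> responsiveness -> selectivity census -> abs(z) mixed model -> dPCA
# pipeline with a JSON report bundle.

#' Behavioral summary per patient and emotion
#'
#' Computes per patient x emotion the Remember/Know/New response
#' proportions to old items, the hit rate (Remember responses to old
#' items), the false-alarm rate (R or K responses to new items), corrected
#' recognition `PR = hit - FA`, and signal-detection `d' =
#' qnorm(hit) - qnorm(FA)` with the extreme-rate correction (rates of 0 or
#' 1 replaced by `1/(2N)` and `1 - 1/(2N)`). Also fits the cohort-level
#' two-factor repeated-measures ANOVA comparing remembered% against FA%
#' across emotions (factors memory and emotion within patient).
#'
#' @param trials_by_patient Named list (by patient) of labeled trial lists
#'   as returned by [assign_behavior()] (or a list of recognition tables).
#' @return List: `table` (per patient x emotion rates and d'), `anova`
#'   (data frame of the repeated-measures ANOVA with F and p per term).
#' @export
behavioral_summary <- function(trials_by_patient) {
  rows <- list()
  for (pid in names(trials_by_patient)) {
    rec <- trials_by_patient[[pid]]
    if (is.list(rec) && !is.data.frame(rec)) rec <- rec$recognition
    for (emo in c("emotional", "neutral")) {
      old <- rec[rec$emotion == emo & rec$old_new == "old", ]
      new <- rec[rec$emotion == emo & rec$old_new == "new", ]
      if (nrow(new) == 0L) {
        stop(sprintf("patient %s has no new %s trials", pid, emo),
             call. = FALSE)
      }
      hit <- mean(old$response == "R")
      fa <- mean(new$response != "N")
      corr <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
      dprime <- stats::qnorm(corr(hit, nrow(old))) -
        stats::qnorm(corr(fa, nrow(new)))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, emotion = emo,
        p_R = mean(old$response == "R"), p_K = mean(old$response == "K"),
        p_N = mean(old$response == "N"),
        hit_rate = hit, fa_rate = fa, PR = hit - fa, d_prime = dprime,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  long <- rbind(
    data.frame(patient = tab$patient_id, emotion = tab$emotion,
               memory = "remembered", pct = 100 * tab$hit_rate),
    data.frame(patient = tab$patient_id, emotion = tab$emotion,
               memory = "false_alarm", pct = 100 * tab$fa_rate))
  long$patient <- factor(long$patient)
  long$emotion <- factor(long$emotion)
  long$memory <- factor(long$memory)
  fit <- stats::aov(pct ~ memory * emotion +
                      Error(patient / (memory * emotion)), data = long)
  sm <- summary(fit)
  an <- do.call(rbind, lapply(sm, function(s) {
    d <- as.data.frame(s[[1]])
    d$term <- trimws(rownames(d))
    d
  }))
  an <- an[!grepl("Residuals", an$term), ]
  anova_tab <- data.frame(term = an$term, df = an$Df,
                          F = an[["F value"]], p = an[["Pr(>F)"]],
                          stringsAsFactors = FALSE)
  rownames(anova_tab) <- NULL
  list(table = tab, anova = anova_tab)
}

#' Assemble a run configuration
#'
#' Central parameter container for [run_full_analysis()]; every stage
#' reads its parameters from here. A stable hash of the configuration is
#' embedded in the report for provenance.
#'
#' @param windows Analysis windows ([default_windows()]).
#' @param alpha Per-unit significance level.
#' @param n_perm Responsiveness permutations.
#' @param B Census bootstrap iterations.
#' @param n_iter,n_shuffles Decoding CV iterations and shuffles.
#' @param n_components dPCA components.
#' @param lambda dPCA ridge (or `"cv"`).
#' @param seed Master seed.
#' @param phases Phases to analyze.
#' @param stratify Stratified census keys (subset of `"region"`,
#'   `"patient"`; empty to skip).
#' @param min_pr,min_dprime Behavioral patient-exclusion thresholds
#'   (patients below either, averaged over emotions, are excluded from
#'   neuronal analyses).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(windows = default_windows(), alpha = 0.05,
                       n_perm = 1000, B = 10000, n_iter = 1000,
                       n_shuffles = 1000, n_components = 20, lambda = 0,
                       seed = 1, phases = c("encoding", "recognition"),
                       stratify = "region", min_pr = 0.05,
                       min_dprime = 0.1) {
  for (w in c("baseline", "stimulus", "peri", "psth")) {
    if (is.null(windows[[w]])) {
      stop("windows must define '", w, "'", call. = FALSE)
    }
    assert_window(windows[[w]], w)
  }
  structure(list(windows = windows, alpha = alpha, n_perm = n_perm, B = B,
                 n_iter = n_iter, n_shuffles = n_shuffles,
                 n_components = n_components, lambda = lambda, seed = seed,
                 phases = phases, stratify = stratify, min_pr = min_pr,
                 min_dprime = min_dprime),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sprintf("%08x", child_seed(0, s))
}

#' Run the full analysis pipeline
#'
#' Executes, per phase: unit quality control (artifact-spike removal +
#' inclusion rules), event-responsiveness permutation tests, the ANOVA
#' selectivity census with bootstrap nulls (optionally stratified), the
#' abs(z) mixed-effects population model with pairwise contrasts, and the
#' dPCA population analysis (fit, explained variance, signal-variance
#' ceiling, decoding significance, PCA baseline). Behavioral summaries and
#' patient exclusions are computed first. All randomness derives from
#' `config$seed`, so a fixed (dataset, config) pair reproduces the report
#' exactly.
#'
#' @param dataset List with `units` (list of [unit_spikes]) and `trials`
#'   (per patient: labeled `encoding`/`recognition` tables), e.g. from
#'   [simulate_cohort()] or [read_dataset()].
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the report is written to
#'   `report.json` there.
#' @return Nested list report (invisibly also written as JSON): behavioral
#'   summary, per-phase QC report, responsiveness summary, census results,
#'   mixed-model terms and contrasts, dPCA variance/decoding summaries,
#'   config hash.
#' @export
run_full_analysis <- function(dataset, config = run_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  report <- list(config_hash = config_hash(config),
                 seed = config$seed)

  beh <- stage("behavior", behavioral_summary(dataset$trials))
  report$behavior <- list(
    table = beh$table,
    anova = beh$anova)
  by_pat <- split(beh$table, beh$table$patient_id)
  keep_pat <- names(by_pat)[vapply(by_pat, function(d) {
    mean(d$PR) >= config$min_pr && mean(d$d_prime) >= config$min_dprime
  }, logical(1))]
  report$behavior$included_patients <- keep_pat

  for (phase in config$phases) {
    units <- Filter(function(u) {
      u$phase == phase && u$patient_id %in% keep_pat
    }, dataset$units)
    trials_by_patient <- lapply(dataset$trials[keep_pat], `[[`, phase)
    ph <- list()

    units <- stage("artifact_removal",
                   lapply(units, remove_artifact_spikes))
    qc <- stage("quality_filter", quality_filter(units, phase))
    ph$qc <- list(n_input = length(units),
                  n_retained = length(qc$units),
                  report = qc$report)
    units <- qc$units
    if (!length(units)) {
      report[[phase]] <- c(ph, list(note = "no units passed QC"))
      next
    }

    resp <- stage("responsiveness", responsiveness_scan(
      units, trials_by_patient, phase, n_perm = config$n_perm,
      seed = child_seed(config$seed, phase, "resp"),
      baseline = config$windows$baseline,
      stimulus = config$windows$stimulus))
    ph$responsiveness <- responsiveness_summary(resp, config$alpha)

    census <- list()
    for (eff in c("E", "M", "X")) {
      cs <- stage(paste0("census_", eff), census_bootstrap(
        units, trials_by_patient, phase, effect = eff, B = config$B,
        alpha = config$alpha,
        seed = child_seed(config$seed, phase, "census", eff),
        stimulus = config$windows$stimulus))
      census[[eff]] <- list(observed = cs$observed_count, p = cs$p,
                            n_units = cs$n_units, B = cs$B)
    }
    ph$census <- census
    if (length(config$stratify)) {
      ph$stratified <- lapply(config$stratify, function(by) {
        lapply(stratified_census(
          units, trials_by_patient, by = by, phase = phase, effect = "E",
          B = config$B, alpha = config$alpha,
          seed = child_seed(config$seed, phase, "strat", by)),
          function(cs) list(observed = cs$observed_count, p = cs$p,
                            n_units = cs$n_units,
                            underpowered = isTRUE(cs$underpowered)))
      })
      names(ph$stratified) <- config$stratify
    }
    if (phase == "recognition") {
      pw <- stage("pairwise_census", pairwise_census(
        units, trials_by_patient, B = config$B, alpha = config$alpha,
        seed = child_seed(config$seed, "pairwise"),
        stimulus = config$windows$stimulus))
      ph$pairwise <- lapply(pw, function(cs) {
        list(observed = cs$observed_count, p = cs$p,
             significant = cs$significant)
      })
    }

    zt <- stage("ztable", build_ztable(
      units, trials_by_patient, baseline = config$windows$baseline,
      stimulus = config$windows$stimulus))
    mm <- stage("mixed_model", fit_mixed_model(zt, phase))
    ph$mixed_model <- list(anova = mm$anova, varcomp = mm$varcomp,
                           singular = mm$singular,
                           contrasts = pairwise_contrasts(mm))

    tensor <- stage("tensor", build_population_tensor(
      units, trials_by_patient, phase, window = config$windows$psth,
      min_trials = 2L))
    model <- stage("dpca", fit_dpca(
      tensor, n_components = min(config$n_components,
                                 nrow(tensor$units)),
      lambda = config$lambda,
      seed = child_seed(config$seed, phase, "dpca")))
    ev <- explained_variance(model, tensor)
    sig <- stage("decoding", decode_significance(
      model, tensor, n_iter = config$n_iter,
      n_shuffles = config$n_shuffles,
      seed = child_seed(config$seed, phase, "decode")))
    pca <- pca_baseline(tensor, n_components = 5)
    ph$dpca <- list(
      n_units = nrow(tensor$units),
      lambda = model$lambda,
      component_var_pct = model$explained_var_pct,
      component_marg = model$marg,
      marginalization_pct = ev$marginalization_pct,
      pie_pct = ev$pie_pct,
      cumulative = ev$cumulative,
      signal_fraction = as.numeric(estimate_signal_variance(tensor)),
      pca_var_pct = pca$explained_var_pct,
      decoding = lapply(sig, function(s) {
        list(component = s$component, n_significant_bins = sum(s$significant),
             significant = s$significant, accuracy = s$accuracy)
      }))
    report[[phase]] <- ph
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  invisible(report)
}
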