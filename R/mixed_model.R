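# Population summary of firing-rate modulation: linear mixed-effects model
#   abs_z ~ 1 + Emotion * Memory + (1 | patient / unit)
# fitted by REML (lme4), omnibus Wald chi-square tests per fixed term
# (car::Anova, type II), and estimated-marginal-mean pairwise contrasts
# with Benjamini-Hochberg adjustment (emmeans, asymptotic Z ratios).

#' Fit the abs(z) linear mixed-effects model
#'
#' Models per-trial abs(z) firing-rate scores with fixed effects Emotion,
#' Memory and their interaction, and nested random intercepts for patient
#' and neuron-within-patient. Memory has 2 levels (R/F) at encoding and 3
#' (RHit/Miss/CR) at recognition. Fixed terms are tested with omnibus Wald
#' chi-square tests (type II).
#'
#' @param ztable Data frame from [build_ztable()] (columns `patient_id`,
#'   `unit_id`, `emotion`, `memory`, `abs_z`).
#' @param phase `"encoding"` or `"recognition"` (fixes the memory levels).
#' @return Object of class `mixed_model_result`: `model` (the `lmerMod`
#'   fit), `anova` (data frame: term, chisq, df, p), `varcomp` (named
#'   variance components), `singular` (logical convergence flag),
#'   `n_units`, `n_patients`, `n_rows`.
#' @export
fit_mixed_model <- function(ztable, phase = c("encoding", "recognition")) {
  phase <- match.arg(phase)
  memories <- if (phase == "encoding") c("R", "F") else
    c("RHit", "Miss", "CR")
  d <- ztable[ztable$memory %in% memories, , drop = FALSE]
  d$emotion <- factor(d$emotion, levels = c("e", "n"))
  d$memory <- factor(d$memory, levels = memories)
  d$patient_id <- factor(d$patient_id)
  d$unit_id <- factor(d$unit_id)
  if (nlevels(d$patient_id) < 2L) {
    stop("mixed model needs >= 2 patients", call. = FALSE)
  }
  if (any(tabulate(d$patient_id) == 0L) ||
      min(table(d$patient_id[!duplicated(d$unit_id)])) < 2L) {
    stop("mixed model needs >= 2 neurons per patient", call. = FALSE)
  }
  fit <- lme4::lmer(abs_z ~ 1 + emotion * memory + (1 | patient_id / unit_id),
                    data = d, REML = TRUE)
  an <- car::Anova(fit, type = 2, test.statistic = "Chisq")
  anova_tab <- data.frame(term = rownames(an), chisq = an[["Chisq"]],
                          df = an[["Df"]], p = an[["Pr(>Chisq)"]],
                          stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  structure(list(model = fit, anova = anova_tab, varcomp = varcomp,
                 singular = lme4::isSingular(fit),
                 n_units = nlevels(d$unit_id),
                 n_patients = nlevels(d$patient_id), n_rows = nrow(d),
                 phase = phase),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> %s: %d patients, %d neurons, %d trials%s\n",
              x$phase, x$n_patients, x$n_units, x$n_rows,
              if (x$singular) "  [singular fit]" else ""))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Pairwise memory contrasts on the fitted mixed model
#'
#' Estimated marginal mean differences between memory levels within each
#' emotion level (encoding: R - F within emotional and within neutral;
#' recognition: all three memory pairs within each emotion), with
#' asymptotic Z ratios and p-values adjusted by the Benjamini-Hochberg
#' false discovery rate within the contrast family.
#'
#' @param result A `mixed_model_result` from [fit_mixed_model()].
#' @param method Multiplicity adjustment (default `"BH"`).
#' @return Data frame: `contrast`, `emotion`, `estimate`, `SE`, `z_ratio`,
#'   `p`, `p_adj`.
#' @export
pairwise_contrasts <- function(result, method = "BH") {
  emm <- emmeans::emmeans(result$model, ~ memory | emotion,
                          lmer.df = "asymptotic")
  cts <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  df <- as.data.frame(cts)
  out <- data.frame(contrast = df$contrast, emotion = df$emotion,
                    estimate = df$estimate, SE = df$SE,
                    z_ratio = df$z.ratio, p = df$p.value,
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out
}
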