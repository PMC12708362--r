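#' Build the baseline-adjusted analysis frame for one outcome
#'
#' Merges baseline and follow-up rows of a scores table by participant and
#' keeps complete cases only: a participant enters a model only if the
#' outcome is non-missing at both waves (and, downstream, all model
#' covariates are non-missing) - the complete-case, intention-to-treat
#' frame.
#'
#' @param scores a scores table from [score_records()] (both waves).
#' @param outcome outcome column stem, e.g. `"knowledge_pct"`.
#' @return data.frame with `y` (follow-up), `baseline`, `arm`, `cluster_id`
#'   and the demographic covariates.
#' @export
prepare_model_frame <- function(scores, outcome) {
  stopifnot(outcome %in% names(scores))
  base <- scores[scores$wave == "baseline",
                 c("participant_id", "cluster_id", "arm", "age", "sex",
                   "education", "income", "prior_training", outcome)]
  names(base)[names(base) == outcome] <- "baseline"
  fu <- scores[scores$wave == "followup", c("participant_id", outcome)]
  names(fu)[names(fu) == outcome] <- "y"
  mf <- merge(base, fu, by = "participant_id")
  mf <- mf[stats::complete.cases(mf[, c("y", "baseline")]), ]
  mf$age_group <- factor(ifelse(mf$age < 40, "below_40", "above_40"),
                         levels = c("below_40", "above_40"))
  mf
}

adjust_covariates <- function() {
  c("age_group", "sex", "education", "income", "prior_training")
}

#' Baseline-adjusted mixed-effects intervention-effect estimates
#'
#' Fits, for one outcome on the percent-of-maximum scale, the model
#' `followup ~ arm + baseline (+ covariates) + (1 | cluster)` by REML,
#' with the first arm level as reference - the ANCOVA-with-cluster-
#' random-intercept estimator of a baseline-adjusted cluster trial. Arm
#' coefficients are percent-point differences versus control.
#'
#' Model variants: `"primary"` (arm + baseline), `"adjusted"` (adds age
#' group, sex, education, income, prior training; constant covariates are
#' dropped so a degenerate design reduces to the primary model), and
#' `"combined"` (pools the intervention arms into a single indicator).
#'
#' If the cluster variance is estimated at zero (singular fit), the model
#' falls back to the corresponding fixed-effects-only least-squares fit
#' with a warning.
#'
#' @param scores two-wave scores table from [score_records()].
#' @param outcome outcome column, e.g. `"knowledge_pct"`.
#' @param variant `"primary"`, `"adjusted"` or `"combined"`.
#' @param ci_method `"satterthwaite"` (t intervals on Satterthwaite
#'   denominator df; appropriate with few clusters) or `"wald"`
#'   (large-sample z intervals).
#' @param conf_level confidence level (default 0.95).
#' @param reference reference arm label (default `"control"`).
#' @return data.frame of class `kap_effects`, one row per fixed-effect
#'   contrast of interest: `outcome`, `variant`, `term`, `contrast`,
#'   `estimate`, `se`, `df`, `conf_low`, `conf_high`, `p_value`,
#'   `baseline_coef`, `n`, `n_clusters`, `singular`.
#' @export
fit_effect_model <- function(scores, outcome, variant = c("primary",
                                                          "adjusted",
                                                          "combined"),
                             ci_method = c("satterthwaite", "wald"),
                             conf_level = 0.95, reference = "control") {
  variant <- match.arg(variant)
  ci_method <- match.arg(ci_method)
  mf <- prepare_model_frame(scores, outcome)
  if (!reference %in% mf$arm)
    stop("reference arm '", reference, "' absent from data", call. = FALSE)
  other_arms <- setdiff(unique(mf$arm), reference)
  if (length(other_arms) == 0L)
    stop("no intervention rows: only the reference arm is present",
         call. = FALSE)
  mf$arm <- factor(mf$arm, levels = c(reference, sort(other_arms)))

  if (variant == "combined") {
    mf$treat <- factor(ifelse(mf$arm == reference, "control", "intervention"),
                       levels = c("control", "intervention"))
    rhs <- "treat + baseline"
  } else {
    rhs <- "arm + baseline"
  }
  if (variant == "adjusted") {
    covs <- adjust_covariates()
    keep <- vapply(covs, function(v) length(unique(mf[[v]])) > 1L, logical(1))
    mf <- mf[stats::complete.cases(mf[, covs]), ]
    if (any(keep)) rhs <- paste(rhs, "+", paste(covs[keep], collapse = " + "))
  }

  form <- stats::as.formula(paste("y ~", rhs, "+ (1 | cluster_id)"))
  fit <- suppressMessages(lmerTest::lmer(form, data = mf, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("cluster variance estimated at zero; falling back to the ",
            "fixed-effects least-squares model", call. = FALSE)
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = mf)
  }

  co <- if (inherits(fit, "lm")) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               df = stats::df.residual(fit), p_value = s[, 4],
               stringsAsFactors = FALSE)
  } else {
    s <- stats::coef(summary(fit))  # lmerTest: Satterthwaite df column
    data.frame(term = rownames(s), estimate = s[, "Estimate"],
               se = s[, "Std. Error"], df = s[, "df"],
               p_value = s[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  }
  crit <- if (ci_method == "wald" && !inherits(fit, "lm")) {
    stats::qnorm(1 - (1 - conf_level) / 2)
  } else NA_real_  # filled per-term from t df below
  co$crit <- if (is.na(crit)) stats::qt(1 - (1 - conf_level) / 2, co$df)
             else crit
  co$conf_low <- co$estimate - co$crit * co$se
  co$conf_high <- co$estimate + co$crit * co$se

  baseline_coef <- co$estimate[co$term == "baseline"]
  keep_terms <- co$term[grepl("^(arm|treat)", co$term) |
                          (variant == "adjusted" &
                             !co$term %in% c("(Intercept)", "baseline"))]
  out <- co[co$term %in% keep_terms, , drop = FALSE]
  out$contrast <- ifelse(grepl("^arm", out$term),
                         paste(sub("^arm", "", out$term), "vs", reference),
                         ifelse(grepl("^treat", out$term),
                                paste("intervention vs", reference),
                                out$term))
  out <- data.frame(outcome = outcome, variant = variant,
                    term = out$term, contrast = out$contrast,
                    estimate = out$estimate, se = out$se, df = out$df,
                    conf_low = out$conf_low, conf_high = out$conf_high,
                    p_value = out$p_value,
                    baseline_coef = baseline_coef,
                    n = nrow(mf),
                    n_clusters = length(unique(mf$cluster_id)),
                    singular = singular,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("kap_effects", "data.frame")
  out
}

#' @rdname fit_effect_model
#' @param ... passed to [fit_effect_model()].
#' @export
fit_primary <- function(scores, outcome, ...)
  fit_effect_model(scores, outcome, variant = "primary", ...)

#' @rdname fit_effect_model
#' @export
fit_adjusted <- function(scores, outcome, ...)
  fit_effect_model(scores, outcome, variant = "adjusted", ...)

#' @rdname fit_effect_model
#' @export
fit_combined <- function(scores, outcome, ...)
  fit_effect_model(scores, outcome, variant = "combined", ...)

#' Sub-component models for the EIS protective factors
#'
#' Fits the primary model form with each EIS sub-score (PPE, time-to-
#' change, time-to-shower, percent scale) as the outcome.
#'
#' @param scores two-wave scores table.
#' @param ... passed to [fit_effect_model()].
#' @return row-bound `kap_effects` data.frame for the three sub-scores.
#' @export
subcomponent_models <- function(scores, ...) {
  out <- lapply(c("ppe_pct", "change_pct", "shower_pct"),
                function(o) fit_effect_model(scores, o, ...))
  out <- do.call(rbind, out)
  class(out) <- c("kap_effects", "data.frame")
  out
}

#' Fit all trial outcomes under one model variant
#'
#' @param scores two-wave scores table.
#' @param outcomes outcome columns (default the five trial outcomes on
#'   the percent scale).
#' @param ... passed to [fit_effect_model()].
#' @return row-bound `kap_effects` data.frame.
#' @export
fit_all_outcomes <- function(scores,
                             outcomes = c("knowledge_pct", "attitude_pct",
                                          "practice_pct", "eis_pct",
                                          "symptom_pct"),
                             ...) {
  out <- do.call(rbind, lapply(outcomes, function(o)
    fit_effect_model(scores, o, ...)))
  class(out) <- c("kap_effects", "data.frame")
  out
}
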