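# Shared fixtures and oracles, all built in code.

# One fully exposed participant-wave row: mixes, knapsack application,
# no PPE, latest hygiene categories, all items correct, all symptoms.
max_exposure_record <- function(id = "P0001", wave = "baseline",
                                cluster = "c01", arm = "control") {
  r <- list(participant_id = id, cluster_id = cluster, arm = arm,
            wave = wave)
  for (k in sprintf("k%02d", 1:15)) r[[k]] <- 1L
  for (a in sprintf("a%02d", 1:15)) r[[a]] <- "5"
  for (p in sprintf("p%02d", 1:15)) r[[p]] <- "5"
  r$mixes_pesticides <- TRUE
  r$applies_knapsack <- TRUE
  for (part in c("upper_body", "mouth", "eye", "hand", "leg", "feet")) {
    r[[sprintf("ppe_%s_access", part)]] <- FALSE
    r[[sprintf("ppe_%s_freq", part)]] <- "never"
  }
  r$change_time <- "later"
  r$shower_time <- "later"
  for (s in sprintf("sym%02d", 1:31)) r[[s]] <- 1L
  r$age <- 40
  r$sex <- "male"
  r$education <- "above_primary"
  r$income <- "above_poverty"
  r$prior_training <- TRUE
  as.data.frame(r, stringsAsFactors = FALSE)
}

# Small valid two-wave record table via the generator.
tiny_records <- function(n_per_arm = 12, seed = 7, icc = 0.1, ...) {
  cfg <- small_config(n_per_arm = n_per_arm, icc = icc, ...)
  generate_cohort(cfg, seed = seed)$records
}

small_config <- function(n_per_arm = 40, icc = 0.4, effects = NULL,
                         dropout = 0.13, ...) {
  oc <- default_outcomes()
  if (!is.null(effects)) {
    oc$eff_education <- effects[1]
    oc$eff_education_sms <- effects[2]
  }
  simulation_config(
    arms = c(control = n_per_arm, education = n_per_arm,
             education_sms = n_per_arm),
    icc = icc, outcomes = oc, dropout_rate = dropout, ...)
}

zero_effect_outcomes <- function() {
  oc <- default_outcomes()
  oc$eff_education <- 0
  oc$eff_education_sms <- 0
  oc
}

# Closed-form least-squares oracle: solves the ANCOVA normal equations
# directly (independent of lme4 and of the package's fitting path).
ols_ancova_oracle <- function(mf) {
  arm <- factor(mf$arm, levels = c("control", sort(setdiff(unique(mf$arm),
                                                           "control"))))
  X <- cbind(1, stats::model.matrix(~arm)[, -1, drop = FALSE], mf$baseline)
  qr.solve(crossprod(X), crossprod(X, mf$y))
}

# Scores-table fixture in which every cluster within an arm holds an
# identical copy of the same participants, so the between-cluster
# variance is exactly zero and the REML cluster variance must hit the
# boundary (deterministic singular fit).
replicated_cluster_scores <- function(outcome = "knowledge_pct") {
  arms <- c("control", "education", "education_sms")
  base_y <- list(control = c(40, 55, 60, 70, 85),
                 education = c(45, 50, 65, 75, 90),
                 education_sms = c(35, 60, 70, 80, 95))
  fu_y <- list(control = c(50, 52, 66, 72, 80),
               education = c(58, 60, 74, 83, 92),
               education_sms = c(55, 68, 79, 88, 99))
  rows <- list()
  pid <- 0L
  for (a in arms) for (cl in 1:2) {
    ids <- sprintf("P%04d", pid + seq_along(base_y[[a]]))
    pid <- pid + length(ids)
    for (w in c("baseline", "followup")) {
      y <- if (w == "baseline") base_y[[a]] else fu_y[[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids, cluster_id = sprintf("%s_c%d", a, cl),
        arm = a, wave = w, age = 40, sex = "male",
        education = "above_primary", income = "above_poverty",
        prior_training = TRUE, stringsAsFactors = FALSE,
        check.names = FALSE)
      rows[[length(rows)]][[outcome]] <- y
    }
  }
  do.call(rbind, rows)
}

# Expected mean of a N(mu, sd) latent clamped to [0, 100] (closed form),
# the generator's observable target under ceiling/floor compression.
clamped_normal_mean <- function(mu, sd) {
  a <- (0 - mu) / sd
  b <- (100 - mu) / sd
  100 * (1 - stats::pnorm(b)) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

# Run n_sims cohorts and collect arm-contrast estimates for the given
# outcome columns; returns a matrix (sims x contrasts).
simulate_estimates <- function(n_sims, config, outcomes, seed_base,
                               what = "estimate") {
  one <- function(i) {
    coh <- generate_cohort(config, seed = seed_base + i)
    sc <- score_records(coh$records)
    unlist(lapply(outcomes, function(o) {
      est <- suppressWarnings(fit_primary(sc, o))
      stats::setNames(est[[what]], paste(o, est$contrast))
    }))
  }
  do.call(rbind, lapply(seq_len(n_sims), one))
}
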