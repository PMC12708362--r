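#' Simulation configuration for a synthetic two-wave cluster trial
#'
#' Defaults emulate the motivating trial: 12 clusters randomized 1:1:1 to
#' three arms of 180/180/179 farmers, an intraclass correlation of 0.4, a
#' 13% loss to follow-up, and baseline outcome distributions / follow-up
#' arm effects (percent-of-maximum scale) matching the trial's reported
#' values. The baseline-follow-up residual correlation is a free
#' parameter (not reported by the trial); default 0.5.
#'
#' @param n_clusters number of clusters (subcounties).
#' @param arms named integer vector of per-arm enrolment; names are arm
#'   labels, first name is the reference (control) arm.
#' @param icc target intraclass correlation of the latent outcomes.
#' @param outcomes data.frame with columns `name`, `mean`, `sd` (baseline,
#'   percent scale) and one `eff_<arm>` column per non-reference arm
#'   (follow-up effect in percent points).
#' @param baseline_followup_correlation correlation of the individual
#'   residuals between waves (the shared cluster effect adds further
#'   wave-to-wave correlation on top).
#' @param dropout_rate probability a participant misses follow-up.
#' @param dropout_mode `"mcar"` (completely at random, default) or
#'   `"practice"` (odds of dropout decrease with baseline practice score;
#'   for robustness experiments).
#' @param covariate_effects named list: for a covariate level (currently
#'   `"above_primary"`) a named numeric vector of percent-point shifts
#'   added to follow-up latents of the named outcomes.
#' @return list of class `kap_simconfig`.
#' @export
simulation_config <- function(
    n_clusters = 12,
    arms = c(control = 180L, education = 180L, education_sms = 179L),
    icc = 0.4,
    outcomes = default_outcomes(),
    baseline_followup_correlation = 0.5,
    dropout_rate = 0.13,
    dropout_mode = c("mcar", "practice"),
    covariate_effects = list()) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(icc >= 0, icc < 1, dropout_rate >= 0, dropout_rate < 1,
            baseline_followup_correlation >= -1,
            baseline_followup_correlation <= 1,
            length(arms) >= 2, !is.null(names(arms)),
            all(arms >= n_clusters / length(arms)))
  eff_cols <- paste0("eff_", names(arms)[-1])
  stopifnot(all(c("name", "mean", "sd", eff_cols) %in% names(outcomes)))
  structure(list(
    n_clusters = as.integer(n_clusters), arms = arms, icc = icc,
    outcomes = outcomes,
    baseline_followup_correlation = baseline_followup_correlation,
    dropout_rate = dropout_rate, dropout_mode = dropout_mode,
    covariate_effects = covariate_effects
  ), class = "kap_simconfig")
}

#' Default outcome parameters of the synthetic cohort
#'
#' Baseline means/SDs on the percent-of-maximum scale and follow-up arm
#' effects in percent points (education / education + text-message arms):
#' knowledge 73.9 (11.4) with effects +4.4/+6.1; attitude 72.3 (15.9)
#' with +2.0/+6.6; practice 60.3 (15.8) with 0/0; EIS 34.8 (11.5) with
#' -1.21/-1.64; symptom count mean 5 of 31 (16.13%) with 0/-1.1. The
#' symptom SD (10) is a chosen realistic value; the trial reports only
#' the mean.
#'
#' @return data.frame with columns `name`, `mean`, `sd`, `eff_education`,
#'   `eff_education_sms`.
#' @export
default_outcomes <- function() {
  data.frame(
    name = c("knowledge", "attitude", "practice", "eis", "symptom"),
    mean = c(73.9, 72.3, 60.3, 34.8, 100 * 5 / 31),
    sd = c(11.4, 15.9, 15.8, 11.5, 10),
    eff_education = c(4.4, 2.0, 0, -1.21, 0),
    eff_education_sms = c(6.1, 6.6, 0, -1.64, -1.1),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-wave cohort
#'
#' For each outcome the latent percent-scale value is
#' `y = mu + b_j + e` with cluster effect `b_j ~ N(0, sd^2 * icc)` and
#' residual `e ~ N(0, sd^2 * (1 - icc))`; the follow-up residual
#' correlates with the baseline residual at the configured level and the
#' follow-up mean adds the arm effect (plus any configured covariate
#' effect). Latents are clamped to \[0, 100\] and inverse-mapped to item
#' responses ([item_synthesis()]); loss to follow-up removes a random
#' subset's follow-up wave.
#'
#' @param config a `kap_simconfig`.
#' @param seed integer RNG seed; required (reproducibility contract).
#' @param codebook a `kap_codebook` used for the inverse item mapping.
#' @return list of class `kap_cohort`: `records` (participant-wave rows,
#'   both waves), `latents` (unclamped ground-truth latent percents per
#'   participant-wave), `assignment` (cluster -> arm), `config`, `seed`.
#' @export
generate_cohort <- function(config = simulation_config(), seed,
                            codebook = default_codebook()) {
  if (missing(seed) || is.null(seed))
    stop("generate_cohort requires an explicit seed", call. = FALSE)
  arms <- config$arms
  n_arm <- length(arms)
  cluster_ids <- sprintf("c%02d", seq_len(config$n_clusters))
  assignment <- randomize_clusters(cluster_ids, names(arms), seed = seed)
  # randomize_clusters seeds the stream; everything below continues it

  # participants: split each arm's enrolment near-equally over its clusters
  rows <- list()
  for (a in names(arms)) {
    cl <- names(assignment)[assignment == a]
    sizes <- diff(round(seq(0, arms[[a]], length.out = length(cl) + 1)))
    rows[[a]] <- data.frame(cluster_id = rep(cl, sizes), arm = a,
                            stringsAsFactors = FALSE)
  }
  ppl <- do.call(rbind, rows)
  n <- nrow(ppl)
  ppl$participant_id <- sprintf("P%04d", seq_len(n))
  rownames(ppl) <- NULL

  # demographics (arm-independent by design; randomization guarantees
  # balance only in expectation, as in a real trial)
  age <- pmin(pmax(round(stats::rnorm(n, 41, 12)), 18), 85)
  sex <- ifelse(stats::runif(n) < 0.846, "male", "female")
  education <- ifelse(stats::runif(n) < 0.523, "primary_or_below",
                      "above_primary")
  income <- ifelse(stats::runif(n) < 0.176, "below_poverty", "above_poverty")
  prior_training <- stats::runif(n) < 0.319

  # latent outcomes per wave
  oc <- config$outcomes
  rho <- config$baseline_followup_correlation
  cl_index <- match(ppl$cluster_id, cluster_ids)
  lat_base <- lat_fu <- matrix(NA_real_, n, nrow(oc),
                               dimnames = list(NULL, oc$name))
  for (i in seq_len(nrow(oc))) {
    sd_b <- oc$sd[i] * sqrt(config$icc)
    sd_e <- oc$sd[i] * sqrt(1 - config$icc)
    b <- stats::rnorm(config$n_clusters, 0, sd_b)[cl_index]
    e1 <- stats::rnorm(n, 0, sd_e)
    e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n, 0, sd_e)
    eff <- rep(0, n)
    for (a in names(arms)[-1])
      eff[ppl$arm == a] <- oc[[paste0("eff_", a)]][i]
    cov_eff <- rep(0, n)
    ce <- config$covariate_effects[["above_primary"]]
    if (!is.null(ce) && oc$name[i] %in% names(ce))
      cov_eff[education == "above_primary"] <- ce[[oc$name[i]]]
    lat_base[, i] <- oc$mean[i] + b + e1
    lat_fu[, i] <- oc$mean[i] + eff + cov_eff + b + e2
  }

  # attrition
  retained <- if (config$dropout_mode == "mcar") {
    stats::runif(n) >= config$dropout_rate
  } else {
    z <- as.vector(scale(lat_base[, "practice"]))
    p <- stats::plogis(stats::qlogis(config$dropout_rate) - 0.5 * z)
    stats::runif(n) >= p
  }

  clamp <- function(x) pmin(pmax(x, 0), 100)
  make_wave <- function(lat, wave, keep) {
    idx <- which(keep)
    df <- data.frame(
      participant_id = ppl$participant_id[idx],
      cluster_id = ppl$cluster_id[idx],
      arm = ppl$arm[idx], wave = wave,
      stringsAsFactors = FALSE
    )
    df <- cbind(df,
                item_synthesis(clamp(lat[idx, "knowledge"]), "knowledge",
                               codebook),
                item_synthesis(clamp(lat[idx, "attitude"]), "attitude",
                               codebook),
                item_synthesis(clamp(lat[idx, "practice"]), "practice",
                               codebook),
                item_synthesis(clamp(lat[idx, "eis"]), "eis", codebook),
                item_synthesis(clamp(lat[idx, "symptom"]), "symptoms",
                               codebook))
    df$age <- age[idx]
    df$sex <- sex[idx]
    df$education <- education[idx]
    df$income <- income[idx]
    df$prior_training <- prior_training[idx]
    df
  }
  records <- rbind(make_wave(lat_base, "baseline", rep(TRUE, n)),
                   make_wave(lat_fu, "followup", retained))
  records <- records[, record_columns(codebook)]

  latents <- rbind(
    data.frame(participant_id = ppl$participant_id,
               cluster_id = ppl$cluster_id, arm = ppl$arm,
               wave = "baseline", lat_base, stringsAsFactors = FALSE),
    data.frame(participant_id = ppl$participant_id[retained],
               cluster_id = ppl$cluster_id[retained],
               arm = ppl$arm[retained],
               wave = "followup", lat_fu[retained, , drop = FALSE],
               stringsAsFactors = FALSE)
  )
  rownames(latents) <- NULL

  structure(list(records = records, latents = latents,
                 assignment = assignment, config = config, seed = seed),
            class = "kap_cohort")
}

#' Inverse-map latent percent values to raw item responses
#'
#' The inverse of the scoring layer: KAP domains draw 15 Bernoulli
#' (latent/100) correctness indicators and emit raw responses that code
#' back to them (respecting answer keys and reverse flags); symptoms draw
#' 31 Bernoulli indicators; the EIS domain picks exposure inputs on the
#' discrete PPE/hygiene lattice whose computed EIS percent is nearest to
#' the latent target (a coarse-lattice approximation).
#'
#' @param latent_percent numeric vector of targets; values outside
#'   \[0, 100\] are clamped with a warning.
#' @param domain one of "knowledge", "attitude", "practice", "symptoms",
#'   "eis".
#' @param codebook a `kap_codebook`.
#' @return data.frame of raw item/input columns (one row per latent).
#' @export
item_synthesis <- function(latent_percent,
                           domain = c("knowledge", "attitude", "practice",
                                      "symptoms", "eis"),
                           codebook = default_codebook()) {
  domain <- match.arg(domain)
  if (any(latent_percent < 0 | latent_percent > 100, na.rm = TRUE)) {
    warning("latent percent outside [0, 100]; clamped", call. = FALSE)
    latent_percent <- pmin(pmax(latent_percent, 0), 100)
  }
  n <- length(latent_percent)
  p <- latent_percent / 100

  if (domain == "knowledge") {
    correct <- matrix(stats::runif(n * 15) < p, n, 15)
    keyed_yes <- matrix(rep(codebook$knowledge$key == "yes", each = n), n, 15)
    # correct answer token: 1 for yes-keyed, 2 for no-keyed; wrong answers
    # split between the other substantive option and "do not know"
    other <- matrix(sample(c(TRUE, FALSE), n * 15, replace = TRUE), n, 15)
    resp <- ifelse(correct, ifelse(keyed_yes, 1L, 2L),
                   ifelse(other, ifelse(keyed_yes, 2L, 1L), 3L))
    out <- as.data.frame(resp)
    names(out) <- codebook$knowledge$id
    return(out)
  }

  if (domain %in% c("attitude", "practice")) {
    items <- codebook[[domain]]
    correct <- matrix(stats::runif(n * 15) < p, n, 15)
    hi <- matrix(sample(4:5, n * 15, replace = TRUE), n, 15)
    lo <- matrix(sample(1:3, n * 15, replace = TRUE), n, 15)
    r <- ifelse(correct, hi, lo)
    rev <- matrix(rep(items$reverse, each = n), n, 15)
    raw <- ifelse(rev, 6L - r, r)
    out <- as.data.frame(matrix(as.character(raw), n, 15),
                         stringsAsFactors = FALSE)
    names(out) <- items$id
    return(out)
  }

  if (domain == "symptoms") {
    s <- matrix(as.integer(stats::runif(n * 31) < p), n, 31)
    out <- as.data.frame(s)
    names(out) <- codebook$symptoms
    return(out)
  }

  # eis: nearest achievable point on the discrete exposure-input lattice
  lattice <- build_eis_lattice(codebook)
  target <- p * 13
  iv <- findInterval(target, lattice$eis)
  iv_lo <- pmax(iv, 1L)
  iv_hi <- pmin(iv + 1L, nrow(lattice))
  pick <- ifelse(target - lattice$eis[iv_lo] <= lattice$eis[iv_hi] - target,
                 iv_lo, iv_hi)  # ties break to the lower EIS value
  pick[iv == 0L] <- 1L
  chosen <- lattice[pick, , drop = FALSE]
  out <- data.frame(mixes_pesticides = chosen$mix,
                    applies_knapsack = chosen$app,
                    stringsAsFactors = FALSE)
  fr <- quarters_to_fractions(chosen$k, length(codebook$ppe$part))
  inv_freq <- names(codebook$freq_map)[
    vapply(seq(0, 1, by = 0.25), function(v)
      which.min(abs(codebook$freq_map - v)), integer(1))]
  for (j in seq_along(codebook$ppe$part)) {
    part <- codebook$ppe$part[j]
    out[[sprintf("ppe_%s_access", part)]] <- fr[, j] > 0
    out[[sprintf("ppe_%s_freq", part)]] <- inv_freq[fr[, j] * 4 + 1]
  }
  out$change_time <- chosen$change
  out$shower_time <- chosen$shower
  rownames(out) <- NULL
  out
}

# Enumerate the achievable (mix, application, PPE, hygiene) lattice.
# Protection is distributed in quarter-steps: k in 0..24 quarters spread
# greedily over the six parts in codebook order.
build_eis_lattice <- function(codebook) {
  n_parts <- nrow(codebook$ppe)
  grid <- expand.grid(mix = c(FALSE, TRUE), app = c(FALSE, TRUE),
                      k = 0:(4 * n_parts),
                      change = names(codebook$hygiene$change_time),
                      shower = names(codebook$hygiene$shower_time),
                      stringsAsFactors = FALSE)
  fr <- quarters_to_fractions(grid$k, n_parts)
  ppe <- ppe_score(fr, codebook$ppe)
  grid$ppe <- ppe
  grid$eis <- eis(grid$mix, grid$app, ppe,
                  hygiene_factor(grid$change, codebook$hygiene$change_time),
                  hygiene_factor(grid$shower, codebook$hygiene$shower_time),
                  codebook$eis_variant)
  # one deterministic representative per achievable EIS value
  grid <- grid[order(grid$eis, grid$mix, grid$app, grid$k,
                     grid$change, grid$shower), ]
  grid <- grid[!duplicated(round(grid$eis, 10)), ]
  rownames(grid) <- NULL
  grid
}

# k quarters of protection spread greedily over parts: part 1 fills to
# 4 quarters first, then part 2, etc. Returns an n x n_parts fraction
# matrix with entries in {0, .25, .5, .75, 1}.
quarters_to_fractions <- function(k, n_parts) {
  taken <- outer(k, (seq_len(n_parts) - 1) * 4,
                 function(kk, base) pmin(pmax(kk - base, 0), 4))
  taken / 4
}
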