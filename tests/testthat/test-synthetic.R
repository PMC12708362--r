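test_that("cohort generation is reproducible and refuses a missing seed", {
  expect_error(generate_cohort(simulation_config()), "seed")
  cfg <- small_config(n_per_arm = 15)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a$records, b$records)
  expect_identical(a$latents, b$latents)
  # byte-identical CSV
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_records(a$records, pa)
  write_records(b$records, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_false(identical(a$records,
                         generate_cohort(cfg, seed = 6)$records))
})

test_that("default cohort matches the trial structure", {
  coh <- generate_cohort(simulation_config(), seed = 31)
  rec <- coh$records
  base <- rec[rec$wave == "baseline", ]
  expect_equal(nrow(base), 539)
  expect_equal(as.vector(table(base$arm)[c("control", "education",
                                           "education_sms")]),
               c(180L, 180L, 179L))
  # clusters balanced 4/4/4 and arm constant within cluster
  expect_equal(as.vector(table(coh$assignment)), c(4L, 4L, 4L))
  expect_silent(validate_records(base))
  # follow-up size within 3 binomial SDs of 539 * 0.87
  fu <- sum(rec$wave == "followup")
  expect_true(abs(fu - 539 * 0.87) < 3 * sqrt(539 * 0.13 * 0.87))
  # follow-up only for retained baseline participants
  expect_true(all(rec$participant_id[rec$wave == "followup"] %in%
                    base$participant_id))
})

test_that("degenerate icc=0, zero-effect config has no cluster signal", {
  cfg <- small_config(n_per_arm = 200, icc = 0, effects = c(0, 0),
                      dropout = 0)
  coh <- generate_cohort(cfg, seed = 41)
  lat <- coh$latents[coh$latents$wave == "baseline", ]
  # between-cluster share of latent variance ~ 0 (anova estimator)
  av <- stats::anova(stats::lm(knowledge ~ cluster_id, data = lat))
  ms_b <- av$`Mean Sq`[1]
  ms_w <- av$`Mean Sq`[2]
  m <- nrow(lat) / 12
  icc_hat <- (ms_b - ms_w) / (ms_b + (m - 1) * ms_w)
  expect_lt(abs(icc_hat), 0.05)
})

test_that("the generator hits its target intraclass correlation", {
  cfg <- small_config(n_per_arm = 400, icc = 0.4, dropout = 0)
  icc_one <- function(seed) {
    lat <- generate_cohort(cfg, seed = seed)$latents
    lat <- lat[lat$wave == "baseline", ]
    av <- stats::anova(stats::lm(knowledge ~ cluster_id, data = lat))
    ms_b <- av$`Mean Sq`[1]
    ms_w <- av$`Mean Sq`[2]
    m <- nrow(lat) / 12
    (ms_b - ms_w) / (ms_b + (m - 1) * ms_w)
  }
  # one 12-cluster cohort gives an ICC estimate with sampling SD ~ 0.1;
  # average 20 independent cohorts to test the generator, not the draw
  est <- mean(vapply(1:20, function(i) icc_one(500 + i), numeric(1)))
  expect_gt(est, 0.3)
  expect_lt(est, 0.5)
})

test_that("item synthesis inverts the scoring layer at the extremes", {
  cb <- default_codebook()
  k <- item_synthesis(rep(100, 5), "knowledge", cb)
  expect_true(all(as.matrix(k) == 1L))
  rec5 <- max_exposure_record()[rep(1, 5), ]
  rec5$participant_id <- sprintf("P%04d", 1:5)
  rec5[names(k)] <- k
  expect_equal(score_records(rec5)$knowledge, rep(15, 5))
  s <- item_synthesis(rep(0, 5), "symptoms", cb)
  expect_true(all(as.matrix(s) == 0L))
  e <- item_synthesis(c(0, 100), "eis", cb)
  expect_equal(e$mixes_pesticides, c(FALSE, TRUE))
  expect_equal(e$applies_knapsack, c(FALSE, TRUE))
  expect_warning(item_synthesis(120, "knowledge", cb), "clamped")
})

test_that("synthesized knowledge items are Binomial(15, p) around target", {
  set.seed(77)
  k <- item_synthesis(rep(66.7, 2000), "knowledge")
  scores <- rowSums(vapply(seq_len(15), function(i)
    code_knowledge_item(k[[i]]), integer(2000)))
  expect_lt(abs(mean(scores) - 10), 0.5)
  expect_lt(abs(stats::var(scores) - 15 * 2 / 3 * (1 - 2 / 3)), 0.5)
})

test_that("scoring the synthesized cohort recovers the latent means", {
  cfg <- small_config(n_per_arm = 1700, icc = 0, effects = c(0, 0),
                      dropout = 0)
  coh <- generate_cohort(cfg, seed = 61)
  sc <- score_records(coh$records)
  base <- sc[sc$wave == "baseline", ]
  oc <- cfg$outcomes
  cols <- c(knowledge = "knowledge_pct", attitude = "attitude_pct",
            practice = "practice_pct", eis = "eis_pct",
            symptom = "symptom_pct")
  for (i in seq_len(nrow(oc))) {
    x <- base[[cols[[oc$name[i]]]]]
    # observable target is the [0,100]-clamped latent mean; band is 3
    # empirical SEs (item/lattice noise included)
    target <- clamped_normal_mean(oc$mean[i], oc$sd[i])
    expect_lt(abs(mean(x, na.rm = TRUE) - target),
              3 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
              label = sprintf("|mean-%s target|", oc$name[i]))
  }
})

test_that("practice-dependent attrition lowers retention for low scorers", {
  cfg <- small_config(n_per_arm = 600, dropout = 0.2,
                      dropout_mode = "practice")
  coh <- generate_cohort(cfg, seed = 71)
  lat <- coh$latents
  base <- lat[lat$wave == "baseline", ]
  retained <- base$participant_id %in%
    lat$participant_id[lat$wave == "followup"]
  expect_gt(mean(base$practice[retained]), mean(base$practice[!retained]))
})
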