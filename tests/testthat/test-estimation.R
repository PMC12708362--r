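test_that("mixed-model ANCOVA equals the closed-form OLS oracle when the
          cluster variance is zero", {
  sc <- replicated_cluster_scores("knowledge_pct")
  expect_warning(fit <- fit_primary(sc, "knowledge_pct"),
                 "cluster variance")
  expect_true(all(fit$singular))
  beta <- ols_ancova_oracle(prepare_model_frame(sc, "knowledge_pct"))
  expect_equal(fit$estimate[fit$contrast == "education vs control"],
               beta[2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$estimate[fit$contrast == "education_sms vs control"],
               beta[3], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unique(fit$baseline_coef), beta[4], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("estimates are invariant to row order and id relabeling", {
  rec <- tiny_records(n_per_arm = 40, seed = 81, icc = 0.3)
  sc <- score_records(rec)
  f1 <- suppressWarnings(fit_primary(sc, "knowledge_pct"))
  set.seed(1)
  sc2 <- sc[sample(nrow(sc)), ]
  f2 <- suppressWarnings(fit_primary(sc2, "knowledge_pct"))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
  expect_equal(f1$conf_low, f2$conf_low, tolerance = 1e-6)
  # relabel participant ids consistently across waves
  sc3 <- sc
  sc3$participant_id <- sprintf("Q_%s", sc$participant_id)
  f3 <- suppressWarnings(fit_primary(sc3, "knowledge_pct"))
  expect_equal(f1$estimate, f3$estimate, tolerance = 1e-10)
})

test_that("swapping the reference arm negates the mirrored contrast", {
  rec <- tiny_records(n_per_arm = 40, seed = 82, icc = 0.3)
  sc <- score_records(rec)
  f_ctrl <- suppressWarnings(fit_primary(sc, "knowledge_pct"))
  f_edu <- suppressWarnings(fit_primary(sc, "knowledge_pct",
                                        reference = "education"))
  b_edu_vs_ctrl <- f_ctrl$estimate[f_ctrl$contrast == "education vs control"]
  b_ctrl_vs_edu <- f_edu$estimate[f_edu$contrast == "control vs education"]
  expect_equal(b_edu_vs_ctrl, -b_ctrl_vs_edu, tolerance = 1e-6)
})

test_that("constant covariates reduce the adjusted model to the primary", {
  sc <- replicated_cluster_scores("knowledge_pct")  # demographics constant
  fp <- suppressWarnings(fit_primary(sc, "knowledge_pct"))
  fa <- suppressWarnings(fit_adjusted(sc, "knowledge_pct"))
  expect_equal(fa$estimate[grepl("^arm", fa$term)],
               fp$estimate, tolerance = 1e-10)
})

test_that("adjusted and primary arm effects agree when covariates are
          orthogonal to arm", {
  rec <- tiny_records(n_per_arm = 120, seed = 83, icc = 0.2)
  sc <- score_records(rec)
  fp <- suppressWarnings(fit_primary(sc, "knowledge_pct"))
  fa <- suppressWarnings(fit_adjusted(sc, "knowledge_pct"))
  arm_rows <- grepl("^arm", fa$term)
  expect_equal(fa$estimate[arm_rows], fp$estimate, tolerance = 1.5)
  # covariate coefficients are reported
  expect_true(any(fa$term == "educationprimary_or_below" |
                    fa$term == "educationabove_primary"))
})

test_that("combining the intervention arms pools a common effect", {
  cfg <- small_config(n_per_arm = 150, icc = 0.05, effects = c(5, 5),
                      dropout = 0)
  est <- vapply(1:60, function(i) {
    coh <- generate_cohort(cfg, seed = 900 + i)
    sc <- score_records(coh$records)
    suppressWarnings(fit_combined(sc, "knowledge_pct"))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 5), 0.7)
})

test_that("a control-only table is rejected", {
  sc <- replicated_cluster_scores("knowledge_pct")
  sc <- sc[sc$arm == "control", ]
  expect_error(suppressWarnings(fit_primary(sc, "knowledge_pct")),
               "no intervention rows")
  expect_error(fit_primary(replicated_cluster_scores(), "knowledge_pct",
                           reference = "nonexistent"),
               "absent")
})

test_that("complete-case filtering drops incomplete participants only", {
  rec <- tiny_records(n_per_arm = 40, seed = 84, icc = 0.2)
  sc <- score_records(rec)
  sc$knowledge_pct[which(sc$wave == "followup")[1:3]] <- NA
  mf <- prepare_model_frame(sc, "knowledge_pct")
  n_fu <- sum(sc$wave == "followup")
  expect_equal(nrow(mf), n_fu - 3)
  f <- suppressWarnings(fit_primary(sc, "knowledge_pct"))
  expect_equal(unique(f$n), n_fu - 3)
})

test_that("sub-component models run on the EIS protective factors", {
  rec <- tiny_records(n_per_arm = 60, seed = 85, icc = 0.2)
  sc <- score_records(rec)
  sub <- suppressWarnings(subcomponent_models(sc))
  expect_setequal(unique(sub$outcome),
                  c("ppe_pct", "change_pct", "shower_pct"))
  expect_true(all(is.finite(sub$estimate)))
  expect_true(all(sub$conf_low <= sub$estimate &
                    sub$estimate <= sub$conf_high))
})

test_that("an intervention that lowers EIS lowers its PPE sub-score", {
  cfg <- small_config(n_per_arm = 250, icc = 0.02, dropout = 0)
  cfg$outcomes$eff_education[cfg$outcomes$name == "eis"] <- -15
  cfg$outcomes$eff_education_sms[cfg$outcomes$name == "eis"] <- -15
  coh <- generate_cohort(cfg, seed = 86)
  sc <- score_records(coh$records)
  fu <- sc[sc$wave == "followup", ]
  expect_lt(mean(fu$ppe_pct[fu$arm != "control"]),
            mean(fu$ppe_pct[fu$arm == "control"]))
  sub <- suppressWarnings(subcomponent_models(sc))
  ppe_rows <- sub[sub$outcome == "ppe_pct", ]
  expect_true(all(ppe_rows$estimate < 0))
})
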