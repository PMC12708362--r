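test_that("knowledge coding awards a point only for the keyed answer", {
  expect_identical(code_knowledge_item(1L, "yes"), 1L)  # yes, keyed yes
  expect_identical(code_knowledge_item(2L, "yes"), 0L)  # no
  expect_identical(code_knowledge_item(3L, "yes"), 0L)  # do not know
  expect_identical(code_knowledge_item(2L, "no"), 1L)   # negatively keyed
  expect_identical(code_knowledge_item(3L, "no"), 0L)
  expect_error(code_knowledge_item(4L), "coding error")
  expect_error(code_knowledge_item(1L, "maybe"), "coding error")
  expect_identical(code_knowledge_item(NA_integer_), NA_integer_)
})

test_that("Likert coding dichotomizes at 4-5 after optional reverse scoring", {
  expect_identical(code_likert_item("4"), 1L)
  expect_identical(code_likert_item("3"), 0L)
  expect_identical(code_likert_item("2", reverse = TRUE), 1L)  # 6-2 = 4
  expect_identical(code_likert_item("5", reverse = TRUE), 0L)  # 6-5 = 1
  expect_identical(code_likert_item("no_opinion"), NA_integer_)
  expect_error(code_likert_item("6"), "coding error")
  # reverse is an involution on 1..5
  for (r in 1:5) expect_equal(6L - (6L - r), r)
  # coded value under double application of reverse equals plain coding
  expect_identical(code_likert_item(as.character(6L - (6L - (1:5)))),
                   code_likert_item(as.character(1:5)))
})

test_that("domain scores sum 15 items with the complete-domain policy", {
  s <- domain_score(rep(1, 15))
  expect_equal(s$score, 15)
  expect_equal(s$percent, 100)
  s <- domain_score(c(rep(1, 10), rep(0, 5)))
  expect_equal(s$score, 10)
  expect_equal(report_percent(s$percent), 66.7)
  expect_true(is.na(domain_score(c(rep(1, 14), NA))$score))
  expect_equal(domain_score(c(rep(1, 14), NA), "prorate")$score, 15)
  expect_error(domain_score(rep(1, 14)), "contract error")
  expect_error(domain_score(c(rep(1, 14), 2)), "contract error")
})

test_that("domain score is permutation-invariant and monotone in flips", {
  set.seed(42)
  for (i in 1:25) {
    coded <- sample(0:1, 15, replace = TRUE)
    expect_equal(domain_score(sample(coded))$score,
                 domain_score(coded)$score)
    zero <- which(coded == 0)
    if (length(zero)) {
      flipped <- coded
      flipped[sample(zero, 1)] <- 1
      expect_equal(domain_score(flipped)$score,
                   domain_score(coded)$score + 1)
    }
  }
})

test_that("symptom counts span 0-31 with percent of 31", {
  expect_equal(symptom_count(rep(0, 31))$count, 0)
  expect_equal(symptom_count(rep(1, 31))$percent, 100)
  s <- symptom_count(c(rep(1, 5), rep(0, 26)))
  expect_equal(s$count, 5)
  expect_equal(report_percent(s$percent), 16.1)
  expect_error(symptom_count(rep(0, 30)), "contract error")
  expect_error(symptom_count(c(rep(0, 30), 2)), "contract error")
})

test_that("score_records recovers the coded sums row-wise", {
  rec <- rbind(max_exposure_record("P0001", "baseline"),
               max_exposure_record("P0002", "baseline", cluster = "c02",
                                   arm = "education"))
  sc <- score_records(rec)
  expect_equal(sc$knowledge, c(15, 15))
  expect_equal(sc$attitude_pct, c(100, 100))
  expect_equal(sc$symptom_count, c(31, 31))
  expect_equal(sc$eis, c(13, 13))
  # percents are exact score/max ratios
  rec2 <- tiny_records(n_per_arm = 8, seed = 21)
  sc2 <- score_records(rec2)
  expect_equal(sc2$practice_pct, 100 * sc2$practice / 15)
  expect_equal(sc2$eis_pct, 100 * sc2$eis / 13)
  expect_true(all(sc2$knowledge >= 0 & sc2$knowledge <= 15, na.rm = TRUE))
  expect_true(all(sc2$symptom_pct >= 0 & sc2$symptom_pct <= 100))
})

test_that("reverse-scored items code consistently through score_records", {
  cb <- default_codebook()
  cb$attitude$reverse[1] <- TRUE
  rec <- max_exposure_record()
  rec$a01 <- "2"  # reversed -> 4 -> correct
  sc <- score_records(rec, cb)
  expect_equal(sc$attitude, 15)
  rec$a01 <- "5"  # reversed -> 1 -> incorrect
  sc <- score_records(rec, cb)
  expect_equal(sc$attitude, 14)
})
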