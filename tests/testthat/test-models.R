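test_that("the factorial model reports the full predictor set once each", {
  pre <- fixture_exp1_pre()
  fit <- fit_adaptation_model(pre$region_table, random = "intercepts")
  expected <- c("Log stimulus order", "Ambiguity", "Sentence type",
                "Item order", "Sentence type : Ambiguity",
                "Sentence type : Item order", "Ambiguity : Item order",
                "Sentence type : Ambiguity : Item order")
  expect_setequal(fit$coefficients$predictor, expected)
  expect_identical(anyDuplicated(fit$coefficients$predictor), 0L)
  expect_identical(fit$coefficients$significant,
                   abs(fit$coefficients$t_value) >= 1.96)
  expect_true(fit$converged)
  expect_identical(fit$n_observations,
                   nrow(pre$region_table[pre$region_table$region ==
                                           "disambiguating_region", ]))
})

test_that("adaptation-on data shows the predicted focal signs", {
  pre <- fixture_exp1_pre()
  fit <- fit_adaptation_model(pre$region_table, random = "intercepts")
  cf <- fit$coefficients
  three <- cf$beta[cf$predictor == "Sentence type : Ambiguity : Item order"]
  expect_gt(three, 0)
  # the garden path itself: ambiguous slower, mostly for RCs early on
  expect_gt(cf$beta[cf$predictor == "Ambiguity"], 0)
  # task practice speeds everything up
  expect_lt(cf$beta[cf$predictor == "Log stimulus order"], 0)

  rc <- simple_effects(pre$region_table, "RC", random = "intercepts")
  mv <- simple_effects(pre$region_table, "MV", random = "intercepts")
  rc_i <- rc$coefficients$beta[rc$coefficients$predictor ==
                                 "Ambiguity : Item order"]
  mv_i <- mv$coefficients$beta[mv$coefficients$predictor ==
                                 "Ambiguity : Item order"]
  expect_lt(rc_i, 0)
  expect_lt(abs(mv_i), abs(rc_i))
})

test_that("rank-deficient designs fail naming the aliased predictors", {
  pre <- fixture_exp1_pre()
  rc_only <- pre$region_table[pre$region_table$structure == "RC", ]
  expect_error(fit_adaptation_model(rc_only, random = "intercepts"),
               "aliased")
})

test_that("the maximal ladder backs off and records the retained structure", {
  pre <- fixture_exp1_pre()
  small <- pre$region_table[pre$region_table$subject_id <= 10, ]
  fit <- simple_effects(small, "RC", random = "maximal")
  expect_true(grepl("subject_id", fit$re_formula))
  expect_s3_class(fit, "adaptation_fit")
})

test_that("blocked-design analyses fit the stated models per question", {
  pre <- fixture_exp2_pre()
  q1 <- exp2_analyses(pre$region_table, "Q1", random = "intercepts")
  expect_setequal(q1$coefficients$predictor,
                  c("Ambiguity", "Group", "Ambiguity : Group"))
  q2 <- exp2_analyses(pre$region_table, "Q2", random = "intercepts")
  expect_named(q2, c("blocked", "continuous"))
  expect_setequal(q2$blocked$coefficients$predictor,
                  c("Ambiguity", "Block", "Ambiguity : Block"))
  expect_setequal(q2$continuous$coefficients$predictor,
                  c("Ambiguity", "Item order", "Log stimulus order",
                    "Ambiguity : Item order"))
  # continuous re-analysis carries the Bonferroni-corrected threshold
  expect_gt(q2$continuous$sig_threshold, 1.96)
  q3 <- exp2_analyses(pre$region_table, "Q3", random = "intercepts")
  expect_setequal(q3$coefficients$predictor,
                  c("Ambiguity", "Group", "Ambiguity : Group"))
})

test_that("blocked-design analyses reject unsuitable tables", {
  pre1 <- fixture_exp1_pre()
  expect_error(exp2_analyses(pre1$region_table, "Q1"), "group")
  pre2 <- fixture_exp2_pre()
  rcf_only <- pre2$region_table[pre2$region_table$group == "RC_First" &
                                  !is.na(pre2$region_table$block) &
                                  pre2$region_table$block == 1, ]
  expect_error(exp2_analyses(rcf_only, "Q1"), "empty")
})

test_that("results flatten to the exportable region/predictor table", {
  pre <- fixture_exp1_pre()
  fit <- fit_adaptation_model(pre$region_table, random = "intercepts")
  rc <- simple_effects(pre$region_table, "RC", random = "intercepts")
  tbl <- results_table(list(fit, rc))
  expect_named(tbl, c("region", "predictor", "beta", "t_value",
                      "significant"))
  expect_identical(nrow(tbl), 12L)
  expect_true(any(grepl("^RC simple", tbl$predictor)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(list(fit, rc), path)
  expect_identical(nrow(readr::read_csv(path, show_col_types = FALSE)), 12L)
})

test_that("the recovery report is deterministic and validates inputs", {
  expect_error(sign_recovery(1), ">= 2")
  a <- sign_recovery(2, seed = 31, n_subjects = 6, simple_effects_too = FALSE)
  b <- sign_recovery(2, seed = 31, n_subjects = 6, simple_effects_too = FALSE)
  expect_equal(a$replicates, b$replicates)
  expect_identical(nrow(a$replicates), 2L)
})
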