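test_that("prior construction scales base probabilities to pseudocounts", {
  s <- make_prior(prior_config())
  expect_equal(unname(s$pseudocounts),
               c(0.7, 0.008, 0.292))
  expect_equal(sum(s$pseudocounts), 1)
  expect_identical(s$n_observed, 0L)

  sym <- make_prior(prior_config(p_mv = 0.5, p_rc = 0.5, alpha0 = 2))
  expect_equal(unname(sym$pseudocounts), c(1, 1, 0))

  expect_error(prior_config(alpha0 = 0), "alpha0")
  expect_error(prior_config(p_mv = 0.7, p_rc = 0.5), "<= 1")
})

test_that("predictive probabilities follow the conjugate closed form", {
  s <- make_prior(prior_config())
  expect_equal(predictive_prob(s, "MV"), 0.7)
  for (i in 1:26) s <- observe(s, "RC")
  expect_equal(predictive_prob(s, "MV"), 0.7 / 27)
  expect_equal(predictive_prob(s, "RC"), 26.008 / 27)
  expect_equal(s$pseudocounts[["RC"]], 26.008)
  expect_equal(sum(s$pseudocounts), 27)
})

test_that("observation updating increments one category and is commutative", {
  s <- make_prior(prior_config())
  s1 <- observe(s, "RC")
  expect_equal(unname(s1$pseudocounts), c(0.7, 1.008, 0.292))
  expect_identical(s1$n_observed, 1L)

  ab <- observe(observe(s, "MV"), "RC")
  ba <- observe(observe(s, "RC"), "MV")
  expect_equal(ab$pseudocounts, ba$pseudocounts)

  expect_error(observe(s, "XX"), "unknown structure category")
})

test_that("surprisal is -log2(p) with a guarded domain", {
  expect_equal(surprisal_bits(0.5), 1)
  expect_equal(surprisal_bits(1), 0)
  expect_error(surprisal_bits(0), "\\(0, 1\\]")
  expect_error(surprisal_bits(-0.1), "\\(0, 1\\]")
  expect_error(surprisal_bits(1.2), "\\(0, 1\\]")
  # strictly decreasing in p
  p <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(surprisal_bits(p)) < 0))
})

test_that("predictive distribution stays normalized and matches a counting oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:100, 1)
    seq_cat <- sample(c("MV", "RC", "OTHER"), n, replace = TRUE)
    s <- make_prior(prior_config(p_mv = runif(1, 0.1, 0.6),
                                 p_rc = runif(1, 0.01, 0.3),
                                 alpha0 = runif(1, 0.5, 5)))
    alpha0 <- s$alpha0
    base <- s$pseudocounts / alpha0
    for (cat in seq_cat) s <- observe(s, cat)
    probs <- predictive_prob(s, c("MV", "RC", "OTHER"))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    # independent oracle: count category occurrences directly
    counts <- vapply(c("MV", "RC", "OTHER"),
                     function(cat) sum(seq_cat == cat), numeric(1))
    oracle <- (alpha0 * base + counts) / (alpha0 + n)
    expect_equal(probs, unname(oracle), tolerance = 1e-12)
  }
})

test_that("beliefs converge to the environment distribution", {
  set.seed(7)
  env <- c(MV = 0.45, RC = 0.35, OTHER = 0.2)
  draws <- sample(names(env), 10000, replace = TRUE, prob = env)
  s <- make_prior(prior_config())
  for (cat in draws) s <- observe(s, cat)
  emp <- table(factor(draws, levels = names(env))) / length(draws)
  expect_equal(predictive_prob(s, names(env)), as.numeric(emp),
               tolerance = 0.01)
})

test_that("an overwhelming prior suppresses adaptation", {
  s <- make_prior(prior_config(alpha0 = 1e9))
  for (i in 1:100) s <- observe(s, "RC")
  expect_lt(abs(predictive_prob(s, "MV") - 0.7), 1e-6)
  expect_lt(abs(predictive_prob(s, "RC") - 0.008), 1e-6)
})

test_that("trajectories record the query before absorbing each event", {
  # own-category evidence makes the query's surprisal strictly decrease
  tr <- simulate_trajectory(rep("RC", 10), prior_config(), query = "RC")
  expect_true(all(diff(tr$surprisal_bits) < 0))
  expect_equal(tr$surprisal_bits[1], surprisal_bits(0.008))

  # zero evidence events: a single record holding the prior
  tr0 <- simulate_trajectory(character(0), prior_config(), query = "MV")
  expect_identical(nrow(tr0), 1L)
  expect_equal(tr0$surprisal_bits, surprisal_bits(0.7))

  # blocked design, RC-First: MV surprisal rises through blocks 1-2
  # even though no MV occurs there
  tr_mv <- simulate_trajectory(exp2_schedule("RC_First"), prior_config(),
                               query = "MV")
  b12 <- tr_mv[tr_mv$block %in% 1:2, ]
  expect_true(all(diff(b12$surprisal_bits) > 0))
})

test_that("maximum-change ratio matches its closed form and guards degeneracy", {
  cfg <- prior_config()
  ref <- log2(0.7 / 0.5) / log2(0.5 / 0.008) # independent arithmetic
  expect_equal(max_change_ratio(cfg, 0.5), ref)
  expect_equal(max_change_ratio(prior_config(p_mv = 0.5, p_rc = 0.008), 0.5), 0)
  expect_error(max_change_ratio(prior_config(p_mv = 0.5, p_rc = 0.5), 0.5),
               "degenerate")
})

test_that("prior-strength calibration reports a best fit and a base diagnostic", {
  cal <- calibrate_alpha0()
  expect_true(is.finite(cal$alpha0) && cal$alpha0 > 0)
  expect_named(cal$fitted, c("block3_onset_mv", "block3_mean_mv_rc_first",
                             "block3_mean_mv_filler_first", "exp1_mean_mv"))
  expect_true(cal$sse >= 0)
  d <- cal$block3_onset_diagnostic
  expect_equal(unname(d["surprisal_bits"]), -log2(d[["prob"]]))
  expect_equal(unname(d["surprisal_nats"]), -log(d[["prob"]]))
  # fillers-as-evidence variant runs and changes the fit
  cal_f <- calibrate_alpha0(include_fillers = TRUE)
  expect_false(isTRUE(all.equal(cal$alpha0, cal_f$alpha0)))
})
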