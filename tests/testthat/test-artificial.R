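test_that("crossed designs enumerate every factor-level pair exactly once", {
  d <- make_crossed_design(c(w = 2, s = 2))
  expect_equal(nrow(d), 4)
  expect_setequal(paste(d$w, d$s), c("1 1", "2 1", "1 2", "2 2"))

  d2 <- make_crossed_design(c(w = 7, s = 13))
  expect_equal(nrow(d2), 91)
  expect_equal(anyDuplicated(paste(d2$w, d2$s)), 0)

  expect_error(make_crossed_design(c(a = 1e4, b = 1e4)), "max_rows")
  expect_error(make_crossed_design(c(3, 4)), "named")
  expect_error(make_crossed_design(c(a = 1, b = 4)), ">= 2")
})

test_that("block-constant codes follow the allocation by largest remainder", {
  d <- make_crossed_design(c(Word = 10, Subject = 20))
  d <- assign_categorical(d, "NativeLanguage", codes = c(-0.5, 0.5),
                          ratio = c(0.5, 0.5), blocking_factor = "Subject")
  expect_equal(sum(d$NativeLanguage), 0)
  per_subj <- tapply(d$NativeLanguage, d$Subject, unique)
  expect_true(all(lengths(per_subj) == 1))  # constant within subject
  expect_equal(sum(unlist(per_subj) == -0.5), 10)

  d2 <- assign_categorical(make_crossed_design(c(Word = 5, Subject = 20)),
                           "g", codes = c(-0.5, 0.5),
                           ratio = c(0.25, 0.75), blocking_factor = "Subject")
  tab <- table(tapply(d2$g, d2$Subject, unique))
  expect_equal(as.vector(tab[c("-0.5", "0.5")]), c(5L, 15L))

  d3 <- assign_categorical(make_crossed_design(c(Word = 5, Subject = 4)),
                           "g", codes = c(1, 2), ratio = c(1, 0),
                           blocking_factor = "Subject")
  expect_true(all(d3$g == 1))

  expect_error(assign_categorical(d, "h", codes = c(1, 2), ratio = c(1),
                                  blocking_factor = "Subject"),
               "one proportion per code")
})

test_that("the balanced reference design reproduces the half-and-half layout", {
  d <- make_lexdec_design(seed = 1)
  # Word varies fastest, so the first 10 subjects fill the first 1000 rows
  expect_equal(d$NativeLanguage, c(rep(-0.5, 1000), rep(0.5, 1000)))
  expect_equal(names(d), c("Word", "Subject", "NativeLanguage",
                           "Frequency", "CenteredFrequency"))
})

test_that("continuous predictors attach one draw per level and center exactly", {
  d <- make_lexdec_design(seed = 3)
  per_word <- tapply(d$Frequency, d$Word, unique)
  expect_true(all(lengths(per_word) == 1))
  expect_equal(as.integer(table(d$Word)[as.character(1:5)]), rep(20L, 5))
  expect_lt(abs(mean(d$CenteredFrequency)), 1e-12)
  # centering is idempotent
  again <- d$CenteredFrequency - mean(d$CenteredFrequency)
  expect_equal(again, d$CenteredFrequency)

  # uncentered draws recover the sampling mean over many regenerations
  means <- vapply(1:200, function(i) {
    dd <- make_crossed_design(c(Word = 100, Subject = 2))
    dd <- sample_continuous(dd, "f", mean = 5, sd = 1,
                            attach_factor = "Word", seed = 5000 + i)
    mean(tapply(dd$f, dd$Word, unique))
  }, numeric(1))
  expect_lt(abs(mean(means) - 5), 3 * 1 / sqrt(200 * 100))

  expect_error(sample_continuous(d, "g", sd = 0, attach_factor = "Word"),
               "positive")
})

test_that("artificial models echo their parameters exactly", {
  m <- make_artificial_model(
    model_spec(c("NativeLanguage", "CenteredFrequency",
                 "NativeLanguage:CenteredFrequency"),
               grouping = c("Subject", "Word"), family = "binomial"),
    beta = c(-4.3, 0.35, -0.4, -0.32),
    variances = c(Subject = 1.04, Word = 0.65))
  expect_equal(unname(m$beta), c(-4.3, 0.35, -0.4, -0.32))
  expect_equal(m$variances, c(Subject = 1.04, Word = 0.65))
  expect_null(m$residual_variance)

  # positional variances are accepted with a warning, named silently
  spec <- model_spec("x", grouping = c("a", "b"), family = "gaussian")
  expect_warning(m2 <- mixed_model(spec, c(0, 1), c(2, 3),
                                   residual_variance = 1),
                 "positional")
  expect_equal(m2$variances, c(a = 2, b = 3))
  expect_error(mixed_model(spec, c(0, 1), c(a = 2, wrong = 3),
                           residual_variance = 1), "match grouping")
  expect_error(mixed_model(spec, c(0, 1, 5), c(a = 2, b = 3),
                           residual_variance = 1), "length 2")
  expect_error(mixed_model(spec, c(0, 1), c(a = 2, b = 3)),
               "residual_variance")

  # a null Gaussian model simulates pure standard normal noise
  null_spec <- model_spec(grouping = c("a", "b"), family = "gaussian")
  null_m <- mixed_model(null_spec, 0, c(a = 0, b = 0),
                        residual_variance = 1)
  dd <- make_crossed_design(c(a = 100, b = 100))
  y <- simulate_response(null_m, dd, seed = 4)
  expect_lt(abs(mean(y)), 3 / sqrt(length(y)))
  expect_lt(abs(stats::var(y) - 1), 3 * sqrt(2 / (length(y) - 1)))
})

test_that("simulated response rates match the logistic-normal integral", {
  m <- make_lexdec_model()
  total_var <- sum(m$variances)
  diffs <- vapply(1:25, function(i) {
    d <- make_lexdec_design(seed = 300 + i)
    des <- build_design(d, m$spec)
    eta <- drop(des$X %*% m$beta)
    predicted <- mean(logistic_normal_mean(eta, total_var))
    observed <- mean(simulate_response(m, d, seed = 600 + i))
    observed - predicted
  }, numeric(1))
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("power responds to predictor spread and group balance as designed", {
  m <- make_lexdec_model()
  plan <- scan_plan("Subject", steps = 20, nsim = 40, seed = 14)
  rule <- significance_rule(1.96)

  # halving (and more) the frequency sd lowers the frequency effect's power
  d_wide <- make_lexdec_design(freq_sd = 1, seed = 21)
  d_narrow <- make_lexdec_design(freq_sd = 0.3, seed = 21)
  p_wide <- run_power_scan(m, d_wide, effects = "CenteredFrequency",
                           plan = plan, rule = rule)$cells$power_percent
  p_narrow <- run_power_scan(m, d_narrow, effects = "CenteredFrequency",
                             plan = plan, rule = rule)$cells$power_percent
  expect_lt(p_narrow, p_wide + 10)  # directional, with Monte Carlo slack

  # unbalanced groups lower the categorical effect's power
  m_strong <- make_lexdec_model(beta = c(-2.5, 1.2, -0.4, -0.32))
  d_bal <- make_lexdec_design(seed = 22)
  d_unbal <- make_lexdec_design(ratio = c(0.1, 0.9), seed = 22)
  p_bal <- run_power_scan(m_strong, d_bal, effects = "NativeLanguage",
                          plan = plan, rule = rule)$cells$power_percent
  p_unbal <- run_power_scan(m_strong, d_unbal, effects = "NativeLanguage",
                            plan = plan, rule = rule)$cells$power_percent
  expect_lt(p_unbal, p_bal + 10)
})
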