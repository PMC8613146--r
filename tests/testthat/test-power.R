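test_that("Clopper-Pearson intervals are exact, with closed boundaries", {
  ci <- clopper_pearson(167, 1000, 0.95)
  expect_equal(round(unname(ci), 2), c(14.44, 19.16))
  expect_equal(unname(clopper_pearson(0, 10))[1], 0)
  expect_equal(unname(clopper_pearson(10, 10))[2], 100)

  # brute-force inversion of the binomial tails on a fine grid
  k <- 5; n <- 10; a <- 0.025
  grid <- seq(1e-6, 1 - 1e-6, by = 1e-6)
  low_bf <- grid[which.min(abs(1 - pbinom(k - 1, n, grid) - a))]
  high_bf <- grid[which.min(abs(pbinom(k, n, grid) - a))]
  ci2 <- clopper_pearson(k, n, 0.95) / 100
  expect_equal(unname(ci2), c(low_bf, high_bf), tolerance = 1e-4)

  expect_error(clopper_pearson(11, 10), "k <= n")
  expect_error(clopper_pearson(-1, 10), "k <= n")
  expect_error(clopper_pearson(2, 10, level = 1), "between 0 and 1")
})

test_that("scan plans validate their ingredients", {
  expect_error(scan_plan("s", steps = integer()), "non-empty")
  expect_error(scan_plan("s", steps = c(10, 1)), ">= 2")
  expect_error(scan_plan("s", steps = 10, nsim = 0), "nsim")
  expect_error(scan_plan("s", steps = 10, r2var = "w"), "together")
  expect_error(scan_plan("s", steps = 10, databased = FALSE), "nothing to run")
})

test_that("reported power equals a brute-force recount of the audit log", {
  toy <- make_toy_lmm(n_subjects = 12, n_items = 5)
  plan <- scan_plan("subject", steps = c(8, 12), nsim = 15, seed = 6,
                    sesoi = c(1, 0.5, 0.12))
  pt <- run_power_scan(toy$model, toy$data, plan = plan)
  cells <- summarize_table(pt)
  expect_equal(nrow(cells), 2 * 2 * 2)  # 2 effects x 2 steps x 2 modes

  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    sub <- pt$log[pt$log$effect == row$effect & pt$log$step == row$step &
                    pt$log$mode == row$mode, ]
    expect_equal(row$k_significant, sum(sub$significant, na.rm = TRUE))
    expect_equal(row$n_valid, sum(!is.na(sub$significant)))
    expect_equal(row$power_percent,
                 100 * row$k_significant / row$n_valid)
    ci <- clopper_pearson(row$k_significant, row$n_valid)
    expect_lte(row$ci_low, row$power_percent)
    expect_gte(row$ci_high, row$power_percent)
    expect_equal(c(row$ci_low, row$ci_high), unname(ci))
  }
})

test_that("scans are reproducible from the base seed alone", {
  toy <- make_toy_lmm(n_subjects = 10, n_items = 4)
  plan <- scan_plan("subject", steps = 8, nsim = 8, seed = 99)
  pt1 <- run_power_scan(toy$model, toy$data, plan = plan)
  pt2 <- run_power_scan(toy$model, toy$data, plan = plan)
  expect_identical(pt1$cells, pt2$cells)
  expect_identical(pt1$log, pt2$log)
})

test_that("an enormous effect is detected in every repetition", {
  toy <- make_toy_lmm(beta = c(1, 50, 0.1), subj_var = 0.01,
                      item_var = 0.01, resid_var = 0.01)
  plan <- scan_plan("subject", steps = c(8, 14), nsim = 8, seed = 2)
  pt <- run_power_scan(toy$model, toy$data, effects = "x1", plan = plan)
  expect_true(all(pt$cells$power_percent == 100))
})

test_that("unknown effects and model/data mismatches are caught up front", {
  toy <- make_toy_lmm(n_subjects = 4, n_items = 4)
  plan <- scan_plan("subject", steps = 4, nsim = 2, seed = 1)
  expect_error(run_power_scan(toy$model, toy$data, effects = "nope",
                              plan = plan), "unknown effect")
  expect_error(run_power_scan(toy$model, toy$data,
                              plan = scan_plan("bogus", steps = 4,
                                               nsim = 2)),
               "not a grouping factor")
  plan$r2var <- "item"; plan$r2level <- 4L
  expect_error(run_power_scan(toy$model, toy$data, plan = plan),
               "run_r2_scan")
})

test_that("a two-factor scan with identity second resize matches a plain scan", {
  toy <- make_toy_lmm(n_subjects = 10, n_items = 6)
  plain <- scan_plan("subject", steps = c(8, 10), nsim = 10, seed = 5)
  with_r2 <- scan_plan("subject", steps = c(8, 10), nsim = 10, seed = 5,
                       r2var = "item", r2level = 6)  # item count unchanged
  pt1 <- run_power_scan(toy$model, toy$data, plan = plain)
  pt2 <- run_r2_scan(toy$model, toy$data, plan = with_r2)
  expect_identical(pt1$cells[names(pt1$cells) != "mode"],
                   pt2$cells[names(pt2$cells) != "mode"])
  expect_error(run_r2_scan(toy$model, toy$data, plan = plain),
               "run_power_scan")
  bad <- scan_plan("subject", steps = 8, nsim = 2, seed = 1,
                   r2var = "subject", r2level = 8)
  expect_error(run_r2_scan(toy$model, toy$data, plan = bad),
               "differ from simvar")
})

test_that("type-I scans zero the effects and record it; huge thresholds reject nothing", {
  toy <- make_toy_lmm(n_subjects = 8, n_items = 4)
  plan <- scan_plan("subject", steps = 8, nsim = 10, seed = 3)
  pt <- estimate_type1(toy$model, toy$data, plan = plan,
                       rule = significance_rule(1e6))
  expect_true(isTRUE(pt$metadata$null_model))
  expect_equal(pt$metadata$zeroed_terms, c("x1", "x2"))
  expect_equal(unlist(pt$metadata$beta[-1], use.names = FALSE), c(0, 0))
  expect_true(all(pt$cells$power_percent == 0))
})

test_that("failed refits are tallied and excluded from both counts", {
  # a virtually impossible event rate makes most simulated responses
  # constant, which the binomial fitter reports as a failed refit
  d <- make_lexdec_design(n_subjects = 4, n_words = 6, seed = 8)
  m <- make_lexdec_model(beta = c(-14, 0, 0, 0),
                         subject_variance = 0.1, word_variance = 0.1)
  plan <- scan_plan("Subject", steps = 4, nsim = 8, seed = 10)
  wn <- capture_warnings(
    pt <- run_power_scan(m, d, effects = "NativeLanguage", plan = plan,
                         rule = significance_rule(1.96)))
  expect_true(any(grepl("failed", wn)))
  cells <- pt$cells
  expect_equal(cells$n_valid + cells$n_failed, rep(8L, nrow(cells)))
  expect_gt(sum(cells$n_failed), 0)
  # denominators use valid refits only
  ok <- cells$n_valid > 0
  expect_equal(cells$power_percent[ok],
               100 * cells$k_significant[ok] / cells$n_valid[ok])
})

test_that("summaries are long-format, stably ordered, effect-major", {
  toy <- make_toy_lmm(n_subjects = 8, n_items = 4)
  plan <- scan_plan("subject", steps = c(6, 8, 10), nsim = 2, seed = 4,
                    sesoi = c(1, 0.5, 0.12))
  pt <- run_power_scan(toy$model, toy$data, plan = plan)
  s <- summarize_table(pt)
  expect_equal(nrow(s), 2 * 3 * 2)  # 2 effects x 3 steps x 2 modes
  expect_false(is.unsorted(s$effect))
  expect_true(all(s[s$effect == "x1", "step"] ==
                    rep(c(6, 8, 10), each = 2)))
})
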