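fake_cohort <- function(cbf, cbd = cbf / 10, label = "x",
                        intervals = NULL) {
  ev <- if (is.null(intervals)) list()
        else list(data.frame(interval_after = intervals))
  list(label = label,
       measurements = data.frame(cilium = seq_along(cbf), cbf = cbf,
                                 cbd = cbd, n_waves_used = 10,
                                 t_eff_mean = 44, t_rec_mean = 40),
       events = ev)
}

test_that("condition summaries use sample SD with the n = 1 convention", {
  s1 <- summarize_condition(fake_cohort(5), label = "solo")
  expect_equal(s1$n_cilia, 1)
  expect_equal(s1$cbf_mean, 5)
  expect_equal(s1$cbf_sd, 0)

  s4 <- summarize_condition(fake_cohort(c(3, 3, 4, 4)))
  expect_equal(s4$cbf_mean, 3.5)
  expect_equal(s4$cbf_sd, 0.5773503, tolerance = 1e-6)

  expect_error(summarize_condition(list(measurements = NULL)), "empty")
})

test_that("ratios are normalized to the reference condition", {
  summ <- rbind(summarize_condition(fake_cohort(3.4, 0.57, "pH7.0")),
                summarize_condition(fake_cohort(8.8, 0.98, "pH7.4")))
  out <- normalize_to_reference(summ, "pH7.4")
  expect_equal(out$cbf_ratio[out$label == "pH7.4"], 1)
  expect_equal(out$cbd_ratio[out$label == "pH7.4"], 1)
  expect_equal(out$cbf_ratio[out$label == "pH7.0"], 0.386, tolerance = 1e-3)
  expect_error(normalize_to_reference(summ, "pH9"), "not present")
  bad <- summ; bad$cbf_mean[2] <- 0
  expect_error(normalize_to_reference(bad, "pH7.4"), "zero")
})

test_that("Welch test agrees with the closed-form oracle on fixtures", {
  fixtures <- list(
    list(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10)),
    list(a = c(19.8, 23.4, 21.1, 20.0, 21.9), b = c(28.2, 26.6, 20.1, 23.3, 25.2)),
    list(a = c(3.1, 3.5, 2.9, 3.3), b = c(3.0, 3.6, 3.1, 3.2, 3.4)),
    list(a = c(0.38, 0.42, 0.31, 0.45, 0.29), b = c(1.44, 1.12, 1.70, 1.55, 1.31)),
    list(a = c(136, 130, 142, 128), b = c(44, 40, 47, 45)))
  for (fx in fixtures) {
    got <- welch_t_test(fx$a, fx$b)
    want <- oracle_welch(fx$a, fx$b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-4)
    expect_equal(got$df, want$df, tolerance = 1e-4)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-6)
  }
})

test_that("Welch test degenerate cases have defined outputs", {
  g <- c(1, 2, 3)
  expect_equal(welch_t_test(g, g)$statistic, 0)
  expect_equal(welch_t_test(g, g)$p_value, 1)
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t_test(c(2, 2), c(3, 3))$p_value, 0)
  expect_equal(welch_t_test(1, c(1, 2))$p_value, 1)   # n < 2
  ## paired on identical pairs
  expect_equal(welch_t_test(g, g, paired = TRUE)$statistic, 0)
  ## a 10-sd shift is decisively significant
  expect_lt(welch_t_test(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)
})

test_that("one-way ANOVA agrees with the oracle and the t^2 identity", {
  with_seed(5, {
    groups <- list(rnorm(6, 0), rnorm(6, 1), rnorm(6, 3))
  })
  got <- one_way_anova(groups)
  want <- oracle_anova(groups)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-4)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-6)

  ## two groups: F equals the square of the pooled two-sample t
  two <- groups[1:2]
  expect_equal(one_way_anova(two)$statistic,
               oracle_pooled_t(two[[1]], two[[2]])^2, tolerance = 1e-6)

  expect_equal(one_way_anova(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2, 2)))$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "two observations")
})

test_that("ANOVA detects well-separated groups in most replicates", {
  hits <- with_seed(11, {
    sum(replicate(200, {
      g <- list(rnorm(6, 0, 1), rnorm(6, 3, 1), rnorm(6, 6, 1))
      one_way_anova(g)$p_value < 0.05
    }))
  })
  expect_gte(hits, 190)                               # >= 95% power
})

test_that("the results driver is deterministic and reports every quantity", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages({
    r1 <- reproduce_paper(123, d1, presets = "rep_pH8.0")
    r2 <- reproduce_paper(123, d2, presets = "rep_pH8.0")
  })
  f1 <- file.path(d1, "representatives.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(file.path(d2, "representatives.csv")))
  expect_identical(readLines(file.path(d1, "recovery_report.csv")),
                   readLines(file.path(d2, "recovery_report.csv")))
  expect_true("cbf_rep_pH8.0" %in% r1$report$quantity)
  expect_true(all(c("recovered", "target", "tolerance", "pass") %in%
                    names(r1$report)))
})

test_that("recovered cohort means are stable across master seeds", {
  cbfs <- vapply(1:5, function(s) {
    co <- simulate_cohort(get_preset("pH8.0", "rate_matched"), s)
    mean(co$measurements$cbf)
  }, numeric(1))
  expect_lt(max(cbfs) - min(cbfs), 0.10 * 15.4)
  expect_lt(max(abs(cbfs - 15.4)), 0.10 * 15.4)
})
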