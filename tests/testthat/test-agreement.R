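test_that("ICC equals the independent ANOVA mean-squares oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    k <- sample(2:4, 1)
    x <- sim_icc_table(n, k, stats::runif(1, 0.1, 0.9), sigma_total = 2)
    for (form in c("consistency", "absolute_agreement")) {
      r <- icc_two_way(x, form = form)
      expect_equal(r$icc, icc_oracle_aov(x, form), tolerance = 1e-10)
    }
  }
})

test_that("identical ratings with between-subject spread give ICC 1, excellent", {
  x <- cbind(1:10, 1:10)
  r <- icc_two_way(x)
  expect_equal(r$icc, 1)
  expect_identical(r$band, "excellent")
  expect_equal(r$ci_low, 1)
})

test_that("ICC contracts are enforced", {
  expect_error(icc_two_way(cbind(1:2, 1:2)), class = "nova24r_contract_error")
  expect_error(icc_two_way(matrix(1:9, 3, 3)[, 1, drop = FALSE]),
               class = "nova24r_contract_error")
  expect_error(icc_two_way(matrix(5, 10, 2)), class = "nova24r_degenerate_error")
})

test_that("ICC interpretation bands follow the 0.50/0.75/0.90 thresholds", {
  expect_identical(icc_band(c(0.54, 0.72, 0.78, 0.75)),
                   c("moderate", "moderate", "good", "good"))
  expect_identical(icc_band(c(0.10, 0.49, 0.50, 0.90, 0.95)),
                   c("poor", "poor", "moderate", "good", "excellent"))
  # total and monotone
  xs <- seq(-0.5, 1, by = 0.01)
  bands <- icc_band(xs)
  expect_false(any(is.na(bands)))
  lvl <- match(bands, c("poor", "moderate", "good", "excellent"))
  expect_true(all(diff(lvl) >= 0))
})

test_that("PABAK bands follow the modified Landis-Koch scale", {
  expect_identical(pabak_band(c(0.69, 0.77, 0.78, 0.81)),
                   c("substantial", "substantial", "substantial", "almost_perfect"))
  expect_identical(pabak_band(c(-0.2, 0, 0.1, 0.3, 0.5)),
                   c("none", "none", "none_to_slight", "fair", "moderate"))
  xs <- seq(-1, 1, by = 0.01)
  lvl <- match(pabak_band(xs), c("none", "none_to_slight", "fair", "moderate",
                                 "substantial", "almost_perfect"))
  expect_true(all(diff(lvl) >= 0))
})

test_that("ICC confidence intervals bracket the estimate", {
  set.seed(5)
  for (i in 1:20) {
    x <- sim_icc_table(15, 2, stats::runif(1, 0.2, 0.9))
    r <- icc_two_way(x)
    expect_lte(r$ci_low, r$icc)
    expect_gte(r$ci_high, r$icc)
  }
})

test_that("ICC recovers the generating correlation with nominal CI coverage", {
  # two-way model, n = 120, k = 2, 300 replicates per true value
  set.seed(2024)
  for (rho in c(0.3, 0.75)) {
    est <- numeric(300)
    cover <- logical(300)
    for (r in 1:300) {
      x <- sim_icc_table(120, 2, rho)
      fit <- icc_two_way(x)
      est[r] <- fit$icc
      cover[r] <- fit$ci_low <= rho && rho <= fit$ci_high
    }
    expect_lt(abs(mean(est) - rho), 0.05)
    expect_gte(mean(cover), 0.90)
    expect_lte(mean(cover), 0.99)
  }
})

test_that("paired mean comparison flags identical and shifted tools correctly", {
  set.seed(3)
  base <- tibble::tibble(
    participant_id = rep(sprintf("p%03d", 1:50), each = 4),
    nova_group = rep(1:4, 50),
    share_pct = as.vector(replicate(50, { v <- rgamma(4, 2); 100 * v / sum(v) }))
  )
  identical_tools <- dplyr::bind_rows(
    dplyr::mutate(base, tool = "a"), dplyr::mutate(base, tool = "b"))
  out <- compare_means(identical_tools)
  expect_equal(out$mean_diff, rep(0, 4))
  expect_true(all(out$degenerate))
  expect_true(all(is.na(out$p_value)))

  # constant +5 shift: difference exactly 5, degenerate CI of width 0
  shifted <- dplyr::bind_rows(
    dplyr::mutate(base, tool = "a", share_pct = share_pct + 5),
    dplyr::mutate(base, tool = "b"))
  out <- compare_means(shifted)
  expect_equal(out$mean_diff, rep(5, 4))
  expect_true(all(out$degenerate))
  expect_equal(out$diff_ci_high - out$diff_ci_low, rep(0, 4))

  # noisy shift is detected
  noisy <- dplyr::bind_rows(
    dplyr::mutate(base, tool = "a", share_pct = share_pct + 5 + rnorm(200)),
    dplyr::mutate(base, tool = "b"))
  out <- compare_means(noisy)
  expect_true(all(out$significant))
  out_w <- compare_means(noisy, method = "wilcoxon")
  expect_true(all(out_w$significant))
})

test_that("quintile agreement: identical rankings give PABAK 1, almost perfect", {
  set.seed(8)
  v <- stats::runif(100, 0, 60)
  q <- quintile_agreement(data.frame(a = v, b = v))
  expect_equal(q$p_same, 1)
  expect_equal(q$pabak, 1)
  expect_identical(q$band, "almost_perfect")
  expect_equal(sum(q$cross_table), 100)
})

test_that("PABAK closed form equals brute force on random tables", {
  set.seed(12)
  for (i in 1:50) {
    a <- stats::rnorm(60)
    b <- 0.5 * a + stats::rnorm(60)
    q <- quintile_agreement(data.frame(a, b))
    # brute force (c*Po - 1)/(c - 1) from the cross-table itself
    po <- sum(diag(q$cross_table)) / sum(q$cross_table)
    expect_equal(q$pabak, (5 * po - 1) / 4, tolerance = 1e-12)
    expect_lte(q$p_same, q$p_same_or_adjacent)
    expect_gte(q$p_same, 0)
    expect_lte(q$p_same_or_adjacent, 1)
  }
  # chance agreement for 5 balanced categories: p_same = 0.2 -> PABAK = 0
  expect_equal((5 * 0.2 - 1) / 4, 0)
})

test_that("independent rankings give PABAK near zero", {
  set.seed(99)
  q <- quintile_agreement(data.frame(a = stats::rnorm(5000), b = stats::rnorm(5000)))
  expect_lt(abs(q$pabak), 0.02)
})

test_that("quantile-threshold mode falls back to ranks under heavy ties", {
  v <- c(rep(0, 80), 1:20)  # 80% ties at zero empty the lower quintiles
  expect_warning(
    q <- quintile_agreement(data.frame(a = v, b = v), mode = "quantile"),
    class = "nova24r_tie_warning"
  )
  expect_equal(q$pabak, 1)
})

test_that("reliability sample size reproduces the published minimum of 152", {
  expect_identical(icc_sample_size(0, 0.2, k = 2, alpha = 0.05, power = 0.80), 152L)
  # monotone decreasing in the alternative ICC, diverging near the null
  ns <- vapply(c(0.05, 0.1, 0.2, 0.5, 0.8), function(r1) icc_sample_size(0, r1),
               integer(1))
  expect_true(all(diff(ns) < 0))
  expect_gt(icc_sample_size(0, 0.001), 1e6)
  expect_error(icc_sample_size(0.3, 0.2), class = "nova24r_contract_error")
})

test_that("sample size delivers its nominal power in simulation", {
  # Monte-Carlo power oracle at the returned n for detecting rho1 = 0.5 vs 0:
  # one-sided F-test of MS_R/MS_E > F_crit under H0 theta = 0
  n <- icc_sample_size(0, 0.5, k = 2, alpha = 0.05, power = 0.80)
  set.seed(7)
  reps <- 400
  crit <- stats::qf(0.95, n - 1, n - 1)  # k = 2: df2 = (n-1)(k-1) = n-1
  rejections <- vapply(seq_len(reps), function(i) {
    x <- sim_icc_table(n, 2, 0.5)
    r <- icc_two_way(x)
    unname(r$ms["msr"] / r$ms["mse"]) > crit
  }, logical(1))
  expect_gte(mean(rejections), 0.80 - 2 * sqrt(0.2 * 0.8 / reps))
})

test_that("stratified ICC analyses each stratum and skips undersized ones", {
  set.seed(21)
  x <- sim_icc_table(60, 2, 0.7)
  strata <- rep(c("s1", "s2"), each = 30)
  out <- stratified_icc(x, strata)
  expect_identical(out$stratum, c("s1", "s2"))
  # identical strata give identical ICCs
  x2 <- rbind(x[1:30, ], x[1:30, ])
  out2 <- stratified_icc(x2, strata)
  expect_equal(out2$icc[1], out2$icc[2])
  # a random split leaves stratum ICCs near the pooled value
  pooled <- icc_two_way(x)$icc
  expect_lt(max(abs(out$icc - pooled)), 0.2)
  # n = 2 stratum skipped with warning
  expect_warning(
    out3 <- stratified_icc(x, c(rep("big", 58), "tiny", "tiny")),
    class = "nova24r_stratum_warning"
  )
  expect_identical(out3$stratum, "big")
})

test_that("the agreement report combines means, ICC and quintile agreement", {
  spec <- cohort_spec(n_participants = 120, seed = 31)
  paired <- simulate_paired_shares(spec)
  rep <- agreement_report(paired)
  td <- tidy(rep)
  expect_identical(nrow(td), 4L)
  expect_true(all(c("mean_a", "icc", "icc_band", "pabak", "pabak_band") %in% names(td)))
  gl <- glance(rep)
  expect_identical(gl$icc_form, "consistency")
  expect_output(print(rep), "ICC")
  # report round-trips to a serialisable list
  lst <- nova24r:::report_to_list(rep)
  expect_named(lst, c("tools", "settings", "means", "per_group"))
})
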