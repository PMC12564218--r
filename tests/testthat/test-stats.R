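test_that("the normality check has its nominal level and detects skew", {
  level_ok <- 0
  power_ok <- 0
  for (seed in 1:100) {
    set.seed(seed)
    if (normality_p(rnorm(500)) > 0.05) level_ok <- level_ok + 1
    if (normality_p(rexp(500)) <= 0.05) power_ok <- power_ok + 1
  }
  expect_gte(level_ok, 95)
  expect_gte(power_ok, 99)
  expect_error(normality_p(c(1, 2)), "3 <= n")
  expect_error(normality_p(rep(4, 10)), "constant")
})

test_that("method selection follows the normality and outlier rules", {
  set.seed(10)
  x <- rnorm(80)
  y <- 0.5 * x + rnorm(80, sd = 0.5)
  expect_identical(choose_method(x, y), "pearson")
  expect_identical(choose_method(x, exp(3 * y)), "spearman")
  x_out <- x
  x_out[1] <- x_out[1] + 10 * sd(x)
  expect_identical(choose_method(x_out, y), "spearman")
  expect_error(choose_method(x, y[-1]), "lengths differ")
})

test_that("correlation results match closed-form oracles", {
  z <- c(3, 1, 4, 1.5, 9)
  expect_equal(correlate(z, z, "pearson")$r, 1)
  expect_equal(correlate(z, exp(z), "spearman")$r, 1)

  ## hand covariance formula on the 5-point example
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  hand_r <- sum((x - 3) * (y - 3)) / sqrt(sum((x - 3)^2) * sum((y - 3)^2))
  expect_equal(hand_r, 0.8)
  res <- correlate(x, y, "pearson")
  expect_equal(res$r, hand_r, tolerance = 1e-12)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)

  ## Fisher-z interval agrees with the explicit transform
  set.seed(3)
  a <- rnorm(60)
  b <- a + rnorm(60)
  rr <- correlate(a, b, "pearson")
  z0 <- atanh(rr$r)
  expect_equal(rr$ci_low, tanh(z0 - qnorm(0.975) / sqrt(57)),
               tolerance = 1e-12)
  ## Spearman interval is wider by the 1.06 variance inflation
  rs <- correlate(a, b, "spearman")
  zs <- atanh(rs$r)
  expect_equal(rs$ci_high, tanh(zs + qnorm(0.975) * sqrt(1.06 / 57)),
               tolerance = 1e-12)

  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("Pearson is affine-invariant and Spearman monotone-invariant", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(40)
    y <- x + rnorm(40)
    expect_equal(correlate(2 + 3 * x, y, "pearson")$r,
                 correlate(x, y, "pearson")$r, tolerance = 1e-12)
    expect_equal(correlate(x, exp(y / 2), "spearman")$r,
                 correlate(x, y, "spearman")$r, tolerance = 1e-12)
  }
})

test_that("the required sample size follows the Fisher-z power formula", {
  ## independent hand computation for the design effect size r = 0.26
  z <- qnorm(0.975) + qnorm(0.80)
  hand_n <- ceiling((z / atanh(0.26))^2 + 3)
  expect_identical(required_n(0.26), as.integer(hand_n))
  expect_identical(required_n(0.26), 114L)

  ## near-perfect correlations need only the minimum handful of patients
  expect_lte(required_n(0.999), 5L)
  ## quadratic small-r law: doubling r quarters the required n
  ratio <- (required_n(0.05) - 3) / (required_n(0.10) - 3)
  expect_lt(abs(ratio - 4), 0.2)
  expect_error(required_n(0), "0 < \\|r\\| < 1")
  expect_error(required_n(0.5, alpha = 0), "alpha")
})

test_that("the correlation battery has the full table layout and is deterministic", {
  coh <- simulate_cohort(sim_params(n_patients = 100, seed = 44))
  b1 <- correlation_battery(coh)
  expect_identical(nrow(b1), 17L)
  expect_identical(sum(b1$index_group == "Total AoC"), 5L)
  expect_identical(sum(b1$index_group == "AoCN"), 6L)
  expect_identical(sum(b1$index_group == "AoCD"), 6L)
  expect_true(all(b1$index[c(11, 17)] == c("1 (40 cm)", "1 (300 cm)")))
  expect_true(all(b1$ci_low <= b1$r & b1$r <= b1$ci_high))
  expect_true(all(b1$n == 100))
  ## no hidden randomness
  expect_identical(b1, correlation_battery(coh))
  ## Holm option appends an adjusted column, never smaller than raw p
  bh <- correlation_battery(coh, p_adjust = "holm")
  expect_true(all(bh$p_adjusted >= bh$p_value))
})

test_that("a null generator yields a null battery", {
  coh <- simulate_cohort(sim_params(n_patients = 400, seed = 45,
                                    target_rho_qol = 0))
  b <- correlation_battery(coh)
  expect_true(all(abs(b$r) < 0.2))
  expect_false(any(b$stars == "***"))
})

test_that("quartile comparison splits 25/75 and applies the right tests", {
  coh <- simulate_cohort(sim_params(n_patients = 100, seed = 46))
  covars <- tibble::tibble(
    patient_id = coh$qol$patient_id,
    age = round(rnorm(100, 62, 8.87)),
    gender = rep(c("M", "F"), c(54, 46)),
    rare = rep(c("a", "b"), c(97, 3)))
  q <- quartile_compare(coh, covariates = covars)
  expect_identical(unique(q$n_lowest), 25L)
  expect_identical(unique(q$n_rest), 75L)
  expect_identical(unique(q$n_lowest + q$n_rest), 100L)
  expect_identical(nrow(q), 18L)  # 15 AoC indices + 3 covariates
  expect_identical(q$test_used[q$variable == "gender"], "chi_square")
  expect_identical(q$test_used[q$variable == "rare"], "fisher_exact")
  expect_true(all(q$test_used[q$type == "continuous"] %in%
                    c("t_test", "mann_whitney")))
  ## AoC is depressed in the lowest-QoL quartile by construction
  expect_lt(q$lowest_mean[q$variable == "s9_total"],
            q$rest_mean[q$variable == "s9_total"])
})

test_that("degenerate variables are flagged rather than tested", {
  coh <- simulate_cohort(sim_params(n_patients = 40, seed = 47))
  covars <- tibble::tibble(patient_id = coh$qol$patient_id, flatvar = 1)
  q <- quartile_compare(coh, covariates = covars)
  row <- q[q$variable == "flatvar", ]
  expect_identical(row$test_used, "none")
  expect_true(is.na(row$p_value))
  expect_match(row$note, "constant")
})

test_that("a one-pooled-SD group difference is detected in most cohorts", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed + 900)
    low <- rnorm(25, 0, 1)
    rest <- rnorm(75, 1, 1)
    res <- vicurve:::group_test_continuous(low, rest)
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
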