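degenerate_mn_fit <- function(b = -4.575, scf = 2.44, S = 1) {
  fake_fit(mn_model_registry()[["1_4"]],
           cbind(b = rep(b, S), scf = rep(scf, S)))
}

test_that("degenerate posterior reproduces the printed MN probabilities", {
  fit <- degenerate_mn_fit()
  q0 <- predict_mn_prob(fit, c())
  q1 <- predict_mn_prob(fit, c(SCF = 1))
  expect_equal(q0$average, 0.0102, tolerance = 1e-3)
  expect_equal(q1$average, 0.106, tolerance = 1e-2)
  # all-zero coefficients give exactly 0.5
  flat <- degenerate_mn_fit(b = 0, scf = 0, S = 10)
  expect_equal(predict_mn_prob(flat, c(SCF = 1))$samples, rep(0.5, 10))
})

test_that("fold change divides averaged probabilities", {
  fit <- degenerate_mn_fit()
  fc <- mn_fold_change(fit, c(SCF = 1), c())
  expect_equal(fc$ratio, 0.105741258571 / 0.0102011629408, tolerance = 1e-6)
  expect_equal(fc$ratio, 10.3, tolerance = 0.01)  # the 10.3x headline effect
  # identical covariates give exactly 1
  expect_equal(mn_fold_change(fit, c(SCF = 1), c(SCF = 1))$ratio, 1)
  # small-probability limit: odds multiplier ~ probability multiplier
  tiny <- degenerate_mn_fit(b = -12, scf = log(4))
  expect_equal(mn_fold_change(tiny, c(SCF = 1), c())$ratio, 4,
               tolerance = 1e-3)
})

test_that("predictive MN probability stays inside the draw envelope", {
  set.seed(3)
  fit <- fake_fit(mn_model_registry()[["1_4"]],
                  cbind(b = rnorm(200, -4.5, 0.2),
                        scf = rnorm(200, 2.4, 0.2)))
  p <- predict_mn_prob(fit, c(SCF = 1))
  expect_true(all(p$samples >= 0 & p$samples <= 1))
  expect_gte(p$average, min(p$samples))
  expect_lte(p$average, max(p$samples))
  expect_error(predict_mn_prob(fit, c(BOGUS = 1)), "covariate error")
})

degenerate_dur_fit <- function(b = log(17), micro = 0.820, sigma = 0.3,
                               S = 1) {
  sig <- matrix(rep(sigma, S * 6), nrow = S)
  colnames(sig) <- paste0("sigma[", condition_table()$condition, "]")
  fake_fit(duration_model_registry()[["2_2"]],
           cbind(b = rep(b, S), micro = rep(micro, S),
                 scf = 0, rnf = 0, stg = 0, sis2_3 = 0, sig))
}

test_that("sigma -> 0 predictive durations collapse to exp(mu)", {
  fit <- degenerate_dur_fit(sigma = 1e-12)
  ps <- predictive_durations(fit, c(), mn_status = 0,
                             condition = "CTRL48:mCit:N+x", m = 50, seed = 1)
  expect_equal(ps$samples, rep(17, 50), tolerance = 1e-6)
})

test_that("toggling MN multiplies the predictive median by exp(micro) = 2.27", {
  fit <- degenerate_dur_fit()
  cond <- "SIS2-3:sgF11:N+x"
  s0 <- predictive_durations(fit, c(), 0, cond, m = 60000, seed = 2)
  s1 <- predictive_durations(fit, c(), 1, cond, m = 60000, seed = 3)
  ratio <- median(s1$samples) / median(s0$samples)
  expect_equal(ratio, exp(0.820), tolerance = 0.02)
  expect_equal(exp(0.820), 2.27, tolerance = 0.005)
})

test_that("predictive quartiles match closed-form log-normal quantiles", {
  fit <- degenerate_dur_fit()
  ps <- predictive_durations(fit, c(), 0, "CTRL48:mCit:N+x",
                             m = 1e5, seed = 4)
  q <- duration_quartiles(ps)
  expect_equal(q$q25, 17 * exp(qnorm(0.25) * 0.3), tolerance = 0.01)
  expect_equal(q$q75, 17 * exp(qnorm(0.75) * 0.3), tolerance = 0.01)
  expect_equal(q$iqr, 20.812699 - 13.885753, tolerance = 0.02)
  expect_error(predictive_durations(fit, c(), 0, "nope", m = 10),
               "unknown condition")
})

test_that("duration quartiles follow the linear-interpolation convention", {
  q <- duration_quartiles(c(1, 2, 3, 4))
  expect_equal(q$q25, 1.75)
  expect_equal(q$q50, 2.5)
  expect_equal(q$q75, 3.25)
  expect_equal(q$iqr, 1.5)
  expect_equal(duration_quartiles(rep(7, 10))$iqr, 0)
  expect_error(duration_quartiles(c(1, 2, 3)), "at least 4")
})

test_that("IQR is monotone under scaling", {
  set.seed(5)
  x <- rlnorm(500, 3, 0.4)
  q1 <- duration_quartiles(x)$iqr
  q3 <- duration_quartiles(3 * x)$iqr
  expect_equal(q3, 3 * q1, tolerance = 1e-12)
})

test_that("KS distance matches the numeric CDF-difference oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_distance(c(1, 2), c(10, 11))$D, 1)
  set.seed(6)
  a <- rlnorm(4000, log(17), 0.3)
  b <- rlnorm(4000, log(17) + 0.82, 0.3)
  # numeric sup |F1 - F2| of the two closed-form distributions
  grid <- seq(5, 120, by = 0.01)
  d_true <- max(abs(plnorm(grid, log(17), 0.3) -
                      plnorm(grid, log(17) + 0.82, 0.3)))
  ks <- ks_distance(a, b)
  expect_equal(ks$D, d_true, tolerance = 0.05)
  expect_lt(ks$p_value, 1e-10)
})

test_that("predict() dispatches on the fitted response", {
  mn <- degenerate_mn_fit(S = 3)
  expect_s3_class(predict(mn, c(SCF = 1)), "predictive_samples")
  dur <- degenerate_dur_fit(S = 3)
  ps <- predict(dur, c(), mn_status = 1, condition = "SIS2-3:sgF11:1+x",
                m = 20, seed = 1)
  expect_length(ps$samples, 20)
  expect_true(all(ps$samples > 0))
})
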