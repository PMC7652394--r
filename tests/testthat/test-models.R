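test_that("the MN registry holds the six canonical structures", {
  reg <- mn_model_registry()
  expect_length(reg, 6L)
  expect_equal(reg[["1_4"]]$terms, "scf")
  expect_equal(reg[["1_4"]]$lineage_effect, "none")
  expect_setequal(reg[["1_2"]]$terms, c("scf", "rnf", "stg", "sis2_3"))
  expect_equal(reg[["1_2"]]$lineage_effect, "none")
  effects <- vapply(reg, `[[`, "", "lineage_effect")
  expect_equal(sum(effects == "normal"), 2L)
  expect_equal(sum(effects == "student_t"), 2L)
  expect_true(all(vapply(reg, `[[`, "", "likelihood") == "bernoulli_logit"))
})

test_that("the duration registry holds eight structures, micro always present", {
  reg <- duration_model_registry()
  expect_length(reg, 8L)
  expect_setequal(reg[["2_2"]]$terms, c("micro", "scf", "rnf", "stg", "sis2_3"))
  expect_equal(reg[["2_2"]]$lineage_effect, "none")
  expect_equal(reg[["2_2"]]$sigma_grouping, "by_condition")
  expect_equal(reg[["2_2_exp"]]$likelihood, "exponential")
  expect_setequal(reg[["2_2_exp"]]$terms, reg[["2_2"]]$terms)
  expect_equal(reg[["2_2_gamma"]]$likelihood, "gamma")
  expect_true(all(vapply(reg, function(s) "micro" %in% s$terms, logical(1))))
})

test_that("invalid model specifications are rejected", {
  expect_error(model_spec("x", "MN", "bernoulli_logit", "micro"), "micro")
  expect_error(model_spec("x", "MN", "lognormal"), "bernoulli_logit")
  expect_error(model_spec("x", "interphase_duration", "lognormal",
                          "micro", sigma_grouping = "none"), "sigma_grouping")
  expect_error(model_spec("x", "MN", "bernoulli_logit", "banana"), "unknown")
})

test_that("model specs round-trip through JSON", {
  spec <- duration_model_registry()[["2_2_gamma"]]
  f <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, f)
  expect_equal(unclass(read_model_spec(f)), unclass(spec))
})

test_that("Bernoulli log-likelihood matches hand evaluations", {
  spec <- model_spec("b_only", "MN", "bernoulli_logit")
  md <- fake_modeldata(MN = c(0L, 1L))
  ll <- pointwise_loglik(spec, list(b = 0), md)
  expect_equal(ll, rep(log(0.5), 2), tolerance = 1e-12)

  # b = -4.575, scf = 2.44, SCF = 1, MN = 1 -> log inv_logit(-2.135)
  spec14 <- mn_model_registry()[["1_4"]]
  md1 <- fake_modeldata(MN = 1L, SCF = 1L, SIS = 1L)
  ll1 <- pointwise_loglik(spec14, list(b = -4.575, scf = 2.44), md1)
  expect_equal(ll1, -2.2467601, tolerance = 1e-6)
  expect_equal(exp(ll1), 0.106, tolerance = 0.005)
})

test_that("Bernoulli log-likelihoods are normalized over both outcomes", {
  spec <- mn_model_registry()[["1_2"]]
  set.seed(1)
  for (rep in 1:20) {
    pars <- list(b = rnorm(1), scf = rnorm(1), rnf = rnorm(1),
                 stg = rnorm(1), sis2_3 = rnorm(1))
    covs <- sample(0:1, 4, replace = TRUE)
    md0 <- fake_modeldata(MN = 0L, SCF = covs[1], RNF = covs[2],
                          SIS = covs[3], STG = covs[4])
    md1 <- fake_modeldata(MN = 1L, SCF = covs[1], RNF = covs[2],
                          SIS = covs[3], STG = covs[4])
    tot <- exp(pointwise_loglik(spec, pars, md0)) +
      exp(pointwise_loglik(spec, pars, md1))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("log-normal density at its median matches the closed form", {
  spec <- duration_model_registry()[["2_4"]]
  mu <- log(17); sigma <- 0.3
  md <- fake_modeldata(MN = 0L, duration = exp(mu))
  pars <- list(b = mu, micro = 0, sigma = rep(sigma, 6))
  ll <- pointwise_loglik(spec, pars, md)
  expect_equal(ll, log(1 / (exp(mu) * sigma * sqrt(2 * pi))),
               tolerance = 1e-12)
})

test_that("missing durations contribute zero; non-positive durations error", {
  spec <- duration_model_registry()[["2_4"]]
  md <- fake_modeldata(MN = c(0L, 0L), duration = c(17, NA))
  ll <- pointwise_loglik(spec, list(b = log(17), micro = 0,
                                    sigma = rep(0.3, 6)), md)
  expect_equal(ll[2], 0)
  md_bad <- fake_modeldata(MN = 0L, duration = -2)
  expect_error(pointwise_loglik(spec, list(b = 1, micro = 0,
                                           sigma = rep(0.3, 6)), md_bad),
               "domain")
})

test_that("gamma with shape 1 reduces to the exponential likelihood", {
  dur_reg <- duration_model_registry()
  md <- fake_modeldata(MN = c(0L, 1L, 0L), SCF = c(1L, 1L, 0L),
                       SIS = c(1L, 1L, 0L),
                       duration = c(12, 40, 22))
  pars <- list(b = log(18), micro = 0.8, scf = 0.1, rnf = 0, stg = 0,
               sis2_3 = 0.05)
  ll_exp <- pointwise_loglik(dur_reg[["2_2_exp"]], pars, md)
  ll_gam <- pointwise_loglik(dur_reg[["2_2_gamma"]],
                             c(pars, list(sigma = rep(1, 6))), md)
  expect_equal(ll_gam, ll_exp, tolerance = 1e-12)
})

test_that("a mu shift multiplies the log-normal median exactly by exp(delta)", {
  # the mechanism behind reporting exp(micro) as a fold change on duration
  delta <- 0.820
  mu <- log(17)
  expect_equal(qlnorm(0.5, mu + delta, 0.3) / qlnorm(0.5, mu, 0.3),
               exp(delta), tolerance = 1e-12)
  expect_equal(exp(delta), 2.27, tolerance = 0.005)
})

test_that("dimension mismatches are shape errors", {
  spec <- model_spec("h", "MN", "bernoulli_logit", "scf", "normal")
  md <- fake_modeldata(MN = c(0L, 1L), lineage = c(1L, 2L))
  expect_error(pointwise_loglik(spec, list(b = 0, scf = 1, lin = numeric(5)),
                                md), "shape error")
})
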