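test_that("noiseless generation and fitting recover the identity exactly", {
  # sigma = 0, b = 1, a = 0: time = exp(surrogate)
  hd <- generate_historical_data(50, a = 0, b = 1, sigma = 0,
                                 surrogate_law = list(dist = "uniform",
                                                      min = -2, max = 2),
                                 seed = 3)
  expect_equal(hd$time_weeks, exp(hd$surrogate))
  fit <- fit_lognormal_model(hd, n_draws = 2500, n_burnin = 500, seed = 4)
  sm <- summarize_posterior(fit)
  expect_equal(sm$b_mean, 1, tolerance = 1e-3)
  expect_equal(sm$a_mean, 0, tolerance = 1e-3)
})

test_that("a fixed surrogate with sigma = 0 maps to the exact time", {
  hd <- generate_historical_data(1, a = 0, b = 1, sigma = 0,
                                 surrogate_law = list(dist = "normal",
                                                      mean = 2, sd = 0),
                                 seed = 1)
  expect_equal(hd$time_weeks, exp(2))
})

test_that("generated log-times obey the law of large numbers", {
  hd <- generate_historical_data(2000, ref_params[["a"]], ref_params[["b"]],
                                 ref_params[["sigma"]], seed = 11)
  # E[surrogate] = 0 under Uniform(-4, 4); Var(logT) = b^2 * 16/3 + sigma^2
  se <- sqrt((ref_params[["b"]]^2 * 16 / 3 + ref_params[["sigma"]]^2) / 2000)
  expect_lt(abs(mean(log(hd$time_weeks)) - ref_params[["a"]]), 3 * se)
})

test_that("administrative censoring flags and truncates correctly", {
  # huge intercept pushes every latent time beyond the censor time
  hd <- generate_historical_data(30, a = 20, b = 0.1, sigma = 0.1,
                                 censor_time = 156, seed = 5)
  expect_true(all(hd$event == 0))
  expect_true(all(hd$time_weeks == 156))
  expect_error(fit_lognormal_model(hd), "uncensored")
})

test_that("posterior means match the least-squares oracle on complete data", {
  set.seed(21)
  hd <- generate_historical_data(200, ref_params[["a"]], ref_params[["b"]],
                                 ref_params[["sigma"]], seed = 21)
  fit <- fit_lognormal_model(hd, n_draws = 6000, n_burnin = 1000, seed = 22)
  ols <- stats::lm(log(time_weeks) ~ surrogate, data = hd)
  sm <- summarize_posterior(fit)
  # flat priors on (a, b): posterior mean equals the OLS solution up to
  # Monte-Carlo error; conjugate Gibbs draws mix fast, ESS >= n/3 is
  # conservative
  ess <- length(fit$a) / 3
  expect_lt(abs(sm$a_mean - coef(ols)[1]), 3 * sd(fit$a) / sqrt(ess))
  expect_lt(abs(sm$b_mean - coef(ols)[2]), 3 * sd(fit$b) / sqrt(ess))
})

test_that("the sampler recovers generating parameters within 3 posterior SDs", {
  hd <- generate_historical_data(500, ref_params[["a"]], ref_params[["b"]],
                                 ref_params[["sigma"]], seed = 31)
  fit <- fit_lognormal_model(hd, n_draws = 4000, n_burnin = 1000, seed = 32)
  expect_lt(abs(mean(fit$a) - ref_params[["a"]]), 3 * sd(fit$a))
  expect_lt(abs(mean(fit$b) - ref_params[["b"]]), 3 * sd(fit$b))
  expect_lt(abs(mean(fit$sigma) - ref_params[["sigma"]]), 3 * sd(fit$sigma))
})

test_that("censored records are handled by data augmentation", {
  hd <- generate_historical_data(600, a = 1, b = -1, sigma = 1,
                                 censor_time = 20, seed = 41)
  expect_true(any(hd$event == 0))
  fit <- fit_lognormal_model(hd, n_draws = 4000, n_burnin = 1000, seed = 42)
  expect_lt(abs(mean(fit$b) - (-1)), 3 * sd(fit$b))
  expect_lt(abs(mean(fit$sigma) - 1), 3 * sd(fit$sigma))
  # naive censoring-ignoring fit would be biased toward zero slope; the
  # augmented fit must beat it
  naive <- coef(stats::lm(log(time_weeks) ~ surrogate, data = hd))[2]
  expect_lt(abs(mean(fit$b) - (-1)), abs(naive - (-1)))
})

test_that("a direct Gamma prior on sigma gives compatible estimates", {
  hd <- generate_historical_data(300, ref_params[["a"]], ref_params[["b"]],
                                 ref_params[["sigma"]], seed = 51)
  fit_prec <- fit_lognormal_model(hd, prior_spec(prior_on = "precision"),
                                  n_draws = 3000, n_burnin = 500, seed = 52)
  fit_sig <- fit_lognormal_model(hd, prior_spec(prior_on = "sigma"),
                                 n_draws = 3000, n_burnin = 500, seed = 52)
  expect_lt(abs(mean(fit_sig$sigma) - mean(fit_prec$sigma)),
            3 * sd(fit_prec$sigma))
  expect_lt(abs(mean(fit_sig$b) - mean(fit_prec$b)), 3 * sd(fit_prec$b))
})

test_that("more data shrinks the slope's posterior SD", {
  hd_small <- generate_historical_data(200, ref_params[["a"]],
                                       ref_params[["b"]],
                                       ref_params[["sigma"]], seed = 61)
  hd_big <- generate_historical_data(2000, ref_params[["a"]],
                                     ref_params[["b"]],
                                     ref_params[["sigma"]], seed = 61)
  f_small <- fit_lognormal_model(hd_small, n_draws = 3000, n_burnin = 500,
                                 seed = 62)
  f_big <- fit_lognormal_model(hd_big, n_draws = 3000, n_burnin = 500,
                               seed = 62)
  expect_lt(sd(f_big$b), sd(f_small$b))
})

test_that("summaries of degenerate and two-point draws are exact", {
  const <- structure(list(a = rep(0.16, 1000), b = rep(-1.37, 1000),
                          sigma = rep(1.53, 1000)),
                     class = "posterior_draws")
  sm <- summarize_posterior(const)
  expect_equal(sm$a_mean, 0.16)
  expect_equal(sm$b_mean, -1.37)
  expect_equal(sm$sigma_mean, 1.53)
  expect_equal(sm$b_ci95, c(-1.37, -1.37))

  two <- structure(list(a = rep(0, 1000), b = rep(c(-1, -2), 500),
                        sigma = rep(1, 1000)),
                   class = "posterior_draws")
  expect_equal(summarize_posterior(two)$b_mean, -1.5)
  expect_error(summarize_posterior(list(a = numeric(0), b = numeric(0),
                                        sigma = numeric(0))), "empty")
})

test_that("slope validity uses the closed credible interval", {
  mk <- function(lo, hi) structure(list(a_mean = 0, b_mean = (lo + hi) / 2,
                                        sigma_mean = 1, b_ci95 = c(lo, hi)),
                                   class = "model_summary")
  expect_true(check_slope_validity(mk(-1.53, -1.22)))
  expect_false(check_slope_validity(mk(-0.5, 0.5)))
  expect_false(check_slope_validity(mk(0.0, 1.0)))  # boundary covers zero
  expect_true(check_slope_validity(mk(0.1, 1.0)))
})

test_that("slope validity is invariant to a joint sign flip of surrogates", {
  hd <- generate_historical_data(300, ref_params[["a"]], ref_params[["b"]],
                                 ref_params[["sigma"]], seed = 71)
  hd_flip <- hd
  hd_flip$surrogate <- -hd$surrogate
  f1 <- fit_lognormal_model(hd, n_draws = 3000, n_burnin = 500, seed = 72)
  f2 <- fit_lognormal_model(hd_flip, n_draws = 3000, n_burnin = 500,
                            seed = 72)
  expect_equal(check_slope_validity(summarize_posterior(f1)),
               check_slope_validity(summarize_posterior(f2)))
})

test_that("input validation rejects degenerate datasets", {
  ok <- data.frame(surrogate = c(0, 1, 2, 3), time_weeks = c(1, 2, 3, 4),
                   event = c(1, 1, 1, 0))
  expect_silent(surradapt:::validate_historical_data(ok))
  bad_few <- ok; bad_few$event <- c(1, 1, 0, 0)
  expect_error(fit_lognormal_model(bad_few), "uncensored")
  bad_na <- ok; bad_na$surrogate[1] <- NA
  expect_error(fit_lognormal_model(bad_na), "finite")
  bad_t <- ok; bad_t$time_weeks[1] <- 0
  expect_error(fit_lognormal_model(bad_t), "> 0")
  expect_error(fit_lognormal_model(ok, n_draws = 1500, n_burnin = 1000),
               "n_draws")
})

test_that("historical and posterior CSV round-trips preserve the data", {
  hd <- generate_historical_data(20, 0.16, -1.37, 1.53, seed = 81,
                                 censor_time = 100)
  f_h <- tempfile(fileext = ".csv")
  utils::write.csv(hd, f_h, row.names = FALSE)
  back <- read_historical_data(f_h)
  expect_equal(back$surrogate, hd$surrogate, tolerance = 1e-12)
  expect_equal(back$event, hd$event)

  draws <- structure(list(a = rnorm(1200), b = rnorm(1200) - 1,
                          sigma = rexp(1200) + 0.1,
                          n_burnin = 0L, seed = 1L),
                     class = "posterior_draws")
  f_p <- tempfile(fileext = ".csv")
  write_posterior_draws(draws, f_p)
  back_d <- read_posterior_draws(f_p)
  expect_equal(mean(back_d$b), mean(draws$b), tolerance = 1e-12)
  unlink(c(f_h, f_p))
})
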