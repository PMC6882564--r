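test_that("closed-form posterior moments match their textbook values", {
  ap <- analytic_posterior(100, 1.681, 0.264)
  expect_equal(ap$mu_mean, 1.681)
  # SD(mu) = s * sqrt((n-1)/(n(n-4)))
  expect_equal(ap$mu_sd, 0.264 * sqrt(99 / (100 * 96)), tolerance = 1e-12)
  expect_equal(ap$mu_sd, 0.0268, tolerance = 0.002)
  # E[sigma^2] = (n-1) s^2 / (n-4)
  expect_equal(ap$sigma2_mean, 99 * 0.264^2 / 96, tolerance = 1e-12)
  expect_equal(ap$sigma2_mean, 0.0719, tolerance = 0.001)
  # E[sigma] ~ s (1 + 3/(4(n-2))) to first asymptotic order
  expect_equal(ap$sigma_mean, 0.264 * (1 + 3 / (4 * 98)), tolerance = 0.01)
  # median of mu is the sample mean; quantiles are ordered
  expect_equal(ap$mu_quantile(0.5), 1.681)
  expect_true(ap$sigma_quantile(0.025) < ap$sigma_quantile(0.975))
  expect_error(analytic_posterior(3, 1, 0.1), "n >= 4")
})

test_that("closed form agrees with brute-force grid integration of the posterior", {
  y <- c(1.764, 2.011, 1.393, 1.455, 2.471, 1.626, 2.529, 2.25, 1.982, 1.598,
         1.669, 1.861)
  grid <- grid_posterior_moments(y)
  ap <- analytic_posterior(length(y), mean(y), sd(y))
  expect_equal(ap$mu_mean, grid$mu_mean, tolerance = 1e-4)
  expect_equal(ap$mu_sd, grid$mu_sd, tolerance = 1e-3)
  expect_equal(ap$sigma_mean, grid$sigma_mean, tolerance = 1e-3)
  expect_equal(ap$sigma_sd, grid$sigma_sd, tolerance = 2e-3)
})

test_that("the Gibbs sampler reproduces the closed-form posterior", {
  y <- withr::with_seed(71, rnorm(100, 1.681, 0.264))
  y <- moment_match(y, 1.681, 0.264)
  draws <- sample_posterior(y, small_mcmc(72, n_chains = 4,
                                          draws_per_chain = 6000, burn_in = 500))
  ap <- analytic_posterior(100, 1.681, 0.264)
  expect_equal(mean(draws$mu), 1.681, tolerance = 0.02)
  expect_equal(mean(draws$sigma), ap$sigma_mean, tolerance = 0.02)
  expect_equal(sd(draws$mu), ap$mu_sd, tolerance = 0.05)
  expect_equal(sd(draws$sigma), ap$sigma_sd, tolerance = 0.05)
  expect_equal(unname(quantile(draws$mu, 0.975)), ap$mu_quantile(0.975),
               tolerance = 0.005)
})

test_that("draws are seeded, reproducible, and obey the retention contract", {
  y <- withr::with_seed(73, rnorm(30, 1.7, 0.3))
  cfg <- small_mcmc(74, n_chains = 3, draws_per_chain = 1200, burn_in = 200)
  a <- sample_posterior(y, cfg)
  b <- sample_posterior(y, cfg)
  expect_identical(a$mu, b$mu)
  expect_identical(a$sigma, b$sigma)
  expect_equal(dim(a$mu), c(1000, 3))
  expect_true(all(a$sigma > 0))
  c2 <- sample_posterior(y, small_mcmc(75, n_chains = 3, draws_per_chain = 1200,
                                       burn_in = 200))
  expect_false(identical(a$mu, c2$mu))
})

test_that("draws respect the uniform prior box", {
  y <- withr::with_seed(76, rnorm(40, 1.7, 0.3))
  cfg <- mcmc_config(n_chains = 2, draws_per_chain = 2000, burn_in = 200,
                     mu_bounds = c(1.65, 1.75), sigma_bounds = c(0.25, 0.35),
                     seed = 77)
  draws <- sample_posterior(y, cfg)
  expect_true(all(draws$mu >= 1.65 & draws$mu <= 1.75))
  expect_true(all(draws$sigma > 0.25 & draws$sigma <= 0.35))
})

test_that("degenerate data and inconsistent priors are rejected", {
  expect_error(sample_posterior(rep(2, 10)), "zero-variance")
  expect_error(sample_posterior(c(1, 2)), "at least 3")
  y <- withr::with_seed(78, rnorm(20, 8, 0.5))
  expect_error(sample_posterior(y, mcmc_config(mu_bounds = c(0, 2), seed = 1)),
               "outside the prior bounds")
})

test_that("widening an already-wide prior leaves the summaries unchanged", {
  y <- withr::with_seed(79, rnorm(100, 1.7, 0.3))
  wide <- sample_posterior(y, small_mcmc(80))
  wider <- sample_posterior(y, mcmc_config(n_chains = 2, draws_per_chain = 2500,
                                           burn_in = 250, mu_bounds = c(-100, 100),
                                           sigma_bounds = c(1e-9, 50), seed = 80))
  expect_lt(abs(mean(wider$mu) - mean(wide$mu)) / mean(wide$mu), 0.001)
  expect_lt(abs(mean(wider$sigma) - mean(wide$sigma)) / mean(wide$sigma), 0.001)
})

test_that("the Metropolis sampler agrees with the Gibbs sampler's target", {
  y <- withr::with_seed(81, rnorm(60, 1.7, 0.3))
  ap <- analytic_posterior(60, mean(y), sd(y))
  draws <- sample_posterior(y, mcmc_config(n_chains = 4, draws_per_chain = 8000,
                                           burn_in = 2000, seed = 82,
                                           sampler = "metropolis"))
  expect_equal(mean(draws$mu), ap$mu_mean, tolerance = 0.01 * ap$mu_mean)
  expect_equal(mean(draws$sigma), ap$sigma_mean, tolerance = 0.03 * ap$sigma_mean)
  expect_lt(max(gelman_rubin(draws)), 1.05)
})

test_that("exceedance probability matches the per-draw normal CDF", {
  y <- withr::with_seed(83, rnorm(50, 1.7, 0.3))
  draws <- sample_posterior(y, small_mcmc(84))
  p <- exceedance_probability(draws, 2.0)
  expect_equal(p$draws, pnorm((2.0 - draws$mu) / draws$sigma))
  expect_equal(p$mean, mean(p$draws))
  expect_true(p$mean >= 0 && p$mean <= 1)
  expect_true(p$ci[1] < p$ci[2])
})

test_that("the attainment probability is 1/2 when the dose limit sits at mu", {
  fake <- structure(list(mu = matrix(1.7, 100, 2),
                         sigma = matrix(runif(200, 0.1, 2), 100, 2),
                         data = list(n = 10, mean = 1.7, sd = 0.3),
                         config = mcmc_config(n_chains = 2)),
                    class = "posterior_draws")
  p <- exceedance_probability(fake, 1.7)
  expect_equal(p$mean, 0.5)
  expect_equal(p$sd, 0)
})

test_that("plug-in helpers evaluate the normal model directly", {
  expect_equal(plugin_exceedance(1.681, 0.264, 2.0),
               pnorm((2.0 - 1.681) / 0.264))
  expect_equal(plugin_coverage_dose(1.681, 0.264, 0.95),
               1.681 + qnorm(0.95) * 0.264)
  expect_equal(plugin_coverage_dose(1.7, 0.4, 0.5), 1.7)  # median
})

test_that("coverage dose and exceedance probability are mutually consistent", {
  y <- withr::with_seed(85, rnorm(40, 1.7, 0.3))
  draws <- sample_posterior(y, small_mcmc(86))
  q <- coverage_dose(draws, 0.95)
  # plugging each per-draw dose back into its own normal model returns 0.95
  back <- pnorm((q$draws - draws$mu) / draws$sigma)
  expect_equal(as.vector(back), rep(0.95, length(back)), tolerance = 1e-12)
  # degenerate scale: dose collapses onto mu
  fake <- structure(list(mu = matrix(1.7, 50, 2), sigma = matrix(1e-12, 50, 2),
                         data = list(n = 10, mean = 1.7, sd = 0.3),
                         config = mcmc_config(n_chains = 2)),
                    class = "posterior_draws")
  expect_equal(coverage_dose(fake, 0.95)$mean, 1.7, tolerance = 1e-10)
})

test_that("derived quantities are monotone in dose limit and coverage", {
  y <- withr::with_seed(87, rnorm(40, 1.7, 0.3))
  draws <- sample_posterior(y, small_mcmc(88))
  p_means <- vapply(c(1.5, 1.8, 2.1, 2.4),
                    function(L) exceedance_probability(draws, L)$mean, numeric(1))
  expect_true(all(diff(p_means) > 0))
  q_means <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                    function(cv) coverage_dose(draws, cv)$mean, numeric(1))
  expect_true(all(diff(q_means) > 0))
})

test_that("split-chain R-hat separates mixed from unmixed chains", {
  identical_chains <- structure(
    list(mu = matrix(rep(withr::with_seed(89, rnorm(500)), 3), 500, 3),
         sigma = matrix(rep(withr::with_seed(90, rgamma(500, 5)), 3), 500, 3),
         data = list(n = 10, mean = 0, sd = 1),
         config = mcmc_config(n_chains = 3)),
    class = "posterior_draws")
  r <- gelman_rubin(identical_chains)
  expect_equal(unname(r["mu"]), 1, tolerance = 0.01)

  shifted <- identical_chains
  shifted$mu[, 2] <- shifted$mu[, 2] + 10  # 10 SDs apart
  expect_gt(gelman_rubin(shifted)["mu"], 1.5)

  y <- withr::with_seed(91, rnorm(100, 1.7, 0.3))
  mixed <- sample_posterior(y, small_mcmc(92, n_chains = 4))
  expect_lt(max(gelman_rubin(mixed)), 1.01)

  one_chain <- sample_posterior(y, small_mcmc(93, n_chains = 1))
  expect_error(gelman_rubin(one_chain), "at least 2 chains")
})

test_that("delta-method SD tracks the transformed-parameter uncertainty", {
  expect_equal(delta_method_sd(100, 1.681, 0.264, 2.0), 0.0253, tolerance = 0.002)
  expect_equal(delta_method_sd(100, 1.818, 0.482, 2.0), 0.0385, tolerance = 0.002)
  # posterior concentration: SD -> 0 as n grows
  expect_lt(delta_method_sd(1e8, 1.681, 0.264, 2.0), 1e-3)
  expect_gt(delta_method_sd(10, 1.681, 0.264, 2.0),
            delta_method_sd(1000, 1.681, 0.264, 2.0))
})

test_that("posterior_summary collates moments, quantiles and diagnostics", {
  y <- withr::with_seed(94, rnorm(60, 1.7, 0.3))
  draws <- sample_posterior(y, small_mcmc(95))
  s <- posterior_summary(draws, dose_limit = 2.0, coverage = 0.95)
  expect_setequal(s$quantity, c("mu", "sigma", "attainment_prob", "coverage_dose"))
  expect_true(all(s$q2.5 < s$q97.5))
  expect_true(all(s$rhat > 1 - 0.01))
  expect_true(all(s$ess > 100))
  p_row <- s[s$quantity == "attainment_prob", ]
  expect_true(p_row$mean >= 0 && p_row$mean <= 1)
})

test_that("draw export writes one row per retained draw with derived columns", {
  y <- withr::with_seed(96, rnorm(30, 1.7, 0.3))
  draws <- sample_posterior(y, small_mcmc(97, draws_per_chain = 600, burn_in = 100))
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(draws, f, dose_limit = 2.0, coverage = 0.95)
  d <- read.csv(f)
  expect_equal(nrow(d), 2 * 500)
  expect_setequal(names(d), c("chain", "iteration", "mu", "sigma", "p", "q"))
  expect_equal(d$mu[1:500], draws$mu[, 1])
  expect_equal(d$p, pnorm((2 - d$mu) / d$sigma), tolerance = 1e-6)
})
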