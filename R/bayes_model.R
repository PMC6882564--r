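#' MCMC configuration for the normal location-scale model
#'
#' The study default is five chains of 21,000 draws with the first 1,000 of
#' each chain discarded as burn-in, retaining 100,000 draws in total. The
#' prior on (mu, sigma) is uniform over a box: mu in `mu_bounds`, sigma in
#' `sigma_bounds`; the defaults (0-10 mL/kg, up to 5 mL/kg spread) are wide
#' enough to be effectively flat for required-volume data. For inference in
#' enhancement space pass bounds on the HU scale, e.g. `mu_bounds = c(0,
#' 1000)`, `sigma_bounds = c(1e-6, 200)`.
#'
#' @param n_chains Number of chains (>= 1; >= 2 for R-hat).
#' @param draws_per_chain Total draws per chain including burn-in.
#' @param burn_in Draws discarded at the start of each chain.
#' @param mu_bounds Length-2 uniform prior bounds for the location.
#' @param sigma_bounds Length-2 uniform prior bounds for the scale; lower
#'   bound may be machine-small but must be > 0.
#' @param seed Integer seed.
#' @param sampler `"gibbs"` (conjugate, exact full conditionals) or
#'   `"metropolis"` (random-walk alternative).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 5, draws_per_chain = 21000, burn_in = 1000,
                        mu_bounds = c(0, 10), sigma_bounds = c(1e-6, 5),
                        seed = 1L, sampler = c("gibbs", "metropolis")) {
  sampler <- match.arg(sampler)
  if (n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  if (burn_in < 0 || burn_in >= draws_per_chain)
    stop("burn_in must lie in [0, draws_per_chain)", call. = FALSE)
  if (length(mu_bounds) != 2 || diff(mu_bounds) <= 0 || any(!is.finite(mu_bounds)))
    stop("mu_bounds must be finite and increasing", call. = FALSE)
  if (length(sigma_bounds) != 2 || sigma_bounds[1] <= 0 || diff(sigma_bounds) <= 0 ||
      any(!is.finite(sigma_bounds)))
    stop("sigma_bounds must be finite, increasing, with positive lower bound",
         call. = FALSE)
  cfg <- list(n_chains = as.integer(n_chains),
              draws_per_chain = as.integer(draws_per_chain),
              burn_in = as.integer(burn_in),
              mu_bounds = as.numeric(mu_bounds),
              sigma_bounds = as.numeric(sigma_bounds),
              seed = as.integer(seed), sampler = sampler)
  class(cfg) <- "mcmc_config"
  cfg
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("MCMC config: %d chain(s) x %d draws (burn-in %d, %d retained in total), %s sampler\n",
              x$n_chains, x$draws_per_chain, x$burn_in,
              x$n_chains * (x$draws_per_chain - x$burn_in), x$sampler))
  cat(sprintf("  uniform prior: mu in [%g, %g], sigma in (%g, %g]\n",
              x$mu_bounds[1], x$mu_bounds[2], x$sigma_bounds[1], x$sigma_bounds[2]))
  invisible(x)
}

# One Gibbs chain under the flat boxed prior, using sufficient statistics.
# Full conditionals:
#   sigma^2 | mu, y  ~  S(mu) / chisq_{n-1},  S(mu) = (n-1)s^2 + n(mu-ybar)^2
#   mu | sigma, y    ~  N(ybar, sigma^2 / n)
# Draws falling outside the prior box are redrawn (rejection), which is the
# exact conditional under the truncated prior.
run_gibbs_chain <- function(n, ybar, s2, cfg, mu0, sigma2_0) {
  keep <- cfg$draws_per_chain - cfg$burn_in
  mu_out <- numeric(keep)
  sigma_out <- numeric(keep)
  slo <- cfg$sigma_bounds[1]; shi <- cfg$sigma_bounds[2]
  mlo <- cfg$mu_bounds[1]; mhi <- cfg$mu_bounds[2]
  nm1 <- n - 1
  base_S <- nm1 * s2
  mu <- mu0
  for (t in seq_len(cfg$draws_per_chain)) {
    S <- base_S + n * (mu - ybar)^2
    repeat {
      sigma2 <- S / stats::rchisq(1, nm1)
      sigma <- sqrt(sigma2)
      if (sigma > slo && sigma <= shi) break
    }
    sd_mu <- sigma / sqrt(n)
    repeat {
      mu <- stats::rnorm(1, ybar, sd_mu)
      if (mu >= mlo && mu <= mhi) break
    }
    if (t > cfg$burn_in) {
      mu_out[t - cfg$burn_in] <- mu
      sigma_out[t - cfg$burn_in] <- sigma
    }
  }
  list(mu = mu_out, sigma = sigma_out)
}

# Random-walk Metropolis alternative on (mu, sigma); flat boxed prior means
# the log target is -n log sigma - S(mu)/(2 sigma^2) inside the box.
run_metropolis_chain <- function(n, ybar, s2, cfg, mu0, sigma2_0) {
  keep <- cfg$draws_per_chain - cfg$burn_in
  mu_out <- numeric(keep)
  sigma_out <- numeric(keep)
  log_post <- function(mu, sigma) {
    if (mu < cfg$mu_bounds[1] || mu > cfg$mu_bounds[2] ||
        sigma <= cfg$sigma_bounds[1] || sigma > cfg$sigma_bounds[2]) return(-Inf)
    S <- (n - 1) * s2 + n * (mu - ybar)^2
    -n * log(sigma) - S / (2 * sigma^2)
  }
  s <- sqrt(s2)
  step_mu <- 2.4 * s / sqrt(n)
  step_sigma <- 2.4 * s / sqrt(2 * n)
  mu <- mu0; sigma <- sqrt(sigma2_0)
  lp <- log_post(mu, sigma)
  for (t in seq_len(cfg$draws_per_chain)) {
    mu_p <- mu + stats::rnorm(1, 0, step_mu)
    sigma_p <- sigma + stats::rnorm(1, 0, step_sigma)
    lp_p <- log_post(mu_p, sigma_p)
    if (log(stats::runif(1)) < lp_p - lp) {
      mu <- mu_p; sigma <- sigma_p; lp <- lp_p
    }
    if (t > cfg$burn_in) {
      mu_out[t - cfg$burn_in] <- mu
      sigma_out[t - cfg$burn_in] <- sigma
    }
  }
  list(mu = mu_out, sigma = sigma_out)
}

#' Sample the posterior of the normal location-scale model
#'
#' Fits `y_i ~ Normal(mu, sigma^2)` under a uniform prior on `(mu, sigma)`
#' over the configured box, by MCMC. The default sampler is a conjugate
#' Gibbs sampler whose full conditionals are exact, so chains mix in
#' essentially one step; a random-walk Metropolis sampler is available to
#' demonstrate sampler-independence of the results. Identical seed and
#' configuration give identical draws.
#'
#' @param y Numeric data vector (required volumes in mL/kg, or enhancement
#'   in HU), n >= 3, with positive spread; the sample mean must lie inside
#'   the prior bounds for the location.
#' @param config An [mcmc_config()].
#' @return An object of class `posterior_draws`: list with matrices `mu`
#'   and `sigma` of dimension (retained draws per chain) x (chains), `data`
#'   (n, sample mean, sample sd) and the `config`.
#' @seealso [analytic_posterior()] for the closed form this sampler targets,
#'   [exceedance_probability()], [coverage_dose()], [gelman_rubin()].
#' @export
sample_posterior <- function(y, config = mcmc_config()) {
  if (!inherits(config, "mcmc_config")) stop("config must be an mcmc_config", call. = FALSE)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(y))) stop("data must be finite", call. = FALSE)
  ybar <- mean(y)
  s <- stats::sd(y)
  if (s == 0) stop("zero-variance data: the scale is not identified", call. = FALSE)
  if (ybar < config$mu_bounds[1] || ybar > config$mu_bounds[2])
    stop(sprintf("sample mean %.4g lies outside the prior bounds [%g, %g] for mu",
                 ybar, config$mu_bounds[1], config$mu_bounds[2]), call. = FALSE)
  s2 <- s^2
  keep <- config$draws_per_chain - config$burn_in
  mu_mat <- matrix(NA_real_, keep, config$n_chains)
  sigma_mat <- matrix(NA_real_, keep, config$n_chains)
  runner <- if (config$sampler == "gibbs") run_gibbs_chain else run_metropolis_chain
  with_seed(config$seed, {
    for (c in seq_len(config$n_chains)) {
      # overdispersed initial values, clipped into the prior box
      mu0 <- ybar + stats::rnorm(1, 0, 2 * s / sqrt(n))
      mu0 <- min(max(mu0, config$mu_bounds[1]), config$mu_bounds[2])
      sigma2_0 <- s2 * exp(stats::runif(1, -1, 1))
      sigma2_0 <- min(max(sigma2_0, (1.001 * config$sigma_bounds[1])^2),
                      (0.999 * config$sigma_bounds[2])^2)
      ch <- runner(n, ybar, s2, config, mu0, sigma2_0)
      mu_mat[, c] <- ch$mu
      sigma_mat[, c] <- ch$sigma
    }
  })
  out <- list(mu = mu_mat, sigma = sigma_mat,
              data = list(n = n, mean = ybar, sd = s),
              config = config)
  class(out) <- "posterior_draws"
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chain(s) x %d retained (%s sampler)\n",
              ncol(x$mu), nrow(x$mu), x$config$sampler))
  cat(sprintf("  data: n = %d, mean = %.4g, sd = %.4g\n",
              x$data$n, x$data$mean, x$data$sd))
  cat(sprintf("  posterior mu: %.4g +/- %.4g | sigma: %.4g +/- %.4g\n",
              mean(x$mu), stats::sd(x$mu), mean(x$sigma), stats::sd(x$sigma)))
  invisible(x)
}

#' Closed-form flat-prior posterior for the normal model
#'
#' Under the improper uniform prior on `(mu, sigma)` the posterior for a
#' normal sample with size `n`, sample mean `m` and sample SD `s` has known
#' marginals:
#' \describe{
#'   \item{location}{`mu = m + s * sqrt((n-1)/(n(n-2))) * T`, `T ~ t(n-2)`;}
#'   \item{scale}{`sigma^2 = (n-1) s^2 / X`, `X ~ chisq(n-2)`.}
#' }
#' Posterior moments follow: `E[mu] = m`,
#' `SD(mu) = s * sqrt((n-1)/(n(n-4)))`, `E[sigma^2] = (n-1)s^2/(n-4)`, and
#' `E[sigma] = s * sqrt((n-1)/2) * Gamma((n-3)/2)/Gamma((n-2)/2)`
#' (approximately `s (1 + 3/(4(n-2)))`). This object is the independent
#' oracle used to validate [sample_posterior()]; it assumes prior bounds
#' wide enough that their truncation is negligible.
#'
#' @param n Sample size (>= 4; SDs are finite for n > 4).
#' @param sample_mean Sample mean of the data.
#' @param sample_sd Sample standard deviation (> 0), n-1 convention.
#' @return An object of class `analytic_posterior` with fields `mu_mean`,
#'   `mu_sd`, `sigma_mean`, `sigma_sd`, `sigma2_mean`, and quantile
#'   functions `mu_quantile(p)` and `sigma_quantile(p)`.
#' @examples
#' ap <- analytic_posterior(100, 1.681, 0.264)
#' ap$mu_mean   # 1.681
#' ap$mu_sd     # ~0.0268
#' @export
analytic_posterior <- function(n, sample_mean, sample_sd) {
  if (n < 4) stop("undefined moments: closed-form posterior requires n >= 4",
                  call. = FALSE)
  if (!is.finite(sample_sd) || sample_sd <= 0)
    stop("sample_sd must be positive", call. = FALSE)
  nu <- n - 2
  scale_mu <- sample_sd * sqrt((n - 1) / (n * nu))
  mu_sd <- if (n > 4) sample_sd * sqrt((n - 1) / (n * (n - 4))) else Inf
  # E[sigma^k] for sigma^2 = (n-1)s^2 / chisq_nu:
  #   ((n-1)s^2/2)^(k/2) * Gamma((nu-k)/2) / Gamma(nu/2)
  sigma_moment <- function(k) {
    if (nu <= k) return(Inf)
    ((n - 1) * sample_sd^2 / 2)^(k / 2) *
      exp(lgamma((nu - k) / 2) - lgamma(nu / 2))
  }
  sigma_mean <- sigma_moment(1)
  sigma2_mean <- sigma_moment(2)
  sigma_sd <- if (is.finite(sigma2_mean) && is.finite(sigma_mean))
    sqrt(max(sigma2_mean - sigma_mean^2, 0)) else Inf
  out <- list(
    n = n, sample_mean = sample_mean, sample_sd = sample_sd,
    mu_mean = sample_mean, mu_sd = mu_sd, mu_scale = scale_mu, mu_df = nu,
    sigma_mean = sigma_mean, sigma_sd = sigma_sd, sigma2_mean = sigma2_mean,
    mu_quantile = function(p) sample_mean + scale_mu * stats::qt(p, nu),
    sigma_quantile = function(p) sqrt((n - 1) * sample_sd^2 / stats::qchisq(1 - p, nu)),
    mu_density = function(x) stats::dt((x - sample_mean) / scale_mu, nu) / scale_mu,
    sigma_density = function(x) {
      A <- (n - 1) * sample_sd^2
      stats::dchisq(A / x^2, nu) * 2 * A / x^3
    }
  )
  class(out) <- "analytic_posterior"
  out
}

#' @export
print.analytic_posterior <- function(x, ...) {
  cat(sprintf("Flat-prior normal posterior (n = %d, mean = %.4g, sd = %.4g)\n",
              x$n, x$sample_mean, x$sample_sd))
  cat(sprintf("  mu: %.4g +/- %.4g (t, df = %d)\n", x$mu_mean, x$mu_sd, x$mu_df))
  cat(sprintf("  sigma: %.4g +/- %.4g\n", x$sigma_mean, x$sigma_sd))
  invisible(x)
}

# Summarize a per-draw derived quantity as mean +/- SD with a central 95%
# credible interval, keeping the draws for downstream use.
posterior_quantity <- function(draws_mat, name) {
  v <- as.vector(draws_mat)
  out <- list(name = name, mean = mean(v), sd = stats::sd(v),
              ci = unname(stats::quantile(v, c(0.025, 0.975))),
              draws = draws_mat)
  class(out) <- "posterior_quantity"
  out
}

#' @export
print.posterior_quantity <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (95%% CrI %.4g-%.4g)\n",
              x$name, x$mean, x$sd, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Posterior probability of attaining the diagnostic threshold
#'
#' For each posterior draw `(mu_k, sigma_k)` of the required-volume model,
#' computes `p_k = Phi((dose_limit - mu_k) / sigma_k)`: the modelled
#' fraction of patients whose required contrast volume does not exceed the
#' administered dose, i.e. the probability of optimal enhancement at that
#' dose. Summarised as posterior mean +/- SD over all retained draws.
#'
#' @param draws A `posterior_draws` object fitted to required volumes.
#' @param dose_limit Administered dose, mL/kg (> 0).
#' @return A `posterior_quantity` for the attainment probability (on the
#'   0-1 scale).
#' @examples
#' # plug-in value at the posterior point estimate:
#' plugin_exceedance(1.681, 0.264, 2.0)  # 0.887
#' @export
exceedance_probability <- function(draws, dose_limit) {
  if (!inherits(draws, "posterior_draws"))
    stop("draws must be a posterior_draws object", call. = FALSE)
  if (!is.finite(dose_limit) || dose_limit <= 0)
    stop("dose_limit must be positive", call. = FALSE)
  p <- stats::pnorm((dose_limit - draws$mu) / draws$sigma)
  posterior_quantity(p, sprintf("P(required volume <= %g mL/kg)", dose_limit))
}

#' Dose covering a target fraction of patients
#'
#' For each posterior draw computes `q_k = mu_k + z(coverage) * sigma_k`,
#' the dose at which the modelled fraction `coverage` of patients reach the
#' diagnostic threshold (`z` the standard-normal quantile; `z(0.95) =
#' 1.6449`). Summarised as posterior mean +/- SD.
#'
#' @param draws A `posterior_draws` object fitted to required volumes.
#' @param coverage Target fraction in (0, 1); default 0.95.
#' @return A `posterior_quantity` for the coverage dose (mL/kg).
#' @export
coverage_dose <- function(draws, coverage = 0.95) {
  if (!inherits(draws, "posterior_draws"))
    stop("draws must be a posterior_draws object", call. = FALSE)
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must lie strictly between 0 and 1", call. = FALSE)
  q <- draws$mu + stats::qnorm(coverage) * draws$sigma
  posterior_quantity(q, sprintf("dose covering %g%% of patients (mL/kg)",
                                100 * coverage))
}

#' Plug-in attainment probability and coverage dose
#'
#' Point-estimate versions of [exceedance_probability()] and
#' [coverage_dose()]: evaluate the normal model at a single `(mean, sd)`
#' pair instead of averaging over posterior draws. Useful for tying out
#' published posterior summaries.
#'
#' @param mean,sd Normal model location and scale (sd > 0).
#' @param dose_limit Administered dose, mL/kg.
#' @param coverage Target fraction in (0, 1).
#' @return A single number: probability in (0, 1), or dose in mL/kg.
#' @export
plugin_exceedance <- function(mean, sd, dose_limit) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, dose_limit > 0)
  stats::pnorm((dose_limit - mean) / sd)
}

#' @rdname plugin_exceedance
#' @export
plugin_coverage_dose <- function(mean, sd, coverage = 0.95) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, coverage > 0, coverage < 1)
  mean + stats::qnorm(coverage) * sd
}

#' Delta-method posterior SD of the attainment probability
#'
#' First-order analytic approximation to the posterior standard deviation
#' of `p = Phi((dose_limit - mu)/sigma)` at sample size `n`: with
#' `z = (dose_limit - mean)/sd`,
#' `SD(p) ~ phi(z) * sqrt((1 + z^2/2)/n)`
#' (the `z^2/2` term carries the scale uncertainty, `Var(sigma) ~
#' sigma^2/(2n)`). Used to cross-check the MCMC "+/-" values analytically.
#'
#' @param n Sample size (>= 4).
#' @param mean,sd Normal model location and scale.
#' @param dose_limit Administered dose, mL/kg.
#' @return Approximate posterior SD of the attainment probability (0-1 scale).
#' @export
delta_method_sd <- function(n, mean, sd, dose_limit) {
  stopifnot(n >= 4, is.finite(sd), sd > 0)
  z <- (dose_limit - mean) / sd
  stats::dnorm(z) * sqrt((1 + z^2 / 2) / n)
}

#' Full posterior summary table
#'
#' Summarises location, scale, attainment probability and coverage dose in
#' one table with convergence diagnostics.
#'
#' @param draws A `posterior_draws` object.
#' @param dose_limit Administered dose, mL/kg.
#' @param coverage Target coverage fraction.
#' @return A `data.frame` with one row per quantity (`mu`, `sigma`,
#'   `attainment_prob`, `coverage_dose`) and columns `mean`, `sd`, `q2.5`,
#'   `q50`, `q97.5`, `rhat`, `ess`.
#' @export
posterior_summary <- function(draws, dose_limit = 2.0, coverage = 0.95) {
  if (!inherits(draws, "posterior_draws"))
    stop("draws must be a posterior_draws object", call. = FALSE)
  p <- stats::pnorm((dose_limit - draws$mu) / draws$sigma)
  q <- draws$mu + stats::qnorm(coverage) * draws$sigma
  mats <- list(mu = draws$mu, sigma = draws$sigma, attainment_prob = p,
               coverage_dose = q)
  multi <- ncol(draws$mu) >= 2
  rows <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    v <- as.vector(m)
    qs <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(quantity = nm, mean = mean(v), sd = stats::sd(v),
               q2.5 = qs[1], q50 = qs[2], q97.5 = qs[3],
               rhat = if (multi) split_rhat(m) else NA_real_,
               ess = effective_size(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export posterior draws as CSV
#'
#' Writes `chain,iteration,mu,sigma` (plus per-draw attainment probability
#' `p` and coverage dose `q` when `dose_limit`/`coverage` are given), one
#' row per retained draw.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output file.
#' @param dose_limit Optional administered dose for the `p` column.
#' @param coverage Optional coverage fraction for the `q` column.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path, dose_limit = NULL, coverage = NULL) {
  if (!inherits(draws, "posterior_draws"))
    stop("draws must be a posterior_draws object", call. = FALSE)
  keep <- nrow(draws$mu)
  out <- data.frame(
    chain = rep(seq_len(ncol(draws$mu)), each = keep),
    iteration = rep(seq_len(keep), ncol(draws$mu)),
    mu = as.vector(draws$mu),
    sigma = as.vector(draws$sigma)
  )
  if (!is.null(dose_limit))
    out$p <- stats::pnorm((dose_limit - out$mu) / out$sigma)
  if (!is.null(coverage))
    out$q <- out$mu + stats::qnorm(coverage) * out$sigma
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
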