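# Independent oracles and small fixtures shared across tests.

# Brute-force posterior moments for the flat-prior normal model by 2-D grid
# integration of sigma^-n * exp(-S(mu)/(2 sigma^2)). Independent of both the
# sampler and the closed-form formulas it validates.
grid_posterior_moments <- function(y, grid_n = 800) {
  n <- length(y)
  m <- mean(y)
  s <- sd(y)
  mu_g <- seq(m - 10 * s, m + 10 * s, length.out = grid_n)
  sg <- seq(s / 8, s * 8, length.out = grid_n)
  lg <- outer(mu_g, sg, function(mu, sig)
    -n * log(sig) - ((n - 1) * s^2 + n * (mu - m)^2) / (2 * sig^2))
  w <- exp(lg - max(lg))
  w <- w / sum(w)
  mu_w <- rowSums(w)
  sig_w <- colSums(w)
  mu_mean <- sum(mu_w * mu_g)
  sig_mean <- sum(sig_w * sg)
  list(
    mu_mean = mu_mean,
    mu_sd = sqrt(sum(mu_w * mu_g^2) - mu_mean^2),
    sigma_mean = sig_mean,
    sigma_sd = sqrt(sum(sig_w * sg^2) - sig_mean^2)
  )
}

# Small, fast MCMC configuration for tests that only need a correct sampler,
# not the full production chain length.
small_mcmc <- function(seed, n_chains = 2, draws_per_chain = 2500,
                       burn_in = 250, ...) {
  mcmc_config(n_chains = n_chains, draws_per_chain = draws_per_chain,
              burn_in = burn_in, seed = seed, ...)
}

# A tiny two-patient cohort with hand-picked CT numbers.
toy_cohort <- function() {
  data.frame(
    patient_id = c("p1", "p2"),
    protocol_kvp = c(120L, 120L),
    sex = c("M", "F"), age = c(70, 65),
    height_cm = c(160, 155), weight_kg = c(55, 50),
    administered_ml_per_kg = c(2, 2),
    aorta_unenh_hu = c(40, 45),
    aorta_hap_hu = c(380, 350),
    liver_r_unenh_hu = c(55, 58),
    liver_l_unenh_hu = c(57, 60),
    liver_r_pvp_hu = c(110, 115),
    liver_l_pvp_hu = c(116, 119),
    stringsAsFactors = FALSE
  )
}
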