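# Convergence diagnostics for multi-chain MCMC output.
# Matrices are (iterations x chains) throughout.

# Split-chain potential scale reduction factor (each chain halved, so m
# chains contribute 2m sequences; detects both between-chain disagreement
# and within-chain trends).
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  splits <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  nn <- nrow(splits)
  chain_means <- colMeans(splits)
  chain_vars <- apply(splits, 2, stats::var)
  W <- mean(chain_vars)
  B <- nn * stats::var(chain_means)
  if (W == 0) return(1)
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

#' Gelman-Rubin R-hat convergence diagnostic
#'
#' Split-chain potential scale reduction factor for the location and scale
#' draws: each chain is split in half and the between-/within-sequence
#' variance ratio is formed over the resulting sequences. Values near 1
#' indicate that the chains have mixed; values above ~1.01 warrant a longer
#' run.
#'
#' @param draws A `posterior_draws` object with at least 2 chains and 10
#'   retained draws per chain.
#' @return Named numeric vector with elements `mu` and `sigma`.
#' @export
gelman_rubin <- function(draws) {
  if (!inherits(draws, "posterior_draws"))
    stop("draws must be a posterior_draws object", call. = FALSE)
  if (ncol(draws$mu) < 2)
    stop("R-hat requires at least 2 chains", call. = FALSE)
  if (nrow(draws$mu) < 10)
    stop("R-hat requires at least 10 retained draws per chain", call. = FALSE)
  c(mu = split_rhat(draws$mu), sigma = split_rhat(draws$sigma))
}

# Effective sample size, summed over chains. Per chain: n / (1 + 2 sum rho_t)
# with the autocorrelation sum truncated by Geyer's initial positive
# sequence rule on successive pairs.
effective_size <- function(mat) {
  mat <- as.matrix(mat)
  ess_one <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    lag_max <- min(500, n - 2)
    rho <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
    tau <- 1
    t <- 1
    while (t + 1 <= length(rho)) {
      pair <- rho[t] + rho[t + 1]
      if (pair <= 0) break
      tau <- tau + 2 * pair
      t <- t + 2
    }
    min(n, n / tau)
  }
  sum(apply(mat, 2, ess_one))
}
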