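# short MCMC runs for tests: the Gibbs conditionals are exact, so modest
# chains already give small Monte-Carlo error
test_settings <- function(iterations = 4000, burn_in = 500, seed = 1,
                          thin = 1, n_chains = 2) {
  mcmc_settings(n_chains = n_chains, iterations = iterations,
                burn_in = burn_in, thin = thin, seed = seed)
}

# brute-force posterior moments by 2-D grid integration over (mu_C, delta);
# independent of both the conjugate algebra and the sampler
grid_posterior_moments <- function(data, prior, half_width = 6, n = 301) {
  stopifnot(prior$parameterization == "muC_delta")
  centre_C <- data$mu_hat_C
  centre_D <- data$mu_hat_B - data$mu_hat_C
  wC <- half_width * max(sqrt(data$var_C), prior$muC$sd / 3)
  wD <- half_width * max(sqrt(data$var_B + data$var_C),
                         prior$delta$sd / 3)
  muC <- seq(centre_C - wC, centre_C + wC, length.out = n)
  del <- seq(centre_D - wD, centre_D + wD, length.out = n)
  gg <- expand.grid(mu_C = muC, delta = del)
  lp <- prior_density(prior, gg$mu_C + gg$delta, gg$mu_C, log = TRUE) +
    loglik_subgroups(data, gg$mu_C + gg$delta, gg$mu_C)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mC <- sum(w * gg$mu_C)
  mD <- sum(w * gg$delta)
  c(mu_B = mC + mD, mu_C = mC, delta = mD,
    sd_mu_C = sqrt(sum(w * (gg$mu_C - mC)^2)),
    sd_delta = sqrt(sum(w * (gg$delta - mD)^2)))
}

# random untruncated normal-prior configuration and simulated data,
# reproducible given a seed
random_normal_config <- function(seed) {
  set.seed(seed)
  data <- subgroup_estimates(
    mu_hat_B = stats::rnorm(1, 0, 0.5),
    mu_hat_C = stats::rnorm(1, 0, 0.5),
    var_B = stats::runif(1, 0.01, 0.2),
    var_C = stats::runif(1, 0.01, 0.2),
    cov_BC = 0)
  prior <- joint_prior(
    muC = normal_prior(stats::rnorm(1, 0, 0.3), stats::runif(1, 0.2, 5)),
    delta = normal_prior(stats::rnorm(1, 0, 0.3), stats::runif(1, 0.2, 5)))
  list(data = data, prior = prior)
}

meteor_design_rates <- function() {
  list(B = c(active = 0.6, control = 0.8),
       C = c(active = 0.5, control = 0.7))
}
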