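#' MCMC settings
#'
#' Defaults mirror a conventional two-chain run of 50,000 iterations per
#' chain with 20,000 burn-in and thinning of 2. Tests and examples use
#' smaller runs; the Gibbs conditionals here are exact, so chains mix
#' quickly.
#'
#' @param n_chains Number of chains.
#' @param iterations Iterations per chain (including burn-in).
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Optional integer seed; chain `c` uses `seed + c - 1`.
#' @return An object of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_chains = 2, iterations = 50000,
                          burn_in = 20000, thin = 2, seed = NULL) {
  stopifnot(n_chains >= 1, iterations >= 1, burn_in >= 0, thin >= 1,
            burn_in < iterations)
  structure(list(n_chains = as.integer(n_chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_settings")
}

#' Fit the Bayesian subgroup model
#'
#' The main fitting function: updates a [joint_prior()] with the observed
#' subgroup estimates through the bivariate normal likelihood and returns
#' posterior draws of `(mu_B, mu_C, delta)` plus any latent variables of
#' the prior (category index `M`, slab indicator `R`, inclusion
#' probability `P`).
#'
#' Sampling is by Gibbs with exact conditional (truncated) normals for
#' all normal-component priors, a closed-form categorical update for the
#' discrete prior, a collapsed marginal-likelihood update for the
#' spike-and-slab indicator (the interaction is integrated out
#' analytically when updating `R`, which keeps mixing healthy even when
#' the slab is very diffuse), and Metropolis-within-Gibbs on the latent
#' unrectified variables for the rectified joint prior (with proposal
#' scales adapted during burn-in). With `method = "conjugate"` the exact
#' closed-form posterior is computed instead and independent draws are
#' taken from it, so all draw-based methods work identically.
#'
#' @param data A [subgroup_estimates()] object.
#' @param prior A [joint_prior()] object.
#' @param settings An [mcmc_settings()] object.
#' @param method `"mcmc"` (default) or `"conjugate"` (normal priors only).
#' @return An object of class `"bsgfit"`: a list with `draws` (data frame
#'   with columns `chain`, `mu_B`, `mu_C`, `delta` and any auxiliaries,
#'   where `delta = mu_B - mu_C` holds exactly row by row),
#'   `diagnostics` (split-Rhat and effective sample size per parameter),
#'   and the inputs. A warning is raised if any split-Rhat exceeds 1.01.
#' @examples
#' fit <- fit_subgroups(stampede_estimates(), vague_prior(),
#'                      mcmc_settings(iterations = 2000, burn_in = 500,
#'                                    thin = 1, seed = 1))
#' summary(fit)
#' @export
fit_subgroups <- function(data, prior, settings = mcmc_settings(),
                          method = c("mcmc", "conjugate")) {
  stopifnot(inherits(data, "subgroup_estimates"),
            inherits(prior, "bsg_prior"),
            inherits(settings, "mcmc_settings"))
  method <- match.arg(method)
  n_keep <- (settings$iterations - settings$burn_in) %/% settings$thin

  if (method == "conjugate") {
    post <- conjugate_posterior(data, prior)
    if (!is.null(settings$seed)) set.seed(settings$seed)
    draws <- .sample_conjugate(post, n_keep * settings$n_chains)
    draws <- cbind(chain = rep(seq_len(settings$n_chains), each = n_keep),
                   draws)
    diag_tab <- data.frame(parameter = c("mu_B", "mu_C", "delta"),
                           rhat = NA_real_,
                           ess = as.numeric(nrow(draws)))
    out <- list(draws = draws, diagnostics = diag_tab, exact = post,
                data = data, prior = prior, settings = settings,
                method = method)
    class(out) <- "bsgfit"
    return(out)
  }

  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    if (!is.null(settings$seed)) set.seed(settings$seed + ch - 1L)
    raw <- .run_chain(data, prior, settings$iterations, ch)
    keep <- seq(settings$burn_in + 1L, settings$iterations, by = settings$thin)
    chains[[ch]] <- raw[keep, , drop = FALSE]
  }

  diag_tab <- .mcmc_diagnostics(chains)
  draws <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    cbind(chain = ch, as.data.frame(chains[[ch]]))
  }))
  # enforce the identity delta = mu_B - mu_C at machine precision
  draws$delta <- draws$mu_B - draws$mu_C

  if (any(diag_tab$rhat > 1.01, na.rm = TRUE)) {
    warning("split-Rhat above 1.01 for: ",
            paste(diag_tab$parameter[which(diag_tab$rhat > 1.01)],
                  collapse = ", "),
            "; consider longer chains", call. = FALSE)
  }
  out <- list(draws = draws, diagnostics = diag_tab, exact = NULL,
              data = data, prior = prior, settings = settings,
              method = method)
  class(out) <- "bsgfit"
  out
}

# run one chain; returns a matrix with columns mu_B, mu_C, delta (+ aux)
.run_chain <- function(data, prior, iterations, chain_id) {
  Sigma <- matrix(c(data$var_B, data$cov_BC, data$cov_BC, data$var_C), 2, 2)
  Omega <- solve(Sigma)
  x <- c(data$mu_hat_B, data$mu_hat_C)
  jitter <- 0.5 * (chain_id - 1)  # overdispersed starts across chains

  if (prior$parameterization == "muC_delta") {
    dp <- prior$delta
    if (inherits(dp, "normal_prior")) {
      .chain_normal(data, prior, Omega, x, iterations, jitter)
    } else if (inherits(dp, "discrete_prior")) {
      .chain_discrete(data, prior, Omega, x, iterations, jitter)
    } else {
      .chain_spike_slab(data, prior, Omega, x, iterations, jitter)
    }
  } else if (inherits(prior$joint, "bivariate_normal_prior")) {
    .chain_bivariate(data, prior, Omega, x, iterations, jitter)
  } else {
    .chain_rectified(data, prior, iterations, jitter)
  }
}

# conditional draw of a parameter with normal likelihood contribution
# (precision 'prec_lik', linear 'lin_lik') and normal_prior 'pr'
.draw_conditional <- function(prec_lik, lin_lik, pr) {
  if (pr$sd == 0) return(pr$mean)
  prec <- prec_lik + 1 / pr$sd^2
  mean <- (lin_lik + pr$mean / pr$sd^2) / prec
  .rnorm_trunc(1L, mean, sqrt(1 / prec), pr$upper)
}

.chain_normal <- function(data, prior, Omega, x, iterations, jitter) {
  A <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  M <- t(A) %*% Omega %*% A
  h <- drop(t(A) %*% Omega %*% x)
  pc <- prior$muC; pd <- prior$delta
  muC <- data$mu_hat_C + jitter
  if (!is.null(pc$upper)) muC <- min(muC, pc$upper - 0.1)
  if (pc$sd == 0) muC <- pc$mean
  delta <- data$mu_hat_B - data$mu_hat_C - jitter
  if (!is.null(pd$upper)) delta <- min(delta, pd$upper - 0.1)
  if (pd$sd == 0) delta <- pd$mean
  out <- matrix(NA_real_, iterations, 3,
                dimnames = list(NULL, c("mu_B", "mu_C", "delta")))
  for (i in seq_len(iterations)) {
    muC <- .draw_conditional(M[1, 1], h[1] - M[1, 2] * delta, pc)
    delta <- .draw_conditional(M[2, 2], h[2] - M[1, 2] * muC, pd)
    out[i, ] <- c(muC + delta, muC, delta)
  }
  out
}

.chain_discrete <- function(data, prior, Omega, x, iterations, jitter) {
  A <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  M <- t(A) %*% Omega %*% A
  h <- drop(t(A) %*% Omega %*% x)
  pc <- prior$muC; dp <- prior$delta
  J <- length(dp$values)
  lp0 <- log(dp$probs)
  muC <- data$mu_hat_C + jitter
  Mi <- which.min(abs(dp$values - (data$mu_hat_B - data$mu_hat_C)))
  out <- matrix(NA_real_, iterations, 4,
                dimnames = list(NULL, c("mu_B", "mu_C", "delta", "M")))
  for (i in seq_len(iterations)) {
    delta <- dp$values[Mi]
    muC <- .draw_conditional(M[1, 1], h[1] - M[1, 2] * delta, pc)
    lw <- lp0 + .dbvnorm_log(x[1], x[2], muC + dp$values, muC,
                             data$var_B, data$var_C, data$cov_BC)
    lw <- lw - max(lw)
    Mi <- sample.int(J, 1L, prob = exp(lw))
    delta <- dp$values[Mi]
    out[i, ] <- c(muC + delta, muC, delta, Mi)
  }
  out
}

.chain_spike_slab <- function(data, prior, Omega, x, iterations, jitter) {
  A <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  M <- t(A) %*% Omega %*% A
  h <- drop(t(A) %*% Omega %*% x)
  pc <- prior$muC; dp <- prior$delta
  s2 <- c(dp$spike_sd^2, dp$slab_sd^2)  # indexed by R + 1
  muC <- data$mu_hat_C + jitter
  R <- 1L; P <- 0.5
  delta <- data$mu_hat_B - data$mu_hat_C
  out <- matrix(NA_real_, iterations, 5,
                dimnames = list(NULL, c("mu_B", "mu_C", "delta", "R", "P")))
  for (i in seq_len(iterations)) {
    muC <- .draw_conditional(M[1, 1], h[1] - M[1, 2] * delta, pc)
    # collapsed update of R: delta integrated out of the likelihood, so
    # the data covariance gains s_R^2 in the mu_hat_B entry
    lm0 <- .dbvnorm_log(x[1], x[2], muC, muC,
                        data$var_B + s2[1], data$var_C, data$cov_BC)
    lm1 <- .dbvnorm_log(x[1], x[2], muC, muC,
                        data$var_B + s2[2], data$var_C, data$cov_BC)
    p1 <- 1 / (1 + exp(log1p(-P) - log(P) + lm0 - lm1))
    R <- as.integer(stats::runif(1) < p1)
    delta <- .draw_conditional(M[2, 2], h[2] - M[1, 2] * muC,
                               normal_prior(0, sqrt(s2[R + 1L])))
    P <- stats::rbeta(1, 1 + R, 2 - R)
    out[i, ] <- c(muC + delta, muC, delta, R, P)
  }
  out
}

.chain_bivariate <- function(data, prior, Omega, x, iterations, jitter) {
  j <- prior$joint
  K <- solve(j$cov)
  kl <- drop(K %*% j$mean)
  h <- drop(Omega %*% x)
  muB <- data$mu_hat_B + jitter
  muC <- data$mu_hat_C - jitter
  out <- matrix(NA_real_, iterations, 3,
                dimnames = list(NULL, c("mu_B", "mu_C", "delta")))
  for (i in seq_len(iterations)) {
    precB <- Omega[1, 1] + K[1, 1]
    muB <- stats::rnorm(1, (h[1] - Omega[1, 2] * muC + kl[1] - K[1, 2] * muC) / precB,
                        sqrt(1 / precB))
    precC <- Omega[2, 2] + K[2, 2]
    muC <- stats::rnorm(1, (h[2] - Omega[1, 2] * muB + kl[2] - K[1, 2] * muB) / precC,
                        sqrt(1 / precC))
    out[i, ] <- c(muB, muC, muB - muC)
  }
  out
}

.chain_rectified <- function(data, prior, iterations, jitter) {
  j <- prior$joint
  logpost <- function(YB, YC) {
    muC <- min(0, YC); muB <- min(0, YB)
    v <- max(j$d^2 + j$e * muC, 1e-12)
    stats::dnorm(YC, j$a, j$b, log = TRUE) +
      stats::dnorm(YB, j$c * muC, sqrt(v), log = TRUE) +
      loglik_subgroups(data, muB, muC)
  }
  YC <- min(-0.05, data$mu_hat_C) - jitter
  YB <- min(-0.05, data$mu_hat_B) + jitter
  # proposal scales: roughly the smaller of prior and likelihood sds,
  # then adapted toward 44% acceptance during burn-in
  lsC <- log(min(j$b, sqrt(data$var_C)))
  lsB <- log(min(j$d + abs(j$c) * j$b, sqrt(data$var_B)))
  lp <- logpost(YB, YC)
  out <- matrix(NA_real_, iterations, 3,
                dimnames = list(NULL, c("mu_B", "mu_C", "delta")))
  adapt_until <- floor(iterations / 3)
  for (i in seq_len(iterations)) {
    prop <- YC + exp(lsC) * stats::rnorm(1)
    lpp <- logpost(YB, prop)
    accC <- log(stats::runif(1)) < lpp - lp
    if (accC) { YC <- prop; lp <- lpp }
    prop <- YB + exp(lsB) * stats::rnorm(1)
    lpp <- logpost(prop, YC)
    accB <- log(stats::runif(1)) < lpp - lp
    if (accB) { YB <- prop; lp <- lpp }
    if (i <= adapt_until) {
      gamma <- 1 / sqrt(i + 10)
      lsC <- lsC + gamma * ((accC) - 0.44)
      lsB <- lsB + gamma * ((accB) - 0.44)
    }
    muB <- min(0, YB); muC <- min(0, YC)
    out[i, ] <- c(muB, muC, muB - muC)
  }
  out
}

# --- diagnostics -----------------------------------------------------------

# split-Rhat (Gelman-Rubin on half-chains)
.split_rhat <- function(chains_par) {
  halves <- unlist(lapply(chains_par, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial positive sequence, per chain
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 250L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0; k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

.mcmc_diagnostics <- function(chains) {
  pars <- intersect(colnames(chains[[1L]]), c("mu_B", "mu_C", "delta"))
  data.frame(
    parameter = pars,
    rhat = vapply(pars, function(p) {
      .split_rhat(lapply(chains, function(m) m[, p]))
    }, numeric(1)),
    ess = vapply(pars, function(p) {
      sum(vapply(chains, function(m) .ess(m[, p]), numeric(1)))
    }, numeric(1)),
    row.names = NULL)
}
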