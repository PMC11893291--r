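#' Normal prior, optionally truncated above
#'
#' Conjugate prior component for either the control-subgroup effect
#' `mu_C` or the interaction `delta = mu_B - mu_C`. An upper truncation
#' bound restricts support to `(-Inf, upper]` with the density
#' renormalized; a typical use case is restricting `mu_C` to
#' clinically plausible hazard ratios (e.g. below log 0.8 = -0.223).
#' A zero standard deviation is allowed and denotes a point mass at
#' `mean` (the "no interaction" prior when used for `delta` with mean 0).
#'
#' @param mean Prior mean.
#' @param sd Prior standard deviation (non-negative; 0 = point mass).
#' @param upper Optional upper truncation bound.
#' @return An object of class `"normal_prior"`.
#' @export
normal_prior <- function(mean = 0, sd = 10, upper = NULL) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L,
            length(sd) == 1L, sd >= 0)
  if (!is.null(upper)) {
    stopifnot(is.numeric(upper), length(upper) == 1L)
    if (sd == 0 && mean > upper) stop("point mass lies above the truncation bound")
  }
  structure(list(mean = mean, sd = sd, upper = upper),
            class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  cat(sprintf("Normal prior N(%.4g, %.4g^2)", x$mean, x$sd))
  if (!is.null(x$upper)) cat(sprintf(", truncated to (-Inf, %.4g]", x$upper))
  cat("\n")
  invisible(x)
}

#' Discount a normal prior with a power prior
#'
#' Raises the historical likelihood behind a normal prior to the power
#' `k`, which for a normal kernel simply inflates the variance by `1/k`:
#' the prior mean is unchanged and the sd becomes `sd / sqrt(k)`. `k = 1`
#' keeps the historical information at face value; smaller `k` moves
#' toward a vague prior. Discounting is multiplicative: applying `k1`
#' then `k2` equals applying `k1 * k2`.
#'
#' @param base A [normal_prior()].
#' @param k Discount factor in `(0, 1]`.
#' @return A [normal_prior()] with inflated variance.
#' @examples
#' power_prior(normal_prior(-0.288, 0.108), k = 0.25)  # sd 0.216
#' @export
power_prior <- function(base, k) {
  stopifnot(inherits(base, "normal_prior"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 1) {
    stop("'k' must lie in (0, 1]")
  }
  normal_prior(base$mean, base$sd / sqrt(k), upper = base$upper)
}

#' Discrete prior on the interaction
#'
#' Prior placing probability `probs[j]` on `delta = values[j]`. Internally
#' the sampler carries a categorical indicator `M` whose posterior gives
#' the updated plausibility of each candidate interaction value; this is
#' the natural representation of a "chips and bins" elicitation.
#'
#' @param values Candidate interaction values (distinct reals).
#' @param probs Prior probabilities (non-negative, summing to 1).
#' @return An object of class `"discrete_prior"`.
#' @export
discrete_prior <- function(values, probs = rep(1 / length(values), length(values))) {
  stopifnot(is.numeric(values), is.numeric(probs),
            length(values) == length(probs), length(values) >= 1L)
  if (any(probs < 0)) stop("'probs' must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("'probs' must sum to 1")
  if (anyDuplicated(values)) stop("'values' must be distinct")
  structure(list(values = values, probs = probs), class = "discrete_prior")
}

#' Spike-and-slab prior on the interaction
#'
#' Two-component mixture prior for `delta`: a near-point-mass spike
#' `N(0, spike_sd^2)` expressing "no subgroup difference" and a diffuse
#' slab `N(0, slab_sd^2)`. A latent Bernoulli indicator `R` selects the
#' component and its success probability `P` carries a uniform hyper-prior
#' on `[0, 1]`, so the marginal prior inclusion probability of the slab
#' is 1/2.
#'
#' @param slab_sd Slab standard deviation (the scale of interactions
#'   considered plausible a priori).
#' @param spike_sd Spike standard deviation; default 0.01 (variance 1e-4).
#' @return An object of class `"spike_slab_prior"`.
#' @export
spike_slab_prior <- function(slab_sd, spike_sd = 0.01) {
  stopifnot(is.numeric(slab_sd), is.numeric(spike_sd),
            slab_sd > 0, spike_sd > 0)
  if (slab_sd <= 10 * spike_sd) {
    warning("slab_sd is not much larger than spike_sd; ",
            "the two components are poorly separated")
  }
  structure(list(slab_sd = slab_sd, spike_sd = spike_sd),
            class = "spike_slab_prior")
}

#' Bivariate normal prior on the two subgroup effects
#'
#' Joint prior directly on `(mu_B, mu_C)`. The vague default uses
#' marginal variances of 100 and correlation 0.5 so that all three of
#' `mu_B`, `mu_C` and `delta` receive the same marginal variance.
#'
#' @param mean Length-2 mean vector `(mu_B, mu_C)`.
#' @param cov 2x2 symmetric positive-definite covariance matrix.
#' @return An object of class `"bivariate_normal_prior"`.
#' @export
bivariate_normal_prior <- function(mean = c(0, 0),
                                   cov = matrix(c(100, 50, 50, 100), 2, 2)) {
  stopifnot(is.numeric(mean), length(mean) == 2L,
            is.matrix(cov), all(dim(cov) == 2L))
  if (abs(cov[1, 2] - cov[2, 1]) > 1e-12) stop("'cov' must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("'cov' must be positive definite")
  structure(list(mean = as.numeric(mean), cov = cov),
            class = "bivariate_normal_prior")
}

#' Right-rectified-normal joint prior on the two subgroup effects
#'
#' The marginal prior for `mu_C` is a right-rectified normal
#' `RN(a, b^2)` (a normal with positive values reset to 0, giving an atom
#' of size `1 - pnorm(-a/b)` at "no effect"), and the conditional prior
#' for `mu_B` given `mu_C` is `RN(c * mu_C, max(d^2 + e * mu_C, 0))`.
#' This encodes three clinical judgements: harm is implausible (no support
#' above 0), "no effect in either subgroup" has positive probability, and
#' the location and spread of beliefs about `mu_B` may depend on `mu_C`.
#'
#' @param a,b Marginal location and scale for `mu_C` (`b > 0`).
#' @param c,d,e Conditional constants for `mu_B` given `mu_C`
#'   (`d > 0`); the conditional variance `d^2 + e * mu_C` is floored at 0,
#'   in which case the conditional collapses to a point mass at
#'   `min(0, c * mu_C)`.
#' @return An object of class `"rectified_joint_prior"`.
#' @seealso [fit_rectified_prior()] to obtain the constants from an
#'   elicited probability grid.
#' @export
rectified_joint_prior <- function(a, b, c, d, e) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(d), is.numeric(e))
  if (b <= 0 || d <= 0) stop("'b' and 'd' must be positive")
  structure(list(a = a, b = b, c = c, d = d, e = e),
            class = "rectified_joint_prior")
}

#' @export
print.rectified_joint_prior <- function(x, digits = 4, ...) {
  cat("Right-rectified-normal joint prior\n")
  cat(sprintf("  mu_C ~ RN(a = %.*g, b^2 = %.*g^2); atom at 0: %.3f\n",
              digits, x$a, digits, x$b, 1 - stats::pnorm(-x$a / x$b)))
  cat(sprintf("  mu_B | mu_C ~ RN(%.*g * mu_C, max(%.*g^2 %+.*g * mu_C, 0))\n",
              digits, x$c, digits, x$d, digits, x$e))
  invisible(x)
}

#' Joint prior specification for the subgroup model
#'
#' A joint prior over two of the three linearly dependent parameters
#' `(mu_B, mu_C, delta)`; the third is always defined through
#' `delta = mu_B - mu_C`. Supply either independent component priors for
#' `mu_C` and `delta` (normal, discrete or spike-and-slab for `delta`),
#' or a joint prior on `(mu_B, mu_C)` (bivariate normal or rectified).
#'
#' @param muC A [normal_prior()] for `mu_C` (ignored when `joint` given).
#' @param delta A [normal_prior()], [discrete_prior()] or
#'   [spike_slab_prior()] for `delta` (ignored when `joint` given).
#' @param joint A [bivariate_normal_prior()] or [rectified_joint_prior()]
#'   on `(mu_B, mu_C)`.
#' @return An object of class `"bsg_prior"` with a `parameterization`
#'   field of `"muC_delta"` or `"muB_muC"`.
#' @examples
#' vague_prior()
#' joint_prior(muC = normal_prior(-0.288, 0.108), delta = normal_prior(0, 10))
#' joint_prior(joint = bivariate_normal_prior())
#' @export
joint_prior <- function(muC = normal_prior(0, 10),
                        delta = normal_prior(0, 10),
                        joint = NULL) {
  if (!is.null(joint)) {
    if (!inherits(joint, c("bivariate_normal_prior", "rectified_joint_prior"))) {
      stop("'joint' must be a bivariate_normal_prior or rectified_joint_prior")
    }
    out <- list(parameterization = "muB_muC", joint = joint)
  } else {
    if (!inherits(muC, "normal_prior")) {
      stop("'muC' must be a normal_prior")
    }
    if (!inherits(delta, c("normal_prior", "discrete_prior", "spike_slab_prior"))) {
      stop("'delta' must be a normal_prior, discrete_prior or spike_slab_prior")
    }
    out <- list(parameterization = "muC_delta", muC = muC, delta = delta)
  }
  structure(out, class = "bsg_prior")
}

#' Vague prior on `mu_C` and `delta`
#'
#' Independent `N(0, sd^2)` priors for both parameters (default variance
#' 100). Note the implied prior variance of `mu_B` is then `2 * sd^2`.
#'
#' @param sd Common prior standard deviation.
#' @return A [joint_prior()] object.
#' @export
vague_prior <- function(sd = 10) {
  joint_prior(muC = normal_prior(0, sd), delta = normal_prior(0, sd))
}

#' @export
print.bsg_prior <- function(x, ...) {
  cat("Joint prior (", x$parameterization, " parameterization)\n", sep = "")
  if (x$parameterization == "muC_delta") {
    cat("mu_C:  "); print(x$muC)
    cat("delta: ")
    if (inherits(x$delta, "normal_prior")) {
      print(x$delta)
    } else if (inherits(x$delta, "discrete_prior")) {
      cat(sprintf("discrete on %d values in [%.3g, %.3g]\n",
                  length(x$delta$values), min(x$delta$values),
                  max(x$delta$values)))
    } else {
      cat(sprintf("spike-and-slab, spike sd %.3g, slab sd %.3g\n",
                  x$delta$spike_sd, x$delta$slab_sd))
    }
  } else {
    if (inherits(x$joint, "rectified_joint_prior")) {
      print(x$joint)
    } else {
      cat(sprintf("(mu_B, mu_C) ~ N(c(%.3g, %.3g), cov), correlation %.3f\n",
                  x$joint$mean[1], x$joint$mean[2],
                  stats::cov2cor(x$joint$cov)[1, 2]))
    }
  }
  invisible(x)
}

#' Informative interaction prior from two historical subgroup results
#'
#' Builds a normal prior for `delta = mu_B - mu_C` as the difference of
#' two independent historical log hazard ratios: mean `log(hr1) -
#' log(hr2)` and variance the sum of the two squared standard errors
#' obtained from the confidence intervals.
#'
#' @param hr1,ci1 Historical result for subgroup B (hazard ratio and
#'   length-2 confidence interval).
#' @param hr2,ci2 Historical result for subgroup C.
#' @inheritParams log_hr_from_ci
#' @return A [normal_prior()].
#' @examples
#' difference_prior(0.54, c(0.32, 0.92), 0.61, c(0.41, 0.89))
#' # N(-0.122, 0.334^2)
#' @export
difference_prior <- function(hr1, ci1, hr2, ci2, level = 0.95) {
  r1 <- log_hr_from_ci(hr1, ci1[1L], ci1[2L], level = level)
  r2 <- log_hr_from_ci(hr2, ci2[1L], ci2[2L], level = level)
  normal_prior(r1$estimate - r2$estimate, sqrt(r1$se^2 + r2$se^2))
}

#' Analytic posterior slab weight for the spike-and-slab prior
#'
#' In the simplified one-dimensional setting where only the interaction
#' estimate `delta_hat` (with known variance `var_delta_hat`) enters the
#' analysis, the posterior of `delta` is a mixture of the two conditional
#' posteriors and the slab receives the marginal-likelihood weight
#' \deqn{w = \frac{p\,\phi(\hat\delta; 0, \tau^2 + v)}
#'   {p\,\phi(\hat\delta; 0, \tau^2 + v) +
#'    (1-p)\,\phi(\hat\delta; 0, v_0 + v)}}
#' where `v0` is the spike variance and `p` the prior slab weight. As
#' `tau2` grows without bound the weight tends to zero (Lindley–Bartlett
#' behaviour), which is why a plausible slab scale matters. Used as an
#' analytic oracle for the MCMC slab-inclusion rate.
#'
#' @param delta_hat Interaction estimate.
#' @param var_delta_hat Its variance (positive).
#' @param tau2 Slab variance (positive).
#' @param spike_var Spike variance, default 1e-4.
#' @param prior_slab_weight Prior probability of the slab; 0.5 under the
#'   uniform hyper-prior on the inclusion probability.
#' @return Posterior slab weight in (0, 1). Vectorized over `tau2`.
#' @export
slab_weight <- function(delta_hat, var_delta_hat, tau2,
                        spike_var = 1e-4, prior_slab_weight = 0.5) {
  if (var_delta_hat <= 0 || any(tau2 <= 0) || spike_var <= 0) {
    stop("variances must be positive")
  }
  l1 <- stats::dnorm(delta_hat, 0, sqrt(tau2 + var_delta_hat), log = TRUE)
  l0 <- stats::dnorm(delta_hat, 0, sqrt(spike_var + var_delta_hat), log = TRUE)
  p <- prior_slab_weight
  1 / (1 + exp(log(1 - p) - log(p) + l0 - l1))
}

#' Sample from a right-rectified normal distribution
#'
#' Draws `min(0, Y)` for `Y ~ N(mean, sd^2)`: continuous on the negative
#' half-line with a point mass of `1 - pnorm(-mean/sd)` at zero.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the underlying normal (`sd > 0`).
#' @return Numeric vector of non-positive draws.
#' @export
rrectnorm <- function(n, mean = 0, sd = 1) {
  stopifnot(sd > 0)
  pmin(0, stats::rnorm(n, mean, sd))
}

#' Distribution function of the right-rectified normal
#'
#' @param q Quantiles.
#' @inheritParams rrectnorm
#' @return `P(min(0, Y) <= q)`; equals the normal CDF below zero and 1 at
#'   or above zero.
#' @export
prectnorm <- function(q, mean = 0, sd = 1) {
  stopifnot(sd > 0)
  ifelse(q >= 0, 1, stats::pnorm(q, mean, sd))
}

# --- component densities and samplers used by prior_density/sample_prior ---

# log density of a (possibly truncated above, possibly degenerate) normal
.dnorm_trunc_log <- function(x, prior) {
  if (prior$sd == 0) {
    return(ifelse(x == prior$mean, Inf, -Inf))
  }
  out <- stats::dnorm(x, prior$mean, prior$sd, log = TRUE)
  if (!is.null(prior$upper)) {
    out <- out - stats::pnorm(prior$upper, prior$mean, prior$sd, log.p = TRUE)
    out[x > prior$upper] <- -Inf
  }
  out
}

# inverse-CDF sampler for normal truncated above at 'upper'
.rnorm_trunc <- function(n, mean, sd, upper = NULL) {
  if (sd == 0) return(rep(mean, n))
  if (is.null(upper)) return(stats::rnorm(n, mean, sd))
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, 0, pu)
  # clamp away from 0/1 for numerical safety far in the tail
  u <- pmin(pmax(u, 1e-300), 1 - 1e-16)
  stats::qnorm(u, mean, sd)
}

# marginal prior log density of delta for each component family
.ddelta_log <- function(x, delta_prior) {
  if (inherits(delta_prior, "normal_prior")) {
    .dnorm_trunc_log(x, delta_prior)
  } else if (inherits(delta_prior, "discrete_prior")) {
    vapply(x, function(xi) {
      j <- which(abs(delta_prior$values - xi) < 1e-9)
      if (length(j)) log(delta_prior$probs[j[1L]]) else -Inf
    }, numeric(1))
  } else { # spike_slab: marginal mixture with weight 1/2 each
    log(0.5 * stats::dnorm(x, 0, delta_prior$spike_sd) +
        0.5 * stats::dnorm(x, 0, delta_prior$slab_sd))
  }
}

#' Joint prior density
#'
#' Evaluates the joint prior (log) density of the two free parameters at
#' `(mu_B, mu_C)`, with `delta = mu_B - mu_C` substituted where the prior
#' is parameterized on `(mu_C, delta)`. For discrete components the value
#' is a probability mass; for rectified components the continuous density
#' is returned on the negative half-line and the atom mass exactly at 0.
#' Points outside the support (above a truncation bound, or positive
#' values under a rectified prior) return 0 (`-Inf` on the log scale).
#'
#' @param prior A [joint_prior()] object.
#' @param mu_B,mu_C Evaluation points (vectorized).
#' @param log Return the log density?
#' @return Numeric vector.
#' @export
prior_density <- function(prior, mu_B, mu_C, log = FALSE) {
  stopifnot(inherits(prior, "bsg_prior"))
  n <- max(length(mu_B), length(mu_C))
  mu_B <- rep_len(mu_B, n); mu_C <- rep_len(mu_C, n)
  if (prior$parameterization == "muC_delta") {
    ld <- .dnorm_trunc_log(mu_C, prior$muC) + .ddelta_log(mu_B - mu_C, prior$delta)
  } else if (inherits(prior$joint, "bivariate_normal_prior")) {
    j <- prior$joint
    ld <- .dbvnorm_log(mu_B, mu_C, j$mean[1], j$mean[2],
                       j$cov[1, 1], j$cov[2, 2], j$cov[1, 2])
  } else {
    j <- prior$joint
    # marginal for mu_C: density below 0, atom mass at 0
    ldC <- ifelse(mu_C < 0, stats::dnorm(mu_C, j$a, j$b, log = TRUE),
                  ifelse(mu_C == 0,
                         stats::pnorm(-j$a / j$b, lower.tail = FALSE, log.p = TRUE),
                         -Inf))
    v <- pmax(j$d^2 + j$e * mu_C, 0)
    m <- j$c * mu_C
    ldB <- ifelse(v > 0,
                  ifelse(mu_B < 0, stats::dnorm(mu_B, m, sqrt(v), log = TRUE),
                         ifelse(mu_B == 0,
                                stats::pnorm(-m / sqrt(v), lower.tail = FALSE,
                                             log.p = TRUE),
                                -Inf)),
                  ifelse(mu_B == pmin(0, m), Inf, -Inf))
    ld <- ldC + ldB
  }
  if (log) ld else exp(ld)
}

#' Sample from a joint prior
#'
#' Draws `(mu_B, mu_C, delta)` from the joint prior, with
#' `delta = mu_B - mu_C` holding exactly for every draw. Truncated
#' normal components are sampled by inverse-CDF; spike-and-slab draws
#' include the latent inclusion indicator `R` and probability `P`;
#' discrete draws include the category index `M`.
#'
#' @param prior A [joint_prior()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A data frame with columns `mu_B`, `mu_C`, `delta` and any
#'   auxiliary latent variables.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "bsg_prior"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  aux <- NULL
  if (prior$parameterization == "muC_delta") {
    muC <- .rnorm_trunc(n, prior$muC$mean, prior$muC$sd, prior$muC$upper)
    dp <- prior$delta
    if (inherits(dp, "normal_prior")) {
      delta <- .rnorm_trunc(n, dp$mean, dp$sd, dp$upper)
    } else if (inherits(dp, "discrete_prior")) {
      M <- sample.int(length(dp$values), n, replace = TRUE, prob = dp$probs)
      delta <- dp$values[M]
      aux <- data.frame(M = M)
    } else {
      P <- stats::runif(n)
      R <- stats::rbinom(n, 1, P)
      delta <- stats::rnorm(n, 0, ifelse(R == 1, dp$slab_sd, dp$spike_sd))
      aux <- data.frame(R = R, P = P)
    }
    muB <- muC + delta
  } else if (inherits(prior$joint, "bivariate_normal_prior")) {
    j <- prior$joint
    L <- chol(j$cov)
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
    muB <- j$mean[1] + z[, 1]
    muC <- j$mean[2] + z[, 2]
  } else {
    j <- prior$joint
    muC <- rrectnorm(n, j$a, j$b)
    v <- pmax(j$d^2 + j$e * muC, 0)
    y <- j$c * muC + sqrt(v) * stats::rnorm(n)
    muB <- pmin(0, y)
  }
  out <- data.frame(mu_B = muB, mu_C = muC, delta = muB - muC)
  if (!is.null(aux)) out <- cbind(out, aux)
  out
}
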