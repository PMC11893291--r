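#' Exact conjugate posterior under normal priors
#'
#' For untruncated normal priors — either independent normals on
#' `(mu_C, delta)` or a bivariate normal on `(mu_B, mu_C)` — the model is
#' fully Gaussian and the joint posterior is bivariate normal in closed
#' form. Writing the likelihood mean as a linear map of the two free
#' parameters, the posterior precision is the sum of the prior precision
#' and the Gram matrix of the map under the data precision, and the
#' posterior mean solves the usual normal equations. The induced
#' marginals for all three of `mu_B`, `mu_C` and `delta` are returned.
#'
#' A component prior with `sd = 0` is treated as a point mass (the
#' parameter is held fixed at its prior mean and the remaining parameter
#' updated in one dimension); truncated priors are not conjugate and are
#' rejected.
#'
#' @param data A [subgroup_estimates()] object.
#' @param prior A [joint_prior()] whose components are untruncated
#'   normals, or a bivariate normal joint prior.
#' @return An object of class `"bsg_conjugate"` with elements `mean` and
#'   `cov` (the `(mu_C, delta)` posterior) and `marginals`, a data frame
#'   of mean, sd, equal-tailed 95% interval and `P(<0)` for `mu_B`,
#'   `mu_C` and `delta`.
#' @examples
#' conjugate_posterior(stampede_estimates(), vague_prior())
#' @export
conjugate_posterior <- function(data, prior) {
  stopifnot(inherits(data, "subgroup_estimates"), inherits(prior, "bsg_prior"))
  Sigma <- matrix(c(data$var_B, data$cov_BC, data$cov_BC, data$var_C), 2, 2)
  Omega <- solve(Sigma)
  x <- c(data$mu_hat_B, data$mu_hat_C)

  if (prior$parameterization == "muC_delta") {
    pc <- prior$muC; pd <- prior$delta
    if (!inherits(pd, "normal_prior")) {
      stop("conjugate posterior requires a normal prior for delta")
    }
    if (!is.null(pc$upper) || !is.null(pd$upper)) {
      stop("truncated priors are not conjugate; use fit_subgroups()")
    }
    # theta = (mu_C, delta); likelihood mean = A theta, A = [[1,1],[1,0]]
    A <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
    M <- t(A) %*% Omega %*% A
    h <- drop(t(A) %*% Omega %*% x)
    m0 <- c(pc$mean, pd$mean)
    free <- c(pc$sd > 0, pd$sd > 0)
    if (!any(free)) {
      mean2 <- m0
      cov2 <- matrix(0, 2, 2)
    } else if (all(free)) {
      K0 <- diag(1 / c(pc$sd^2, pd$sd^2))
      cov2 <- solve(K0 + M)
      mean2 <- drop(cov2 %*% (K0 %*% m0 + h))
    } else {
      i <- which(free); j <- which(!free)
      prec <- M[i, i] + 1 / c(pc$sd, pd$sd)[i]^2
      lin <- h[i] - M[i, j] * m0[j] + m0[i] / c(pc$sd, pd$sd)[i]^2
      mean2 <- m0; mean2[i] <- lin / prec
      cov2 <- matrix(0, 2, 2); cov2[i, i] <- 1 / prec
    }
  } else if (inherits(prior$joint, "bivariate_normal_prior")) {
    j <- prior$joint
    K0 <- solve(j$cov)
    Vp <- solve(K0 + Omega)
    mp <- drop(Vp %*% (K0 %*% j$mean + Omega %*% x))
    # re-express (mu_B, mu_C) as (mu_C, delta)
    Tm <- matrix(c(0, 1, 1, -1), 2, 2, byrow = TRUE)
    mean2 <- drop(Tm %*% mp)
    cov2 <- Tm %*% Vp %*% t(Tm)
  } else {
    stop("no conjugate posterior for this prior family; use fit_subgroups()")
  }

  # marginals for (mu_B, mu_C, delta); mu_B = mu_C + delta
  mB <- mean2[1] + mean2[2]
  vB <- cov2[1, 1] + cov2[2, 2] + 2 * cov2[1, 2]
  means <- c(mu_B = mB, mu_C = mean2[1], delta = mean2[2])
  vars <- c(max(vB, 0), cov2[1, 1], cov2[2, 2])
  sds <- sqrt(vars)
  marg <- data.frame(
    parameter = names(means),
    mean = unname(means),
    sd = sds,
    ci_lo = unname(means) - 1.959963984540054 * sds,
    ci_hi = unname(means) + 1.959963984540054 * sds,
    prob_below_0 = ifelse(sds > 0, stats::pnorm(0, unname(means), sds),
                          as.numeric(means < 0)))
  structure(list(mean = stats::setNames(mean2, c("mu_C", "delta")),
                 cov = cov2, marginals = marg,
                 data = data, prior = prior),
            class = "bsg_conjugate")
}

#' @export
print.bsg_conjugate <- function(x, digits = 4, ...) {
  cat("Conjugate normal posterior\n")
  m <- x$marginals
  m[, -1] <- round(m[, -1], digits)
  print(m, row.names = FALSE)
  invisible(x)
}

# draw n samples from the exact conjugate posterior (used by
# fit_subgroups(method = "conjugate") so the draw-based methods work
# uniformly across fitting methods)
.sample_conjugate <- function(post, n) {
  cov2 <- post$cov
  if (all(cov2 == 0)) {
    muC <- rep(post$mean[1], n); delta <- rep(post$mean[2], n)
  } else {
    ev <- eigen(cov2, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
    z <- matrix(stats::rnorm(2 * n), 2, n)
    th <- post$mean + L %*% z
    muC <- th[1, ]; delta <- th[2, ]
  }
  muB <- muC + delta
  data.frame(mu_B = muB, mu_C = muC, delta = muB - muC)
}
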