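#' Summarise a vector of posterior draws
#'
#' Mean, standard deviation, equal-tailed 95% credible interval and the
#' probability of lying below zero (on the log hazard ratio scale,
#' "below zero" means treatment benefit).
#'
#' @param x Numeric vector of draws.
#' @return Named numeric vector with elements `mean`, `sd`, `ci_lo`,
#'   `ci_hi`, `prob_below_0`.
#' @export
draw_summary <- function(x) {
  q <- unname(stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7))
  c(mean = mean(x), sd = stats::sd(x), ci_lo = q[1], ci_hi = q[2],
    prob_below_0 = mean(x < 0))
}

#' @export
print.bsgfit <- function(x, digits = 4, ...) {
  cat("Bayesian two-subgroup model fit (", x$method, ")\n", sep = "")
  cat("data: ", x$data$label_B, " / ", x$data$label_C, "\n", sep = "")
  cm <- coef(x)
  cat("posterior means:\n")
  print(round(cm, digits))
  invisible(x)
}

#' @export
coef.bsgfit <- function(object, ...) {
  c(mu_B = mean(object$draws$mu_B),
    mu_C = mean(object$draws$mu_C),
    delta = mean(object$draws$delta))
}

#' Summarise a fitted subgroup model
#'
#' Per-parameter posterior mean, sd, equal-tailed 95% credible interval,
#' probability below zero, effective sample size and split-Rhat. For a
#' spike-and-slab prior the posterior slab-inclusion probability
#' `P(R = 1)` and the posterior mean of the inclusion probability `P`
#' are reported; for a discrete prior, the posterior category
#' probabilities.
#'
#' @param object A [fit_subgroups()] result.
#' @param ... Unused.
#' @return An object of class `"summary.bsgfit"`.
#' @export
summary.bsgfit <- function(object, ...) {
  d <- object$draws
  pars <- c("mu_B", "mu_C", "delta")
  tab <- t(vapply(pars, function(p) draw_summary(d[[p]]), numeric(5)))
  tab <- data.frame(parameter = pars, tab, row.names = NULL)
  dg <- object$diagnostics
  tab$ess <- dg$ess[match(pars, dg$parameter)]
  tab$rhat <- dg$rhat[match(pars, dg$parameter)]
  aux <- NULL
  if ("R" %in% names(d)) {
    aux <- c(prob_slab = mean(d$R == 1), mean_P = mean(d$P))
  } else if ("M" %in% names(d)) {
    vals <- object$prior$delta$values
    pm <- tabulate(d$M, nbins = length(vals)) / nrow(d)
    aux <- stats::setNames(pm, paste0("P(delta=", signif(vals, 3), ")"))
  }
  structure(list(table = tab, aux = aux, method = object$method,
                 n_draws = nrow(d)),
            class = "summary.bsgfit")
}

#' @export
print.summary.bsgfit <- function(x, digits = 4, ...) {
  cat("Posterior summary (", x$n_draws, " draws, ", x$method, ")\n", sep = "")
  tab <- x$table
  tab[, -1] <- lapply(tab[, -1], function(col) round(col, digits))
  print(tab, row.names = FALSE)
  if (!is.null(x$aux)) {
    cat("latent-variable posterior:\n")
    print(round(x$aux, digits))
  }
  invisible(x)
}

#' Posterior sign probabilities
#'
#' Monte-Carlo posterior probabilities that each effect is negative:
#' the treatment is beneficial in subgroup B, in subgroup C, and more
#' effective in subgroup B than in C (`delta < 0`).
#'
#' @param fit A [fit_subgroups()] result.
#' @return Named numeric vector `P(mu_B < 0)`, `P(mu_C < 0)`,
#'   `P(delta < 0)`.
#' @export
sign_probabilities <- function(fit) {
  stopifnot(inherits(fit, "bsgfit"))
  d <- fit$draws
  c("P(mu_B<0)" = mean(d$mu_B < 0),
    "P(mu_C<0)" = mean(d$mu_C < 0),
    "P(delta<0)" = mean(d$delta < 0))
}

#' Posterior draws of the overall treatment effect
#'
#' Per draw, the population-level effect is the proportion-weighted
#' average `mu_A = pi * mu_B + (1 - pi) * mu_C`, where `pi` is the
#' proportion of subgroup-B patients in the target population. For
#' non-collapsible effect measures such as the hazard ratio this is an
#' approximation.
#'
#' @param fit A [fit_subgroups()] result.
#' @param pi Proportion of B patients in `[0, 1]`.
#' @return Numeric vector of `mu_A` draws; summarise with
#'   [draw_summary()].
#' @export
overall_effect <- function(fit, pi) {
  stopifnot(inherits(fit, "bsgfit"), is.numeric(pi), length(pi) == 1L,
            pi >= 0, pi <= 1)
  pi * fit$draws$mu_B + (1 - pi) * fit$draws$mu_C
}

#' Posterior-predictive replicates of the observed estimates
#'
#' Draws replicate summary estimates `(mu_hat_B, mu_hat_C)` from the
#' observed-data model at posterior draws of the subgroup effects, using
#' the fixed covariance matrix of the fitted data.
#'
#' @param object A [fit_subgroups()] result.
#' @param nsim Number of replicates (recycled over posterior draws).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with columns `mu_hat_B`, `mu_hat_C`.
#' @export
simulate.bsgfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  idx <- rep_len(seq_len(nrow(d)), nsim)
  Sigma <- matrix(c(object$data$var_B, object$data$cov_BC,
                    object$data$cov_BC, object$data$var_C), 2, 2)
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(2 * nsim), nsim, 2) %*% L
  data.frame(mu_hat_B = d$mu_B[idx] + z[, 1],
             mu_hat_C = d$mu_C[idx] + z[, 2])
}

#' Plot posterior densities
#'
#' Kernel density estimates of the posteriors of `mu_B`, `mu_C` and
#' `delta`, with the observed estimates marked for the two subgroup
#' effects.
#'
#' @param x A [fit_subgroups()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bsgfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  d <- x$draws
  obs <- c(x$data$mu_hat_B, x$data$mu_hat_C, NA)
  for (i in seq_along(pars <- c("mu_B", "mu_C", "delta"))) {
    dens <- stats::density(d[[pars[i]]])
    graphics::plot(dens, main = pars[i], xlab = "log hazard ratio", ...)
    graphics::abline(v = 0, lty = 3)
    if (!is.na(obs[i])) graphics::abline(v = obs[i], col = 2, lty = 2)
  }
  invisible(x)
}
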