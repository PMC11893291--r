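#' Simulate subgroup estimates from the observed-data model
#'
#' Draws replicate pairs of summary estimates `(mu_hat_B, mu_hat_C)` from
#' the bivariate normal observed-data model at chosen true subgroup
#' effects. This is the study-condition generator used throughout the
#' test suite: it emulates exactly what the model assumes about the data
#' (normal estimators with known covariance) and nothing more, so
#' calibration checks against it probe the inference machinery, not the
#' adequacy of the normal approximation itself.
#'
#' @param true_mu_B,true_mu_C True subgroup effects (log scale).
#' @param var_B,var_C Estimator variances (positive).
#' @param cov_BC Estimator covariance.
#' @param n_replicates Number of replicate trials.
#' @param seed Optional seed.
#' @param labels Subgroup labels attached to each replicate.
#' @return A list of [subgroup_estimates()] objects of length
#'   `n_replicates`.
#' @examples
#' reps <- simulate_scenario(-0.3, -0.5, 0.05, 0.02, n_replicates = 3,
#'                           seed = 1)
#' @export
simulate_scenario <- function(true_mu_B, true_mu_C, var_B, var_C,
                              cov_BC = 0, n_replicates = 1, seed = NULL,
                              labels = c("B", "C")) {
  stopifnot(is.numeric(true_mu_B), is.numeric(true_mu_C),
            var_B > 0, var_C > 0, n_replicates >= 1)
  if (cov_BC^2 > var_B * var_C) stop("invalid covariance matrix")
  if (!is.null(seed)) set.seed(seed)
  Sigma <- matrix(c(var_B, cov_BC, cov_BC, var_C), 2, 2)
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(2 * n_replicates), n_replicates, 2) %*% L
  lapply(seq_len(n_replicates), function(i) {
    subgroup_estimates(true_mu_B + z[i, 1], true_mu_C + z[i, 2],
                       var_B, var_C, cov_BC = cov_BC, labels = labels)
  })
}
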