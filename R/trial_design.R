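#' Design specification for a new two-subgroup trial
#'
#' A trial of `n_total` patients with a proportion `pi` recruited to
#' subgroup B and 1:1 randomisation within each subgroup (stratified
#' randomisation). `event_rates` gives the expected event (death)
#' proportions over the study period per subgroup and arm.
#'
#' @param n_total Total number of patients.
#' @param pi Proportion recruited to subgroup B, in (0, 1).
#' @param event_rates Named list `list(B = c(active =, control =),
#'   C = c(active =, control =))` with rates in `[0, 1]`.
#' @param crit Critical value for declaring significance with the
#'   intended direction; the default -1.96 is a two-sided 5% test with a
#'   directional claim of benefit.
#' @return An object of class `"trial_design"`.
#' @examples
#' trial_design(900, 2/3,
#'              list(B = c(active = 0.6, control = 0.8),
#'                   C = c(active = 0.5, control = 0.7)))
#' @export
trial_design <- function(n_total, pi, event_rates, crit = -1.96) {
  stopifnot(is.numeric(n_total), n_total > 0,
            is.numeric(pi), pi > 0, pi < 1,
            is.list(event_rates), all(c("B", "C") %in% names(event_rates)))
  for (g in c("B", "C")) {
    r <- event_rates[[g]]
    if (length(r) != 2L || any(r < 0) || any(r > 1)) {
      stop("event rates for subgroup ", g,
           " must be two proportions in [0, 1]")
    }
  }
  structure(list(n_total = n_total, pi = pi, event_rates = event_rates,
                 crit = crit),
            class = "trial_design")
}

#' Predicted events and variance approximations
#'
#' Predicts the number of events in each subgroup analysis as the product
#' of patient numbers and event rates (halved within subgroup for the 1:1
#' randomisation), and in the all-comer analysis as their sum. The
#' variance of each analysis's estimated log hazard ratio is approximated
#' as 4 divided by its predicted events (the standard approximation for
#' the Cox score statistic). Event counts are carried as reals; no
#' rounding is applied.
#'
#' @param design A [trial_design()].
#' @return An object of class `"predicted_analysis"` with fields
#'   `events_B`, `events_C`, `events_A`, `sigma2_B`, `sigma2_C`,
#'   `sigma2_A`.
#' @export
predict_events <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  nB <- design$n_total * design$pi
  nC <- design$n_total * (1 - design$pi)
  eB <- nB / 2 * sum(design$event_rates$B)
  eC <- nC / 2 * sum(design$event_rates$C)
  eA <- eB + eC
  if (eB <= 0 || eC <= 0) {
    stop("zero predicted events in a subgroup analysis: variance undefined")
  }
  structure(list(events_B = eB, events_C = eC, events_A = eA,
                 sigma2_B = 4 / eB, sigma2_C = 4 / eC, sigma2_A = 4 / eA,
                 pi = design$pi, crit = design$crit),
            class = "predicted_analysis")
}

#' @export
print.predicted_analysis <- function(x, digits = 4, ...) {
  cat("Predicted analysis\n")
  tab <- data.frame(analysis = c("B", "C", "A"),
                    events = c(x$events_B, x$events_C, x$events_A),
                    sigma2 = round(c(x$sigma2_B, x$sigma2_C, x$sigma2_A),
                                   digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Posterior-predictive draws for a planned trial
#'
#' For each posterior draw of `(mu_B, mu_C)`, samples the future trial's
#' estimated log hazard ratios `mu_hat_B_new ~ N(mu_B, sigma2_B)` and
#' `mu_hat_C_new ~ N(mu_C, sigma2_C)` independently, forms the all-comer
#' estimate as the proportion-weighted average, and standardises each
#' into a Z statistic using the design's predicted standard errors. The
#' draws mix posterior uncertainty about the true effects with the
#' sampling noise of the future trial.
#'
#' @param fit A [fit_subgroups()] result (the analysis providing the
#'   posterior beliefs).
#' @param design A [trial_design()], or a [predict_events()] result.
#' @param seed Optional seed for the predictive noise.
#' @return An object of class `"predictive_draws"`: data frame columns
#'   `mu_hat_B_new`, `mu_hat_C_new`, `mu_hat_A_new`, `Z_B`, `Z_C`, `Z_A`
#'   plus the `analysis` attribute.
#' @export
predictive_draws <- function(fit, design, seed = NULL) {
  stopifnot(inherits(fit, "bsgfit"))
  analysis <- if (inherits(design, "predicted_analysis")) design
              else predict_events(design)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fit$draws)
  mhB <- stats::rnorm(n, fit$draws$mu_B, sqrt(analysis$sigma2_B))
  mhC <- stats::rnorm(n, fit$draws$mu_C, sqrt(analysis$sigma2_C))
  mhA <- analysis$pi * mhB + (1 - analysis$pi) * mhC
  out <- data.frame(
    mu_hat_B_new = mhB, mu_hat_C_new = mhC, mu_hat_A_new = mhA,
    Z_B = mhB / sqrt(analysis$sigma2_B),
    Z_C = mhC / sqrt(analysis$sigma2_C),
    Z_A = mhA / sqrt(analysis$sigma2_A))
  attr(out, "analysis") <- analysis
  class(out) <- c("predictive_draws", class(out))
  out
}

#' @rdname predictive_draws
#' @param object A [fit_subgroups()] result.
#' @param ... Unused.
#' @export
predict.bsgfit <- function(object, design, seed = NULL, ...) {
  predictive_draws(object, design, seed = seed)
}

#' Bayesian predictive power
#'
#' The posterior-predictive probability that the planned trial's test
#' statistic crosses the critical value (assurance), for the all-comer
#' population and each subgroup: the proportion of predictive draws with
#' `Z < crit`.
#'
#' @param pred A [predictive_draws()] result.
#' @param crit Critical value; defaults to the design's.
#' @return Named numeric vector `(A, B, C)` of probabilities in `[0, 1]`.
#' @export
bayesian_predictive_power <- function(pred, crit = NULL) {
  stopifnot(inherits(pred, "predictive_draws"))
  if (is.null(crit)) crit <- attr(pred, "analysis")$crit
  c(A = mean(pred$Z_A < crit),
    B = mean(pred$Z_B < crit),
    C = mean(pred$Z_C < crit))
}

#' Conditional predictive power under gated testing
#'
#' For a hierarchical strategy that tests a subgroup only after
#' significance in the all-comer population, the conditional power is the
#' proportion of predictive draws significant in the target subgroup
#' among those already significant overall.
#'
#' @param pred A [predictive_draws()] result.
#' @param gate `"B_given_A"` or `"C_given_A"`.
#' @param crit_gate Critical value for the all-comer gate.
#' @param crit_target Critical value for the target subgroup (the
#'   appropriate value depends on the multiplicity strategy; none is
#'   imposed here).
#' @return The conditional probability. Errors if fewer than 100 draws
#'   pass the gate (the estimate would be unstable).
#' @export
conditional_power <- function(pred, gate = c("B_given_A", "C_given_A"),
                              crit_gate = -1.96, crit_target = -1.96) {
  stopifnot(inherits(pred, "predictive_draws"))
  gate <- match.arg(gate)
  pass <- pred$Z_A < crit_gate
  if (sum(pass) == 0L) stop("no predictive draws pass the gate")
  if (sum(pass) < 100L) {
    stop("only ", sum(pass),
         " draws pass the gate; conditional power estimate unstable")
  }
  zt <- if (gate == "B_given_A") pred$Z_B else pred$Z_C
  mean(zt[pass] < crit_target)
}

#' Predictive power across candidate subgroup proportions
#'
#' Recomputes predicted events and Bayesian predictive power for a grid
#' of recruitment proportions `pi`, holding the posterior and the other
#' design inputs fixed.
#'
#' @param fit A [fit_subgroups()] result.
#' @param n_total Total patients.
#' @param pi_values Vector of candidate proportions of subgroup B.
#' @param event_rates As in [trial_design()].
#' @param crit Critical value.
#' @param seed Optional seed (each `pi` uses an offset of it).
#' @return Data frame with one row per `pi`: events, variances and the
#'   three predictive powers.
#' @export
power_curve <- function(fit, n_total, pi_values, event_rates,
                        crit = -1.96, seed = NULL) {
  rows <- lapply(seq_along(pi_values), function(i) {
    des <- trial_design(n_total, pi_values[i], event_rates, crit)
    an <- predict_events(des)
    pr <- predictive_draws(fit, an,
                           seed = if (is.null(seed)) NULL else seed + i - 1L)
    bpp <- bayesian_predictive_power(pr)
    data.frame(pi = pi_values[i],
               events_B = an$events_B, events_C = an$events_C,
               events_A = an$events_A,
               BPP_A = bpp[["A"]], BPP_B = bpp[["B"]], BPP_C = bpp[["C"]])
  })
  do.call(rbind, rows)
}
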