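#' Build a prior from a configuration list
#'
#' Translates the configuration-file prior schema into a [joint_prior()].
#' Families: `"normal"` (normal components for `muC` and `delta`, each
#' with `mean`, `sd`, optional `upper` truncation and optional power
#' discount `k`), `"discrete"` (`values`/`probs` for `delta` plus a
#' normal `muC`), `"spike_slab"` (`slab_sd`, optional `spike_sd`, normal
#' `muC`), `"bivariate_normal"` (`mean`, `cov`) and `"rectified"`
#' (`a`, `b`, `c`, `d`, `e`).
#'
#' @param cfg Named list, e.g. parsed from YAML or JSON.
#' @return A [joint_prior()].
#' @export
prior_from_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$family))
  np <- function(x) {
    if (is.null(x)) return(normal_prior(0, 10))
    p <- normal_prior(x$mean %||% 0, x$sd %||% 10, upper = x$upper)
    if (!is.null(x$k)) p <- power_prior(p, x$k) else p
  }
  switch(cfg$family,
    normal = joint_prior(muC = np(cfg$muC), delta = np(cfg$delta)),
    discrete = joint_prior(
      muC = np(cfg$muC),
      delta = discrete_prior(as.numeric(cfg$values),
                             as.numeric(cfg$probs %||%
                               rep(1 / length(cfg$values),
                                   length(cfg$values))))),
    spike_slab = joint_prior(
      muC = np(cfg$muC),
      delta = spike_slab_prior(cfg$slab_sd, cfg$spike_sd %||% 0.01)),
    bivariate_normal = joint_prior(joint = bivariate_normal_prior(
      as.numeric(cfg$mean %||% c(0, 0)),
      matrix(unlist(cfg$cov %||% list(c(100, 50), c(50, 100))), 2, 2,
             byrow = TRUE))),
    rectified = joint_prior(joint = rectified_joint_prior(
      cfg$a, cfg$b, cfg$c, cfg$d, cfg$e)),
    stop("unknown prior family: ", cfg$family))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    if (ext == "json") jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("'config' must be a file path or a list")
  }
}

.data_from_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.null(cfg$file)) {
    read_subgroup_estimates(cfg$file, cov_BC = cfg$cov_BC %||% 0)
  } else if (!is.null(cfg$hr_B)) {
    estimates_from_hr(cfg$hr_B, as.numeric(cfg$ci_B),
                      cfg$hr_C, as.numeric(cfg$ci_C),
                      cov_BC = cfg$cov_BC %||% 0,
                      labels = as.character(cfg$labels %||% c("B", "C")))
  } else if (!is.null(cfg$estimate_B)) {
    subgroup_estimates(cfg$estimate_B, cfg$estimate_C,
                       cfg$se_B^2, cfg$se_C^2,
                       cov_BC = cfg$cov_BC %||% 0,
                       labels = as.character(cfg$labels %||% c("B", "C")))
  } else {
    stop("config 'data' must give a file, hazard-ratio summaries, ",
         "or log-scale estimates")
  }
}

#' Run a configured analysis end to end
#'
#' Reads the data and prior from a configuration (YAML/JSON file path or
#' equivalent list), fits the model by MCMC, and returns a report with
#' posterior summaries for `mu_B`, `mu_C`, `delta`, the overall effect
#' `mu_A` for each requested population proportion, sign probabilities,
#' diagnostics and full provenance (inputs, prior, settings, seed,
#' package version). If the config names output files, the report is
#' written as JSON and the draws optionally as CSV.
#'
#' @param config File path or list with fields `data`, `prior`, `mcmc`
#'   (must include a `seed`), optional `pi` (vector of proportions) and
#'   optional `output` (`summary` and/or `draws` paths).
#' @return The report list, invisibly. The fitted model is included as
#'   attribute `"fit"`.
#' @export
run_analysis <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg$mcmc) || is.null(cfg$mcmc$seed)) {
    stop("config must supply mcmc settings with a seed ",
         "(stochastic runs require one)")
  }
  data <- .data_from_config(cfg$data)
  prior <- prior_from_config(cfg$prior)
  settings <- mcmc_settings(
    n_chains = cfg$mcmc$n_chains %||% 2,
    iterations = cfg$mcmc$iterations %||% 50000,
    burn_in = cfg$mcmc$burn_in %||% 20000,
    thin = cfg$mcmc$thin %||% 2,
    seed = cfg$mcmc$seed)
  fit <- fit_subgroups(data, prior, settings)
  sm <- summary(fit)
  report <- list(
    inputs = list(
      mu_hat_B = data$mu_hat_B, mu_hat_C = data$mu_hat_C,
      var_B = data$var_B, var_C = data$var_C, cov_BC = data$cov_BC,
      labels = c(data$label_B, data$label_C)),
    prior = cfg$prior,
    mcmc = list(n_chains = settings$n_chains,
                iterations = settings$iterations,
                burn_in = settings$burn_in, thin = settings$thin,
                seed = settings$seed),
    posterior = sm$table,
    latent = as.list(sm$aux),
    sign_probabilities = as.list(sign_probabilities(fit)),
    diagnostics = fit$diagnostics,
    version = as.character(utils::packageVersion("bayesubgroup")))
  if (!is.null(cfg$pi)) {
    report$overall_effect <- lapply(as.numeric(cfg$pi), function(p) {
      c(list(pi = p), as.list(draw_summary(overall_effect(fit, p))))
    })
  }
  if (!is.null(cfg$output)) {
    if (!is.null(cfg$output$summary)) {
      jsonlite::write_json(report, cfg$output$summary, auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
    }
    if (!is.null(cfg$output$draws)) {
      utils::write.csv(fit$draws, cfg$output$draws, row.names = FALSE)
    }
  }
  attr(report, "fit") <- fit
  invisible(report)
}

#' Run a configured trial-design evaluation
#'
#' Fits the analysis model described by the config (as in
#' [run_analysis()]) and evaluates predicted events and Bayesian
#' predictive power over the configured grid of recruitment proportions.
#'
#' @param config File path or list with fields `data`, `prior`, `mcmc`
#'   (with `seed`) and `design` (`n_total`, `pi` scalar or vector,
#'   `event_rates` with `B`/`C` each `active`/`control`, optional
#'   `crit`), plus optional `output$table` (CSV path).
#' @return Data frame from [power_curve()], invisibly, with the fitted
#'   model as attribute `"fit"`.
#' @export
run_design <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg$design)) stop("config must include a 'design' block")
  report <- run_analysis(cfg[setdiff(names(cfg), c("design", "output"))])
  fit <- attr(report, "fit")
  des <- cfg$design
  rates <- list(B = unlist(des$event_rates$B), C = unlist(des$event_rates$C))
  tab <- power_curve(fit, des$n_total, as.numeric(des$pi), rates,
                     crit = des$crit %||% -1.96,
                     seed = cfg$mcmc$seed)
  if (!is.null(cfg$output) && !is.null(cfg$output$table)) {
    utils::write.csv(tab, cfg$output$table, row.names = FALSE)
  }
  attr(tab, "fit") <- fit
  invisible(tab)
}
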