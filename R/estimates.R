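#' Convert a hazard ratio and confidence interval to the log scale
#'
#' Published time-to-event subgroup results are usually reported as a hazard
#' ratio with a 95% confidence interval. On the log scale the point estimate
#' is `log(hr)` and the standard error is recovered as the length of the
#' confidence interval on the log scale divided by twice the normal
#' quantile (1.96 for the default 95% level).
#'
#' @param hr Hazard ratio point estimate (positive).
#' @param ci_lo,ci_hi Lower and upper confidence limits (positive,
#'   `ci_lo <= hr <= ci_hi`).
#' @param level Confidence level of the interval; for the default 0.95 the
#'   multiplier is exactly 1.96 (matching the conventional arithmetic used
#'   when reading estimates off a forest plot), otherwise the exact normal
#'   quantile is used.
#' @return A list with components `estimate` (log hazard ratio) and `se`.
#' @examples
#' log_hr_from_ci(0.75, 0.61, 0.93)  # N(-0.288, 0.108^2)
#' @export
log_hr_from_ci <- function(hr, ci_lo, ci_hi, level = 0.95) {
  if (!is.numeric(hr) || !is.numeric(ci_lo) || !is.numeric(ci_hi) ||
      any(c(hr, ci_lo, ci_hi) <= 0)) {
    stop("'hr', 'ci_lo' and 'ci_hi' must be positive numbers")
  }
  if (ci_lo > hr || hr > ci_hi) {
    stop("confidence limits must bracket the estimate: ci_lo <= hr <= ci_hi")
  }
  if (ci_lo == ci_hi) {
    stop("degenerate confidence interval (ci_lo == ci_hi): zero variance")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("'level' must lie strictly between 0 and 1")
  }
  z <- if (level == 0.95) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  list(estimate = log(hr), se = (log(ci_hi) - log(ci_lo)) / (2 * z))
}

#' Summary estimates for two disjoint subgroups
#'
#' Container for the observed data of the model: log-scale treatment-effect
#' estimates in subgroups B and C, their (squared standard error) variances
#' and an optional covariance. The two estimators are modelled as bivariate
#' normal around the true subgroup effects with this covariance matrix
#' treated as fixed and known.
#'
#' @param mu_hat_B,mu_hat_C Log-scale effect estimates (e.g. log hazard
#'   ratios) in subgroups B and C.
#' @param var_B,var_C Variances of the two estimators (positive).
#' @param cov_BC Covariance between the estimators; zero when the subgroups
#'   are analysed separately with no shared covariate adjustment. It is
#'   never inferred from data, only accepted as input.
#' @param labels Length-2 character vector naming the subgroups.
#' @return An object of class `"subgroup_estimates"`.
#' @seealso [estimates_from_hr()], [stampede_estimates()],
#'   [meteor_estimates()]
#' @export
subgroup_estimates <- function(mu_hat_B, mu_hat_C, var_B, var_C,
                               cov_BC = 0,
                               labels = c("B", "C")) {
  stopifnot(is.numeric(mu_hat_B), is.numeric(mu_hat_C),
            length(mu_hat_B) == 1L, length(mu_hat_C) == 1L,
            is.numeric(var_B), is.numeric(var_C), is.numeric(cov_BC),
            length(labels) == 2L)
  if (var_B <= 0 || var_C <= 0) stop("'var_B' and 'var_C' must be positive")
  if (cov_BC^2 > var_B * var_C) {
    stop("invalid covariance: cov_BC^2 exceeds var_B * var_C")
  }
  structure(
    list(mu_hat_B = mu_hat_B, mu_hat_C = mu_hat_C,
         var_B = var_B, var_C = var_C, cov_BC = cov_BC,
         label_B = as.character(labels[1L]),
         label_C = as.character(labels[2L])),
    class = "subgroup_estimates")
}

#' @export
print.subgroup_estimates <- function(x, digits = 4, ...) {
  cat("Subgroup summary estimates (log scale)\n")
  tab <- data.frame(
    subgroup = c(x$label_B, x$label_C),
    estimate = round(c(x$mu_hat_B, x$mu_hat_C), digits),
    se = round(sqrt(c(x$var_B, x$var_C)), digits))
  print(tab, row.names = FALSE)
  if (x$cov_BC != 0) cat("covariance:", format(x$cov_BC, digits = digits), "\n")
  invisible(x)
}

#' Build subgroup estimates from published hazard ratios
#'
#' Applies [log_hr_from_ci()] to each subgroup's hazard ratio and confidence
#' interval, storing squared standard errors as variances. The two
#' estimators are taken as conditionally independent (`cov_BC = 0`) unless a
#' covariance is supplied.
#'
#' @param hr_B,hr_C Hazard ratio point estimates.
#' @param ci_B,ci_C Length-2 numeric vectors `(lower, upper)`.
#' @param cov_BC Covariance between the log-scale estimators.
#' @param labels Subgroup labels.
#' @inheritParams log_hr_from_ci
#' @return A [subgroup_estimates()] object.
#' @examples
#' estimates_from_hr(0.75, c(0.48, 1.18), 0.61, c(0.49, 0.75))
#' @export
estimates_from_hr <- function(hr_B, ci_B, hr_C, ci_C, cov_BC = 0,
                              labels = c("B", "C"), level = 0.95) {
  b <- log_hr_from_ci(hr_B, ci_B[1L], ci_B[2L], level = level)
  cc <- log_hr_from_ci(hr_C, ci_C[1L], ci_C[2L], level = level)
  subgroup_estimates(b$estimate, cc$estimate, b$se^2, cc$se^2,
                     cov_BC = cov_BC, labels = labels)
}

#' STAMPEDE overall-survival subgroup estimates
#'
#' Hazard ratios 0.75 (0.48, 1.18) for non-metastatic (B) and 0.61
#' (0.49, 0.75) for metastatic (C) prostate cancer patients, comparing
#' abiraterone plus prednisolone added to androgen-deprivation therapy
#' versus ADT alone, converted to the log scale.
#'
#' @return A [subgroup_estimates()] object.
#' @export
stampede_estimates <- function() {
  estimates_from_hr(0.75, c(0.48, 1.18), 0.61, c(0.49, 0.75),
                    labels = c("non-metastatic", "metastatic"))
}

#' METEOR overall-survival subgroup estimates
#'
#' Hazard ratios 0.54 (0.34, 0.84) for patients with bone metastases (B)
#' and 0.71 (0.55, 0.91) for those without (C), cabozantinib versus
#' everolimus in advanced renal cell carcinoma, converted to the log scale.
#'
#' @return A [subgroup_estimates()] object.
#' @export
meteor_estimates <- function() {
  estimates_from_hr(0.54, c(0.34, 0.84), 0.71, c(0.55, 0.91),
                    labels = c("bone metastases", "no bone metastases"))
}

# 2x2 bivariate normal log density; vectorized over (x1, x2) or (m1, m2)
.dbvnorm_log <- function(x1, x2, m1, m2, v1, v2, cv) {
  det <- v1 * v2 - cv^2
  if (det <= 0) stop("singular covariance matrix")
  r1 <- x1 - m1
  r2 <- x2 - m2
  q <- (v2 * r1^2 - 2 * cv * r1 * r2 + v1 * r2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Log likelihood of the subgroup estimates
#'
#' Evaluates the bivariate normal log density of the observed estimates
#' `(mu_hat_B, mu_hat_C)` at candidate subgroup effects `(mu_B, mu_C)`,
#' with the covariance matrix fixed at the values stored in `data`. With
#' `cov_BC = 0` this is the sum of two univariate normal log densities.
#' Vectorized over `mu_B` and `mu_C`.
#'
#' @param data A [subgroup_estimates()] object.
#' @param mu_B,mu_C Candidate true subgroup effects (log scale).
#' @return Numeric vector of log density values.
#' @export
loglik_subgroups <- function(data, mu_B, mu_C) {
  stopifnot(inherits(data, "subgroup_estimates"))
  .dbvnorm_log(data$mu_hat_B, data$mu_hat_C, mu_B, mu_C,
               data$var_B, data$var_C, data$cov_BC)
}

#' Read subgroup estimates from a CSV or JSON file
#'
#' The file must describe exactly two subgroups, one per record, either as
#' hazard-ratio summaries (columns/fields `subgroup`, `hr`, `ci_lo`,
#' `ci_hi`) or directly on the log scale (`subgroup`, `estimate`, `se`).
#' The first record is taken as subgroup B, the second as subgroup C.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param cov_BC Covariance between the two estimators.
#' @return A [subgroup_estimates()] object.
#' @export
read_subgroup_estimates <- function(path, cov_BC = 0) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) != 2L) stop("expected exactly two subgroup records, got ", nrow(df))
  labs <- if ("subgroup" %in% names(df)) as.character(df$subgroup) else c("B", "C")
  if (all(c("hr", "ci_lo", "ci_hi") %in% names(df))) {
    estimates_from_hr(df$hr[1L], c(df$ci_lo[1L], df$ci_hi[1L]),
                      df$hr[2L], c(df$ci_lo[2L], df$ci_hi[2L]),
                      cov_BC = cov_BC, labels = labs)
  } else if (all(c("estimate", "se") %in% names(df))) {
    subgroup_estimates(df$estimate[1L], df$estimate[2L],
                       df$se[1L]^2, df$se[2L]^2,
                       cov_BC = cov_BC, labels = labs)
  } else {
    stop("need columns (hr, ci_lo, ci_hi) or (estimate, se)")
  }
}
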