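#' Discrete joint elicitation grid for the two subgroup effects
#'
#' A joint probability table over a discrete set of candidate values for
#' `mu_B` (columns) and `mu_C` (rows), as produced by a chips-and-bins
#' style elicitation: a marginal distribution for `mu_C` times a
#' conditional distribution for `mu_B` given each `mu_C` value.
#'
#' @param muB_values,muC_values Strictly increasing candidate values
#'   (log scale).
#' @param joint_probs Matrix of probabilities, rows indexed by
#'   `muC_values` and columns by `muB_values`; non-negative, summing to 1
#'   (renormalized with a warning if the total is off by more than 1e-6).
#' @return An object of class `"elicitation_grid"`.
#' @seealso [stampede_grid()], [grid_from_conditionals()]
#' @export
elicitation_grid <- function(muB_values, muC_values, joint_probs) {
  stopifnot(is.numeric(muB_values), is.numeric(muC_values),
            is.matrix(joint_probs),
            nrow(joint_probs) == length(muC_values),
            ncol(joint_probs) == length(muB_values))
  if (any(diff(muB_values) <= 0) || any(diff(muC_values) <= 0)) {
    stop("candidate values must be strictly increasing")
  }
  if (any(joint_probs < 0)) stop("probabilities must be non-negative")
  tot <- sum(joint_probs)
  if (tot == 0) stop("all probabilities are zero")
  if (abs(tot - 1) > 1e-6) {
    warning("joint probabilities sum to ", format(tot),
            "; renormalizing to 1")
    joint_probs <- joint_probs / tot
  }
  structure(list(muB_values = muB_values, muC_values = muC_values,
                 joint_probs = joint_probs),
            class = "elicitation_grid")
}

#' @export
print.elicitation_grid <- function(x, digits = 4, ...) {
  cat("Elicitation grid (rows mu_C, cols mu_B)\n")
  m <- round(x$joint_probs, digits)
  dimnames(m) <- list(paste0("mu_C=", signif(x$muC_values, 3)),
                      paste0("mu_B=", signif(x$muB_values, 3)))
  print(m)
  invisible(x)
}

#' Build a joint grid from a marginal and conditional probabilities
#'
#' Mirrors the elicitation process: joint probability = marginal
#' probability of each `mu_C` value times the conditional probability of
#' each `mu_B` value given that `mu_C`.
#'
#' @param muB_values,muC_values Candidate values.
#' @param marginal_muC Marginal probabilities of the `mu_C` values
#'   (sums to 1).
#' @param conditional_muB Matrix of conditional probabilities, one row
#'   per `mu_C` value (each row sums to 1).
#' @return An [elicitation_grid()].
#' @export
grid_from_conditionals <- function(muB_values, muC_values,
                                   marginal_muC, conditional_muB) {
  stopifnot(length(marginal_muC) == length(muC_values),
            is.matrix(conditional_muB),
            nrow(conditional_muB) == length(muC_values),
            ncol(conditional_muB) == length(muB_values))
  if (abs(sum(marginal_muC) - 1) > 1e-6) {
    stop("marginal probabilities must sum to 1")
  }
  rs <- rowSums(conditional_muB)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("each conditional row must sum to 1")
  }
  elicitation_grid(muB_values, muC_values,
                   marginal_muC * conditional_muB)
}

#' The STAMPEDE elicitation grid
#'
#' The illustrative joint discrete prior over hazard ratios 0.5-1.0
#' (log scale) for the metastatic (`mu_C`) and non-metastatic (`mu_B`)
#' prostate cancer subgroups, based on informal discussions with
#' clinicians.
#'
#' @return An [elicitation_grid()].
#' @export
stampede_grid <- function() {
  p <- matrix(c(
    0.0030, 0.0025, 0.0020, 0.0015, 0.0005, 0.0005,
    0.0090, 0.0315, 0.0225, 0.0135, 0.0090, 0.0045,
    0.0150, 0.0300, 0.1050, 0.0900, 0.0450, 0.0150,
    0.0000, 0.0175, 0.0525, 0.1400, 0.1050, 0.0350,
    0.0000, 0.0000, 0.0100, 0.0400, 0.0900, 0.0600,
    0.0000, 0.0000, 0.0005, 0.0020, 0.0050, 0.0425),
    nrow = 6, ncol = 6, byrow = TRUE)
  v <- log(seq(0.5, 1.0, by = 0.1))
  elicitation_grid(muB_values = v, muC_values = v, joint_probs = p)
}

#' Read an elicitation grid from CSV or JSON
#'
#' CSV layout: the header row gives the candidate hazard ratios for
#' `mu_B`, the first column those for `mu_C`, and the cells the joint
#' probabilities; hazard ratios are converted to the log scale. JSON
#' files carry `muB_values`, `muC_values` (already on the log scale) and
#' `joint_probs`.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return An [elicitation_grid()].
#' @export
read_elicitation_grid <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::fromJSON(path)
    return(elicitation_grid(as.numeric(x$muB_values),
                            as.numeric(x$muC_values),
                            matrix(unlist(x$joint_probs),
                                   length(x$muC_values),
                                   length(x$muB_values), byrow = TRUE)))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  muC <- log(as.numeric(df[[1L]]))
  muB <- log(as.numeric(names(df)[-1L]))
  elicitation_grid(muB, muC, as.matrix(df[, -1L, drop = FALSE]))
}

#' Moment-match a bivariate normal prior to an elicitation grid
#'
#' Returns the bivariate normal distribution on `(mu_B, mu_C)` whose mean
#' vector and covariance matrix equal the first two moments of the
#' discrete joint distribution exactly.
#'
#' @param grid An [elicitation_grid()].
#' @return A [bivariate_normal_prior()].
#' @export
moment_match <- function(grid) {
  stopifnot(inherits(grid, "elicitation_grid"))
  p <- grid$joint_probs
  vB <- grid$muB_values; vC <- grid$muC_values
  pB <- colSums(p); pC <- rowSums(p)
  mB <- sum(pB * vB); mC <- sum(pC * vC)
  varB <- sum(pB * vB^2) - mB^2
  varC <- sum(pC * vC^2) - mC^2
  cv <- sum(p * outer(vC, vB)) - mB * mC
  if (varB <= 0 || varC <= 0 || cv^2 >= varB * varC) {
    stop("grid moments do not give a positive-definite covariance")
  }
  bivariate_normal_prior(mean = c(mB, mC),
                         cov = matrix(c(varB, cv, cv, varC), 2, 2))
}

#' Partition of the real line into intervals
#'
#' Interior breakpoints define intervals `(-Inf, b1], (b1, b2], ...,
#' (bk, Inf)`. The Cartesian product of the partition with itself splits
#' the `(mu_B, mu_C)` plane into rectangular regions used to compare an
#' elicited grid with a parametric joint prior.
#'
#' @param breakpoints Strictly increasing numeric vector.
#' @return An object of class `"region_partition"`.
#' @export
region_partition <- function(breakpoints = log(seq(0.55, 0.95, by = 0.1))) {
  stopifnot(is.numeric(breakpoints), length(breakpoints) >= 1L)
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be increasing")
  structure(list(breakpoints = breakpoints,
                 n_intervals = length(breakpoints) + 1L),
            class = "region_partition")
}

# interval index of value x under partition (intervals are (lo, hi])
.interval_index <- function(x, partition) {
  vapply(x, function(xi) sum(xi > partition$breakpoints) + 1L, integer(1))
}

# interval probabilities of a right-rectified normal RN(m, s^2); the atom
# at 0 falls in the interval whose half-open closure contains 0
.rect_interval_probs <- function(m, s, partition) {
  br <- partition$breakpoints
  k <- partition$n_intervals
  if (s <= 0) {
    out <- numeric(k)
    out[.interval_index(min(0, m), partition)] <- 1
    return(out)
  }
  Fv <- stats::pnorm(pmin(br, 0), m, s)  # rectified CDF at breakpoints
  Fv[br >= 0] <- 1
  diff(c(0, Fv, 1))
}

#' Region probabilities implied by a rectified joint prior
#'
#' Approximates the prior probability that `(mu_B, mu_C)` falls in each
#' rectangular region of the partition product: the marginal probability
#' that `mu_C` lies in each interval (from the rectified marginal, atom
#' at 0 included) times the conditional probability that `mu_B` lies in
#' each interval, with the conditional evaluated at representative
#' `mu_C` values taken from the elicitation grid.
#'
#' When several grid values fall in one interval the representative is
#' their average, weighted by marginal grid probability if
#' `weighted = TRUE` (default) or unweighted otherwise. An interval
#' containing no grid value uses its midpoint (its finite endpoint for
#' unbounded intervals), with a message.
#'
#' @param params A [rectified_joint_prior()].
#' @param partition A [region_partition()].
#' @param grid An [elicitation_grid()] supplying representative values.
#' @param weighted Weight representative values by marginal probability?
#' @return A list with `E` (matrix of expected region probabilities,
#'   rows = `mu_C` intervals, cols = `mu_B` intervals), `marginal`,
#'   `conditional` and `rep_values`.
#' @export
rectified_region_probs <- function(params, partition, grid,
                                   weighted = TRUE) {
  stopifnot(inherits(params, "rectified_joint_prior"),
            inherits(partition, "region_partition"),
            inherits(grid, "elicitation_grid"))
  k <- partition$n_intervals
  idx <- .interval_index(grid$muC_values, partition)
  wts <- rowSums(grid$joint_probs)
  rep_vals <- numeric(k)
  for (i in seq_len(k)) {
    sel <- which(idx == i)
    if (length(sel) == 0L) {
      br <- partition$breakpoints
      rep_vals[i] <- if (i == 1L) br[1L] else if (i == k) br[k - 1L] else
        (br[i - 1L] + br[i]) / 2
      message("interval ", i, " contains no grid value; using ",
              signif(rep_vals[i], 4))
    } else if (length(sel) == 1L || !weighted || sum(wts[sel]) == 0) {
      rep_vals[i] <- mean(grid$muC_values[sel])
    } else {
      rep_vals[i] <- sum(grid$muC_values[sel] * wts[sel]) / sum(wts[sel])
    }
  }
  marg <- .rect_interval_probs(params$a, params$b, partition)
  cond <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    v <- max(params$d^2 + params$e * rep_vals[i], 0)
    cond[i, ] <- .rect_interval_probs(params$c * rep_vals[i], sqrt(v),
                                      partition)
  }
  list(E = marg * cond, marginal = marg, conditional = cond,
       rep_values = rep_vals)
}

# observed region probabilities: grid mass summed into regions
.grid_region_probs <- function(grid, partition) {
  k <- partition$n_intervals
  iC <- .interval_index(grid$muC_values, partition)
  iB <- .interval_index(grid$muB_values, partition)
  O <- matrix(0, k, k)
  for (r in seq_along(iC)) {
    for (cl in seq_along(iB)) {
      O[iC[r], iB[cl]] <- O[iC[r], iB[cl]] + grid$joint_probs[r, cl]
    }
  }
  O
}

#' Fit a rectified joint prior to an elicitation grid by least squares
#'
#' Finds the five constants `(a, b, c, d, e)` of the rectified joint
#' prior that minimize the sum of squared differences between the
#' observed region probabilities of the grid and the model-implied
#' expected probabilities over the rectangular regions of the partition.
#' The objective is non-smooth (variance floor and atom terms), so a
#' derivative-free Nelder-Mead search is restarted from multiple
#' randomized perturbations of moment-based initial values, with `b` and
#' `d` kept positive through a log transform.
#'
#' @param grid An [elicitation_grid()].
#' @param partition A [region_partition()].
#' @param starts Number of multistarts (>= 1).
#' @param seed Integer seed making the restarts reproducible.
#' @param weighted Passed to [rectified_region_probs()].
#' @return An object of class `"rectified_fit"`: `params` (the fitted
#'   [rectified_joint_prior()]), `O` and `E` (observed and expected
#'   region probability matrices), `sse`, and optimizer diagnostics.
#' @examples
#' \donttest{
#' fit <- fit_rectified_prior(stampede_grid(), seed = 1)
#' fit$params  # approximately (-0.252, 0.131, 0.816, 0.054, -0.045)
#' }
#' @export
fit_rectified_prior <- function(grid, partition = region_partition(),
                                starts = 30, seed = 1, weighted = TRUE) {
  stopifnot(inherits(grid, "elicitation_grid"),
            inherits(partition, "region_partition"), starts >= 1)
  O <- .grid_region_probs(grid, partition)

  obj <- function(par) {
    p <- rectified_joint_prior(par[1], exp(par[2]), par[3], exp(par[4]),
                               par[5])
    E <- suppressMessages(
      rectified_region_probs(p, partition, grid, weighted = weighted)$E)
    sum((O - E)^2)
  }

  # moment-based centre for the starts: marginal mean/sd of mu_C, the
  # regression slope of mu_B on mu_C, and the residual sd
  pC <- rowSums(grid$joint_probs); pB <- colSums(grid$joint_probs)
  mC <- sum(pC * grid$muC_values); mB <- sum(pB * grid$muB_values)
  vC <- sum(pC * grid$muC_values^2) - mC^2
  vB <- sum(pB * grid$muB_values^2) - mB^2
  cv <- sum(grid$joint_probs * outer(grid$muC_values, grid$muB_values)) -
    mB * mC
  slope <- cv / vC
  resid_sd <- sqrt(max(vB - slope^2 * vC, 1e-4))
  centre <- c(mC, log(sqrt(vC)), slope, log(resid_sd), 0)

  set.seed(seed)
  best <- NULL; values <- numeric(starts)
  for (s in seq_len(starts)) {
    st <- centre + stats::rnorm(5, 0, c(0.1, 0.3, 0.2, 0.3, 0.02))
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    values[s] <- o$value
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("optimizer failed to converge from any start")
  }
  params <- rectified_joint_prior(best$par[1], exp(best$par[2]),
                                  best$par[3], exp(best$par[4]),
                                  best$par[5])
  E <- suppressMessages(
    rectified_region_probs(params, partition, grid, weighted = weighted)$E)
  structure(list(params = params, O = O, E = E,
                 sse = best$value, start_values = values,
                 convergence = best$convergence),
            class = "rectified_fit")
}

#' @export
print.rectified_fit <- function(x, digits = 4, ...) {
  cat("Least-squares fit of the rectified joint prior\n")
  p <- x$params
  cat(sprintf("  a = %.*g, b = %.*g, c = %.*g, d = %.*g, e = %.*g\n",
              digits, p$a, digits, p$b, digits, p$c, digits, p$d,
              digits, p$e))
  cat(sprintf("  sse = %.3e over %d regions\n", x$sse, length(x$O)))
  invisible(x)
}
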