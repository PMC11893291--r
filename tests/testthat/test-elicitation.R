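test_that("the packaged elicitation grid is a valid joint distribution", {
  g <- stampede_grid()
  expect_equal(sum(g$joint_probs), 1, tolerance = 1e-12)
  expect_true(all(g$joint_probs >= 0))
  # marginal of mu_C at log 0.7 is the printed row sum 0.30
  expect_equal(rowSums(g$joint_probs)[3], 0.30, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("joint grids are built as marginal times conditional", {
  v <- log(c(0.6, 0.8, 1.0))
  uni <- grid_from_conditionals(v, v, rep(1 / 3, 3),
                                matrix(1 / 3, 3, 3))
  expect_true(all(abs(uni$joint_probs - 1 / 9) < 1e-12))
  cond <- matrix(c(0.5, 0.3, 0.2,
                   0.1, 0.6, 0.3,
                   0.0, 0.2, 0.8), 3, 3, byrow = TRUE)
  g <- grid_from_conditionals(v, v, c(0.2, 0.5, 0.3), cond)
  expect_equal(g$joint_probs[2, 3], 0.5 * 0.3, tolerance = 1e-12)
  # degenerate marginal concentrates the joint on one row
  d <- grid_from_conditionals(v, v, c(0, 1, 0), cond)
  expect_equal(rowSums(d$joint_probs), c(0, 1, 0), tolerance = 1e-12)
  expect_error(grid_from_conditionals(v, v, c(0.2, 0.5, 0.3),
                                      matrix(0.5, 3, 3)), "sum to 1")
})

test_that("moment matching reproduces the grid moments exactly", {
  g <- stampede_grid()
  mm <- moment_match(g)
  # independent brute-force moment oracle over the 36 cells
  cells <- expand.grid(iC = 1:6, iB = 1:6)
  w <- mapply(function(i, j) g$joint_probs[i, j], cells$iC, cells$iB)
  xB <- g$muB_values[cells$iB]; xC <- g$muC_values[cells$iC]
  expect_equal(mm$mean, c(sum(w * xB), sum(w * xC)), tolerance = 1e-12)
  expect_equal(mm$cov[1, 1], sum(w * xB^2) - sum(w * xB)^2,
               tolerance = 1e-12)
  expect_equal(mm$cov[1, 2], sum(w * xB * xC) - sum(w * xB) * sum(w * xC),
               tolerance = 1e-12)
  # hand-computable symmetric grid
  sym <- elicitation_grid(c(-1, 1), c(-1, 1), matrix(0.25, 2, 2))
  ms <- moment_match(sym)
  expect_equal(ms$mean, c(0, 0), tolerance = 1e-12)
  expect_equal(ms$cov, diag(2), tolerance = 1e-12)
  # zero-variance grid errors
  degen <- elicitation_grid(c(-1, 1), c(-1, 1),
                            matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(moment_match(degen), "positive-definite")
})

test_that("rectified region probabilities are coherent", {
  g <- stampede_grid()
  part <- region_partition()
  p <- rectified_joint_prior(-0.252, 0.131, 0.816, 0.054, -0.045)
  rr <- rectified_region_probs(p, part, g)
  expect_true(all(rr$E >= 0 & rr$E <= 1))
  expect_equal(sum(rr$marginal), 1, tolerance = 1e-10)
  expect_true(all(abs(rowSums(rr$conditional) - 1) < 1e-10))
  # one representative value per interval here, so total mass is exact
  expect_equal(sum(rr$E), 1, tolerance = 1e-10)
  # concentration limit: tiny scales put almost all mass in one region
  tight <- rectified_joint_prior(-0.7, 1e-4, 1, 1e-4, 0)
  rt <- rectified_region_probs(tight, part, g)
  expect_gt(max(rt$E), 0.999)
})

test_that("Monte-Carlo draws from a rectified prior reproduce the regions", {
  part <- region_partition()
  g <- stampede_grid()
  p <- rectified_joint_prior(-0.252, 0.131, 0.816, 0.054, -0.045)
  rr <- rectified_region_probs(p, part, g)
  s <- sample_prior(joint_prior(joint = p), 2e5, seed = 31)
  iC <- findInterval(s$mu_C, part$breakpoints, left.open = TRUE) + 1L
  iB <- findInterval(s$mu_B, part$breakpoints, left.open = TRUE) + 1L
  emp <- matrix(0, 6, 6)
  for (k in seq_along(iC)) emp[iC[k], iB[k]] <- emp[iC[k], iB[k]] + 1
  emp <- emp / sum(emp)
  # the E matrix approximates the conditional at grid representatives, so
  # agreement is within the representative-value approximation error
  expect_lt(max(abs(emp - rr$E)), 0.02)
})

test_that("least-squares fitting recovers known rectified parameters", {
  part <- region_partition()
  g <- stampede_grid()
  truth <- rectified_joint_prior(-0.30, 0.15, 0.7, 0.06, -0.03)
  E <- rectified_region_probs(truth, part, g)$E
  synth <- elicitation_grid(g$muB_values, g$muC_values, E)
  fit <- fit_rectified_prior(synth, part, starts = 15, seed = 32)
  expect_lt(fit$sse, 1e-6)
  expect_equal(fit$params$a, truth$a, tolerance = 0.01)
  expect_equal(fit$params$b, truth$b, tolerance = 0.01)
  expect_equal(fit$params$c, truth$c, tolerance = 0.05)
  expect_equal(fit$params$d, truth$d, tolerance = 0.01)
  expect_equal(fit$params$e, truth$e, tolerance = 0.01)
})

test_that("the fitted optimum is at least a local minimum of the objective", {
  part <- region_partition()
  g <- stampede_grid()
  fit <- fit_rectified_prior(g, part, starts = 10, seed = 33)
  obj <- function(p) {
    sum((fit$O - rectified_region_probs(
      rectified_joint_prior(p[1], p[2], p[3], p[4], p[5]),
      part, g)$E)^2)
  }
  par0 <- with(fit$params, c(a, b, c, d, e))
  expect_equal(obj(par0), fit$sse, tolerance = 1e-10)
  set.seed(34)
  for (i in 1:10) {
    pert <- par0 + rnorm(5, 0, 0.01) * c(1, 1, 1, 1, 1)
    pert[2] <- abs(pert[2]); pert[4] <- abs(pert[4])
    expect_gte(obj(pert), fit$sse - 1e-10)
  }
})

test_that("the grid reader reproduces the packaged table", {
  csv <- system.file("extdata", "table1_grid.csv", package = "bayesubgroup")
  g <- read_elicitation_grid(csv)
  ref <- stampede_grid()
  expect_equal(g$muC_values, ref$muC_values, tolerance = 1e-12)
  expect_equal(unname(g$joint_probs), unname(ref$joint_probs),
               tolerance = 1e-12)
})
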