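test_that("power priors inflate the variance and compose multiplicatively", {
  base <- normal_prior(-0.288, 0.108)
  expect_equal(power_prior(base, 1), base)
  expect_equal(power_prior(base, 0.25)$sd, 0.216, tolerance = 1e-12)
  # the METEOR-style delta prior at k = 0.5
  d <- power_prior(normal_prior(-0.122, 0.334), 0.5)
  expect_equal(d$sd^2, 0.334^2 / 0.5, tolerance = 1e-12)
  # composition
  two_step <- power_prior(power_prior(base, 0.8), 0.5)
  expect_equal(two_step$sd, power_prior(base, 0.4)$sd, tolerance = 1e-12)
  expect_error(power_prior(base, 0), "k")
  expect_error(power_prior(base, 1.2), "k")
})

test_that("difference of two historical results gives the printed prior", {
  ch <- difference_prior(0.54, c(0.32, 0.92), 0.61, c(0.41, 0.89))
  expect_equal(ch$mean, -0.122, tolerance = 1e-3)
  expect_equal(ch$sd, 0.334, tolerance = 1e-3)
  self <- difference_prior(0.7, c(0.5, 0.98), 0.7, c(0.5, 0.98))
  expect_equal(self$mean, 0, tolerance = 1e-12)
  hand <- difference_prior(0.5, c(0.25, 1.0), 1.0, c(0.5, 2.0))
  expect_equal(hand$mean, log(0.5), tolerance = 1e-12)
  expect_equal(hand$sd, sqrt(2) * log(4) / 3.92, tolerance = 1e-12)
})

test_that("prior density evaluates all families on and off support", {
  vague <- vague_prior()
  expect_equal(prior_density(vague, 0, 0, log = TRUE),
               2 * dnorm(0, 0, 10, log = TRUE), tolerance = 1e-12)
  # truncation bound respected
  tr <- joint_prior(muC = normal_prior(0, 10, upper = -0.23),
                    delta = normal_prior(0, 10))
  expect_identical(prior_density(tr, 0, -0.2, log = TRUE), -Inf)
  expect_gt(prior_density(tr, 0, -0.3), 0)
  # discrete support
  dp <- joint_prior(muC = normal_prior(0, 10),
                    delta = discrete_prior(c(-0.5, 0, 0.5)))
  expect_gt(prior_density(dp, -0.5, -1.0), 0)   # delta = 0.5 in the grid
  expect_identical(prior_density(dp, -0.45, -1.0), 0)
  # rectified: no support above zero, atom mass exactly at zero
  rp <- joint_prior(joint = rectified_joint_prior(-0.252, 0.131, 0.816,
                                                  0.054, -0.045))
  expect_identical(prior_density(rp, 0.1, -0.3), 0)
  atom <- 1 - pnorm(0.252 / 0.131)
  expect_equal(prior_density(rp, 0, 0),
               atom * (1 - pnorm(0 / 0.054)), tolerance = 1e-10)
})

test_that("truncated normal density renormalizes to total mass one", {
  for (upper in c(-0.23, 0.5)) {
    pr <- joint_prior(muC = normal_prior(-0.1, 0.4, upper = upper),
                      delta = normal_prior(0, 1e6))
    x <- seq(-6, upper, length.out = 20001)
    dens <- prior_density(pr, x + 0.123, x) /
      dnorm(0.123, 0, 1e6)  # divide out the (flat) delta factor
    dx <- diff(x[1:2])
    mass <- (sum(dens) - 0.5 * (dens[1] + dens[length(dens)])) * dx
    expect_equal(mass, 1, tolerance = 1e-4)
  }
})

test_that("sampled prior moments match the specification", {
  s <- sample_prior(vague_prior(), 2e5, seed = 11)
  expect_equal(var(s$mu_C), 100, tolerance = 0.05)
  # Var(mu_B) = Var(mu_C) + b^2 = 200 for the vague spec
  expect_equal(var(s$mu_B), 200, tolerance = 0.05)
  # Cov(mu_B, mu_C) = Var(mu_C)
  expect_equal(cov(s$mu_B, s$mu_C), 100, tolerance = 0.06)
  # implied prior correlation is Var(muC)/sqrt(Var(muC)(Var(muC)+b^2))
  expect_equal(cor(s$mu_B, s$mu_C), 100 / sqrt(100 * 200), tolerance = 0.02)
  # identity holds exactly draw by draw
  expect_identical(s$delta, s$mu_B - s$mu_C)
})

test_that("prior sampling and density agree for a truncated component", {
  pr <- joint_prior(muC = normal_prior(-0.2, 0.3, upper = -0.1),
                    delta = normal_prior(0, 0.5))
  s <- sample_prior(pr, 2e5, seed = 12)
  expect_lte(max(s$mu_C), -0.1)
  # empirical interval mass vs renormalized normal
  p_emp <- mean(s$mu_C > -0.4 & s$mu_C <= -0.2)
  p_th <- (pnorm(-0.2, -0.2, 0.3) - pnorm(-0.4, -0.2, 0.3)) /
    pnorm(-0.1, -0.2, 0.3)
  expect_equal(p_emp, p_th, tolerance = 0.01)
})

test_that("spike-and-slab prior draws carry the latent structure", {
  pr <- joint_prior(muC = normal_prior(0, 10),
                    delta = spike_slab_prior(1))
  s <- sample_prior(pr, 2e5, seed = 13)
  expect_true(all(s$R %in% 0:1))
  expect_equal(mean(s$R), 0.5, tolerance = 0.01)  # E[P] = 1/2
  expect_equal(sd(s$delta[s$R == 1]), 1, tolerance = 0.02)
  expect_equal(sd(s$delta[s$R == 0]), 0.01, tolerance = 0.02)
  expect_warning(spike_slab_prior(0.05), "poorly separated")
})

test_that("analytic slab weight behaves as the mixture theory predicts", {
  # identical components -> weight 1/2
  expect_equal(slab_weight(0, 0.04, 1e-4), 0.5, tolerance = 1e-12)
  # weight vanishes as the slab becomes arbitrarily diffuse, monotonically
  # beyond its maximum
  taus <- 10^seq(-2, 6, length.out = 40)
  w <- slab_weight(0.2, 0.06, taus)
  peak <- which.max(w)
  expect_true(all(diff(w[peak:length(w)]) < 0))
  expect_lt(w[length(w)], 1e-2)
  # a large interaction estimate favours the slab at moderate tau
  expect_gt(slab_weight(1.5, 0.04, 1), 0.5)
  expect_error(slab_weight(0, -1, 1), "positive")
})

test_that("rectified normal sampler has the advertised atom at zero", {
  expect_equal(mean(rrectnorm(2e5, -10, 0.1) == 0), 0, tolerance = 1e-6)
  set.seed(14)
  expect_equal(mean(rrectnorm(2e5, 0, 1) == 0), 0.5, tolerance = 0.01)
  set.seed(15)
  atom <- mean(rrectnorm(2e5, -0.252, 0.131) == 0)
  expect_lt(abs(atom - (1 - pnorm(0.252 / 0.131))), 0.005)
  expect_true(all(rrectnorm(100, 1, 1) <= 0))
  # CDF consistency
  expect_equal(prectnorm(-0.3, -0.252, 0.131),
               pnorm(-0.3, -0.252, 0.131), tolerance = 1e-12)
  expect_identical(prectnorm(0, -0.252, 0.131), 1)
})

test_that("rectified joint prior draws respect the conditional structure", {
  rp <- rectified_joint_prior(-0.252, 0.131, 0.816, 0.054, -0.045)
  s <- sample_prior(joint_prior(joint = rp), 2e5, seed = 16)
  expect_true(all(s$mu_B <= 0) && all(s$mu_C <= 0))
  expect_lt(abs(mean(s$mu_C == 0) - (1 - pnorm(0.252 / 0.131))), 0.005)
  # conditional mean of the unrectified mu_B is c * mu_C; check on a slice
  # where rectification is negligible (mu_C well below 0)
  sl <- s[s$mu_C < -0.35 & s$mu_C > -0.45, ]
  expect_equal(mean(sl$mu_B), mean(0.816 * sl$mu_C), tolerance = 0.02)
})
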