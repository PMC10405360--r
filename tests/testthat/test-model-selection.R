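test_that("posterior model probabilities reproduce the reference comparisons", {
  # baobab target-enrichment models: the two with the within-Madagascar
  # introgression split 0.27 / 0.73
  adansonia <- c(none = -1701076, wx = -1701050, yz = -1700996,
                 wx_yz = -1700995)
  p <- posterior_model_probs(adansonia)
  expect_equal(round(unname(p[3:4]), 2), c(0.27, 0.73))
  expect_equal(signif(unname(p[2]), 2), 9.5e-25)

  jaltomata <- c(-1914473, -1914404, -1914369)
  pj <- posterior_model_probs(jaltomata)
  expect_equal(signif(unname(pj[1]), 2), 6.8e-46)
  expect_equal(signif(unname(pj[2]), 2), 6.3e-16)
  expect_gt(unname(pj[3]), 0.999)
})

test_that("model probabilities are invariant to constant shifts and weights", {
  x <- c(-10, -12, -9)
  expect_equal(posterior_model_probs(x), posterior_model_probs(x + 1000))
  expect_equal(unname(posterior_model_probs(c(-5, -5))), c(0.5, 0.5))
  w <- posterior_model_probs(c(0, 0), weights = c(3, 1))
  expect_equal(unname(w), c(0.75, 0.25))
  expect_error(posterior_model_probs(numeric()), "no models")
  tab <- model_comparison(c("m1", "m2"), c(-5, -5), se = c(1, 1))
  expect_equal(tab$p_model, c(0.5, 0.5))
})

test_that("Savage-Dickey matches its algebra and the analytic Beta ratio", {
  # back-solved posterior null masses reproduce the reference Bayes factors
  expect_equal(round(savage_dickey_bf(
    c(runif(8260, 0, 0.01), runif(1740, 0.011, 1)), 0.01)$b21, 4), 0.0121)
  expect_equal(round(0.001 / 0.2326, 4), 0.0043)
  x <- c(runif(2326, 0, 0.001), runif(7674, 0.002, 1))
  expect_equal(round(savage_dickey_bf(x, 0.001)$b21, 4), 0.0043)

  # prior == posterior gives B21 = 1
  set.seed(2)
  u <- runif(2e5)
  expect_equal(savage_dickey_bf(u, 0.3)$b21, 1, tolerance = 0.02)

  # i.i.d. Beta posteriors across a parameter grid match eps / pbeta(eps)
  set.seed(3)
  for (ab in list(c(1, 5), c(2, 8), c(0.5, 3))) {
    n <- 4e4
    draws <- rbeta(n, ab[1], ab[2])
    for (eps in c(0.01, 0.05)) {
      got <- savage_dickey_bf(draws, eps)
      p <- pbeta(eps, ab[1], ab[2])
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(got$post_mass - p), 3 * se)
      expect_equal(got$b21, eps / got$post_mass)
    }
  }

  # no draws below eps: conservative lower bound flagged
  res <- savage_dickey_bf(runif(100, 0.5, 1), 0.01)
  expect_equal(res$bound, "lower")
  expect_equal(res$b21, 0.01 * 100)
  expect_error(savage_dickey_bf(runif(10), 1.5), "eps")
})

test_that("stepping-stone recovers a known normal-normal evidence", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1): log evidence available in closed form
  set.seed(4)
  n <- 20
  y <- rnorm(n, 0.5, 1)
  # z = integral of prod N(y|mu,1) N(mu|0,1) dmu, available in closed form
  s2 <- 1 / (n + 1)
  mu_hat <- sum(y) * s2
  logml_exact <- -n / 2 * log(2 * pi) + 0.5 * log(s2) -
    0.5 * (sum(y^2) - mu_hat^2 / s2)
  ss <- stepping_stone_generic(
    loglik = function(mu) sum(dnorm(y, mu, 1, log = TRUE)),
    logprior = function(mu) dnorm(mu, 0, 1, log = TRUE),
    init = 0, step = 0.5, steps = 16, nsamples = 1500, burnin = 300, seed = 5
  )
  expect_lt(abs(ss$logml - logml_exact), 2 * ss$se)
  expect_true(all(ss$steps$converged))
})

test_that("stepping-stone runs on the coalescent model and is seed-stable", {
  spec <- scenario_spec("sister", "msc", theta = 0.01, nloci = 4, L = 60,
                        nseq = 2, seed = 51)
  ds <- generate_dataset(spec)
  pri <- prior_spec(0.01, 0.03)
  cfg <- mcmc_config(burnin = 150, nsamples = 300, thin = 1, seed = 1)
  ss1 <- stepping_stone_logml(ds$loci, ds$cfg, ds$net, "msc", pri,
                              steps = 4, config = cfg)
  expect_true(is.finite(ss1$logml))
  expect_lt(ss1$logml, 0)
  cfg2 <- mcmc_config(burnin = 150, nsamples = 300, thin = 1, seed = 99)
  ss2 <- stepping_stone_logml(ds$loci, ds$cfg, ds$net, "msc", pri,
                              steps = 4, config = cfg2)
  expect_lt(abs(ss1$logml - ss2$logml),
            3 * sqrt(ss1$se^2 + ss2$se^2) + 2)
  expect_error(stepping_stone_logml(ds$loci, ds$cfg, ds$net, "msc", pri,
                                    steps = 1, config = cfg), "at least 2")
})
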