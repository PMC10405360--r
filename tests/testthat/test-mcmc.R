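test_that("with the likelihood off the sampler reproduces its priors", {
  net <- scenario_network("sister", 0.01, rate = 0.2, mode = "msci")
  pri <- prior_spec(theta_mean = 0.01, tau_mean = 0.03)
  tr <- run_mcmc(list(), sample_config(c(A = 1)), net, model = "msci",
                 priors = pri, config = quick_mcmc(5, 2000, 30000, 1),
                 likelihood = FALSE)
  # theta ~ IG(3, 0.02): mean 0.01; tau_r ~ IG(3, 0.06): mean 0.03;
  # phi ~ U(0,1)
  n_eff <- ess(tr$theta_A)
  expect_lt(abs(mean(tr$theta_A) - 0.01), 3 * stats::sd(tr$theta_A) / sqrt(n_eff))
  n_eff <- ess(tr$tau_r)
  expect_lt(abs(mean(tr$tau_r) - 0.03), 3 * stats::sd(tr$tau_r) / sqrt(n_eff))
  n_eff <- ess(tr$phi_h)
  expect_lt(abs(mean(tr$phi_h) - 0.5), 3 * stats::sd(tr$phi_h) / sqrt(n_eff))
  # order constraints always hold; interior times flat given the root:
  # E[tau_t / tau_r] = 1/2 for the sister network (tau_h < tau_t < tau_s)
  expect_true(all(tr$tau_t < tr$tau_s & tr$tau_s < tr$tau_r &
                    tr$tau_h < tr$tau_t))
})

test_that("model and network must agree, and data must match the Imap", {
  msci <- scenario_network("sister", 0.01, rate = 0.2, mode = "msci")
  msc <- scenario_network("sister", 0.01, mode = "msc")
  pri <- prior_spec(0.01, 0.03)
  expect_error(run_mcmc(list(), sample_config(c(A = 1)), msc, "msci",
                        priors = pri), "hybrid")
  expect_error(run_mcmc(list(), sample_config(c(A = 1)), msci, "msc",
                        priors = pri), "without hybrid")
  im <- scenario_network("sister", 0.01, rate = 0.1, mode = "im")
  expect_error(run_mcmc(list(), sample_config(c(A = 1)), im, "msc",
                        priors = pri), "migration")
  ld <- locus_data(c(x1 = "ACGT", b1 = "ACGT"))
  expect_error(run_mcmc(list(ld), sample_config(c(A = 1, B = 1)), msc, "msc",
                        priors = pri, config = quick_mcmc()), "missing")
})

test_that("the cached likelihoods equal fresh recomputation after sampling", {
  spec <- scenario_spec("sister", "msci", theta = 0.01, rate = 0.2,
                        nloci = 6, L = 80, nseq = 2, seed = 41)
  ds <- generate_dataset(spec)
  pri <- prior_spec(0.01, 0.03)
  tr <- run_mcmc(ds$loci, ds$cfg, ds$net, model = "msci", priors = pri,
                 config = quick_mcmc(2, 300, 300, 1))
  expect_lt(attr(tr, "audit"), 1e-8)
})

test_that("posterior ranks of generating parameters are uniform (SBC)", {
  # joint-distribution calibration at tiny scale: draw truth from the prior,
  # simulate data, fit, and record where the truth ranks in its posterior
  ndat <- 50
  ranks <- matrix(NA_real_, ndat, 3,
                  dimnames = list(NULL, c("tau_r", "theta_A", "theta_r")))
  set.seed(99)
  for (d in seq_len(ndat)) {
    tau <- rinvgamma(1, 3, 2 * 0.005)
    th <- rinvgamma(3, 3, 2 * 0.01)
    net <- species_network(tibble::tibble(
      name = c("A", "B", "r"), parent = c("r", "r", NA),
      age = c(0, 0, tau), theta = th
    ))
    cfg <- sample_config(c(A = 2, B = 2))
    loci <- lapply(seq_len(20), function(i) {
      evolve_jc69(simulate_gene_tree(net, cfg), 100)
    })
    tr <- run_mcmc(loci, cfg, net, model = "msc",
                   priors = prior_spec(0.01, 0.005),
                   config = quick_mcmc(d, 500, 400, 4))
    ranks[d, ] <- c(mean(tr$tau_r < tau), mean(tr$theta_A < th[1]),
                    mean(tr$theta_r < th[3]))
  }
  for (p in colnames(ranks)) {
    expect_gt(suppressWarnings(
      stats::ks.test(ranks[, p], stats::punif)$p.value), 0.005)
  }
})

test_that("convergence_check reports discrepancy, ESS and bimodality", {
  set.seed(1)
  base <- tibble::tibble(tau_r = rnorm(500, 1, 0.1),
                         theta_A = rgamma(500, 5, 100))
  t1 <- base
  class(t1) <- c("mscoal_trace", class(t1))
  rep <- convergence_check(list(t1, t1))
  expect_equal(rep$discrepancy, c(0, 0))
  expect_false(any(rep$bimodal))

  stuck <- t1
  stuck$tau_r <- rep(1, 500)
  expect_equal(ess(stuck$tau_r), 1)

  bimod <- t1
  bimod$tau_r <- c(rnorm(250, 0, 0.05), rnorm(250, 3, 0.05))
  rep2 <- convergence_check(list(bimod, bimod))
  expect_true(rep2$bimodal[rep2$parameter == "tau_r"])

  t2 <- t1
  attr(t1, "model") <- "msc"
  attr(t2, "model") <- "msci"
  expect_error(convergence_check(list(t1, t2)), "different models")
  expect_error(convergence_check(list(t1)), "at least 2")
})

test_that("independent prior-sampling runs agree across seeds", {
  net <- scenario_network("sister", 0.01, mode = "msc")
  pri <- prior_spec(0.01, 0.03)
  traces <- lapply(c(11, 12), function(s) {
    run_mcmc(list(), sample_config(c(A = 1)), net, "msc", priors = pri,
             config = quick_mcmc(s, 1000, 8000, 1), likelihood = FALSE)
  })
  rep <- convergence_check(traces)
  expect_true(all(rep$discrepancy < 0.2))
})

test_that("traces round-trip through TSV and tidiers work", {
  net <- scenario_network("sister", 0.01, mode = "msc")
  pri <- prior_spec(0.01, 0.03)
  tr <- run_mcmc(list(), sample_config(c(A = 1)), net, "msc", priors = pri,
                 config = quick_mcmc(1, 200, 200, 1), likelihood = FALSE)
  path <- withr::local_tempfile()
  write_trace(tr, path)
  back <- read_trace(path)
  for (cl in names(tr)) expect_equal(back[[cl]], tr[[cl]], tolerance = 1e-12)
  expect_equal(attr(back, "model"), "msc")

  td <- generics::tidy(tr)
  expect_true(all(c("parameter", "mean", "hpd_lo", "hpd_hi") %in% names(td)))
  expect_true(all(td$hpd_lo <= td$mean & td$mean <= td$hpd_hi))
  gl <- generics::glance(tr)
  expect_equal(gl$nsamples, nrow(tr))
  p <- ggplot2::autoplot(tr, params = c("tau_r", "theta_A"))
  expect_s3_class(p, "ggplot")
})
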