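test_that("within-population pairwise coalescence follows Exp(2/theta)", {
  net <- one_pop_net(theta = 0.01)
  cfg <- sample_config(c(A = 2))
  set.seed(7)
  tt <- replicate(4000, max(simulate_gene_tree(net, cfg)$nodes$age))
  # mean pairwise divergence 2 E[T] = theta, within 3 MC standard errors
  se <- stats::sd(2 * tt) / sqrt(length(tt))
  expect_lt(abs(mean(2 * tt) - 0.01), 3 * se)
  expect_gt(stats::ks.test(tt, stats::pexp, 2 / 0.01)$p.value, 0.01)
})

test_that("waiting times with k lineages follow Exp(k(k-1)/theta)", {
  net <- one_pop_net(theta = 0.02)
  cfg <- sample_config(c(A = 4))
  set.seed(8)
  first <- replicate(4000, min(simulate_gene_tree(net, cfg)$nodes$age[5:7]))
  expect_gt(stats::ks.test(first, stats::pexp, 4 * 3 / 0.02)$p.value, 0.01)
})

test_that("phi = 1 forces every recipient lineage through the donor path", {
  net <- scenario_network("sister", theta = 0.01, rate = 1, mode = "msci")
  cfg <- sample_config(c(A = 2, B = 1))
  set.seed(9)
  for (i in 1:20) {
    gt <- simulate_gene_tree(net, cfg)
    ch <- gt$choices[gt$choices$node %in% 1:2, ]
    # tip lineages of A still alive at tau_h must all take the donor path
    expect_true(all(ch$choice == "donor"))
  }
})

test_that("hybrid-path choice frequency matches phi", {
  net <- scenario_network("sister", theta = 0.01, rate = 0.2, mode = "msci")
  cfg <- sample_config(c(A = 1, B = 1))
  set.seed(10)
  n <- 3000
  hits <- replicate(n, {
    gt <- simulate_gene_tree(net, cfg)
    any(gt$choices$node == 1 & gt$choices$choice == "donor")
  })
  expect_lt(abs(mean(hits) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("MSci with phi = 0 and IM with M = 0 are seed-for-seed MSC", {
  cfg <- sample_config(c(A = 2, B = 2, C = 2, D = 2))
  msc <- scenario_network("sister", 0.01, mode = "msc")
  msci0 <- scenario_network("sister", 0.01, rate = 0, mode = "msci")
  im0 <- scenario_network("sister", 0.01, rate = 0, mode = "im")
  for (seed in c(1, 23, 456)) {
    g0 <- simulate_gene_tree(msc, cfg, seed = seed)
    g1 <- simulate_gene_tree(msci0, cfg, seed = seed)
    g2 <- simulate_gene_tree(im0, cfg, seed = seed)
    expect_identical(g1$nodes$parent, g0$nodes$parent)
    expect_equal(g1$nodes$age, g0$nodes$age, tolerance = 1e-15)
    expect_identical(g2$nodes$parent, g0$nodes$parent)
    expect_equal(g2$nodes$age, g0$nodes$age, tolerance = 1e-15)
  }
})

test_that("locus sets are reproducible and locus-index stable", {
  net <- scenario_network("nonsister", 0.01, rate = 0.2, mode = "msci")
  cfg <- sample_config(c(A = 2, B = 2, C = 2, D = 2))
  a <- simulate_locus_set(net, cfg, nloci = 5, seed = 77)
  b <- simulate_locus_set(net, cfg, nloci = 5, seed = 77)
  expect_equal(a, b)
  wide <- simulate_locus_set(net, cfg, nloci = 8, seed = 77)
  expect_equal(wide[1:5], a) # locus i independent of nloci
  expect_error(simulate_locus_set(net, cfg, nloci = 0, seed = 1), "nloci")
})

test_that("cross-species coalescence cannot predate the species MRCA", {
  # C and D never exchange genes in the sister scenario: their lineages
  # cannot meet below tau_r
  net <- scenario_network("sister", 0.01, rate = 0.2, mode = "msci")
  cfg <- sample_config(c(C = 2, D = 2))
  set.seed(11)
  for (i in 1:50) {
    nd <- simulate_gene_tree(net, cfg)$nodes
    # species sets below each node, bottom-up
    below <- lapply(seq_len(nrow(nd)), function(v) nd$species[v])
    for (v in order(nd$age)) {
      if (!is.na(nd$parent[v])) {
        below[[nd$parent[v]]] <- union(below[[nd$parent[v]]], below[[v]])
      }
    }
    mixed <- vapply(below, function(s) all(c("C", "D") %in% s), TRUE)
    expect_gte(min(nd$age[mixed]), 0.03 - 1e-12)
  }
})

test_that("zero sampled lineages and ghost-tagged samples are rejected", {
  net <- scenario_network("ghost", 0.01, rate = 0.2, mode = "msci")
  expect_error(simulate_gene_tree(net, sample_config(integer())),
               "no lineages")
  bad <- tibble::tibble(tag = "o1", species = "O")
  class(bad) <- c("sample_config", class(bad))
  expect_error(simulate_gene_tree(net, bad), "ghost")
})

test_that("migration events are logged with times inside the band", {
  net <- scenario_network("sister", 0.01, rate = 1, mode = "im")
  cfg <- sample_config(c(A = 2, B = 2))
  set.seed(12)
  logs <- event_log(simulate_locus_set(net, cfg, nloci = 30, seed = 5))
  expect_gt(nrow(logs), 0)
  expect_true(all(logs$event == "migration"))
  expect_true(all(logs$from == "A" & logs$to == "B"))
  expect_true(all(logs$time <= 0.01 + 1e-12))
})
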