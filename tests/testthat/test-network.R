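test_that("plain Newick parses to an ultrametric tree with given ages", {
  net <- parse_network("((A:1,B:1):1,C:2);", attributes = list(theta = 0.01))
  expect_setequal(network_tips(net), c("A", "B", "C"))
  expect_equal(max(net$nodes$age), 2)
  expect_equal(unique(net$nodes$theta), 0.01)
})

test_that("hybrid edges parse with phi from the minor edge", {
  s <- paste0("(((A:0.005)h#H1:0.005,(h#H1:0::0.2,B:0.005)g:0.005)t:0.01,",
              "C:0.02)s[&theta=0.02];")
  net <- parse_network(s, attributes = list(theta = 0.01))
  expect_equal(nrow(net$hybrids), 1)
  expect_equal(net$hybrids$phi, 0.2)
  expect_equal(net$hybrids$donor, "g")
  expect_equal(net$hybrids$recipient, "h")
  expect_equal(net$nodes$theta[net$nodes$name == "s"], 0.02)
  expect_equal(net$nodes$age[net$nodes$name == "h"], 0.005)
})

test_that("malformed networks are rejected with informative errors", {
  expect_error(parse_network("((A:1)h#H1:1,B:2);", list(theta = 0.01)),
               "exactly twice")
  expect_error(
    parse_network("(((A:0.5)h#H1:0.5,(h#H1:0::1.5,B:0.5)g:0.5)t:1,C:2);",
                  list(theta = 0.01)),
    "phi")
  expect_error(parse_network("((A:1,B:2):1,C:2);", list(theta = 0.01)),
               "ultrametric")
  expect_error(parse_network("((A:1,B:1):1,C:2);"), "theta")
  expect_error(species_network(tibble::tibble(
    name = c("A", "r"), parent = c("r", NA), age = c(0.5, 1), theta = 0.01
  )), "ultrametric|younger")
})

test_that("write/parse round-trips preserve topology, ages, theta and phi", {
  for (scen in c("sister", "nonsister", "ghost")) {
    net <- scenario_network(scen, theta = 0.01, rate = 0.2, mode = "msci")
    net2 <- parse_network(write_network(net))
    net2$nodes$ghost <- net$nodes$ghost[match(net2$nodes$name,
                                              net$nodes$name)]
    expect_network_equal(net, net2)
  }
  set.seed(42)
  for (i in 1:100) {
    net <- random_network(5)
    expect_network_equal(net, parse_network(write_network(net)))
  }
})

test_that("hybrid edge times must sit strictly inside both branches", {
  nodes <- tibble::tibble(
    name = c("A", "B", "h", "g", "r"),
    parent = c("h", "g", "r", "r", NA),
    age = c(0, 0, 0.005, 0.004, 0.01),
    theta = 0.01
  )
  hyb <- tibble::tibble(label = "H1", donor = "g", recipient = "h", phi = 0.3)
  expect_error(species_network(nodes, hybrids = hyb), "same age")
})

test_that("major_tree collapses hybrids and drops ghost tips", {
  net <- scenario_network("ghost", theta = 0.01, rate = 0.2, mode = "msci")
  mt <- major_tree(net)
  expect_setequal(network_tips(mt), c("A", "B", "C", "D"))
  expect_equal(nrow(mt$hybrids), 0)
  expect_equal(max(mt$nodes$age), 0.03) # ghost root (4 theta) pruned away
  direct <- scenario_network("ghost", theta = 0.01, mode = "msc")
  expect_network_equal(mt, direct)
})

test_that("Imap round-trips and validates against the network", {
  path <- withr::local_tempfile()
  writeLines(c("a1 A", "a2 A", "b1 B"), path)
  cfg <- read_imap(path)
  expect_equal(config_counts(cfg), c(A = 2L, B = 1L))
  write_imap(cfg, path)
  expect_equal(read_imap(path), cfg)

  writeLines(character(), path)
  expect_equal(nrow(read_imap(path)), 0)

  writeLines(c("a1 A", "a1 B"), path)
  expect_error(read_imap(path), "duplicate")

  net <- scenario_network("ghost", theta = 0.01, rate = 0.2, mode = "msci")
  writeLines(c("a1 A", "o1 O"), path)
  expect_error(read_imap(path, net = net), "ghost")
  writeLines(c("a1 A", "x1 X"), path)
  expect_error(read_imap(path, net = net), "absent")
})

test_that("migration bands default to the populations' full coexistence", {
  net <- scenario_network("nonsister", theta = 0.01, rate = 0.1, mode = "im")
  expect_equal(net$bands$start, 0)
  expect_equal(net$bands$end, 0.02) # C-D coexistence = tau_s = 2 theta
  expect_error(
    species_network(two_species_net()$nodes, bands = tibble::tibble(
      donor = "A", recipient = "A", rate = 1, start = 0, end = 0.01
    )), "donor equals recipient")
})
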