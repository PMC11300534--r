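test_that("tree probabilities factorize and normalize over the support", {
  # uniform 3-taxon CCD gives every topology probability 1/3
  u <- uniform_sbn(full_subsplit_support(c("A", "B", "C")))
  for (tau in enumerate_topologies(c("A", "B", "C"))) {
    expect_equal(tree_probability(u, tau), 1 / 3)
  }
  # out-of-support subsplit gives zero
  one <- estimate_from_trees(list(parse_newick("((A,B),C);")), "ccd", min_count = 1)
  expect_equal(tree_probability(one, parse_newick("((A,C),B);")), 0)
  # random CCDs and SCDs: enumerated masses equal tree_probability, sum to 1
  set.seed(601)
  for (kind in c("ccd", "scd")) {
    d <- random_sbn(sprintf("t%d", 1:5), kind, concentration = 0.8)
    td <- enumerate_support_trees(d)
    expect_equal(sum(td$prob), 1, tolerance = 1e-12)
    for (k in names(td$trees)[seq(1, length(td$trees), by = 11)]) {
      expect_equal(tree_probability(d, td$trees[[k]]), unname(td$prob[k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("top-down sampling has the marginal law of tree_probability", {
  # point mass
  one <- estimate_from_trees(list(parse_newick("((A,B),C);")), "scd", min_count = 1)
  expect_identical(write_newick(sample_topology(one, seed = 1)),
                   write_newick(parse_newick("((A,B),C);")))
  # uniform 3-taxon CCD: frequencies within 3 binomial SE of 1/3
  u <- uniform_sbn(full_subsplit_support(c("A", "B", "C")))
  n <- 30000
  draws <- sample_topologies(u, n, seed = 602)
  freq <- table(vapply(draws, topology_key, ""))
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_length(freq, 3)
  expect_true(all(abs(freq / n - 1 / 3) < 3 * se))
  # fixed seed reproduces the sequence
  a <- sample_topologies(u, 5, seed = 603)
  b <- sample_topologies(u, 5, seed = 603)
  expect_identical(vapply(a, topology_key, ""), vapply(b, topology_key, ""))
})

test_that("estimation recovers weighted relative frequencies with trimming", {
  trees <- list(parse_newick("((A,B),C);"), parse_newick("((A,B),C);"),
                parse_newick("((A,C),B);"))
  d <- estimate_from_trees(trees, "ccd", min_count = 1)
  expect_equal(unname(d$cond["C|A,B"]), 2 / 3)
  expect_equal(unname(d$cond["B|A,C"]), 1 / 3)
  expect_equal(unname(d$cond["A|B"]), 1)
  # min_count = 2 trims the topology seen once
  d2 <- estimate_from_trees(trees, "ccd", min_count = 2)
  expect_setequal(names(d2$cond), c("C|A,B", "A|B"))
  expect_equal(unname(d2$cond), c(1, 1))
  expect_error(estimate_from_trees(trees[3], "ccd", min_count = 2), "min_count")
  # self-consistency: estimating from an SBN's exact enumeration recovers it
  set.seed(604)
  for (kind in c("ccd", "scd")) {
    d0 <- random_sbn(sprintf("t%d", 1:5), kind, support_source = "trees",
                     n_support_trees = 4)
    td <- enumerate_support_trees(d0)
    est <- estimate_from_trees(unname(td$trees), kind, weights = unname(td$prob),
                               min_count = 0)
    expect_setequal(names(est$cond), names(d0$cond))
    expect_equal(max(abs(est$cond[names(d0$cond)] - d0$cond)), 0, tolerance = 1e-12)
  }
})

test_that("unconditional subsplit, PCSP and path probabilities match enumeration", {
  set.seed(605)
  for (kind in c("ccd", "scd")) {
    d <- random_sbn(sprintf("t%d", 1:5), kind, support_source = "trees",
                    n_support_trees = 4)
    td <- enumerate_support_trees(d)
    u <- sbn_unconditional(d)
    for (k in names(u$split)) {
      expect_equal(unname(u$split[k]), oracle_subsplit_prob(td, k), tolerance = 1e-12)
    }
    if (kind == "scd") {
      for (k in names(u$pcsp)) {
        expect_equal(unname(u$pcsp[k]), oracle_pcsp_prob(td, k), tolerance = 1e-12)
      }
      # unconditional_pcsp_prob agrees and validates its input
      p1 <- d$support$pcsps[[1]]
      expect_equal(unconditional_pcsp_prob(d, p1$parent, p1$child),
                   unname(u$pcsp[1]), tolerance = 1e-12)
    }
    # path probabilities q(a ->* d) over all support pairs; the convention
    # is zero whenever d is not a valid descendant of a
    skeys <- names(d$support$splits)
    for (ak in skeys) {
      a <- d$support$splits[[ak]]
      for (dk in skeys) {
        dsub <- d$support$splits[[dk]]
        oracle <- if (is_descendant(a, dsub)) oracle_pair_prob(td, ak, dk) else 0
        expect_equal(path_probability(d, a, dsub), oracle, tolerance = 1e-12)
      }
    }
  }
  # q(a ->* a) = q(a); non-descendants get 0
  d <- random_sbn(c("A", "B", "C", "D"), "scd", seed = 606)
  s <- parse_subsplit_key("A,B|C,D")
  expect_equal(path_probability(d, s, s), unconditional_subsplit_prob(d, s))
  expect_equal(path_probability(d, parse_subsplit_key("A|B"),
                                parse_subsplit_key("C|D")), 0)
})

test_that("closed-form KL equals the explicit oracle", {
  # the 3-taxon hand value via CCDs
  tops3 <- enumerate_topologies(c("A", "B", "C"))
  p <- estimate_from_trees(tops3, "ccd", weights = rep(1 / 3, 3), min_count = 0)
  q <- estimate_from_trees(tops3, "ccd", weights = c(1 / 2, 1 / 4, 1 / 4), min_count = 0)
  expect_equal(kl_ccd(p, p), 0)
  expect_equal(kl_ccd(p, q), (5 * log(2) - 3 * log(3)) / 3, tolerance = 1e-12)
  # the same distributions as SCDs give the same divergence
  ps <- estimate_from_trees(tops3, "scd", weights = rep(1 / 3, 3), min_count = 0)
  qs <- estimate_from_trees(tops3, "scd", weights = c(1 / 2, 1 / 4, 1 / 4), min_count = 0)
  expect_equal(kl_scd(ps, qs), kl_ccd(p, q), tolerance = 1e-12)
  # random pairs on 5 taxa agree with the enumeration oracle
  set.seed(607)
  for (kind in c("ccd", "scd")) {
    for (i in 1:4) {
      support <- if (kind == "ccd") full_subsplit_support(sprintf("t%d", 1:5))
                 else full_pcsp_support(sprintf("t%d", 1:5))
      blocks <- if (kind == "ccd") support$by_clade else support$by_focal
      mk <- function() {
        cond <- numeric(0)
        for (keys in blocks) { v <- rgamma(length(keys), 1) + 0.05; cond[keys] <- v / sum(v) }
        if (kind == "ccd") ccd(support, cond) else scd(support, cond)
      }
      dp <- mk(); dq <- mk()
      expect_equal(kl_sbn(dp, dq),
                   kl_divergence_explicit(enumerate_support_trees(dp),
                                          enumerate_support_trees(dq)),
                   tolerance = 1e-10)
    }
  }
  # support incompatibility raises
  narrow <- estimate_from_trees(tops3[1:2], "ccd", min_count = 0)
  wide <- estimate_from_trees(tops3, "ccd", min_count = 0)
  expect_error(kl_ccd(wide, narrow), "support incompatibility")
})

test_that("SBN JSON serialization round-trips distributions and supports", {
  set.seed(608)
  for (kind in c("ccd", "scd")) {
    d <- random_sbn(sprintf("t%d", 1:4), kind, support_source = "trees",
                    n_support_trees = 3)
    path <- tempfile(fileext = ".json")
    write_sbn_json(d, path)
    d2 <- read_sbn_json(path)
    expect_identical(sbn_taxa(d2), sbn_taxa(d))
    expect_setequal(names(d2$cond), names(d$cond))
    expect_equal(max(abs(d2$cond[names(d$cond)] - d$cond)), 0)
    # bare support
    spath <- tempfile(fileext = ".json")
    write_sbn_json(d$support, spath)
    s2 <- read_sbn_json(spath)
    expect_false(inherits(s2, "sbn"))
    expect_identical(support_size(s2), support_size(d$support))
  }
})
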