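test_that("restriction to the full taxon set leaves conditionals unchanged", {
  set.seed(701)
  d <- random_sbn(sprintf("t%d", 1:4), "ccd", concentration = 0.8)
  r <- restrict_ccd(d, sbn_taxa(d))
  expect_equal(max(abs(r$cond[names(d$cond)] - d$cond)), 0, tolerance = 1e-12)
  ds <- random_sbn(sprintf("t%d", 1:4), "scd", concentration = 0.8)
  rs <- restrict_scd(ds, sbn_taxa(ds))
  expect_setequal(names(rs$cond), names(ds$cond))
  expect_equal(max(abs(rs$cond[names(ds$cond)] - ds$cond)), 0, tolerance = 1e-12)
})

test_that("point-mass SCD restriction bridges a trivially-restricting parent", {
  # dropping C removes the A,B|C node, so the restricted parent of A|B
  # becomes the former grandparent A,B,C|D
  d <- estimate_from_trees(list(parse_newick("(((A,B),C),D);")), "scd", min_count = 1)
  r <- restrict_scd(d, c("A", "B", "D"))
  expect_setequal(names(r$cond), c("|A,B,D -> D|A,B", "D|A,B -> A|B"))
  expect_equal(unname(r$cond), c(1, 1))
})

test_that("uniform CCD over 4-taxon trees restricts to uniform over 3", {
  u <- uniform_sbn(full_subsplit_support(c("A", "B", "C", "D")))
  # all 15 topologies equiprobable; drop D
  r <- restrict_ccd(u, c("A", "B", "C"))
  td <- enumerate_support_trees(r)
  expect_length(td$prob, 3)
  expect_equal(unname(td$prob), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("SCD restriction equals the marginalization oracle exactly", {
  set.seed(702)
  taxa <- sprintf("t%d", 1:5)
  for (i in 1:3) {
    q <- if (i == 1) random_sbn(taxa, "scd", concentration = 0.7)
         else random_sbn(taxa, "scd", support_source = "trees",
                         n_support_trees = 3 + i)
    td <- enumerate_support_trees(q)
    for (drop in taxa[c(1, 4, 5)]) {
      xbar <- setdiff(taxa, drop)
      r <- restrict_sbn(q, xbar)
      expect_equal(max_prob_diff(enumerate_support_trees(r),
                                 restrict_distribution(td, xbar)),
                   0, tolerance = 1e-10)
    }
    # size-3 subset exercises multi-step trivial chains
    xbar3 <- taxa[c(1, 3, 5)]
    expect_equal(max_prob_diff(enumerate_support_trees(restrict_sbn(q, xbar3)),
                               restrict_distribution(td, xbar3)),
                 0, tolerance = 1e-10)
  }
})

test_that("CCD restriction carries exact conditional clade frequencies", {
  # complete-support instances: the restricted distribution stayed
  # CCD-representable on these seeds, so the match is distribution-level
  set.seed(712)
  taxa <- sprintf("t%d", 1:5)
  for (i in 1:2) {
    q <- random_sbn(taxa, "ccd", concentration = 0.7)
    td <- enumerate_support_trees(q)
    for (drop in taxa[c(1, 5)]) {
      xbar <- setdiff(taxa, drop)
      expect_equal(max_prob_diff(enumerate_support_trees(restrict_ccd(q, xbar)),
                                 restrict_distribution(td, xbar)),
                   0, tolerance = 1e-10)
    }
  }
})

test_that("on sparse supports CCD restriction is the conditional-frequency projection", {
  # the clade-conditional family is not closed under restriction: here the
  # true restricted distribution is not a CCD, and the restricted CCD equals
  # its maximum-likelihood CCD (same conditional clade frequencies) while an
  # SCD represents the same restricted distribution exactly
  taxa <- sprintf("t%d", 1:6)
  q <- random_sbn(taxa, "ccd", seed = 1, support_source = "trees",
                  n_support_trees = 4)
  td <- enumerate_support_trees(q)
  xbar <- taxa[1:5]
  oracle <- restrict_distribution(td, xbar)
  r <- restrict_ccd(q, xbar)
  mle <- estimate_from_trees(unname(oracle$trees), "ccd",
                             weights = unname(oracle$prob), min_count = 0)
  expect_setequal(names(r$cond), names(mle$cond))
  expect_equal(max(abs(r$cond[names(mle$cond)] - mle$cond)), 0,
               tolerance = 1e-12)
  # the projection genuinely differs from the true restricted distribution
  expect_gt(max_prob_diff(enumerate_support_trees(r), oracle), 1e-3)
  # whereas the SCD family represents it exactly
  mle_scd <- estimate_from_trees(unname(oracle$trees), "scd",
                                 weights = unname(oracle$prob), min_count = 0)
  expect_equal(max_prob_diff(enumerate_support_trees(mle_scd), oracle), 0,
               tolerance = 1e-12)
})

test_that("restriction satisfies the tower property on SBNs", {
  set.seed(703)
  taxa <- sprintf("t%d", 1:5)
  for (kind in c("ccd", "scd")) {
    # complete support for the CCD (where restriction is closed on these
    # instances); sparse support for the SCD (closed everywhere)
    q <- if (kind == "ccd") random_sbn(taxa, kind, concentration = 0.8)
         else random_sbn(taxa, kind, support_source = "trees", n_support_trees = 5)
    two <- restrict_sbn(restrict_sbn(q, taxa[1:4]), taxa[1:3])
    one <- restrict_sbn(q, taxa[1:3])
    expect_equal(max_prob_diff(enumerate_support_trees(two),
                               enumerate_support_trees(one)),
                 0, tolerance = 1e-10)
  }
})

test_that("subsplits sharing a nontrivial restriction never co-occur in a tree", {
  # the mutual-exclusivity premise behind fiber additivity
  set.seed(704)
  taxa <- sprintf("t%d", 1:5)
  q <- random_sbn(taxa, "ccd", concentration = 1)
  td <- enumerate_support_trees(q)
  xbar <- taxa[1:4]
  fiber <- list()
  for (k in names(q$support$splits)) {
    sb <- restrict_subsplit(q$support$splits[[k]], xbar)
    if (!is_trivial_subsplit(sb)) {
      fiber[[subsplit_key(sb)]] <- c(fiber[[subsplit_key(sb)]], k)
    }
  }
  for (sk in names(fiber)) {
    members <- fiber[[sk]]
    if (length(members) < 2) next
    for (tau in td$trees) {
      expect_lte(sum(members %in% names(tau$splits)), 1)
    }
  }
})

test_that("restriction domain errors are raised", {
  d <- random_sbn(c("A", "B", "C"), "ccd", seed = 705)
  expect_error(restrict_ccd(d, c("A", "Z")), "subset")
  expect_error(restrict_ccd(d, "A"), "at least 2")
})
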