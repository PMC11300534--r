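# Synthetic fixtures: ground-truth SBNs, coalescent topology sampling, and
# leave-one-taxon-out reference problems.  These generators stand in for the
# posterior tree samples a Bayesian analysis would provide, preserving the
# statistical structure the supertree method consumes (tree samples with
# support noise on overlapping taxon sets) without any external sampler.

#' Sample a coalescent tree topology
#'
#' Topology of the isochronous constant-population-size coalescent:
#' repeatedly merge a uniformly chosen pair of lineages until one remains
#' (times are irrelevant for topologies and are not drawn).
#'
#' @param taxa taxon set (at least 2 taxa... a single taxon gives the
#'   degenerate one-tip topology).
#' @param seed optional integer seed.
#' @return rooted topology.
#' @export
sample_coalescent_topology <- function(taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- clade(taxa)
  lineages <- as.list(taxa)
  splits <- list()
  while (length(lineages) > 1) {
    ij <- sample.int(length(lineages), 2)
    s <- subsplit(lineages[[ij[1]]], lineages[[ij[2]]])
    splits[[subsplit_key(s)]] <- s
    merged <- subsplit_clade(s)
    lineages <- c(lineages[-ij], list(merged))
  }
  rooted_topology(taxa, splits, validate = FALSE)
}

#' Complete subsplit/PCSP supports on a taxon set
#'
#' Every subsplit of every clade (\code{full_subsplit_support}), or every
#' valid parent-child pair (\code{full_pcsp_support}).  Sizes grow
#' super-exponentially; both are capped at 7 taxa.
#'
#' @param taxa taxon set, between 2 and 7 taxa.
#' @return \code{subsplit_support} / \code{pcsp_support}.
#' @export
full_subsplit_support <- function(taxa) {
  taxa <- clade(taxa)
  n <- length(taxa)
  if (n < 2 || n > 7) stop("full supports are limited to 2..7 taxa")
  splits <- list()
  for (mask in seq_len(2^n - 1)) {
    w <- taxa[bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), mask) != 0L]
    m <- length(w)
    if (m < 2) next
    for (sub in 0:(2^(m - 1) - 1)) {
      y <- c(w[1], w[-1][bitwAnd(bitwShiftL(1L, seq_len(m - 1) - 1L), sub) != 0L])
      z <- setdiff(w, y)
      if (length(z) == 0) next
      s <- subsplit(y, z)
      splits[[subsplit_key(s)]] <- s
    }
  }
  subsplit_support(taxa, splits)
}

#' @rdname full_subsplit_support
#' @export
full_pcsp_support <- function(taxa) {
  cs <- full_subsplit_support(taxa)
  pcsps <- list()
  rootp <- trivial_subsplit(cs$taxa)
  for (s in cs$splits) {
    w <- subsplit_clade(s)
    parents <- if (identical(w, cs$taxa)) list(rootp) else list()
    for (t in cs$splits) {
      if (clade_key(t$y) == clade_key(w) || clade_key(t$z) == clade_key(w)) {
        parents <- c(parents, list(t))
      }
    }
    for (t in parents) {
      p <- pcsp(t, s)
      pcsps[[pcsp_key(p)]] <- p
    }
  }
  pcsp_support(cs$taxa, pcsps)
}

#' Support spanned by a list of topologies
#'
#' @param trees list of rooted topologies on one taxon set.
#' @param kind \code{"ccd"} (subsplit support) or \code{"scd"} (PCSP
#'   support).
#' @return \code{subsplit_support} or \code{pcsp_support}.
#' @export
support_from_trees <- function(trees, kind = c("ccd", "scd")) {
  kind <- match.arg(kind)
  taxa <- trees[[1]]$taxa
  if (kind == "ccd") {
    splits <- list()
    for (tau in trees) for (s in tau$splits) splits[[subsplit_key(s)]] <- s
    subsplit_support(taxa, splits)
  } else {
    pcsps <- list()
    for (tau in trees) for (p in pcsp_decomposition(tau)) pcsps[[pcsp_key(p)]] <- p
    pcsp_support(taxa, pcsps)
  }
}

# Dirichlet(concentration) draw over each conditional block of a support
random_conditionals <- function(blocks, concentration) {
  cond <- numeric(0)
  for (keys in blocks) {
    v <- stats::rgamma(length(keys), shape = concentration, rate = 1)
    # guard against degenerate all-zero draws at tiny concentrations
    if (sum(v) == 0) v <- rep(1, length(v))
    v <- pmax(v, 1e-12)
    cond[keys] <- v / sum(v)
  }
  cond
}

#' Generate a random ground-truth SBN
#'
#' The support is either complete (\code{support_source = "full"}, up to 7
#' taxa) or spanned by \code{n_support_trees} coalescent-sampled topologies
#' (\code{"trees"}, emulating the sparse support of a posterior sample).
#' Conditional blocks are drawn independently from a symmetric
#' Dirichlet(\code{concentration}); large concentrations approach uniform
#' conditionals.
#'
#' @param taxa taxon set.
#' @param kind \code{"ccd"} or \code{"scd"}.
#' @param concentration positive Dirichlet parameter (default 1, flat).
#' @param seed optional integer seed.
#' @param support_source \code{"full"} or \code{"trees"}.
#' @param n_support_trees number of coalescent topologies spanning the
#'   support when \code{support_source = "trees"}.
#' @return \code{ccd} or \code{scd} distribution.
#' @export
random_sbn <- function(taxa, kind = c("ccd", "scd"), concentration = 1,
                       seed = NULL, support_source = c("full", "trees"),
                       n_support_trees = 10) {
  kind <- match.arg(kind)
  support_source <- match.arg(support_source)
  if (!is.null(seed)) set.seed(seed)
  taxa <- clade(taxa)
  if (support_source == "full") {
    support <- if (kind == "ccd") full_subsplit_support(taxa) else full_pcsp_support(taxa)
  } else {
    trees <- replicate(n_support_trees, sample_coalescent_topology(taxa), simplify = FALSE)
    support <- support_from_trees(trees, kind)
  }
  if (kind == "ccd") {
    ccd(support, random_conditionals(support$by_clade, concentration))
  } else {
    scd(support, random_conditionals(support$by_focal, concentration))
  }
}

#' Build a complete synthetic reference problem
#'
#' Emulates the leave-one-taxon-out simulation design: a ground-truth SBN on
#' the full taxon set; references obtained by exact restriction to each
#' subset, optionally re-estimated from sampled topologies with min-count
#' trimming (the posterior-sample stand-in); the mutual supertree support of
#' the reference supports; and truth/references trimmed to the elements
#' covered by (the appropriate restriction of) the mutual support, then
#' renormalized within each conditional block.
#'
#' @param n_taxa number of taxa (taxa are labelled t01, t02, ...).
#' @param kind \code{"ccd"} or \code{"scd"}.
#' @param subsets list of taxon subsets; default: two subsets, the first
#'   omitting the last taxon and the second omitting the one before it.
#' @param concentration Dirichlet concentration of the truth's conditionals.
#' @param support_source,n_support_trees passed to \code{\link{random_sbn}}.
#' @param n_samples topologies to sample per reference; 0 keeps the exact
#'   restrictions as references.
#' @param min_count trim threshold for sampled references (default 2).
#' @param seed integer seed controlling the truth and all sampling.
#' @return list with \code{truth} (trimmed to the mutual support),
#'   \code{references} (list of SBNs), \code{mutual_support},
#'   \code{subsets}, and \code{samples} (tree lists, when sampled).
#' @export
make_reference_problem <- function(n_taxa = 6, kind = c("scd", "ccd"),
                                   subsets = NULL, concentration = 1,
                                   support_source = "trees", n_support_trees = 10,
                                   n_samples = 0, min_count = 2, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  taxa <- clade(sprintf("t%02d", seq_len(n_taxa)))
  if (is.null(subsets)) {
    subsets <- list(clade_setdiff(taxa, taxa[n_taxa]),
                    clade_setdiff(taxa, taxa[n_taxa - 1]))
  }
  subsets <- lapply(subsets, clade)
  if (!identical(Reduce(clade_union, subsets), taxa)) {
    stop("the union of the subsets must equal the full taxon set")
  }
  truth <- random_sbn(taxa, kind, concentration,
                      support_source = support_source,
                      n_support_trees = n_support_trees)
  exact_refs <- lapply(subsets, function(xs) restrict_sbn(truth, xs))
  samples <- NULL
  if (n_samples > 0) {
    samples <- lapply(exact_refs, function(r) sample_topologies(r, n_samples))
    references <- lapply(samples, function(tl) {
      estimate_from_trees(tl, kind = kind, min_count = min_count)
    })
  } else {
    references <- exact_refs
  }
  mutual <- mutualize_many(lapply(references, function(r) r$support))
  # trim references (and the truth) to what the mutual support covers
  references <- lapply(seq_along(references), function(i) {
    covered <- restricted_support(mutual, subsets[[i]])
    trim_sbn(references[[i]], covered)
  })
  truth <- trim_sbn(truth, mutual)
  list(truth = truth, references = references, mutual_support = mutual,
       subsets = subsets, samples = samples)
}

# The support of the restriction of a (uniform) SBN on `support` to xbar:
# which restricted elements are representable by the mutual support.
restricted_support <- function(support, xbar) {
  u <- uniform_sbn(support)
  restrict_sbn(u, xbar)$support
}

#' Uniform SBN on a support
#'
#' All conditional blocks uniform (the high-entropy distribution used to
#' initialize training).
#'
#' @param support \code{subsplit_support} or \code{pcsp_support}.
#' @return \code{ccd} or \code{scd}.
#' @export
uniform_sbn <- function(support) {
  if (inherits(support, "subsplit_support")) {
    cond <- numeric(0)
    for (keys in support$by_clade) cond[keys] <- 1 / length(keys)
    ccd(support, cond)
  } else {
    cond <- numeric(0)
    for (keys in support$by_focal) cond[keys] <- 1 / length(keys)
    scd(support, cond)
  }
}

#' Trim an SBN to the elements of a covering support
#'
#' Drops support elements absent from \code{cover}, renormalizes each
#' conditional block, and prunes the result back to a closed, reachable
#' support.  Mirrors the support-compatibility trimming applied to
#' posterior-sample SBNs before training.
#'
#' @param d \code{ccd} or \code{scd}.
#' @param cover \code{subsplit_support} or \code{pcsp_support} on the same
#'   taxon set.
#' @return trimmed distribution of the same kind.
#' @export
trim_sbn <- function(d, cover) {
  if (inherits(d, "ccd")) {
    keep <- intersect(names(d$support$splits), names(cover$splits))
    if (length(keep) == 0) stop("trimming removed the entire support")
    splits <- prune_subsplit_set(d$support$taxa, d$support$splits[keep])
    support <- subsplit_support(d$support$taxa, splits)
    cond <- d$cond[names(support$splits)]
    for (keys in support$by_clade) cond[keys] <- cond[keys] / sum(cond[keys])
    ccd(support, cond)
  } else {
    keep <- intersect(names(d$support$pcsps), names(cover$pcsps))
    if (length(keep) == 0) stop("trimming removed the entire support")
    pcsps <- prune_pcsp_set(d$support$taxa, d$support$pcsps[keep])
    support <- pcsp_support(d$support$taxa, pcsps)
    cond <- d$cond[names(support$pcsps)]
    for (keys in support$by_focal) cond[keys] <- cond[keys] / sum(cond[keys])
    scd(support, cond)
  }
}
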