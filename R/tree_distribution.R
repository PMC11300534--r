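# Explicit, finite distributions over rooted topologies.  This module is the
# deliberately-slow oracle: every SBN quantity (restriction, KL, marginal
# probabilities) can be recomputed here by direct summation over trees.

#' Construct an explicit tree distribution
#'
#' @param trees list of rooted topologies sharing one taxon set.
#' @param prob numeric probabilities (or nonnegative weights when
#'   \code{normalize = TRUE}).
#' @param normalize divide by the total mass instead of requiring it to be 1.
#' @return object of class \code{"tree_distribution"}: list with \code{taxa},
#'   \code{trees} (named by canonical Newick) and \code{prob} (named numeric).
#' @export
tree_distribution <- function(trees, prob, normalize = FALSE) {
  if (length(trees) == 0) stop("empty tree distribution")
  if (length(trees) != length(prob)) stop("trees and prob lengths differ")
  taxa <- trees[[1]]$taxa
  keys <- character(length(trees))
  for (i in seq_along(trees)) {
    if (!identical(trees[[i]]$taxa, taxa)) stop("all topologies must share one taxon set")
    keys[i] <- topology_key(trees[[i]])
  }
  if (anyDuplicated(keys)) {
    # merge duplicate topologies
    prob <- as.numeric(tapply(prob, keys, sum)[unique(keys)])
    trees <- trees[!duplicated(keys)]
    keys <- unique(keys)
  }
  if (any(prob < 0)) stop("negative probability")
  if (normalize) prob <- prob / sum(prob)
  if (abs(sum(prob) - 1) > 1e-12) stop("probabilities sum to ", sum(prob), ", not 1")
  names(trees) <- keys
  names(prob) <- keys
  structure(list(taxa = taxa, trees = trees, prob = prob), class = "tree_distribution")
}

#' @export
print.tree_distribution <- function(x, ...) {
  cat("tree distribution on ", length(x$taxa), " taxa, ", length(x$prob),
      " topologies\n", sep = "")
  invisible(x)
}

#' Restrict an explicit distribution to a taxon subset
#'
#' Marginalizes over restriction fibers: the restricted probability of a
#' topology on \code{xbar} is the total probability of all topologies that
#' restrict to it.
#'
#' @param q tree distribution.
#' @param xbar clade, subset of the taxon set, size at least 2 (a single
#'   taxon gives the degenerate point distribution on the one-tip tree).
#' @return tree distribution on \code{xbar}.
#' @export
restrict_distribution <- function(q, xbar) {
  xbar <- clade(xbar)
  if (!clade_contains(q$taxa, xbar)) stop("xbar is not a subset of the taxon set")
  if (length(xbar) == 0) stop("cannot restrict to the empty set")
  acc <- new.env(hash = TRUE, parent = emptyenv())
  reps <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(q$trees)) {
    r <- restrict_topology(q$trees[[k]], xbar)
    rk <- topology_key(r)
    prev <- acc[[rk]]
    if (is.null(prev)) { acc[[rk]] <- q$prob[[k]]; reps[[rk]] <- r }
    else acc[[rk]] <- prev + q$prob[[k]]
  }
  keys <- sort(ls(acc), method = "radix")
  tree_distribution(lapply(keys, function(k) reps[[k]]),
                    vapply(keys, function(k) acc[[k]], 0), normalize = TRUE)
}

#' KL divergence between two explicit tree distributions
#'
#' Natural-log KL divergence \eqn{-\sum_\tau p(\tau) \log(q(\tau)/p(\tau))}
#' in nats, with the convention 0 log 0 = 0.  The support of \code{p} must
#' be contained in the support of \code{q}.
#'
#' @param p,q tree distributions on the same taxon set.
#' @return nonnegative number (nats).
#' @export
kl_divergence_explicit <- function(p, q) {
  if (!identical(p$taxa, q$taxa)) stop("taxon sets differ")
  total <- 0
  for (k in names(p$prob)) {
    pp <- p$prob[[k]]
    if (pp == 0) next
    qq <- unname(q$prob[k])
    if (is.na(qq) || qq == 0) {
      stop("support incompatibility: q assigns zero probability to ", k,
           "; the KL divergence is undefined")
    }
    total <- total - pp * (log(qq) - log(pp))
  }
  total
}

#' Restricted-KL loss against explicit reference distributions
#'
#' Computes the (optionally weighted) sum of KL divergences between each
#' reference distribution and the restriction of \code{q} to the reference
#' taxon set.
#'
#' @param refs list of tree distributions (references on taxon subsets).
#' @param q tree distribution on the union taxon set.
#' @param weights positive weights, recycled default 1.
#' @return loss in nats.
#' @export
loss_explicit <- function(refs, q, weights = rep(1, length(refs))) {
  if (length(refs) == 0) stop("at least one reference required")
  if (any(weights <= 0)) stop("weights must be positive")
  total <- 0
  for (i in seq_along(refs)) {
    qi <- restrict_distribution(q, refs[[i]]$taxa)
    total <- total + weights[i] * kl_divergence_explicit(refs[[i]], qi)
  }
  total
}

#' Read/write explicit tree distributions as weighted Newick lists
#'
#' Column 2 holds the probability (or a count; counts are normalized on
#' load).
#'
#' @param path file path.
#' @export
read_tree_distribution <- function(path) {
  tl <- read_tree_list(path)
  tree_distribution(tl$trees, tl$weights, normalize = TRUE)
}

#' @rdname read_tree_distribution
#' @param d tree distribution.
#' @export
write_tree_distribution <- function(d, path) {
  write_tree_list(unname(d$trees), unname(d$prob), path)
}
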