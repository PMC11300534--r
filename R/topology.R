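# Rooted, bifurcating tree topologies represented as sets of subsplits.
# A topology on n taxa contains exactly n - 1 nontrivial subsplits; a
# degenerate single-tip "topology" (arising from restriction to one taxon)
# has zero.

#' Construct a rooted topology from its subsplit set
#'
#' @param taxa character vector: the tip set.
#' @param splits list of subsplits (the n - 1 nontrivial subsplits of a
#'   bifurcating tree; empty for a single tip).
#' @param validate check the subsplit set encodes a bifurcating tree.
#' @return object of class \code{"rooted_topology"} with fields \code{taxa}
#'   (sorted) and \code{splits} (named list keyed by subsplit key).
#' @export
rooted_topology <- function(taxa, splits = list(), validate = TRUE) {
  taxa <- clade(taxa)
  if (length(taxa) == 0) stop("topology requires at least one taxon")
  names(splits) <- vapply(splits, subsplit_key, "")
  tau <- structure(list(taxa = taxa, splits = splits), class = "rooted_topology")
  if (validate) validate_topology(tau)
  tau
}

#' @rdname rooted_topology
#' @param tau rooted topology.
#' @export
validate_topology <- function(tau) {
  n <- length(tau$taxa)
  if (length(tau$splits) != n - 1) {
    stop("a bifurcating topology on ", n, " taxa must contain ", n - 1,
         " subsplits, found ", length(tau$splits))
  }
  if (n == 1) return(invisible(tau))
  # map clade key -> subsplit dividing it; each clade divided exactly once
  div <- new.env(hash = TRUE, parent = emptyenv())
  for (s in tau$splits) {
    if (is_trivial_subsplit(s)) stop("topologies contain nontrivial subsplits only")
    w <- clade_key(subsplit_clade(s))
    if (!is.null(div[[w]])) stop("clade ", w, " divided by more than one subsplit")
    div[[w]] <- s
  }
  # walk down from the root; every non-singleton clade reached must be divided
  seen <- 0L
  stack <- list(tau$taxa)
  while (length(stack) > 0) {
    w <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    s <- div[[clade_key(w)]]
    if (is.null(s)) stop("clade ", clade_key(w), " is not divided by any subsplit")
    seen <- seen + 1L
    for (child in list(s$y, s$z)) {
      if (length(child) >= 2) stack[[length(stack) + 1L]] <- child
    }
  }
  if (seen != length(tau$splits)) {
    stop("subsplit set contains elements unreachable from the root")
  }
  invisible(tau)
}

#' @rdname rooted_topology
#' @export
topology_key <- function(tau) write_newick(tau)

#' @export
print.rooted_topology <- function(x, ...) {
  cat("rooted topology on ", length(x$taxa), " taxa: ", write_newick(x), "\n", sep = "")
  invisible(x)
}

# subsplit dividing clade w in tau, or NULL
dividing_subsplit <- function(tau, w) {
  kw <- clade_key(w)
  for (s in tau$splits) if (clade_key(subsplit_clade(s)) == kw) return(s)
  NULL
}

#' Decompose a topology into its PCSPs
#'
#' Pairs every nontrivial subsplit with its parent subsplit; the root
#' subsplit is paired with the trivial subsplit \{X, 0\}.
#'
#' @param tau rooted topology.
#' @return named list of PCSPs (one per nontrivial subsplit).
#' @export
pcsp_decomposition <- function(tau) {
  out <- list()
  if (length(tau$taxa) < 2) return(out)
  # parent of each subsplit: the subsplit having U(s) as a child clade
  by_clade <- new.env(hash = TRUE, parent = emptyenv())
  for (s in tau$splits) by_clade[[clade_key(subsplit_clade(s))]] <- s
  root_parent <- trivial_subsplit(tau$taxa)
  walk <- function(parent, w) {
    s <- by_clade[[clade_key(w)]]
    p <- pcsp(parent, s)
    out[[pcsp_key(p)]] <<- p
    for (child in list(s$y, s$z)) {
      if (length(child) >= 2) walk(s, child)
    }
  }
  walk(root_parent, tau$taxa)
  out
}

#' Restrict a topology to a taxon subset
#'
#' Prunes tips outside \code{xbar} and suppresses internal nodes left with a
#' single child.  Restriction to a single taxon yields the degenerate
#' one-tip topology; restriction to the empty set is an error.
#'
#' @param tau rooted topology.
#' @param xbar clade, a nonempty subset of \code{tau$taxa}.
#' @return rooted topology on \code{intersect(tau$taxa, xbar)}.
#' @export
restrict_topology <- function(tau, xbar) {
  xbar <- clade(xbar)
  if (!clade_contains(tau$taxa, xbar)) stop("xbar is not a subset of the taxon set")
  if (length(xbar) == 0) stop("cannot restrict a topology to the empty taxon set")
  splits <- list()
  # prune-and-suppress, recursively: returns the surviving tip set under w
  descend <- function(w) {
    keep <- clade_intersect(w, xbar)
    if (length(keep) <= 1) return(keep)
    s <- dividing_subsplit(tau, w)
    cy <- descend(s$y)
    cz <- descend(s$z)
    if (length(cy) == 0) return(cz)
    if (length(cz) == 0) return(cy)
    r <- subsplit(cy, cz)
    splits[[subsplit_key(r)]] <<- r
    keep
  }
  descend(tau$taxa)
  rooted_topology(xbar, splits)
}

#' Enumerate all rooted bifurcating topologies on a taxon set
#'
#' Recursive enumeration over all clade bipartitions; there are
#' (2n - 3)!! topologies on n taxa.
#'
#' @param x clade of size between 1 and \code{cap}.
#' @param cap capacity guard on the number of taxa (default 8, i.e. at most
#'   135135 topologies).
#' @return list of rooted topologies, each exactly once, in deterministic
#'   order.
#' @export
enumerate_topologies <- function(x, cap = 8) {
  x <- clade(x)
  n <- length(x)
  if (n < 1) stop("taxon set must be nonempty")
  if (n > cap) stop("refusing to enumerate topologies on ", n, " > cap = ", cap, " taxa")
  # returns list of subsplit-key-keyed lists of subsplits
  rec <- function(w) {
    if (length(w) <= 1) return(list(list()))
    first <- w[1]; rest <- w[-1]
    out <- list()
    m <- length(rest)
    # enumerate subsets of rest joining `first` in child Y (avoids double count)
    for (mask in 0:(2^m - 1)) {
      sel <- rest[bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), mask) != 0L]
      y <- clade(c(first, sel))
      z <- clade_setdiff(w, y)
      if (length(z) == 0) next
      s <- subsplit(y, z)
      for (ly in rec(y)) for (lz in rec(z)) {
        sp <- c(list(s), ly, lz)
        out[[length(out) + 1L]] <- sp
      }
    }
    out
  }
  lapply(rec(x), function(sp) rooted_topology(x, sp, validate = FALSE))
}
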