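# Restriction of SBN distributions to taxon subsets, computed directly from
# the SBN parameters (no tree enumeration).
#
# CCD: restricted subsplit probabilities are sums of unconditional subsplit
# probabilities over the restriction fiber (subsplits restricting to the
# same nontrivial subsplit are mutually exclusive, so the sum is exact);
# clade probabilities are sums over dividing subsplits, and restricted
# conditionals are their ratio.
#
# SCD: a restricted PCSP tbar -> sbar arises from every ancestor-descendant
# pair (a, d) with a restricting to tbar, d restricting to sbar; every
# subsplit strictly between a and d then necessarily restricts to a trivial
# subsplit, so the unconditional restricted PCSP probability is the sum of
# path probabilities q(a ->* d) over the fiber pairs.

#' Restrict a CCD-parameterized SBN to a taxon subset
#'
#' The returned CCD carries the exact clade-conditional probabilities of the
#' marginalized restriction: its unconditional restricted subsplit and clade
#' probabilities are exact fiber sums, and its conditionals are their
#' ratios.  Note that the clade-conditional family is not closed under
#' restriction: on sparse supports the true restricted distribution may not
#' be representable as a CCD at all, in which case the result is its
#' conditional-frequency (maximum-likelihood) CCD projection rather than an
#' exact representation.  The subsplit-conditional family does not have this
#' limitation; see \code{\link{restrict_scd}}.
#'
#' @param q \code{ccd} distribution.
#' @param xbar clade, subset of the taxon set with at least 2 taxa.
#' @return \code{ccd} distribution on \code{xbar}.
#' @export
restrict_ccd <- function(q, xbar) {
  stopifnot(inherits(q, "ccd"))
  xbar <- clade(xbar)
  if (!clade_contains(sbn_taxa(q), xbar)) stop("xbar is not a subset of the taxon set")
  if (length(xbar) < 2) stop("restriction target must contain at least 2 taxa")
  u <- sbn_unconditional(q)$split
  acc <- new.env(hash = TRUE, parent = emptyenv())
  objs <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(q$support$splits)) {
    sb <- restrict_subsplit(q$support$splits[[k]], xbar)
    if (is_trivial_subsplit(sb)) next
    sk <- subsplit_key(sb)
    prev <- acc[[sk]]
    acc[[sk]] <- if (is.null(prev)) u[[k]] else prev + u[[k]]
    objs[[sk]] <- sb
  }
  keys <- sort(ls(acc), method = "radix")
  keys <- keys[vapply(keys, function(k) acc[[k]] > 0, TRUE)]
  if (length(keys) == 0) stop("restriction produced an empty support")
  clade_prob <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) {
    wk <- clade_key(subsplit_clade(objs[[k]]))
    prev <- clade_prob[[wk]]
    clade_prob[[wk]] <- if (is.null(prev)) acc[[k]] else prev + acc[[k]]
  }
  support <- subsplit_support(xbar, lapply(keys, function(k) objs[[k]]))
  cond <- vapply(names(support$splits), function(k) {
    acc[[k]] / clade_prob[[clade_key(subsplit_clade(objs[[k]]))]]
  }, 0)
  ccd(support, cond)
}

#' Restrict an SCD-parameterized SBN to a taxon subset
#'
#' Restriction is exact for subsplit-conditional distributions: the induced
#' tree distribution of the result equals the marginalized restriction of
#' \code{q}'s tree distribution (conditioning on the parent subsplit is rich
#' enough to carry the dependence that survives marginalization, via the
#' ancestor-descendant path equivalence).
#'
#' @param q \code{scd} distribution.
#' @param xbar clade, subset of the taxon set with at least 2 taxa.
#' @param ws optional precomputed workspace for \code{q} (reused path
#'   probabilities); one is created when NULL.
#' @return \code{scd} distribution on \code{xbar} whose induced tree
#'   distribution equals the marginalized restriction of \code{q}'s.
#' @export
restrict_scd <- function(q, xbar, ws = NULL) {
  stopifnot(inherits(q, "scd"))
  xbar <- clade(xbar)
  if (!clade_contains(sbn_taxa(q), xbar)) stop("xbar is not a subset of the taxon set")
  if (length(xbar) < 2) stop("restriction target must contain at least 2 taxa")
  if (is.null(ws)) ws <- sbn_workspace(q)
  usplit <- ws$uncond$split
  # subsplits with nontrivial restriction, grouped by restricted subsplit
  fiber <- list()   # restricted key -> character vector of original keys
  robj <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(q$support$splits)) {
    sb <- restrict_subsplit(q$support$splits[[k]], xbar)
    if (is_trivial_subsplit(sb)) next
    sk <- subsplit_key(sb)
    fiber[[sk]] <- c(fiber[[sk]], k)
    robj[[sk]] <- sb
  }
  if (length(fiber) == 0) stop("restriction produced an empty support")
  rkeys <- sort(names(fiber), method = "radix")
  # unconditional restricted subsplit probabilities (also parent probabilities)
  rprob <- vapply(rkeys, function(sk) sum(usplit[fiber[[sk]]]), 0)
  names(rprob) <- rkeys
  pcsps <- list()
  uncond_pcsp <- numeric(0)
  xk <- clade_key(xbar)
  rootbar <- trivial_subsplit(xbar)
  for (sk in rkeys) {
    sb <- robj[[sk]]
    if (clade_key(subsplit_clade(sb)) == xk) {
      # root PCSP of the restricted SBN
      p <- pcsp(rootbar, sb)
      pcsps[[pcsp_key(p)]] <- p
      uncond_pcsp[pcsp_key(p)] <- rprob[[sk]]
    }
  }
  # non-root restricted PCSPs: sum q(a ->* d) over fiber pairs
  for (tk in rkeys) {
    tb <- robj[[tk]]
    for (sk in rkeys) {
      if (sk == tk) next
      sb <- robj[[sk]]
      usb <- clade_key(subsplit_clade(sb))
      if (usb != clade_key(tb$y) && usb != clade_key(tb$z)) next
      a_keys <- fiber[[tk]]
      d_keys <- fiber[[sk]]
      # G is zero wherever no support path exists, so no pair filtering needed
      total <- sum(usplit[a_keys] *
                     rowSums(ws$G[a_keys, d_keys, drop = FALSE]))
      if (total > 0) {
        p <- pcsp(tb, sb)
        pcsps[[pcsp_key(p)]] <- p
        uncond_pcsp[pcsp_key(p)] <- total
      }
    }
  }
  support <- pcsp_support(xbar, pcsps)
  cond <- vapply(names(support$pcsps), function(k) {
    p <- support$pcsps[[k]]
    parent_prob <- if (subsplit_key(p$parent) == subsplit_key(rootbar)) 1
                   else rprob[[subsplit_key(p$parent)]]
    uncond_pcsp[[k]] / parent_prob
  }, 0)
  scd(support, cond)
}

#' @rdname restrict_ccd
#' @export
restrict_sbn <- function(q, xbar, ws = NULL) {
  if (inherits(q, "ccd")) restrict_ccd(q, xbar) else restrict_scd(q, xbar, ws)
}
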