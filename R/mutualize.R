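# Mutual supertree supports: combine two reference supports on overlapping
# taxon sets into a support on the union that (1) only contains elements
# restricting into every reference and (2) contains every topology whose
# restrictions lie in all references.  Both algorithms are top-down stack
# traversals driven by the box product.

#' Box product of two subsplits
#'
#' Combines two subsplits into up to two candidate supertree subsplits by
#' crosswise unions of child clades,
#' \{Y1 u Y2, Z1 u Z2\} and \{Y1 u Z2, Z1 u Y2\}.  Candidates whose children
#' overlap are invalid and excluded, as are trivial results.
#'
#' @param s1,s2 subsplits (possibly trivial, singleton or empty).
#' @return list of valid nontrivial subsplits (0, 1 or 2 of them).
#' @export
box_product <- function(s1, s2) {
  out <- list()
  for (z2first in c(FALSE, TRUE)) {
    a2 <- if (z2first) s2$z else s2$y
    b2 <- if (z2first) s2$y else s2$z
    ya <- union(s1$y, a2)
    zb <- union(s1$z, b2)
    if (length(intersect(ya, zb)) > 0) next
    if (length(ya) == 0 || length(zb) == 0) next
    s <- subsplit(ya, zb)
    out[[subsplit_key(s)]] <- s
  }
  unname(out)
}

# reference-side candidate subsplits for a restricted clade
ccd_side_candidates <- function(cs, w_i) {
  if (length(w_i) == 0) return(list(subsplit(character(0))))
  if (length(w_i) == 1) return(list(subsplit(w_i)))
  keys <- support_query_clade(cs, w_i)
  c(lapply(keys, function(k) cs$splits[[k]]), list(trivial_subsplit(w_i)))
}

scd_side_candidates <- function(ps, lp, w_i) {
  if (length(w_i) == 0) return(list(subsplit(character(0))))
  if (length(w_i) == 1) return(list(subsplit(w_i)))
  keys <- support_query_focal(ps, lp, w_i)
  c(lapply(keys, function(k) ps$pcsps[[k]]$child), list(trivial_subsplit(w_i)))
}

#' Mutual subsplit support (CCD references)
#'
#' Top-down traversal from the union root clade: at each popped clade W,
#' every pair of candidate subsplits from the two references (dividing the
#' restricted clades, trivial subsplits included) is combined via the box
#' product; valid nontrivial results are emitted and their non-singleton
#' child clades pushed.  The output is pruned to a closed, reachable
#' support, and may be empty when the references are incompatible.
#'
#' @param c1,c2 \code{subsplit_support} references with taxon sets X1, X2.
#' @param taxa optional expected union taxon set (checked).
#' @return \code{subsplit_support} on X1 u X2 (possibly empty).
#' @export
mutualize_subsplit_supports <- function(c1, c2, taxa = NULL) {
  x1 <- c1$taxa; x2 <- c2$taxa
  x <- clade_union(x1, x2)
  if (!is.null(taxa) && !identical(clade(taxa), x)) {
    stop("X1 u X2 does not equal the stated taxon set")
  }
  out <- list()
  visited <- new.env(hash = TRUE, parent = emptyenv())
  stack <- list(x)
  while (length(stack) > 0) {
    w <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    wk <- clade_key(w)
    if (!is.null(visited[[wk]])) next
    visited[[wk]] <- TRUE
    cand1 <- ccd_side_candidates(c1, clade_intersect(w, x1))
    cand2 <- ccd_side_candidates(c2, clade_intersect(w, x2))
    for (s1 in cand1) for (s2 in cand2) {
      for (s in box_product(s1, s2)) {
        out[[subsplit_key(s)]] <- s
        for (child in list(s$y, s$z)) {
          if (length(child) >= 2 && is.null(visited[[clade_key(child)]])) {
            stack[[length(stack) + 1L]] <- child
          }
        }
      }
    }
  }
  splits <- prune_subsplit_set(x, out)
  subsplit_support(x, splits, validate = length(splits) > 0)
}

#' Mutual PCSP support (SCD references)
#'
#' As \code{\link{mutualize_subsplit_supports}}, but stack frames carry the
#' focal parent subsplit and clade on the union taxon set together with the
#' most recent nontrivially-restricting parent subsplit in each reference
#' (parents that become trivial under restriction are carried forward
#' unchanged, so reference-side candidates are always drawn from a real
#' focal clade of that reference).
#'
#' @param p1,p2 \code{pcsp_support} references.
#' @param taxa optional expected union taxon set (checked).
#' @return \code{pcsp_support} on X1 u X2 (possibly empty).
#' @export
mutualize_pcsp_supports <- function(p1, p2, taxa = NULL) {
  x1 <- p1$taxa; x2 <- p2$taxa
  x <- clade_union(x1, x2)
  if (!is.null(taxa) && !identical(clade(taxa), x)) {
    stop("X1 u X2 does not equal the stated taxon set")
  }
  out <- list()
  visited <- new.env(hash = TRUE, parent = emptyenv())
  root <- trivial_subsplit(x)
  stack <- list(list(t = root, w = x,
                     lp1 = trivial_subsplit(x1), lp2 = trivial_subsplit(x2)))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    frkey <- paste(focal_key(fr$t, fr$w), subsplit_key(fr$lp1), subsplit_key(fr$lp2),
                   sep = " / ")
    if (!is.null(visited[[frkey]])) next
    visited[[frkey]] <- TRUE
    cand1 <- scd_side_candidates(p1, fr$lp1, clade_intersect(fr$w, x1))
    cand2 <- scd_side_candidates(p2, fr$lp2, clade_intersect(fr$w, x2))
    for (s1 in cand1) for (s2 in cand2) {
      for (s in box_product(s1, s2)) {
        p <- pcsp(fr$t, s)
        out[[pcsp_key(p)]] <- p
        r1 <- restrict_subsplit(s, x1)
        r2 <- restrict_subsplit(s, x2)
        lp1 <- if (is_trivial_subsplit(r1)) fr$lp1 else r1
        lp2 <- if (is_trivial_subsplit(r2)) fr$lp2 else r2
        for (child in list(s$y, s$z)) {
          if (length(child) >= 2) {
            stack[[length(stack) + 1L]] <- list(t = s, w = child, lp1 = lp1, lp2 = lp2)
          }
        }
      }
    }
  }
  pcsps <- prune_pcsp_set(x, out)
  pcsp_support(x, pcsps, validate = length(pcsps) > 0)
}

#' @rdname mutualize_subsplit_supports
#' @param s1,s2 two supports of the same kind.
#' @export
mutualize_supports <- function(s1, s2, taxa = NULL) {
  if (inherits(s1, "subsplit_support")) mutualize_subsplit_supports(s1, s2, taxa)
  else mutualize_pcsp_supports(s1, s2, taxa)
}

#' Incremental mutualization of several supports
#'
#' Left fold: mutualize the first two supports, then the result with the
#' third, and so on.  One-at-a-time mutualization is not guaranteed to be
#' order independent; callers who care should compare orders.
#'
#' @param supports ordered list of two or more supports of one kind.
#' @param taxa optional expected union taxon set.
#' @return mutual support on the union of all taxon sets.
#' @export
mutualize_many <- function(supports, taxa = NULL) {
  if (length(supports) < 2) stop("at least two supports required")
  acc <- supports[[1]]
  for (i in 2:length(supports)) {
    acc <- mutualize_supports(acc, supports[[i]])
    if (support_size(acc) == 0 && i < length(supports)) {
      stop("mutual support became empty after ", i, " references")
    }
  }
  if (!is.null(taxa) && !identical(clade(taxa), acc$taxa)) {
    stop("union of taxon sets does not equal the stated taxon set")
  }
  acc
}

#' Number of elements in a support
#' @param s support.
#' @export
support_size <- function(s) {
  if (inherits(s, "subsplit_support")) length(s$splits) else length(s$pcsps)
}

# ---------------------------------------------------------------------------
# Pruning to closed, reachable supports

# iteratively drop subsplits with an undivided non-singleton child clade,
# then restrict to the part reachable from the root clade
prune_subsplit_set <- function(taxa, splits) {
  repeat {
    if (length(splits) == 0) return(list())
    divided <- unique(vapply(splits, function(s) clade_key(subsplit_clade(s)), ""))
    ok <- vapply(splits, function(s) {
      for (child in list(s$y, s$z)) {
        if (length(child) >= 2 && !(clade_key(child) %in% divided)) return(FALSE)
      }
      TRUE
    }, TRUE)
    if (all(ok)) break
    splits <- splits[ok]
  }
  # reachability from the root clade
  by_clade <- split(seq_along(splits),
                    vapply(splits, function(s) clade_key(subsplit_clade(s)), ""))
  keep <- logical(length(splits))
  stack <- list(clade(taxa))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  while (length(stack) > 0) {
    w <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    wk <- clade_key(w)
    if (!is.null(seen[[wk]])) next
    seen[[wk]] <- TRUE
    for (i in by_clade[[wk]]) {
      keep[i] <- TRUE
      s <- splits[[i]]
      for (child in list(s$y, s$z)) {
        if (length(child) >= 2) stack[[length(stack) + 1L]] <- child
      }
    }
  }
  splits[keep]
}

# same for PCSP sets: closure per focal clade of each child, reachability of
# each parent from the root parent
prune_pcsp_set <- function(taxa, pcsps) {
  taxa <- clade(taxa)
  rootk <- subsplit_key(trivial_subsplit(taxa))
  repeat {
    if (length(pcsps) == 0) return(list())
    provided <- unique(unlist(lapply(pcsps, function(p) {
      focal_key(p$parent, subsplit_clade(p$child))
    })))
    ok <- vapply(pcsps, function(p) {
      ch <- p$child
      for (child in list(ch$y, ch$z)) {
        if (length(child) >= 2 && !(focal_key(ch, child) %in% provided)) return(FALSE)
      }
      TRUE
    }, TRUE)
    if (all(ok)) break
    pcsps <- pcsps[ok]
  }
  # reachability: walk down from the root focal clade
  keep <- logical(length(pcsps))
  by_focal <- split(seq_along(pcsps), vapply(pcsps, function(p) {
    focal_key(p$parent, subsplit_clade(p$child))
  }, ""))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  stack <- list(focal_key(trivial_subsplit(taxa), taxa))
  idx_focal <- function(fk) if (is.null(by_focal[[fk]])) integer(0) else by_focal[[fk]]
  while (length(stack) > 0) {
    fk <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (!is.null(seen[[fk]])) next
    seen[[fk]] <- TRUE
    for (i in idx_focal(fk)) {
      keep[i] <- TRUE
      ch <- pcsps[[i]]$child
      for (child in list(ch$y, ch$z)) {
        if (length(child) >= 2) {
          stack[[length(stack) + 1L]] <- focal_key(ch, child)
        }
      }
    }
  }
  pcsps[keep]
}

# ---------------------------------------------------------------------------
# Requirement verification (exhaustive, for enumerable taxon sets)

#' Verify the supertree-support requirements
#'
#' Requirement 1: every element of the mutual support must restrict into
#' each reference support (for PCSP supports, via a path whose intermediate
#' subsplits restrict trivially).  Requirement 2: every topology on the
#' union taxon set whose restrictions lie entirely within every reference
#' support must be representable by the mutual support.  Requirement 2 is
#' checked by exhaustive enumeration of topologies, so the union taxon set
#' must be small.
#'
#' @param m mutual support (\code{subsplit_support} or \code{pcsp_support}).
#' @param refs list of reference supports of the same kind.
#' @param cap maximum union taxon count for enumeration (default 8).
#' @return list with \code{ok} (logical), \code{req1_violations} and
#'   \code{req2_violations} (character vectors), and
#'   \code{n_required_trees}.
#' @export
verify_requirements <- function(m, refs, cap = 8) {
  x <- m$taxa
  if (length(x) > cap) stop("union taxon set exceeds enumeration cap = ", cap)
  is_ccd_kind <- inherits(m, "subsplit_support")
  req1 <- character(0)
  if (is_ccd_kind) {
    for (k in names(m$splits)) {
      for (i in seq_along(refs)) {
        sb <- restrict_subsplit(m$splits[[k]], refs[[i]]$taxa)
        if (!is_trivial_subsplit(sb) && is.na(match(subsplit_key(sb), names(refs[[i]]$splits)))) {
          req1 <- c(req1, paste0(k, " restricts to ", subsplit_key(sb),
                                 " absent from reference ", i))
        }
      }
    }
  } else {
    for (i in seq_along(refs)) {
      lna <- last_nontrivial_ancestors(m, refs[[i]]$taxa)
      for (k in names(m$pcsps)) {
        p <- m$pcsps[[k]]
        sb <- restrict_subsplit(p$child, refs[[i]]$taxa)
        if (is_trivial_subsplit(sb)) next
        us <- lna[[subsplit_key(p$parent)]]
        found <- FALSE
        for (uk in us) {
          u <- parse_subsplit_key(uk)
          cand <- tryCatch(pcsp(u, sb), error = function(e) NULL)
          if (!is.null(cand) && !is.na(match(pcsp_key(cand), names(refs[[i]]$pcsps)))) {
            found <- TRUE; break
          }
        }
        if (!found) {
          req1 <- c(req1, paste0(k, " has no restricted parent path into reference ", i))
        }
      }
    }
  }
  # Requirement 2 by enumeration
  req2 <- character(0)
  n_required <- 0L
  for (tau in enumerate_topologies(x, cap = cap)) {
    required <- TRUE
    for (ref in refs) {
      rt <- restrict_topology(tau, clade_intersect(x, ref$taxa))
      inside <- if (is_ccd_kind) {
        all(names(rt$splits) %in% names(ref$splits))
      } else {
        all(names(pcsp_decomposition(rt)) %in% names(ref$pcsps))
      }
      if (!inside) { required <- FALSE; break }
    }
    if (!required) next
    n_required <- n_required + 1L
    contained <- if (is_ccd_kind) {
      all(names(tau$splits) %in% names(m$splits))
    } else {
      all(names(pcsp_decomposition(tau)) %in% names(m$pcsps))
    }
    if (!contained) {
      req2 <- c(req2, paste0("required topology ", topology_key(tau), " not representable"))
    }
  }
  list(ok = length(req1) == 0 && length(req2) == 0,
       req1_violations = req1, req2_violations = req2,
       n_required_trees = n_required)
}

# For every subsplit appearing as a PCSP parent in m (plus the root parent),
# the set of possible restrictions of its last nontrivially-restricting
# ancestor (itself included), as subsplit keys on xbar.  Used by the
# Requirement 1 path check.
last_nontrivial_ancestors <- function(m, xbar) {
  xbar <- clade_intersect(m$taxa, xbar)
  rootk <- subsplit_key(trivial_subsplit(m$taxa))
  rootbar <- subsplit_key(trivial_subsplit(xbar))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  lna <- function(tk) {
    v <- memo[[tk]]
    if (!is.null(v)) return(v)
    memo[[tk]] <- character(0)  # cycle guard (supports are acyclic anyway)
    if (tk == rootk) {
      res <- rootbar
    } else {
      t <- parse_subsplit_key(tk)
      tb <- restrict_subsplit(t, xbar)
      if (!is_trivial_subsplit(tb)) {
        res <- subsplit_key(tb)
      } else {
        res <- character(0)
        for (k in m$by_child[[tk]]) {
          res <- union(res, lna(subsplit_key(m$pcsps[[k]]$parent)))
        }
      }
    }
    memo[[tk]] <- res
    res
  }
  parents <- unique(c(rootk, vapply(m$pcsps, function(p) subsplit_key(p$parent), "")))
  out <- lapply(parents, lna)
  names(out) <- parents
  out
}
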