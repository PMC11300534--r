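# Subsplit Bayesian networks over rooted bifurcating topologies, in the two
# parameterizations used throughout the package:
#   CCD  - clade-conditional distributions, p(s | U(s))
#   SCD  - subsplit-conditional distributions, p(s | (t, U(s)))
# A distribution is a support (the building blocks with positive
# probability) plus conditional probability tables, one softmax-normalized
# block per clade (CCD) or per focal parent clade (SCD).

focal_key <- function(t, w) paste0(subsplit_key(t), " @ ", clade_key(w))

#' Subsplit support
#'
#' The set of nontrivial subsplits with positive probability under a
#' CCD-parameterized SBN.  A valid support is closed and reachable: the root
#' clade is divided, and every non-singleton child clade of every member is
#' divided by at least one member.
#'
#' @param taxa taxon set.
#' @param splits list of subsplits.
#' @param validate check closure/reachability.
#' @return object of class \code{"subsplit_support"} with a by-clade index.
#' @export
subsplit_support <- function(taxa, splits, validate = TRUE) {
  taxa <- clade(taxa)
  names(splits) <- vapply(splits, subsplit_key, "")
  splits <- splits[!duplicated(names(splits))]
  by_clade <- list()
  for (k in names(splits)) {
    s <- splits[[k]]
    if (is_trivial_subsplit(s)) stop("supports store nontrivial subsplits only")
    w <- clade_key(subsplit_clade(s))
    by_clade[[w]] <- c(by_clade[[w]], k)
  }
  obj <- structure(list(taxa = taxa, splits = splits, by_clade = by_clade),
                   class = "subsplit_support")
  if (validate) validate_subsplit_support(obj)
  obj
}

#' @rdname subsplit_support
#' @param cs subsplit support.
#' @export
validate_subsplit_support <- function(cs) {
  if (length(cs$taxa) < 2) stop("support taxon set must have >= 2 taxa")
  if (is.null(cs$by_clade[[clade_key(cs$taxa)]])) stop("root clade is not divided")
  for (s in cs$splits) {
    for (child in list(s$y, s$z)) {
      if (length(child) >= 2 && is.null(cs$by_clade[[clade_key(child)]])) {
        stop("support is not closed: clade ", clade_key(child), " is not divided")
      }
    }
  }
  invisible(cs)
}

#' @rdname subsplit_support
#' @param w clade.
#' @return \code{support_query_clade}: character vector of member keys
#'   dividing \code{w} (the trivial subsplit is handled implicitly by
#'   callers).
#' @export
support_query_clade <- function(cs, w) {
  keys <- cs$by_clade[[clade_key(w)]]
  if (is.null(keys)) character(0) else keys
}

#' PCSP support
#'
#' The set of parent-child subsplit pairs with positive probability under an
#' SCD-parameterized SBN (singleton children and trivial subsplits are kept
#' implicit).  Valid supports are reachable from the root parent \{X, 0\}
#' and closed: every non-singleton child clade of every member's child
#' subsplit is divided by a member with that child subsplit as parent.
#'
#' @param taxa taxon set.
#' @param pcsps list of PCSPs.
#' @param validate check closure/reachability.
#' @return object of class \code{"pcsp_support"} with by-focal and by-child
#'   indices.
#' @export
pcsp_support <- function(taxa, pcsps, validate = TRUE) {
  taxa <- clade(taxa)
  names(pcsps) <- vapply(pcsps, pcsp_key, "")
  pcsps <- pcsps[!duplicated(names(pcsps))]
  by_focal <- list(); by_child <- list(); splits <- list()
  for (k in names(pcsps)) {
    p <- pcsps[[k]]
    if (is_trivial_subsplit(p$child)) stop("supports store nontrivial child subsplits only")
    fk <- focal_key(p$parent, subsplit_clade(p$child))
    ck <- subsplit_key(p$child)
    by_focal[[fk]] <- c(by_focal[[fk]], k)
    by_child[[ck]] <- c(by_child[[ck]], k)
    splits[[ck]] <- p$child
  }
  obj <- structure(list(taxa = taxa, pcsps = pcsps, by_focal = by_focal,
                        by_child = by_child, splits = splits),
                   class = "pcsp_support")
  if (validate) validate_pcsp_support(obj)
  obj
}

#' @rdname pcsp_support
#' @param ps PCSP support.
#' @export
validate_pcsp_support <- function(ps) {
  x <- ps$taxa
  if (length(x) < 2) stop("support taxon set must have >= 2 taxa")
  rootp <- subsplit_key(trivial_subsplit(x))
  if (is.null(ps$by_focal[[focal_key(trivial_subsplit(x), x)]])) {
    stop("root clade is not divided")
  }
  for (k in names(ps$pcsps)) {
    p <- ps$pcsps[[k]]
    pk <- subsplit_key(p$parent)
    if (pk != rootp && is.null(ps$by_child[[pk]])) {
      stop("support is not reachable: parent of ", k, " is not a member child")
    }
    ch <- p$child
    for (child in list(ch$y, ch$z)) {
      if (length(child) >= 2 && is.null(ps$by_focal[[focal_key(ch, child)]])) {
        stop("support is not closed: focal clade (", subsplit_key(ch), ", ",
             clade_key(child), ") is not divided")
      }
    }
  }
  invisible(ps)
}

#' @rdname pcsp_support
#' @param t parent subsplit; \code{w} its child clade under focus.
#' @return \code{support_query_focal}: member keys dividing the focal clade
#'   \code{(t, w)}.
#' @export
support_query_focal <- function(ps, t, w) {
  keys <- ps$by_focal[[focal_key(t, w)]]
  if (is.null(keys)) character(0) else keys
}

#' @export
print.subsplit_support <- function(x, ...) {
  cat("subsplit support on ", length(x$taxa), " taxa: ", length(x$splits),
      " subsplits\n", sep = "")
  invisible(x)
}

#' @export
print.pcsp_support <- function(x, ...) {
  cat("PCSP support on ", length(x$taxa), " taxa: ", length(x$pcsps),
      " PCSPs\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Distributions

check_block_sums <- function(sums, what, tol = 1e-9) {
  bad <- abs(sums - 1) > tol
  if (any(bad)) {
    stop(what, " block does not normalize: ", names(sums)[bad][1],
         " sums to ", sums[bad][1])
  }
}

#' Clade-conditional (CCD) SBN distribution
#'
#' @param support \code{subsplit_support}.
#' @param cond named numeric: conditional probability p(s | U(s)) for every
#'   support subsplit key; each clade block must sum to 1.
#' @return object of class \code{c("ccd", "sbn")}.
#' @export
ccd <- function(support, cond) {
  stopifnot(inherits(support, "subsplit_support"))
  if (!setequal(names(cond), names(support$splits))) {
    stop("cond must cover exactly the support subsplits")
  }
  cond <- cond[names(support$splits)]
  if (any(cond <= 0)) stop("conditional probabilities must be positive on the support")
  sums <- vapply(support$by_clade, function(keys) sum(cond[keys]), 0)
  check_block_sums(sums, "clade")
  structure(list(support = support, cond = cond), class = c("ccd", "sbn"))
}

#' Subsplit-conditional (SCD) SBN distribution
#'
#' @param support \code{pcsp_support}.
#' @param cond named numeric: conditional probability p(s | (t, U(s))) for
#'   every support PCSP key; each focal-clade block must sum to 1.
#' @return object of class \code{c("scd", "sbn")}.
#' @export
scd <- function(support, cond) {
  stopifnot(inherits(support, "pcsp_support"))
  if (!setequal(names(cond), names(support$pcsps))) {
    stop("cond must cover exactly the support PCSPs")
  }
  cond <- cond[names(support$pcsps)]
  if (any(cond <= 0)) stop("conditional probabilities must be positive on the support")
  sums <- vapply(support$by_focal, function(keys) sum(cond[keys]), 0)
  check_block_sums(sums, "focal-clade")
  structure(list(support = support, cond = cond), class = c("scd", "sbn"))
}

#' @export
print.sbn <- function(x, ...) {
  kind <- if (inherits(x, "ccd")) "CCD" else "SCD"
  cat(kind, "-parameterized SBN on ", length(x$support$taxa), " taxa, ",
      length(x$cond), " conditional parameters\n", sep = "")
  invisible(x)
}

sbn_kind <- function(d) if (inherits(d, "ccd")) "ccd" else "scd"

sbn_taxa <- function(d) d$support$taxa

#' SBN probability of a topology
#'
#' Product of conditional probabilities over the subsplits (CCD) or PCSPs
#' (SCD) of the topology; 0 if any factor lies outside the support.
#' Accumulated in log space.
#'
#' @param d SBN distribution (\code{ccd} or \code{scd}).
#' @param tau rooted topology on the same taxon set.
#' @return probability in [0, 1].
#' @export
tree_probability <- function(d, tau) {
  if (!identical(sbn_taxa(d), tau$taxa)) stop("taxon sets differ")
  keys <- if (inherits(d, "ccd")) names(tau$splits) else names(pcsp_decomposition(tau))
  lp <- 0
  for (k in keys) {
    ck <- d$cond[k]
    if (is.na(ck)) return(0)
    lp <- lp + log(ck[[1]])
  }
  exp(lp)
}

#' Sample topologies from an SBN
#'
#' Recursive top-down sampling: starting from the root clade (root focal
#' clade for SCDs), repeatedly draw a dividing subsplit from the conditional
#' distribution.  The marginal law equals \code{\link{tree_probability}}.
#'
#' @param d SBN distribution.
#' @param n number of draws.
#' @param seed optional integer seed (set locally for reproducibility).
#' @return \code{sample_topologies}: list of rooted topologies;
#'   \code{sample_topology}: a single topology.
#' @export
sample_topologies <- function(d, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n, sample_one(d), simplify = FALSE)
}

#' @rdname sample_topologies
#' @export
sample_topology <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_one(d)
}

sample_one <- function(d) {
  x <- sbn_taxa(d)
  splits <- list()
  if (inherits(d, "ccd")) {
    rec <- function(w) {
      if (length(w) < 2) return()
      keys <- support_query_clade(d$support, w)
      k <- if (length(keys) == 1) keys else sample(keys, 1, prob = d$cond[keys])
      s <- d$support$splits[[k]]
      splits[[k]] <<- s
      rec(s$y); rec(s$z)
    }
    rec(x)
  } else {
    rec <- function(t, w) {
      if (length(w) < 2) return()
      keys <- support_query_focal(d$support, t, w)
      k <- if (length(keys) == 1) keys else sample(keys, 1, prob = d$cond[keys])
      s <- d$support$pcsps[[k]]$child
      splits[[subsplit_key(s)]] <<- s
      rec(s, s$y); rec(s, s$z)
    }
    rec(trivial_subsplit(x), x)
  }
  rooted_topology(x, splits, validate = FALSE)
}

#' Maximum-likelihood SBN estimation from weighted topologies
#'
#' Topologies whose total weight is below \code{min_count} are trimmed
#' before estimation (the default 2 removes topologies appearing only once
#' in a posterior sample; 1 disables trimming).  Conditional probabilities
#' are weighted relative frequencies, the maximum-likelihood estimate for
#' rooted SBNs.
#'
#' @param trees list of rooted topologies on one taxon set.
#' @param kind \code{"ccd"} or \code{"scd"}.
#' @param weights nonnegative weights (default all 1).
#' @param min_count trim threshold on per-topology total weight.
#' @return \code{ccd} or \code{scd} distribution.
#' @export
estimate_from_trees <- function(trees, kind = c("ccd", "scd"),
                                weights = rep(1, length(trees)), min_count = 2) {
  kind <- match.arg(kind)
  if (length(trees) == 0) stop("no input trees")
  keys <- vapply(trees, topology_key, "")
  tot <- tapply(weights, keys, sum)
  keep <- names(tot)[tot >= min_count]
  if (length(keep) == 0) stop("no topologies survive min_count = ", min_count, " trimming")
  trees <- trees[match(keep, keys)]
  w <- as.numeric(tot[keep])
  taxa <- trees[[1]]$taxa
  cnt <- new.env(hash = TRUE, parent = emptyenv())
  denom <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(env, k, v) {
    prev <- env[[k]]
    env[[k]] <- if (is.null(prev)) v else prev + v
  }
  elements <- list()
  if (kind == "ccd") {
    for (i in seq_along(trees)) {
      for (s in trees[[i]]$splits) {
        k <- subsplit_key(s)
        add(cnt, k, w[i])
        add(denom, clade_key(subsplit_clade(s)), w[i])
        elements[[k]] <- s
      }
    }
    support <- subsplit_support(taxa, elements)
    cond <- vapply(names(support$splits), function(k) {
      s <- support$splits[[k]]
      cnt[[k]] / denom[[clade_key(subsplit_clade(s))]]
    }, 0)
    ccd(support, cond)
  } else {
    for (i in seq_along(trees)) {
      for (p in pcsp_decomposition(trees[[i]])) {
        k <- pcsp_key(p)
        add(cnt, k, w[i])
        add(denom, focal_key(p$parent, subsplit_clade(p$child)), w[i])
        elements[[k]] <- p
      }
    }
    support <- pcsp_support(taxa, elements)
    cond <- vapply(names(support$pcsps), function(k) {
      p <- support$pcsps[[k]]
      cnt[[k]] / denom[[focal_key(p$parent, subsplit_clade(p$child))]]
    }, 0)
    scd(support, cond)
  }
}

# ---------------------------------------------------------------------------
# Unconditional probabilities (top-down accumulation)

#' Unconditional subsplit, clade and PCSP probability tables
#'
#' One top-down pass accumulating arrival probabilities: for CCDs, clade
#' probabilities feed subsplit probabilities; for SCDs, subsplit
#' probabilities feed PCSP probabilities.
#'
#' @param d SBN distribution.
#' @return list with named numeric components \code{split} (unconditional
#'   subsplit probabilities), \code{clade} (CCD only) and \code{pcsp}
#'   (SCD only).
#' @export
sbn_unconditional <- function(d) {
  if (inherits(d, "ccd")) {
    cs <- d$support
    clades <- names(cs$by_clade)
    clades <- clades[order(-vapply(clades, function(k) length(parse_clade_key(k)), 0L), clades)]
    h <- structure(numeric(length(clades)), names = clades)
    h[clade_key(cs$taxa)] <- 1
    ps <- structure(numeric(length(cs$splits)), names = names(cs$splits))
    for (wk in clades) {
      for (k in cs$by_clade[[wk]]) {
        s <- cs$splits[[k]]
        pk <- h[[wk]] * d$cond[[k]]
        ps[[k]] <- pk
        for (child in list(s$y, s$z)) {
          if (length(child) >= 2) {
            ck <- clade_key(child)
            h[[ck]] <- h[[ck]] + pk
          }
        }
      }
    }
    list(split = ps, clade = h)
  } else {
    ps <- d$support
    x <- ps$taxa
    split_keys <- names(ps$splits)
    ord <- order(-vapply(ps$splits, function(s) length(subsplit_clade(s)), 0L), split_keys)
    split_keys <- split_keys[ord]
    psub <- structure(numeric(length(split_keys)), names = split_keys)
    ppc <- structure(numeric(length(ps$pcsps)), names = names(ps$pcsps))
    rootp <- trivial_subsplit(x)
    for (k in support_query_focal(ps, rootp, x)) {
      ppc[[k]] <- d$cond[[k]]
      ck <- subsplit_key(ps$pcsps[[k]]$child)
      psub[[ck]] <- psub[[ck]] + ppc[[k]]
    }
    for (tk in split_keys) {
      t <- ps$splits[[tk]]
      pt <- psub[[tk]]
      for (child in list(t$y, t$z)) {
        if (length(child) < 2) next
        for (k in support_query_focal(ps, t, child)) {
          ppc[[k]] <- pt * d$cond[[k]]
          ck <- subsplit_key(ps$pcsps[[k]]$child)
          psub[[ck]] <- psub[[ck]] + ppc[[k]]
        }
      }
    }
    list(split = psub, pcsp = ppc)
  }
}

#' Unconditional probability of one subsplit
#'
#' @param d SBN distribution.
#' @param s subsplit.
#' @return probability that \code{s} occurs in a topology drawn from
#'   \code{d}; 0 if \code{s} is outside the support.
#' @export
unconditional_subsplit_prob <- function(d, s) {
  tab <- sbn_unconditional(d)$split
  v <- tab[subsplit_key(s)]
  if (is.na(v)) 0 else unname(v)
}

#' Unconditional probability of one PCSP
#'
#' @param d SCD distribution.
#' @param t parent subsplit; \code{s} child subsplit (\code{t -> s} must be
#'   a valid PCSP).
#' @return probability p(s | (t, U(s))) p(t).
#' @export
unconditional_pcsp_prob <- function(d, t, s) {
  stopifnot(inherits(d, "scd"))
  key <- pcsp_key(pcsp(t, s))  # validates the PCSP
  tab <- sbn_unconditional(d)$pcsp
  v <- tab[key]
  if (is.na(v)) 0 else unname(v)
}

# ---------------------------------------------------------------------------
# Workspace: memoized conditional path probabilities
#
# g(a, d)      = Pr(d in tau | a in tau), the conditional ancestor-descendant
#                path probability q(a ->* d | a); 1 when a = d.
# cc(W, d)     = Pr(d in tau | clade W in tau) for CCDs, q(W ->* d | W).
# f(t, W, d)   = Pr(d in tau | focal clade (t, W) in tau) for SCDs,
#                q((t, W) ->* d | (t, W)).
# All values are memoized per workspace; a workspace is valid for one fixed
# distribution.

#' Create a memoization workspace for path probabilities
#'
#' @param d SBN distribution.
#' @return environment with closures \code{g(a_key, d_key)} and, depending
#'   on the parameterization, \code{cc(w_key, d_key)} (CCD) or
#'   \code{f(t_key, w_key, d_key)} (SCD), plus the unconditional tables in
#'   \code{$uncond} and split objects in \code{$split_obj(key)}.
#' @keywords internal
sbn_workspace <- function(d) {
  ws <- new.env(parent = emptyenv())
  ws$d <- d
  ws$uncond <- sbn_unconditional(d)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  obj_cache <- new.env(hash = TRUE, parent = emptyenv())
  split_obj <- function(k) {
    o <- obj_cache[[k]]
    if (is.null(o)) { o <- parse_subsplit_key(k); obj_cache[[k]] <- o }
    o
  }
  ws$split_obj <- split_obj
  if (inherits(d, "ccd")) {
    cs <- d$support
    cc <- function(wk, dk) {
      key <- paste0("c\r", wk, "\r", dk)
      v <- memo[[key]]
      if (!is.null(v)) return(v)
      dd <- split_obj(dk)
      ud <- clade_key(subsplit_clade(dd))
      v <- 0
      if (ud == wk) {
        v <- if (is.na(d$cond[dk])) 0 else unname(d$cond[dk])
      } else if (clade_contains(parse_clade_key(wk), subsplit_clade(dd))) {
        for (k in cs$by_clade[[wk]]) {
          s <- cs$splits[[k]]
          for (child in list(s$y, s$z)) {
            if (length(child) >= 2 && clade_contains(child, subsplit_clade(dd))) {
              v <- v + d$cond[[k]] * cc(clade_key(child), dk)
            }
          }
        }
      }
      memo[[key]] <- v
      v
    }
    g <- function(ak, dk) {
      if (ak == dk) return(1)
      a <- split_obj(ak); dd <- split_obj(dk)
      ud <- subsplit_clade(dd)
      for (child in list(a$y, a$z)) {
        if (length(child) >= 2 && clade_contains(child, ud)) {
          return(cc(clade_key(child), dk))
        }
      }
      0
    }
    ws$cc <- cc
    ws$g <- g
  } else {
    # full path-probability matrices by dynamic programming:
    #   G[s, dk] = q(s ->* d | s), computed column-wise in decreasing clade
    #   size of d (a column only depends on the columns of d's parents);
    #   F[(t, W), dk] = q((t, W) ->* d | (t, W)), a conditional mix of G rows.
    ps <- d$support
    skeys <- names(ps$splits)
    sizes <- vapply(ps$splits, function(s) length(subsplit_clade(s)), 0L)
    ord <- skeys[order(-sizes, skeys)]
    G <- matrix(0, length(skeys), length(skeys), dimnames = list(skeys, skeys))
    for (dk in ord) {
      col <- numeric(length(skeys))
      for (k in ps$by_child[[dk]]) {
        tk <- subsplit_key(ps$pcsps[[k]]$parent)
        if (!is.na(match(tk, skeys))) col <- col + d$cond[[k]] * G[, tk]
      }
      col[match(dk, skeys)] <- 1
      G[, dk] <- col
    }
    fkeys <- names(ps$by_focal)
    F <- matrix(0, length(fkeys), length(skeys), dimnames = list(fkeys, skeys))
    for (fk in fkeys) {
      for (k in ps$by_focal[[fk]]) {
        F[fk, ] <- F[fk, ] + d$cond[[k]] * G[subsplit_key(ps$pcsps[[k]]$child), ]
      }
    }
    ws$G <- G
    ws$F <- F
    ws$g <- function(ak, dk) G[[ak, dk]]
    ws$f <- function(tk, wk, dk) {
      i <- match(paste0(tk, " @ ", wk), fkeys)
      if (is.na(i)) 0 else F[[i, match(dk, skeys)]]
    }
  }
  ws
}

#' Ancestor-descendant path probability
#'
#' The probability q(a ->* d) that subsplits \code{a} and \code{d} co-occur
#' in a topology drawn from \code{d}; zero when \code{dsub} is not a valid
#' descendant of \code{a}, and q(a) when they coincide.
#'
#' @param d SBN distribution.
#' @param a ancestor subsplit.
#' @param dsub descendant subsplit.
#' @return probability.
#' @export
path_probability <- function(d, a, dsub) {
  ws <- sbn_workspace(d)
  ak <- subsplit_key(a)
  dk <- subsplit_key(dsub)
  qa <- ws$uncond$split[ak]
  if (is.na(qa)) return(0)
  if (ak == dk) return(unname(qa))
  if (is.na(match(dk, names(d$support$splits)))) return(0)
  unname(qa) * ws$g(ak, dk)
}

# ---------------------------------------------------------------------------
# Closed-form KL divergences

#' KL divergence between two CCD-parameterized SBNs
#'
#' \eqn{-\sum_s p(s) [\log q(s|U(s)) - \log p(s|U(s))]}, a sum over the
#' subsplit support of \code{p}; linear time in the support size.
#'
#' @param p,q \code{ccd} distributions on the same taxon set.
#' @return KL divergence in nats.
#' @export
kl_ccd <- function(p, q) {
  stopifnot(inherits(p, "ccd"), inherits(q, "ccd"))
  if (!identical(sbn_taxa(p), sbn_taxa(q))) stop("taxon sets differ")
  pu <- sbn_unconditional(p)$split
  total <- 0
  for (k in names(p$cond)) {
    qc <- q$cond[k]
    if (is.na(qc)) {
      stop("support incompatibility: subsplit ", k, " absent from q; ",
           "the KL divergence is undefined")
    }
    total <- total - pu[[k]] * (log(qc) - log(p$cond[[k]]))
  }
  unname(total)
}

#' KL divergence between two SCD-parameterized SBNs
#'
#' \eqn{-\sum_{t \to s} p(t \to s) [\log q(s|(t,U(s))) - \log p(s|(t,U(s)))]},
#' a sum over the PCSP support of \code{p}; linear time in the support size.
#'
#' @param p,q \code{scd} distributions on the same taxon set.
#' @return KL divergence in nats.
#' @export
kl_scd <- function(p, q) {
  stopifnot(inherits(p, "scd"), inherits(q, "scd"))
  if (!identical(sbn_taxa(p), sbn_taxa(q))) stop("taxon sets differ")
  pu <- sbn_unconditional(p)$pcsp
  total <- 0
  for (k in names(p$cond)) {
    qc <- q$cond[k]
    if (is.na(qc)) {
      stop("support incompatibility: PCSP ", k, " absent from q; ",
           "the KL divergence is undefined")
    }
    total <- total - pu[[k]] * (log(qc) - log(p$cond[[k]]))
  }
  unname(total)
}

#' @rdname kl_ccd
#' @export
kl_sbn <- function(p, q) if (inherits(p, "ccd")) kl_ccd(p, q) else kl_scd(p, q)

# ---------------------------------------------------------------------------
# Explicit enumeration of an SBN (the oracle bridge)

#' Enumerate the tree distribution induced by an SBN
#'
#' Assembles every topology representable by the support together with its
#' probability; the masses of a valid SBN sum to 1.
#'
#' @param d SBN distribution.
#' @param cap capacity guard on the number of topologies (default 2e5).
#' @return \code{tree_distribution}.
#' @export
enumerate_support_trees <- function(d, cap = 2e5) {
  x <- sbn_taxa(d)
  count_guard <- function(n) if (n > cap) stop("support contains more than cap = ", cap, " topologies")
  combine <- function(s, k, left, right, condv) {
    out <- vector("list", length(left) * length(right))
    i <- 0L
    for (a in left) for (b in right) {
      i <- i + 1L
      out[[i]] <- list(splits = c(a$splits, b$splits, list(s)),
                       prob = condv * a$prob * b$prob)
    }
    out
  }
  if (inherits(d, "ccd")) {
    memo <- new.env(hash = TRUE, parent = emptyenv())
    rec <- function(w) {
      if (length(w) < 2) return(list(list(splits = list(), prob = 1)))
      wk <- clade_key(w)
      v <- memo[[wk]]
      if (!is.null(v)) return(v)
      out <- list()
      for (k in support_query_clade(d$support, w)) {
        s <- d$support$splits[[k]]
        out <- c(out, combine(s, k, rec(s$y), rec(s$z), d$cond[[k]]))
        count_guard(length(out))
      }
      memo[[wk]] <- out
      out
    }
    res <- rec(x)
  } else {
    memo <- new.env(hash = TRUE, parent = emptyenv())
    rec <- function(t, w) {
      if (length(w) < 2) return(list(list(splits = list(), prob = 1)))
      fk <- focal_key(t, w)
      v <- memo[[fk]]
      if (!is.null(v)) return(v)
      out <- list()
      for (k in support_query_focal(d$support, t, w)) {
        s <- d$support$pcsps[[k]]$child
        out <- c(out, combine(s, k, rec(s, s$y), rec(s, s$z), d$cond[[k]]))
        count_guard(length(out))
      }
      memo[[fk]] <- out
      out
    }
    res <- rec(trivial_subsplit(x), x)
  }
  trees <- lapply(res, function(r) rooted_topology(x, r$splits, validate = FALSE))
  prob <- vapply(res, function(r) r$prob, 0)
  tree_distribution(trees, prob)
}
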