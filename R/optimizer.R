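# Variational training of the supertree SBN: softmax parameterization over
# a (mutual) support, restricted-KL loss against reference SBNs, analytic
# gradients, and plain gradient descent with step halving.

#' Softmax-parameterized SBN
#'
#' Conditional probabilities are softmax transforms of an unconstrained
#' parameter vector v, one block per clade (CCD supports) or per focal
#' parent clade (SCD supports).  Adding a constant to all parameters of one
#' block leaves the distribution unchanged (softmax gauge freedom).  The
#' default v = 0 is the high-entropy start: all conditionals uniform.
#'
#' @param support \code{subsplit_support} or \code{pcsp_support}.
#' @param v named numeric over the support element keys (default all 0).
#' @return object of class \code{"sbn_params"}.
#' @export
sbn_params <- function(support, v = NULL) {
  kind <- if (inherits(support, "subsplit_support")) "ccd" else "scd"
  keys <- if (kind == "ccd") names(support$splits) else names(support$pcsps)
  if (is.null(v)) v <- structure(numeric(length(keys)), names = keys)
  if (!setequal(names(v), keys)) stop("v must be named by the support element keys")
  v <- v[keys]
  blocks <- if (kind == "ccd") support$by_clade else support$by_focal
  structure(list(kind = kind, support = support, v = v, blocks = blocks),
            class = "sbn_params")
}

#' @rdname sbn_params
#' @param params \code{sbn_params}.
#' @return \code{as_sbn}: the \code{ccd}/\code{scd} distribution the
#'   parameters define.
#' @export
as_sbn <- function(params) {
  cond <- params$v
  for (keys in params$blocks) {
    e <- exp(params$v[keys] - max(params$v[keys]))
    cond[keys] <- e / sum(e)
  }
  if (params$kind == "ccd") ccd(params$support, cond) else scd(params$support, cond)
}

check_reference <- function(params, ref, i) {
  x <- clade(params$support$taxa)
  if (!clade_contains(x, ref$support$taxa)) {
    stop("reference ", i, " taxon set is not a subset of the supertree taxon set")
  }
  want <- if (params$kind == "ccd") "ccd" else "scd"
  if (sbn_kind(ref) != want) stop("reference ", i, " is not ", toupper(want), "-parameterized")
}

#' Restricted-KL loss of a supertree SBN against reference SBNs
#'
#' \eqn{\sum_i w_i KL(p_i || q\downharpoonright_{X_i}) + \lambda ||v||^2}.
#' Each reference support must be covered by the restriction of the
#' supertree support to the reference taxon set; otherwise the KL divergence
#' is undefined and an error names the offending reference.
#'
#' @param params \code{sbn_params} for the supertree distribution q.
#' @param references list of reference SBNs (same parameterization) on
#'   subsets of q's taxon set.
#' @param weights positive reference weights (default all 1).
#' @param lambda nonnegative L2 penalty coefficient on v (default 0, the
#'   plain loss).
#' @return loss in nats.
#' @export
sbn_loss <- function(params, references, weights = rep(1, length(references)),
                     lambda = 0) {
  q <- as_sbn(params)
  total <- if (lambda > 0) lambda * sum(params$v^2) else 0
  for (i in seq_along(references)) {
    ref <- references[[i]]
    check_reference(params, ref, i)
    qi <- if (identical(ref$support$taxa, sbn_taxa(q))) q
          else restrict_sbn(q, ref$support$taxa)
    kl <- tryCatch(kl_sbn(ref, qi), error = function(e) {
      stop("reference ", i, ": ", conditionMessage(e))
    })
    total <- total + weights[i] * kl
  }
  total
}

#' Analytic gradient of the restricted-KL loss
#'
#' CCD parameters: for each support subsplit s with nontrivial restriction,
#' the KL derivative weights d q(s) / d v_{s'} by the mismatch between
#' reference and restricted clade/subsplit probabilities, with
#' \deqn{\partial_{s'} q(s) = q(U(s')) q(s'|U(s')) [q(s' \to_* s | s') -
#'   q(U(s') \to_* s | U(s'))].}
#' SCD parameters: the two-term form, a sum over restricted parents
#' (weighted by the number of their size->=2 child clades) of derivatives of
#' fiber subsplit probabilities, minus a sum over restricted PCSPs of
#' derivatives of fiber ancestor-descendant path probabilities.
#'
#' @inheritParams sbn_loss
#' @return named numeric gradient over the parameter keys.
#' @export
sbn_gradient <- function(params, references, weights = rep(1, length(references)),
                         lambda = 0) {
  q <- as_sbn(params)
  ws <- sbn_workspace(q)
  grad <- structure(numeric(length(params$v)), names = names(params$v))
  for (i in seq_along(references)) {
    check_reference(params, ref <- references[[i]], i)
    gi <- if (params$kind == "ccd") {
      gradient_ccd_one(q, ws, ref)
    } else {
      gradient_scd_one(q, ws, ref)
    }
    grad <- grad + weights[i] * gi
  }
  if (lambda > 0) grad <- grad + 2 * lambda * params$v
  grad
}

# gradient of KL(p || q restricted to p's taxa) w.r.t. CCD softmax params.
# The denominators are the exact restricted subsplit/clade probabilities
# (fiber sums over unconditional probabilities), the quantities whose ratios
# define the restricted conditionals in the loss.
gradient_ccd_one <- function(q, ws, p) {
  xbar <- p$support$taxa
  up <- sbn_unconditional(p)
  keys <- names(q$support$splits)
  grad <- structure(numeric(length(keys)), names = keys)
  at0 <- function(tab, k) { v <- tab[k]; if (is.na(v)) 0 else unname(v) }
  # exact restricted subsplit and clade probabilities (fiber sums)
  usplit_full <- ws$uncond$split
  rsub <- numeric(0); rclade <- numeric(0); rkey <- character(length(keys))
  for (idx in seq_along(keys)) {
    k <- keys[idx]
    sb <- restrict_subsplit(q$support$splits[[k]], xbar)
    if (is_trivial_subsplit(sb)) { rkey[idx] <- NA_character_; next }
    sk <- subsplit_key(sb)
    rkey[idx] <- sk
    rsub[sk] <- (if (is.na(rsub[sk])) 0 else rsub[sk]) + usplit_full[[k]]
  }
  for (sk in names(rsub)) {
    wk <- clade_key(subsplit_clade(parse_subsplit_key(sk)))
    rclade[wk] <- (if (is.na(rclade[wk])) 0 else rclade[wk]) + rsub[[sk]]
  }
  # coefficient of d q(s) for each support subsplit with nontrivial restriction
  for (idx in seq_along(keys)) {
    k <- keys[idx]
    sk <- rkey[idx]
    if (is.na(sk)) next
    wk <- clade_key(subsplit_clade(parse_subsplit_key(sk)))
    coef <- at0(up$clade, wk) / rclade[[wk]] - at0(up$split, sk) / rsub[[sk]]
    if (coef == 0) next
    for (pk in keys) {
      # d q(s=k) / d v_{s'=pk}
      sprime <- q$support$splits[[pk]]
      uk <- clade_key(subsplit_clade(sprime))
      arr <- ws$uncond$clade[[uk]]
      if (arr == 0) next
      dterm <- ws$g(pk, k) - ws$cc(uk, k)
      if (dterm == 0) next
      grad[pk] <- grad[pk] + coef * arr * q$cond[[pk]] * dterm
    }
  }
  grad
}

# gradient of KL(p || q restricted) w.r.t. SCD softmax params.  The
# per-parameter derivative pieces D(s'|t'; a) are assembled once into a
# parameters x fiber-subsplits matrix so the accumulation over restricted
# parents and PCSPs is vectorized over parameters.
gradient_scd_one <- function(q, ws, p) {
  xbar <- p$support$taxa
  full <- identical(sbn_taxa(q), xbar)
  qr <- if (full) q else restrict_scd(q, xbar, ws)
  up <- sbn_unconditional(p)
  usplit <- ws$uncond$split
  support <- q$support
  pkeys <- names(support$pcsps)
  rootbar_k <- subsplit_key(trivial_subsplit(xbar))
  at0 <- function(tab, k) { v <- tab[k]; if (is.na(v)) 0 else unname(v) }

  # restriction fibers: restricted subsplit key -> original subsplit keys
  fiber <- list()
  for (k in names(support$splits)) {
    sb <- restrict_subsplit(support$splits[[k]], xbar)
    if (!is_trivial_subsplit(sb)) fiber[[subsplit_key(sb)]] <- c(fiber[[subsplit_key(sb)]], k)
  }
  targets <- unique(unlist(fiber, use.names = FALSE))
  # exact restricted parent probabilities (fiber sums)
  rprob <- vapply(fiber, function(ks) sum(usplit[ks]), 0)

  par_keys <- vapply(support$pcsps, function(pc) subsplit_key(pc$parent), "")
  child_keys <- vapply(support$pcsps, function(pc) subsplit_key(pc$child), "")
  childw_keys <- vapply(support$pcsps, function(pc) clade_key(subsplit_clade(pc$child)), "")
  condv <- unname(q$cond[pkeys])
  qp <- unname(usplit[par_keys]); qp[is.na(qp)] <- 1  # root parent has prob 1

  # D[i, j] = q(s'_i | t'_i) [ g(s'_i, a_j) - f((t'_i, U(s'_i)), a_j) ]
  focal_of_param <- paste0(par_keys, " @ ", childw_keys)
  D <- condv * (ws$G[child_keys, targets, drop = FALSE] -
                  ws$F[focal_of_param, targets, drop = FALSE])
  dimnames(D) <- list(pkeys, targets)
  # GPT[i, j] = q(a_j ->* t'_i | a_j), zero for the root parent
  GPT <- matrix(0, length(pkeys), length(targets), dimnames = list(pkeys, targets))
  real_parent <- !is.na(match(par_keys, names(support$splits)))
  if (any(real_parent)) {
    GPT[real_parent, ] <- t(ws$G[targets, par_keys[real_parent], drop = FALSE])
  }

  grad <- structure(numeric(length(pkeys)), names = pkeys)
  # first term: restricted parents tbar (non-root) in p's support;
  # d q(a) = q(t') D(s'|t'; a)
  parent_keys <- unique(vapply(p$support$pcsps, function(pp) subsplit_key(pp$parent), ""))
  for (tbk in setdiff(parent_keys, rootbar_k)) {
    tb <- parse_subsplit_key(tbk)
    k_t <- sum(vapply(list(tb$y, tb$z), function(cl) length(cl) >= 2, TRUE))
    if (k_t == 0) next
    coef <- k_t * at0(up$split, tbk) / at0(rprob, tbk)
    if (coef == 0) next
    for (ak in fiber[[tbk]]) grad <- grad + coef * qp * D[, ak]
  }
  # second term: restricted PCSPs in p's support;
  # d q(a ->* d) = q(a) q(a ->* t'|a) D(s'|t'; d) + q(t') D(s'|t'; a) q(a ->* d|a)
  for (rk in names(p$support$pcsps)) {
    pp <- p$support$pcsps[[rk]]
    tbk <- subsplit_key(pp$parent)
    sbk <- subsplit_key(pp$child)
    qcond_r <- qr$cond[rk]
    if (is.na(qcond_r)) {
      stop("support incompatibility: PCSP ", rk, " absent from the restricted support")
    }
    qt <- if (tbk == rootbar_k) 1 else at0(rprob, tbk)
    coef <- at0(up$pcsp, rk) / (qt * unname(qcond_r))
    if (coef == 0) next
    if (tbk == rootbar_k) {
      # root PCSP: unconditional restricted prob is a plain fiber sum over d
      for (dk in fiber[[sbk]]) grad <- grad - coef * qp * D[, dk]
    } else {
      for (ak in fiber[[tbk]]) {
        qa <- unname(usplit[ak])
        for (dk in fiber[[sbk]]) {
          gad <- ws$G[[ak, dk]]
          contrib <- qp * D[, ak] * gad
          if (qa > 0) contrib <- contrib + qa * GPT[, ak] * D[, dk]
          grad <- grad - coef * contrib
        }
      }
    }
  }
  grad
}

#' Train a supertree SBN by gradient descent
#'
#' Plain gradient descent on the restricted-KL loss with step halving: a
#' step that fails to decrease the loss is retried at half the step size, so
#' the recorded loss trace is non-increasing.  Training stops at the
#' iteration cap, when an accepted step improves the loss by less than
#' \code{tolerance}, or when no improvement is possible within
#' \code{max_halvings}.
#'
#' @inheritParams sbn_loss
#' @param iterations maximum gradient steps.
#' @param step_size initial step size (default 0.5).
#' @param tolerance convergence threshold on loss improvement.
#' @param max_halvings step-halving attempts per iteration.
#' @param truth optional SBN on the full taxon set; when given, the KL
#'   divergence from it to the current iterate is recorded in the trace.
#' @return list with \code{params} (trained), \code{fitted} (the SBN),
#'   \code{trace} (data frame: iteration, loss, per-reference KL, grad_norm,
#'   step, and kl_truth when \code{truth} is given), and \code{converged}.
#' @export
sbn_train <- function(params, references, weights = rep(1, length(references)),
                      lambda = 0, iterations = 100, step_size = 0.5,
                      tolerance = 1e-10, max_halvings = 40, truth = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  # one restriction pass per reference yields both the loss and the trace KLs
  eval_loss <- function(pp) {
    q <- as_sbn(pp)
    qws <- if (inherits(q, "scd")) sbn_workspace(q) else NULL
    kls <- vapply(seq_along(references), function(i) {
      ref <- references[[i]]
      check_reference(pp, ref, i)
      qi <- if (identical(ref$support$taxa, sbn_taxa(q))) q
            else restrict_sbn(q, ref$support$taxa, qws)
      tryCatch(kl_sbn(ref, qi), error = function(e) {
        stop("reference ", i, ": ", conditionMessage(e))
      })
    }, 0)
    penalty <- if (lambda > 0) lambda * sum(pp$v^2) else 0
    list(loss = sum(weights * kls) + penalty, kls = kls,
         kl_truth = if (is.null(truth)) NA_real_ else kl_sbn(truth, q))
  }
  cur <- eval_loss(params)
  if (!is.finite(cur$loss)) stop("non-finite loss at initialization")
  step <- step_size
  rows <- list()
  push_row <- function(it, ev, gnorm, step) {
    rows[[length(rows) + 1L]] <<- data.frame(
      iteration = it, loss = ev$loss,
      t(structure(ev$kls, names = paste0("kl_ref", seq_along(ev$kls)))),
      kl_truth = ev$kl_truth, grad_norm = gnorm, step = step)
  }
  push_row(0L, cur, NA_real_, NA_real_)
  converged <- FALSE
  for (it in seq_len(iterations)) {
    grad <- sbn_gradient(params, references, weights, lambda)
    if (any(!is.finite(grad))) stop("non-finite gradient at iteration ", it)
    gnorm <- sqrt(sum(grad^2))
    accepted <- FALSE
    for (h in 0:max_halvings) {
      cand <- params
      cand$v <- params$v - step * grad
      cand_ev <- eval_loss(cand)
      if (!is.finite(cand_ev$loss)) stop("non-finite loss at iteration ", it)
      if (cand_ev$loss <= cur$loss) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    improved <- cur$loss - cand_ev$loss
    params <- cand
    cur <- cand_ev
    push_row(it, cur, gnorm, step)
    if (improved < tolerance) { converged <- TRUE; break }
    # let the step recover after a success (bounded, so halving still bites)
    step <- min(step * 2, 64 * step_size)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  list(params = params, fitted = as_sbn(params), trace = trace,
       converged = converged)
}

#' Check analytic gradients against central finite differences
#'
#' Central differences of the loss at step \code{h} compared to the analytic
#' gradient.  Relative errors are computed with the scale
#' \code{max(|analytic|, |fd|, 1)}, so components near zero are compared
#' absolutely.
#'
#' @inheritParams sbn_loss
#' @param h finite-difference step (default 1e-5).
#' @param indices parameter keys to check (default all).
#' @return list with \code{max_rel_error} and a per-component data frame
#'   \code{table} (key, analytic, fd, rel_error).
#' @export
finite_difference_check <- function(params, references,
                                    weights = rep(1, length(references)),
                                    lambda = 0, h = 1e-5, indices = NULL) {
  if (h <= 0) stop("h must be positive")
  grad <- sbn_gradient(params, references, weights, lambda)
  if (is.null(indices)) indices <- names(params$v)
  fd <- vapply(indices, function(k) {
    vp <- params; vp$v[k] <- vp$v[k] + h
    vm <- params; vm$v[k] <- vm$v[k] - h
    (sbn_loss(vp, references, weights, lambda) -
       sbn_loss(vm, references, weights, lambda)) / (2 * h)
  }, 0)
  a <- unname(grad[indices])
  rel <- abs(a - fd) / pmax(abs(a), abs(fd), 1)
  list(max_rel_error = max(rel),
       table = data.frame(key = indices, analytic = a, fd = unname(fd),
                          rel_error = unname(rel)))
}
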