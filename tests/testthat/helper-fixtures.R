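# shared helpers: everything is generated in code at test time

tree_support <- function(nwk, kind = "ccd") {
  tau <- parse_newick(nwk)
  if (kind == "ccd") {
    subsplit_support(tau$taxa, tau$splits)
  } else {
    pcsp_support(tau$taxa, pcsp_decomposition(tau))
  }
}

# largest absolute probability difference between two explicit distributions
max_prob_diff <- function(d1, d2) {
  keys <- union(names(d1$prob), names(d2$prob))
  max(vapply(keys, function(k) {
    a <- d1$prob[k]; b <- d2$prob[k]
    abs((if (is.na(a)) 0 else a) - (if (is.na(b)) 0 else b))
  }, 0))
}

# brute-force unconditional probability of a subsplit from an enumerated
# tree distribution
oracle_subsplit_prob <- function(td, key) {
  sum(td$prob[vapply(td$trees, function(tt) key %in% names(tt$splits), TRUE)])
}

oracle_pcsp_prob <- function(td, key) {
  sum(td$prob[vapply(td$trees, function(tt) {
    key %in% names(pcsp_decomposition(tt))
  }, TRUE)])
}

oracle_pair_prob <- function(td, k1, k2) {
  sum(td$prob[vapply(td$trees, function(tt) {
    all(c(k1, k2) %in% names(tt$splits))
  }, TRUE)])
}
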