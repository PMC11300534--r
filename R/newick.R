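# Newick I/O for rooted bifurcating topologies.  Parsing goes through ape;
# branch lengths, support values and internal node labels are accepted and
# discarded.  Writing is canonical: children appear in the canonical
# subsplit order, so write_newick is deterministic and round-trips.

#' Parse a rooted bifurcating Newick string
#'
#' @param text a single Newick tree string (trailing semicolon optional for
#'   the degenerate single-tip form \code{"A;"}).
#' @return a \code{rooted_topology}.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!grepl("[(),]", text)) {
    # degenerate single-tip tree
    lab <- sub(";$", "", text)
    return(rooted_topology(lab, list()))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick: ", text)
  phylo_to_topology(phy)
}

# convert an ape phylo object, checking rootedness/bifurcation/tip uniqueness
phylo_to_topology <- function(phy) {
  tips <- phy$tip.label
  if (anyDuplicated(tips)) stop("duplicate tip label in Newick tree")
  ntip <- length(tips)
  if (ntip == 2 && is.null(phy$Nnode)) stop("malformed tree")
  nnode <- phy$Nnode
  children <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(phy$edge))) {
    par <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    children[[par]] <- c(children[[par]], ch)
  }
  splits <- list()
  tipset <- function(node) {
    if (node <= ntip) return(tips[node])
    ch <- children[[node]]
    if (length(ch) != 2) {
      stop("tree is not strictly bifurcating (node with ", length(ch), " children)")
    }
    y <- tipset(ch[1]); z <- tipset(ch[2])
    s <- subsplit(y, z)
    splits[[subsplit_key(s)]] <<- s
    c(y, z)
  }
  tipset(ntip + 1L)  # ape root node
  rooted_topology(tips, splits)
}

#' Write a topology as a canonical Newick string
#'
#' The two children of every node are emitted in canonical subsplit order
#' (smaller child clade first), so the output is deterministic and
#' \code{parse_newick(write_newick(tau))} reproduces \code{tau}.
#'
#' @param tau rooted topology.
#' @return Newick string ending in \code{";"}.
#' @export
write_newick <- function(tau) {
  if (length(tau$taxa) == 1) return(paste0(tau$taxa, ";"))
  by_clade <- new.env(hash = TRUE, parent = emptyenv())
  for (s in tau$splits) by_clade[[clade_key(subsplit_clade(s))]] <- s
  render <- function(w) {
    if (length(w) == 1) return(w)
    s <- by_clade[[clade_key(w)]]
    if (is.null(s)) stop("invalid topology: clade ", clade_key(w), " undivided")
    paste0("(", render(s$y), ",", render(s$z), ")")
  }
  paste0(render(tau$taxa), ";")
}

#' Read a weighted Newick tree list
#'
#' One tree per line; an optional tab-separated numeric weight (count or
#' probability) may follow the tree.  Missing weights default to 1.
#'
#' @param path file path.
#' @return list with components \code{trees} (list of rooted topologies) and
#'   \code{weights} (numeric).
#' @export
read_tree_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no trees in ", path)
  trees <- vector("list", length(lines))
  weights <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    trees[[i]] <- tryCatch(parse_newick(parts[1]),
                           error = function(e) stop("line ", i, ": ", conditionMessage(e)))
    weights[i] <- if (length(parts) >= 2) as.numeric(parts[2]) else 1
    if (is.na(weights[i]) || weights[i] <= 0) stop("line ", i, ": bad weight")
  }
  list(trees = trees, weights = weights)
}

#' Write a weighted Newick tree list
#'
#' @param trees list of rooted topologies.
#' @param weights numeric weights (optional; omitted from the file if NULL).
#' @param path file path.
#' @export
write_tree_list <- function(trees, weights = NULL, path) {
  nwk <- vapply(trees, write_newick, "")
  lines <- if (is.null(weights)) nwk else paste(nwk, format(weights, digits = 17, scientific = FALSE, trim = TRUE), sep = "\t")
  writeLines(lines, path)
}
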