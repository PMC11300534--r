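# Clades, subsplits and parent-child subsplit pairs (PCSPs): the atomic
# combinatorial objects of subsplit Bayesian networks.  All objects are kept
# in a canonical form so that string keys give deterministic equality,
# hashing and serialization.

#' Construct a clade
#'
#' A clade is a subset of the taxon set, represented as a sorted character
#' vector of taxon labels.  The empty clade is permitted.
#'
#' @param taxa character vector of taxon labels (duplicates are an error).
#' @return sorted character vector of class preserving-none (plain vector).
#' @export
clade <- function(taxa = character(0)) {
  if (length(taxa) == 0) return(character(0))
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels in clade")
  if (any(grepl("[,|;()\\s]|->", taxa, perl = TRUE))) {
    stop("taxon labels may not contain ',', '|', ';', '->', parentheses or whitespace")
  }
  sort(taxa, method = "radix")
}

#' @rdname clade
#' @param x clade.
#' @export
clade_key <- function(x) paste(x, collapse = ",")

# inverse of clade_key
parse_clade_key <- function(key) {
  if (identical(key, "")) return(character(0))
  strsplit(key, ",", fixed = TRUE)[[1]]
}

# set helpers on sorted character vectors (results re-sorted for determinism)
clade_intersect <- function(a, b) sort(intersect(a, b), method = "radix")
clade_union     <- function(a, b) sort(union(a, b), method = "radix")
clade_setdiff   <- function(a, b) sort(setdiff(a, b), method = "radix")
clade_contains  <- function(a, b) all(b %in% a)  # b subseteq a

#' Construct a subsplit
#'
#' A subsplit is an unordered pair of disjoint clades \{Y, Z\}.  The pair is
#' stored canonically: the child with fewer taxa first, ties broken by the
#' lexicographically smaller comma-joined label string.  A subsplit is
#' \emph{trivial} if one child is empty.
#'
#' @param y,z character vectors of taxon labels (clades).
#' @return object of class \code{"subsplit"} with fields \code{y}, \code{z}
#'   (canonically ordered clades).
#' @export
subsplit <- function(y, z = character(0)) {
  y <- clade(y); z <- clade(z)
  if (length(intersect(y, z)) > 0) stop("subsplit children must be disjoint")
  ky <- clade_key(y); kz <- clade_key(z)
  if (length(y) > length(z) || (length(y) == length(z) && ky > kz)) {
    tmp <- y; y <- z; z <- tmp
  }
  structure(list(y = y, z = z), class = "subsplit")
}

#' @rdname subsplit
#' @param s subsplit.
#' @export
subsplit_key <- function(s) paste0(clade_key(s$y), "|", clade_key(s$z))

#' @rdname subsplit
#' @export
subsplit_clade <- function(s) clade_union(s$y, s$z)  # U(s)

#' @rdname subsplit
#' @export
is_trivial_subsplit <- function(s) length(s$y) == 0 || length(s$z) == 0

# trivial subsplit {W, 0} of a clade W
trivial_subsplit <- function(w) subsplit(w, character(0))

#' Parse the text form of a subsplit, e.g. \code{"A|B,C"}.
#' @param key subsplit key string \code{"<clade>|<clade>"}.
#' @export
parse_subsplit_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(parts) > 2) stop("malformed subsplit key: ", key)
  if (length(parts) == 0) parts <- c("", "")
  if (length(parts) == 1) parts <- c(parts, "")
  # strsplit drops a leading empty field only when key starts with "|"
  if (startsWith(key, "|")) parts <- c("", strsplit(substring(key, 2), "|", fixed = TRUE)[[1]])
  subsplit(parse_clade_key(parts[1]), parse_clade_key(parts[2]))
}

#' @export
print.subsplit <- function(x, ...) {
  cat("subsplit ", subsplit_key(x), "\n", sep = "")
  invisible(x)
}

#' Restrict a subsplit to a taxon subset
#'
#' Intersects both child clades with \code{xbar}; the result may be trivial
#' or empty.
#'
#' @param s subsplit.
#' @param xbar clade (character vector of taxa).
#' @return subsplit on \code{xbar}.
#' @export
restrict_subsplit <- function(s, xbar) {
  subsplit(clade_intersect(s$y, xbar), clade_intersect(s$z, xbar))
}

#' Construct a parent-child subsplit pair (PCSP)
#'
#' A PCSP \code{t -> s} pairs a child subsplit \code{s} with its parent
#' subsplit \code{t}; the focal clade U(s) must equal exactly one child
#' clade of \code{t}.  The parent of a root subsplit is the trivial subsplit
#' \{X, 0\} of the full taxon set.
#'
#' @param parent,child subsplits.
#' @return object of class \code{"pcsp"}.
#' @export
pcsp <- function(parent, child) {
  w <- subsplit_clade(child)
  ky <- clade_key(parent$y); kz <- clade_key(parent$z); kw <- clade_key(w)
  if (kw != ky && kw != kz) {
    stop("invalid PCSP: U(child) is not a child clade of parent (",
         subsplit_key(parent), " -> ", subsplit_key(child), ")")
  }
  structure(list(parent = parent, child = child), class = "pcsp")
}

#' @rdname pcsp
#' @param p PCSP.
#' @export
pcsp_key <- function(p) paste0(subsplit_key(p$parent), " -> ", subsplit_key(p$child))

#' Parse the text form of a PCSP, e.g. \code{"A,B|C -> A|B"}.
#' @param key PCSP key string.
#' @export
parse_pcsp_key <- function(key) {
  parts <- strsplit(key, " -> ", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed PCSP key: ", key)
  pcsp(parse_subsplit_key(parts[1]), parse_subsplit_key(parts[2]))
}

#' @export
print.pcsp <- function(x, ...) {
  cat("PCSP ", pcsp_key(x), "\n", sep = "")
  invisible(x)
}

# Is subsplit d a valid descendant of subsplit a (a ->* d)?  True when a = d
# or U(d) is contained in one child clade of a.
is_descendant <- function(a, d) {
  if (subsplit_key(a) == subsplit_key(d)) return(TRUE)
  ud <- subsplit_clade(d)
  if (length(ud) == 0) return(FALSE)
  clade_contains(a$y, ud) || clade_contains(a$z, ud)
}
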