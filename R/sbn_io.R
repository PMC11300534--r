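# JSON serialization for SBN distributions and supports.
#
# Format: {"taxa": [...], "kind": "CCD"|"SCD",
#          "entries": [{"parent": "...", "child": "...", "prob": x}, ...]}
# For CCDs the parent field holds the clade (comma-joined labels) and the
# child field the subsplit text form "Y|Z"; for SCDs both fields are
# subsplit text forms.  Supports use the same layout without "prob".

#' Write an SBN distribution or support to JSON
#'
#' @param x \code{ccd}, \code{scd}, \code{subsplit_support} or
#'   \code{pcsp_support}.
#' @param path file path.
#' @export
write_sbn_json <- function(x, path) {
  if (inherits(x, "sbn")) {
    support <- x$support
    cond <- x$cond
  } else {
    support <- x
    cond <- NULL
  }
  if (inherits(support, "subsplit_support")) {
    kind <- "CCD"
    entries <- lapply(names(support$splits), function(k) {
      e <- list(parent = clade_key(subsplit_clade(support$splits[[k]])), child = k)
      if (!is.null(cond)) e$prob <- unname(cond[k])
      e
    })
  } else {
    kind <- "SCD"
    entries <- lapply(names(support$pcsps), function(k) {
      p <- support$pcsps[[k]]
      e <- list(parent = subsplit_key(p$parent), child = subsplit_key(p$child))
      if (!is.null(cond)) e$prob <- unname(cond[k])
      e
    })
  }
  obj <- list(taxa = as.list(support$taxa), kind = kind, entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an SBN distribution or support from JSON
#'
#' Entries carrying a \code{prob} field yield a distribution; entries
#' without one yield a bare support.
#'
#' @param path file path.
#' @return \code{ccd}/\code{scd} (with probabilities) or
#'   \code{subsplit_support}/\code{pcsp_support} (without).
#' @export
read_sbn_json <- function(path) {
  obj <- jsonlite::read_json(path)
  taxa <- clade(unlist(obj$taxa))
  kind <- toupper(obj$kind)
  if (!kind %in% c("CCD", "SCD")) stop("unknown SBN kind: ", obj$kind)
  has_prob <- length(obj$entries) > 0 && !is.null(obj$entries[[1]]$prob)
  if (kind == "CCD") {
    splits <- lapply(obj$entries, function(e) parse_subsplit_key(e$child))
    support <- subsplit_support(taxa, splits)
    if (!has_prob) return(support)
    cond <- vapply(obj$entries, function(e) as.numeric(e$prob), 0)
    names(cond) <- vapply(splits, subsplit_key, "")
    ccd(support, cond)
  } else {
    pcsps <- lapply(obj$entries, function(e) {
      pcsp(parse_subsplit_key(e$parent), parse_subsplit_key(e$child))
    })
    support <- pcsp_support(taxa, pcsps)
    if (!has_prob) return(support)
    cond <- vapply(obj$entries, function(e) as.numeric(e$prob), 0)
    names(cond) <- vapply(pcsps, pcsp_key, "")
    scd(support, cond)
  }
}
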