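# Phrase-tree nodes. A tree's leaves carry exactly one tagged token each, and
# an in-order traversal of the leaves reproduces the sentence's token
# sequence (the leaf-partition invariant).

PHRASE_LABELS <- c("Sentence", "Document", "ActionPhrase", "NounPhrase",
                   "VerbPhrase", "PrepPhrase", "MOLECULE", "QUANTITY",
                   "Unmatched")

#' Construct a phrase node
#'
#' @param label phrase label (Sentence, ActionPhrase, NounPhrase, VerbPhrase,
#'   PrepPhrase, MOLECULE, QUANTITY, Unmatched) or, for leaves, a tag name.
#' @param children list of child \code{phrase_node}s (empty for leaves).
#' @param attrs named list of string attributes (e.g. the ActionPhrase type).
#' @param token for leaves, a one-row slice of a tagged-token data.frame.
#' @return an object of class \code{phrase_node}.
#' @export
phrase_node <- function(label, children = list(), attrs = list(),
                        token = NULL) {
  structure(list(label = label, children = children, attrs = attrs,
                 token = token),
            class = "phrase_node")
}

leaf_node <- function(token_row) {
  phrase_node(token_row$tag, token = as.list(token_row))
}

#' @export
is_leaf <- function(node) {
  inherits(node, "phrase_node") && length(node$children) == 0L &&
    !is.null(node$token)
}

#' In-order leaf tokens of a phrase tree
#'
#' Returns the tagged tokens at the leaves, left to right. Used by the
#' leaf-partition invariant, by span computation and by evaluation-span
#' extraction.
#'
#' @param node a \code{phrase_node}.
#' @return a data.frame of tagged tokens (possibly zero rows).
#' @export
ast_leaf_tokens <- function(node) {
  stopifnot(inherits(node, "phrase_node"))
  collect <- function(nd) {
    if (is_leaf(nd)) return(list(nd$token))
    unlist(lapply(nd$children, collect), recursive = FALSE)
  }
  toks <- collect(node)
  if (!length(toks)) {
    return(data.frame(id = integer(0), surface = character(0),
                      start = integer(0), end = integer(0),
                      tag = character(0), namespace = character(0),
                      stringsAsFactors = FALSE))
  }
  cols <- c("id", "surface", "start", "end", "tag", "namespace")
  out <- do.call(rbind, lapply(toks, function(t) {
    as.data.frame(t[cols], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Character span of a phrase node over the original text
#'
#' @param node a \code{phrase_node}.
#' @return integer vector \code{c(start, end)} (0-based, half-open), or
#'   \code{c(NA, NA)} for an empty node.
#' @export
node_span <- function(node) {
  toks <- ast_leaf_tokens(node)
  if (!nrow(toks)) return(c(NA_integer_, NA_integer_))
  c(min(toks$start), max(toks$end))
}

#' @export
node_text <- function(node) {
  paste(ast_leaf_tokens(node)$surface, collapse = " ")
}

#' Find all descendant nodes with a given label
#'
#' @param node a \code{phrase_node}.
#' @param label label to search for.
#' @param include_self include \code{node} itself if it matches.
#' @return list of matching \code{phrase_node}s in document order.
#' @export
find_nodes <- function(node, label, include_self = TRUE) {
  out <- list()
  if (include_self && identical(node$label, label)) out <- list(node)
  for (ch in node$children) {
    out <- c(out, find_nodes(ch, label, include_self = TRUE))
  }
  out
}

#' Check the leaf-partition invariant
#'
#' Every token of the parsed sentence must appear exactly once among the
#' leaves, in input order.
#'
#' @param node the Sentence (or any) node.
#' @param tokens the token data.frame the tree was parsed from; if omitted,
#'   only ordering/uniqueness of leaf ids is checked.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
validate_leaf_partition <- function(node, tokens = NULL) {
  leaves <- ast_leaf_tokens(node)
  ids <- leaves$id
  if (anyDuplicated(ids)) return(FALSE)
  if (is.unsorted(ids, strictly = TRUE)) return(FALSE)
  if (!is.null(tokens)) return(identical(as.integer(ids), as.integer(tokens$id)))
  TRUE
}

#' Structural equality of two phrase trees
#'
#' Compares labels, attributes and leaf surfaces/tags; token character
#' offsets are compared only when \code{offsets = TRUE}.
#'
#' @param a,b \code{phrase_node}s.
#' @param offsets also require identical leaf offsets and ids.
#' @return logical.
#' @export
ast_equal <- function(a, b, offsets = FALSE) {
  if (!identical(a$label, b$label)) return(FALSE)
  norm <- function(at) if (length(at)) at[order(names(at))] else list()
  aa <- norm(a$attrs)
  bb <- norm(b$attrs)
  if (!identical(lapply(aa, as.character), lapply(bb, as.character))) {
    return(FALSE)
  }
  if (is_leaf(a) || is_leaf(b)) {
    if (!(is_leaf(a) && is_leaf(b))) return(FALSE)
    if (!identical(a$token$surface, b$token$surface)) return(FALSE)
    if (!identical(a$token$tag, b$token$tag)) return(FALSE)
    if (offsets) {
      return(identical(as.integer(a$token$start), as.integer(b$token$start)) &&
               identical(as.integer(a$token$end), as.integer(b$token$end)) &&
               identical(as.integer(a$token$id), as.integer(b$token$id)))
    }
    return(TRUE)
  }
  if (length(a$children) != length(b$children)) return(FALSE)
  for (k in seq_along(a$children)) {
    if (!ast_equal(a$children[[k]], b$children[[k]], offsets)) return(FALSE)
  }
  TRUE
}

#' @export
print.phrase_node <- function(x, indent = 0L, ...) {
  pad <- strrep("  ", indent)
  if (is_leaf(x)) {
    cat(pad, x$label, ": ", x$token$surface, "\n", sep = "")
  } else {
    attrs <- if (length(x$attrs)) {
      paste0(" [", paste(names(x$attrs), unlist(x$attrs), sep = "=",
                         collapse = ", "), "]")
    } else ""
    cat(pad, x$label, attrs, "\n", sep = "")
    for (ch in x$children) print(ch, indent = indent + 1L)
  }
  invisible(x)
}
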