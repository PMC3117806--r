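# XML serialisation of phrase trees. Element names equal node labels (leaf
# elements are named by the token's tag, e.g. OSCAR-CM, VB-ADD, VBD); the
# ActionPhrase type is an attribute; child order is document order.

LEAF_TAG_PATTERN <- "^[A-Z][A-Z0-9$-]*$"

#' Serialise a phrase tree to XML
#'
#' Structure-preserving: one element per node, named by its label, with the
#' ActionPhrase type as a \code{type} attribute and token surfaces as leaf
#' text. The tree must satisfy the leaf-partition invariant, otherwise
#' serialisation is refused.
#'
#' @param root a \code{phrase_node} (typically a Sentence).
#' @param offsets also write \code{id}, \code{start}, \code{end} attributes
#'   on leaves, making the round trip through [xml_to_ast()] exact.
#' @return an \code{xml2} document.
#' @export
ast_to_xml <- function(root, offsets = FALSE) {
  stopifnot(inherits(root, "phrase_node"))
  if (!validate_leaf_partition(root)) {
    stop("refusing to serialise: leaf tokens do not form an ordered partition")
  }
  doc <- xml2::xml_new_root(root$label)
  .write_attrs(doc, root)
  for (ch in root$children) .append_node(doc, ch, offsets)
  if (is_leaf(root)) xml2::xml_text(doc) <- root$token$surface
  doc
}

.write_attrs <- function(el, node) {
  if (length(node$attrs)) {
    for (nm in names(node$attrs)) {
      xml2::xml_set_attr(el, nm, as.character(node$attrs[[nm]]))
    }
  }
}

.append_node <- function(parent, node, offsets) {
  el <- xml2::xml_add_child(parent, node$label)
  .write_attrs(el, node)
  if (is_leaf(node)) {
    xml2::xml_text(el) <- node$token$surface
    if (offsets) {
      xml2::xml_set_attr(el, "id", as.character(node$token$id))
      xml2::xml_set_attr(el, "start", as.character(node$token$start))
      xml2::xml_set_attr(el, "end", as.character(node$token$end))
    }
  } else {
    for (ch in node$children) .append_node(el, ch, offsets)
  }
  invisible(el)
}

#' Read a phrase tree back from XML
#'
#' Inverse of [ast_to_xml()]. Without offset attributes the reconstructed
#' leaf tokens carry surfaces and tags but \code{NA} offsets (the printed
#' dialect does not record them); with \code{offsets = TRUE} at write time
#' the round trip is exact.
#'
#' @param doc an \code{xml2} document, XML string or file path.
#' @return a \code{phrase_node}.
#' @export
xml_to_ast <- function(doc) {
  if (!inherits(doc, "xml_document") && !inherits(doc, "xml_node")) {
    doc <- xml2::read_xml(doc)
  }
  counter <- new.env(parent = emptyenv())
  counter$next_id <- 0L
  .read_node(xml2::xml_root(doc), counter)
}

.read_node <- function(el, counter) {
  name <- xml2::xml_name(el)
  kids <- xml2::xml_children(el)
  attrs <- as.list(xml2::xml_attrs(el))
  if (length(kids) == 0L && !(name %in% PHRASE_LABELS)) {
    if (!grepl(LEAF_TAG_PATTERN, name)) {
      stop("unknown element name: ", name)
    }
    id <- if (!is.null(attrs$id)) as.integer(attrs$id) else counter$next_id
    counter$next_id <- max(counter$next_id, id) + 1L
    token <- list(
      id = id,
      surface = trimws(xml2::xml_text(el)),
      start = if (!is.null(attrs$start)) as.integer(attrs$start) else NA_integer_,
      end = if (!is.null(attrs$end)) as.integer(attrs$end) else NA_integer_,
      tag = name,
      namespace = if (startsWith(name, "OSCAR-")) "CHEM" else
        if (grepl("-", name)) "REGEX" else "POS")
    return(phrase_node(name, token = token))
  }
  if (!(name %in% PHRASE_LABELS)) {
    stop("unknown element name: ", name)
  }
  attrs$id <- NULL
  attrs$start <- NULL
  attrs$end <- NULL
  phrase_node(name, children = lapply(kids, .read_node, counter = counter),
              attrs = attrs)
}
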