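# End-to-end pipeline: raw preparation text -> tagged, parsed,
# action-labelled, role-assigned document.

#' Parse an experimental paragraph end to end
#'
#' Runs the full pipeline: text normalisation, tokenisation, sentence
#' splitting, the three-step tagging cascade, phrase parsing, Action-phrase
#' identification and role inference. A title line (the product name with
#' its compound reference number, ending in ":") can be passed separately,
#' as the \code{title}/\code{text} elements of a list, or left at the head
#' of \code{x}, where it is detected automatically.
#'
#' @param x the paragraph text, or a list with elements \code{title} and
#'   \code{text} (as returned by [sample_preparation()]).
#' @param title optional title line.
#' @param lexicon,rules,triggers see [chemical_lexicon()],
#'   [default_tag_rules()], [action_triggers()].
#' @param ner optional pre-computed named entities (see [ingest_ner_xml()]);
#'   aligned per document against the token stream.
#' @return an object of class \code{chem_document}: a list with the original
#'   \code{text} and \code{title}, the token table, per-sentence tagged
#'   tokens and phrase trees, the Action-phrase table, the role table and
#'   the named-entity table.
#' @examples
#' doc <- chem_tag(sample_preparation())
#' doc$roles
#' @export
chem_tag <- function(x, title = NULL, lexicon = chemical_lexicon(),
                     rules = default_tag_rules(),
                     triggers = action_triggers(), ner = NULL) {
  if (is.list(x) && !is.null(x$text)) {
    if (is.null(title)) title <- x$title
    x <- x$text
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (is.null(title) && grepl("\n", x)) {
    first <- sub("\n.*$", "", x)
    if (grepl("[0-9]\\s*:\\s*$", first)) {
      title <- trimws(first)
      x <- sub("^[^\n]*\n", "", x)
    }
  }
  norm <- normalize_text(x)
  tokens <- tokenize(norm)
  sents <- split_sentences(tokens)
  if (is.null(ner)) {
    tagged <- lapply(sents, cascade_tag, lexicon = lexicon, rules = rules)
  } else {
    full <- cascade_tag(tokens, lexicon = lexicon, rules = rules, ner = ner)
    tagged <- lapply(sents, function(s) {
      full[match(s$id, full$id), , drop = FALSE]
    })
  }
  entities <- do.call(rbind, lapply(tagged, function(t) {
    e <- attr(t, "entities")
    if (is.null(e)) NULL else e[, c("id", "surface", "type", "confidence")]
  }))
  parsed <- lapply(tagged, parse_sentence)
  labelled <- lapply(seq_along(parsed), function(k) {
    identify_actions(parsed[[k]], triggers = triggers, sentence_index = k)
  })
  trees <- lapply(labelled, `[[`, "tree")
  actions <- do.call(rbind, lapply(labelled, `[[`, "actions"))
  roles <- assign_roles(trees, title = title)
  structure(list(
    text = x, title = title,
    title_ref = if (is.null(title)) NA_integer_ else
      extract_reference_number(title),
    normalized = norm, tokens = tokens, tagged = tagged,
    sentences = trees, actions = actions, roles = roles,
    entities = entities),
    class = "chem_document")
}

#' @export
print.chem_document <- function(x, ...) {
  cat("<chem_document>\n")
  if (!is.null(x$title)) cat("  title:    ", x$title, "\n", sep = "")
  cat("  tokens:   ", nrow(x$tokens), " in ", length(x$sentences),
      " sentence(s)\n", sep = "")
  if (nrow(x$actions)) {
    cat("  actions:  ", paste(x$actions$type, collapse = ", "), "\n", sep = "")
  } else {
    cat("  actions:  none\n")
  }
  assigned <- x$roles[x$roles$role != "unassigned", , drop = FALSE]
  if (nrow(assigned)) {
    cat("  roles:    ",
        paste(sprintf("%s=%s", assigned$surface, assigned$role),
              collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialise a parsed document to XML
#'
#' A \code{Document} root holding one \code{Sentence} element per sentence,
#' in the hyphenated leaf-tag dialect (OSCAR-CM, VB-ADD, ...).
#'
#' @param doc a \code{chem_document}.
#' @param offsets write leaf offset attributes (see [ast_to_xml()]).
#' @return an \code{xml2} document.
#' @export
chem_xml <- function(doc, offsets = FALSE) {
  stopifnot(inherits(doc, "chem_document"))
  root <- xml2::xml_new_root("Document")
  for (tree in doc$sentences) {
    sent <- xml2::xml_add_child(root, "Sentence")
    for (ch in tree$children) .append_node(sent, ch, offsets)
  }
  root
}

#' Typed amounts in a parsed document, with their owning compound
#'
#' Collects every QUANTITY group in the document, parses it with
#' [parse_quantity()] and attaches the compound it belongs to: the enclosing
#' MOLECULE's surface, or \code{"title compound"} for the product noun
#' phrase of a Yield phrase.
#'
#' @param doc a \code{chem_document}.
#' @return data.frame with columns \code{compound}, \code{kind},
#'   \code{value}, \code{unit}, \code{qualifier}, \code{repeats},
#'   \code{sentence}.
#' @export
doc_quantities <- function(doc) {
  stopifnot(inherits(doc, "chem_document"))
  rows <- list()
  owner_of <- function(node) {
    if (identical(node$label, "MOLECULE")) {
      cm <- Filter(function(ch) is_leaf(ch) && startsWith(ch$label, "OSCAR-"),
                   node$children)
      return(paste(vapply(cm, function(ch) ch$token$surface, character(1)),
                   collapse = " "))
    }
    low <- tolower(ast_leaf_tokens(node)$surface)
    if (any(low == "title" & c(low[-1], "") == "compound")) {
      return("title compound")
    }
    NA_character_
  }
  visit <- function(node, sentence) {
    for (ch in node$children) {
      if (identical(ch$label, "QUANTITY")) {
        q <- parse_quantity(ch)
        if (nrow(q)) {
          q$compound <- owner_of(node)
          q$sentence <- sentence
          rows[[length(rows) + 1L]] <<- q
        }
      } else {
        visit(ch, sentence)
      }
    }
  }
  for (k in seq_along(doc$sentences)) visit(doc$sentences[[k]], k)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(kind = character(0), value = numeric(0),
                      unit = character(0), qualifier = character(0),
                      repeats = numeric(0), compound = character(0),
                      sentence = integer(0), stringsAsFactors = FALSE)
  }
  out[, c("compound", "kind", "value", "unit", "qualifier", "repeats",
          "sentence")]
}
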