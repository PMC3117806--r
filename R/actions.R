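# Action-phrase identification: post-processing of the phrase tree that
# wraps triggered clause segments in ActionPhrase nodes carrying one of the
# 21 closed phrase types, with support for nesting.

.trigger_maps <- function(triggers) {
  verb <- stats::setNames(triggers$type, triggers$tag)
  nom <- triggers[nzchar(triggers$nominal), , drop = FALSE]
  nominal <- stats::setNames(nom$type, sub("^VB-", "NN-", nom$tag))
  list(verb = verb, nominal = nominal)
}

# Action type triggered by a VerbPhrase's own verb group (direct leaf
# children only: a trigger inside a nested PrepPhrase is not a main verb).
.vp_trigger <- function(node, verb_map) {
  if (!identical(node$label, "VerbPhrase")) return(NA_character_)
  for (ch in node$children) {
    if (is_leaf(ch) && !is.na(verb_map[ch$label])) {
      return(unname(verb_map[ch$label]))
    }
  }
  NA_character_
}

.np_nominal_trigger <- function(node, nominal_map) {
  if (!identical(node$label, "NounPhrase")) return(NA_character_)
  for (ch in node$children) {
    if (is_leaf(ch) && !is.na(nominal_map[ch$label])) {
      return(unname(nominal_map[ch$label]))
    }
  }
  NA_character_
}

.action_node <- function(type, children) {
  phrase_node("ActionPhrase", children, attrs = list(type = type))
}

.contains_molecule <- function(node) {
  length(find_nodes(node, "MOLECULE")) > 0L
}

.prep_surface <- function(pp) {
  if (!identical(pp$label, "PrepPhrase") || !length(pp$children)) return("")
  first <- pp$children[[1]]
  if (is_leaf(first)) tolower(first$token$surface) else ""
}

# "X 50 (0.50 g) in DMF (33 cm3)" inside an Add phrase is a solution: wrap
# the dissolved material and its "in"-phrase as a nested Dissolve phrase.
.wrap_implicit_dissolve <- function(node, enclosing = NA_character_) {
  typ <- if (identical(node$label, "ActionPhrase")) node$attrs$type else enclosing
  node$children <- lapply(node$children, .wrap_implicit_dissolve, enclosing = typ)
  ch <- node$children
  if (identical(typ, "Add") && length(ch) >= 2L) {
    for (k in seq_len(length(ch) - 1L)) {
      a <- ch[[k]]
      b <- ch[[k + 1L]]
      if (a$label %in% c("PrepPhrase", "NounPhrase") && .contains_molecule(a) &&
          identical(b$label, "PrepPhrase") && .prep_surface(b) == "in" &&
          .contains_molecule(b)) {
        wrapped <- .action_node("Dissolve", list(a, b))
        node$children <- c(ch[seq_len(k - 1L)], list(wrapped),
                           if (k + 2L <= length(ch)) ch[(k + 2L):length(ch)])
        break
      }
    }
  }
  node
}

.wrap_nested_vps <- function(node, verb_map, top = TRUE) {
  node$children <- lapply(node$children, function(ch) {
    ch <- .wrap_nested_vps(ch, verb_map, top = FALSE)
    ch
  })
  if (identical(node$label, "VerbPhrase")) {
    node$children <- lapply(node$children, function(ch) {
      typ <- .vp_trigger(ch, verb_map)
      if (!is.na(typ)) .action_node(typ, list(ch)) else ch
    })
  }
  node
}

.segment_sentence <- function(sent, maps) {
  ch <- sent$children
  if (!length(ch)) return(sent)
  trig <- vapply(ch, .vp_trigger, character(1), verb_map = maps$verb)
  tidx <- which(!is.na(trig))
  if (!length(tidx)) {
    # nominalisation head: "Synthesis of ..." wraps the whole sentence
    np_first <- which(vapply(ch, function(nd)
      identical(nd$label, "NounPhrase"), logical(1)))
    if (length(np_first) && np_first[1] <= 2L) {
      nom <- .np_nominal_trigger(ch[[np_first[1]]], maps$nominal)
      if (!is.na(nom)) {
        return(phrase_node("Sentence", list(.action_node(nom, ch))))
      }
    }
    return(sent)
  }
  out <- list()
  pos <- 1L
  for (k in seq_along(tidx)) {
    t <- tidx[k]
    s <- pos
    while (s < t && is_leaf(ch[[s]]) && ch[[s]]$label %in% c("CC", "COMMA")) {
      out[[length(out) + 1L]] <- ch[[s]]
      s <- s + 1L
    }
    if (k < length(tidx)) {
      between <- if (t + 1L <= tidx[k + 1L] - 1L) (t + 1L):(tidx[k + 1L] - 1L)
      ccpos <- NA_integer_
      for (j in rev(between)) {
        if (is_leaf(ch[[j]]) && ch[[j]]$label == "CC") { ccpos <- j; break }
      }
      e <- if (!is.na(ccpos)) ccpos - 1L else t
      pos <- if (!is.na(ccpos)) ccpos else t + 1L
    } else {
      e <- length(ch)
      pos <- length(ch) + 1L
    }
    out[[length(out) + 1L]] <- .action_node(trig[t], ch[s:e])
  }
  phrase_node("Sentence", out)
}

.collect_actions <- function(node, depth = 0L, sentence = NA_integer_) {
  rows <- list()
  if (identical(node$label, "ActionPhrase")) {
    sp <- node_span(node)
    rows[[1]] <- data.frame(
      type = node$attrs$type, start = sp[1], end = sp[2],
      surface = node_text(node), depth = depth, sentence = sentence,
      stringsAsFactors = FALSE)
    depth <- depth + 1L
  }
  for (ch in node$children) {
    rows <- c(rows, list(.collect_actions(ch, depth, sentence)))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      depth = integer(0), sentence = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Identify Action phrases in a parsed sentence
#'
#' Scans the phrase tree for clause segments whose verb group carries an
#' action-verb tag (or, for verbless headings, whose leading noun phrase
#' carries a nominalisation such as "Synthesis of ...") and wraps each
#' segment in an \code{ActionPhrase} node typed with one of the 21 Action
#' types. Nested phrases are produced for triggered infinitive verb phrases
#' ("... to give the title compound ...") and for implicit solutions inside
#' Add phrases ("X (0.5 g) in DMF (33 cm3)" becomes a nested Dissolve
#' phrase).
#'
#' @param sentence a \code{Sentence} \code{phrase_node} from
#'   [parse_sentence()].
#' @param triggers the action-trigger table, see [action_triggers()].
#' @param sentence_index optional ordinal recorded in the action table.
#' @return list with \code{tree} (the rewritten sentence) and \code{actions}
#'   (data.frame: \code{type}, \code{start}, \code{end}, \code{surface},
#'   \code{depth}, \code{sentence}); sentences with no trigger yield a
#'   zero-row table.
#' @export
identify_actions <- function(sentence, triggers = action_triggers(),
                             sentence_index = NA_integer_) {
  stopifnot(inherits(sentence, "phrase_node"))
  maps <- .trigger_maps(triggers)
  tree <- .segment_sentence(sentence, maps)
  tree <- .wrap_nested_vps(tree, maps$verb)
  tree <- .wrap_implicit_dissolve(tree)
  list(tree = tree, actions = .collect_actions(tree, sentence = sentence_index))
}
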