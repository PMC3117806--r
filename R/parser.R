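# Deterministic recursive-descent phrase parser over tagged tokens.
# PEG-style ordered choice with unbounded lookahead and backtracking; ordered
# alternatives resolve ambiguity, longest match preferred. Inputs that fit no
# rule degrade into Unmatched nodes -- the parse never fails.

NOUN_TAGS <- c("NN", "NNS", "NNP", "EX", "PRP", "WDT",
               "NN-STATE", "NN-MIXTURE", "NN-SOLUTION",
               "NN-MASS", "NN-MOLAR", "NN-VOL", "NN-TIME", "NN-TEMP",
               "NN-EQUIV", "NN-PERCENT")
ADJ_TAGS <- c("JJ", "JJR", "JJS")
UNIT_TAGS <- c("NN-MASS", "NN-MOLAR", "NN-VOL", "NN-PERCENT", "NN-TEMP",
               "NN-TIME", "NN-EQUIV")
FUSED_AMOUNT_TAGS <- c("CD-PERCENT", "CD-TEMP", "CD-TIME")
FINITE_TAGS <- c("VBD", "VBZ", "VBP", "MD")
AUX_SURFACES <- c("was", "were", "is", "are", "be", "been", "being",
                  "has", "have", "had", "did", "does", "do")
QUALIFIER_SURFACES <- c("ca.", "~", "approx.", "about", "approximately")

UNIT_KIND <- c("NN-MASS" = "mass", "NN-MOLAR" = "molar", "NN-VOL" = "volume",
               "NN-PERCENT" = "percent", "NN-TEMP" = "temperature",
               "NN-TIME" = "time", "NN-EQUIV" = "equivalents",
               "CD-PERCENT" = "percent", "CD-TEMP" = "temperature",
               "CD-TIME" = "time")

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_state <- function(tagged) {
  st <- new.env(parent = emptyenv())
  st$toks <- tagged
  st$i <- 1L
  st$n <- nrow(tagged)
  st$verb_seen <- FALSE
  st
}
.tg <- function(st, k = 0L) {
  j <- st$i + k
  if (j >= 1L && j <= st$n) st$toks$tag[j] else ""
}
.sf <- function(st, k = 0L) {
  j <- st$i + k
  if (j >= 1L && j <= st$n) st$toks$surface[j] else ""
}
.take <- function(st) {
  nd <- leaf_node(st$toks[st$i, , drop = FALSE])
  st$i <- st$i + 1L
  nd
}
.is_verb_tag <- function(tag) {
  startsWith(tag, "VB-") || tag %in% c("VB", "VBD", "VBG", "VBN", "VBZ", "VBP")
}
.is_finite_start <- function(st, k = 0L) {
  tag <- .tg(st, k)
  tag %in% FINITE_TAGS || startsWith(tag, "VB-")
}

# ---- quantity -------------------------------------------------------------

.p_amount_leaves <- function(st) {
  save <- st$i
  kids <- list()
  if (tolower(.sf(st)) %in% QUALIFIER_SURFACES) kids <- c(kids, list(.take(st)))
  if (.tg(st) %in% FUSED_AMOUNT_TAGS) {
    kids <- c(kids, list(.take(st)))
    return(kids)
  }
  if (.tg(st) != "CD") { st$i <- save; return(NULL) }
  kids <- c(kids, list(.take(st)))
  if (.tg(st) == "TIMES" && .tg(st, 1L) == "CD") {
    kids <- c(kids, list(.take(st)), list(.take(st)))
  }
  if (.tg(st) %in% UNIT_TAGS || .tg(st) %in% FUSED_AMOUNT_TAGS) {
    kids <- c(kids, list(.take(st)))
  }
  kids
}

.p_quantity_node <- function(st) {
  if (.tg(st) != "LRB") return(NULL)
  save <- st$i
  kids <- list(.take(st))
  first <- TRUE
  repeat {
    if (.tg(st) == "RRB") break
    if (!first) {
      if (.tg(st) != "COMMA") { st$i <- save; return(NULL) }
      kids <- c(kids, list(.take(st)))
    }
    am <- .p_amount_leaves(st)
    if (is.null(am)) { st$i <- save; return(NULL) }
    kids <- c(kids, am)
    first <- FALSE
    # tolerate one trailing word after an amount ("57% yield")
    if (!(.tg(st) %in% c("COMMA", "RRB")) && .tg(st, 1L) == "RRB") {
      kids <- c(kids, list(.take(st)))
    }
  }
  if (.tg(st) != "RRB") { st$i <- save; return(NULL) }
  kids <- c(kids, list(.take(st)))
  phrase_node("QUANTITY", kids)
}

.p_bare_quantity <- function(st) {
  save <- st$i
  kids <- list()
  if (.tg(st) %in% FUSED_AMOUNT_TAGS) {
    kids <- list(.take(st))
  } else if (.tg(st) == "CD" &&
             (.tg(st, 1L) %in% UNIT_TAGS ||
              (.tg(st, 1L) == "TIMES" && .tg(st, 2L) == "CD"))) {
    kids <- list(.take(st))
    if (.tg(st) == "TIMES" && .tg(st, 1L) == "CD") {
      kids <- c(kids, list(.take(st)), list(.take(st)))
    }
    if (.tg(st) %in% UNIT_TAGS) kids <- c(kids, list(.take(st)))
  } else {
    return(NULL)
  }
  if (!length(kids)) { st$i <- save; return(NULL) }
  phrase_node("QUANTITY", kids)
}

#' Parse a bracketed quantity group into typed amounts
#'
#' Interprets a comma-separated bracketed group of numbers and units --
#' \code{"( 0.63 g , 4.56 mmol )"} -- as typed physical amounts. Fused
#' number-unit tokens (\code{100\%}, \code{80°C}), qualifiers
#' (\code{ca.}) and multiplicative volumes (\code{5 × 50 cm3}, recorded once
#' with a repeat count) are supported. A number with no unit yields kind
#' \code{"unknown"}.
#'
#' @param tagged a tagged-token data.frame whose first row is a left bracket
#'   (or a \code{QUANTITY} \code{phrase_node}).
#' @return data.frame with columns \code{kind} (mass, molar, volume, percent,
#'   temperature, time, equivalents, unknown), \code{value}, \code{unit},
#'   \code{qualifier} and \code{repeats}.
#' @export
parse_quantity <- function(tagged) {
  if (inherits(tagged, "phrase_node")) tagged <- ast_leaf_tokens(tagged)
  stopifnot(is.data.frame(tagged))
  bracketed <- nrow(tagged) > 0L && tagged$tag[1] == "LRB"
  if (!bracketed && !(nrow(tagged) > 0L &&
                      (tagged$tag[1] %in% c("CD", FUSED_AMOUNT_TAGS) ||
                       tolower(tagged$surface[1]) %in% QUALIFIER_SURFACES))) {
    stop("quantity group must start with a left bracket")
  }
  out <- data.frame(kind = character(0), value = numeric(0),
                    unit = character(0), qualifier = character(0),
                    repeats = numeric(0), stringsAsFactors = FALSE)
  qualifier <- NA_character_
  value <- NA_real_
  repeats <- 1
  flush <- function(unit_tag, unit_surface) {
    kind <- if (is.na(unit_tag)) "unknown" else unname(UNIT_KIND[unit_tag])
    out[nrow(out) + 1L, ] <<- list(kind, value, unit_surface, qualifier,
                                   repeats)
    qualifier <<- NA_character_
    value <<- NA_real_
    repeats <<- 1
  }
  for (k in seq_len(nrow(tagged))) {
    tag <- tagged$tag[k]
    surf <- tagged$surface[k]
    if (tag %in% c("LRB", "RRB")) next
    if (tag == "COMMA") { if (!is.na(value)) flush(NA, NA_character_); next }
    if (tolower(surf) %in% QUALIFIER_SURFACES) { qualifier <- tolower(surf); next }
    if (tag == "CD") {
      if (!is.na(value)) flush(NA, NA_character_)
      value <- as.numeric(surf)
    } else if (tag == "TIMES") {
      repeats <- value
      value <- NA_real_
    } else if (tag %in% FUSED_AMOUNT_TAGS) {
      if (!is.na(value)) flush(NA, NA_character_)
      value <- as.numeric(sub("^(-?[0-9.]+).*$", "\\1", surf))
      flush(tag, sub("^-?[0-9.]+", "", surf))
    } else if (tag %in% UNIT_TAGS) {
      if (is.na(value)) next
      flush(tag, surf)
    } else {
      next # stray word such as "yield"
    }
  }
  if (!is.na(value)) flush(NA, NA_character_)
  out
}

# ---- noun phrases ---------------------------------------------------------

.p_molecule <- function(st) {
  if (!startsWith(.tg(st), "OSCAR-")) return(NULL)
  kids <- list()
  while (startsWith(.tg(st), "OSCAR-")) kids <- c(kids, list(.take(st)))
  # compound reference number: bold dialect, or bare integer in reference
  # position (immediately before a bracketed quantity / colon / stop)
  if (.tg(st) == "CD-BOLD" ||
      (.tg(st) == "CD" &&
       .tg(st, 1L) %in% c("LRB", "COLON", "STOP", ""))) {
    kids <- c(kids, list(.take(st)))
  }
  q <- .p_quantity_node(st)
  if (!is.null(q)) kids <- c(kids, list(q))
  phrase_node("MOLECULE", kids)
}

.p_paren_group <- function(st) {
  if (.tg(st) != "LRB") return(NULL)
  save <- st$i
  kids <- list(.take(st))
  mol <- .p_molecule(st)
  if (is.null(mol) || .tg(st) != "RRB") { st$i <- save; return(NULL) }
  kids <- c(kids, list(mol), list(.take(st)))
  phrase_node("NounPhrase", kids)
}

.p_np_item <- function(st) {
  nd <- .p_molecule(st)
  if (!is.null(nd)) return(nd)
  nd <- .p_quantity_node(st) %||% .p_paren_group(st)
  if (!is.null(nd)) return(nd)
  tag <- .tg(st)
  if (tag %in% NOUN_TAGS || tag == "CD-BOLD" ||
      startsWith(tag, "NN-")) return(.take(st))
  if (tag == "CD") return(.take(st))
  NULL
}

.p_np_core <- function(st) {
  save <- st$i
  kids <- list()
  if (.tg(st) == "DT") kids <- c(kids, list(.take(st)))
  repeat {
    tag <- .tg(st)
    nounish_next <- .tg(st, 1L) %in% NOUN_TAGS ||
      startsWith(.tg(st, 1L), "OSCAR-") || .tg(st, 1L) %in% ADJ_TAGS ||
      .tg(st, 1L) %in% c("VBD", "VBN", "VBG", "JJ")
    if (tag %in% ADJ_TAGS ||
        (tag %in% c("VBD", "VBN", "VBG") && nounish_next)) {
      kids <- c(kids, list(.take(st)))
    } else {
      break
    }
  }
  n_items <- 0L
  repeat {
    it <- .p_np_item(st)
    if (is.null(it)) break
    kids <- c(kids, list(it))
    n_items <- n_items + 1L
  }
  if (n_items == 0L) { st$i <- save; return(NULL) }
  kids
}

.p_nounphrase <- function(st) {
  kids <- .p_np_core(st)
  if (is.null(kids)) return(NULL)
  # conjunction absorption: "A and B" joins inside one NounPhrase unless the
  # conjunct opens a new finite clause ("... and the mixture was stirred")
  while (.tg(st) == "CC") {
    save <- st$i
    cc <- .take(st)
    core2 <- .p_np_core(st)
    if (is.null(core2) || (st$verb_seen && .is_finite_start(st))) {
      st$i <- save
      break
    }
    kids <- c(kids, list(cc), core2)
  }
  phrase_node("NounPhrase", kids)
}

# ---- prepositional and verb phrases ---------------------------------------

.p_prepphrase <- function(st) {
  if (!(.tg(st) %in% c("TO", "IN"))) return(NULL)
  save <- st$i
  prep <- .take(st)
  obj <- .p_bare_quantity(st) %||% .p_nounphrase(st)
  if (is.null(obj) && (.tg(st) %in% c("VBG") || startsWith(.tg(st), "VB-"))) {
    obj <- .take(st) # gerund object: "under stirring", "without heating"
  }
  if (is.null(obj)) { st$i <- save; return(NULL) }
  phrase_node("PrepPhrase", list(prep, obj))
}

.p_to_infinitive <- function(st) {
  if (.tg(st) != "TO" || !.is_verb_tag(.tg(st, 1L))) return(NULL)
  save <- st$i
  to <- .take(st)
  vp <- .p_verbphrase(st, infinitive = TRUE)
  if (is.null(vp)) { st$i <- save; return(NULL) }
  phrase_node("VerbPhrase", c(list(to), vp$children))
}

.p_verbphrase <- function(st, infinitive = FALSE) {
  save <- st$i
  kids <- list()
  contentful <- FALSE
  while (.tg(st) == "RB") kids <- c(kids, list(.take(st)))
  n_verbs <- 0L
  repeat {
    tag <- .tg(st)
    if (!.is_verb_tag(tag)) break
    if (tag %in% c("VBD", "VBG", "VBN") &&
        !(tolower(.sf(st)) %in% AUX_SURFACES)) {
      # participle opening a noun phrase ("Deionised water") is not a verb
      nxt <- .tg(st, 1L)
      if (startsWith(nxt, "OSCAR-") || nxt %in% NOUN_TAGS || nxt %in% ADJ_TAGS) {
        break
      }
    }
    if (!(tolower(.sf(st)) %in% AUX_SURFACES)) contentful <- TRUE
    kids <- c(kids, list(.take(st)))
    n_verbs <- n_verbs + 1L
    while (.tg(st) == "RB") kids <- c(kids, list(.take(st)))
  }
  if (n_verbs == 0L || !contentful) { st$i <- save; return(NULL) }
  if (!infinitive) st$verb_seen <- TRUE
  # complements: prep phrases, infinitives, noun phrases, quantities,
  # trailing participial verb phrases
  repeat {
    tag <- .tg(st)
    if (tag %in% c("", "STOP", "CC", "COMMA", "SEMICOLON", "COLON")) break
    comp <- .p_to_infinitive(st) %||% .p_prepphrase(st) %||%
      .p_bare_quantity(st) %||% .p_quantity_node(st) %||%
      .p_nounphrase(st)
    if (is.null(comp) && .is_verb_tag(tag)) comp <- .p_verbphrase(st)
    if (is.null(comp) && tag == "RB") comp <- .take(st)
    if (is.null(comp)) break
    kids <- c(kids, list(comp))
  }
  phrase_node("VerbPhrase", kids)
}

# ---- sentence -------------------------------------------------------------

.merge_unmatched <- function(kids) {
  out <- list()
  for (nd in kids) {
    prev <- if (length(out)) out[[length(out)]] else NULL
    if (identical(nd$label, "Unmatched") && !is.null(prev) &&
        identical(prev$label, "Unmatched")) {
      prev$children <- c(prev$children, nd$children)
      out[[length(out)]] <- prev
    } else {
      out[[length(out) + 1L]] <- nd
    }
  }
  out
}

#' Parse one tagged sentence into a phrase tree
#'
#' Deterministic recursive-descent chunking of a fully tagged sentence into
#' noun, verb and prepositional phrases with MOLECULE and QUANTITY subunits.
#' The grammar covers the procedural fragment of synthesis prose; token
#' subsequences matching no rule are wrapped in \code{Unmatched} nodes rather
#' than aborting, so parsing always yields a tree whose leaves partition the
#' input tokens.
#'
#' @param tagged a tagged-token data.frame from [cascade_tag()] (one
#'   sentence).
#' @return a \code{phrase_node} with label \code{"Sentence"}.
#' @export
parse_sentence <- function(tagged) {
  stopifnot(is.data.frame(tagged), "tag" %in% names(tagged))
  st <- .new_state(tagged)
  kids <- list()
  while (st$i <= st$n) {
    tag <- .tg(st)
    nd <- NULL
    if (tag == "STOP") {
      nd <- .take(st)
    } else if (tag == "CC" && st$verb_seen) {
      nd <- .take(st)
    } else if (tag == "COMMA") {
      nd <- .take(st)
    } else {
      nd <- .p_nounphrase(st) %||% .p_verbphrase(st) %||% .p_prepphrase(st)
      if (is.null(nd)) {
        nd <- phrase_node("Unmatched", list(.take(st)))
      }
    }
    kids[[length(kids) + 1L]] <- nd
  }
  phrase_node("Sentence", .merge_unmatched(kids))
}
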