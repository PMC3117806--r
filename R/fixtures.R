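# Seeded generator of synthetic experimental paragraphs with gold trees and
# annotations, and a perturbation model emulating annotator disagreement.

#' Sentence templates, one set per Action type
#'
#' Grammar-conformant sentence patterns for each of the 21 Action types,
#' with placeholders for chemicals (\code{\{CM\}}, \code{\{CM2\}},
#' \code{\{GAS\}}), amounts (\code{\{mass\}}, \code{\{molar\}},
#' \code{\{vol\}}, \code{\{vol2\}}, \code{\{percent\}}, \code{\{time\}},
#' \code{\{n\}}) and compound reference numbers (\code{\{ref\}}). Stored as
#' a tab-separated data file so templates can be extended without code
#' changes.
#'
#' @param path optional alternative template file.
#' @return data.frame with columns \code{type} and \code{template}.
#' @export
action_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "action_templates.tsv", package = "chemtagr")
  }
  read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Configuration for the synthetic paragraph generator
#'
#' @param seed integer seed; all sampling is driven by it.
#' @param n_sentences number of sentences to generate.
#' @param action_mix named probability vector over the 21 Action types
#'   (default uniform); must sum to 1.
#' @param chemicals chemical names sampled into templates.
#' @param boundary_jitter_tokens,label_confusion_prob,drop_prob perturbation
#'   rates used by [perturb_annotations()]: spans have their boundaries
#'   moved by up to this many tokens, their label swapped with this
#'   probability, and are dropped entirely with this probability.
#' @return a \code{generation_config} list.
#' @export
generation_config <- function(seed = 1L, n_sentences = 10L,
                              action_mix = NULL,
                              chemicals = NULL,
                              boundary_jitter_tokens = 0L,
                              label_confusion_prob = 0,
                              drop_prob = 0) {
  types <- action_types()
  if (is.null(action_mix)) {
    action_mix <- stats::setNames(rep(1 / length(types), length(types)), types)
  }
  stopifnot(all(names(action_mix) %in% types),
            abs(sum(action_mix) - 1) < 1e-8,
            all(action_mix >= 0),
            label_confusion_prob >= 0, label_confusion_prob <= 1,
            drop_prob >= 0, drop_prob <= 1)
  if (is.null(chemicals)) {
    chemicals <- c("potassium carbonate", "thiophenol", "methanol",
                   "ethyl acetate", "diethyl ether", "toluene", "water",
                   "brine", "ethanol", "dichloromethane", "acetonitrile",
                   "sodium chloride")
  }
  structure(list(seed = as.integer(seed),
                 n_sentences = as.integer(n_sentences),
                 action_mix = action_mix, chemicals = chemicals,
                 boundary_jitter_tokens = as.integer(boundary_jitter_tokens),
                 label_confusion_prob = label_confusion_prob,
                 drop_prob = drop_prob),
            class = "generation_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.fill_template <- function(template, cfg) {
  cm <- sample(cfg$chemicals, 2L)
  subs <- c(
    "\\{CM\\}" = cm[1], "\\{CM2\\}" = cm[2],
    "\\{GAS\\}" = sample(c("argon", "nitrogen", "helium"), 1L),
    "\\{mass\\}" = format(round(stats::runif(1, 0.05, 5), 2), nsmall = 2),
    "\\{molar\\}" = format(round(stats::runif(1, 0.1, 20), 2), nsmall = 2),
    "\\{vol\\}" = as.character(sample(5:500, 1L)),
    "\\{vol2\\}" = as.character(sample(5:500, 1L)),
    "\\{percent\\}" = as.character(sample(10:99, 1L)),
    "\\{time\\}" = as.character(sample(1:48, 1L)),
    "\\{n\\}" = as.character(sample(2:10, 1L)),
    "\\{ref\\}" = as.character(sample(1:99, 1L)))
  for (k in seq_along(subs)) {
    template <- gsub(names(subs)[k], subs[k], template)
  }
  # sentence-initial capital, as in real prose
  paste0(toupper(substr(template, 1, 1)), substr(template, 2, nchar(template)))
}

# Gold derivation for one generated sentence: the whole sentence is one
# ActionPhrase of the template's type, with whitespace-token leaves.
.gold_tree <- function(sentence_text, type) {
  toks <- strsplit(trimws(sentence_text), "\\s+")[[1]]
  leaves <- lapply(seq_along(toks), function(k) {
    phrase_node(
      "TOKEN",
      token = list(id = k - 1L, surface = toks[k], start = NA_integer_,
                   end = NA_integer_, tag = "TOKEN", namespace = "GOLD"))
  })
  phrase_node("Sentence",
              list(phrase_node("ActionPhrase", leaves,
                               attrs = list(type = type))))
}

#' Generate a synthetic experimental paragraph with gold annotations
#'
#' Instantiates grammar-conformant sentence templates (one per sampled
#' Action type) with sampled chemicals, quantities and conditions.
#' Deterministic under a fixed seed.
#'
#' @param config a [generation_config()].
#' @return list with \code{text} (the paragraph), \code{types} (the gold
#'   Action type per sentence), \code{gold_trees} (the generating
#'   derivations, one \code{phrase_node} per sentence) and \code{gold}
#'   (the gold annotation spans: one phrase per sentence, offsets into
#'   \code{text}, with the paragraph attached as \code{attr(, "text")}).
#' @export
generate_paragraph <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  templates <- action_templates()
  if (config$n_sentences == 0L) {
    empty <- annotation_spans(integer(0), integer(0), character(0),
                              character(0))
    attr(empty, "text") <- ""
    return(list(text = "", types = character(0), gold_trees = list(),
                gold = empty))
  }
  .with_seed(config$seed, {
    types <- sample(names(config$action_mix), config$n_sentences,
                    replace = TRUE, prob = config$action_mix)
    sents <- vapply(types, function(ty) {
      tpl <- templates$template[templates$type == ty]
      .fill_template(tpl[1], config)
    }, character(1), USE.NAMES = FALSE)
    text <- paste(sents, collapse = " ")
    offs <- cumsum(c(0L, nchar(sents[-length(sents)]) + 1L))
    gold <- annotation_spans(offs, offs + nchar(sents), sents, types)
    attr(gold, "text") <- text
    list(text = text, types = types,
         gold_trees = Map(.gold_tree, sents, types, USE.NAMES = FALSE),
         gold = gold)
  })
}

#' Perturb gold annotations to emulate annotator disagreement
#'
#' Each span independently: its boundaries are jittered by up to
#' \code{boundary_jitter_tokens} whitespace tokens (emulating disagreement
#' about where a phrase starts, e.g. whether a leading "To a" belongs), its
#' label is swapped for a random other Action type with probability
#' \code{label_confusion_prob}, and it is dropped entirely with probability
#' \code{drop_prob}. The output is re-sorted by start offset.
#'
#' @param gold gold annotation data.frame with the document in
#'   \code{attr(gold, "text")} (as produced by [generate_paragraph()]).
#' @param config a [generation_config()] carrying the perturbation rates and
#'   seed.
#' @param text the document text (defaults to the attribute on \code{gold}).
#' @return a perturbed annotation data.frame.
#' @export
perturb_annotations <- function(gold, config, text = attr(gold, "text")) {
  stopifnot(inherits(config, "generation_config"), is.character(text))
  if (nrow(gold) == 0L) return(gold)
  bounds <- gregexpr("\\S+", text)[[1]]
  tok_start <- as.integer(bounds) - 1L
  tok_end <- tok_start + attr(bounds, "match.length")
  .with_seed(config$seed + 1L, {
    keep <- stats::runif(nrow(gold)) >= config$drop_prob
    rows <- list()
    for (i in which(keep)) {
      s <- gold$start[i]
      e <- gold$end[i]
      lab <- gold$label[i]
      j <- config$boundary_jitter_tokens
      if (j > 0L) {
        si <- which.min(abs(tok_start - s))
        ei <- which.min(abs(tok_end - e))
        si <- min(max(1L, si + sample(-j:j, 1L)), length(tok_start))
        ei <- min(max(si, ei + sample(-j:j, 1L)), length(tok_end))
        s <- tok_start[si]
        e <- tok_end[ei]
      }
      if (stats::runif(1) < config$label_confusion_prob) {
        lab <- sample(setdiff(action_types(), lab), 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, surface = substr(text, s + 1L, e),
        label = lab, stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      out <- gold[0, , drop = FALSE]
    } else {
      out <- do.call(rbind, rows)
      out <- annotation_spans(out$start, out$end, out$surface, out$label)
    }
    attr(out, "text") <- text
    out
  })
}
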