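#' Bundled chemical-name lexicon
#'
#' Common reagents, solvents, element names, formulae and acronyms used by the
#' bundled chemical named-entity tagger. Entries may span several tokens
#' ("potassium carbonate"). The file format is one entry per line with
#' \code{#} comments, so the lexicon can be extended without code changes.
#'
#' @param path optional path to an alternative lexicon file.
#' @return character vector of lexicon entries.
#' @export
chemical_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chemical_lexicon.txt", package = "chemtagr")
  }
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

# Systematic-name suffix morphology used when a token is not in the lexicon.
CHEM_SUFFIXES <- c("ol", "ene", "ane", "yne", "ide", "ine", "ate", "ite",
                   "amide", "amine", "ium", "one", "ose", "oxide", "ether",
                   "ylene", "idine", "azole", "phene")

# Molecular-formula pattern: two or more element-symbol groups (H2O, MgSO4,
# EtOAc); also matches short all-caps acronyms.
FORMULA_PATTERN <- "^([A-Z][a-z]?[0-9]*){2,6}$"

#' The action-trigger table
#'
#' One row per Action family: the phrase type, the regex tag assigned to its
#' trigger verbs, the accepted verb forms, and (where applicable) noun
#' nominalisations ("Synthesis of ..."). Stored as a tab-separated file so the
#' trigger lexicon is editable without code changes.
#'
#' @param path optional path to an alternative trigger file.
#' @return data.frame with columns \code{type}, \code{tag}, \code{forms},
#'   \code{nominal}.
#' @export
action_triggers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "action_triggers.tsv", package = "chemtagr")
  }
  read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
             fileEncoding = "UTF-8")
}

#' The closed set of Action phrase types
#'
#' @return character vector of the 21 supported Action types, in registry
#'   order.
#' @examples
#' length(action_types())
#' @export
action_types <- function() {
  action_triggers()$type
}

#' Default regex tagging rules
#'
#' The ordered rules file of the domain regex tagger: units (mass, amount of
#' substance, volume, percent, temperature, time), physical states, mixture
#' and solution nouns, fused number-unit forms ("100%", "80°C"), compound
#' reference numbers in the selected bold dialect, and the action-verb
#' families of [action_triggers()]. Patterns are anchored to whole tokens;
#' the first matching rule wins.
#'
#' @param bold_dialect how bold compound reference numbers appear in the
#'   plain-text input: \code{"markdown"} (\code{**82**}), \code{"html"}
#'   (\code{<b>82</b>}) or \code{"positional"} (bare integers in reference
#'   positions, resolved later by the parser).
#' @param path optional path to an alternative rules file (unit/state rules).
#' @param triggers action-trigger table, see [action_triggers()].
#' @return data.frame with columns \code{pattern} and \code{tag}, in
#'   application order.
#' @export
default_tag_rules <- function(bold_dialect = c("markdown", "html", "positional"),
                              path = NULL, triggers = action_triggers()) {
  bold_dialect <- match.arg(bold_dialect)
  if (is.null(path)) {
    path <- system.file("extdata", "tag_rules.tsv", package = "chemtagr")
  }
  rules <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  bold <- switch(bold_dialect,
    markdown = data.frame(pattern = "^\\*\\*[0-9]+\\*\\*$", tag = "CD-BOLD"),
    html = data.frame(pattern = "^<b>[0-9]+</b>$", tag = "CD-BOLD"),
    positional = NULL)
  verb <- data.frame(
    pattern = paste0("^(", triggers$forms, ")$"),
    tag = triggers$tag, stringsAsFactors = FALSE)
  nom <- triggers[nzchar(triggers$nominal), , drop = FALSE]
  nominal <- if (nrow(nom)) data.frame(
    pattern = paste0("^(", nom$nominal, ")$"),
    tag = sub("^VB-", "NN-", nom$tag), stringsAsFactors = FALSE)
  out <- rbind(rules, bold, nominal, verb)
  rownames(out) <- NULL
  out
}

#' The bundled worked example: a complete preparation paragraph
#'
#' A benzazepine preparation in the classic style of organic-chemistry
#' experimental sections: a title line naming the product with its compound
#' reference number, followed by three sentences covering addition,
#' stirring, aqueous work-up, drying, concentration and yield.
#'
#' @return list with elements \code{title} (the title line) and \code{text}
#'   (the paragraph body).
#' @examples
#' sample_preparation()$title
#' @export
sample_preparation <- function() {
  list(
    title = "5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine 82:",
    text = paste(
      "Potassium carbonate (0.63 g, 4.56 mmol) and thiophenol (0.19 g,",
      "1.69 mmol) were added to the 2-nitrobenzene sulfonamide **50**",
      "(0.50 g, 1.302 mmol) in N, N-dimethylformamide (33 cm3) at room",
      "temperature and the mixture was stirred for 16 h. Deionised water",
      "(50 cm3) was added and the aqueous phase was extracted with ethyl",
      "acetate (5 × 50 cm3). The organic extracts were dried (MgSO4) and",
      "concentrated under reduced pressure to give the title compound **82**",
      "(0.259 g, 1.302 mmol, ca. 100%) as an oil used without further",
      "purification.")
  )
}

#' Bundled two-annotator alignment example
#'
#' A pair of span-annotation lists over the same apparatus/work-up passage in
#' which the two annotators chose slightly different phrase boundaries and one
#' phrase was marked by only one of them. Character offsets are synthesised
#' from the cumulative surface lengths (the alignment operates on surfaces).
#'
#' @return list with annotation data.frames \code{a} and \code{b} (columns
#'   \code{start}, \code{end}, \code{surface}, \code{label}).
#' @export
alignment_example <- function() {
  path <- system.file("extdata", "alignment_demo.tsv", package = "chemtagr")
  x <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mk <- function(d) {
    len <- nchar(d$surface)
    end <- cumsum(len + 1L) - 1L
    data.frame(start = end - len, end = end, surface = d$surface,
               label = d$label, stringsAsFactors = FALSE)
  }
  list(a = mk(x[x$annotator == "A", ]), b = mk(x[x$annotator == "B", ]))
}
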