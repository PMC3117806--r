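# Unicode code points treated as nonprinting and stripped during
# normalisation; tab/newline/CR are word delimiters and become spaces instead.
NONPRINTING_CODEPOINTS <- c(0:31, 127L, 129L, 141L, 143L, 144L, 157L)
WHITESPACE_CONTROL <- c(9L, 10L, 13L)

# Dotted abbreviations that keep their full stop attached (a single token) and
# therefore never trigger a sentence boundary. Bare unit symbols ("h", "g")
# are deliberately absent: "stirred for 16 h." ends its sentence.
ABBREVIATIONS <- c("ca.", "e.g.", "i.e.", "etc.", "vs.", "approx.", "wt.",
                   "no.", "approximately.")

#' Decide whether a whitespace-delimited chunk looks like a chemical name
#'
#' Locant/affix morphology: digits joined to hyphens ("2-nitrobenzene"),
#' bracketed isotope/ring locants ("[1H]"), or leading element-style locants
#' ("N,N-"). Commas and brackets inside such chunks are part of the name and
#' must not be split off.
#'
#' @param s a single chunk (no internal whitespace).
#' @return logical scalar.
#' @keywords internal
is_chemical_candidate <- function(s) {
  grepl("[0-9]-[A-Za-z([]", s) ||
    grepl("[])A-Za-z]-[0-9]", s) ||
    grepl("\\[[0-9]*[A-Za-z]\\]", s) ||
    grepl("^[A-Z](,[A-Z])*-", s) ||
    grepl("^[A-Z],$", s)
}

# Positions (after which to cut) splitting one whitespace chunk into tokens.
chunk_cuts <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(integer(0))
  if (tolower(s) %in% ABBREVIATIONS) return(integer(0))
  cs <- strsplit(s, "", fixed = FALSE)[[1]]
  chem <- is_chemical_candidate(s)
  alnum <- grepl("[[:alnum:]]", cs)
  digit <- grepl("[0-9]", cs)
  cuts <- integer(0)
  isolate <- function(i) c(i - 1L, i)
  for (i in seq_len(n)) {
    c1 <- cs[i]
    if (c1 %in% c("(", ")", "[", "]", "{", "}")) {
      if (!chem) cuts <- c(cuts, isolate(i))
    } else if (c1 == ",") {
      keep <- (chem && i > 1L && i < n && alnum[i - 1L] && alnum[i + 1L]) ||
        grepl("^[A-Z],$", s)
      if (!keep) cuts <- c(cuts, isolate(i))
    } else if (c1 == ".") {
      decimal <- i > 1L && i < n && digit[i - 1L] && digit[i + 1L]
      if (!decimal) cuts <- c(cuts, isolate(i))
    } else if (c1 %in% c(";", ":", "!", "?", "\"", "“", "”", "×")) {
      cuts <- c(cuts, isolate(i))
    }
  }
  sort(unique(cuts[cuts >= 1L & cuts < n]))
}

#' Normalise raw experimental text
#'
#' Removes nonprinting Unicode characters (code points 0-31, 127, 129, 141,
#' 143, 144 and 157; tab/newline/CR become spaces first, as does the
#' non-breaking space), collapses whitespace runs, and inserts spaces between
#' alphanumeric and non-alphanumeric characters so that strings such as
#' \code{"(0.63 g,"} break into their constituent parts. Decimal points inside
#' numbers and commas/brackets/hyphens inside chemical-name candidates are
#' protected. An offset map projects every normalised character back onto the
#' original text.
#'
#' @param raw a single character string (the original document text).
#' @return an object of class \code{chem_normalized}: a list with \code{text}
#'   (the normalised string) and \code{map} (integer vector, one entry per
#'   character of \code{text}, giving the 1-based index of the originating
#'   character in \code{raw}, or \code{NA} for inserted spaces).
#' @examples
#' normalize_text("Potassium carbonate (0.63 g, 4.56 mmol)")$text
#' @export
normalize_text <- function(raw) {
  if (inherits(raw, "chem_normalized")) return(raw)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single character string")
  }
  cp <- utf8ToInt(raw)
  ch <- if (length(cp)) vapply(cp, intToUtf8, character(1)) else character(0)
  ch[cp %in% WHITESPACE_CONTROL | cp == 160L] <- " "
  keep <- !(cp %in% setdiff(NONPRINTING_CODEPOINTS, WHITESPACE_CONTROL))
  ch <- ch[keep]
  raw_idx <- which(keep)
  is_space <- ch == " "

  pieces <- character(0)
  piece_maps <- list()
  i <- 1L
  n <- length(ch)
  while (i <= n) {
    if (is_space[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && !is_space[j + 1L]) j <- j + 1L
    s <- paste(ch[i:j], collapse = "")
    idx <- raw_idx[i:j]
    cuts <- chunk_cuts(s)
    bounds <- c(0L, cuts, nchar(s))
    for (k in seq_len(length(bounds) - 1L)) {
      from <- bounds[k] + 1L
      to <- bounds[k + 1L]
      pieces <- c(pieces, substr(s, from, to))
      piece_maps <- c(piece_maps, list(idx[from:to]))
    }
    i <- j + 1L
  }
  if (!length(pieces)) {
    stop(structure(
      class = c("chemtagr_empty_document", "error", "condition"),
      list(message = "document is empty after normalisation", call = sys.call())
    ))
  }
  text <- paste(pieces, collapse = " ")
  map <- integer(0)
  for (k in seq_along(pieces)) {
    map <- c(map, piece_maps[[k]], if (k < length(pieces)) NA_integer_)
  }
  structure(list(text = text, map = map), class = "chem_normalized")
}

#' @export
print.chem_normalized <- function(x, ...) {
  cat("<chem_normalized> ", nchar(x$text), " chars\n", sep = "")
  cat(x$text, "\n")
  invisible(x)
}

#' Tokenise normalised text
#'
#' Splits a normalised string on whitespace. Punctuation separated during
#' normalisation becomes its own token; hyphenated chemical words stay single
#' tokens. Concatenating the surfaces with single spaces reproduces the
#' normalised string. Offsets are 0-based half-open over the \emph{original}
#' text (projected through the normalisation offset map).
#'
#' @param x a \code{chem_normalized} object, or an already-normalised string.
#' @return a data.frame with columns \code{id} (0-based ordinal),
#'   \code{surface}, \code{start}, \code{end} (raw-text offsets) and
#'   \code{norm_start}, \code{norm_end} (offsets into the normalised string).
#' @export
tokenize <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("`x` must be a single string")
    if (!nzchar(x)) {
      return(data.frame(id = integer(0), surface = character(0),
                        start = integer(0), end = integer(0),
                        norm_start = integer(0), norm_end = integer(0),
                        stringsAsFactors = FALSE))
    }
    x <- list(text = x, map = seq_len(nchar(x)))
  }
  text <- x$text
  map <- x$map
  m <- gregexpr("[^ ]+", text)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(text, starts, starts + lens - 1L)
  raw_start <- integer(length(starts))
  raw_end <- integer(length(starts))
  for (k in seq_along(starts)) {
    span <- map[starts[k]:(starts[k] + lens[k] - 1L)]
    span <- span[!is.na(span)]
    raw_start[k] <- if (length(span)) min(span) - 1L else NA_integer_
    raw_end[k] <- if (length(span)) max(span) else NA_integer_
  }
  data.frame(id = seq_along(surfaces) - 1L, surface = surfaces,
             start = raw_start, end = raw_end,
             norm_start = starts - 1L, norm_end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

#' Split a token stream into sentences
#'
#' Boundaries fall after full-stop (or ! / ?) tokens when the following token
#' starts with an uppercase letter, a digit or an opening bracket, or when the
#' stop ends the document. Decimal points never produce stop tokens (they are
#' protected during normalisation) and dotted abbreviations such as
#' \code{"ca."} keep their stop attached, so neither can open a boundary.
#'
#' @param tokens a token data.frame from [tokenize()].
#' @return a list of token data.frames, one per sentence; every input token is
#'   assigned to exactly one sentence.
#' @export
split_sentences <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0L) return(list())
  boundary <- logical(n)
  for (i in seq_len(n)) {
    if (!tokens$surface[i] %in% c(".", "!", "?")) next
    if (i == n) { boundary[i] <- TRUE; next }
    if (grepl("^[A-Z0-9(\\[]", tokens$surface[i + 1L])) boundary[i] <- TRUE
  }
  boundary[n] <- TRUE
  ends <- which(boundary)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(k) {
    out <- tokens[starts[k]:ends[k], , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# head() shim avoidance: utils::head is imported via NAMESPACE.
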