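# Inter-annotator agreement machinery: Dice coefficient over span
# annotations, exact and filtered phrase matching, Needleman-Wunsch global
# alignment of annotation sequences, and pairwise agreement matrices.

# Stock words removed before filtered comparison, plus leading
# adverbs/prepositions dropped from phrase starts.
STOCK_TOKENS <- c(".", ",", ";", "and", "to", "the", "a")
LEADING_DROP <- c("then", "subsequently", "slowly", "after", "before",
                  "which", "while", "in", "at", "on", "with", "by", "under",
                  "over", "from", "for", "into", "during", "upon", "was",
                  "were", "that")

#' Construct a span-annotation table
#'
#' @param start,end 0-based half-open character offsets into the document.
#' @param surface the annotated text.
#' @param label the Action type of each phrase.
#' @return data.frame sorted by \code{start}.
#' @export
annotation_spans <- function(start, end, surface, label) {
  out <- data.frame(start = as.integer(start), end = as.integer(end),
                    surface = as.character(surface),
                    label = as.character(label), stringsAsFactors = FALSE)
  stopifnot(all(out$start < out$end))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write annotation files
#'
#' Tab-separated files with columns \code{doc_id}, \code{start}, \code{end},
#' \code{label}, \code{surface}.
#'
#' @param path file path.
#' @param spans annotation data.frame.
#' @param doc_id document identifier written alongside each span.
#' @return \code{read_annotations}: an annotation data.frame (with a
#'   \code{doc_id} column); \code{write_annotations}: \code{path}, invisibly.
#' @export
read_annotations <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("doc_id", "start", "end", "label", "surface") %in% names(x)))
  x[order(x$doc_id, x$start), , drop = FALSE]
}

#' @rdname read_annotations
#' @export
write_annotations <- function(spans, path, doc_id = "doc1") {
  out <- data.frame(doc_id = doc_id, start = spans$start, end = spans$end,
                    label = spans$label, surface = spans$surface,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

.span_tokens <- function(surface) {
  s <- gsub("([\\[\\]().,;:])", " \\1 ", tolower(surface), perl = TRUE)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.filtered_tokens <- function(surface) {
  toks <- .span_tokens(surface)
  toks <- toks[!(toks %in% STOCK_TOKENS)]
  while (length(toks) &&
         (toks[1] %in% LEADING_DROP || grepl("ly$", toks[1]))) {
    toks <- toks[-1]
  }
  toks
}

#' Exact and filtered matching of two annotation spans
#'
#' \code{exact_match} requires string-identical surfaces. \code{filtered_match}
#' compares token sequences after removing common stock words and tokens
#' (".", ",", ";", "and", "to", "the", "a") and dropping leading adverbs and
#' prepositions, so phrases that differ only in such trimmings still match.
#'
#' @param a,b one-row annotation records (or lists with a \code{surface}).
#' @return logical.
#' @export
exact_match <- function(a, b) {
  identical(trimws(a$surface), trimws(b$surface))
}

#' @rdname exact_match
#' @export
filtered_match <- function(a, b) {
  ta <- .filtered_tokens(a$surface)
  tb <- .filtered_tokens(b$surface)
  if (length(ta) == 0L && length(tb) == 0L) return(TRUE)
  if (length(ta) != length(tb)) return(FALSE)
  all(ta == tb)
}

# Token-overlap Dice between two spans' filtered token multisets; the
# similarity score used to fill the Needleman-Wunsch matrix.
span_similarity <- function(a, b) {
  ta <- .filtered_tokens(a$surface)
  tb <- .filtered_tokens(b$surface)
  if (length(ta) == 0L && length(tb) == 0L) return(1)
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  common <- 0L
  pool <- tb
  for (t in ta) {
    j <- match(t, pool)
    if (!is.na(j)) {
      common <- common + 1L
      pool <- pool[-j]
    }
  }
  2 * common / (length(ta) + length(tb))
}

#' Dice coefficient between two annotation sets
#'
#' \eqn{s = 2|X \cap Y| / (|X| + |Y|)}, with the intersection defined by the
#' supplied pair predicate (exact string match, filtered match, or any other
#' matcher). Elements pair greedily in document order and each element is
#' used at most once. Two empty sets have coefficient 1 by convention;
#' empty versus non-empty gives 0.
#'
#' @param x,y annotation data.frames.
#' @param match predicate \code{function(a, b)} over one-row records.
#' @return coefficient in \eqn{[0, 1]}.
#' @examples
#' a <- annotation_spans(0, 5, c("x y"), "Add")
#' dice(a, a, exact_match)
#' @export
dice <- function(x, y, match = exact_match) {
  nx <- nrow(x)
  ny <- nrow(y)
  if (nx == 0L && ny == 0L) return(1)
  if (nx == 0L || ny == 0L) return(0)
  used <- logical(ny)
  m <- 0L
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (!used[j] && match(x[i, , drop = FALSE], y[j, , drop = FALSE])) {
        used[j] <- TRUE
        m <- m + 1L
        break
      }
    }
  }
  2 * m / (nx + ny)
}

#' Globally align two annotation sequences (Needleman-Wunsch)
#'
#' Dynamic-programming global alignment of two ordered span sequences, the
#' algorithm bioinformatics uses for protein sequences applied to phrase
#' annotations: aligned pairs score their token-overlap Dice similarity and
#' gaps are heavily penalised, so phrases that differ only at their
#' boundaries still align while unmatched phrases align to gaps.
#'
#' @param a,b annotation data.frames in document order.
#' @param gap gap penalty (per unmatched phrase).
#' @param similarity pair scoring function, defaulting to token-overlap Dice
#'   on filtered tokens.
#' @return object of class \code{chem_alignment}: \code{index_map_a} and
#'   \code{index_map_b} (1-based original indices per alignment column, -1
#'   for gaps), \code{score}, and the column similarities \code{sims}.
#' @export
align_annotations <- function(a, b, gap = -1, similarity = span_similarity) {
  n <- nrow(a)
  m <- nrow(b)
  S <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i, j] <- similarity(a[i, , drop = FALSE], b[j, , drop = FALSE])
    }
  }
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1] <- gap * (0:n)
  F[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1L, j + 1L] <- max(F[i, j] + S[i, j],
                               F[i, j + 1L] + gap,
                               F[i + 1L, j] + gap)
    }
  }
  ia <- integer(0)
  ib <- integer(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        isTRUE(all.equal(F[i + 1L, j + 1L], F[i, j] + S[i, j]))) {
      ia <- c(i, ia); ib <- c(j, ib); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               isTRUE(all.equal(F[i + 1L, j + 1L], F[i, j + 1L] + gap))) {
      ia <- c(i, ia); ib <- c(-1L, ib); i <- i - 1L
    } else {
      ia <- c(-1L, ia); ib <- c(j, ib); j <- j - 1L
    }
  }
  sims <- vapply(seq_along(ia), function(k) {
    if (ia[k] > 0L && ib[k] > 0L) S[ia[k], ib[k]] else NA_real_
  }, numeric(1))
  structure(list(index_map_a = ia, index_map_b = ib,
                 score = F[n + 1L, m + 1L], sims = sims),
            class = "chem_alignment")
}

#' @export
print.chem_alignment <- function(x, ...) {
  cat("<chem_alignment> score:", format(x$score), "\n")
  cat(" a:", paste(x$index_map_a, collapse = ", "), "\n")
  cat(" b:", paste(x$index_map_b, collapse = ", "), "\n")
  invisible(x)
}

#' Alignment-based phrase agreement
#'
#' Dice coefficient whose intersection is the set of aligned phrase pairs
#' whose similarity clears the match threshold, computed on the
#' Needleman-Wunsch alignment of the two annotation sequences.
#'
#' @param a,b annotation data.frames in document order.
#' @param threshold minimum pair similarity for an aligned pair to count as
#'   a match.
#' @param gap gap penalty passed to [align_annotations()].
#' @return agreement in percent.
#' @export
aligned_agreement <- function(a, b, threshold = 0.5, gap = -1) {
  if (nrow(a) == 0L && nrow(b) == 0L) return(100)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  al <- align_annotations(a, b, gap = gap)
  m <- sum(!is.na(al$sims) & al$sims >= threshold)
  100 * 2 * m / (nrow(a) + nrow(b))
}

#' Action-name agreement
#'
#' Pairs the two annotation sequences by alignment, then applies a string
#' match to the Action labels: the Dice intersection counts aligned,
#' sufficiently similar pairs whose labels are identical.
#'
#' @inheritParams aligned_agreement
#' @return agreement in percent.
#' @export
action_name_agreement <- function(a, b, threshold = 0.5, gap = -1) {
  if (nrow(a) == 0L && nrow(b) == 0L) return(100)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  al <- align_annotations(a, b, gap = gap)
  m <- 0L
  for (k in seq_along(al$index_map_a)) {
    i <- al$index_map_a[k]
    j <- al$index_map_b[k]
    if (i > 0L && j > 0L && !is.na(al$sims[k]) && al$sims[k] >= threshold &&
        identical(a$label[i], b$label[j])) {
      m <- m + 1L
    }
  }
  100 * 2 * m / (nrow(a) + nrow(b))
}

#' Exact and filtered phrase agreement in percent
#'
#' @param a,b annotation data.frames.
#' @return Dice agreement in percent under the respective match predicate.
#' @export
exact_agreement <- function(a, b) 100 * dice(a, b, exact_match)

#' @rdname exact_agreement
#' @export
filtered_agreement <- function(a, b) 100 * dice(a, b, filtered_match)

#' Pairwise agreement matrix over annotators and the machine
#'
#' Computes the chosen agreement metric for every pair of annotation sets
#' and summarises it as the machine-annotator mean (machine versus each
#' annotator) and the inter-annotator mean (all annotator pairs).
#'
#' @param annotators named list of at least two annotation data.frames.
#' @param machine optional machine annotation data.frame.
#' @param metric one of \code{"aligned"}, \code{"filtered"}, \code{"exact"},
#'   \code{"action"}, or a function \code{(a, b) -> percent}.
#' @param ... passed to the metric function.
#' @return object of class \code{agreement_report}: the symmetric percentage
#'   \code{matrix}, \code{machine_annotator_mean} and
#'   \code{inter_annotator_mean}.
#' @export
agreement_matrix <- function(annotators, machine = NULL,
                             metric = c("aligned", "filtered", "exact",
                                        "action"), ...) {
  if (length(annotators) < 2L) stop("need at least two annotator sets")
  fn <- if (is.function(metric)) {
    metric
  } else {
    switch(match.arg(metric),
           aligned = aligned_agreement,
           filtered = filtered_agreement,
           exact = exact_agreement,
           action = action_name_agreement)
  }
  if (is.null(names(annotators))) {
    names(annotators) <- paste0("Annotator", seq_along(annotators))
  }
  sets <- annotators
  if (!is.null(machine)) sets <- c(sets, list(Machine = machine))
  k <- length(sets)
  M <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- fn(sets[[i]], sets[[j]], ...)
    }
  }
  na <- length(annotators)
  inter <- mean(M[seq_len(na), seq_len(na)][upper.tri(diag(na))])
  mach <- if (!is.null(machine)) mean(M[k, seq_len(na)]) else NA_real_
  structure(list(matrix = M, machine_annotator_mean = mach,
                 inter_annotator_mean = inter,
                 metric = if (is.function(metric)) "custom" else
                   match.arg(metric)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 1, ...) {
  cat("<agreement_report> metric:", x$metric, "\n")
  print(round(x$matrix, digits))
  if (!is.na(x$machine_annotator_mean)) {
    cat("Machine-Annotator Agreement:",
        round(x$machine_annotator_mean, digits), "\n")
  }
  cat("Inter-Annotator Agreement:", round(x$inter_annotator_mean, digits),
      "\n")
  invisible(x)
}
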