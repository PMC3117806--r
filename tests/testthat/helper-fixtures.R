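# Shared fixtures: the canonical example sentence per Action type, a
# brute-force alignment oracle, and random annotation-instance generators.

table1_sentences <- function() {
  data.frame(
    type = c("Add", "ApparatusAction", "Concentrate", "Cool", "Degass",
             "Dissolve", "Dry", "Extract", "Filter", "Heat", "Partition",
             "Precipitate", "Purify", "Quench", "Recover", "Remove", "Stir",
             "Synthesize", "Wait", "Wash", "Yield"),
    sentence = c(
      "Benzoyl peroxide (85 mg) was added to the solution",
      "A 50-ml round-bottom flask sealed with a septum.",
      "The filtrate was concentrated under reduced pressure without heating.",
      "The reaction was then cooled to rt.",
      "The solution was purged with argon for 30 min.",
      "Salt was dissolved in water.",
      "The yellow product was dried under vacuum.",
      "the products were extracted with diethyl ether (3 × 100 ml).",
      "The solution was filtered through a short silica gel column.",
      "The mixture was heated under reflux for 8 h.",
      "The reaction mixture was partitioned between H2O (100 ml) and EtOAc (400 ml).",
      "Precipitating in methanol.",
      "The mixture was purified by column chromatography.",
      "The reaction was quenched with methanol.",
      "The precipitate was recovered by filtration.",
      "The solvent was removed under reduced pressure.",
      "The reaction mixture was stirred at room temperature for 16 h.",
      "Synthesis of aromatic polyethers by Scholl reaction.",
      "The mixture was left 2d under stirring.",
      "The resin was washed with DMF.",
      "Chromatography afforded the alcohol 10 as a colourless oil (88 mg, 70%)."),
    stringsAsFactors = FALSE)
}

# Exhaustive enumeration of all monotone alignments; the independent oracle
# for Needleman-Wunsch optimality on small instances.
brute_force_alignment_score <- function(a, b, gap = -1,
                                        similarity = chemtagr:::span_similarity) {
  n <- nrow(a)
  m <- nrow(b)
  S <- matrix(0, max(n, 1L), max(m, 1L))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i, j] <- similarity(a[i, , drop = FALSE], b[j, , drop = FALSE])
    }
  }
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n) best <- max(best, gap + rec(i + 1L, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1L))
    if (i <= n && j <= m) best <- max(best, S[i, j] + rec(i + 1L, j + 1L))
    best
  }
  rec(1L, 1L)
}

random_annotation_set <- function(n, vocab = c("flask", "mixture", "stirred",
                                               "added", "solvent", "water",
                                               "heated", "cooled", "washed",
                                               "reflux", "oil", "solid")) {
  if (n == 0L) {
    return(annotation_spans(integer(0), integer(0), character(0),
                            character(0)))
  }
  surfaces <- vapply(seq_len(n), function(i) {
    paste(sample(vocab, sample(2:5, 1), replace = TRUE), collapse = " ")
  }, character(1))
  starts <- cumsum(c(0L, nchar(surfaces[-n]) + 1L))
  annotation_spans(starts, starts + nchar(surfaces), surfaces,
                   sample(action_types(), n, replace = TRUE))
}

random_instance_pair <- function(max_n = 6L) {
  a <- random_annotation_set(sample(0:max_n, 1))
  # b: a noisy variant of a plus independent spans, keeping document order
  surfaces <- character(0)
  labels <- character(0)
  for (i in seq_len(nrow(a))) {
    r <- runif(1)
    if (r < 0.4) {
      surfaces <- c(surfaces, a$surface[i])
      labels <- c(labels, a$label[i])
    } else if (r < 0.7) {
      toks <- strsplit(a$surface[i], " ")[[1]]
      toks <- c(sample(c("then", "and", "which"), 1), toks)
      surfaces <- c(surfaces, paste(toks, collapse = " "))
      labels <- c(labels, a$label[i])
    } # else dropped
  }
  extra <- sample(0:2, 1)
  if (extra > 0) {
    ex <- random_annotation_set(extra)
    surfaces <- c(surfaces, ex$surface)
    labels <- c(labels, ex$label)
  }
  nb <- length(surfaces)
  b <- if (nb) {
    starts <- cumsum(c(0L, nchar(surfaces[-nb]) + 1L))
    annotation_spans(starts, starts + nchar(surfaces), surfaces, labels)
  } else {
    random_annotation_set(0L)
  }
  list(a = a, b = b)
}
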