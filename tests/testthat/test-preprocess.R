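test_that("normalisation splits fused punctuation but protects decimals and chemical names", {
  expect_equal(normalize_text("(0.63 g,")$text, "( 0.63 g ,")
  expect_equal(normalize_text("1.302 mmol")$text, "1.302 mmol")
  expect_equal(normalize_text("(MgSO4)")$text, "( MgSO4 )")
  # commas/brackets inside chemical-name candidates stay put
  expect_equal(normalize_text("5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine 82:")$text,
               "5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine 82 :")
  expect_equal(normalize_text("N, N-dimethylformamide")$text,
               "N, N-dimethylformamide")
  # dotted abbreviations keep their stop attached
  expect_equal(normalize_text("ca. 100%)")$text, "ca. 100% )")
})

test_that("nonprinting characters are removed and line breaks become spaces", {
  raw <- paste0("Potassium", intToUtf8(1), " carbonate\nwas\tadded",
                intToUtf8(127))
  expect_equal(normalize_text(raw)$text, "Potassium carbonate was added")
  # words separated only by a newline must not fuse
  expect_equal(normalize_text("salt\nwater")$text, "salt water")
  expect_error(normalize_text(intToUtf8(c(1, 2, 31))),
               class = "chemtagr_empty_document")
})

test_that("normalisation is idempotent", {
  cases <- c("Potassium carbonate (0.63 g, 4.56 mmol) and thiophenol",
             "the  title   compound **82** (0.259 g, 1.302 mmol, ca. 100%)",
             "cooled to rt. Deionised water", "a\n\tb  c")
  for (x in cases) {
    once <- normalize_text(x)$text
    expect_equal(normalize_text(once)$text, once)
  }
})

test_that("tokenisation splits on whitespace and keeps chemical words whole", {
  toks <- tokenize(normalize_text("(0.63 g,"))
  expect_equal(toks$surface, c("(", "0.63", "g", ","))
  toks <- tokenize(normalize_text("2-nitrobenzene sulfonamide"))
  expect_equal(toks$surface, c("2-nitrobenzene", "sulfonamide"))
  expect_equal(nrow(tokenize("")), 0L)
})

test_that("token surfaces joined by single spaces reproduce the normalised string", {
  norm <- normalize_text(sample_preparation()$text)
  toks <- tokenize(norm)
  expect_equal(paste(toks$surface, collapse = " "), norm$text)
  expect_false(any(grepl("\\s", toks$surface)))
})

test_that("token offsets project back onto the raw text", {
  raw <- "Potassium carbonate (0.63 g,\n4.56 mmol) was added."
  toks <- tokenize(normalize_text(raw))
  expect_true(all(toks$start < toks$end))
  expect_true(all(diff(toks$start) > 0))
  for (k in seq_len(nrow(toks))) {
    seen <- substr(raw, toks$start[k] + 1L, toks$end[k])
    expect_equal(gsub("\\s", "", seen), gsub("\\s", "", toks$surface[k]))
  }
})

test_that("sentence splitting finds the three sentences of the worked paragraph", {
  sents <- split_sentences(tokenize(normalize_text(sample_preparation()$text)))
  expect_length(sents, 3L)
  last_words <- vapply(sents, function(s) {
    paste(utils::tail(s$surface, 2), collapse = " ")
  }, character(1))
  expect_equal(last_words, c("h .", ") .", "purification ."))
  # every token lands in exactly one sentence
  all_ids <- unlist(lapply(sents, `[[`, "id"))
  expect_equal(all_ids, tokenize(normalize_text(sample_preparation()$text))$id)
})

test_that("sentence boundaries respect abbreviations and missing stops", {
  sents <- split_sentences(tokenize(normalize_text(
    "The reaction was cooled to rt. Deionised water was added.")))
  expect_length(sents, 2L)
  expect_equal(sents[[2]]$surface[1], "Deionised")
  # "ca." keeps its stop: no boundary
  sents <- split_sentences(tokenize(normalize_text(
    "yield was ca. 100% of theory")))
  expect_length(sents, 1L)
  # no terminal stop: still one sentence
  expect_length(split_sentences(tokenize(normalize_text("salt in water"))), 1L)
})
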