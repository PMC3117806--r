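tagged <- function(x) cascade_tag(tokenize(normalize_text(x)))

test_that("the sample sentence parses to the expected phrase skeleton", {
  tree <- parse_sentence(tagged(paste(
    "Potassium carbonate (0.63 g, 4.56 mmol) and thiophenol (0.19 g,",
    "1.69 mmol) were added to the 2-nitrobenzene sulfonamide.")))
  expect_equal(tree$label, "Sentence")
  np <- tree$children[[1]]
  expect_equal(np$label, "NounPhrase")
  labs <- vapply(np$children, `[[`, character(1), "label")
  expect_equal(labs, c("MOLECULE", "CC", "MOLECULE"))
  vp <- tree$children[[2]]
  expect_equal(vp$label, "VerbPhrase")
  vlabs <- vapply(vp$children, `[[`, character(1), "label")
  expect_equal(vlabs, c("VBD", "VB-ADD", "PrepPhrase"))
  pp <- vp$children[[3]]
  expect_equal(pp$children[[1]]$label, "TO")
  expect_length(find_nodes(tree, "MOLECULE"), 3L)
  expect_length(find_nodes(tree, "QUANTITY"), 2L)
})

test_that("minimal and ungrammatical inputs degrade without losing tokens", {
  lone <- parse_sentence(tagged("thiophenol"))
  expect_equal(lone$children[[1]]$label, "NounPhrase")
  expect_equal(lone$children[[1]]$children[[1]]$label, "MOLECULE")
  tg <- tagged("the was to and")
  tree <- parse_sentence(tg)
  labs <- vapply(tree$children, `[[`, character(1), "label")
  expect_true(all(labs == "Unmatched"))
  expect_true(validate_leaf_partition(tree, tg))
  expect_equal(nrow(ast_leaf_tokens(tree)), 4L)
})

test_that("quantity parsing recovers typed amounts", {
  q <- parse_quantity(tagged("( 0.63 g , 4.56 mmol )"))
  expect_equal(q$kind, c("mass", "molar"))
  expect_equal(q$value, c(0.63, 4.56))
  expect_equal(q$unit, c("g", "mmol"))
  q <- parse_quantity(tagged("( 0.259 g , 1.302 mmol , ca. 100% )"))
  expect_equal(q$kind, c("mass", "molar", "percent"))
  expect_equal(q$value, c(0.259, 1.302, 100))
  expect_equal(q$qualifier[3], "ca.")
  # multiplicative volume: one amount with a repeat count
  q <- parse_quantity(tagged("( 5 × 50 cm3 )"))
  expect_equal(nrow(q), 1L)
  expect_equal(q$kind, "volume")
  expect_equal(q$value, 50)
  expect_equal(q$repeats, 5)
  # empty brackets and unit-less numbers
  expect_equal(nrow(parse_quantity(tagged("( )"))), 0L)
  q <- parse_quantity(tagged("( 3 )"))
  expect_equal(q$kind, "unknown")
  expect_error(parse_quantity(tagged("no brackets here")), "bracket")
})

test_that("leaf traversal returns the full in-order token sequence", {
  tg <- tagged("Salt was dissolved in water.")
  tree <- parse_sentence(tg)
  leaves <- ast_leaf_tokens(tree)
  expect_equal(leaves$surface, tg$surface)
  expect_equal(leaves$id, tg$id)
  # a leaf node yields a singleton
  leaf <- tree$children[[1]]$children[[1]]
  while (!is_leaf(leaf)) leaf <- leaf$children[[1]]
  expect_equal(nrow(ast_leaf_tokens(leaf)), 1L)
})

test_that("leaf partition holds across generated sentences", {
  cfg <- generation_config(seed = 101, n_sentences = 100)
  g <- generate_paragraph(cfg)
  sents <- split_sentences(tokenize(normalize_text(g$text)))
  expect_length(sents, 100L)
  for (s in sents) {
    tg <- cascade_tag(s)
    tree <- parse_sentence(tg)
    expect_true(validate_leaf_partition(tree, tg))
  }
})

test_that("parsing is deterministic", {
  tg <- tagged(sample_preparation()$text)
  expect_true(ast_equal(parse_sentence(tg), parse_sentence(tg),
                        offsets = TRUE))
})
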