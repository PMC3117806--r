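sentence_tokens <- function(x) tokenize(normalize_text(x))

test_that("chemical tagger finds lexicon and morphology entities", {
  ents <- tag_chemicals(sentence_tokens("thiophenol was added"))
  expect_equal(ents$surface[1], "thiophenol")
  expect_equal(ents$type[1], "CM")
  # multi-token lexicon entry becomes one entity
  ents <- tag_chemicals(sentence_tokens("Potassium carbonate (0.63 g)"))
  expect_equal(ents$surface[1], "Potassium carbonate")
  expect_length(ents$token_ids[[1]], 2L)
  # plain English verbs are not entities
  expect_equal(nrow(tag_chemicals(sentence_tokens("stirred"))), 0L)
  # morphology: systematic suffixes and formulae
  ents <- tag_chemicals(sentence_tokens("washed with 2-bromotoluene and MgSO4"))
  expect_setequal(ents$surface, c("2-bromotoluene", "MgSO4"))
})

test_that("ne XML ingestion parses the four-attribute dialect", {
  ne <- paste0(
    "<ne id='o1960' surface=' Potassium carbonate ' type='CM' ",
    "confidence='0.9448241038775597 '>Potassium carbonate</ne> ",
    "(0.63 g, 4.56 mmol) and ",
    "<ne id='o1962' surface=' thiophenol ' type='CM' ",
    "confidence='0.9676694757597625'>thiophenol</ne> were added")
  ents <- ingest_ner_xml(ne)
  expect_equal(nrow(ents), 2L)
  expect_equal(ents$confidence[1], 0.9448241038775597)
  expect_equal(ents$surface[2], "thiophenol")
  # confidence optional
  e2 <- ingest_ner_xml("<doc><ne id='x' surface='water' type='CM'>water</ne></doc>")
  expect_true(is.na(e2$confidence))
  # zero ne elements, malformed XML, unalignable surface
  expect_equal(nrow(ingest_ner_xml("<doc>no entities</doc>")), 0L)
  expect_error(ingest_ner_xml("<doc><ne></doc>"))
  toks <- sentence_tokens("nothing matches here")
  expect_warning(out <- ingest_ner_xml(
    "<doc><ne id='x' surface='thiophenol' type='CM'>thiophenol</ne></doc>",
    tokens = toks), "align")
  expect_equal(nrow(out), 0L)
})

test_that("regex tagger covers units, action verbs, states and bold numbers", {
  tg <- tag_regex(sentence_tokens("mmol g added oil mixture solution **82** xyzzy"))
  expect_equal(tg$tag[tg$surface == "mmol"], "NN-MOLAR")
  expect_equal(tg$tag[tg$surface == "g"], "NN-MASS")
  expect_equal(tg$tag[tg$surface == "added"], "VB-ADD")
  expect_equal(tg$tag[tg$surface == "oil"], "NN-STATE")
  expect_equal(tg$tag[tg$surface == "mixture"], "NN-MIXTURE")
  expect_equal(tg$tag[tg$surface == "solution"], "NN-SOLUTION")
  expect_equal(tg$tag[tg$surface == "**82**"], "CD-BOLD")
  expect_true(is.na(tg$tag[tg$surface == "xyzzy"]))
})

test_that("action-verb tags are suppressed in noun positions", {
  tg <- tag_regex(sentence_tokens("The precipitate was recovered"))
  expect_false(identical(tg$tag[2], "VB-PRECIPITATE"))
  tg <- tag_regex(sentence_tokens("the combined organic extracts were dried"))
  expect_true(is.na(tg$tag[tg$surface == "extracts"]))
  expect_equal(tg$tag[tg$surface == "dried"], "VB-DRY")
})

test_that("POS tagger emits Penn tags deterministically", {
  tg <- tag_pos(sentence_tokens("were and to the aqueous phase slowly"))
  expect_equal(tg$tag,
               c("VBD", "CC", "TO", "DT", "JJ", "NN", "RB"))
  expect_identical(tg$tag, tag_pos(sentence_tokens(
    "were and to the aqueous phase slowly"))$tag)
})

test_that("cascade is total, exclusive and idempotent", {
  toks <- sentence_tokens(paste(
    "Potassium carbonate (0.63 g, 4.56 mmol) and thiophenol were added to",
    "the 2-nitrobenzene sulfonamide."))
  tg <- cascade_tag(toks)
  expect_false(any(is.na(tg$tag)))
  expect_true(all(tg$namespace %in% c("CHEM", "REGEX", "POS")))
  chem <- tg$surface[tg$namespace == "CHEM"]
  expect_setequal(chem, c("Potassium", "carbonate", "thiophenol",
                          "2-nitrobenzene", "sulfonamide"))
  expect_equal(tg$tag[tg$surface == "added"], "VB-ADD")
  expect_true(all(c("g", "mmol") %in% tg$surface[tg$namespace == "REGEX"]))
  expect_true(all(c("were", "to", "the", "and") %in%
                    tg$surface[tg$namespace == "POS"]))
  # retagging the same tokens is a fixed point
  tg2 <- cascade_tag(toks)
  expect_identical(tg$tag, tg2$tag)
  # all-chemical sentence has no POS namespace
  tgc <- cascade_tag(sentence_tokens("thiophenol methanol MgSO4"))
  expect_equal(sum(tgc$namespace == "POS"), 0L)
})
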