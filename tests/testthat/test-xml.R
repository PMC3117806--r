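sample_tree <- function() {
  tg <- cascade_tag(tokenize(normalize_text(paste(
    "Potassium carbonate (0.63 g, 4.56 mmol) and thiophenol (0.19 g,",
    "1.69 mmol) were added to the 2-nitrobenzene sulfonamide."))))
  identify_actions(parse_sentence(tg))$tree
}

test_that("serialised XML matches the expected element skeleton", {
  x <- ast_to_xml(sample_tree())
  expect_equal(xml2::xml_name(xml2::xml_root(x)), "Sentence")
  ap <- xml2::xml_find_first(x, "./ActionPhrase")
  expect_equal(xml2::xml_attr(ap, "type"), "Add")
  expect_length(xml2::xml_find_all(x, ".//MOLECULE"), 3L)
  for (leaf in c("VB-ADD", "VBD", "TO", "CC")) {
    expect_length(xml2::xml_find_all(x, paste0(".//", leaf)), 1L)
  }
  expect_equal(
    xml2::xml_text(xml2::xml_find_first(x, ".//VB-ADD")), "added")
  expect_length(
    xml2::xml_find_all(x, "./ActionPhrase/NounPhrase/MOLECULE/OSCAR-CM"), 3L)
  expect_length(
    xml2::xml_find_all(
      x, "./ActionPhrase/VerbPhrase/PrepPhrase/NounPhrase/MOLECULE"), 1L)
})

test_that("XML round trip reproduces the tree", {
  tree <- sample_tree()
  expect_true(ast_equal(tree, xml_to_ast(ast_to_xml(tree))))
  expect_true(ast_equal(tree, xml_to_ast(ast_to_xml(tree, offsets = TRUE)),
                        offsets = TRUE))
  # single-leaf tree and empty Sentence element
  leaf <- phrase_node("NN", token = list(id = 0L, surface = "salt",
                                         start = 0L, end = 4L, tag = "NN",
                                         namespace = "POS"))
  expect_true(ast_equal(leaf, xml_to_ast(ast_to_xml(leaf))))
  empty <- xml_to_ast("<Sentence></Sentence>")
  expect_equal(empty$label, "Sentence")
  expect_length(empty$children, 0L)
})

test_that("round trip holds across generated fixture sentences", {
  g <- generate_paragraph(generation_config(seed = 5, n_sentences = 25))
  doc <- chem_tag(g$text)
  for (tree in doc$sentences) {
    expect_true(ast_equal(tree, xml_to_ast(ast_to_xml(tree, offsets = TRUE)),
                          offsets = TRUE))
  }
})

test_that("invalid trees and unknown elements are refused", {
  tok <- list(id = 0L, surface = "salt", start = 0L, end = 4L, tag = "NN",
              namespace = "POS")
  dup <- phrase_node("Sentence", list(
    phrase_node("NN", token = tok), phrase_node("NN", token = tok)))
  expect_error(ast_to_xml(dup), "partition")
  expect_error(xml_to_ast("<Sentence><weird>x</weird></Sentence>"), "weird")
  expect_error(xml_to_ast("<Sentence><oops><NN>x</NN></oops></Sentence>"),
               "oops")
  expect_error(xml_to_ast("<Sentence><NN>x</NN>"))
})

test_that("whole documents serialise with one Sentence element per sentence", {
  doc <- chem_tag(sample_preparation())
  x <- chem_xml(doc)
  expect_equal(xml2::xml_name(xml2::xml_root(x)), "Document")
  expect_length(xml2::xml_find_all(x, "./Sentence"), 3L)
  expect_length(xml2::xml_find_all(x, ".//ActionPhrase[@type='Yield']"), 1L)
})
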