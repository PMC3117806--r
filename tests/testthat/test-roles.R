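test_that("reference numbers are extracted from titles and molecules", {
  expect_equal(extract_reference_number(
    "5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine 82:"), 82L)
  doc <- chem_tag(sample_preparation())
  mol <- Filter(function(m) grepl("sulfonamide", node_text(m)),
                find_nodes(doc$sentences[[1]], "MOLECULE"))[[1]]
  expect_equal(extract_reference_number(mol), 50L)
  expect_true(is.na(extract_reference_number("plain words only")))
  bare <- chem_tag("thiophenol was added.")
  mols <- find_nodes(bare$sentences[[1]], "MOLECULE")
  expect_true(is.na(extract_reference_number(mols[[1]])))
})

test_that("roles are inferred on the worked paragraph", {
  doc <- chem_tag(sample_preparation())
  roles <- doc$roles
  dmf <- roles[grepl("dimethylformamide", roles$surface), ]
  expect_equal(dmf$role, "solvent")
  sulf <- roles[grepl("sulfonamide", roles$surface), ]
  expect_equal(sulf$role, "reactant")
  expect_equal(sulf$ref, 50L)
  prod <- roles[roles$role == "product", ]
  expect_equal(prod$surface, "5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine")
  expect_equal(prod$ref, 82L)
})

test_that("wash-with phrases mark solvents", {
  doc <- chem_tag("The resin was washed with brine.")
  r <- doc$roles[doc$roles$surface == "brine", ]
  expect_equal(r$role, "solvent")
  expect_match(r$evidence, "Wash")
})

test_that("documents without actions leave molecules unassigned", {
  doc <- chem_tag("The thiophenol solution is shown below.")
  expect_true(all(doc$roles$role == "unassigned"))
})

test_that("the reaction graph links reactant to product with the product state", {
  doc <- chem_tag(sample_preparation())
  rg <- build_reaction_graph(doc)
  expect_setequal(rg$nodes$ref, c(50L, 82L))
  expect_equal(rg$edges$from, 50L)
  expect_equal(rg$edges$to, 82L)
  expect_equal(rg$nodes$state[rg$nodes$ref == 82L], "oil")
  expect_s3_class(rg$graph, "igraph")
  expect_equal(igraph::ecount(rg$graph), 1)
})

test_that("preparations sharing a reactant give that node out-degree two", {
  prep2 <- function(ref_prod) list(
    title = sprintf("2-bromotoluene %d:", ref_prod),
    text = sprintf(paste(
      "Potassium carbonate (0.63 g, 4.56 mmol) was added to the",
      "2-nitrobenzene sulfonamide **50** (0.50 g, 1.302 mmol) in",
      "N, N-dimethylformamide (33 cm3). Chromatography gave the title",
      "compound **%d** (0.1 g, 50%%) as a white solid."), ref_prod))
  docs <- list(chem_tag(prep2(81L)), chem_tag(prep2(82L)))
  rg <- build_reaction_graph(docs)
  expect_setequal(rg$nodes$ref, c(50L, 81L, 82L))
  deg <- igraph::degree(rg$graph, mode = "out")
  expect_equal(unname(deg["50"]), 2)
  expect_equal(rg$nodes$colour[rg$nodes$ref == 81L], "white")
  expect_equal(rg$nodes$state[rg$nodes$ref == 81L], "solid")
})

test_that("an empty document list and missing products are handled", {
  rg <- build_reaction_graph(list())
  expect_equal(nrow(rg$nodes), 0L)
  expect_equal(nrow(rg$edges), 0L)
  doc <- chem_tag(paste(
    "Potassium carbonate **50** (0.63 g) was added to the thiophenol."))
  expect_warning(rg <- build_reaction_graph(doc), "without a product")
  expect_equal(nrow(rg$edges), 0L)
})

test_that("graph export writes node, edge and GraphML files", {
  doc <- chem_tag(sample_preparation())
  rg <- build_reaction_graph(doc)
  dir <- tempfile("graph")
  paths <- write_reaction_graph(rg, dir)
  expect_true(all(file.exists(paths)))
  nodes <- read.delim(paths["nodes"])
  expect_setequal(nodes$ref, c(50L, 82L))
  gml <- readLines(paths["graphml"], warn = FALSE)
  expect_true(any(grepl("graphml", gml)))
})
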