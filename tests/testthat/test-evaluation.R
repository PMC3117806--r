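spans_from <- function(surfaces, labels = rep("Add", length(surfaces))) {
  n <- length(surfaces)
  if (n == 0L) {
    return(annotation_spans(integer(0), integer(0), character(0),
                            character(0)))
  }
  starts <- cumsum(c(0L, nchar(surfaces[-n]) + 1L))
  annotation_spans(starts, starts + nchar(surfaces), surfaces, labels)
}

test_that("Dice coefficient satisfies its axioms and examples", {
  x <- spans_from(c("a b", "c d", "e f"))
  y <- spans_from(c("a b", "c d"))
  expect_equal(dice(x, x, exact_match), 1)
  expect_equal(dice(x, spans_from(c("q r", "s t")), exact_match), 0)
  expect_equal(dice(x, y, exact_match), 0.8) # 2*2/(3+2)
  # symmetry and range on random pairs
  set.seed(42)
  for (k in 1:20) {
    p <- random_instance_pair(5L)
    d1 <- dice(p$a, p$b, filtered_match)
    d2 <- dice(p$b, p$a, filtered_match)
    expect_equal(d1, d2)
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
  # both empty: 1 by convention; empty vs non-empty: 0
  e <- spans_from(character(0))
  expect_equal(dice(e, e), 1)
  expect_equal(dice(e, x), 0)
})

test_that("exact match is strict and filtered match forgives stock words", {
  a <- list(surface = "concentrated at 80°C")
  b <- list(surface = "and concentrated at 80°C")
  c2 <- list(surface = "concentrated at 80°C.")
  expect_true(exact_match(a, a))
  expect_false(exact_match(a, b))
  expect_true(filtered_match(b, c2))
  expect_false(filtered_match(list(surface = "heated under reflux"),
                              list(surface = "cooled to rt")))
  # a span reduced to nothing by filtering never matches a non-empty one
  expect_false(filtered_match(list(surface = "and the a"), a))
  expect_true(exact_match(list(surface = ""), list(surface = "")))
})

test_that("alignment reproduces the printed five-versus-four example", {
  ex <- alignment_example()
  al <- align_annotations(ex$a, ex$b)
  expect_equal(al$index_map_a, c(1L, 2L, 3L, 4L, 5L))
  expect_equal(al$index_map_b, c(1L, 2L, 3L, -1L, 4L))
  expect_equal(aligned_agreement(ex$a, ex$b), 100 * 2 * 4 / 9)
})

test_that("identical sequences align to the identity with no gaps", {
  a <- spans_from(c("salt was dissolved", "heated under reflux",
                    "washed with brine"))
  al <- align_annotations(a, a)
  expect_equal(al$index_map_a, 1:3)
  expect_equal(al$index_map_b, 1:3)
  expect_equal(aligned_agreement(a, a), 100)
  expect_equal(aligned_agreement(a, spans_from(character(0))), 0)
})

test_that("alignment is optimal against brute force and monotone", {
  set.seed(7)
  for (k in 1:40) {
    p <- random_instance_pair(6L)
    al <- align_annotations(p$a, p$b)
    expect_equal(al$score, brute_force_alignment_score(p$a, p$b),
                 tolerance = 1e-9)
    matched <- al$index_map_a > 0L & al$index_map_b > 0L
    expect_true(all(diff(al$index_map_a[matched]) > 0))
    expect_true(all(diff(al$index_map_b[matched]) > 0))
    expect_false(anyDuplicated(al$index_map_a[al$index_map_a > 0]) > 0)
    expect_false(anyDuplicated(al$index_map_b[al$index_map_b > 0]) > 0)
  }
})

test_that("action-name agreement counts label-identical aligned pairs", {
  a <- spans_from(c("salt was dissolved", "heated under reflux",
                    "washed with brine", "dried under vacuum"),
                  c("Dissolve", "Heat", "Wash", "Dry"))
  expect_equal(action_name_agreement(a, a), 100)
  b <- a
  b$label <- c("Dissolve", "Stir", "Wash", "Cool") # half the labels differ
  expect_equal(action_name_agreement(a, b), 100 * 2 * 2 / 8)
  disjoint <- spans_from(c("x y z", "q r s"), c("Add", "Stir"))
  expect_equal(action_name_agreement(a, disjoint), 0)
})

test_that("agreement matrices are symmetric with correct means", {
  a <- spans_from(c("salt was dissolved", "heated under reflux"),
                  c("Dissolve", "Heat"))
  rep4 <- list(a, a, a, a)
  rpt <- agreement_matrix(rep4, machine = a, metric = "aligned")
  off <- rpt$matrix[upper.tri(rpt$matrix)]
  expect_true(all(off == 100))
  expect_equal(rpt$machine_annotator_mean, 100)
  expect_equal(rpt$inter_annotator_mean, 100)
  expect_true(isSymmetric(unname(rpt$matrix)))
  expect_error(agreement_matrix(list(a)), "two")
})

test_that("metric ordering aligned >= filtered >= exact holds on simulated annotators", {
  cfg <- generation_config(seed = 19, n_sentences = 60,
                           boundary_jitter_tokens = 2,
                           label_confusion_prob = 0.1, drop_prob = 0.05)
  g <- generate_paragraph(cfg)
  pert <- perturb_annotations(g$gold, cfg)
  ex <- exact_agreement(g$gold, pert)
  fi <- filtered_agreement(g$gold, pert)
  al <- aligned_agreement(g$gold, pert)
  expect_gte(al, fi)
  expect_gte(fi, ex)
  expect_gt(al, ex) # jitter guarantees a strict gap
})

test_that("annotation files round trip through TSV", {
  a <- spans_from(c("salt was dissolved", "heated under reflux"),
                  c("Dissolve", "Heat"))
  path <- tempfile(fileext = ".tsv")
  write_annotations(a, path, doc_id = "p1")
  back <- read_annotations(path)
  expect_equal(back$surface, a$surface)
  expect_equal(back$label, a$label)
  expect_equal(back$start, a$start)
})
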