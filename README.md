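# chemtagr

Phrase-based semantic parsing of chemical synthesis text, in R.

Experimental sections of organic-chemistry papers and patents are written
in a formulaic register — "Potassium carbonate (0.63 g, 4.56 mmol) and
thiophenol (0.19 g, 1.69 mmol) were added to the 2-nitrobenzene
sulfonamide **50** ..." — that a rule-based pipeline can parse into
structured data. chemtagr is aimed at text-mining and cheminformatics work
that needs reactions, quantities and compound roles extracted from such
prose, and at annotation studies that need to measure agreement between
annotators (human or machine) over phrase spans.

The pipeline:

1. **Normalise + tokenise** — nonprinting characters removed, fused
   punctuation split (`"(0.63 g,"` → `( 0.63 g ,`) while decimal points and
   chemical-name-internal commas/brackets/hyphens are protected; all spans
   are offsets into the original text.
2. **Tag** — a three-step cascade: chemical named-entity recognition
   (lexicon + systematic-suffix morphology, or ingestion of pre-computed
   `ne`-dialect XML), a domain regex tagger (units, physical states, bold
   compound numbers, action verbs), then a Penn part-of-speech tagger.
   Every token gets exactly one tag.
3. **Parse** — a deterministic recursive-descent grammar chunks each
   sentence into noun/verb/prepositional phrases with MOLECULE and
   QUANTITY subunits; unparseable stretches degrade to `Unmatched` nodes,
   and the tree's leaves always partition the sentence's tokens.
4. **Label + infer** — clause segments are wrapped as ActionPhrases over a
   closed registry of 21 types (Add, Stir, Heat, Yield, ...); compound
   roles follow from context (solvents after in/with inside
   dissolve/wash/extract-type phrases, reactants from leading reference
   numbers, the product from the title line); reaction graphs link
   reference numbers across preparations.
5. **Evaluate** — Dice-coefficient agreement
   (s = 2|X∩Y| / (|X|+|Y|)) between span-annotation sets under exact,
   filtered (stock words removed) and Needleman–Wunsch-aligned matching,
   plus Action-label agreement and pairwise agreement matrices.

A seeded generator of synthetic preparation paragraphs with gold trees and
annotations (`generate_paragraph`, `perturb_annotations`) makes every stage
testable offline.

## Worked example

```r
library(chemtagr)
doc <- chem_tag(sample_preparation())
doc
#> <chem_document>
#>   title:    5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine 82:
#>   tokens:   112 in 3 sentence(s)
#>   actions:  Add, Dissolve, Stir, Add, Extract, Dry, Concentrate, Yield
#>   roles:    5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine=product;
#>             2-nitrobenzene sulfonamide=reactant;
#>             N, N-dimethylformamide=solvent; ethyl acetate=solvent
```

Eight Action phrases are found (the Dissolve and Yield phrases nested
inside the Add and Concentrate phrases respectively), and the quantity
parser types every bracketed amount:

```r
doc_quantities(doc)[c(1, 2, 13), ]
#>               compound    kind value unit qualifier repeats sentence
#> 1  Potassium carbonate    mass  0.63    g      <NA>       1        1
#> 2  Potassium carbonate   molar  4.56 mmol      <NA>       1        1
#> 13      title compound percent 100.0    %       ca.       1        3
```

`0.63 g` / `4.56 mmol` are the mass and amount of substance of the first
reagent; the `ca. 100%` percent entry is the isolated yield of the title
compound. The reaction graph links reactant 50 to product 82, whose
aggregation state is read off the Yield phrase:

```r
rg <- build_reaction_graph(doc)
rg$edges            # from 50 to 82
rg$nodes            # node 82: role product, state "oil"
write_reaction_graph(rg, "graph_out")   # nodes.tsv, edges.tsv, graph.graphml
```

Phrase trees serialise to XML in the hyphenated leaf-tag dialect
(`OSCAR-CM`, `VB-ADD`, ...), with `xml_to_ast()` as the inverse:

```r
cat(as.character(ast_to_xml(doc$sentences[[1]])))
```

For agreement studies, annotation sets are data frames of spans
(`start`, `end`, `surface`, `label`); `align_annotations()` aligns two
sequences globally (gaps report −1) and `agreement_matrix()` builds the
pairwise matrices:

```r
ex <- alignment_example()
align_annotations(ex$a, ex$b)
#> <chem_alignment> score: 2.923077
#>  a: 1, 2, 3, 4, 5
#>  b: 1, 2, 3, -1, 4
aligned_agreement(ex$a, ex$b)   # 88.9
```

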