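---
title: "Parsing chemical synthesis prose with chemtagr"
author: "chemtagr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing chemical synthesis prose with chemtagr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtagr)
```

## The problem

Experimental sections of organic-chemistry papers, theses and patents are
written in a highly formulaic register: a title line names the product and
its bold reference number, and a short paragraph narrates the procedure as a
sequence of steps ("X (0.63 g, 4.56 mmol) was added to ...", "the mixture
was stirred for 16 h", "... to give the title compound **82** (0.259 g,
1.302 mmol, ca. 100%) as an oil"). Because the register is so constrained,
a rule-based pipeline — tokeniser, cascading taggers, a small formal grammar
and a handful of post-processing rules — recovers most of the procedural
semantics without any statistical model. chemtagr implements that pipeline
together with the evaluation machinery needed to measure how well machine
annotations agree with human ones.

## Pipeline and assumptions

The pipeline has five stages, each exposed as an ordinary function so any
stage can be replaced or inspected.

**Normalisation** (`normalize_text`) removes nonprinting code points (0–31,
127, 129, 141, 143, 144, 157; tab/newline/CR and the non-breaking space
become ordinary spaces first, so words separated only by a line break do not
fuse), collapses whitespace, and inserts spaces between alphanumeric and
non-alphanumeric characters so that fused strings such as `"(0.63 g,"`
break into their parts. Two protections apply: decimal points flanked by
digits, and commas/brackets/hyphens inside *chemical-name candidates*. A
candidate is recognised by locant/affix morphology — digits joined to
hyphens (`2-nitrobenzene`), bracketed locants (`[1H]`), leading element
locants (`N,N-`). This morphological test is a design choice: nothing short
of a full name parser can decide the question exactly, and the test errs
towards keeping tokens whole, which the downstream grammar tolerates well.
An offset map projects every normalised character back to the raw text, so
all downstream spans are 0-based half-open offsets into the *original*
document.

**Tokenisation** (`tokenize`) is whitespace splitting of the normalised
string; by construction, rejoining token surfaces with single spaces
reproduces it. **Sentence splitting** (`split_sentences`) places boundaries
after stop tokens followed by an uppercase letter, digit or opening
bracket. Dotted abbreviations ("ca.", "e.g.", "i.e.", "etc.") keep their
stop attached and so never open a boundary; bare unit symbols deliberately
do not block boundaries — "...stirred for 16 h." ends its sentence.

**Tagging** (`cascade_tag`) is a three-step cascade in which each token
receives exactly one tag and a token tagged at one stage is invisible to
later stages:

1. *Chemical NER* (`tag_chemicals`): longest-match lookup in an editable
   lexicon of reagents, solvents, elements and acronyms, plus
   systematic-suffix morphology (-ol, -ene, -amide, -ate, ...) and
   molecular-formula patterns (MgSO4, EtOAc). Pre-computed entities in the
   four-attribute `ne` XML dialect (id, surface, type, confidence) can be
   ingested instead (`ingest_ner_xml`); member tokens are tagged
   `OSCAR-<type>`. Bundled deterministic hits report confidence 1 —
   confidence is metadata only and is never used downstream.
2. *Domain regex* (`tag_regex`): an ordered rules file covering units
   (NN-MASS, NN-MOLAR, NN-VOL, ...), physical states, mixture/solution
   nouns, bold compound numbers and action verbs (VB-ADD, VB-STIR, ...).
   Action-verb rules are suppressed directly after a determiner or
   attributive adjective so that noun readings ("the precipitate", "the
   combined organic extracts") survive.
3. *English POS* (`tag_pos`): a bundled deterministic Penn-tag tagger
   (closed-class lexicon plus suffix rules, noun default). The backend
   contract is just "emit Penn tags", so a statistical tagger can be
   plugged in; the bundled one keeps every test assertion stable offline.

Bold reference numbers need a dialect decision because plain text has no
typography: `default_tag_rules(bold_dialect =)` accepts `**82**`
(markdown, the default), `<b>82</b>` (HTML), or bare integers in reference
positions (immediately before a bracketed quantity, colon or stop), which
the parser resolves positionally in every dialect.

**Phrase parsing** (`parse_sentence`) is a deterministic recursive-descent
chunker with ordered choice and backtracking (the procedural fragment is
near-unambiguous, so one parse suffices). The core productions are: a noun
phrase is an optional determiner, adjectives, then one or more items; items
include molecules (one or more chemically tagged tokens, an optional
reference number, an optional quantity group) and bracketed quantity
groups; a verb phrase is adverbs, a verb group with at least one
non-auxiliary verb, then complements (prepositional phrases over an
extended preposition inventory — to, in, with, by, under, at, between,
through, for, as, without, ... — infinitives, noun phrases, bare amounts).
Quantities are comma-separated number–unit pairs in brackets, extended
beyond mass/molar to volume, percent, temperature, time and equivalents,
with `ca.`-style qualifiers and multiplicative volumes ("5 × 50 cm3" is one
volume with a repeat count of 5). Conjunction attachment is the one
genuinely ambiguous point: a conjunct joins the current noun phrase unless
a finite verb has already been seen in the sentence and the conjunct opens
a new finite clause, which separates "potassium carbonate ... and
thiophenol ... were added" (one subject) from "... at room temperature and
the mixture was stirred" (two clauses). Anything that fits no rule is
wrapped in an `Unmatched` node and parsing resynchronises at the next
parsable position — the parse never throws, and every tree satisfies the
*leaf-partition invariant*: its leaves are exactly the sentence's tokens,
in order, each once. Numbers are decimal-point only; comma decimals and
scientific notation are out of scope.

**Action identification** (`identify_actions`) wraps clause segments whose
verb group carries an action tag into `ActionPhrase` nodes carrying one of
a closed registry of 21 types (Add, ApparatusAction, Concentrate, Cool,
Degass, Dissolve, Dry, Extract, Filter, Heat, Partition, Precipitate,
Purify, Quench, Recover, Remove, Stir, Synthesize, Wait, Wash, Yield). The
trigger table ships as an editable data file with several stemmed forms per
family; only the main verb group triggers, so "concentrated ... without
heating" is Concentrate, not Heat. Verbless headings trigger through
nominalisations ("Synthesis of ..."). Nesting arises two ways: triggered
infinitives ("... to give the title compound ..." becomes a Yield phrase
inside the Concentrate phrase), and implicit solutions inside Add phrases
("X (0.50 g) in DMF (33 cm3)" becomes a nested Dissolve phrase). Nested
spans are strictly contained in their parents and siblings never partially
overlap.

**Role inference** (`assign_roles`) uses three ordered rules, precedence
R3 > R1 > R2 on conflicts: solvents are molecules inside in/with
prepositional phrases within Dissolve, Wash, Extract, Quench or Partition
phrases (the action set is a parameter — whether extract/quench/partition
contexts mark solvents is a judgement call, enabled by default because
work-up solvents dominate those phrases); reactants are molecules in the
first two sentences carrying a reference number ("near the document start"
needed a concrete value; two sentences covers single-sentence and
two-sentence openings); the product is the title-line compound,
corroborated when a Yield phrase mentions "the title compound" with the
same number. `build_reaction_graph` then links reactant numbers to product
numbers across preparations, attaching the product's aggregation state
(unknown, solid, oil, gum, foam, crystals) and a colour adjective when one
precedes the state word.

**XML** (`ast_to_xml` / `xml_to_ast`) serialises trees with element names
equal to node labels, the ActionPhrase type as an attribute and token
surfaces as leaf text, in the hyphenated dialect (OSCAR-CM, VB-ADD).
Quantity groups serialise as their member leaf tokens — the reference
document format elides quantity internals, so this is the package's own
resolution. The printed dialect cannot carry character offsets, so the
round trip is exact up to offsets by default and fully exact with
`offsets = TRUE`, which adds id/start/end leaf attributes.

## Agreement evaluation

Two annotators rarely mark identical phrase extents, so the package
implements three increasingly tolerant agreement metrics, all built on the
Dice coefficient $s = 2|X \cap Y| / (|X| + |Y|)$ (two empty sets score 1 by
convention, empty versus non-empty 0):

* **exact** — surfaces must be string-identical;
* **filtered** — token sequences must be identical after removing stock
  tokens (".", ",", ";", "and", "to", "the", "a") and leading
  adverbs/prepositions;
* **aligned** — the two annotation sequences are globally aligned with
  Needleman–Wunsch dynamic programming, scoring aligned pairs by their
  token-overlap Dice similarity with gaps penalised at −1; aligned pairs
  with similarity ≥ 0.5 count as matches. The pair score, threshold and gap
  penalty are parameters; the defaults make a gap costlier than any
  mismatched pairing while never beating a genuine boundary-variant match.

By construction exact ⊆ filtered ⊆ aligned matching, so the three
agreements are ordered — the property suite verifies this on simulated
annotators. `action_name_agreement` pairs spans by alignment and then
string-matches the Action labels (alignment-based pairing is the natural
reading once extents are acknowledged to vary; exact-span pairing would
conflate extent and label disagreement). `agreement_matrix` assembles
pairwise percentage matrices over any number of annotators plus the
machine, summarised as the mean of the machine-versus-annotator cells and
the mean of the annotator-pair cells.

```{r}
ex <- alignment_example()
align_annotations(ex$a, ex$b)
aligned_agreement(ex$a, ex$b)
```

## The synthetic-data generator

`generate_paragraph` instantiates one grammar-conformant template per
sampled Action type (templates are a data file, one per type, patterned on
the canonical example sentence for that type) with chemicals drawn from the
bundled lexicon, masses of 0.05–5 g, amounts of 0.1–20 mmol, volumes of
5–500 ml, times of 1–48 h and yields of 10–99% — ranges a bench chemist
would call unremarkable. Every sentence yields a gold annotation span and a
gold derivation (the sentence's tokens under one typed ActionPhrase), and a
single seed drives all sampling, so outputs are bit-reproducible.
`perturb_annotations` emulates annotator disagreement by independently
jittering span boundaries by up to a token count, swapping labels, and
dropping spans at configured rates — the boundary ambiguity it models is
exactly the leading-"To a" type of disagreement the aligned metric exists
to absorb.

What the generator deliberately does not emulate: anaphora chains,
cross-paragraph references, free narrative interleaved with procedure, OCR
noise, and typographic structure. Tests that pass on generated paragraphs
therefore demonstrate grammar coverage and invariant preservation on
in-register prose, not robustness to the full messiness of published text.

## Numerical and testing choices

All randomised tests fix seeds. The Needleman–Wunsch implementation is
checked against an exhaustive enumeration of all monotone alignments on 200
random instances with up to six spans per side; the leaf-partition
invariant is checked on 500 generated sentences; XML round-trips are
checked structurally (and exactly, with offsets). Alignment traceback
breaks ties deterministically (diagonal, then a-side gap), so index maps
are reproducible. Degenerate inputs are defined, not exceptional: empty
documents raise a typed condition at normalisation, empty token lists
tokenise to empty tables, empty bracket pairs are empty quantity lists, and
ungrammatical sentences parse to Unmatched wrappers that still partition
the tokens.

## Known limitations

The chemical tagger is a lexicon-plus-morphology emulation, not a trained
recogniser: rare trivial names absent from the lexicon and suffix table are
missed, and suffix morphology occasionally fires on lookalike English words
(a small exclusion list covers the common ones). The grammar covers the
procedural fragment; discursive sentences degrade to Unmatched regions by
design. Role inference is deliberately conservative — reagents without
reference numbers stay unassigned rather than being guessed as reactants.
The trigger lexicon carries a handful of stems per Action family and is
meant to be extended through its data file as new corpora demand.
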