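# varminer

Rule-based extraction, normalization, post-processing, ensembling and
evaluation of genetic variant mentions in biomedical text.

## The problem

Published articles describe the same point mutation in many surface forms:
compact wNm notation (`T790M`), three-letter notation (`Thr790Met`), natural
language ("threonine 790 substituted with methionine"), nucleotide changes
("G>A polymorphism at nucleotide 5557"), codon changes ("A to G transition at
codon 557 (AAG>GAG)"), or dbSNP identifiers (`rs121434569`). Text-mining
pipelines that harvest variants for curation databases must recognize all of
these, normalize them to one canonical *wild-type residue + position + mutant
residue* record, and then clean up the systematic false positives that plague
Alphabet–Number–Alphabet matching: cell-line names (`T47D`), microarray
platforms (`U133A`), supplementary-figure labels (`S13A`), silent
substitutions (`L367L`), and descriptions too vague to normalize ("valine 600
is mutated"). varminer is a tidyverse-native toolkit for that whole workflow,
aimed at biomedical text-mining practitioners who need a transparent,
rule-level-auditable baseline extractor and a common scoring harness for
comparing extractors.

## What it implements

* **Normalization.** Every mention is reduced to a canonical key
  `level|kind|wild|position|mutant` (e.g. `p|SUB|T|790|M`,
  `c|SUB|G|5557|A`), with residue names resolved through a three-layer
  table (full name / three-letter / one-letter) and codons translated with
  the standard genetic code.
* **A seven-rule post-processing module.** Corrections first, filters second:
  (5) imbalanced forms are re-anchored to the explicit change
  ("V 1691G" inside "factor V 1691G > A" becomes `c|SUB|G|1691|A`);
  (6) hyphen/minus/plus/asterisk between residue tokens are disambiguated
  (`Arg-23-Thr` is R23T, `Arg-23Thr` places the residue at location −23);
  (7) in "substitution of X for Y" the residue after *for* is the wild type.
  Then (1) lexicon/decoy filtering, (2) non-informative removal,
  (3) substitution-matrix plausibility filtering (PAM-family log-odds,
  default PAM120 with cutoff −4), (4) synonymous-substitution removal.
  Every decision is logged per mention.
* **Ensembles.** Simple merging (union) and majority voting (quorum over
  inputs) over answer sets from any number of extractors.
* **Evaluation.** Micro-averaged precision / recall / F1, with
  P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), under three modes:
  *Extracted Mentions* (every occurrence counts), *Normalized Mutations*
  (one entity per document), *Document Retrieval* (binary per document).
* **A unified answer-set format.** Deterministic TSV exchanged between
  extractors, ensembles and the scorer.
* **A seeded synthetic-corpus generator** that embeds catalogued variant
  forms among decoys and returns the exact gold annotations, so the whole
  pipeline is testable end to end without any downloads.

## Worked example

```r
library(varminer)

text <- paste("Fifteen patients were heterozygous for the G–≥A polymorphism at",
              "nucleotide 5557, which causes substitution of asparagine for",
              "aspartic acid at position 1853 of the ATM protein. Controls were",
              "T47D cells profiled on the U133A platform; the silent L367L",
              "change (Supplementary Figure S13A) was ignored.")
ans <- extract_variants(c(PMID17517479 = text))
ans[, c("doc_id", "key", "multiplicity")]
#> 1 PMID17517479 c|SUB|G|5557|A            1
#> 2 PMID17517479 p|SUB|D|1853|N            1
```

Both true variants survive — the DNA-level substitution at nucleotide 5557
and the protein-level D1853N, with the "for"-preposition correctly making
aspartic acid the wild type. The decoys do not: the attached log shows
`T47D`, `U133A` and `S13A` removed by the lexicon/decoy rule and `L367L` by
the synonymous rule.

Scoring against a known gold standard:

```r
corpus <- generate_corpus(corpus_spec(seed = 42, n_docs = 50))
pred   <- extract_variants(corpus$documents)
score_answerset(pred, corpus$gold, "normalized_mutations")
#> <variant_eval> metric: normalized_mutations (50 docs)
#>   TP 88  FP 0  FN 0
#>   precision 1.000  recall 1.000  F1 1.000
```

On synthetic corpora whose decoys come from the bundled lexicons and whose
variants come from the supported form catalogue, the pipeline is exact;
`tidy()`, `glance()` and `autoplot()` expose results for further analysis.

A thin command-line front end with `extract`, `postprocess`, `merge`,
`vote`, `evaluate` and `simulate` subcommands lives at
`inst/cli/varminer.R`.

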