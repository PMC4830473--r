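Package: varminer
Title: Rule-Based Extraction, Normalization and Evaluation of Genetic
    Variant Mentions in Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mentions of genetic variants (point substitutions in
    wNm form such as T790M or Thr790Met, natural-language descriptions,
    nucleotide and codon changes, dbSNP identifiers, and simple
    deletion/insertion/frameshift forms) in biomedical text, normalizes
    them to a canonical wild-type/position/mutant representation, and
    cleans the results with a seven-rule post-processing module (lexicon
    and decoy filtering, non-informative and synonymous mention removal,
    substitution-matrix plausibility filtering, imbalanced-form,
    special-symbol and 'for'-preposition corrections). Includes
    simple-merging and majority-voting ensembles over answer sets from
    multiple extractors, micro-averaged precision/recall/F1 scoring under
    mention-level, normalized-mutation and document-retrieval metrics, a
    unified tab-separated answer-set format, and a seeded synthetic-corpus
    generator with known gold annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
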