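---
title: "Mining variant mentions: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining variant mentions: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varminer)
```

## The extraction model

varminer is a deliberately rule-based extractor. The unit of analysis is a
*mention*: a substring of a document matched by one of the patterns in
`pattern_catalogue()`, annotated with a form category and, where possible, a
normalized variant record — level (protein / coding DNA / RNA), kind
(substitution, deletion, insertion, duplication, indel, frameshift, SNP),
wild-type symbol, integer position, mutant symbol, and dbSNP identifier.
The canonical serialization `level|kind|wild|position|mutant` (with the rs
identifier appended for SNPs) is the identity used everywhere downstream:
post-processing, ensembling and scoring all operate on these keys, and keys
are level-aware on purpose — a protein-level and a DNA-level description of
the same biological event are different factual claims and are never merged.

Matching is longest-match-wins on overlap, with catalogue order breaking
length ties, and the returned mentions are non-overlapping and sorted. The
longest-match rule is what lets a composite phrase like

> "A to G transition at codon 557 (AAG–≥GAG)"

be consumed as one codon-change mention — translated to `p|SUB|K|557|E` via
the standard genetic code — rather than as an inner base change that would
wrongly read 557 as a nucleotide position. The same machinery deliberately
*under*-commits when information is missing: a base change at a codon
position without the codon pair, a positionless "replacement of lysine by
glutamic acid", or "valine 600 is mutated" all parse to a non-informative
marker instead of a guessed record. Non-informative mentions are kept in
the extraction output (with `informative = FALSE`) so the filtering stage
can remove and log them; nothing is silently discarded.

One matching choice is wider than the normalization alphabet: the compact
one-letter pattern accepts any `Letter-Digits-Letter` token, not only the
twenty residue letters. This mirrors how real extractors behave (and why
they over-extract): strings like `U133A` are matched, fail normalization or
hit the lexicon, and are then removed *visibly*, with a logged outcome,
rather than never being seen.

## The seven post-processing rules

The rules come in two families. Corrections (rules 5–7) modify mentions in
place and never change the mention count; filters (rules 1–4) remove
mentions and never modify them. varminer applies corrections before
filters, so the filters judge corrected forms, not raw ones: a mention
whose orientation or anchoring is fixable should be rescued before any
removal decision. The rule order within each family follows the order the
rules are most informative in: lexicon decoys are removed before
informativeness is judged, and plausibility before synonymy.

1. **Lexicon/decoy filter.** Surfaces matching cell-line names, gene
   symbols, platform names (case-insensitive after whitespace removal) or
   decoy patterns are removed. The bundled lists are deliberately small
   seeds containing the classic mutation-like offenders (`T47D`, `U133A`);
   production users should plug in full lists (e.g. HUGO) via
   `read_lexicon()` — a complete gene catalogue is a moving target and not
   something a package should freeze. Supplementary-figure labels are a
   *productive* pattern, not an enumerable list, so they are handled as a
   decoy pattern: `S13A` is only a decoy when the preceding context is a
   figure reference, which is why mentions carry a short `context_before`
   window.
2. **Non-informative filter.** Mentions that cannot be converted to wNm
   form are removed. This is an annotation-policy decision as much as a
   filtering one: a variant you cannot normalize is a variant you cannot
   deduplicate, vote on, or score.
3. **Substitution-matrix filter.** Protein substitutions scoring strictly
   below a threshold in a PAM-family log-odds matrix are considered
   unlikely to be real variant reports. The default matrix is PAM120 from
   Biostrings — the canonical point-accepted-mutation family member
   available offline — restricted to the twenty standard residues
   (selenocysteine and pyrrolysine are excluded; PAM matrices do not score
   them). The default cutoff is −4, chosen so that ordinary conservative
   and moderately radical exchanges (P/A = 1, D/N = 2, K/E, M/R, T/M = −1)
   pass comfortably while only strongly disfavoured exchanges such as W/G
   (−8) are removed; about a fifth of all ordered pairs fall below it. Both
   the matrix (any NCBI-style square table via
   `read_substitution_matrix()`) and the threshold are pluggable, and the
   filter applies to protein-level substitutions only — a DNA-level base
   change carries no residue-exchange plausibility.
4. **Synonymous filter.** Substitutions with wild type equal to mutant
   (`L367L`) are removed at every level.
5. **Imbalanced-form correction.** When a candidate's surface looks like a
   stray wild-type token glued to a number–base fragment (`V 1691G`) and
   the document contains an explicit change with the same position
   (`1691G > A`), the mention is re-anchored to the explicit change and
   re-normalized as a DNA substitution. The factor-V fragment is the
   canonical case: the "V" is the protein's name, not a wild-type valine.
6. **Special-symbol disambiguation.** `X-N-Y` treats hyphens as
   separators (position +N); `X-NY` treats the minus as part of the
   location. The default reads that location as upstream, i.e. negative
   (`Arg-23Thr` → R at −23), because a minus that "denotes location" most
   naturally denotes a signed one; the alternative plain-position reading
   is one switch away (`pp_config(minus_denotes_location = FALSE)`), since
   real-world usage is genuinely ambiguous. A plus in the same slot yields
   a plain positive position; an asterisk is treated as a separator.
7. **"for"-preposition inversion.** In "substitution of X for Y", Y is the
   wild type and X the mutant — the phrase means X replaces Y. Extractors
   that bind tokens left to right get this backwards; the rule detects the
   phrase in the stored surface and swaps the fields when they are in the
   naive orientation (or fills them when absent). Note the correction can
   only fire when the original surface string is available; an answer set
   that stores only normalized fields carries no trace of the phrasing.

Every rule emits exactly one outcome record per mention per stage
(`kept`, `modified` or `removed`, with the rule responsible), so
`|input| = |survivors| + |removed|` holds by construction and pipelines are
auditable after the fact. The whole module is idempotent: corrected forms
re-derive to themselves, and filters pass survivors unchanged.

`postprocess_answerset()` applies the same rules to answer sets from
*other* tools. Rows without stored surfaces are judged on a surface
reconstructed from their normalized fields (`T47D` for a claimed
T-47-D substitution), which is exactly what lets the lexicon catch
cell-line names that arrived as "variants".

## Ensembles and scoring

`simple_merge()` is the per-document union of canonical keys;
`majority_vote()` keeps keys present in at least `quorum` inputs, counting
presence once per input regardless of mention multiplicity. The classic
two-of-three vote is `quorum = 2` over three inputs; the quorum is
parameterized because nothing in the definition is specific to three
extractors. Documents absent from an input count as empty for that input.
Merged rows take the maximum multiplicity claimed by any input (a union
semantics for mention counts) and record contributing inputs in `source`.
By construction `majority_vote(x, q) ⊆ simple_merge(x)` for every `q`, the
vote is antitone in the quorum, and `quorum = 1` coincides with merging —
all properties the test suite checks against a brute-force
membership-counting oracle on randomized instances.

`score_answerset()` pools TP/FP/FN over documents before computing the
ratios (micro-averaging), matching the convention of reporting one
precision/recall/F1 triple per corpus. Mention-level scoring matches by
(key, multiplicity) per document and ignores character offsets: answer
sets exchanged between tools do not carry reliable offsets, and the
multiset semantics ("extract T790M twice when it appears twice") is the
meaningful part. When denominators vanish, precision (resp. recall) is 1
when both sides are empty and 0 otherwise, keeping a perfect-empty corpus
at 1.0 rather than undefined; F1 is 0 when P + R = 0.

## The synthetic generator

`generate_corpus()` exists so that every stage — patterns, parsing,
corrections, filters, ensembles, scoring, I/O — can be exercised with a
known gold standard and no network. It emulates the *surface* phenomena
the extractor must survive: variant realizations drawn from the form
catalogue with glyph noise (en-dash arrows, `–≥`) in the arrow slot,
mutation-like decoys drawn from the bundled lexicons (cell lines,
platforms), productive figure-label decoys, chemical formulae, duplicate
mentions, and optional injections of synonymous and matrix-implausible
substitutions that appear in the text but not in the gold. Positions are
uniform on 1–2000, substitution pairs are constrained to matrix-plausible
ones so that the gold survives the default filters, and generated compact
surfaces are resampled if they collide with a lexicon entry. Generation is
a pure function of the seed.

What it does **not** emulate is discourse: full-text article length,
section structure, tables, novel phrasings outside the catalogue, typos,
or decoys outside the bundled lists. A perfect score on synthetic corpora
therefore demonstrates internal consistency of the pipeline over the
supported catalogue — not performance on arbitrary literature, where
recall is bounded by catalogue coverage and precision by lexicon coverage.

Default generator conditions: 1–3 variants per document, a
substitution-heavy form mix (compact and three-letter wNm 45%, natural
language 20%, nucleotide changes 15%, codon changes 10%, dbSNP 5%,
deletions and frameshifts 5%) reflecting the observed dominance of point
substitutions in variant-centric corpora, one decoy per document in
expectation, and a 15% duplicate-mention rate. The test suite runs the
end-to-end check at 100 documents and the randomized ensemble/scoring
oracles at up to 5 sets × 10 keys × 1000 trials and 200 corpora — sizes
chosen to exercise the combinatorics thoroughly while keeping the suite
fast.

A second, fixed corpus (`fixture_corpus()`) carries seven hand-checked
sentences and fragments — the classic stress cases discussed above — whose
gold answers anchor the acceptance script. One of them, the positionless
"substitution of arginine for methionine", deliberately has *empty* gold:
its orientation is tested on the correction output directly, because a
positionless substitution is, by policy, not an annotatable variant.

## Numerical and convention choices

* Character offsets are 0-based, half-open (`surface == substr(text,
  start+1, end)`), stated explicitly to avoid off-by-one ambiguity.
* U is folded to T at nucleic levels during normalization; the alphabet
  still accepts U so RNA-level records can be represented.
* Stop codons translate to `"*"`; a codon change whose endpoint is a stop
  is non-informative rather than a substitution record with an out-of-
  alphabet symbol.
* Duplicate (document, key) rows on answer-set read are merged with summed
  multiplicities and a warning — they are almost always the same variant
  reported twice by a tool — while structurally malformed rows are errors
  naming the row and field.
* Written answer sets sort documents by id and variants by key, making
  output byte-deterministic.

## Known limitations

The extractor is rule-based by design: no statistical sequence labelling,
no gene/disease/drug entity recognition, no genome-coordinate liftover,
and no validation of positions against reference sequences (which would
require online sequence databases). dbSNP identifiers are kept as opaque
keys rather than expanded to wNm records, since expansion needs a local
dbSNP snapshot. Whether the majority vote should generalize weights or
confidences is out of scope; the quorum is the only dial. The bundled
lexicons are seeds, not catalogues, and the natural-language grammar
covers the documented constructions — extending either is a data change
(`pattern_catalogue()` rows, lexicon files), not a code change.
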