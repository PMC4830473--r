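test_that("catalogued surface forms are detected and normalized", {
  m <- extract_mentions("Resistance involves the T790M mutation in EGFR.")
  expect_equal(nrow(m), 1L)
  expect_equal(m$form, "wnm_short")
  expect_equal(m$key, "p|SUB|T|790|M")

  m <- extract_mentions("here threonine 790 substituted with methionine occurs")
  expect_equal(m$form, "natural_language")
  expect_equal(m$key, "p|SUB|T|790|M")

  m <- extract_mentions("genotype rs121434569 was present")
  expect_equal(m$form, "dbsnp_id")
  expect_equal(m$kind, "SNP")
  expect_equal(m$rs_id, "rs121434569")

  expect_equal(nrow(extract_mentions("")), 0L)
  expect_equal(nrow(extract_mentions("no variants here at all")), 0L)
})

test_that("mention offsets are 0-based half-open and non-overlapping", {
  fx <- fixture_corpus()
  m <- extract_mentions(fx$documents)
  txt <- setNames(fx$documents$text, fx$documents$doc_id)
  for (i in seq_len(nrow(m))) {
    t <- txt[[m$doc_id[[i]]]]
    expect_identical(substr(t, m$start[[i]] + 1L, m$end[[i]]), m$surface[[i]])
    expect_true(m$start[[i]] >= 0 && m$start[[i]] < m$end[[i]] &&
                  m$end[[i]] <= nchar(t))
  }
  # no overlaps within any document
  by_doc <- split(m, m$doc_id)
  for (d in by_doc) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("equivalent surface forms co-normalize to one canonical key", {
  keys <- extract_mentions(c(
    "T790M", "Thr790Met", "threonine 790 substituted with methionine",
    "p.T790M", "p.Thr790Met"
  ))$key
  expect_equal(unique(keys), "p|SUB|T|790|M")
})

test_that("worked-example phrases parse to their printed answers", {
  v <- parse_mention("substitution of alanine for proline at amino acid 286",
                     "natural_language")
  expect_equal(v$key, "p|SUB|P|286|A")

  v <- parse_mention("A to G transition at codon 557 (AAG–≥GAG)",
                     "codon_change")
  expect_equal(v$key, "p|SUB|K|557|E")

  v <- parse_mention("G–≥A polymorphism at nucleotide 5557",
                     "nucleotide_change")
  expect_equal(v$key, "c|SUB|G|5557|A")

  v <- parse_mention("valine 600 is mutated", "natural_language")
  expect_false(v$informative)
})

test_that("codon positions are never emitted as nucleotide positions", {
  # without the codon pair the base change at an amino-acid position is
  # uninformative, never A557G
  m <- extract_mentions("a heterozygous A to G transition at codon 557 here")
  expect_false(any(!is.na(m$key) & m$key == "c|SUB|A|557|G"))
  expect_true(all(!m$informative))

  # with the codon pair, the full phrase wins and binds the codon index
  m <- extract_mentions("a A to G transition at codon 557 (AAG–≥GAG) here")
  expect_equal(sum(m$informative), 1L)
  expect_equal(m$key[m$informative], "p|SUB|K|557|E")
  expect_false(any(m$level %in% "dna" & m$position %in% 557L))
})

test_that("untranslatable or stop-codon surfaces are flagged, not errors", {
  v <- parse_mention("T to A transition at codon 5 (TAC–≥TAA)", "codon_change")
  expect_false(v$informative)
  v <- parse_mention("AAG–≥GAG", "codon_change") # codon pair, no position
  expect_false(v$informative)
})

test_that("deletion, insertion and frameshift keyword forms normalize", {
  m <- extract_mentions("we saw E746del and K557fs and T790ins events")
  expect_equal(m$kind, c("DEL", "FS", "INS"))
  expect_equal(m$position, c(746L, 557L, 790L))
  expect_true(all(m$mutant == ""))
})

test_that("extraction is deterministic", {
  fx <- fixture_corpus()
  expect_identical(extract_mentions(fx$documents),
                   extract_mentions(fx$documents))
})

test_that("recall is perfect on decoy-free corpora of catalogued forms", {
  corpus <- generate_corpus(corpus_spec(seed = 5, n_docs = 30, decoy_rate = 0))
  pred <- mentions_to_answerset(extract_mentions(corpus$documents))
  r <- score_answerset(pred, corpus$gold, "normalized_mutations")
  expect_equal(r$recall, 1.0)
})
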