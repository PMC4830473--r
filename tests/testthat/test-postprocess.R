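test_that("filters remove lexicon decoys, non-informative and synonymous mentions", {
  m <- extract_mentions(
    "T47D and U133A lines; the T790M variant; L367L silent; see Figure S13A; valine 600 is mutated"
  )
  res <- filter_mentions(m)
  expect_equal(res$mentions$surface, "T790M")
  log <- res$log
  expect_equal(log$rule_id[log$surface == "T47D"], "lexicon")
  expect_equal(log$rule_id[log$surface == "U133A"], "lexicon")
  expect_equal(log$rule_id[log$surface == "S13A"], "lexicon")
  expect_equal(log$rule_id[log$surface == "L367L"], "synonymous")
  expect_equal(log$rule_id[log$surface == "valine 600 is mutated"],
               "non_informative")
  # outcome-log conservation: |input| = |survivors| + |removed|
  expect_equal(nrow(log), nrow(m))
  expect_equal(sum(log$action == "kept") + sum(log$action == "removed"),
               nrow(m))
})

test_that("the substitution-matrix rule removes implausible substitutions only", {
  m <- extract_mentions("compare W100G with L100I here")
  res <- filter_mentions(m)
  expect_equal(res$mentions$surface, "L100I")
  expect_equal(res$log$rule_id[res$log$surface == "W100G"],
               "substitution_matrix")
  # threshold override re-admits it
  res2 <- filter_mentions(m, config = pp_config(matrix_threshold = -100))
  expect_equal(nrow(res2$mentions), 2L)
})

test_that("disabling all rules makes filtering the identity", {
  m <- extract_mentions("T47D, L367L and valine 600 is mutated")
  cfg <- pp_config(lexicon = FALSE, non_informative = FALSE,
                   substitution_matrix = FALSE, synonymous = FALSE)
  res <- filter_mentions(m, config = cfg)
  expect_identical(res$mentions, m)
  expect_true(all(res$log$action == "kept"))
})

test_that("filters are pure: output is a subset and never grows", {
  corpus <- generate_corpus(corpus_spec(seed = 9, n_docs = 15,
                                        synonymous_rate = 0.5,
                                        implausible_rate = 0.5))
  m <- extract_mentions(corpus$documents)
  res <- filter_mentions(m)
  expect_lte(nrow(res$mentions), nrow(m))
  expect_true(all(res$mentions$surface %in% m$surface))
})

test_that("rule 5 re-anchors an imbalanced candidate to the explicit change", {
  spurious <- tibble::tibble(
    doc_id = "d", surface = "V 1691G", level = "protein", kind = "SUB",
    wild = "V", position = 1691L, mutant = "G", rs_id = "",
    informative = TRUE, key = "p|SUB|V|1691|G"
  )
  docs <- tibble::tibble(doc_id = "d", text = "factor V 1691G > A")
  res <- correct_forms(spurious, documents = docs)
  expect_equal(nrow(res$mentions), 1L)
  expect_equal(res$mentions$key, "c|SUB|G|1691|A")
  expect_equal(res$mentions$position, 1691L)
  expect_equal(res$log$rule_id, "imbalanced_form")
  expect_equal(res$log$action, "modified")
})

test_that("rule 6 resolves hyphen versus minus-as-location", {
  # hyphenated separators: plain position
  m <- extract_mentions("the Arg-23-Thr substitution")
  expect_equal(m$key, "p|SUB|R|23|T")
  # minus attached to the position only: upstream location by default
  m <- extract_mentions("the Arg-23Thr substitution")
  expect_equal(m$key, "p|SUB|R|-23|T")
  # ... and a plain position under the alternative convention
  m <- extract_mentions("the Arg-23Thr substitution",
                        config = pp_config(minus_denotes_location = FALSE))
  expect_equal(m$key, "p|SUB|R|23|T")
  # one-letter analogues
  expect_equal(extract_mentions("an A-23-T change")$key, "p|SUB|A|23|T")
  expect_equal(extract_mentions("an A-23T change")$key, "p|SUB|A|-23|T")

  # an externally supplied naive parse is corrected and logged
  naive <- tibble::tibble(
    doc_id = "d", surface = "Arg-23Thr", level = "protein", kind = "SUB",
    wild = "R", position = 23L, mutant = "T", rs_id = "",
    informative = TRUE, key = "p|SUB|R|23|T"
  )
  res <- correct_forms(naive)
  expect_equal(res$mentions$key, "p|SUB|R|-23|T")
  expect_equal(res$log$rule_id, "special_symbol")
})

test_that("rule 7 makes the residue after 'for' the wild type", {
  naive <- tibble::tibble(
    doc_id = "d", surface = "substitution of arginine for methionine",
    level = "protein", kind = "SUB", wild = "R", position = NA_integer_,
    mutant = "M", rs_id = "", informative = FALSE, key = NA_character_
  )
  res <- correct_forms(naive)
  expect_equal(res$mentions$wild, "M")
  expect_equal(res$mentions$mutant, "R")
  expect_equal(res$log$rule_id, "for_preposition")
  # a correctly oriented mention is confirmed, not flipped
  ok <- extract_mentions("substitution of alanine for proline at amino acid 286")
  res2 <- correct_forms(ok)
  expect_equal(res2$mentions$key, "p|SUB|P|286|A")
  expect_equal(res2$log$action, "kept")
})

test_that("corrections preserve mention count", {
  fx <- fixture_corpus()
  m <- extract_mentions(fx$documents)
  res <- correct_forms(m, documents = fx$documents)
  expect_equal(nrow(res$mentions), nrow(m))
  expect_equal(nrow(res$log), nrow(m))
})

test_that("answer-set post-processing composes corrections and filters", {
  mixed <- as_answerset(tibble::tribble(
    ~doc_id, ~level, ~kind, ~wild, ~position, ~mutant, ~rs_id, ~multiplicity,
    "d1", "protein", "SUB", "P", 286L, "A", "", 1L,
    "d1", "protein", "SUB", "L", 367L, "L", "", 1L,
    "d1", "dna", "SUB", "U", 133L, "A", "", 1L
  ))
  res <- postprocess_answerset(mixed)
  expect_equal(res$answers$key, "p|SUB|P|286|A")
  removed <- res$log[res$log$action == "removed", ]
  expect_setequal(removed$rule_id, c("synonymous", "lexicon"))

  # a lone cell-line "variant" is removed by the lexicon rule
  t47d <- as_answerset(tibble::tibble(
    doc_id = "d2", level = "protein", kind = "SUB", wild = "T",
    position = 47L, mutant = "D", rs_id = "", multiplicity = 1L
  ))
  res2 <- postprocess_answerset(t47d)
  expect_equal(nrow(res2$answers), 0L)
  expect_equal(res2$log$rule_id[res2$log$action == "removed"], "lexicon")

  # true positives from the curated examples are never removed
  fx <- fixture_corpus()
  res3 <- postprocess_answerset(fx$gold, documents = fx$documents)
  expect_equal(res3$answers$key, fx$gold$key)
  expect_equal(res3$answers$multiplicity, fx$gold$multiplicity)
})

test_that("answer-set post-processing is idempotent", {
  mixed <- as_answerset(tibble::tribble(
    ~doc_id, ~level, ~kind, ~wild, ~position, ~mutant, ~rs_id, ~multiplicity, ~surfaces,
    "d1", "protein", "SUB", "P", 286L, "A", "", 1L, "",
    "d1", "protein", "SUB", "R", 23L, "T", "", 1L, "Arg-23Thr",
    "d1", "protein", "SUB", "L", 367L, "L", "", 2L, ""
  ))
  once <- postprocess_answerset(mixed)
  twice <- postprocess_answerset(once$answers)
  expect_equal(twice$answers, once$answers)
  expect_true(all(twice$log$action == "kept"))
})
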