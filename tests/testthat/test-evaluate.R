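modes <- c("normalized_mutations", "extracted_mentions", "document_retrieval")

test_that("perfect agreement scores 1.0 in every mode", {
  a <- answerset_from_keys(rep(c("d1", "d2"), each = 2), key_pool(4),
                           multiplicity = c(1L, 2L, 1L, 3L))
  for (mode in modes) {
    r <- score_answerset(a, a, mode)
    expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  }
})

test_that("repeated mentions count per mention or per entity by mode", {
  gold <- answerset_from_keys("d1", "p|SUB|T|790|M", multiplicity = 2L)
  pred <- answerset_from_keys("d1", "p|SUB|T|790|M", multiplicity = 2L)
  expect_equal(score_answerset(pred, gold, "extracted_mentions")$tp, 2L)
  expect_equal(score_answerset(pred, gold, "normalized_mutations")$tp, 1L)
  # predicting it once misses one mention but still nails the entity
  once <- answerset_from_keys("d1", "p|SUB|T|790|M", multiplicity = 1L)
  r <- score_answerset(once, gold, "extracted_mentions")
  expect_equal(c(r$tp, r$fp, r$fn), c(1L, 0L, 1L))
  expect_equal(score_answerset(once, gold, "normalized_mutations")$f1, 1)
})

test_that("the printed precision/recall/F1 formulas are applied to counts", {
  pool <- key_pool(4) # A, B, C, D
  gold <- answerset_from_keys("d1", pool[1:3])
  pred <- answerset_from_keys("d1", pool[c(1, 2, 4)])
  r <- score_answerset(pred, gold, "normalized_mutations")
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 1L, 1L))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)
})

test_that("zero-denominator conventions", {
  none <- empty_answerset()
  some <- answerset_from_keys("d1", key_pool(1))
  r <- score_answerset(none, none, "normalized_mutations")
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  r <- score_answerset(none, some, "normalized_mutations")
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))
  r <- score_answerset(some, none, "normalized_mutations")
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))
})

test_that("document retrieval only cares about emptiness per document", {
  pool <- key_pool(4)
  gold <- answerset_from_keys(c("d1", "d2"), pool[1:2])
  pred_right_docs_wrong_keys <- answerset_from_keys(c("d1", "d2"), pool[3:4])
  r <- score_answerset(pred_right_docs_wrong_keys, gold, "document_retrieval")
  expect_equal(c(r$precision, r$recall), c(1, 1))
})

test_that("counts are conserved against predicted and gold totals", {
  set.seed(31)
  pool <- key_pool(8)
  for (trial in 1:25) {
    docs <- paste0("d", 1:sample(1:6, 1))
    pred <- rand_answerset(docs, pool, 0.4)
    gold <- rand_answerset(docs, pool, 0.4)
    r <- score_answerset(pred, gold, "normalized_mutations")
    expect_equal(r$tp + r$fp, nrow(pred))
    expect_equal(r$tp + r$fn, nrow(gold))
    rm_ <- score_answerset(pred, gold, "extracted_mentions")
    expect_equal(rm_$tp + rm_$fp, sum(pred$multiplicity))
    expect_equal(rm_$tp + rm_$fn, sum(gold$multiplicity))
    # F1 is the harmonic mean wherever defined
    if (r$precision + r$recall > 0) {
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
    }
  }
})

test_that("scores agree with the brute-force pairwise oracle", {
  set.seed(99)
  pool <- key_pool(8)
  for (trial in 1:40) {
    docs <- paste0("d", 1:sample(1:10, 1))
    pred <- rand_answerset(docs, pool, 0.35)
    gold <- rand_answerset(docs, pool, 0.35)
    for (mode in modes) {
      r <- score_answerset(pred, gold, mode)
      o <- oracle_score(pred, gold, mode)
      expect_equal(c(r$tp, r$fp, r$fn), unname(o[c("tp", "fp", "fn")]))
    }
  }
})

test_that("diff partitions predicted and gold keys exhaustively", {
  pool <- key_pool(3)
  gold <- answerset_from_keys("d1", pool[1])
  pred <- answerset_from_keys("d1", pool[2])
  d <- diff_answerset(pred, gold)
  expect_equal(d$status[d$key == pool[1]], "FN")
  expect_equal(d$status[d$key == pool[2]], "FP")

  expect_equal(nrow(dplyr::filter(diff_answerset(gold, gold),
                                  status != "TP")), 0L)
  d2 <- diff_answerset(empty_answerset(), gold)
  expect_equal(d2$status, "FN")

  set.seed(12)
  pred <- rand_answerset(c("d1", "d2"), key_pool(6), 0.5)
  gold <- rand_answerset(c("d1", "d2"), key_pool(6), 0.5)
  d <- diff_answerset(pred, gold)
  expect_identical(
    sort(paste(d$doc_id[d$status != "FN"], d$key[d$status != "FN"])),
    sort(paste(pred$doc_id, pred$key))
  )
  expect_identical(
    sort(paste(d$doc_id[d$status != "FP"], d$key[d$status != "FP"])),
    sort(paste(gold$doc_id, gold$key))
  )
})

test_that("tidiers and autoplot expose the result", {
  r <- score_answerset(answerset_from_keys("d1", key_pool(2)),
                       answerset_from_keys("d1", key_pool(3)))
  td <- tidy(r)
  expect_equal(td$measure, c("precision", "recall", "f1"))
  gl <- glance(r)
  expect_equal(gl$tp + gl$fn, 3L)
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
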