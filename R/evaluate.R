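#' Score a predicted answer set against gold
#'
#' Computes micro-averaged precision, recall and F1 under one of three
#' metric modes: `"extracted_mentions"` matches mention occurrences per
#' document (a variant mentioned twice must be predicted twice for a
#' perfect score); `"normalized_mutations"` matches canonical keys per
#' document, counting repeated mentions of the same variant as one entity;
#' `"document_retrieval"` compares, per document, only whether any variant
#' is present. Counts are pooled over all documents before the ratios are
#' computed:
#' \deqn{P = TP/(TP+FP),\quad R = TP/(TP+FN),\quad F1 = 2PR/(P+R).}
#'
#' When a denominator is zero, precision (resp. recall) is 1 if both the
#' predictions and the gold are empty, else 0; F1 is 0 when `P + R = 0`.
#'
#' @param pred,gold `answer_set` objects (or data frames coercible via
#'   [as_answerset()]).
#' @param metric One of `"normalized_mutations"` (default),
#'   `"extracted_mentions"`, `"document_retrieval"`.
#' @return A `variant_eval` object with fields `metric`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `n_docs`. Use [tidy()] / [glance()] for a
#'   tibble, `autoplot()` for a bar chart.
#' @export
#' @examples
#' gold <- answerset_from_keys("d1", c("p|SUB|T|790|M", "p|SUB|L|858|R"))
#' pred <- answerset_from_keys("d1", c("p|SUB|T|790|M", "p|SUB|G|12|D"))
#' score_answerset(pred, gold)
score_answerset <- function(pred, gold,
                            metric = c("normalized_mutations",
                                       "extracted_mentions",
                                       "document_retrieval")) {
  metric <- match.arg(metric)
  pred <- as_answerset(pred)
  gold <- as_answerset(gold)
  if (metric == "extracted_mentions" &&
      (anyNA(pred$multiplicity) || anyNA(gold$multiplicity))) {
    abort("extracted_mentions scoring requires mention multiplicities",
          class = "varminer_bad_metric")
  }
  counts <- switch(
    metric,
    normalized_mutations = {
      j <- dplyr::full_join(
        dplyr::distinct(pred[, c("doc_id", "key")]) |> dplyr::mutate(p = 1L),
        dplyr::distinct(gold[, c("doc_id", "key")]) |> dplyr::mutate(g = 1L),
        by = c("doc_id", "key")
      )
      c(tp = sum(!is.na(j$p) & !is.na(j$g)),
        fp = sum(!is.na(j$p) & is.na(j$g)),
        fn = sum(is.na(j$p) & !is.na(j$g)))
    },
    extracted_mentions = {
      j <- dplyr::full_join(
        pred[, c("doc_id", "key", "multiplicity")] |> dplyr::rename(mp = "multiplicity"),
        gold[, c("doc_id", "key", "multiplicity")] |> dplyr::rename(mg = "multiplicity"),
        by = c("doc_id", "key")
      ) |>
        dplyr::mutate(mp = dplyr::coalesce(.data$mp, 0L),
                      mg = dplyr::coalesce(.data$mg, 0L))
      c(tp = sum(pmin(j$mp, j$mg)),
        fp = sum(pmax(j$mp - j$mg, 0L)),
        fn = sum(pmax(j$mg - j$mp, 0L)))
    },
    document_retrieval = {
      dp <- unique(pred$doc_id)
      dg <- unique(gold$doc_id)
      c(tp = length(intersect(dp, dg)),
        fp = length(setdiff(dp, dg)),
        fn = length(setdiff(dg, dp)))
    }
  )
  .new_variant_eval(metric, counts[["tp"]], counts[["fp"]], counts[["fn"]],
                    n_docs = length(union(unique(pred$doc_id),
                                          unique(gold$doc_id))))
}

.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(fn == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(fp == 0)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

.new_variant_eval <- function(metric, tp, fp, fn, n_docs) {
  r <- .prf(tp, fp, fn)
  structure(
    list(metric = metric, tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), precision = r$precision, recall = r$recall,
         f1 = r$f1, n_docs = as.integer(n_docs)),
    class = "variant_eval"
  )
}

#' @export
print.variant_eval <- function(x, ...) {
  cat("<variant_eval> metric: ", x$metric, " (", x$n_docs, " docs)\n",
      sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn),
      sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1),
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for evaluation results
#'
#' `tidy()` returns one row per count/ratio pair; `glance()` returns the
#' one-row summary.
#'
#' @param x A `variant_eval`.
#' @param ... Unused.
#' @export
tidy.variant_eval <- function(x, ...) {
  tibble(
    metric = x$metric,
    measure = c("precision", "recall", "f1"),
    value = c(x$precision, x$recall, x$f1)
  )
}

#' @rdname tidy.variant_eval
#' @export
glance.variant_eval <- function(x, ...) {
  tibble(metric = x$metric, tp = x$tp, fp = x$fp, fn = x$fn,
         precision = x$precision, recall = x$recall, f1 = x$f1,
         n_docs = x$n_docs)
}

#' @rdname tidy.variant_eval
#' @param object A `variant_eval`.
#' @export
autoplot.variant_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Scoring mode: ", object$metric),
                  subtitle = sprintf("TP %d / FP %d / FN %d over %d documents",
                                     object$tp, object$fp, object$fn,
                                     object$n_docs)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-document diff of predicted vs gold variants
#'
#' Partitions canonical keys into true positives, false positives and false
#' negatives per document, supporting error analysis of an extractor's
#' output. `TP` and `FP` together are exactly the predicted keys, `TP` and
#' `FN` exactly the gold keys.
#'
#' @inheritParams score_answerset
#' @return A tibble with columns `doc_id`, `status` (`"TP"`, `"FP"`,
#'   `"FN"`), `key`.
#' @export
diff_answerset <- function(pred, gold) {
  pred <- as_answerset(pred)
  gold <- as_answerset(gold)
  j <- dplyr::full_join(
    dplyr::distinct(pred[, c("doc_id", "key")]) |> dplyr::mutate(p = TRUE),
    dplyr::distinct(gold[, c("doc_id", "key")]) |> dplyr::mutate(g = TRUE),
    by = c("doc_id", "key")
  )
  j |>
    dplyr::mutate(status = dplyr::case_when(
      isTRUE_vec(.data$p) & isTRUE_vec(.data$g) ~ "TP",
      isTRUE_vec(.data$p) ~ "FP",
      TRUE ~ "FN"
    )) |>
    dplyr::select("doc_id", "status", "key") |>
    dplyr::arrange(.data$doc_id, .data$status, .data$key)
}
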