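#' Combine answer sets from multiple extractors
#'
#' `simple_merge()` keeps, per document, every variant extracted by at
#' least one input (the union of canonical keys); `majority_vote()` keeps
#' variants present in at least `quorum` inputs (presence is counted once
#' per input, regardless of mention multiplicity — the classic two-of-three
#' vote is `quorum = 2` over three inputs). Documents absent from an input
#' count as empty for that input. Identity is the level-aware canonical
#' key, so protein-level and DNA-level descriptions of the same event
#' remain distinct variants.
#'
#' For merged rows, `multiplicity` is the maximum multiplicity claimed by
#' any contributing input and `source` lists the contributing inputs.
#'
#' @param answersets A list of `answer_set` objects (named, optionally; the
#'   names become provenance tags).
#' @param quorum Minimum number of inputs that must contain a variant.
#' @return An `answer_set`.
#' @export
#' @examples
#' a <- answerset_from_keys("d1", c("p|SUB|T|790|M", "p|SUB|L|858|R"))
#' b <- answerset_from_keys("d1", "p|SUB|T|790|M")
#' majority_vote(list(a, b), quorum = 2)$key
simple_merge <- function(answersets) {
  .combine_answersets(answersets, quorum = 1L, op = "simple_merge")
}

#' @rdname simple_merge
#' @export
majority_vote <- function(answersets, quorum = 2L) {
  if (length(answersets) < 2) {
    abort("majority_vote needs at least two answer sets",
          class = "varminer_bad_ensemble")
  }
  .combine_answersets(answersets, quorum = quorum, op = "majority_vote")
}

.combine_answersets <- function(answersets, quorum, op) {
  if (!is.list(answersets) || !length(answersets)) {
    abort(paste0(op, " needs a non-empty list of answer sets"),
          class = "varminer_bad_ensemble")
  }
  quorum <- as.integer(quorum)
  if (is.na(quorum) || quorum < 1L) {
    abort("quorum must be an integer >= 1", class = "varminer_bad_ensemble")
  }
  if (quorum > length(answersets)) {
    abort("quorum exceeds the number of input answer sets",
          class = "varminer_bad_ensemble")
  }
  tags <- names(answersets) %||% paste0("input", seq_along(answersets))
  tags[tags == ""] <- paste0("input", which(tags == ""))
  pooled <- purrr::map2(answersets, tags, function(a, tag) {
    a <- as_answerset(a)
    a$source <- tag
    a
  })
  pooled <- dplyr::bind_rows(pooled)
  if (!nrow(pooled)) return(empty_answerset())
  kept <- pooled |>
    dplyr::group_by(.data$doc_id, .data$key) |>
    dplyr::summarise(
      dplyr::across(c("level", "kind", "wild", "position", "mutant", "rs_id"),
                    dplyr::first),
      n_inputs = dplyr::n_distinct(.data$source),
      multiplicity = max(.data$multiplicity),
      surfaces = paste(setdiff(unique(unlist(
        strsplit(.data$surfaces, ";", fixed = TRUE))), ""), collapse = ";"),
      source = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_inputs >= quorum)
  as_answerset(dplyr::select(kept, -"key", -"n_inputs"))
}
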