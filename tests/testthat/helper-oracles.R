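# Shared fixtures and independent brute-force oracles.

# pool of simple, valid canonical keys for randomized set algebra
key_pool <- function(n = 10) {
  aa <- residue_alphabet()
  canonical_key(tibble::tibble(
    level = "protein", kind = "SUB",
    wild = aa[seq_len(n)], position = 100L + seq_len(n),
    mutant = aa[rev(seq_len(n))], rs_id = ""
  ))
}

rand_answerset <- function(doc_ids, pool, p = 0.4, max_mult = 3L) {
  rows <- list()
  for (d in doc_ids) {
    take <- pool[stats::runif(length(pool)) < p]
    if (length(take)) {
      rows[[d]] <- answerset_from_keys(
        d, take, multiplicity = sample.int(max_mult, length(take), replace = TRUE)
      )
    }
  }
  if (!length(rows)) return(empty_answerset())
  as_answerset(dplyr::bind_rows(rows))
}

# brute-force ensemble oracle: enumerate every (doc, key), count memberships
oracle_combine <- function(sets, quorum) {
  docs <- unique(unlist(lapply(sets, function(s) s$doc_id)))
  out <- list()
  for (d in docs) {
    keys <- unique(unlist(lapply(sets, function(s) s$key[s$doc_id == d])))
    for (k in keys) {
      n_in <- sum(vapply(sets, function(s) any(s$doc_id == d & s$key == k),
                         logical(1)))
      if (n_in >= quorum) out[[length(out) + 1L]] <- c(d, k)
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(x) paste(x, collapse = "\r"), character(1)))
}

set_signature <- function(a) sort(paste(a$doc_id, a$key, sep = "\r"))

# brute-force scoring oracle: explicit per-document loops
oracle_score <- function(pred, gold, metric) {
  docs <- union(unique(pred$doc_id), unique(gold$doc_id))
  tp <- fp <- fn <- 0L
  for (d in docs) {
    p <- pred[pred$doc_id == d, ]
    g <- gold[gold$doc_id == d, ]
    if (metric == "document_retrieval") {
      tp <- tp + (nrow(p) > 0 && nrow(g) > 0)
      fp <- fp + (nrow(p) > 0 && nrow(g) == 0)
      fn <- fn + (nrow(p) == 0 && nrow(g) > 0)
    } else if (metric == "normalized_mutations") {
      tp <- tp + length(intersect(p$key, g$key))
      fp <- fp + length(setdiff(p$key, g$key))
      fn <- fn + length(setdiff(g$key, p$key))
    } else {
      for (k in union(p$key, g$key)) {
        mp <- sum(p$multiplicity[p$key == k])
        mg <- sum(g$multiplicity[g$key == k])
        tp <- tp + min(mp, mg)
        fp <- fp + max(mp - mg, 0L)
        fn <- fn + max(mg - mp, 0L)
      }
    }
  }
  c(tp = tp, fp = fp, fn = fn)
}
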