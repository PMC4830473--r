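#' Answer sets: per-document collections of normalized variants
#'
#' An answer set is the unit exchanged between extractors, ensembles and the
#' scorer: one row per (document, canonical variant), with a `multiplicity`
#' carrying how many times the variant is mentioned, optional semicolon-joined
#' raw `surfaces`, and an optional `source` tag recording which extractor(s)
#' contributed the row. Within a document canonical keys are unique.
#'
#' @param x A data frame with columns `doc_id`, `level`, `kind`, `wild`,
#'   `position`, `mutant`, `rs_id`, `multiplicity` (and optionally
#'   `surfaces`, `source`). Inapplicable fields are empty strings.
#' @return A tibble of class `answer_set` with a derived `key` column.
#' @export
#' @examples
#' as_answerset(data.frame(
#'   doc_id = "d1", level = "protein", kind = "SUB",
#'   wild = "T", position = 790, mutant = "M", rs_id = "", multiplicity = 2
#' ))
as_answerset <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("doc_id", "level", "kind", "wild", "position", "mutant", "rs_id",
            "multiplicity")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("answer set is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "varminer_bad_answerset")
  }
  x <- as_tibble(x)
  if (!"surfaces" %in% names(x)) x$surfaces <- ""
  if (!"source" %in% names(x)) x$source <- ""
  x <- dplyr::mutate(
    x,
    doc_id = as.character(.data$doc_id),
    level = as.character(.data$level), kind = as.character(.data$kind),
    wild = dplyr::coalesce(as.character(.data$wild), ""),
    position = suppressWarnings(as.integer(.data$position)),
    mutant = dplyr::coalesce(as.character(.data$mutant), ""),
    rs_id = dplyr::coalesce(as.character(.data$rs_id), ""),
    multiplicity = as.integer(.data$multiplicity),
    surfaces = dplyr::coalesce(as.character(.data$surfaces), ""),
    source = dplyr::coalesce(as.character(.data$source), "")
  )
  .check_answerset_rows(x)
  x$key <- canonical_key(x)
  x <- .merge_duplicate_keys(x)
  x <- dplyr::arrange(x, .data$doc_id, .data$key)
  x <- dplyr::select(
    x, "doc_id", "key", "level", "kind", "wild", "position", "mutant",
    "rs_id", "multiplicity", "surfaces", "source"
  )
  class(x) <- c("answer_set", class(tibble()))
  x
}

.check_answerset_rows <- function(x, rows = seq_len(nrow(x))) {
  fail <- function(i, field, why) {
    abort(paste0("malformed answer-set row ", rows[[i]], ": field '", field,
                 "' ", why),
          class = "varminer_bad_answerset")
  }
  aa <- residue_alphabet()
  for (i in seq_len(nrow(x))) {
    if (is.na(x$doc_id[[i]]) || !nzchar(x$doc_id[[i]])) fail(i, "doc_id", "is empty")
    if (!x$level[[i]] %in% names(.levels)) fail(i, "level", "is not protein/dna/rna")
    if (!x$kind[[i]] %in% .kinds) fail(i, "kind", "is not a known kind")
    ok_sym <- function(s) {
      s == "" || (x$level[[i]] == "protein" && s %in% aa) ||
        (x$level[[i]] != "protein" && s %in% c("A", "C", "G", "T", "U"))
    }
    if (!ok_sym(x$wild[[i]])) fail(i, "wild", "is not in the level's alphabet")
    if (!ok_sym(x$mutant[[i]])) fail(i, "mutant", "is not in the level's alphabet")
    if (is.na(x$multiplicity[[i]]) || x$multiplicity[[i]] < 1L) {
      fail(i, "multiplicity", "must be an integer >= 1")
    }
    if (x$kind[[i]] == "SNP" && x$rs_id[[i]] == "") fail(i, "rs_id", "is required for SNP")
  }
  invisible(x)
}

.merge_duplicate_keys <- function(x) {
  dup <- duplicated(x[, c("doc_id", "key")])
  if (!any(dup)) return(x)
  warn(paste0(sum(dup), " duplicate (doc_id, key) row(s) merged; ",
              "multiplicities summed"),
       class = "varminer_duplicate_rows")
  x |>
    dplyr::group_by(.data$doc_id, .data$key) |>
    dplyr::summarise(
      dplyr::across(c("level", "kind", "wild", "position", "mutant", "rs_id"),
                    dplyr::first),
      multiplicity = sum(.data$multiplicity),
      surfaces = paste(unique(unlist(strsplit(.data$surfaces, ";", fixed = TRUE))),
                       collapse = ";"),
      source = paste(sort(unique(unlist(strsplit(.data$source, ";", fixed = TRUE)))),
                     collapse = ";"),
      .groups = "drop"
    )
}

#' Collapse extracted mentions into an answer set
#'
#' Groups informative mentions by document and canonical key; multiplicity
#' is the mention count, surfaces are joined with semicolons.
#' Non-informative mentions carry no canonical key and are dropped (run
#' [filter_mentions()] first if you want them logged).
#'
#' @param mentions A mentions tibble as from [extract_mentions()].
#' @param source Optional extractor tag stored in the `source` column.
#' @return An `answer_set`.
#' @export
mentions_to_answerset <- function(mentions, source = "") {
  m <- mentions[isTRUE_vec(mentions$informative) & !is.na(mentions$key), ,
                drop = FALSE]
  if (!nrow(m)) return(empty_answerset())
  grouped <- m |>
    dplyr::group_by(.data$doc_id, .data$key) |>
    dplyr::summarise(
      dplyr::across(c("level", "kind", "wild", "position", "mutant", "rs_id"),
                    dplyr::first),
      multiplicity = dplyr::n(),
      surfaces = paste(unique(.data$surface), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(source = source)
  as_answerset(dplyr::select(grouped, -"key"))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @rdname as_answerset
#' @export
empty_answerset <- function() {
  as_answerset(tibble(
    doc_id = character(), level = character(), kind = character(),
    wild = character(), position = integer(), mutant = character(),
    rs_id = character(), multiplicity = integer()
  ))
}

#' Build an answer set from canonical keys
#'
#' Convenience constructor used by the ensembles, the scorer and tests.
#'
#' @param doc_id Document id(s), recycled against `keys`.
#' @param keys Character vector of canonical keys (see [canonical_key()]).
#' @param multiplicity Integer multiplicities, recycled.
#' @return An `answer_set`.
#' @export
#' @examples
#' answerset_from_keys("d1", c("p|SUB|T|790|M", "c|SUB|G|5557|A"))
answerset_from_keys <- function(doc_id, keys, multiplicity = 1L) {
  if (!length(keys)) return(empty_answerset())
  v <- parse_canonical_key(keys)
  v$doc_id <- rep_len(doc_id, length(keys))
  v$multiplicity <- rep_len(as.integer(multiplicity), length(keys))
  as_answerset(dplyr::select(v, -"key"))
}

# ---- unified TSV dialect ----------------------------------------------------

.answerset_cols <- c("doc_id", "level", "kind", "wild", "position", "mutant",
                     "rs_id", "multiplicity", "surfaces", "source")

#' Read and write answer sets in the unified tab-separated dialect
#'
#' The dialect is a TSV with header columns `doc_id`, `level`, `kind`,
#' `wild`, `position`, `mutant`, `rs_id`, `multiplicity`, `surfaces`,
#' `source`; inapplicable fields are empty strings. Writing is
#' deterministic: documents are sorted by id and variants by canonical key,
#' so the same answer set always produces byte-identical files. Duplicate
#' (document, key) rows on read are merged with summed multiplicities and a
#' warning; structurally malformed rows raise an error naming the row and
#' field.
#'
#' @param path File path.
#' @return `read_answerset()` returns an `answer_set`;
#'   `write_answerset()` invisibly returns `path`.
#' @export
read_answerset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("answer-set file not found: ", path),
          class = "varminer_missing_resource")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(setdiff(.answerset_cols, c("surfaces", "source")),
                          names(raw))
  if (length(missing_cols)) {
    abort(paste0("answer-set file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "varminer_bad_answerset")
  }
  if (!nrow(raw)) return(empty_answerset())
  raw$position[raw$position == ""] <- NA
  bad_pos <- !is.na(raw$position) & !stringr::str_detect(raw$position, "^-?\\d+$")
  if (any(bad_pos)) {
    abort(paste0("malformed answer-set row ", which(bad_pos)[[1]],
                 ": field 'position' is not an integer"),
          class = "varminer_bad_answerset")
  }
  bad_mult <- !stringr::str_detect(raw$multiplicity, "^\\d+$")
  if (any(bad_mult)) {
    abort(paste0("malformed answer-set row ", which(bad_mult)[[1]],
                 ": field 'multiplicity' is not a positive integer"),
          class = "varminer_bad_answerset")
  }
  as_answerset(raw)
}

#' @rdname read_answerset
#' @param a An `answer_set`.
#' @export
write_answerset <- function(a, path) {
  a <- as_answerset(a)
  out <- dplyr::arrange(a, .data$doc_id, .data$key)
  out <- dplyr::mutate(
    out,
    position = ifelse(is.na(.data$position), "", as.character(.data$position))
  )
  readr::write_tsv(out[, .answerset_cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read documents from plain text or JSON-lines
#'
#' A directory is read as one UTF-8 `.txt` file per document (the file stem
#' becomes the doc id); a `.jsonl`/`.ndjson` file as one
#' `{"doc_id": ..., "text": ...}` object per line; any other single file as
#' one document named after its stem.
#'
#' @param path Directory or file path.
#' @return A tibble with columns `doc_id`, `text`, ordered by `doc_id`.
#' @export
read_documents <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    docs <- tibble(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = purrr::map_chr(files, ~ paste(readLines(.x, warn = FALSE,
                                                     encoding = "UTF-8"),
                                           collapse = "\n"))
    )
  } else if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    recs <- purrr::map(lines, jsonlite::fromJSON)
    docs <- tibble(
      doc_id = purrr::map_chr(recs, "doc_id"),
      text = purrr::map_chr(recs, "text")
    )
  } else if (file.exists(path)) {
    docs <- tibble(
      doc_id = sub("\\.[^.]*$", "", basename(path)),
      text = paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                   collapse = "\n")
    )
  } else {
    abort(paste0("no such file or directory: ", path),
          class = "varminer_missing_resource")
  }
  if (anyDuplicated(docs$doc_id)) {
    abort("duplicate doc_id in documents", class = "varminer_duplicate_doc")
  }
  dplyr::arrange(docs, .data$doc_id)
}
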