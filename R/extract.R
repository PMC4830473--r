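#' Extract variant mentions from documents
#'
#' Scans document text with the mention [pattern_catalogue()] and returns
#' every non-overlapping match, longest-match-wins on overlap (catalogue
#' order breaks length ties), sorted by offset. Each mention is parsed into
#' a normalized variant where possible; mentions lacking any of wild-type,
#' position or mutant (for substitution kinds) are kept but flagged
#' non-informative so the post-processing filters can remove them.
#'
#' Character offsets are 0-based, half-open: `surface` equals
#' `substr(text, start + 1, end)`.
#'
#' @param documents A data frame with columns `doc_id` and `text`, or a
#'   character vector of texts (names become doc ids; unnamed texts are
#'   numbered `doc1`, `doc2`, ...).
#' @param catalogue Pattern catalogue, as from [pattern_catalogue()].
#' @param config Post-processing/parsing options from [pp_config()]; only
#'   the special-symbol conventions are consulted at parse time.
#' @return A tibble with one row per mention: `doc_id`, `start`, `end`,
#'   `surface`, `form`, `pattern`, `context_before`, the normalized fields
#'   (`level`, `kind`, `wild`, `position`, `mutant`, `rs_id`), an
#'   `informative` flag and the canonical `key` (`NA` when non-informative).
#' @export
#' @examples
#' extract_mentions("The T790M mutation confers resistance.")
extract_mentions <- function(documents, catalogue = pattern_catalogue(),
                             config = pp_config()) {
  docs <- as_documents(documents)
  out <- purrr::map2(docs$doc_id, docs$text, function(id, txt) {
    m <- .extract_one(txt, catalogue, config)
    if (nrow(m)) m$doc_id <- id
    m
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(.empty_mentions())
  dplyr::select(res, "doc_id", dplyr::everything())
}

as_documents <- function(documents) {
  if (is.character(documents)) {
    ids <- names(documents) %||% paste0("doc", seq_along(documents))
    ids[ids == ""] <- paste0("doc", which(ids == ""))
    documents <- tibble(doc_id = ids, text = unname(documents))
  }
  stopifnot(is.data.frame(documents), all(c("doc_id", "text") %in% names(documents)))
  if (anyDuplicated(documents$doc_id)) {
    abort("duplicate doc_id in documents", class = "varminer_duplicate_doc")
  }
  as_tibble(documents[, c("doc_id", "text")])
}

.empty_mentions <- function() {
  tibble(
    doc_id = character(), start = integer(), end = integer(),
    surface = character(), form = character(), pattern = character(),
    context_before = character(), level = character(), kind = character(),
    wild = character(), position = integer(), mutant = character(),
    rs_id = character(), informative = logical(), key = character()
  )
}

.extract_one <- function(text, catalogue, config) {
  if (is.na(text) || !nzchar(text)) return(.empty_mentions())
  cands <- purrr::pmap(catalogue, function(name, form, pattern, case_insensitive,
                                           parser, priority) {
    loc <- stringr::str_locate_all(
      text, stringr::regex(pattern, ignore_case = case_insensitive)
    )[[1]]
    if (!nrow(loc)) return(NULL)
    tibble(pattern = name, form = form, parser = parser, priority = priority,
           start1 = loc[, 1], end1 = loc[, 2])
  })
  cands <- dplyr::bind_rows(cands)
  if (!nrow(cands)) return(.empty_mentions())

  # longest-match-wins; catalogue priority then offset break ties
  cands <- cands |>
    dplyr::mutate(len = .data$end1 - .data$start1 + 1L) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$priority, .data$start1)
  keep <- logical(nrow(cands))
  acc_s <- integer(0); acc_e <- integer(0)
  for (i in seq_len(nrow(cands))) {
    s <- cands$start1[[i]]; e <- cands$end1[[i]]
    if (!any(s <= acc_e & e >= acc_s)) {
      keep[[i]] <- TRUE
      acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
    }
  }
  sel <- cands[keep, , drop = FALSE] |> dplyr::arrange(.data$start1)

  parsed <- purrr::pmap(
    list(sel$start1, sel$end1, sel$parser, sel$pattern, sel$form),
    function(s, e, parser, pname, form) {
      surface <- stringr::str_sub(text, s, e)
      row <- catalogue[catalogue$name == pname, ]
      g <- stringr::str_match(
        surface,
        stringr::regex(paste0("^", row$pattern[[1]], "$"),
                       ignore_case = row$case_insensitive[[1]])
      )[1, -1]
      v <- .parse_captures(parser, g, surface, config)
      tibble(
        start = s - 1L, end = e, surface = surface, form = form,
        pattern = pname,
        context_before = stringr::str_sub(text, max(1L, s - 30L), s - 1L),
        level = v$level, kind = v$kind, wild = v$wild, position = v$position,
        mutant = v$mutant, rs_id = v$rs_id, informative = v$informative,
        key = v$key
      )
    }
  )
  dplyr::bind_rows(parsed)
}

#' Parse a single mention surface into a normalized variant
#'
#' Re-derives the normalized wild-type/position/mutant record from a mention
#' surface string, given the form category the detector assigned. Residue
#' tokens go through [aa_to_one()], codon pairs through [translate_codon()].
#' Surfaces that cannot be converted to wNm form (missing position, missing
#' residue, untranslatable or stop codon) yield the non-informative marker
#' (`informative = FALSE`, `NA` fields) rather than an error.
#'
#' @param surface Mention surface string.
#' @param form Form category (see [pattern_catalogue()]).
#' @inheritParams extract_mentions
#' @return A one-row tibble with `level`, `kind`, `wild`, `position`,
#'   `mutant`, `rs_id`, `informative`, `key`.
#' @export
#' @examples
#' parse_mention("Thr790Met", "wnm_long")
#' parse_mention("valine 600 is mutated", "natural_language")
parse_mention <- function(surface, form, catalogue = pattern_catalogue(),
                          config = pp_config()) {
  rows <- catalogue[catalogue$form == form, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    m <- stringr::str_match(
      surface,
      stringr::regex(paste0("^", rows$pattern[[i]], "$"),
                     ignore_case = rows$case_insensitive[[i]])
    )
    if (!is.na(m[1, 1])) {
      return(.parse_captures(rows$parser[[i]], m[1, -1], surface, config))
    }
  }
  .non_informative()
}

.non_informative <- function() {
  tibble(level = NA_character_, kind = NA_character_, wild = NA_character_,
         position = NA_integer_, mutant = NA_character_, rs_id = NA_character_,
         informative = FALSE, key = NA_character_)
}

.mk_variant <- function(level, kind, wild = "", position = NA_integer_,
                        mutant = "", rs_id = "") {
  v <- tryCatch(
    variant(level, kind, wild, position, mutant, rs_id),
    error = function(e) NULL
  )
  if (is.null(v)) return(.non_informative())
  tibble(level = v$level, kind = v$kind, wild = v$wild, position = v$position,
         mutant = v$mutant, rs_id = v$rs_id, informative = TRUE, key = v$key)
}

.fold_u <- function(x) chartr("U", "T", toupper(x))

.sym_position <- function(sym_before, raw_pos, sym_after, config) {
  pos <- as.integer(raw_pos)
  if (identical(sym_before, "-") && !identical(sym_after, "-") &&
      isTRUE(config$minus_denotes_location)) {
    pos <- -abs(pos)
  }
  pos
}

.parse_captures <- function(parser, g, surface, config) {
  g[is.na(g)] <- ""
  safe_aa <- function(x) tryCatch(aa_to_one(x), error = function(e) NA_character_)
  switch(
    parser,
    dbsnp = .mk_variant("dna", "SNP", rs_id = surface),
    num_mid_change = .mk_variant("dna", "SUB", .fold_u(g[[2]]),
                                 as.integer(g[[1]]), .fold_u(g[[3]])),
    letter_first_nt = .mk_variant("dna", "SUB", .fold_u(g[[1]]),
                                  as.integer(g[[2]]), .fold_u(g[[3]])),
    hgvs_p = {
      w <- safe_aa(g[[1]]); m <- safe_aa(g[[3]])
      if (is.na(w) || is.na(m)) .non_informative()
      else .mk_variant("protein", "SUB", w, as.integer(g[[2]]), m)
    },
    codon_full = {
      w <- translate_codon(g[[4]]); m <- translate_codon(g[[5]])
      if (w == "*" || m == "*") .non_informative()
      else .mk_variant("protein", "SUB", w, as.integer(g[[3]]), m)
    },
    base_at_codon = .non_informative(),
    codon_pair = .non_informative(),
    base_change_at = .mk_variant("dna", "SUB", .fold_u(g[[1]]),
                                 as.integer(g[[3]]), .fold_u(g[[2]])),
    base_bare = .non_informative(),
    num_first_change = .mk_variant("dna", "SUB", .fold_u(g[[2]]),
                                   as.integer(g[[1]]), .fold_u(g[[3]])),
    nl_sub_for = {
      if (g[[3]] == "") .non_informative()
      else {
        w <- safe_aa(g[[2]]); m <- safe_aa(g[[1]])
        if (is.na(w) || is.na(m)) .non_informative()
        else .mk_variant("protein", "SUB", w, as.integer(g[[3]]), m)
      }
    },
    nl_wild_pos_mut = {
      w <- safe_aa(g[[1]]); m <- safe_aa(g[[3]])
      if (is.na(w) || is.na(m)) .non_informative()
      else .mk_variant("protein", "SUB", w, as.integer(g[[2]]), m)
    },
    nl_wild_mut_pos = {
      if (g[[3]] == "") .non_informative()
      else {
        w <- safe_aa(g[[1]]); m <- safe_aa(g[[2]])
        if (is.na(w) || is.na(m)) .non_informative()
        else .mk_variant("protein", "SUB", w, as.integer(g[[3]]), m)
      }
    },
    nl_noninformative = .non_informative(),
    wnm3 = {
      w <- safe_aa(g[[1]]); m <- safe_aa(g[[5]])
      if (is.na(w) || is.na(m)) .non_informative()
      else .mk_variant("protein", "SUB", w,
                       .sym_position(g[[2]], g[[3]], g[[4]], config), m)
    },
    wnm1_sym = .mk_variant("protein", "SUB", toupper(g[[1]]),
                           .sym_position(g[[2]], g[[3]], g[[4]], config),
                           toupper(g[[5]])),
    wnm1 = .mk_variant("protein", "SUB", g[[1]], as.integer(g[[2]]), g[[3]]),
    del_res_pos = .mk_variant("protein", "DEL", g[[1]], as.integer(g[[2]])),
    ins_res_pos = .mk_variant("protein", "INS", g[[1]], as.integer(g[[2]])),
    fs_res_pos = .mk_variant("protein", "FS", g[[1]], as.integer(g[[2]])),
    abort(paste0("unknown parser id: ", sQuote(parser)),
          class = "varminer_unknown_parser")
  )
}
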