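#' Post-processing configuration
#'
#' Toggles and conventions for the seven-rule post-processing module. The
#' four filters remove mentions: (1) `lexicon` — surfaces matching cell-line
#' / gene / platform lexicons or decoy patterns; (2) `non_informative` —
#' mentions that cannot be converted to wNm form; (3) `substitution_matrix`
#' — protein substitutions scoring below the plausibility threshold;
#' (4) `synonymous` — substitutions whose wild-type equals the mutant. The
#' three corrections modify mentions in place: (5) `imbalanced_form` —
#' re-anchor a spurious wild-type token to an adjacent explicit change
#' (e.g. "V 1691G" inside "factor V 1691G > A"); (6) `special_symbol` —
#' resolve hyphen/minus/plus/asterisk between residue tokens ("Arg-23-Thr"
#' is a hyphenated R23T, "Arg-23Thr" places the residue at location -23);
#' (7) `for_preposition` — in "substitution of X for Y", Y is the wild type.
#'
#' @param lexicon,non_informative,substitution_matrix,synonymous,imbalanced_form,special_symbol,for_preposition
#'   Logical switches, all on by default.
#' @param minus_denotes_location If `TRUE` (default), a minus attached only
#'   to the left of the position ("Arg-23Thr", "A-23T") yields a negative
#'   (upstream) position; if `FALSE` it is read as a plain separator.
#' @param matrix_threshold Optional override of the substitution matrix's
#'   own plausibility threshold.
#' @return A `pp_config` list.
#' @export
#' @examples
#' pp_config(synonymous = FALSE)
pp_config <- function(lexicon = TRUE, non_informative = TRUE,
                      substitution_matrix = TRUE, synonymous = TRUE,
                      imbalanced_form = TRUE, special_symbol = TRUE,
                      for_preposition = TRUE,
                      minus_denotes_location = TRUE,
                      matrix_threshold = NULL) {
  structure(
    list(
      rules = c(
        lexicon = isTRUE(lexicon), non_informative = isTRUE(non_informative),
        substitution_matrix = isTRUE(substitution_matrix),
        synonymous = isTRUE(synonymous),
        imbalanced_form = isTRUE(imbalanced_form),
        special_symbol = isTRUE(special_symbol),
        for_preposition = isTRUE(for_preposition)
      ),
      minus_denotes_location = isTRUE(minus_denotes_location),
      matrix_threshold = matrix_threshold
    ),
    class = "pp_config"
  )
}

#' @rdname pp_config
#' @param path Path to a YAML file whose keys are `pp_config()` arguments.
#' @export
pp_config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "varminer_missing_resource")
  }
  do.call(pp_config, yaml::read_yaml(path))
}

.empty_log <- function() {
  tibble(doc_id = character(), rule_id = character(), action = character(),
         surface = character(), key_before = character(),
         key_after = character(), note = character())
}

.log_row <- function(doc_id, rule_id, action, surface, key_before, key_after,
                     note = "") {
  tibble(doc_id = doc_id %||% NA_character_, rule_id = rule_id,
         action = action, surface = surface,
         key_before = key_before %||% NA_character_,
         key_after = key_after %||% NA_character_, note = note)
}

# ---- corrections: rules 5, 6, 7 --------------------------------------------

#' Correct irregular mention forms (rules 5-7)
#'
#' Applies the three correction rules to each mention, in order:
#' imbalanced-form re-anchoring, special-symbol disambiguation, and
#' "for"-preposition inversion. Corrections modify or keep mentions; they
#' never create or remove them, so the output has exactly one row (and one
#' log entry) per input mention.
#'
#' @param mentions A mentions tibble as from [extract_mentions()], or any
#'   tibble with at least `doc_id`, `surface` and the normalized fields.
#' @param documents Optional documents tibble (`doc_id`, `text`); needed for
#'   rule 5 to look beyond the mention surface for the explicit change the
#'   spurious candidate should be re-anchored to.
#' @param config A [pp_config()].
#' @return A list with `mentions` (corrected tibble, same row count) and
#'   `log` (one outcome row per mention: `action` is `"modified"` or
#'   `"kept"`, `rule_id` names the rule that modified, `NA` if none did).
#' @export
#' @examples
#' m <- extract_mentions("the Arg-23-Thr substitution")
#' correct_forms(m)$mentions$key
correct_forms <- function(mentions, documents = NULL, config = pp_config()) {
  if (!nrow(mentions)) return(list(mentions = mentions, log = .empty_log()))
  mentions <- .ensure_mention_cols(mentions)
  texts <- NULL
  if (!is.null(documents)) {
    documents <- as_documents(documents)
    texts <- stats::setNames(documents$text, documents$doc_id)
  }
  rules_on <- config$rules
  out <- vector("list", nrow(mentions))
  logs <- vector("list", nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, ]
    key0 <- m$key
    applied <- character(0)

    if (rules_on[["imbalanced_form"]]) {
      r5 <- .rule5_imbalanced(m, texts, config)
      if (!is.null(r5)) { m <- r5; applied <- c(applied, "imbalanced_form") }
    }
    if (rules_on[["special_symbol"]]) {
      r6 <- .rule6_symbols(m, config)
      if (!is.null(r6)) { m <- r6; applied <- c(applied, "special_symbol") }
    }
    if (rules_on[["for_preposition"]]) {
      r7 <- .rule7_for(m, config)
      if (!is.null(r7)) { m <- r7; applied <- c(applied, "for_preposition") }
    }

    modified <- length(applied) > 0
    out[[i]] <- m
    logs[[i]] <- .log_row(
      m$doc_id, if (modified) applied[[1]] else NA_character_,
      if (modified) "modified" else "kept",
      m$surface, key0, m$key,
      note = if (modified) paste(applied, collapse = "+") else ""
    )
  }
  list(mentions = dplyr::bind_rows(out), log = dplyr::bind_rows(logs))
}

.ensure_mention_cols <- function(mentions) {
  need <- c(doc_id = NA_character_, surface = NA_character_,
            context_before = "", level = NA_character_, kind = NA_character_,
            wild = NA_character_, mutant = NA_character_,
            rs_id = NA_character_, key = NA_character_)
  for (nm in names(need)) {
    if (!nm %in% names(mentions)) mentions[[nm]] <- need[[nm]]
  }
  if (!"position" %in% names(mentions)) mentions$position <- NA_integer_
  if (!"informative" %in% names(mentions)) {
    mentions$informative <- !(is.na(mentions$kind) |
      (mentions$kind == "SUB" &
         (is.na(mentions$wild) | mentions$wild == "" |
          is.na(mentions$mutant) | mentions$mutant == "" |
          is.na(mentions$position))))
  }
  mentions
}

.set_fields <- function(m, v) {
  for (nm in c("level", "kind", "wild", "position", "mutant", "rs_id",
               "informative", "key")) {
    m[[nm]] <- v[[nm]]
  }
  m
}

.rx_explicit_change <- function() {
  paste0("(-?\\d+)\\s?(", .rx_base, ")\\s?", .rx_arrow, "\\s?(", .rx_base, ")")
}

# Rule 5: a wild-type token inconsistent with an adjacent explicit change,
# e.g. candidate "V 1691G" inside "factor V 1691G > A". Returns the
# re-anchored mention or NULL.
.rule5_imbalanced <- function(m, texts, config) {
  sus <- stringr::str_match(m$surface,
                            "^([A-Za-z]{1,3})[ .]\\s?(-?\\d+)\\s?([ACGTUacgtu])$")
  in_text <- !is.null(texts) && !is.na(m$doc_id) && m$doc_id %in% names(texts)
  hay <- if (in_text) texts[[m$doc_id]] else m$surface
  loc <- stringr::str_locate_all(hay, .rx_explicit_change())[[1]]
  if (!nrow(loc)) return(NULL)
  caps <- stringr::str_match_all(hay, .rx_explicit_change())[[1]]
  if (is.na(sus[1, 1])) {
    # surface itself may embed the explicit change (fragment input)
    idx <- which(!is.na(stringr::str_locate(m$surface, .rx_explicit_change())[, 1]))
    if (identical(hay, m$surface) && length(idx)) {
      g <- stringr::str_match(m$surface, .rx_explicit_change())
      v <- .mk_variant("dna", "SUB", .fold_u(g[[3]]), as.integer(g[[2]]),
                       .fold_u(g[[4]]))
      if (isTRUE(v$key != m$key) || is.na(m$key)) return(.set_fields(m, v))
    }
    return(NULL)
  }
  # choose the explicit change sharing the candidate's number
  hit <- which(caps[, 2] == sus[1, 3])
  if (!length(hit)) return(NULL)
  j <- hit[[1]]
  v <- .mk_variant("dna", "SUB", .fold_u(caps[j, 3]),
                   as.integer(caps[j, 2]), .fold_u(caps[j, 4]))
  if (!v$informative) return(NULL)
  m <- .set_fields(m, v)
  m$surface <- stringr::str_sub(hay, loc[j, 1], loc[j, 2])
  if (in_text && all(c("start", "end") %in% names(m))) {
    m$start <- loc[j, 1] - 1L
    m$end <- loc[j, 2]
  }
  m
}

# Rule 6: hyphen/minus/plus/asterisk between residue tokens.
.rule6_symbols <- function(m, config) {
  rx3 <- paste0("^(", .rx_aa3(), ")([-+*])(\\d+)(-?)(", .rx_aa3(), ")$")
  rx1 <- paste0("^(", .rx_aa1, ")([-+*])(\\d+)(-?)(", .rx_aa1, ")$")
  g <- stringr::str_match(m$surface, stringr::regex(rx3, ignore_case = TRUE))
  if (is.na(g[1, 1])) g <- stringr::str_match(m$surface, rx1)
  if (is.na(g[1, 1])) return(NULL)
  w <- tryCatch(aa_to_one(g[1, 2]), error = function(e) NA_character_)
  mu <- tryCatch(aa_to_one(g[1, 6]), error = function(e) NA_character_)
  if (is.na(w) || is.na(mu)) return(NULL)
  pos <- .sym_position(g[1, 3], g[1, 4], g[1, 5], config)
  v <- .mk_variant("protein", "SUB", w, pos, mu)
  if (!v$informative || identical(v$key, m$key)) return(NULL)
  .set_fields(m, v)
}

# Rule 7: "substitution of X for Y" means Y -> X (Y is the wild type).
.rule7_for <- function(m, config) {
  rx <- paste0("\\b(", .rx_res_nl(), ")\\s+for\\s+(?:an?\\s+)?(", .rx_res_nl(), ")\\b")
  g <- stringr::str_match(m$surface, stringr::regex(rx, ignore_case = TRUE))
  if (is.na(g[1, 1])) return(NULL)
  mutant <- tryCatch(aa_to_one(g[1, 2]), error = function(e) NA_character_)
  wild <- tryCatch(aa_to_one(g[1, 3]), error = function(e) NA_character_)
  if (is.na(mutant) || is.na(wild)) return(NULL)
  if (!is.na(m$kind) && !(m$kind %in% "SUB")) return(NULL)
  if (identical(m$wild, wild) && identical(m$mutant, mutant)) return(NULL)
  naive <- identical(m$wild, mutant) && identical(m$mutant, wild)
  absent <- is.na(m$wild) || m$wild == "" || is.na(m$mutant) || m$mutant == ""
  if (!naive && !absent) return(NULL)
  m$level <- if (is.na(m$level)) "protein" else m$level
  m$kind <- "SUB"
  m$wild <- wild
  m$mutant <- mutant
  m$rs_id <- ifelse(is.na(m$rs_id), "", m$rs_id)
  m$informative <- !is.na(m$position)
  m$key <- if (m$informative) canonical_key(m) else NA_character_
  m
}

# ---- filters: rules 1-4 -----------------------------------------------------

#' Filter false-positive mentions (rules 1-4)
#'
#' Applies, in order: the lexicon/decoy filter, the non-informative filter,
#' the substitution-matrix plausibility filter, and the synonymous-mutation
#' filter. Filters only remove mentions, never modify them; every input
#' mention receives exactly one outcome row in the log.
#'
#' @inheritParams correct_forms
#' @param lexicons A [lexicon_set()].
#' @param matrix A `substitution_matrix` (see
#'   [default_substitution_matrix()]).
#' @return A list with `mentions` (survivors) and `log`.
#' @export
#' @examples
#' m <- extract_mentions("T47D cells carry T790M but not L367L.")
#' filter_mentions(m)$mentions$surface
filter_mentions <- function(mentions, lexicons = default_lexicons(),
                            matrix = default_substitution_matrix(),
                            config = pp_config()) {
  if (!nrow(mentions)) return(list(mentions = mentions, log = .empty_log()))
  mentions <- .ensure_mention_cols(mentions)
  stopifnot(inherits(lexicons, "lexicon_set"),
            inherits(matrix, "substitution_matrix"))
  thr <- config$matrix_threshold %||% matrix$threshold
  rules_on <- config$rules
  n <- nrow(mentions)
  removed_by <- rep(NA_character_, n)
  note <- rep("", n)

  if (rules_on[["lexicon"]]) {
    hit <- .lexicon_hit(mentions$surface, mentions$context_before, lexicons)
    removed_by[is.na(removed_by) & hit] <- "lexicon"
  }
  if (rules_on[["non_informative"]]) {
    hit <- !mentions$informative
    removed_by[is.na(removed_by) & hit] <- "non_informative"
  }
  if (rules_on[["substitution_matrix"]]) {
    prot_sub <- mentions$informative & mentions$level %in% "protein" &
      mentions$kind %in% "SUB"
    sc <- rep(NA_real_, n)
    sc[prot_sub] <- matrix_score(matrix, mentions$wild[prot_sub],
                                 mentions$mutant[prot_sub])
    hit <- prot_sub & !is.na(sc) & sc < thr
    newly <- is.na(removed_by) & hit
    removed_by[newly] <- "substitution_matrix"
    note[newly] <- paste0("score ", sc[newly], " < ", thr)
  }
  if (rules_on[["synonymous"]]) {
    hit <- mentions$informative & mentions$kind %in% "SUB" &
      mentions$wild == mentions$mutant
    removed_by[is.na(removed_by) & hit] <- "synonymous"
  }

  log <- .log_row(
    mentions$doc_id, removed_by,
    ifelse(is.na(removed_by), "kept", "removed"),
    mentions$surface, mentions$key,
    ifelse(is.na(removed_by), mentions$key, NA_character_),
    note
  )
  list(mentions = mentions[is.na(removed_by), , drop = FALSE], log = log)
}

# ---- answer-set level post-processing --------------------------------------

.reconstruct_surface <- function(a) {
  first_surface <- purrr::map_chr(strsplit(a$surfaces, ";", fixed = TRUE),
                                  ~ if (length(.x)) .x[[1]] else "")
  fallback <- ifelse(
    a$kind == "SUB" & a$wild != "" & a$mutant != "" & !is.na(a$position),
    paste0(a$wild, a$position, a$mutant),
    ifelse(a$kind == "SNP", a$rs_id, a$key)
  )
  ifelse(nzchar(first_surface), first_surface, fallback)
}

#' Post-process a whole answer set
#'
#' Runs the correction rules (5-7) and then the filter rules (1-4) over
#' every row of an answer set, so the corrected forms — not the raw ones —
#' are what the filters judge. Rows carry their stored surfaces through the
#' rules; rows without stored surfaces are judged on a surface
#' reconstructed from the normalized fields (e.g. `T47D` for a claimed
#' T47D substitution), which is what lets the lexicon filter catch
#' cell-line and platform names that arrived as "variants".
#'
#' @param answers An `answer_set` (or coercible data frame).
#' @inheritParams filter_mentions
#' @param documents Optional documents tibble for rule 5 context.
#' @return A list with `answers` (the surviving, possibly corrected
#'   `answer_set`) and `log` (ordered outcome rows from every rule).
#' @export
#' @examples
#' a <- answerset_from_keys("d1", c("p|SUB|P|286|A", "p|SUB|L|367|L"))
#' postprocess_answerset(a)$answers$key
postprocess_answerset <- function(answers, lexicons = default_lexicons(),
                                  matrix = default_substitution_matrix(),
                                  config = pp_config(), documents = NULL) {
  a <- as_answerset(answers)
  if (!nrow(a)) return(list(answers = a, log = .empty_log()))
  pseudo <- a |>
    dplyr::mutate(
      surface = .reconstruct_surface(a),
      context_before = "",
      informative = !(.data$kind == "SUB" &
                        (.data$wild == "" | .data$mutant == "" |
                           is.na(.data$position))),
      key = ifelse(.data$informative, .data$key, NA_character_)
    )
  corrected <- correct_forms(pseudo, documents = documents, config = config)
  filtered <- filter_mentions(corrected$mentions, lexicons = lexicons,
                              matrix = matrix, config = config)
  surv <- filtered$mentions
  out <- if (nrow(surv)) {
    surv |>
      dplyr::group_by(.data$doc_id, .data$key) |>
      dplyr::summarise(
        dplyr::across(c("level", "kind", "wild", "position", "mutant",
                        "rs_id", "source"), dplyr::first),
        multiplicity = sum(.data$multiplicity),
        surfaces = paste(setdiff(unique(unlist(
          strsplit(.data$surfaces, ";", fixed = TRUE))), ""), collapse = ";"),
        .groups = "drop"
      ) |>
      dplyr::select(-"key") |>
      as_answerset()
  } else {
    empty_answerset()
  }
  list(answers = out, log = dplyr::bind_rows(corrected$log, filtered$log))
}

#' Extract, correct and filter in one call
#'
#' Convenience pipeline: [extract_mentions()], then [correct_forms()], then
#' [filter_mentions()], collapsed to an answer set via
#' [mentions_to_answerset()]. The full rule-outcome log is attached as the
#' `"log"` attribute.
#'
#' @inheritParams extract_mentions
#' @inheritParams filter_mentions
#' @param source Extractor tag recorded in the answer set.
#' @return An `answer_set`.
#' @export
#' @examples
#' extract_variants("T47D cells carry the T790M mutation.")
extract_variants <- function(documents, catalogue = pattern_catalogue(),
                             lexicons = default_lexicons(),
                             matrix = default_substitution_matrix(),
                             config = pp_config(), source = "varminer") {
  docs <- as_documents(documents)
  mentions <- extract_mentions(docs, catalogue = catalogue, config = config)
  corrected <- correct_forms(mentions, documents = docs, config = config)
  filtered <- filter_mentions(corrected$mentions, lexicons = lexicons,
                              matrix = matrix, config = config)
  out <- mentions_to_answerset(filtered$mentions, source = source)
  attr(out, "log") <- dplyr::bind_rows(corrected$log, filtered$log)
  out
}
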