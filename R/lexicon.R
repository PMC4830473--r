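#' Read a lexicon file
#'
#' One entry per line, UTF-8, `#` comments and blank lines ignored.
#'
#' @param path Path to a plain-text lexicon file.
#' @return Character vector of entries.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("lexicon file not found: ", path),
          class = "varminer_missing_resource")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- stringr::str_squish(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Lexicons and decoy patterns for false-positive filtering
#'
#' A `lexicon_set` powers post-processing rule 1: mentions whose surface
#' matches a known cell-line name, gene symbol or platform name — or a decoy
#' pattern such as a supplementary-figure label — are removed as false
#' positives. Lookup is case-insensitive after whitespace normalization.
#'
#' `default_lexicons()` loads the seed lists bundled with the package
#' (mutation-like cell lines such as T47D, platform names such as U133A, a
#' small gene-symbol seed) plus the figure-label decoy pattern. Full-scale
#' lists (e.g. HUGO) are user-pluggable via [read_lexicon()].
#'
#' @param cell_lines,gene_symbols,platform_names Character vectors.
#' @param decoy_patterns A data frame with columns `name`,
#'   `surface_pattern` (regex the mention surface must match) and
#'   `context_pattern` (regex the text immediately before the mention must
#'   match; `NA` for no context requirement).
#' @return A `lexicon_set` object.
#' @export
#' @examples
#' lex <- default_lexicons()
#' length(lex$cell_lines)
lexicon_set <- function(cell_lines = character(), gene_symbols = character(),
                        platform_names = character(),
                        decoy_patterns = default_decoy_patterns()) {
  stopifnot(is.data.frame(decoy_patterns),
            all(c("name", "surface_pattern", "context_pattern") %in% names(decoy_patterns)))
  structure(
    list(cell_lines = cell_lines, gene_symbols = gene_symbols,
         platform_names = platform_names,
         decoy_patterns = as_tibble(decoy_patterns)),
    class = "lexicon_set"
  )
}

#' @rdname lexicon_set
#' @export
default_lexicons <- function() {
  dir <- system.file("extdata", "lexicons", package = "varminer", mustWork = TRUE)
  lexicon_set(
    cell_lines = read_lexicon(file.path(dir, "cell_lines.txt")),
    gene_symbols = read_lexicon(file.path(dir, "gene_symbols.txt")),
    platform_names = read_lexicon(file.path(dir, "platform_names.txt"))
  )
}

#' @rdname lexicon_set
#' @export
default_decoy_patterns <- function() {
  tibble::tribble(
    ~name, ~surface_pattern, ~context_pattern,
    # "S13A" is only a decoy when preceded by a figure reference
    "figure_label", "^S\\d+[A-Z]$", "(?i)fig(\\.|ure)?\\s*$",
    # full figure labels arriving as answer-set surfaces
    "figure_label_inline", "(?i)^(supplementary\\s+)?fig(\\.|ure)?\\s*S?\\d+[A-Z]$", NA
  )
}

#' @export
print.lexicon_set <- function(x, ...) {
  cat("<lexicon_set> ",
      length(x$cell_lines), " cell lines, ",
      length(x$gene_symbols), " gene symbols, ",
      length(x$platform_names), " platform names, ",
      nrow(x$decoy_patterns), " decoy patterns\n", sep = "")
  invisible(x)
}

# whitespace-insensitive, case-insensitive comparison key
.norm_entry <- function(x) toupper(gsub("\\s+", "", x))

.lexicon_hit <- function(surface, context_before, lex) {
  stopifnot(inherits(lex, "lexicon_set"))
  entries <- .norm_entry(c(lex$cell_lines, lex$gene_symbols, lex$platform_names))
  hit <- .norm_entry(surface) %in% entries
  ctx <- ifelse(is.na(context_before), "", context_before)
  for (i in seq_len(nrow(lex$decoy_patterns))) {
    p <- lex$decoy_patterns[i, ]
    m <- stringr::str_detect(surface, p$surface_pattern)
    if (!is.na(p$context_pattern)) {
      m <- m & stringr::str_detect(ctx, p$context_pattern)
    }
    hit <- hit | m
  }
  hit
}
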