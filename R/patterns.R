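# Regex building blocks for the mention pattern catalogue.
# Arrows cover the glyph variants seen in published text (en-dash arrows,
# "-->", unicode arrows) in addition to plain ">".
.rx_arrow <- "(?:–≥|−≥|–>|-->|->|=>|⇒|→|>|≥)"
.rx_aa1 <- "[ACDEFGHIKLMNPQRSTVWY]"
.rx_base <- "[ACGTU]"

.rx_aa3 <- function() {
  paste0("(?:", paste(sort(unique(.aa_table$three)), collapse = "|"), ")")
}

# full names and three-letter codes, longest-first so "aspartic acid" wins
# over "aspartate" prefixes etc.
.rx_res_nl <- function() {
  toks <- unique(c(.aa_table$name, .aa_table$three))
  toks <- toks[order(-nchar(toks))]
  paste0("(?:", paste(gsub(" ", "\\\\s+", toks), collapse = "|"), ")")
}

.rx_poshead <- "(?:amino\\s+acid|amino-acid|position|codon|residue|nucleotide)"
.rx_change_word <- "(?:transition|transversion|substitution|polymorphism|mutation|change)"
.rx_base_sep <- function() paste0("(?:-to-|\\s+to\\s+|\\s?", .rx_arrow, "\\s?)")

#' The mention pattern catalogue
#'
#' An ordered table of named regular expressions covering the supported
#' surface forms of variant mentions: compact and three-letter wNm
#' substitutions (`T790M`, `Thr790Met`, hyphen/plus/asterisk variants),
#' HGVS-style `c.`/`p.` notations, natural-language descriptions
#' ("substitution of alanine for proline at amino acid 286"), nucleotide
#' changes ("G>A polymorphism at nucleotide 5557", "1691G > A"), codon
#' changes ("A to G transition at codon 557 (AAG>GAG)"), dbSNP identifiers,
#' and explicit deletion/insertion/frameshift keyword forms. Row order
#' defines priority when two matches of equal length compete; on overlap the
#' longest match always wins.
#'
#' Users may extend the catalogue by appending rows (a `name`, a `form`
#' category, a `pattern`, whether matching is `case_insensitive`, and the
#' `parser` used for normalization — one of the parser ids in the default
#' table) and passing the result to [extract_mentions()].
#'
#' @return A tibble with columns `name`, `form`, `pattern`,
#'   `case_insensitive`, `parser`, `priority`.
#' @export
#' @examples
#' pattern_catalogue()[, c("name", "form")]
pattern_catalogue <- function() {
  aa3 <- .rx_aa3(); res <- .rx_res_nl(); sep <- .rx_base_sep()
  arrow <- .rx_arrow; b <- .rx_base; a1 <- .rx_aa1
  cat <- tibble::tribble(
    ~name, ~form, ~pattern, ~case_insensitive, ~parser,

    "dbsnp_rs", "dbsnp_id", "\\brs\\d+\\b", FALSE, "dbsnp",

    "hgvs_c_number_first", "nucleotide_change",
    paste0("\\bc\\.(-?\\d+)\\s?(", b, ")\\s?", arrow, "\\s?(", b, ")"),
    FALSE, "num_mid_change",

    "hgvs_c_letter_first", "nucleotide_change",
    paste0("\\bc\\.(", b, ")(-?\\d+)(", b, ")\\b"), FALSE, "letter_first_nt",

    "hgvs_p", "wnm_long",
    paste0("\\bp\\.((?:", aa3, ")|", a1, ")(-?\\d+)((?:", aa3, ")|", a1, ")\\b"),
    FALSE, "hgvs_p",

    "codon_change_full", "codon_change",
    paste0("\\b(", b, ")", sep, "(", b, ")\\s+", .rx_change_word,
           "\\s+at\\s+codon\\s+(\\d+)\\s*\\(\\s*(", b, "{3})\\s*", arrow,
           "\\s*(", b, "{3})\\s*\\)"),
    FALSE, "codon_full",

    "base_change_at_codon", "codon_change",
    paste0("\\b(", b, ")", sep, "(", b, ")\\s+", .rx_change_word,
           "\\s+at\\s+codon\\s+(\\d+)\\b"),
    FALSE, "base_at_codon",

    "codon_pair", "codon_change",
    paste0("\\b(", b, "{3})\\s?", arrow, "\\s?(", b, "{3})\\b"),
    FALSE, "codon_pair",

    "nucleotide_change_at", "nucleotide_change",
    paste0("\\b(", b, ")", sep, "(", b, ")(?:\\s+", .rx_change_word, ")?",
           "\\s+at\\s+(?:nucleotide|nt|position)\\s+(-?\\d+)\\b"),
    FALSE, "base_change_at",

    "base_change_bare", "nucleotide_change",
    paste0("\\b(", b, ")", sep, "(", b, ")\\s+", .rx_change_word, "\\b"),
    FALSE, "base_bare",

    "nucleotide_number_first", "nucleotide_change",
    paste0("\\b(-?\\d+)\\s?(", b, ")\\s?", arrow, "\\s?(", b, ")\\b"),
    FALSE, "num_first_change",

    "nl_substitution_for", "natural_language",
    paste0("\\bsubstitutions?\\s+of\\s+(?:an?\\s+)?(", res, ")\\s+for\\s+(?:an?\\s+)?(", res, ")",
           "(?:\\s+at\\s+", .rx_poshead, "\\s+(\\d+))?"),
    TRUE, "nl_sub_for",

    "nl_substituted_with", "natural_language",
    paste0("\\b(", res, ")\\s+(\\d+)\\s+(?:is\\s+|was\\s+)?substituted\\s+(?:with|by)\\s+(", res, ")\\b"),
    TRUE, "nl_wild_pos_mut",

    "nl_replacement", "natural_language",
    paste0("\\breplacements?\\s+of\\s+(?:an?\\s+)?(", res, ")\\s+(?:by|with)\\s+(?:an?\\s+)?(", res, ")",
           "(?:\\s+at\\s+", .rx_poshead, "\\s+(\\d+))?"),
    TRUE, "nl_wild_mut_pos",

    "nl_mutated", "natural_language",
    paste0("\\b(", res, ")\\s+(\\d+)\\s+(?:is|was)\\s+mutated\\b"),
    TRUE, "nl_noninformative",

    "wnm_three_letter", "wnm_long",
    paste0("\\b(", aa3, ")([-+*]?)(-?\\d+)(-?)(", aa3, ")\\b"),
    TRUE, "wnm3",

    # deliberately wider than the residue alphabet: mutation-like strings such
    # as U133A are matched (as real extractors do) and then either rejected as
    # non-informative or removed by the lexicon filter
    "wnm_one_letter_symbol", "wnm_short",
    "\\b([A-Z])([-+*])(\\d+)(-?)([A-Z])\\b", FALSE, "wnm1_sym",

    "wnm_one_letter", "wnm_short",
    "\\b([A-Z])(\\d+)([A-Z])\\b", FALSE, "wnm1",

    "deletion_suffix", "deletion",
    paste0("\\b(", a1, ")(\\d+)del\\b"), FALSE, "del_res_pos",

    "deletion_prefix", "deletion",
    paste0("\\bdel(", a1, ")(\\d+)\\b"), FALSE, "del_res_pos",

    "insertion", "insertion",
    paste0("\\b(", a1, ")(\\d+)ins[A-Z]*\\b"), FALSE, "ins_res_pos",

    "frameshift", "frameshift",
    paste0("\\b(", a1, ")(\\d+)fs(?:\\*?\\d*)?\\b"), FALSE, "fs_res_pos"
  )
  cat$priority <- seq_len(nrow(cat))
  cat
}
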