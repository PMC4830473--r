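#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# The 20 standard residues: full name, three-letter code, one-letter code.
# Selenocysteine and pyrrolysine are deliberately excluded: they do not occur
# in PAM-family matrices and essentially never in variant mentions.
.aa_table <- tibble::tribble(
  ~name,           ~three, ~one,
  "alanine",        "Ala",  "A",
  "arginine",       "Arg",  "R",
  "asparagine",     "Asn",  "N",
  "aspartic acid",  "Asp",  "D",
  "aspartate",      "Asp",  "D",
  "cysteine",       "Cys",  "C",
  "glutamic acid",  "Glu",  "E",
  "glutamate",      "Glu",  "E",
  "glutamine",      "Gln",  "Q",
  "glycine",        "Gly",  "G",
  "histidine",      "His",  "H",
  "isoleucine",     "Ile",  "I",
  "leucine",        "Leu",  "L",
  "lysine",         "Lys",  "K",
  "methionine",     "Met",  "M",
  "phenylalanine",  "Phe",  "F",
  "proline",        "Pro",  "P",
  "serine",         "Ser",  "S",
  "threonine",      "Thr",  "T",
  "tryptophan",     "Trp",  "W",
  "tyrosine",       "Tyr",  "Y",
  "valine",         "Val",  "V"
)

#' Standard residue and nucleotide alphabets
#'
#' `residue_alphabet()` returns the 20 one-letter amino-acid codes;
#' `nucleotide_alphabet()` returns the DNA/RNA bases (U is folded to T
#' throughout the package).
#'
#' @return A character vector of one-letter codes.
#' @export
#' @examples
#' residue_alphabet()
residue_alphabet <- function() sort(unique(.aa_table$one))

#' @rdname residue_alphabet
#' @export
nucleotide_alphabet <- function() c("A", "C", "G", "T", "U")

# lookup vector: lowercase token -> one-letter code
.aa_lookup <- local({
  tab <- .aa_table
  keys <- c(tolower(tab$name), tolower(tab$three), tolower(tab$one))
  vals <- c(tab$one, tab$one, tab$one)
  v <- vals[!duplicated(keys)]
  names(v) <- keys[!duplicated(keys)]
  v
})

#' Convert a residue token to its one-letter code
#'
#' Accepts one-letter codes, three-letter codes ("Thr") and full English
#' names ("threonine", "aspartic acid"), case-insensitively, so that variant
#' mentions such as T790M, Thr790Met and "threonine 790 substituted with
#' methionine" co-normalize to the same wild-type and mutant symbols.
#'
#' @param token Character vector of residue tokens.
#' @return Character vector of uppercase one-letter codes.
#' @export
#' @examples
#' aa_to_one(c("Thr", "aspartic acid", "T"))
aa_to_one <- function(token) {
  if (length(token) == 0) return(character(0))
  key <- tolower(stringr::str_squish(as.character(token)))
  out <- unname(.aa_lookup[key])
  if (anyNA(out) || any(key == "")) {
    bad <- unique(token[is.na(out) | key == ""])
    abort(
      paste0("unknown residue token(s): ", paste(sQuote(bad), collapse = ", ")),
      class = "varminer_unknown_residue"
    )
  }
  out
}

#' Translate a codon with the standard genetic code
#'
#' @param codon Character vector of three-letter codons over A/C/G/T/U
#'   (case-insensitive; U is treated as T). Stop codons translate to `"*"`.
#' @return Character vector of one-letter residue codes (or `"*"`).
#' @export
#' @examples
#' translate_codon(c("AAG", "GAG", "TAA"))
translate_codon <- function(codon) {
  if (length(codon) == 0) return(character(0))
  cd <- chartr("Uu", "Tt", toupper(as.character(codon)))
  ok <- stringr::str_detect(cd, "^[ACGT]{3}$")
  if (!all(ok %in% TRUE)) {
    abort(
      paste0("invalid codon(s): ", paste(sQuote(codon[!ok %in% TRUE]), collapse = ", ")),
      class = "varminer_invalid_codon"
    )
  }
  unname(.genetic_code()[cd])
}

.genetic_code_cache <- new.env(parent = emptyenv())
.genetic_code <- function() {
  if (is.null(.genetic_code_cache$gc)) {
    .genetic_code_cache$gc <- Biostrings::GENETIC_CODE
  }
  .genetic_code_cache$gc
}

# ---- canonical variant keys -------------------------------------------------

.levels <- c(protein = "p", dna = "c", rna = "r")
.kinds <- c("SUB", "DEL", "INS", "INDEL", "DUP", "FS", "SNP")

#' Build a normalized variant record
#'
#' One row per variant in the canonical wild-type / position / mutant (wNm)
#' representation that every downstream module (post-processing, ensembles,
#' scoring) keys on. Substitutions require all three of wild, position and
#' mutant; dbSNP identifiers may stand alone.
#'
#' @param level `"protein"`, `"dna"` or `"rna"`.
#' @param kind One of `"SUB"`, `"DEL"`, `"INS"`, `"INDEL"`, `"DUP"`, `"FS"`,
#'   `"SNP"`.
#' @param wild,mutant Uppercase one-letter residue (protein level) or base
#'   (nucleic levels), or `""` where inapplicable.
#' @param position Integer position; may be negative under the
#'   minus-denotes-location convention; `NA` for bare dbSNP identifiers.
#' @param rs_id dbSNP identifier (e.g. `"rs121434569"`) or `""`.
#' @return A one-row tibble with columns `level`, `kind`, `wild`, `position`,
#'   `mutant`, `rs_id` and the derived `key`.
#' @export
#' @examples
#' variant("protein", "SUB", "T", 790, "M")
variant <- function(level, kind, wild = "", position = NA_integer_,
                    mutant = "", rs_id = "") {
  v <- tibble(
    level = as.character(level), kind = as.character(kind),
    wild = as.character(wild), position = as.integer(position),
    mutant = as.character(mutant), rs_id = as.character(rs_id)
  )
  validate_variants(v)
  v$key <- canonical_key(v)
  v
}

validate_variants <- function(v) {
  stopifnot(all(v$level %in% names(.levels)), all(v$kind %in% .kinds))
  alpha_ok <- function(x, level) {
    x == "" |
      (level == "protein" & x %in% residue_alphabet()) |
      (level != "protein" & x %in% c("A", "C", "G", "T", "U"))
  }
  if (!all(alpha_ok(v$wild, v$level) & alpha_ok(v$mutant, v$level))) {
    abort("wild/mutant must be single uppercase codes from the level's alphabet",
          class = "varminer_invalid_variant")
  }
  sub <- v$kind == "SUB"
  if (any(sub & (v$wild == "" | v$mutant == "" | is.na(v$position)))) {
    abort("kind SUB requires non-empty wild, mutant and position",
          class = "varminer_invalid_variant")
  }
  snp <- v$kind == "SNP"
  if (any(snp & v$rs_id == "")) {
    abort("kind SNP requires an rs_id", class = "varminer_invalid_variant")
  }
  invisible(v)
}

#' Canonical pipe-delimited key for a normalized variant
#'
#' Serializes variants as `level|kind|wild|position|mutant` (with the rs
#' identifier appended for SNP kind), e.g. `p|SUB|P|286|A` or
#' `c|SUB|G|5557|A`. Keys are deterministic, level-aware and lossless:
#' [parse_canonical_key()] inverts them exactly, and distinct variant field
#' tuples always yield distinct keys.
#'
#' @param v A data frame with columns `level`, `kind`, `wild`, `position`,
#'   `mutant`, `rs_id` (as from [variant()]).
#' @return Character vector of keys, one per row.
#' @export
#' @examples
#' canonical_key(variant("protein", "SUB", "P", 286, "A"))
canonical_key <- function(v) {
  pos <- as.character(v$position)
  pos[is.na(pos)] <- ""
  key <- paste(.levels[v$level], v$kind, v$wild, pos, v$mutant, sep = "|")
  snp <- which(v$kind == "SNP")
  key[snp] <- paste(key[snp], v$rs_id[snp], sep = "|")
  key
}

#' @rdname canonical_key
#' @param key Character vector of canonical keys.
#' @export
parse_canonical_key <- function(key) {
  parts <- stringr::str_split(key, stringr::fixed("|"))
  rows <- purrr::map(parts, function(p) {
    if (length(p) < 5) abort(paste0("malformed canonical key: ", sQuote(paste(p, collapse = "|"))),
                             class = "varminer_bad_key")
    lev <- names(.levels)[match(p[[1]], .levels)]
    if (is.na(lev) || !(p[[2]] %in% .kinds)) {
      abort(paste0("malformed canonical key: ", sQuote(paste(p, collapse = "|"))),
            class = "varminer_bad_key")
    }
    tibble(
      level = lev, kind = p[[2]], wild = p[[3]],
      position = if (p[[4]] == "") NA_integer_ else as.integer(p[[4]]),
      mutant = p[[5]],
      rs_id = if (length(p) >= 6) p[[6]] else ""
    )
  })
  out <- dplyr::bind_rows(rows)
  out$key <- canonical_key(out)
  out
}

# ---- substitution matrices --------------------------------------------------

new_substitution_matrix <- function(name, scores, threshold) {
  aa <- residue_alphabet()
  stopifnot(is.matrix(scores), all(aa %in% rownames(scores)), all(aa %in% colnames(scores)))
  scores <- scores[aa, aa]
  storage.mode(scores) <- "double"
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("substitution matrix has missing or non-finite entries",
          class = "varminer_bad_matrix")
  }
  structure(list(name = name, scores = scores, threshold = threshold),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> ", x$name,
      " (20 x 20, plausibility threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Substitution matrices for plausibility filtering
#'
#' `default_substitution_matrix()` returns the PAM120 log-odds matrix
#' (the canonical point-accepted-mutation family member bundled with
#' Biostrings) restricted to the 20 standard residues, together with the
#' default plausibility threshold: protein substitutions scoring strictly
#' below the threshold are considered unlikely to occur and are removed by
#' post-processing rule 3. `read_substitution_matrix()` reads any PAM/BLOSUM
#' style matrix from an NCBI-style whitespace-delimited square table with a
#' header row and column of one-letter codes, so the filter is pluggable.
#'
#' @param threshold Numeric cutoff; substitutions with score `< threshold`
#'   are flagged implausible. The default (-4) keeps all conservative and
#'   moderately radical substitutions (e.g. P/A, D/N, K/E, M/R, T/M all
#'   score -1 or better in PAM120) and removes only strongly disfavoured
#'   exchanges such as W/G.
#' @return A `substitution_matrix` object: list with `name`, 20x20 numeric
#'   `scores`, and `threshold`.
#' @export
#' @examples
#' m <- default_substitution_matrix()
#' matrix_score(m, "L", "I")
default_substitution_matrix <- function(threshold = -4) {
  env <- new.env(parent = emptyenv())
  utils::data("PAM120", package = "Biostrings", envir = env)
  new_substitution_matrix("PAM120", env$PAM120, threshold)
}

#' @rdname default_substitution_matrix
#' @param path Path to a whitespace-delimited square matrix file.
#' @param name Matrix name; defaults to the file stem.
#' @export
read_substitution_matrix <- function(path, threshold = -4, name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("substitution matrix file not found: ", path),
          class = "varminer_missing_resource")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!stringr::str_detect(lines, "^\\s*(#|$)")]
  header <- stringr::str_split_1(stringr::str_squish(lines[[1]]), " ")
  body <- purrr::map(lines[-1], ~ stringr::str_split_1(stringr::str_squish(.x), " "))
  rn <- purrr::map_chr(body, 1)
  vals <- purrr::map(body, ~ as.numeric(.x[-1]))
  m <- do.call(rbind, vals)
  rownames(m) <- rn
  colnames(m) <- header
  new_substitution_matrix(name %||% sub("\\.[^.]*$", "", basename(path)), m, threshold)
}

#' Look up a substitution score
#'
#' Pure lookup of the log-odds score for replacing `wild` by `mutant`.
#'
#' @param m A `substitution_matrix`.
#' @param wild,mutant One-letter residue codes (vectorized, recycled).
#' @return Numeric score vector.
#' @export
matrix_score <- function(m, wild, mutant) {
  stopifnot(inherits(m, "substitution_matrix"))
  aa <- residue_alphabet()
  if (!all(wild %in% aa) || !all(mutant %in% aa)) {
    bad <- setdiff(unique(c(wild, mutant)), aa)
    abort(paste0("residue(s) outside the 20-letter alphabet: ",
                 paste(sQuote(bad), collapse = ", ")),
          class = "varminer_unknown_residue")
  }
  m$scores[cbind(wild, mutant)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
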