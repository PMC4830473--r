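#' Specification for a synthetic corpus
#'
#' Describes a seeded synthetic corpus of short documents embedding variant
#' mentions (realized in randomly chosen catalogued surface forms) among
#' decoy entities: mutation-like cell-line names, microarray platform
#' names, supplementary-figure labels and chemical formulae. Generation is
#' a pure function of the seed, and the generator returns the exact gold
#' annotations it embedded, so every pipeline stage can be tested without
#' external corpora.
#'
#' @param seed Integer seed.
#' @param n_docs Number of documents.
#' @param variants_per_doc Length-2 integer vector `c(min, max)`.
#' @param form_mix Named non-negative weights over the surface-form
#'   categories `wnm_short`, `wnm_long`, `natural_language`,
#'   `nucleotide_change`, `codon_change`, `dbsnp_id`, `deletion`,
#'   `frameshift`. The default mix is substitution-heavy, mirroring the
#'   observed dominance of point substitutions in variant-centric corpora.
#' @param decoy_rate Expected number of decoys per document (Poisson).
#' @param duplicate_mention_rate Probability that a variant is mentioned a
#'   second time in its document.
#' @param synonymous_rate,implausible_rate Rates at which synonymous
#'   (L367L-style) and matrix-implausible substitutions are injected, to
#'   exercise post-processing rules 4 and 3. Injected mentions are *not*
#'   part of the gold annotations.
#' @return A `corpus_spec` object.
#' @export
#' @examples
#' corpus_spec(seed = 7, n_docs = 5)
corpus_spec <- function(seed = 1L, n_docs = 20L,
                        variants_per_doc = c(1L, 3L),
                        form_mix = c(wnm_short = 0.25, wnm_long = 0.20,
                                     natural_language = 0.20,
                                     nucleotide_change = 0.15,
                                     codon_change = 0.10, dbsnp_id = 0.05,
                                     deletion = 0.03, frameshift = 0.02),
                        decoy_rate = 1, duplicate_mention_rate = 0.15,
                        synonymous_rate = 0, implausible_rate = 0) {
  forms <- c("wnm_short", "wnm_long", "natural_language", "nucleotide_change",
             "codon_change", "dbsnp_id", "deletion", "frameshift")
  mix <- stats::setNames(rep(0, length(forms)), forms)
  if (is.null(names(form_mix)) || !all(names(form_mix) %in% forms)) {
    abort("form_mix must be named with known form categories",
          class = "varminer_bad_spec")
  }
  mix[names(form_mix)] <- form_mix
  if (any(mix < 0) || sum(mix) <= 0) {
    abort("form_mix weights must be non-negative with a positive sum",
          class = "varminer_bad_spec")
  }
  stopifnot(length(variants_per_doc) == 2, variants_per_doc[1] >= 0,
            variants_per_doc[2] >= variants_per_doc[1],
            n_docs >= 0, decoy_rate >= 0,
            duplicate_mention_rate >= 0, duplicate_mention_rate <= 1)
  structure(
    list(seed = as.integer(seed), n_docs = as.integer(n_docs),
         variants_per_doc = as.integer(variants_per_doc),
         form_mix = mix / sum(mix), decoy_rate = decoy_rate,
         duplicate_mention_rate = duplicate_mention_rate,
         synonymous_rate = synonymous_rate,
         implausible_rate = implausible_rate),
    class = "corpus_spec"
  )
}

# sample() that never treats a length-1 vector as 1:n
.resample <- function(x, n) x[sample.int(length(x), n)]

# plausible substitution pairs under the default matrix, cached
.plausible_pairs <- function(matrix, plausible = TRUE) {
  aa <- residue_alphabet()
  grid <- expand.grid(w = aa, m = aa, stringsAsFactors = FALSE)
  grid <- grid[grid$w != grid$m, ]
  sc <- matrix_score(matrix, grid$w, grid$m)
  if (plausible) grid[sc >= matrix$threshold, ] else grid[sc < matrix$threshold, ]
}

.arrows <- c(">", " > ", "–≥", "->", "–>")

.realize_variant <- function(form, matrix, lex_norm, config) {
  aa <- residue_alphabet()
  pos <- sample(1:2000, 1)
  pick_pair <- function() {
    pairs <- .plausible_pairs(matrix)
    pairs[sample(nrow(pairs), 1), ]
  }
  arrow <- sample(.arrows, 1)
  if (form == "wnm_short") {
    repeat {
      p <- pick_pair()
      surface <- paste0(p$w, pos, p$m)
      if (!(.norm_entry(surface) %in% lex_norm)) break
      pos <- sample(1:2000, 1)
    }
    list(surface = surface, v = variant("protein", "SUB", p$w, pos, p$m))
  } else if (form == "wnm_long") {
    p <- pick_pair()
    three <- function(x) .aa_table$three[match(x, .aa_table$one)]
    list(surface = paste0(three(p$w), pos, three(p$m)),
         v = variant("protein", "SUB", p$w, pos, p$m))
  } else if (form == "natural_language") {
    p <- pick_pair()
    nm <- function(x) .aa_table$name[match(x, .aa_table$one)]
    tpl <- sample(3, 1)
    surface <- switch(
      tpl,
      paste0("substitution of ", nm(p$m), " for ", nm(p$w),
             " at amino acid ", pos),
      paste0(nm(p$w), " ", pos, " substituted with ", nm(p$m)),
      paste0("replacement of ", nm(p$w), " by ", nm(p$m), " at codon ", pos)
    )
    list(surface = surface, v = variant("protein", "SUB", p$w, pos, p$m))
  } else if (form == "nucleotide_change") {
    b <- sample(c("A", "C", "G", "T"), 2)
    tpl <- sample(3, 1)
    surface <- switch(
      tpl,
      paste0(b[1], arrow, b[2], " polymorphism at nucleotide ", pos),
      paste0(pos, b[1], " ", trimws(arrow), " ", b[2]),
      paste0("c.", pos, b[1], ">", b[2])
    )
    list(surface = surface, v = variant("dna", "SUB", b[1], pos, b[2]))
  } else if (form == "codon_change") {
    repeat {
      c1 <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      i <- sample(3, 1)
      bases <- setdiff(c("A", "C", "G", "T"), substr(c1, i, i))
      c2 <- c1
      substr(c2, i, i) <- sample(bases, 1)
      w <- translate_codon(c1); m <- translate_codon(c2)
      if (w != "*" && m != "*" && w != m &&
          matrix_score(matrix, w, m) >= matrix$threshold) break
    }
    surface <- paste0(substr(c1, i, i), " to ", substr(c2, i, i),
                      " transition at codon ", pos, " (", c1, "–≥", c2, ")")
    list(surface = surface, v = variant("protein", "SUB", w, pos, m))
  } else if (form == "dbsnp_id") {
    rs <- paste0("rs", sample.int(8999999L, 1) + 1000000L)
    list(surface = rs, v = variant("dna", "SNP", rs_id = rs))
  } else if (form == "deletion") {
    w <- sample(aa, 1)
    list(surface = paste0(w, pos, "del"),
         v = variant("protein", "DEL", w, pos))
  } else if (form == "frameshift") {
    w <- sample(aa, 1)
    list(surface = paste0(w, pos, "fs"),
         v = variant("protein", "FS", w, pos))
  } else {
    abort(paste0("unknown form: ", form), class = "varminer_bad_spec")
  }
}

.variant_sentences <- c(
  "We identified the %s variant in the resistant clones.",
  "Sequencing revealed %s in three of the tumour samples.",
  "The %s alteration was confirmed by capillary sequencing.",
  "Carriers of %s showed reduced enzyme activity.",
  "Targeted resequencing detected %s in the index case."
)

.decoy_sentences <- function(lex) {
  function(kind) {
    switch(
      kind,
      cell_line = sprintf("Experiments were performed in %s cells.",
                          sample(lex$cell_lines, 1)),
      platform = sprintf("Expression was profiled on the %s platform.",
                         sample(lex$platform_names, 1)),
      figure = sprintf("Full results are shown in %s Figure S%d%s.",
                       sample(c("Supplementary", "Supplementary", "the"), 1),
                       sample(1:20, 1), sample(LETTERS[1:6], 1)),
      chemical = sprintf("Cultures were stressed with %s before harvest.",
                         sample(c("H2O2", "NaCl", "CaCl2", "MgCl2", "NaHCO3"), 1))
    )
  }
}

#' Generate a seeded synthetic corpus with gold annotations
#'
#' Builds `n_docs` documents of template sentences embedding variant
#' realizations and decoys according to the spec, plus the gold answer set
#' listing exactly the embedded variants with their mention
#' multiplicities. Injected synonymous/implausible substitutions (off by
#' default) appear in the text but not in the gold, exercising filter
#' rules 3 and 4.
#'
#' @param spec A [corpus_spec()].
#' @param lexicons Lexicons the decoys are drawn from (defaults to the
#'   bundled lists, so the default post-processing removes every decoy).
#' @param matrix Substitution matrix constraining generated substitutions
#'   to plausible pairs.
#' @param config Parsing conventions (see [pp_config()]).
#' @return A list with `documents` (tibble `doc_id`, `text`) and `gold`
#'   (an `answer_set`).
#' @export
#' @examples
#' corpus <- generate_corpus(corpus_spec(seed = 42, n_docs = 3))
#' corpus$documents$doc_id
generate_corpus <- function(spec, lexicons = default_lexicons(),
                            matrix = default_substitution_matrix(),
                            config = pp_config()) {
  stopifnot(inherits(spec, "corpus_spec"))
  lex_norm <- .norm_entry(c(lexicons$cell_lines, lexicons$gene_symbols,
                            lexicons$platform_names))
  decoy_of <- .decoy_sentences(lexicons)
  withr::with_seed(spec$seed, {
    docs <- vector("list", spec$n_docs)
    golds <- vector("list", spec$n_docs)
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("synth%04d", d)
      n_var <- .resample(spec$variants_per_doc[1]:spec$variants_per_doc[2], 1)
      sentences <- character(0)
      rows <- vector("list", n_var)
      for (k in seq_len(n_var)) {
        form <- sample(names(spec$form_mix), 1, prob = spec$form_mix)
        r <- .realize_variant(form, matrix, lex_norm, config)
        times <- 1L + stats::rbinom(1, 1, spec$duplicate_mention_rate)
        for (t in seq_len(times)) {
          sentences <- c(sentences,
                         sprintf(sample(.variant_sentences, 1), r$surface))
        }
        row <- r$v
        row$doc_id <- doc_id
        row$multiplicity <- times
        row$surfaces <- r$surface
        rows[[k]] <- row
      }
      if (spec$synonymous_rate > 0 && stats::runif(1) < spec$synonymous_rate) {
        w <- sample(residue_alphabet(), 1)
        sentences <- c(sentences, sprintf(sample(.variant_sentences, 1),
                                          paste0(w, sample(1:2000, 1), w)))
      }
      if (spec$implausible_rate > 0 && stats::runif(1) < spec$implausible_rate) {
        pairs <- .plausible_pairs(matrix, plausible = FALSE)
        p <- pairs[sample(nrow(pairs), 1), ]
        sentences <- c(sentences, sprintf(sample(.variant_sentences, 1),
                                          paste0(p$w, sample(1:2000, 1), p$m)))
      }
      n_decoy <- stats::rpois(1, spec$decoy_rate)
      for (j in seq_len(n_decoy)) {
        kind <- sample(c("cell_line", "platform", "figure", "chemical"), 1)
        sentences <- c(sentences, decoy_of(kind))
      }
      if (!length(sentences)) {
        sentences <- "No sequence alterations were detected in this sample."
      }
      sentences <- sample(sentences)
      docs[[d]] <- tibble(doc_id = doc_id,
                          text = paste(sentences, collapse = " "))
      golds[[d]] <- dplyr::bind_rows(rows)
    }
    gold_rows <- dplyr::bind_rows(golds)
    gold <- if (nrow(gold_rows)) {
      suppressWarnings(as_answerset(dplyr::select(gold_rows, -"key")))
    } else {
      empty_answerset()
    }
    list(documents = dplyr::bind_rows(docs), gold = gold)
  })
}

#' Curated example corpus with hand-checked gold annotations
#'
#' A small bundled corpus of sentences quoted from published articles
#' (identified by their PMIDs) that are classic stress tests for variant
#' extractors — natural-language substitutions whose "for"-preposition
#' inverts wild type and mutant, a DNA- plus protein-level double
#' description, a codon change whose number is an amino-acid position, an
#' imbalanced "factor V 1691G > A" fragment, and hyphenated forms — paired
#' with the hand-checked correct answers.
#'
#' The rule-7 fragment ("substitution of arginine for methionine") carries
#' no position, so its gold is empty: a positionless substitution is not
#' convertible to wNm form and is excluded by the non-informative rule.
#'
#' @return A list with `documents` and `gold` (an `answer_set`).
#' @export
#' @examples
#' fx <- fixture_corpus()
#' fx$gold$key
fixture_corpus <- function() {
  documents <- tibble(
    doc_id = c("PMID21080147", "PMID17517479", "PMID16840830",
               "frag_imbalanced", "frag_for", "frag_hyphen", "frag_minus"),
    text = c(
      paste0("In a patient, a C-to-G transition was identified at nucleotide",
             " 857 in exon 8 that resulted in a substitution of alanine for",
             " proline at amino acid 286 in the first calcium binding EGF",
             " domain."),
      paste0("Fifteen patients were heterozygous for the G–≥A",
             " polymorphism at nucleotide 5557, which causes substitution of",
             " asparagine for aspartic acid at position 1853 of the ATM",
             " protein."),
      paste0("The Turkish patient and her affected relatives all had a",
             " heterozygous A to G transition at codon 557 (AAG–≥GAG)",
             " of exon 10 of MEN1 that results in a replacement of lysine by",
             " glutamic acid."),
      "factor V 1691G > A",
      "substitution of arginine for methionine",
      "Arg-23-Thr",
      "Arg-23Thr"
    )
  )
  gold <- as_answerset(tibble::tribble(
    ~doc_id, ~level, ~kind, ~wild, ~position, ~mutant, ~rs_id, ~multiplicity,
    "PMID21080147", "protein", "SUB", "P", 286L, "A", "", 1L,
    "PMID17517479", "protein", "SUB", "D", 1853L, "N", "", 1L,
    "PMID17517479", "dna", "SUB", "G", 5557L, "A", "", 1L,
    "PMID16840830", "protein", "SUB", "K", 557L, "E", "", 1L,
    "frag_imbalanced", "dna", "SUB", "G", 1691L, "A", "", 1L,
    "frag_hyphen", "protein", "SUB", "R", 23L, "T", "", 1L,
    "frag_minus", "protein", "SUB", "R", -23L, "T", "", 1L
  ))
  list(documents = documents, gold = gold)
}
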