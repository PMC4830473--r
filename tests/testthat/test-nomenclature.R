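test_that("residue tokens normalize across all three naming layers", {
  expect_equal(aa_to_one("Thr"), "T")
  expect_equal(aa_to_one("aspartic acid"), "D")
  expect_equal(aa_to_one("T"), "T")
  expect_equal(aa_to_one(c("thr", "THR", " Thr ")), c("T", "T", "T"))
  expect_equal(aa_to_one("glutamate"), "E")
  # idempotent on its own outputs
  one <- aa_to_one(c("alanine", "Trp", "k"))
  expect_equal(aa_to_one(one), one)
  expect_error(aa_to_one("Xyz"), class = "varminer_unknown_residue")
  expect_error(aa_to_one(""), class = "varminer_unknown_residue")
})

test_that("naming layers agree with an independent conversion table", {
  skip_if_not_installed("seqinr")
  for (code in residue_alphabet()) {
    expect_equal(aa_to_one(seqinr::aaa(code)), code)
  }
})

test_that("codon translation follows the standard genetic code", {
  expect_equal(translate_codon("AAG"), "K")
  expect_equal(translate_codon("GAG"), "E")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("aug"), "M") # case and U folding
  expect_error(translate_codon("AXG"), class = "varminer_invalid_codon")
  expect_error(translate_codon("AA"), class = "varminer_invalid_codon")
})

test_that("all 64 codons agree with an independent translation oracle", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  mine <- translate_codon(codons)
  oracle <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]])
  }, character(1))
  expect_equal(unname(mine), unname(oracle))
})

test_that("canonical keys serialize, round-trip and stay injective", {
  expect_equal(variant("protein", "SUB", "P", 286, "A")$key, "p|SUB|P|286|A")
  expect_equal(variant("dna", "SUB", "G", 5557, "A")$key, "c|SUB|G|5557|A")
  snp <- variant("dna", "SNP", rs_id = "rs121434569")
  expect_equal(snp$key, "c|SNP||||rs121434569")

  # round-trip on a grid of variants, including negative positions
  grid <- dplyr::bind_rows(
    variant("protein", "SUB", "R", -23, "T"),
    variant("protein", "DEL", "K", 557),
    variant("dna", "SUB", "C", 857, "G"),
    variant("rna", "SUB", "A", 5, "U"),
    variant("protein", "FS", "E", 746),
    snp
  )
  back <- parse_canonical_key(grid$key)
  expect_equal(back$key, grid$key)
  expect_equal(back$position, grid$position)
  expect_equal(back$wild, grid$wild)

  # injectivity by enumeration over a small grid
  aa <- c("A", "R", "T")
  combos <- expand.grid(level = c("protein", "dna"), wild = c("A", "T"),
                        position = c(1L, 12L), mutant = c("G", "C"),
                        stringsAsFactors = FALSE)
  combos <- combos[!(combos$level == "protein"), ] # bases only valid at dna
  keys <- canonical_key(tibble::tibble(
    level = combos$level, kind = "SUB", wild = combos$wild,
    position = combos$position, mutant = combos$mutant, rs_id = ""
  ))
  expect_equal(anyDuplicated(keys), 0L)
  # distinct levels give distinct keys for the same event
  expect_false(variant("protein", "SUB", "A", 5, "G")$key ==
                 variant("dna", "SUB", "A", 5, "G")$key)
  expect_error(parse_canonical_key("not|a"), class = "varminer_bad_key")
})

test_that("variant invariants are enforced", {
  expect_error(variant("protein", "SUB", "T", NA, "M"),
               class = "varminer_invalid_variant")
  expect_error(variant("protein", "SUB", "", 790, "M"),
               class = "varminer_invalid_variant")
  expect_error(variant("protein", "SUB", "U", 790, "M"),
               class = "varminer_invalid_variant") # U not an amino acid
  expect_error(variant("dna", "SNP"), class = "varminer_invalid_variant")
  expect_silent(variant("dna", "SUB", "U", 3, "A")) # U valid at nucleic level
})

test_that("the default substitution matrix behaves like a PAM matrix", {
  m <- default_substitution_matrix()
  aa <- residue_alphabet()
  sc <- outer(aa, aa, function(w, x) matrix_score(m, w, x))
  expect_true(all(is.finite(sc)))                       # totality, 400 pairs
  expect_true(all(diag(sc) >= apply(sc, 1, max)))       # diagonal dominance
  expect_equal(matrix_score(m, "W", "W"), max(sc[match("W", aa), ]))
  # conservative substitutions outscore radical ones
  expect_gte(matrix_score(m, "L", "I"), matrix_score(m, "W", "G"))
  expect_error(matrix_score(m, "B", "A"), class = "varminer_unknown_residue")
})

test_that("matrix files in NCBI-style square layout are read back exactly", {
  path <- system.file("extdata", "toy_matrix_synthetic.txt",
                      package = "varminer")
  m <- read_substitution_matrix(path)
  expect_s3_class(m, "substitution_matrix")
  expect_equal(m$name, "toy_matrix_synthetic")
  expect_equal(matrix_score(m, "L", "I"), 2)
  expect_equal(matrix_score(m, "W", "G"), -8)
  expect_equal(matrix_score(m, "A", "A"), 5)
  expect_error(read_substitution_matrix(tempfile()),
               class = "varminer_missing_resource")
})
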