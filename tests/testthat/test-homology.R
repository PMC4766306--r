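test_that("local alignment matches hand-computed and degenerate cases", {
  hit <- local_align("ACDEFG", "ACDEFG")
  # BLOSUM62 diagonal: A4 C9 D6 E5 F6 G6
  expect_equal(hit$raw_score, 36)
  expect_equal(hit$query_span, c(0L, 6L))
  expect_equal(hit$subject_span, c(0L, 6L))

  # no residue pair scores positively (BLOSUM62 P vs W = -4)
  null_hit <- local_align("PPPP", "WWWW")
  expect_equal(null_hit$raw_score, 0)
  expect_equal(null_hit$query_span, c(0L, 0L))
  expect_equal(null_hit$subject_span, c(0L, 0L))

  expect_error(local_align("ACGT", "MKVW"), "alphabet mismatch")
})

test_that("local alignment equals the exhaustive path-enumeration oracle", {
  withr::local_seed(21)
  b62 <- blosum62_matrix()
  dna <- dna_subst_matrix()
  for (i in 1:6) {
    a <- random_aa(4); b <- random_aa(4)
    expect_equal(local_align(a, b)$raw_score,
                 enum_local_score(a, b, b62, 11, 1),
                 info = paste(a, b))
    x <- random_dna(5); y <- random_dna(5)
    expect_equal(local_align(x, y)$raw_score,
                 enum_local_score(x, y, dna, 5, 2),
                 info = paste(x, y))
  }
})

test_that("local alignment equals a textbook Gotoh DP on 12-mers", {
  withr::local_seed(22)
  b62 <- blosum62_matrix()
  dna <- dna_subst_matrix()
  for (i in 1:20) {
    a <- random_aa(12); b <- random_aa(12)
    expect_equal(local_align(a, b)$raw_score,
                 gotoh_local_score(a, b, b62, 11, 1), info = paste(a, b))
    x <- random_dna(12); y <- random_dna(12)
    expect_equal(local_align(x, y)$raw_score,
                 gotoh_local_score(x, y, dna, 5, 2), info = paste(x, y))
  }
})

test_that("alignment score is symmetric and grows with homologous block", {
  withr::local_seed(23)
  for (i in 1:8) {
    a <- random_aa(30); b <- random_aa(30)
    expect_equal(local_align(a, b)$raw_score, local_align(b, a)$raw_score)
  }
  core <- random_aa(20)
  prev <- -Inf
  for (k in c(5, 10, 15, 20)) {
    block <- substr(core, 1, k)
    s <- local_align(paste0(random_aa(10), block, random_aa(10)),
                     paste0(random_aa(8), block, random_aa(12)))$raw_score
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("Karlin-Altschul E-values behave", {
  K <- 0.041; lam <- 0.267
  s1 <- log(K * 200 * 300) / lam
  expect_equal(evalue_of(s1, 200, 300, K, lam), 1)
  expect_equal(evalue_of(40, 100, 100, K, lam), 9.43e-3, tolerance = 1e-3)
  scores <- seq(0, 500, by = 25)
  ev <- log10_evalue_of(scores, 1000, 1000, K, lam)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue_of(10, 100, 100, -1, lam), "positive")
  expect_error(evalue_of(10, 0, 100, K, lam), ">= 1")
})

test_that("find_homologs returns the best passing subject, order-invariant", {
  withr::local_seed(31)
  target <- random_aa(120)
  subjects <- Biostrings::AAStringSet(
    c(s1 = random_aa(120), s2 = target, s3 = random_aa(120)))
  q <- Biostrings::AAStringSet(c(q = target))
  hit <- find_homologs(q, subjects)
  expect_equal(hit$subject_id, "s2")
  hit2 <- find_homologs(q, subjects[c(3, 1, 2)])
  expect_equal(hit2$subject_id, "s2")
  expect_equal(hit2$evalue, hit$evalue)

  # no positive-scoring pair -> empty result
  none <- find_homologs(Biostrings::AAStringSet(c(q = "GGGGG")),
                        Biostrings::AAStringSet(c(s = "WWWWW")))
  expect_equal(nrow(none), 0)
})

test_that("divergent nucleotide homologs pass 1e-4 but not 1e-50", {
  withr::local_seed(32)
  anc <- random_dna(300)
  hom <- as.character(mutate_homolog(anc, 0.75))
  q <- Biostrings::DNAStringSet(c(anc = anc))
  s <- Biostrings::DNAStringSet(c(hom = hom))
  strict <- find_homologs(q, s, e_cutoff = 1e-50)
  loose <- find_homologs(q, s, e_cutoff = 1e-4)
  expect_equal(nrow(strict), 0)
  expect_equal(nrow(loose), 1)
  # and the realized E matches the closed form for the realized score
  hit <- local_align(anc, hom)
  expect_equal(hit$evalue,
               0.46 * 300 * 300 * exp(-1.28 * hit$raw_score))
  # a close homolog over a longer stretch sails past the stringent cutoff
  long_anc <- random_dna(1500)
  long_hom <- as.character(mutate_homolog(long_anc, 0.95))
  expect_equal(nrow(find_homologs(
    Biostrings::DNAStringSet(c(a = long_anc)),
    Biostrings::DNAStringSet(c(h = long_hom)), e_cutoff = 1e-50)), 1)
})

test_that("P450 motif scanning finds the consensus patterns", {
  hits <- scan_p450_motifs("AAEKLRAA")
  expect_equal(hits$motif, "EXXR")
  expect_equal(hits$start, 2L)
  expect_equal(hits$match, "EKLR")

  heme <- scan_p450_motifs("FGAGRRACPG")
  expect_true("heme_FXXGXRXCXG" %in% heme$motif)

  oxy <- scan_p450_motifs("LLAGFDTTLL")
  expect_true("oxygen_binding" %in% oxy$motif)
  expect_equal(oxy$start[oxy$motif == "oxygen_binding"], 2L)

  expect_equal(nrow(scan_p450_motifs("AAEKLA")), 0)
  expect_error(scan_p450_motifs("ACGTACGT"), "protein")
})

test_that("P450 classification separates template from random peptides", {
  cls <- classify_p450(p450_template()[[1]])
  expect_true(cls$is_p450)
  expect_setequal(unique(cls$motifs$motif),
                  c("EXXR", "PXRX", "heme_FXXGXRXCXG", "oxygen_binding"))

  withr::local_seed(41)
  calls <- vapply(1:25, function(i) {
    classify_p450(random_aa(500))$is_p450
  }, logical(1))
  expect_lte(sum(calls), 1)  # random peptides essentially never classify

  expect_error(classify_p450("MKV", Biostrings::AAStringSet()), "empty")
})

test_that("longest ORF prediction is strand-symmetric and matches brute force", {
  expect_equal(as.character(longest_orf_peptide("ATGAAATAA", min_aa = 1)),
               "MK")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAA")))
  expect_equal(as.character(longest_orf_peptide(rc, min_aa = 1)), "MK")

  expect_null(longest_orf_peptide("ATGAAATAA", min_aa = 50))
  expect_error(longest_orf_peptide("ATGXXX"), "ACGTN")

  withr::local_seed(42)
  for (i in 1:8) {
    dna <- random_dna(2000)
    got <- longest_orf_peptide(dna, min_aa = 10)
    oracle <- brute_orf_peptides(dna, min_aa = 10)
    if (is.null(got)) {
      expect_length(oracle, 0)
    } else {
      expect_equal(nchar(as.character(got)), max(nchar(oracle)))
      expect_true(as.character(got) %in% oracle)
    }
  }
})
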