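test_that("primers and restriction sites validate their alphabets", {
  expect_s3_class(primer("f", "ACGT"), "primer")
  expect_error(primer("f", "ACGN"), "non-ACGT")
  expect_error(primer("f", ""), "nonempty")
  expect_s3_class(restriction_site("TTAA", 1), "restriction_site")
  expect_error(restriction_site("TTAA", 5), "between 0")
  expect_error(restriction_site("TTNA", 1), "ACGT")
})

test_that("virtual PCR finds embedded primer pairs with exact coordinates", {
  fwd <- primer("f", "ACTGCGGTTGCTGGTCA")
  rev <- primer("r", "CCCTGCTCATGCTCCTG")
  # 60 bp: fwd at 1, reverse-complement of rev at 44
  mid <- "AAACCCGGGTTTAAACCCGGGTTTAA"
  template <- paste0(fwd$sequence, mid,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(rev$sequence))))
  expect_equal(nchar(template), 60)
  amp <- in_silico_pcr(template, fwd, rev)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 1L)
  expect_equal(amp$end, 60L)
  expect_equal(amp$length, 60L)
  expect_equal(amp$sequence, template)
  # primers absent: empty result, not an error
  expect_equal(nrow(in_silico_pcr("ACGTACGTACGT", fwd, rev)), 0)
  expect_error(in_silico_pcr("", fwd, rev), "nonempty")
  expect_error(in_silico_pcr(template, "ACGTN", rev), "non-ACGT")
})

test_that("amplicons longer than max_length are suppressed", {
  fwd <- primer("f", "ACTGCGGTTGCTGGTCA")
  rev <- primer("r", "CCCTGCTCATGCTCCTG")
  template <- paste0(fwd$sequence, strrep("AC", 100),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(rev$sequence))))
  expect_equal(nrow(in_silico_pcr(template, fwd, rev, max_length = 100)), 0)
  expect_equal(nrow(in_silico_pcr(template, fwd, rev, max_length = 500)), 1)
})

test_that("digestion cuts at every motif occurrence", {
  site <- restriction_site("TTAA", 1)
  expect_equal(digest("AATTAAG", site), c(3L, 4L))
  expect_equal(digest("ACGTACGT", site), 8L)
  # two sites
  seq2 <- paste0("AA", "TTAA", "CCCC", "TTAA", "GG") # cuts after pos 3 and 11
  expect_equal(digest(seq2, site), c(3L, 8L, 5L))
  # overlapping occurrences each cut once: TTAATTAA within TTAATTAA
  expect_equal(digest("TTAATTAA", site), c(1L, 4L, 3L))
  expect_error(digest("", site), "empty")
})

test_that("fragment lengths sum to input length; digestion is complete", {
  set.seed(10)
  site <- restriction_site("TTAA", 1)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    frags <- digest(s, site)
    expect_equal(sum(frags), nchar(s))
    # re-digesting each fragment yields no further cuts
    pos <- cumsum(c(0, frags))
    for (i in seq_along(frags)) {
      sub <- substr(s, pos[i] + 1, pos[i + 1])
      expect_equal(length(digest(sub, site)), 1)
    }
  }
})

test_that("diploid band patterns merge allele fragments symmetrically", {
  site <- restriction_site("TTAA", 1)
  a_uncut <- strrep("AC", 149)                    # 298 bp, no site
  a_cut <- paste0(strrep("AC", 114), "TT", "AATT",
                  strrep("GA", 35))               # cut into 230 + 72... built below
  # simpler: construct exact 302-bp allele cutting into 230 + 72
  left <- strrep("AC", 115)                        # 230 bp ending before motif
  a_cut <- paste0(substr(left, 1, 229), "T", "TAA", strrep("G", 69))
  expect_equal(digest(a_cut, site), c(230L, 72L))
  bands <- diploid_band_pattern(a_uncut, a_cut, site)
  expect_equal(bands, c(298L, 230L, 72L))
  expect_equal(diploid_band_pattern(a_cut, a_uncut, site), bands)
  expect_equal(diploid_band_pattern(a_uncut, a_uncut, site), 298L)
  expect_equal(length(diploid_band_pattern(a_cut, a_cut, site)), 2)
})

test_that("band patterns map to male-sterility genotypes and phenotypes", {
  expect_equal(call_ms_genotype(300)$genotype, "MsMs")
  expect_equal(call_ms_genotype(300)$phenotype, "fertile")
  expect_equal(call_ms_genotype(c(230, 70))$genotype, "msms")
  expect_equal(call_ms_genotype(c(230, 70))$phenotype, "sterile")
  expect_equal(call_ms_genotype(c(300, 230, 70))$genotype, "Msms")
  # sizes within gel tolerance still call
  expect_equal(call_ms_genotype(c(302, 230, 72))$genotype, "Msms")
  # unclassifiable patterns never silently guess
  expect_equal(call_ms_genotype(150)$genotype, "no-call")
  expect_true(is.na(call_ms_genotype(150)$phenotype))
  expect_equal(call_ms_genotype(c(300, 230))$genotype, "no-call")
  expect_equal(call_ms_genotype(c(300, 230),
                                allow_low_band_dropout = TRUE)$genotype,
               "Msms")
})

test_that("synthetic myb80 locus reproduces the assay geometry end to end", {
  loc <- synth_myb80_locus(seed = 4)
  fert_amp <- in_silico_pcr(loc$fertile_allele, loc$fwd, loc$rev)
  ster_amp <- in_silico_pcr(loc$sterile_allele, loc$fwd, loc$rev)
  expect_equal(fert_amp$length, 298L)
  expect_equal(ster_amp$length, 302L)
  expect_equal(digest(fert_amp$sequence, loc$site), 298L)
  expect_equal(digest(ster_amp$sequence, loc$site), c(230L, 72L))
  # the AATT insertion after a TT creates exactly one new recognition site
  count <- function(s, p) sum(gregexpr(paste0("(?=", p, ")"), s,
                                       perl = TRUE)[[1]] > 0)
  expect_equal(count(loc$fertile_allele, "TTAA"), 0)
  expect_equal(count(loc$sterile_allele, "TTAA"), 1)
  expect_equal(count(loc$fertile_allele, "AATT"), 0)
  expect_equal(count(loc$sterile_allele, "AATT"), 1)
  # determinism
  loc2 <- synth_myb80_locus(seed = 4)
  expect_identical(loc$sterile_allele, loc2$sterile_allele)
})

test_that("genotype -> bands -> call round trip recovers all three genotypes", {
  loc <- synth_myb80_locus(seed = 2)
  alleles <- list(
    "MsMs-1" = c(loc$fertile_allele, loc$fertile_allele),
    "Msms-1" = c(loc$fertile_allele, loc$sterile_allele),
    "msms-1" = c(loc$sterile_allele, loc$sterile_allele)
  )
  calls <- in_silico_caps(alleles, loc$fwd, loc$rev, loc$site)
  expect_equal(calls$genotype, c("MsMs", "Msms", "msms"))
  expect_equal(calls$phenotype, c("fertile", "fertile", "sterile"))
})

test_that("marker concordance counts mismatches over valid pairs", {
  a <- rep(c("MsMs", "Msms", "msms"), length.out = 94)
  b <- a
  b[10] <- "msms"
  out <- marker_concordance(a, b)
  expect_equal(out$mismatches, 1)
  expect_equal(out$mismatch_pct, 1.06)
  expect_equal(marker_concordance(a, a)$mismatch_pct, 0)
  flipped <- ifelse(a == "MsMs", "msms", "MsMs")
  expect_equal(marker_concordance(a, flipped)$mismatch_pct, 100)
  # no-calls excluded from the denominator
  b2 <- b; b2[1:4] <- "no-call"
  out2 <- marker_concordance(a, b2)
  expect_equal(out2$n_valid, 90)
  expect_equal(out2$n_excluded, 4)
  expect_error(marker_concordance(a, a[-1]), "equal length")
})
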