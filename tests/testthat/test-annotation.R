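test_that("translation agrees with the standard code for all 64 codons", {
  for (codon in names(.std_code))
    expect_equal(unname(Biostrings::GENETIC_CODE[codon]),
                 unname(.std_code[codon]), label = codon)
})

# Build a plus-strand amplicon whose exon1 starts with a chosen codon run.
.amplicon_with_cds <- function(cds_seq, strand = "+") {
  a <- tiny_amplicon(strand = strand, cds_offset = 0L)
  stopifnot(nchar(cds_seq) <= 60)
  if (strand == "+") {
    substr(a$seq_a, 31, 30 + nchar(cds_seq)) <- cds_seq
  } else {
    # transcription starts at the end of exon2: place revcomp there
    rc <- revcomp(cds_seq)
    substr(a$seq_a, 170 - nchar(rc) + 1, 170) <- rc
  }
  a$seq_b <- a$seq_a
  a
}

test_that("stop-gain, synonymous and missense classifications are exact", {
  a <- .amplicon_with_cds("ATGTGGCTGAAA")   # M W L K
  # TGG -> TGA at codon 2 position 3 (amplicon pos 30+5)
  r <- classify_effect(a, 35, "G", "A")
  expect_equal(r$effect_class, "stop_gained")
  expect_equal(r$codon_ref, "TGG"); expect_equal(r$codon_alt, "TGA")
  expect_equal(r$aa_position, 2)
  # CTG -> CTA (Leu -> Leu) at codon 3
  r2 <- classify_effect(a, 38, "G", "A")
  expect_equal(r2$effect_class, "synonymous")
  expect_equal(r2$aa_ref, "L"); expect_equal(r2$aa_alt, "L")
  # ATG -> GTG missense at codon 1 (not EMS, but annotation is general)
  r3 <- classify_effect(a, 30, "A", "G")
  expect_equal(r3$effect_class, "missense")
  expect_equal(r3$aa_ref, "M"); expect_equal(r3$aa_alt, "V")
})

test_that("splice-site, intronic, primer and noncoding zones are respected", {
  a <- tiny_amplicon()
  # intron is [90, 120): first two intronic bases are the donor site
  expect_equal(classify_effect(a, 90, substr(a$seq_a, 91, 91), "A")$effect_class,
               "splice_site")
  expect_equal(classify_effect(a, 91, substr(a$seq_a, 92, 92), "A")$effect_class,
               "splice_site")
  expect_equal(classify_effect(a, 105, substr(a$seq_a, 106, 106), "A")$effect_class,
               "intronic")
  expect_equal(classify_effect(a, 118, substr(a$seq_a, 119, 119), "A")$effect_class,
               "splice_site")
  # primer region and outside the gene span
  expect_equal(classify_effect(a, 5, substr(a$seq_a, 6, 6), "A")$effect_class,
               "noncoding")
  expect_equal(classify_effect(a, 25, substr(a$seq_a, 26, 26), "A")$effect_class,
               "noncoding")
  # exonic beats splice proximity: last exonic base before the intron
  expect_true(classify_effect(a, 89, substr(a$seq_a, 90, 90),
                              "A")$effect_class %in%
              c("synonymous", "missense", "stop_gained", "stop_lost",
                "noncoding"))
  # wider window reclassifies deeper intronic bases
  expect_equal(classify_effect(a, 93, substr(a$seq_a, 94, 94), "A",
                               splice_window = 5)$effect_class, "splice_site")
})

test_that("minus-strand classification equals the reverse-complement construct", {
  cds <- "ATGTGGCTGAAATCCGGA"
  ap <- .amplicon_with_cds(cds, "+")
  am <- .amplicon_with_cds(cds, "-")
  # plus: CDS occupies [30, 48); minus: transcription-order CDS ends exon2
  for (k in 0:(nchar(cds) - 1)) {
    pp <- 30 + k
    pm <- 169 - k
    rb_p <- substr(ap$seq_a, pp + 1, pp + 1)
    ab_p <- setdiff(c("A", "C", "G", "T"), rb_p)[1]
    rb_m <- substr(am$seq_a, pm + 1, pm + 1)
    ab_m <- chartr("ACGT", "TGCA", ab_p)
    expect_equal(rb_m, chartr("ACGT", "TGCA", rb_p))
    rp <- classify_effect(ap, pp, rb_p, ab_p)
    rm <- classify_effect(am, pm, rb_m, ab_m)
    expect_equal(rm$effect_class, rp$effect_class)
    expect_equal(rm$aa_ref, rp$aa_ref)
    expect_equal(rm$aa_alt, rp$aa_alt)
    expect_equal(rm$aa_position, rp$aa_position)
  }
})

test_that("platform statistics reproduce the worked examples exactly", {
  expect_equal(affecting_fraction(134, 3935), 3.4)
  expect_equal(affecting_fraction(0, 100), 0)
  expect_equal(affecting_fraction(3935, 3935), 100)
  expect_error(affecting_fraction(1, 0), "n_total")

  f <- mutation_frequency(14, 4474)
  expect_equal(f$label, "1/320 kb")
  expect_equal(f$kb_per_mutation, 4474 / 14)
  expect_equal(mutation_frequency(1, 100)$label, "1/100 kb")
  expect_equal(mutation_frequency(0, 100)$label, "none detected")
  expect_error(mutation_frequency(5, 0), "total_screened_kb")

  expect_equal(detection_accuracy(14, 17), 82L)
  expect_equal(detection_accuracy(5, 5), 100L)
  expect_equal(detection_accuracy(0, 17), 0L)
  expect_error(detection_accuracy(1, 0), "n_clean_traces")
})

test_that("percentage statistics are scale-invariant", {
  for (k in c(2, 5, 10)) {
    expect_equal(affecting_fraction(134 * k, 3935 * k),
                 affecting_fraction(134, 3935))
    expect_equal(detection_accuracy(14 * k, 17 * k), detection_accuracy(14, 17))
  }
})

test_that("screened kb recomputes from the amplicon set", {
  amps <- generate_references(17, c(452, 704), seed = 70)
  lens <- vapply(amps, `[[`, 0L, "length")
  expect_equal(screened_kb(amps, 512), sum(lens) * 512 / 1000)
})

test_that("scoring separates true, partial and false candidates", {
  truth <- structure(data.frame(
    family_id = c(10L, 20L), amplicon_id = c("amp01", "amp02"),
    position = c(100L, 200L), ref_base = "G", alt_base = "A",
    zygosity = "het", haplotype = 1L, stringsAsFactors = FALSE),
    class = c("simulation_truth", "data.frame"))
  cand <- data.frame(
    amplicon_id = c("amp01", "amp02", "amp03"),
    position = c(100L, 200L, 300L), ref_base = "G", alt_base = "A",
    status = c("unique", "ambiguous", "unique"),
    families = c("10", "20,21", "5"), stringsAsFactors = FALSE)
  s <- score_against_truth(cand, truth)
  expect_equal(s$n_tp, 1); expect_equal(s$n_partial, 1); expect_equal(s$n_fp, 1)
  expect_equal(s$sensitivity, 0.5)
  expect_equal(s$precision, 1 / 3)
  expect_equal(s$family_accuracy, 0.5)

  perfect <- cand[1, ]
  s2 <- score_against_truth(perfect, truth[1, ])
  expect_equal(s2$sensitivity, 1); expect_equal(s2$precision, 1)

  s3 <- score_against_truth(cand[0, ], truth)
  expect_equal(s3$sensitivity, 0)
})
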