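test_that("reference generation respects divergence bounds", {
  a0 <- generate_references(3, c(452, 704), divergence = 0, seed = 1)
  expect_true(all(vapply(a0, function(a) a$seq_a == a$seq_b, TRUE)))

  a17 <- generate_references(17, c(452, 704), divergence = 0.005, seed = 2)
  lens <- vapply(a17, `[[`, 0L, "length")
  expect_true(all(lens >= 452 & lens <= 704))
  expect_length(a17, 17)
  expect_equal(length(unique(vapply(a17, `[[`, "", "gene_id"))), 13)

  a1 <- generate_references(2, c(100, 100), divergence = 1, primer_length = 10,
                            seed = 3)
  for (a in a1) {
    sa <- strsplit(a$seq_a, "")[[1]]; sb <- strsplit(a$seq_b, "")[[1]]
    inner <- 11:90
    expect_true(all(sa[inner] != sb[inner]))
    expect_true(all(sa[-inner] == sb[-inner]))  # primers conserved
  }
  expect_error(generate_references(2, c(704, 452)), "length_range")
})

test_that("exon models are sorted, disjoint and inside the amplicon", {
  amps <- generate_references(10, c(452, 704), n_exons_range = c(1, 3), seed = 4)
  for (a in amps) {
    ex <- a$exons
    expect_true(all(ex[, "end"] > ex[, "start"]))
    expect_true(all(ex >= 0 & ex <= a$length))
    if (nrow(ex) > 1)
      expect_true(all(ex[-1, "start"] >= ex[-nrow(ex), "end"]))
    expect_true(a$cds_offset %in% 0:2 && a$strand %in% c("+", "-"))
  }
})

test_that("reference generation is reproducible under seed", {
  expect_identical(generate_references(4, c(452, 704), seed = 7),
                   generate_references(4, c(452, 704), seed = 7))
})

test_that("spiked mutations are EMS-canonical at agreeing G/C sites", {
  sc <- build_scheme(512, 8)
  amps <- generate_references(17, c(452, 704), seed = 5)
  tr <- spike_mutations(sc, amps, freq_kb = 100, seed = 6)
  expect_gt(nrow(tr), 0)
  expect_true(all(ems_canonical(tr$ref_base, tr$alt_base)))
  for (i in seq_len(nrow(tr))) {
    a <- amps[[tr$amplicon_id[i]]]
    expect_true(tr$position[i] >= 0 && tr$position[i] < a$length)
    b <- substr(a$seq_a, tr$position[i] + 1, tr$position[i] + 1)
    expect_equal(b, tr$ref_base[i])
    expect_equal(substr(a$seq_b, tr$position[i] + 1, tr$position[i] + 1), b)
  }
  expect_equal(nrow(spike_mutations(sc, amps, freq_kb = Inf, seed = 1)), 0)
})

test_that("mean spike count over 50 seeds matches total_kb / freq", {
  sc <- build_scheme(512, 8)
  amps <- generate_references(17, c(452, 704), seed = 8)
  mu <- screened_kb(amps, 512) / 320
  n <- vapply(1:50, function(s) nrow(spike_mutations(sc, amps, 320, seed = s)), 0L)
  se <- sqrt(mu / 50)   # Poisson standard error of the mean
  expect_lt(abs(mean(n) - mu), 3 * se)
})

test_that("error-free reads all match a parental haplotype", {
  cfg <- small_config()
  sc <- build_scheme(8, 2)
  amps <- generate_references(2, c(452, 500), divergence = 0.01, seed = 9)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 5,
                             error_rate = 0, seed = 10)
  expect_length(sim$pools, 6)
  asn <- assign_reads(sim$pools[["R0"]], amps)
  expect_equal(asn$mapping_efficiency, 1)
  expect_true(all(asn$assignments$mismatches == 0))
})

test_that("pool VAF at a spiked het site converges to 1/(2 * pool size)", {
  sc <- build_scheme(64, 4)   # pools of 16 families
  amps <- generate_references(1, c(452, 452), divergence = 0, seed = 11)
  tr <- structure(data.frame(
    family_id = 21L, amplicon_id = names(amps), position = 226L,
    ref_base = substr(amps[[1]]$seq_a, 227, 227),
    alt_base = "A", zygosity = "het", haplotype = 1L,
    stringsAsFactors = FALSE), class = c("simulation_truth", "data.frame"))
  # make the site EMS-legal for the test
  tr$alt_base <- if (tr$ref_base == "G") "A" else if (tr$ref_base == "C") "T" else {
    substr(amps[[1]]$seq_a, 227, 227) <- "G"
    substr(amps[[1]]$seq_b, 227, 227) <- "G"
    tr$ref_base <- "G"; "A"
  }
  pool <- unname(pools_of(sc, 21L)["R"])
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 200,
                             error_rate = 0, seed = 12, pools = pool)
  asn <- assign_reads(sim$pools[[pool]], amps)
  cnt <- pileup(asn, amps)[[1]]
  depth <- sum(cnt[, 227])
  vaf <- cnt[tr$alt_base, 227] / depth
  p0 <- 1 / 32
  expect_lt(abs(vaf - p0), 3 * sqrt(p0 * (1 - p0) / depth))
})

test_that("per-position pool depth approximates coverage x pool size", {
  sc <- build_scheme(8, 2)
  amps <- generate_references(1, c(600, 600), divergence = 0, seed = 13)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 11.3,
                             error_rate = 0, seed = 14, pools = "R0")
  asn <- assign_reads(sim$pools[["R0"]], amps)
  cnt <- pileup(asn, amps)[[1]]
  depth <- colSums(cnt)
  interior <- 30:570
  expect_lt(abs(mean(depth[interior]) / (11.3 * 4) - 1), 0.05)
  expect_true(all(depth > 0))
})

test_that("simulation is bit-for-bit reproducible and subsettable", {
  sc <- build_scheme(8, 2)
  amps <- generate_references(2, c(452, 500), seed = 15)
  tr <- spike_mutations(sc, amps, 50, seed = 16)
  s1 <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 3, seed = 17)
  s2 <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 3, seed = 17)
  expect_identical(s1$pools, s2$pools)
  s3 <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 3, seed = 17,
                            pools = "C1")
  expect_identical(s3$pools[["C1"]], s1$pools[["C1"]])
})

test_that("reads longer than the amplicon are truncated with a warning", {
  sc <- build_scheme(4, 2)
  amps <- generate_references(1, c(100, 100), divergence = 0,
                              primer_length = 10, seed = 18)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  expect_warning(
    sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 4,
                               read_length = 150, error_rate = 0, seed = 19),
    "truncated")
  expect_true(all(nchar(sim$pools[["R0"]]$seq) == 100))
})

test_that("base quality encodes the error rate as a Phred score", {
  sc <- build_scheme(4, 2)
  amps <- generate_references(1, c(452, 452), seed = 20)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 1,
                             error_rate = 0.002, seed = 21, pools = "R0")
  expect_equal(utf8ToInt(sim$qual_char) - 33L, 27L)  # -10*log10(0.002) ~ 27
})
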