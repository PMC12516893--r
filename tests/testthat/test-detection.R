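test_that("test_position matches closed forms and handles edge cases", {
  r0 <- test_position(0, 100, error_rate = 0.002)
  expect_equal(r0$p_value, 1)
  expect_false(r0$pass)

  r1 <- test_position(10, 10, error_rate = 0.001, n_tests = 1)
  expect_equal(r1$p_value, (0.001 / 3)^10)
  expect_true(r1$pass)

  rz <- test_position(0, 0, error_rate = 0.002)
  expect_true(is.na(rz$p_value))
  expect_false(rz$pass)

  expect_error(test_position(5, 10, error_rate = 0), "error_rate")
  expect_error(test_position(11, 10, error_rate = 0.01), "alt_count")
})

test_that("binomial tail equals brute-force mass summation up to depth 1000", {
  brute_tail <- function(k, n, p) sum(dbinom(k:n, n, p))
  set.seed(50)
  for (i in 1:200) {
    n <- sample(1000, 1)
    k <- sample(n, 1)
    e <- runif(1, 1e-4, 0.05)
    expect_equal(test_position(k, n, e)$p_value, brute_tail(k, n, e / 3),
                 tolerance = 1e-12)
  }
  # a representative operating point: alt 6 of depth 720
  expect_equal(test_position(6, 720, 0.002)$p_value,
               brute_tail(6, 720, 0.002 / 3))
})

test_that("the EMS spectrum filter accepts exactly G>A and C>T", {
  expect_true(ems_canonical("G", "A"))
  expect_true(ems_canonical("C", "T"))
  expect_false(ems_canonical("A", "G"))
  expect_false(ems_canonical("T", "C"))
  expect_false(ems_canonical("G", "T"))
  expect_false(ems_canonical("C", "A"))
  expect_error(ems_canonical("N", "A"), "bases")
})

test_that("divergent sites are masked and never called", {
  a0 <- generate_references(2, c(452, 500), divergence = 0, seed = 51)
  expect_true(all(lengths(mask_divergent_sites(a0)) == 0))

  amps <- generate_references(1, c(452, 452), divergence = 0, seed = 52)
  substr(amps[[1]]$seq_b, 101, 101) <- setdiff(c("A", "C", "G", "T"),
                                               substr(amps[[1]]$seq_a, 101, 101))[1]
  expect_equal(mask_divergent_sites(amps)[[1]], 100L)

  # genome_mix 0.5 puts a ~25-50% VAF signal at the divergent site; the mask
  # must suppress it even with zero mutations and zero error
  sc <- build_scheme(64, 4)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 11.3,
                             error_rate = 0, genome_mix = 0.5, seed = 53)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  cand <- call_mutations(counts, sc, amps)
  expect_equal(nrow(cand), 0)
  vm <- export_vaf_matrix(counts, amps)
  expect_true(vm$masked[vm$pos == 100])
  expect_gt(max(vm[vm$pos == 100, sc$pool_labels]), 0.2)
})

test_that("a single spiked het mutation is called uniquely end-to-end", {
  cfg <- small_config()
  sc <- build_scheme(cfg$n_families, cfg$cube_dim)
  amps <- generate_references(cfg$n_amplicons, cfg$length_range,
                              cfg$divergence, seed = 54)
  sites <- which(strsplit(amps[[2]]$seq_a, "")[[1]] == "G" &
                 strsplit(amps[[2]]$seq_b, "")[[1]] == "G")
  pos <- sites[which.min(abs(sites - 250))] - 1L
  tr <- structure(data.frame(
    family_id = 37L, amplicon_id = names(amps)[2], position = pos,
    ref_base = "G", alt_base = "A", zygosity = "het", haplotype = 1L,
    stringsAsFactors = FALSE), class = c("simulation_truth", "data.frame"))
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = cfg$coverage,
                             error_rate = cfg$error_rate, seed = 55)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  cand <- call_mutations(counts, sc, amps)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$status, "unique")
  expect_equal(cand$families, "37")
  expect_equal(cand$position, pos)
  expect_equal(cand$alt_base, "A")
  expect_setequal(strsplit(cand$pools, ",")[[1]],
                  unname(pools_of(sc, 37L)))
})

test_that("two het mutations in pool-disjoint families give two unique calls", {
  cfg <- small_config()
  sc <- build_scheme(cfg$n_families, cfg$cube_dim)
  amps <- generate_references(cfg$n_amplicons, cfg$length_range,
                              cfg$divergence, seed = 56)
  pick_site <- function(a, near) {
    s <- which(strsplit(a$seq_a, "")[[1]] == "C" &
               strsplit(a$seq_b, "")[[1]] == "C")
    s[which.min(abs(s - near))] - 1L
  }
  # families 0 and 21 share no pool (cells (0,0,0) and (1,1,1))
  tr <- structure(data.frame(
    family_id = c(0L, 21L),
    amplicon_id = c(names(amps)[1], names(amps)[3]),
    position = c(pick_site(amps[[1]], 150), pick_site(amps[[3]], 300)),
    ref_base = "C", alt_base = "T", zygosity = "het", haplotype = 2L,
    stringsAsFactors = FALSE), class = c("simulation_truth", "data.frame"))
  expect_length(intersect(pools_of(sc, 0L), pools_of(sc, 21L)), 0)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = cfg$coverage,
                             error_rate = cfg$error_rate, seed = 57)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  cand <- call_mutations(counts, sc, amps)
  expect_equal(nrow(cand), 2)
  expect_true(all(cand$status == "unique"))
  expect_setequal(cand$families, c("0", "21"))
})

test_that("no mutations and no errors give zero candidates", {
  sc <- build_scheme(27, 3)
  amps <- generate_references(2, c(452, 500), divergence = 0, seed = 58)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 11.3,
                             error_rate = 0, seed = 59)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  expect_equal(nrow(call_mutations(counts, sc, amps)), 0)
  vm <- export_vaf_matrix(counts, amps)
  expect_true(all(vm[, sc$pool_labels] == 0))
})

test_that("counts missing an axis raise a configuration error", {
  sc <- build_scheme(8, 2)
  amps <- generate_references(1, c(452, 452), seed = 60)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 2, seed = 61)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  expect_error(call_mutations(counts[c("R0", "R1", "C0", "C1")], sc, amps),
               "axes.*D|missing: D")
})

test_that("emitted candidates always satisfy the EMS spectrum", {
  for (s in 62:64) {
    cfg <- small_config(seed = s, coverage = 15)
    r <- run_replicate(cfg)
    if (nrow(r$candidates))
      expect_true(all(ems_canonical(r$candidates$ref_base,
                                    r$candidates$alt_base)))
  }
  succeed()
})

test_that("the error-rate estimator recovers the simulated rate", {
  sc <- build_scheme(27, 3)
  amps <- generate_references(2, c(500, 600), divergence = 0, seed = 65)
  tr <- spike_mutations(sc, amps, freq_kb = Inf)
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 11.3,
                             error_rate = 0.002, seed = 66)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  est <- estimate_error_rate(counts, amps)
  expect_true(all(abs(est / 0.002 - 1) < 0.25))
  # floor engages when the data are clean
  sim0 <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 2,
                              error_rate = 0, seed = 67)
  counts0 <- lapply(sim0$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  expect_true(all(estimate_error_rate(counts0, amps) == 1e-4))
})

test_that("the VAF matrix localizes a het mutation to its three pools", {
  sc <- build_scheme(64, 4)
  amps <- generate_references(1, c(452, 452), divergence = 0, seed = 68)
  sites <- which(strsplit(amps[[1]]$seq_a, "")[[1]] == "G")
  pos <- sites[which.min(abs(sites - 200))] - 1L
  tr <- structure(data.frame(
    family_id = 42L, amplicon_id = names(amps), position = pos,
    ref_base = "G", alt_base = "A", zygosity = "het", haplotype = 1L,
    stringsAsFactors = FALSE), class = c("simulation_truth", "data.frame"))
  sim <- simulate_pool_reads(sc, amps, tr, coverage_per_family = 11.3,
                             error_rate = 0, seed = 69)
  counts <- lapply(sim$pools, function(reads)
    pileup(assign_reads(reads, amps), amps))
  vm <- export_vaf_matrix(counts, amps)
  row <- vm[vm$pos == pos, sc$pool_labels]
  expect_setequal(names(row)[row > 0.01], unname(pools_of(sc, 42L)))
})
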