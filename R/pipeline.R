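#' Pipeline configuration
#'
#' A single flat configuration object shared by every pipeline stage. The
#' defaults reproduce the platform-scale scenario: 512 M2 families on an 8x8x8
#' cube (24 pools of 64), 17 amplicons of 452-704 bp, 0.5% inter-genome
#' divergence, EMS spiking at one mutation per 320 kb screened (all
#' heterozygous), 11.3x per-family coverage, 150 bp reads at 0.2% error,
#' exact-binomial calling at alpha 0.05 with 3 supporting reads per pool,
#' a 2 bp essential splice-site window, and PACE design at Tm 57-63 C,
#' primer length 18-30 nt, product 60-120 bp.
#'
#' @param ... Named overrides of any default field.
#' @return A `tbys_config` list.
#' @examples
#' cfg <- tbys_config(n_families = 8, cube_dim = 2, seed = 7)
#' @export
tbys_config <- function(...) {
  cfg <- list(
    cube_dim = 8L,
    n_families = 512L,
    n_amplicons = 17L,
    length_range = c(452L, 704L),
    divergence = 0.005,
    n_exons_range = c(1L, 3L),
    primer_length = 20L,
    freq_kb = 320,
    het_fraction = 1,
    coverage = 11.3,
    error_rate = 0.002,
    genome_mix = 0.5,
    read_length = 150L,
    max_mismatch_frac = 0.1,
    alpha = 0.05,
    min_alt = 3L,
    mode = "strict",
    rescue = TRUE,
    splice_window = 2L,
    tm_window = c(57, 63),
    len_range = c(18L, 30L),
    product_range = c(60L, 120L),
    seed = 1L,
    output_dir = "tillseq_out"
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "tbys_config")
}

#' Load a YAML configuration file
#'
#' Fields in the file override the [tbys_config()] defaults; `...` overrides
#' both (command-line flags beat the file).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param ... Further overrides.
#' @return A `tbys_config`.
#' @export
load_config <- function(path = NULL, ...) {
  file_ov <- if (!is.null(path)) yaml::read_yaml(path) else list()
  do.call(tbys_config, utils::modifyList(file_ov, list(...)))
}

# Stage seeds derived from the run seed, kept inside 32-bit integer range.
.stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * stage) %% .Machine$integer.max)
}

#' Run the full pipeline in memory
#'
#' Generate references, spike mutations, simulate every pool, assign reads,
#' pile up, call, annotate and score -- without touching the file system.
#' Pools are processed one at a time, so platform-scale runs stay modest in
#' memory.
#'
#' @param config A [tbys_config()].
#' @return List: `amplicons`, `scheme`, `truth`, `counts`, `candidates`
#'   (annotated), `score`, `mapping_efficiency`, `n_reads`,
#'   `mean_pool_depth`.
#' @export
run_replicate <- function(config = tbys_config()) {
  stopifnot(inherits(config, "tbys_config"))
  amps <- generate_references(config$n_amplicons, config$length_range,
                              config$divergence, config$n_exons_range,
                              primer_length = config$primer_length,
                              seed = .stage_seed(config$seed, 1L))
  scheme <- build_scheme(config$n_families, config$cube_dim)
  truth <- spike_mutations(scheme, amps, config$freq_kb,
                           config$het_fraction,
                           seed = .stage_seed(config$seed, 2L))
  index <- build_kmer_index(amps)
  counts <- list()
  n_assigned <- 0L; n_total <- 0L; depth_sum <- numeric(0)
  for (pool in scheme$pool_labels) {
    sim <- simulate_pool_reads(scheme, amps, truth,
                               coverage_per_family = config$coverage,
                               read_length = config$read_length,
                               error_rate = config$error_rate,
                               genome_mix = config$genome_mix,
                               seed = .stage_seed(config$seed, 3L),
                               pools = pool)
    reads <- sim$pools[[pool]]
    asn <- assign_reads(reads, amps, config$max_mismatch_frac, index)
    counts[[pool]] <- pileup(asn, amps)
    n_assigned <- n_assigned + asn$n_assigned
    n_total <- n_total + nrow(reads)
    depth_sum[pool] <- mean(unlist(lapply(counts[[pool]], colSums)))
  }
  cand <- call_mutations(counts, scheme, amps, alpha = config$alpha,
                         min_alt = config$min_alt, mode = config$mode,
                         rescue = config$rescue)
  cand <- annotate_candidates(cand, amps, config$splice_window)
  list(amplicons = amps, scheme = scheme, truth = truth, counts = counts,
       candidates = cand, score = score_against_truth(cand, truth),
       mapping_efficiency = if (n_total) n_assigned / n_total else NaN,
       n_reads = n_total, mean_pool_depth = depth_sum)
}

#' Write a complete simulated fixture to disk
#'
#' Two parental FASTA references, the GFF3 gene models, the pooling-scheme
#' TSV, the truth sidecar TSV, one FASTQ per pool and a checksum manifest.
#'
#' @param config A [tbys_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
run_simulate <- function(config = tbys_config(), out_dir = config$output_dir) {
  stopifnot(inherits(config, "tbys_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  amps <- generate_references(config$n_amplicons, config$length_range,
                              config$divergence, config$n_exons_range,
                              primer_length = config$primer_length,
                              seed = .stage_seed(config$seed, 1L))
  scheme <- build_scheme(config$n_families, config$cube_dim)
  truth <- spike_mutations(scheme, amps, config$freq_kb,
                           config$het_fraction,
                           seed = .stage_seed(config$seed, 2L))
  files <- c(file.path(out_dir, "genome_A.fasta"),
             file.path(out_dir, "genome_B.fasta"),
             file.path(out_dir, "amplicons.gff3"),
             file.path(out_dir, "scheme.tsv"),
             file.path(out_dir, "truth.tsv"))
  write_reference_fasta(amps, files[1], files[2])
  write_gff3(amps, files[3])
  write_scheme_tsv(scheme, files[4])
  write_truth_tsv(truth, files[5])
  for (pool in scheme$pool_labels) {
    sim <- simulate_pool_reads(scheme, amps, truth,
                               coverage_per_family = config$coverage,
                               read_length = config$read_length,
                               error_rate = config$error_rate,
                               genome_mix = config$genome_mix,
                               seed = .stage_seed(config$seed, 3L),
                               pools = pool)
    fq <- file.path(out_dir, sprintf("pool_%s.fastq", pool))
    write_fastq(sim$pools[[pool]], fq, sim$qual_char)
    files <- c(files, fq)
  }
  write_manifest(out_dir, files, unclass(config),
                 list(stage = "simulate", n_pools = length(scheme$pool_labels)))
  invisible(out_dir)
}

#' Detect mutations from an on-disk fixture
#'
#' Reads the references, gene models, scheme and per-pool FASTQ files
#' produced by [run_simulate()], assigns and piles up every pool, calls and
#' annotates candidate EMS mutations, and writes `candidates.vcf`,
#' `candidates.tsv`, `pool_calls.tsv`, `vaf_matrix.tsv`, `allele_counts.tsv`
#' and `detect_summary.json`. Succeeds (and writes a header-only VCF) even
#' with zero candidates.
#'
#' @param config A [tbys_config()].
#' @param fixture_dir Directory from [run_simulate()].
#' @param out_dir Results directory (default `fixture_dir`).
#' @return Invisibly, the annotated candidate table.
#' @export
run_detect <- function(config = tbys_config(), fixture_dir,
                       out_dir = fixture_dir) {
  stopifnot(inherits(config, "tbys_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  amps <- read_references(file.path(fixture_dir, "genome_A.fasta"),
                          file.path(fixture_dir, "genome_B.fasta"),
                          file.path(fixture_dir, "amplicons.gff3"),
                          primer_length = config$primer_length)
  scheme <- read_scheme_tsv(file.path(fixture_dir, "scheme.tsv"))
  index <- build_kmer_index(amps)
  counts <- list(); eff <- list(); depths <- list()
  n_assigned <- 0L; n_total <- 0L
  for (pool in scheme$pool_labels) {
    fq <- file.path(fixture_dir, sprintf("pool_%s.fastq", pool))
    if (!file.exists(fq) && file.exists(paste0(fq, ".gz"))) fq <- paste0(fq, ".gz")
    if (!file.exists(fq))
      stop("missing pool FASTQ: ", fq, call. = FALSE)
    reads <- read_fastq(fq)
    asn <- assign_reads(reads, amps, config$max_mismatch_frac, index)
    counts[[pool]] <- pileup(asn, amps)
    eff[[pool]] <- asn$mapping_efficiency
    depths[[pool]] <- mean(unlist(lapply(counts[[pool]], colSums)))
    n_assigned <- n_assigned + asn$n_assigned
    n_total <- n_total + nrow(reads)
  }
  cand <- call_mutations(counts, scheme, amps, alpha = config$alpha,
                         min_alt = config$min_alt, mode = config$mode,
                         rescue = config$rescue)
  cand <- annotate_candidates(cand, amps, config$splice_window)

  write_candidates_vcf(cand, amps, file.path(out_dir, "candidates.vcf"))
  write.table(as.data.frame(cand), file.path(out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- attr(cand, "pool_calls")
  if (!is.null(calls))
    write.table(calls, file.path(out_dir, "pool_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(export_vaf_matrix(counts, amps),
              file.path(out_dir, "vaf_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts_tsv(counts, file.path(out_dir, "allele_counts.tsv"))
  jsonlite::write_json(
    list(stage = "detect",
         mapping_efficiency = if (n_total) n_assigned / n_total else NA,
         per_pool_efficiency = eff,
         per_pool_mean_depth = depths,
         error_rate_estimates = as.list(attr(cand, "error_rate")),
         n_tests = attr(cand, "n_tests"),
         n_candidates = nrow(cand)),
    file.path(out_dir, "detect_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cand)
}

#' Summarize a detection run
#'
#' Combines the candidate table, the detection summary and (when present)
#' the simulation truth into the platform report: candidate counts,
#' mutation frequency over the screened kilobases, mapping efficiency,
#' per-pool coverage, and sensitivity/precision against the truth. Without
#' a truth sidecar the truth-dependent fields are omitted with a warning.
#'
#' @param config A [tbys_config()].
#' @param fixture_dir Directory from [run_simulate()].
#' @param results_dir Directory from [run_detect()] (default
#'   `fixture_dir`).
#' @return The report, a list; also written to `report.json` and
#'   `report.tsv` in `results_dir`.
#' @export
run_report <- function(config = tbys_config(), fixture_dir,
                       results_dir = fixture_dir) {
  stopifnot(inherits(config, "tbys_config"))
  cand <- read.delim(file.path(results_dir, "candidates.tsv"),
                     stringsAsFactors = FALSE,
                     colClasses = c(amplicon_id = "character",
                                    families = "character"))
  summ <- jsonlite::read_json(file.path(results_dir, "detect_summary.json"),
                              simplifyVector = TRUE)
  amps <- read_references(file.path(fixture_dir, "genome_A.fasta"),
                          file.path(fixture_dir, "genome_B.fasta"),
                          file.path(fixture_dir, "amplicons.gff3"),
                          primer_length = config$primer_length)
  total_kb <- screened_kb(amps, config$n_families)
  freq <- mutation_frequency(nrow(cand), total_kb)
  report <- list(
    n_candidates = nrow(cand),
    n_unique = sum(cand$status == "unique"),
    n_ambiguous = sum(cand$status == "ambiguous"),
    total_screened_kb = total_kb,
    mutation_frequency_kb = freq$kb_per_mutation,
    mutation_frequency_label = freq$label,
    mapping_efficiency = summ$mapping_efficiency,
    per_pool_mean_depth = summ$per_pool_mean_depth
  )
  truth_path <- file.path(fixture_dir, "truth.tsv")
  if (file.exists(truth_path)) {
    truth <- read_truth_tsv(truth_path)
    sc <- score_against_truth(cand, truth)
    sc$n_candidates <- NULL   # already reported
    report <- c(report, sc)
  } else {
    warning("no truth sidecar found; truth-dependent fields omitted",
            call. = FALSE)
  }
  jsonlite::write_json(report, file.path(results_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  flat <- report[!vapply(report, is.list, TRUE)]
  write.table(data.frame(field = names(flat),
                         value = vapply(flat, function(x)
                           paste(format(x), collapse = ","), "")),
              file.path(results_dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report
}

#' Run simulate, detect and report in sequence
#'
#' @param config A [tbys_config()].
#' @param out_dir Output directory (default `config$output_dir`).
#' @return The [run_report()] report, invisibly.
#' @export
run_all <- function(config = tbys_config(), out_dir = config$output_dir) {
  run_simulate(config, out_dir)
  run_detect(config, out_dir)
  invisible(run_report(config, out_dir))
}
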