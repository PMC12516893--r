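#' Generate dual-haplotype amplicon references
#'
#' Builds a set of target amplicons as they would be PCR-amplified from two
#' parental genomes with low, substitution-only divergence. Each amplicon
#' carries a gene model (exon intervals, CDS frame, strand) and two primer
#' regions at its ends; primers sit in conserved sequence, so the two
#' parental sequences never differ inside them. The platform-scale screen uses
#' 17 amplicons of 452-704 bp from 13 genes.
#'
#' @param n_amplicons Number of amplicons.
#' @param length_range Integer vector `c(min, max)` amplicon length in bp.
#' @param divergence Per-base probability that the second parental genome
#'   carries a substitution (outside primers).
#' @param n_exons_range `c(min, max)` exons per amplicon gene model.
#' @param n_genes Number of distinct target genes; defaults to
#'   `ceiling(n_amplicons * 13 / 17)` so the platform-scale call gives 13.
#' @param primer_length Primer length in bp at each amplicon end.
#' @param seed Optional integer seed for reproducibility.
#' @return An `amplicon_set`: named list of amplicon models, each a list with
#'   `amplicon_id`, `gene_id`, `seq_a`, `seq_b`, `length`, `exons` (matrix of
#'   0-based half-open `start`,`end`), `cds_offset`, `strand`, `primer_fwd`,
#'   `primer_rev`, `primer_length`.
#' @examples
#' amps <- generate_references(2, c(452, 704), divergence = 0, seed = 1)
#' amps[[1]]$seq_a == amps[[1]]$seq_b   # TRUE at divergence 0
#' @export
generate_references <- function(n_amplicons = 17,
                                length_range = c(452L, 704L),
                                divergence = 0.005,
                                n_exons_range = c(1L, 3L),
                                n_genes = NULL,
                                primer_length = 20L,
                                seed = NULL) {
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("`length_range` must be c(min, max) with min <= max", call. = FALSE)
  if (length_range[1] < 1) stop("minimum amplicon length must be >= 1", call. = FALSE)
  if (divergence < 0 || divergence > 1)
    stop("`divergence` must be a probability in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_genes)) n_genes <- max(1L, as.integer(ceiling(n_amplicons * 13 / 17)))
  n_genes <- min(n_genes, n_amplicons)
  bases <- c("A", "C", "G", "T")

  # gene assignment: every gene gets one amplicon, extras distributed round-robin
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  gene_of <- gene_ids[((seq_len(n_amplicons) - 1L) %% n_genes) + 1L]

  amps <- vector("list", n_amplicons)
  for (i in seq_len(n_amplicons)) {
    L <- as.integer(if (length_range[1] == length_range[2]) length_range[1] else
      sample(length_range[1]:length_range[2], 1L))
    sa <- sample(bases, L, replace = TRUE)
    sb <- sa
    inner <- setdiff(seq_len(L), c(seq_len(primer_length),
                                   (L - primer_length + 1L):L))
    if (divergence > 0 && length(inner)) {
      div <- inner[runif(length(inner)) < divergence]
      for (p in div) sb[p] <- sample(setdiff(bases, sa[p]), 1L)
    }
    amps[[i]] <- list(
      amplicon_id = sprintf("amp%02d", i),
      gene_id = gene_of[i],
      seq_a = paste(sa, collapse = ""),
      seq_b = paste(sb, collapse = ""),
      length = L,
      exons = .draw_exons(L, primer_length, n_exons_range),
      cds_offset = sample(0:2, 1L),
      strand = sample(c("+", "-"), 1L),
      primer_fwd = paste(sa[seq_len(primer_length)], collapse = ""),
      primer_rev = revcomp(paste(sa[(L - primer_length + 1L):L], collapse = "")),
      primer_length = as.integer(primer_length)
    )
  }
  names(amps) <- vapply(amps, `[[`, "", "amplicon_id")
  structure(amps, class = "amplicon_set")
}

# Exon/intron layout inside the non-primer region: alternating blocks with
# minimum exon 40 bp and minimum intron 50 bp; coordinates 0-based half-open.
.draw_exons <- function(L, primer_length, n_exons_range) {
  lo <- as.integer(primer_length)
  hi <- as.integer(L - primer_length)  # exclusive
  span <- hi - lo
  min_ex <- 40L; min_in <- 50L
  n_max <- max(1L, (span + min_in) %/% (min_ex + min_in))
  n <- sample(max(1L, n_exons_range[1]):max(1L, min(n_exons_range[2], n_max)), 1L)
  if (n == 1L) return(matrix(c(lo, hi), 1L, 2L,
                             dimnames = list(NULL, c("start", "end"))))
  # distribute slack over 2n-1 alternating blocks (exon, intron, ..., exon)
  base_len <- rep(c(min_ex, min_in), length.out = 2L * n - 1L)
  slack <- span - sum(base_len)
  add <- if (slack > 0) tabulate(sample(2L * n - 1L, slack, replace = TRUE),
                                 nbins = 2L * n - 1L) else rep(0L, 2L * n - 1L)
  lens <- base_len + add
  ends <- lo + cumsum(lens)
  starts <- c(lo, ends[-length(ends)])
  ex <- seq(1L, 2L * n - 1L, by = 2L)
  matrix(c(starts[ex], ends[ex]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' @export
print.amplicon_set <- function(x, ...) {
  lens <- vapply(x, `[[`, 0L, "length")
  cat(sprintf("amplicon_set: %d amplicons (%d-%d bp), %d genes\n",
              length(x), min(lens), max(lens),
              length(unique(vapply(x, `[[`, "", "gene_id")))))
  invisible(x)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), "")
}

#' Spike EMS mutations into families
#'
#' Draws the number of induced mutations from a Poisson law with mean
#' `total screened kb / freq_kb`, where the screened total is
#' `sum(amplicon lengths) * n_families / 1000`. Each mutation lands on a
#' uniformly chosen G or C site (among sites where the two parental genomes
#' agree, since divergent sites are masked from calling), in a uniformly
#' chosen family, and follows the EMS alkylation spectrum: G>A, or C>T on the
#' other strand. At the platform-scale settings (17 amplicons x 512 families
#' at 1 mutation / 320 kb) the expected count is about 14.
#'
#' @param scheme A [build_scheme()] pooling scheme.
#' @param amplicons An [generate_references()] amplicon set.
#' @param freq_kb Screened kilobases per mutation (`Inf` for none).
#' @param het_fraction Probability that a mutation is heterozygous.
#' @param seed Optional integer seed.
#' @return A `data.frame` (class `simulation_truth`) with columns
#'   `family_id`, `amplicon_id`, `position` (0-based), `ref_base`,
#'   `alt_base`, `zygosity`, `haplotype` (1 or 2; the family haplotype
#'   carrying the allele; both if homozygous).
#' @export
spike_mutations <- function(scheme, amplicons, freq_kb = 320,
                            het_fraction = 1, seed = NULL) {
  stopifnot(inherits(scheme, "pooling_scheme"),
            inherits(amplicons, "amplicon_set"))
  if (freq_kb <= 0) stop("`freq_kb` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  total_kb <- screened_kb(amplicons, scheme$n_families)
  n <- if (is.infinite(freq_kb)) 0L else rpois(1L, total_kb / freq_kb)

  # eligible sites: G/C where both parental genomes agree
  sites <- do.call(rbind, lapply(amplicons, function(a) {
    sa <- strsplit(a$seq_a, "")[[1]]
    sb <- strsplit(a$seq_b, "")[[1]]
    keep <- which(sa == sb & sa %in% c("G", "C"))
    if (!length(keep)) return(NULL)
    data.frame(amplicon_id = a$amplicon_id, position = keep - 1L,
               ref_base = sa[keep], stringsAsFactors = FALSE)
  }))
  empty <- data.frame(family_id = integer(), amplicon_id = character(),
                      position = integer(), ref_base = character(),
                      alt_base = character(), zygosity = character(),
                      haplotype = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(structure(empty, class = c("simulation_truth", "data.frame")))
  if (is.null(sites) || !nrow(sites))
    stop("no G/C sites available for EMS spiking", call. = FALSE)

  pick <- sample(nrow(sites), n, replace = TRUE)
  truth <- sites[pick, , drop = FALSE]
  truth$family_id <- sample(scheme$cells$family_id, n, replace = TRUE)
  # one mutation per (family, site): drop duplicate draws
  truth <- truth[!duplicated(truth[c("family_id", "amplicon_id", "position")]), ]
  n <- nrow(truth)
  truth$alt_base <- ifelse(truth$ref_base == "G", "A", "T")
  truth$zygosity <- ifelse(runif(n) < het_fraction, "het", "hom")
  truth$haplotype <- sample(1:2, n, replace = TRUE)
  truth <- truth[order(truth$amplicon_id, truth$position, truth$family_id),
                 c("family_id", "amplicon_id", "position", "ref_base",
                   "alt_base", "zygosity", "haplotype")]
  rownames(truth) <- NULL
  structure(truth, class = c("simulation_truth", "data.frame"))
}

#' Total screened sequence in kilobases
#'
#' `sum(amplicon lengths) * n_families / 1000` -- the denominator of the
#' platform mutation frequency.
#'
#' @inheritParams spike_mutations
#' @param n_families Number of families screened.
#' @return Numeric, kilobases.
#' @export
screened_kb <- function(amplicons, n_families) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  sum(vapply(amplicons, `[[`, 0L, "length")) * n_families / 1000
}
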