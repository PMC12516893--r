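#' Simulate pooled amplicon sequencing reads
#'
#' Emulates sequencing of the three-dimensional DNA pools: every family in a
#' pool contributes reads from its two haplotypes (each haplotype is parental
#' genome A or B, drawn once per family with probability `genome_mix` of
#' being B), a heterozygous spiked mutation rides on one haplotype (expected
#' pool VAF `1/(2 * pool size)`), and uniform substitution errors are applied
#' at `error_rate`. Reads are tiled at evenly spaced, amplicon-clipped start
#' positions so that per-position depth is close to
#' `coverage_per_family * pool size` across the whole amplicon; the
#' per-family read count is deterministic, emulating equimolar pooling.
#' Read names encode pool and amplicon but never the family -- recovering the
#' family is the deconvolution problem.
#'
#' With `seed` set, each pool is simulated under its own derived seed, so any
#' subset of pools reproduces bit-for-bit.
#'
#' @inheritParams spike_mutations
#' @param truth A [spike_mutations()] truth table.
#' @param coverage_per_family Fold coverage contributed by each family.
#' @param read_length Read length in bp; reads longer than an amplicon are
#'   truncated with a warning.
#' @param error_rate Per-base substitution error probability (< 0.25).
#' @param genome_mix Probability that a family haplotype is parental genome B.
#' @param seed Optional integer seed.
#' @param pools Pool labels to simulate (default: all pools in the scheme).
#' @return List with `pools` (named list of `data.frame(id, seq)`),
#'   `qual_char` (constant Phred character consistent with `error_rate`) and
#'   `fam_haplotypes` (n_families x 2 matrix of "A"/"B").
#' @export
simulate_pool_reads <- function(scheme, amplicons, truth,
                                coverage_per_family = 11.3,
                                read_length = 150L,
                                error_rate = 0.002,
                                genome_mix = 0.5,
                                seed = NULL,
                                pools = NULL) {
  stopifnot(inherits(scheme, "pooling_scheme"),
            inherits(amplicons, "amplicon_set"))
  if (coverage_per_family <= 0) stop("`coverage_per_family` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.25)
    stop("`error_rate` must be in [0, 0.25)", call. = FALSE)
  if (is.null(pools)) pools <- scheme$pool_labels
  if (!is.null(seed)) set.seed(seed)
  fam_hap <- matrix(
    c("A", "B")[rbinom(scheme$n_families * 2L, 1L, genome_mix) + 1L],
    nrow = scheme$n_families, ncol = 2L
  )
  long <- vapply(amplicons, `[[`, 0L, "length")
  if (read_length > min(long))
    warning(sprintf("read_length %d exceeds shortest amplicon (%d bp); reads truncated",
                    read_length, min(long)), call. = FALSE)
  out <- vector("list", length(pools))
  names(out) <- pools
  for (i in seq_along(pools)) {
    if (!is.null(seed))
      set.seed((seed + 7919L * match(pools[i], scheme$pool_labels)) %%
                 .Machine$integer.max)
    out[[i]] <- .sim_pool(pools[i], scheme, amplicons, truth, fam_hap,
                          coverage_per_family, read_length, error_rate)
  }
  phred <- if (error_rate > 0) max(2L, min(40L, round(-10 * log10(error_rate)))) else 40L
  list(pools = out, qual_char = intToUtf8(phred + 33L), fam_haplotypes = fam_hap)
}

# Simulate one pool: all member families x all amplicons.
.sim_pool <- function(pool, scheme, amplicons, truth, fam_hap,
                      coverage, read_length, error_rate) {
  members <- pool_members(scheme, pool)
  nf <- length(members)
  blocks <- vector("list", length(amplicons))
  for (ai in seq_along(amplicons)) {
    a <- amplicons[[ai]]
    L <- a$length
    rl <- min(read_length, L)
    k <- 21L  # seed-anchor length the mapper relies on; reads never shorter
    if (rl >= L) {
      starts <- 0L
      nr <- max(1L, as.integer(round(coverage)))
      starts <- rep(starts, nr)
    } else {
      span_lo <- -(rl - k); span_hi <- L - k
      # clipped tiling grid: starts below 0 yield left-clipped reads, so
      # terminal positions keep near-full depth
      nr <- max(2L, as.integer(round(coverage * (span_hi - span_lo) / rl)) + 1L)
      starts <- as.integer(round(seq(span_lo, span_hi, length.out = nr)))
    }
    n <- nf * nr
    fam <- rep(members, each = nr)
    s <- rep(starts, times = nf)
    s0 <- pmax(s, 0L)
    e0 <- pmin(s + rl, L)
    hap <- rbinom(n, 1L, 0.5) + 1L
    gen <- fam_hap[cbind(fam + 1L, hap)]
    seqs <- character(n)
    ia <- gen == "A"
    if (any(ia))  seqs[ia]  <- substring(a$seq_a, s0[ia] + 1L, e0[ia])
    if (any(!ia)) seqs[!ia] <- substring(a$seq_b, s0[!ia] + 1L, e0[!ia])
    tr <- truth[truth$amplicon_id == a$amplicon_id & truth$family_id %in% members, ,
                drop = FALSE]
    if (nrow(tr)) {
      for (j in seq_len(nrow(tr))) {
        p <- tr$position[j]
        sel <- fam == tr$family_id[j] & s0 <= p & e0 > p &
          (tr$zygosity[j] == "hom" | hap == tr$haplotype[j])
        if (any(sel))
          substr(seqs[sel], p - s0[sel] + 1L, p - s0[sel] + 1L) <- tr$alt_base[j]
      }
    }
    seqs <- cpp_inject_errors(seqs, error_rate)
    blocks[[ai]] <- data.frame(
      id = sprintf("%s:%s:%06d", pool, a$amplicon_id, seq_len(n)),
      seq = seqs, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, blocks)
}
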