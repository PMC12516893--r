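#' Build the exact-seed index over both parental references
#'
#' Every k-mer of every amplicon, in both parental genomes, keyed to its
#' (amplicon, offset). The mapper anchors each read by exact k-mer lookup and
#' then scores it by full-length Hamming distance against both genomes.
#'
#' @inheritParams spike_mutations
#' @param k Seed length in bp.
#' @return A `kmer_index` list used by [assign_reads()].
#' @export
build_kmer_index <- function(amplicons, k = 21L) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  km <- character(0); amp <- integer(0); pos <- integer(0)
  for (i in seq_along(amplicons)) {
    a <- amplicons[[i]]
    if (a$length < k) next
    off <- 0:(a$length - k)
    for (s in c(a$seq_a, a$seq_b)) {
      km <- c(km, substring(s, off + 1L, off + k))
      amp <- c(amp, rep.int(i, length(off)))
      pos <- c(pos, off)
    }
  }
  keep <- !duplicated(km)
  structure(list(kmers = km[keep], amp = amp[keep], pos = pos[keep],
                 k = as.integer(k)),
            class = "kmer_index")
}

#' Assign pooled reads to amplicons and parental genomes
#'
#' Seed-anchored Hamming alignment: each read is placed by exact lookup of
#' its leading k-mer in the dual-genome index (falling back to its trailing
#' k-mer, then to both anchors of the reverse complement), and scored by
#' full-length mismatch count against both parental sequences at that offset.
#' The read is assigned to the genome with fewer mismatches (ties to genome
#' A) when the mismatch fraction is at most `max_mismatch_frac`.
#' Reverse-complement hits are re-oriented to the reference-forward strand
#' before pileup.
#'
#' @param reads `data.frame(id, seq)` (e.g. [read_fastq()] or a pool from
#'   [simulate_pool_reads()]).
#' @inheritParams spike_mutations
#' @param max_mismatch_frac Maximum mismatch fraction for assignment.
#' @param index Optional prebuilt [build_kmer_index()] (rebuilt otherwise).
#' @return A `read_assignment`: list with `assignments` (data.frame `id`,
#'   `amplicon_id`, `offset` 0-based, `genome`, `mismatches`, `assigned`,
#'   `seq` reference-forward oriented), `mapping_efficiency` (`NaN` for
#'   empty input), `n_assigned`, `n_unassigned`.
#' @export
assign_reads <- function(reads, amplicons, max_mismatch_frac = 0.1,
                         index = NULL) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  if (is.null(index)) index <- build_kmer_index(amplicons)
  k <- index$k
  n <- nrow(reads)
  if (n == 0L) {
    return(structure(list(
      assignments = data.frame(id = character(), amplicon_id = character(),
                               offset = integer(), genome = character(),
                               mismatches = integer(), assigned = logical(),
                               seq = character(), stringsAsFactors = FALSE),
      mapping_efficiency = NaN, n_assigned = 0L, n_unassigned = 0L),
      class = "read_assignment"))
  }
  seqs <- reads$seq
  len <- nchar(seqs)
  amp <- rep(NA_integer_, n); off <- rep(NA_integer_, n)

  try_anchor <- function(idx, kmer, shift) {
    hit <- match(kmer, index$kmers)
    ok <- !is.na(hit)
    amp[idx[ok]] <<- index$amp[hit[ok]]
    off[idx[ok]] <<- index$pos[hit[ok]] - shift[ok]
    idx[!ok]
  }
  todo <- which(len >= k)
  todo <- try_anchor(todo, substr(seqs[todo], 1L, k), rep(0L, length(todo)))
  if (length(todo))
    todo <- try_anchor(todo, substr(seqs[todo], len[todo] - k + 1L, len[todo]),
                       len[todo] - k)
  if (length(todo)) {
    rc <- revcomp(seqs[todo])
    before <- todo
    todo <- try_anchor(todo, substr(rc, 1L, k), rep(0L, length(todo)))
    done_rc <- setdiff(before, todo)
    if (length(todo)) {
      keep <- match(todo, before)
      todo2 <- try_anchor(todo, substr(rc[keep], len[todo] - k + 1L, len[todo]),
                          len[todo] - k)
      done_rc <- c(done_rc, setdiff(todo, todo2))
      todo <- todo2
    }
    if (length(done_rc)) seqs[done_rc] <- revcomp(reads$seq[done_rc])
  }

  mm <- rep(NA_integer_, n); gen <- rep(NA_character_, n)
  for (i in seq_along(amplicons)) {
    sel <- which(!is.na(amp) & amp == i)
    if (!length(sel)) next
    # negative anchor offsets cannot be genuine placements
    bad <- off[sel] < 0L
    if (any(bad)) { amp[sel[bad]] <- NA_integer_; sel <- sel[!bad] }
    if (!length(sel)) next
    ma <- cpp_mismatch(seqs[sel], off[sel], amplicons[[i]]$seq_a)
    mb <- cpp_mismatch(seqs[sel], off[sel], amplicons[[i]]$seq_b)
    gen[sel] <- ifelse(mb < ma, "B", "A")
    mm[sel] <- pmin(ma, mb)
  }
  assigned <- !is.na(amp) & !is.na(mm) & mm / len <= max_mismatch_frac
  res <- data.frame(
    id = reads$id,
    amplicon_id = ifelse(assigned, names(amplicons)[amp], NA_character_),
    offset = ifelse(assigned, off, NA_integer_),
    genome = ifelse(assigned, gen, NA_character_),
    mismatches = mm,
    assigned = assigned,
    seq = seqs,
    stringsAsFactors = FALSE
  )
  structure(list(
    assignments = res,
    mapping_efficiency = if (n) sum(assigned) / n else NaN,
    n_assigned = sum(assigned),
    n_unassigned = n - sum(assigned)),
    class = "read_assignment")
}

#' @export
print.read_assignment <- function(x, ...) {
  cat(sprintf("read_assignment: %d assigned / %d unassigned (efficiency %.2f%%)\n",
              x$n_assigned, x$n_unassigned, 100 * x$mapping_efficiency))
  invisible(x)
}

#' Pile assigned reads into per-amplicon allele counts
#'
#' Counts are accumulated in amplicon coordinates on the genome-A frame
#' (valid for genome-B reads too, since parental divergence is
#' substitution-only). At every position `A+C+G+T <= depth of covering
#' reads`; non-ACGT bases are excluded.
#'
#' @param assignment An [assign_reads()] result.
#' @inheritParams spike_mutations
#' @return An `allele_counts`: named list (amplicon id -> 4 x L integer
#'   matrix, rows `A`,`C`,`G`,`T`), with attributes `n_assigned` and
#'   `n_unassigned`.
#' @export
pileup <- function(assignment, amplicons) {
  stopifnot(inherits(assignment, "read_assignment"),
            inherits(amplicons, "amplicon_set"))
  df <- assignment$assignments
  out <- lapply(amplicons, function(a) {
    sel <- which(df$assigned & df$amplicon_id == a$amplicon_id)
    m <- cpp_pileup(df$seq[sel], df$offset[sel], a$length)
    rownames(m) <- c("A", "C", "G", "T")
    m
  })
  names(out) <- names(amplicons)
  structure(out, class = "allele_counts",
            n_assigned = assignment$n_assigned,
            n_unassigned = assignment$n_unassigned)
}

#' Export read assignments as minimal SAM
#'
#' Mandatory columns only, unsorted; unassigned reads carry flag 4.
#'
#' @inheritParams pileup
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(assignment, amplicons, path) {
  stopifnot(inherits(assignment, "read_assignment"))
  df <- assignment$assignments
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(amplicons, function(a)
             sprintf("@SQ\tSN:%s\tLN:%d", a$amplicon_id, a$length), ""))
  flag <- ifelse(df$assigned, 0L, 4L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 df$id, flag,
                 ifelse(df$assigned, df$amplicon_id, "*"),
                 ifelse(df$assigned, df$offset + 1L, 0L),
                 ifelse(df$assigned, 255L, 0L),
                 ifelse(df$assigned, paste0(nchar(df$seq), "M"), "*"),
                 df$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
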