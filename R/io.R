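#' Write the two parental reference FASTA files
#'
#' One FASTA per parental genome; records are the amplicon sequences, named
#' by `amplicon_id` (identical coordinates in both files, divergence is
#' substitution-only).
#'
#' @inheritParams spike_mutations
#' @param path_a,path_b Output FASTA paths for genomes A and B.
#' @return Invisibly, `c(path_a, path_b)`.
#' @export
write_reference_fasta <- function(amplicons, path_a, path_b) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  ids <- names(amplicons)
  sa <- Biostrings::DNAStringSet(vapply(amplicons, `[[`, "", "seq_a"))
  sb <- Biostrings::DNAStringSet(vapply(amplicons, `[[`, "", "seq_b"))
  names(sa) <- ids; names(sb) <- ids
  Biostrings::writeXStringSet(sa, path_a)
  Biostrings::writeXStringSet(sb, path_b)
  invisible(c(path_a, path_b))
}

#' Write amplicon gene models as GFF3
#'
#' One `gene` and one `CDS` feature per exon, per amplicon. Coordinates are
#' converted from the package's 0-based half-open convention to GFF3's
#' 1-based inclusive; CDS phase encodes the reading frame of each exon in
#' transcription order.
#'
#' @inheritParams spike_mutations
#' @param path Output GFF3 path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(amplicons, path) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  rows <- lapply(amplicons, function(a) {
    ex <- a$exons
    n <- nrow(ex)
    lens <- ex[, "end"] - ex[, "start"]
    ord <- if (a$strand == "+") seq_len(n) else rev(seq_len(n))
    cum <- c(0L, cumsum(lens[ord]))[seq_len(n)]
    frame <- (cum + a$cds_offset) %% 3L
    phase <- (3L - frame) %% 3L
    phase_by_exon <- integer(n); phase_by_exon[ord] <- phase
    data.frame(
      seqnames = a$amplicon_id,
      start = c(1L, ex[, "start"] + 1L),
      end = c(a$length, ex[, "end"]),
      strand = a$strand,
      type = c("gene", rep("CDS", n)),
      phase = c(NA_integer_, phase_by_exon),
      ID = c(paste0(a$amplicon_id, ".gene"),
             sprintf("%s.cds%d", a$amplicon_id, seq_len(n))),
      gene_id = a$gene_id,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$source <- "tillseq"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read an amplicon set back from FASTA + GFF3
#'
#' Inverse of [write_reference_fasta()] + [write_gff3()].
#'
#' @param path_a,path_b Parental FASTA files (genomes A and B).
#' @param gff3 GFF3 gene-model file.
#' @param primer_length Primer length used when the references were built.
#' @return An `amplicon_set`.
#' @export
read_references <- function(path_a, path_b, gff3, primer_length = 20L) {
  sa <- Biostrings::readDNAStringSet(path_a)
  sb <- Biostrings::readDNAStringSet(path_b)
  names(sa) <- sub("\\s.*", "", names(sa))
  names(sb) <- sub("\\s.*", "", names(sb))
  if (!identical(sort(names(sa)), sort(names(sb))))
    stop("the two reference FASTA files name different amplicons", call. = FALSE)
  gr <- rtracklayer::import(gff3)
  amps <- lapply(names(sa), function(id) {
    seq_a <- as.character(sa[[id]])
    seq_b <- as.character(sb[[id]])
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == id]
    cds <- sub[S4Vectors::mcols(sub)$type == "CDS"]
    cds <- cds[order(GenomicRanges::start(cds))]
    ex <- cbind(start = GenomicRanges::start(cds) - 1L,
                end = GenomicRanges::end(cds))
    strand <- as.character(GenomicRanges::strand(cds))[1]
    ph <- as.integer(S4Vectors::mcols(cds)$phase)
    first <- if (strand == "+") 1L else length(ph)
    cds_offset <- (3L - ph[first]) %% 3L
    gene <- S4Vectors::mcols(sub)$gene_id[1]
    L <- nchar(seq_a)
    list(
      amplicon_id = id, gene_id = gene, seq_a = seq_a, seq_b = seq_b,
      length = L, exons = ex, cds_offset = cds_offset, strand = strand,
      primer_fwd = substr(seq_a, 1L, primer_length),
      primer_rev = revcomp(substr(seq_a, L - primer_length + 1L, L)),
      primer_length = as.integer(primer_length)
    )
  })
  names(amps) <- names(sa)
  structure(amps[order(names(amps))], class = "amplicon_set")
}

#' Write reads as FASTQ
#'
#' @param reads `data.frame(id, seq)` as produced by [simulate_pool_reads()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param qual_char Constant base-quality character.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  qual <- strrep(qual_char, nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (optionally gzipped).
#' @return `data.frame(id, seq)`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read the simulation truth sidecar TSV
#'
#' @param truth A [spike_mutations()] table.
#' @param path File path.
#' @return `write_truth_tsv()` returns `path` invisibly; `read_truth_tsv()`
#'   the truth `data.frame`.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(amplicon_id = "character"))
  structure(df, class = c("simulation_truth", "data.frame"))
}

#' Export per-pool allele counts as TSV
#'
#' Long format: `pool`, `amplicon`, `pos` (0-based), `A`, `C`, `G`, `T`,
#' `depth`.
#'
#' @param counts Named list (pool -> [pileup()] result).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  rows <- lapply(names(counts), function(pool) {
    cc <- counts[[pool]]
    do.call(rbind, lapply(names(cc), function(amp) {
      m <- cc[[amp]]
      data.frame(pool = pool, amplicon = amp, pos = seq_len(ncol(m)) - 1L,
                 A = m["A", ], C = m["C", ], G = m["G", ], T = m["T", ],
                 depth = colSums(m), stringsAsFactors = FALSE)
    }))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write candidate mutations as VCF
#'
#' One record per candidate; `CHROM` is the amplicon id, positions are
#' 1-based per the VCF standard. INFO carries the supporting pools, the
#' deconvolution status and families, the combined p-value and, when
#' annotated, the predicted effect.
#'
#' @param candidates A [call_mutations()] candidate table.
#' @inheritParams spike_mutations
#' @param path Output VCF path.
#' @return Invisibly, `path`.
#' @export
write_candidates_vcf <- function(candidates, amplicons, path) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=tillseq_%s", as.character(packageVersion("tillseq"))),
    vapply(amplicons, function(a)
      sprintf("##contig=<ID=%s,length=%d>", a$amplicon_id, a$length), ""),
    "##INFO=<ID=POOLS,Number=1,Type=String,Description=\"Supporting pools\">",
    "##INFO=<ID=FAMILIES,Number=1,Type=String,Description=\"Candidate family ids\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Deconvolution status\">",
    "##INFO=<ID=PCOMB,Number=1,Type=Float,Description=\"Combined binomial p-value\">",
    "##INFO=<ID=LOWCONF,Number=0,Type=Flag,Description=\"Two-axis (permissive) call\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Predicted effect class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- character(0)
  if (!is.null(candidates) && nrow(candidates)) {
    info <- sprintf("POOLS=%s;FAMILIES=%s;STATUS=%s;PCOMB=%.3g",
                    gsub(",", "|", candidates$pools),
                    gsub(",", "|", candidates$families),
                    candidates$status, candidates$p_combined)
    if (!is.null(candidates$low_confidence))
      info <- paste0(info, ifelse(candidates$low_confidence, ";LOWCONF", ""))
    if (!is.null(candidates$effect_class))
      info <- paste0(info, ";EFF=", candidates$effect_class)
    qual <- round(pmin(999, -10 * log10(pmax(candidates$p_combined, 1e-99))), 1)
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\t%s",
                    candidates$amplicon_id, candidates$position + 1L,
                    candidates$ref_base, candidates$alt_base, qual, info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# Run manifest: inputs, seed, package version, file checksums.
write_manifest <- function(dir, files, config, extra = list()) {
  man <- c(list(
    package = "tillseq",
    version = as.character(packageVersion("tillseq")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = as.list(tools::md5sum(files[file.exists(files)]))
  ), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
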