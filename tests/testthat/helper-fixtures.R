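# Shared fixtures, built in code.

# Independent frozen copy of the standard genetic code, used as the oracle
# for translation checks.
.std_code <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# A hand-built amplicon model with fully known gene structure, for
# annotation and marker tests. Layout (0-based, half-open):
#   primers [0,20) and [180,200); exon1 [30,90), intron [90,120),
#   exon2 [120,170); CDS frame 0 on the plus strand unless overridden.
tiny_amplicon <- function(seq = NULL, strand = "+", cds_offset = 0L,
                          seed = 99L) {
  if (is.null(seq)) {
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  }
  L <- nchar(seq)
  list(
    amplicon_id = "tiny01", gene_id = "geneT", seq_a = seq, seq_b = seq,
    length = L,
    exons = matrix(c(30L, 120L, 90L, 170L), ncol = 2,
                   dimnames = list(NULL, c("start", "end"))),
    cds_offset = as.integer(cds_offset), strand = strand,
    primer_fwd = substr(seq, 1, 20),
    primer_rev = tillseq::revcomp(substr(seq, L - 19, L)),
    primer_length = 20L
  )
}

tiny_amplicon_set <- function(...) {
  a <- tiny_amplicon(...)
  structure(setNames(list(a), a$amplicon_id), class = "amplicon_set")
}

# Small-but-detectable pipeline configuration: 64 families on a 4^3 cube,
# high coverage so single spiked mutations are recovered deterministically.
small_config <- function(...) {
  tbys_config(n_families = 64L, cube_dim = 4L, n_amplicons = 3L,
              coverage = 30, seed = 101L, ...)
}

# Brute-force deconvolution oracle: enumerate every occupied cell and keep
# families consistent with the positive-pool pattern on every axis that has
# at least one positive pool.
brute_deconvolve <- function(scheme, positive) {
  ax <- substr(positive, 1, 1)
  idx <- as.integer(substr(positive, 2, nchar(positive)))
  keep <- vapply(seq_len(nrow(scheme$cells)), function(i) {
    cell <- scheme$cells[i, ]
    for (a in c("R", "C", "D")) {
      want <- idx[ax == a]
      if (!length(want)) next
      have <- switch(a, R = cell$r, C = cell$c, D = cell$d)
      if (!have %in% want) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(scheme$cells$family_id[keep])
}
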