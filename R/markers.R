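# Unified nearest-neighbor thermodynamic parameters (SantaLucia 1998):
# dH in kcal/mol, dS in cal/(mol K), 1 M NaCl reference state.
.nn_dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Nearest-neighbor melting temperature of a primer
#'
#' Two-state nearest-neighbor model with the unified duplex parameter set:
#' stacking dH/dS summed over dinucleotides, terminal initiation penalties
#' (G/C: dH 0.1, dS -2.8; A/T: dH 2.3, dS 4.1), monovalent-salt entropy
#' correction `0.368 * (n-1) * ln[Na+]`, and
#' `Tm = 1000 * dH / (dS + R * ln(C/4)) - 273.15` for a non-self-complementary
#' duplex at primer concentration `C`.
#'
#' @param seq Primer sequence, 5'->3' (ACGT).
#' @param na Monovalent cation concentration, mol/L.
#' @param primer_conc Primer concentration, mol/L.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' tm_nn("ACGTACGTACGTACGTACGT")
#' @export
tm_nn <- function(seq, na = 0.05, primer_conc = 2e-7) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 2) stop("primer must be at least 2 nt", call. = FALSE)
  b <- strsplit(s, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("primer must be ACGT only", call. = FALSE)
  pairs <- paste0(b[-n], b[-1])
  dH <- sum(.nn_dH[pairs])
  dS <- sum(.nn_dS[pairs])
  for (term in b[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na)
  1000 * dH / (dS + 1.987 * log(primer_conc / 4)) - 273.15
}

# Standard universal fluorophore tails for competitive allele-specific PCR.
.pace_tails <- c(FAM = "GAAGGTGACCAAGTTCATGCT",
                 HEX = "GAAGGTCGGAGTCAACGGATT")

#' Design a PACE/KASP allele-specific PCR marker for a SNP
#'
#' Two allele-specific primers end exactly at the SNP (3'-terminal base =
#' allele) and differ only in that base and their universal fluorophore
#' tails (FAM for the reference allele, HEX for the alternate); one common
#' reverse-strand primer sits downstream. Allele primers are grown 5'-ward
#' from the SNP, and the common primer is scanned over lengths and
#' positions, until each melting temperature ([tm_nn()], tails excluded)
#' falls inside `tm_window` and the product size inside `product_range`.
#'
#' @param amplicon One amplicon model from [generate_references()].
#' @param snp List or one-row data.frame with `position` (0-based),
#'   `ref_base`, `alt_base`.
#' @param tm_window `c(min, max)` primer melting temperature, degrees C.
#' @param len_range `c(min, max)` primer length, nt.
#' @param product_range `c(min, max)` product size, bp.
#' @param na,primer_conc Passed to [tm_nn()].
#' @return A `marker_design`: list with `snp`, `allele_primer_ref`,
#'   `allele_primer_alt` (tailed), `core_ref`, `core_alt`, `common_primer`,
#'   `tm_ref`, `tm_alt`, `tm_common`, `product_size`, `common_start`
#'   (0-based position of the common primer's 3' end on the forward strand).
#' @export
design_pace <- function(amplicon, snp,
                        tm_window = c(57, 63),
                        len_range = c(18L, 30L),
                        product_range = c(60L, 120L),
                        na = 0.05, primer_conc = 2e-7) {
  a <- amplicon
  pos <- as.integer(snp$position)
  ref <- as.character(snp$ref_base)
  alt <- as.character(snp$alt_base)
  if (substr(a$seq_a, pos + 1L, pos + 1L) != ref)
    stop("SNP ref_base does not match the amplicon sequence", call. = FALSE)
  if (pos - len_range[2] + 1L < 0L)
    stop(sprintf("design error: insufficient 5' flank (%d bases upstream of the SNP, %d required)",
                 pos, len_range[2]), call. = FALSE)

  grow_allele <- function() {
    for (len in len_range[1]:len_range[2]) {
      core <- substr(a$seq_a, pos - len + 2L, pos + 1L)
      tm <- tm_nn(core, na, primer_conc)
      if (tm >= tm_window[1] && tm <= tm_window[2]) return(list(core = core, tm = tm))
    }
    stop(sprintf("design error: no allele primer of length %d-%d reaches Tm %.0f-%.0f C",
                 len_range[1], len_range[2], tm_window[1], tm_window[2]),
         call. = FALSE)
  }
  al <- grow_allele()
  core_ref <- al$core
  core_alt <- core_ref
  substr(core_alt, nchar(core_alt), nchar(core_alt)) <- alt
  a_start <- pos - nchar(core_ref) + 1L   # 0-based 5' start of allele primers

  # common primer on the minus strand: its 5' end (rightmost base, 0-based
  # p2) sets the product size; its 3' end (p2 - len + 1) must lie past the SNP
  found <- NULL
  for (size in product_range[1]:product_range[2]) {
    p2 <- a_start + size - 1L
    if (p2 > a$length - 1L) break
    for (len in len_range[1]:len_range[2]) {
      p3 <- p2 - len + 1L
      if (p3 <= pos) break
      core <- revcomp(substr(a$seq_a, p3 + 1L, p2 + 1L))
      tm <- tm_nn(core, na, primer_conc)
      if (tm >= tm_window[1] && tm <= tm_window[2]) {
        found <- list(core = core, tm = tm, p2 = p2, size = size, p3 = p3)
        break
      }
    }
    if (!is.null(found)) break
  }
  if (is.null(found))
    stop(sprintf("design error: no common primer satisfies product size %d-%d bp with Tm %.0f-%.0f C",
                 product_range[1], product_range[2], tm_window[1], tm_window[2]),
         call. = FALSE)

  structure(list(
    snp = list(amplicon_id = a$amplicon_id, position = pos,
               ref_base = ref, alt_base = alt),
    allele_primer_ref = paste0(.pace_tails[["FAM"]], core_ref),
    allele_primer_alt = paste0(.pace_tails[["HEX"]], core_alt),
    core_ref = core_ref, core_alt = core_alt,
    common_primer = found$core,
    tm_ref = al$tm,
    tm_alt = tm_nn(core_alt, na, primer_conc),
    tm_common = found$tm,
    product_size = found$size,
    common_start = found$p3
  ), class = "marker_design")
}

#' @export
print.marker_design <- function(x, ...) {
  cat(sprintf("PACE marker %s:%d %s>%s | product %d bp\n",
              x$snp$amplicon_id, x$snp$position, x$snp$ref_base,
              x$snp$alt_base, x$product_size))
  cat(sprintf("  FAM(ref): %s (Tm %.1f)\n", x$allele_primer_ref, x$tm_ref))
  cat(sprintf("  HEX(alt): %s (Tm %.1f)\n", x$allele_primer_alt, x$tm_alt))
  cat(sprintf("  common  : %s (Tm %.1f)\n", x$common_primer, x$tm_common))
  invisible(x)
}

#' Export marker designs as TSV and primer FASTA
#'
#' @param designs List of [design_pace()] results.
#' @param tsv,fasta Output paths (either may be `NULL` to skip).
#' @return Invisibly, the design table.
#' @export
write_marker_designs <- function(designs, tsv = NULL, fasta = NULL) {
  df <- do.call(rbind, lapply(designs, function(d) data.frame(
    marker = sprintf("%s_%d", d$snp$amplicon_id, d$snp$position),
    primer_ref = d$allele_primer_ref, primer_alt = d$allele_primer_alt,
    common = d$common_primer,
    tm_ref = round(d$tm_ref, 1), tm_alt = round(d$tm_alt, 1),
    tm_common = round(d$tm_common, 1), product_size = d$product_size,
    stringsAsFactors = FALSE)))
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    seqs <- unlist(lapply(designs, function(d) setNames(
      c(d$allele_primer_ref, d$allele_primer_alt, d$common_primer),
      paste0(sprintf("%s_%d", d$snp$amplicon_id, d$snp$position),
             c("_ref", "_alt", "_common")))))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  invisible(df)
}

#' Export segregation results as TSV
#'
#' @param results A (possibly named) list of [segregation_test()] results.
#' @param path Output path.
#' @return Invisibly, the table written.
#' @export
write_segregation_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    s <- results[[i]]
    data.frame(
      marker = if (!is.null(names(results)) && nzchar(names(results)[i]))
        names(results)[i] else sprintf("marker%d", i),
      n_het = s$n_het, n_hom_wt = s$n_hom_wt,
      ratio = paste(s$expected_ratio, collapse = ":"),
      chi2 = s$chi2, p_value = s$p_value, fits = s$fits,
      stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Chi-square test of a genotype segregation ratio
#'
#' Pearson chi-square with one degree of freedom and no continuity
#' correction against an expected heterozygous : homozygous-wild-type
#' ratio (default 1:1, as expected among backcross progeny of a
#' heterozygous mutant). `fits` is `TRUE` when the p-value is at least
#' `alpha`.
#'
#' @param n_het,n_hom_wt Observed genotype counts (sum >= 1).
#' @param ratio Expected `c(het, hom_wt)` ratio.
#' @param alpha Significance level for the fit decision.
#' @return A `segregation_result`: list with the counts, `expected_ratio`,
#'   `chi2`, `p_value` and `fits`.
#' @examples
#' segregation_test(13, 12)$chi2   # 0.04
#' @export
segregation_test <- function(n_het, n_hom_wt, ratio = c(1, 1), alpha = 0.05) {
  if (n_het < 0 || n_hom_wt < 0)
    stop("counts must be non-negative", call. = FALSE)
  n <- n_het + n_hom_wt
  if (n < 1) stop("need at least one observation", call. = FALSE)
  expd <- n * ratio / sum(ratio)
  chi2 <- sum((c(n_het, n_hom_wt) - expd)^2 / expd)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(n_het = n_het, n_hom_wt = n_hom_wt,
                 expected_ratio = ratio, chi2 = chi2, p_value = p,
                 fits = p >= alpha),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation %d:%d vs %s -> chi2 = %.3g, p = %.3g (%s)\n",
              x$n_het, x$n_hom_wt, paste(x$expected_ratio, collapse = ":"),
              x$chi2, x$p_value,
              if (x$fits) "fits" else "does not fit"))
  invisible(x)
}
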