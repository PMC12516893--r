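#' Predict the protein-level effect of a point mutation
#'
#' The position is mapped through the amplicon's exon intervals and CDS
#' frame to a codon, and reference and alternate codons are translated with
#' the standard genetic code (minus-strand gene models are complemented
#' before translation). Intronic positions within `splice_window` bases of
#' an exon-intron boundary are classed `splice_site` (the canonical GT/AG
#' dinucleotides at the default window of 2); positions in primer regions or
#' outside the exon-intron span, and exonic positions whose codon is not
#' fully contained in the amplicon, are `noncoding`. Exonic classification
#' wins over splice-site proximity.
#'
#' @param amplicon One amplicon model from [generate_references()].
#' @param position 0-based position on the amplicon.
#' @param ref_base,alt_base Reference-forward bases.
#' @param splice_window Intronic bases at each boundary classed as splice
#'   site.
#' @return List with `effect_class` (one of `synonymous`, `missense`,
#'   `stop_gained`, `stop_lost`, `splice_site`, `intronic`, `noncoding`),
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `aa_position` (1-based in
#'   the amplicon-local CDS).
#' @examples
#' amps <- generate_references(1, c(500, 500), divergence = 0, seed = 42)
#' ex <- amps[[1]]$exons
#' classify_effect(amps[[1]], ex[1, "start"], "G", "A")
#' @export
classify_effect <- function(amplicon, position, ref_base, alt_base,
                            splice_window = 2L) {
  a <- amplicon
  if (position < 0 || position >= a$length)
    stop("position outside amplicon", call. = FALSE)
  none <- function(class) list(effect_class = class, codon_ref = NA_character_,
                               codon_alt = NA_character_, aa_ref = NA_character_,
                               aa_alt = NA_character_, aa_position = NA_integer_)
  pl <- a$primer_length
  if (position < pl || position >= a$length - pl) return(none("noncoding"))
  ex <- a$exons
  in_exon <- which(position >= ex[, "start"] & position < ex[, "end"])
  if (!length(in_exon)) {
    span <- position >= ex[1, "start"] && position < ex[nrow(ex), "end"]
    if (!span) return(none("noncoding"))
    # intronic: distance to nearest exon boundary
    d_donor <- position - ex[, "end"]        # bases into intron after an exon
    d_accept <- ex[, "start"] - 1L - position  # bases before the next exon
    dmin <- min(c(d_donor[d_donor >= 0], d_accept[d_accept >= 0]))
    return(none(if (dmin < splice_window) "splice_site" else "intronic"))
  }

  # CDS coordinate in transcription order
  lens <- ex[, "end"] - ex[, "start"]
  total <- sum(lens)
  plus_idx <- unname(sum(lens[seq_len(in_exon - 1L)]) +
                       (position - ex[in_exon, "start"]))
  if (a$strand == "+") {
    cds <- paste(substring(a$seq_a, ex[, "start"] + 1L, ex[, "end"]),
                 collapse = "")
    idx <- plus_idx
    rb <- ref_base; ab <- alt_base
  } else {
    cds <- revcomp(paste(substring(a$seq_a, ex[, "start"] + 1L, ex[, "end"]),
                         collapse = ""))
    idx <- total - 1L - plus_idx
    rb <- chartr("ACGT", "TGCA", ref_base)
    ab <- chartr("ACGT", "TGCA", alt_base)
  }
  adj <- idx + a$cds_offset
  codon_i <- adj %/% 3L
  within <- adj %% 3L
  c_start <- codon_i * 3L - a$cds_offset        # transcription-order index
  if (c_start < 0L || c_start + 3L > total) return(none("noncoding"))
  codon_ref <- substr(cds, c_start + 1L, c_start + 3L)
  if (substr(codon_ref, within + 1L, within + 1L) != rb)
    warning("reference base does not match the amplicon sequence", call. = FALSE)
  codon_alt <- codon_ref
  substr(codon_alt, within + 1L, within + 1L) <- ab
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  class <- if (aa_ref == aa_alt) "synonymous"
           else if (aa_alt == "*") "stop_gained"
           else if (aa_ref == "*") "stop_lost"
           else "missense"
  list(effect_class = class, codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt, aa_position = codon_i + 1L)
}

#' Annotate a candidate table with predicted effects
#'
#' @param candidates A [call_mutations()] result.
#' @inheritParams spike_mutations
#' @inheritParams classify_effect
#' @return The candidate table with `effect_class`, `codon_ref`,
#'   `codon_alt`, `aa_ref`, `aa_alt`, `aa_position` columns appended.
#' @export
annotate_candidates <- function(candidates, amplicons, splice_window = 2L) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  cols <- c("effect_class", "codon_ref", "codon_alt", "aa_ref", "aa_alt",
            "aa_position")
  if (!nrow(candidates)) {
    for (cl in cols) candidates[[cl]] <- if (cl == "aa_position") integer() else character()
    return(candidates)
  }
  ann <- lapply(seq_len(nrow(candidates)), function(i)
    classify_effect(amplicons[[candidates$amplicon_id[i]]],
                    candidates$position[i], candidates$ref_base[i],
                    candidates$alt_base[i], splice_window))
  for (cl in cols) candidates[[cl]] <- vapply(
    ann, function(x) x[[cl]],
    if (cl == "aa_position") integer(1) else character(1))
  candidates
}

#' Fraction of mutations predicted to affect protein function
#'
#' `100 * n_affecting / n_total`, reported to one decimal. The WGRS survey
#' of six M2 genomes found a mean of 134 protein-affecting mutations among
#' 3,935 per genome: 3.4%.
#'
#' @param n_affecting,n_total Counts (`n_total >= 1`,
#'   `n_affecting <= n_total`).
#' @return Percentage rounded to 1 decimal.
#' @examples
#' affecting_fraction(134, 3935)  # 3.4
#' @export
affecting_fraction <- function(n_affecting, n_total) {
  if (n_total < 1) stop("`n_total` must be >= 1", call. = FALSE)
  if (n_affecting > n_total || n_affecting < 0)
    stop("need 0 <= n_affecting <= n_total", call. = FALSE)
  round(100 * n_affecting / n_total, 1)
}

#' Platform mutation frequency (one mutation per X kb screened)
#'
#' `total_screened_kb / n_confirmed`; the conventional "1/X kb" report
#' string rounds X to the nearest 10 kb. 14 confirmed mutations over
#' 4,474 kb screened gives 319.6 kb, reported as "1/320 kb".
#'
#' @param n_confirmed Number of confirmed mutations.
#' @param total_screened_kb Total screened sequence in kb (see
#'   [screened_kb()]).
#' @return List with `kb_per_mutation` (raw) and `label`; with zero
#'   confirmed mutations the label is `"none detected"` and the raw value
#'   `NA`.
#' @examples
#' mutation_frequency(14, 4474)$label  # "1/320 kb"
#' @export
mutation_frequency <- function(n_confirmed, total_screened_kb) {
  if (total_screened_kb <= 0) stop("`total_screened_kb` must be > 0", call. = FALSE)
  if (n_confirmed == 0)
    return(list(kb_per_mutation = NA_real_, label = "none detected"))
  kb <- total_screened_kb / n_confirmed
  list(kb_per_mutation = kb,
       label = sprintf("1/%d kb", as.integer(round(kb / 10) * 10)))
}

#' Detection accuracy against confirmation sequencing
#'
#' `100 * n_confirmed / n_clean_traces`, rounded to the nearest integer --
#' the fraction of candidate mutations confirmed among families whose
#' confirmation traces were clean (14 of 17: 82%).
#'
#' @param n_confirmed Confirmed mutations.
#' @param n_clean_traces Families with clean confirmation traces (>= 1).
#' @return Integer percentage.
#' @examples
#' detection_accuracy(14, 17)  # 82
#' @export
detection_accuracy <- function(n_confirmed, n_clean_traces) {
  if (n_clean_traces < 1) stop("`n_clean_traces` must be >= 1", call. = FALSE)
  if (n_confirmed > n_clean_traces || n_confirmed < 0)
    stop("need 0 <= n_confirmed <= n_clean_traces", call. = FALSE)
  as.integer(round(100 * n_confirmed / n_clean_traces))
}

#' Score called candidates against the simulation truth
#'
#' A candidate is a true positive only when its (amplicon, position,
#' alternate) matches a spiked mutation *and* deconvolution resolved it
#' uniquely to the correct family. Candidates at a true site whose family
#' set is wrong, ambiguous or incomplete earn partial credit; candidates at
#' sites absent from the truth are false positives.
#'
#' @param candidates A [call_mutations()] result.
#' @param truth A [spike_mutations()] table.
#' @return List: `sensitivity` (`TP / n_truth`), `precision`
#'   (`TP / n_candidates`), `family_accuracy` (`TP` among candidates at true
#'   sites), `n_tp`, `n_partial`, `n_fp`, `n_truth`, `n_candidates`.
#' @export
score_against_truth <- function(candidates, truth) {
  key <- function(d) paste(d$amplicon_id, d$position, d$alt_base)
  tkey <- key(truth)
  n_tp <- 0L; n_partial <- 0L; n_fp <- 0L
  if (nrow(candidates)) {
    ck <- key(candidates)
    for (i in seq_len(nrow(candidates))) {
      hit <- which(tkey == ck[i])
      if (!length(hit)) { n_fp <- n_fp + 1L; next }
      fams <- as.integer(strsplit(candidates$families[i], ",")[[1]])
      if (candidates$status[i] == "unique" &&
          length(fams) == 1L && fams %in% truth$family_id[hit])
        n_tp <- n_tp + 1L
      else
        n_partial <- n_partial + 1L
    }
  }
  list(
    sensitivity = if (nrow(truth)) n_tp / nrow(truth) else NA_real_,
    precision = if (nrow(candidates)) n_tp / nrow(candidates) else NA_real_,
    family_accuracy = if (n_tp + n_partial > 0) n_tp / (n_tp + n_partial)
                      else NA_real_,
    n_tp = n_tp, n_partial = n_partial, n_fp = n_fp,
    n_truth = nrow(truth), n_candidates = nrow(candidates)
  )
}
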