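#' Exact binomial test of one pool position against the error-only null
#'
#' Under the null, alternate reads at a position arise only from sequencing
#' error, with per-alternate-base probability `error_rate / 3` (an error is
#' equally likely to produce any of the three non-reference bases). The
#' p-value is the upper binomial tail `P(X >= alt_count | depth,
#' error_rate/3)`; the position passes when the p-value clears a Bonferroni
#' threshold `alpha / n_tests` and the raw support reaches `min_alt` reads.
#'
#' @param alt_count Alternate-base read count(s).
#' @param depth Total depth(s); zero depth is untestable (`p_value` `NA`,
#'   fail).
#' @param error_rate Per-base sequencing error rate (0 < error_rate < 1).
#' @param alpha Family-wise error target.
#' @param min_alt Minimum alternate reads.
#' @param n_tests Bonferroni family size (tested positions x 3 alternate
#'   bases).
#' @return List with vectors `p_value` and `pass`.
#' @examples
#' test_position(6, 720, error_rate = 0.002, n_tests = 1)
#' @export
test_position <- function(alt_count, depth, error_rate, alpha = 0.05,
                          min_alt = 3L, n_tests = 1L) {
  if (any(error_rate <= 0) || any(error_rate >= 1))
    stop("`error_rate` must be in (0, 1)", call. = FALSE)
  if (any(depth < 0) || any(alt_count < 0) || any(alt_count > depth, na.rm = TRUE))
    stop("need 0 <= alt_count <= depth", call. = FALSE)
  p <- pbinom(alt_count - 1, depth, error_rate / 3, lower.tail = FALSE)
  p[depth == 0] <- NA_real_
  pass <- !is.na(p) & p < alpha / n_tests & alt_count >= min_alt
  list(p_value = p, pass = pass)
}

#' Is a substitution EMS-canonical?
#'
#' EMS alkylates guanine, producing G:C>A:T transitions; in
#' reference-forward orientation the two strand presentations are G>A and
#' C>T.
#'
#' @param ref_base,alt_base Single-character bases in `A`,`C`,`G`,`T`
#'   (vectorized).
#' @return Logical.
#' @examples
#' ems_canonical("G", "A")  # TRUE
#' ems_canonical("A", "G")  # FALSE (reverse transition)
#' @export
ems_canonical <- function(ref_base, alt_base) {
  ok <- c("A", "C", "G", "T")
  if (!all(ref_base %in% ok) || !all(alt_base %in% ok))
    stop("bases must be one of A, C, G, T", call. = FALSE)
  (ref_base == "G" & alt_base == "A") | (ref_base == "C" & alt_base == "T")
}

#' Positions excluded from calling because the parental genomes differ
#'
#' Inter-genome divergent sites produce high-VAF signals that are genotype,
#' not induced mutation, and are masked.
#'
#' @inheritParams spike_mutations
#' @return Named list (amplicon id -> integer vector of 0-based positions).
#' @export
mask_divergent_sites <- function(amplicons) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  out <- lapply(amplicons, function(a) {
    sa <- strsplit(a$seq_a, "")[[1]]
    sb <- strsplit(a$seq_b, "")[[1]]
    which(sa != sb) - 1L
  })
  names(out) <- names(amplicons)
  out
}

#' Estimate the sequencing error rate from pooled counts
#'
#' Per amplicon: total non-reference reads / total depth across all pools at
#' unmasked positions, floored at `1e-4`. The mean (not a median) is used
#' because at per-pool depths of a few hundred the per-site error counts are
#' small discrete numbers whose median is biased low, which would understate
#' the null and inflate false positives; genuine mutation signal at a
#' handful of sites is diluted over all `positions x pools` and shifts the
#' mean negligibly.
#'
#' @param counts Named list (pool label -> [pileup()] result).
#' @inheritParams spike_mutations
#' @param mask Optional [mask_divergent_sites()] output.
#' @param floor Lower bound on the estimate.
#' @return Named numeric vector, one rate per amplicon.
#' @export
estimate_error_rate <- function(counts, amplicons, mask = NULL, floor = 1e-4) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  if (is.null(mask)) mask <- mask_divergent_sites(amplicons)
  out <- setNames(numeric(length(amplicons)), names(amplicons))
  for (id in names(amplicons)) {
    a <- amplicons[[id]]
    refi <- match(strsplit(a$seq_a, "")[[1]], c("A", "C", "G", "T"))
    keep <- setdiff(seq_len(a$length), mask[[id]] + 1L)
    nonref <- 0; dep <- 0
    for (pool in names(counts)) {
      m <- counts[[pool]][[id]]
      d <- colSums(m)
      r <- m[cbind(refi, seq_len(a$length))]
      nonref <- nonref + sum(d[keep] - r[keep])
      dep <- dep + sum(d[keep])
    }
    out[id] <- if (dep > 0) max(floor, nonref / dep) else floor
  }
  out
}

#' Call candidate EMS mutations from pooled allele counts
#'
#' A pooled low allele-fraction caller built for the tridimensional design.
#' For every unmasked position and alternate base it proceeds in three
#' stages:
#'
#' 1. *Screen* -- a pool supports the site when its alternate count reaches
#'    `min_alt` and its per-pool exact binomial p-value ([test_position()])
#'    is below `alpha`.
#' 2. *Confirm* -- the best-supported pool on each axis is selected and the
#'    three per-pool p-values are Fisher-combined; the site is confirmed
#'    when the combined p-value is below `alpha / (N * cube_dim)` with
#'    `N = unmasked positions x 3 alternates`. The extra `cube_dim` factor
#'    charges for selecting the supporting pool within each axis. When
#'    exactly one axis has no screened pool, the best pool on that axis with
#'    at least `min_alt - 1` alternate reads is admitted (rescue) and the
#'    same corrected threshold applies; rescue keeps single-pool dropouts
#'    (a heterozygote contributes only ~5-6 reads per pool at platform-scale
#'    coverage) from discarding otherwise well-supported sites.
#' 3. *Filter and deconvolve* -- candidates must be EMS-canonical
#'    ([ems_canonical()]) and off the divergence mask; the positive pools
#'    (the selected pools plus any further pool that alone clears the
#'    corrected threshold) are deconvolved to candidate families, and
#'    ambiguous or incomplete patterns are reported, never dropped.
#'
#' In permissive mode sites supported on only two axes are also emitted,
#' flagged low-confidence.
#'
#' @param counts Named list (pool label -> [pileup()] result) covering all
#'   three axes.
#' @inheritParams spike_mutations
#' @param alpha Family-wise error target.
#' @param min_alt Minimum alternate reads per supporting pool.
#' @param error_rate Null error rate; default estimated per amplicon by
#'   [estimate_error_rate()].
#' @param mode `"strict"` (three axes required) or `"permissive"` (two).
#' @param rescue Allow the third-axis rescue described above.
#' @return Candidate table (class `candidate_set`): `amplicon_id`,
#'   `position` (0-based), `ref_base`, `alt_base`, `pools`, `status`,
#'   `families`, `n_axes`, `p_combined`, `low_confidence`, plus per-pool
#'   supporting counts in `support`; all screened per-pool calls in
#'   attribute `pool_calls`.
#' @export
call_mutations <- function(counts, scheme, amplicons, alpha = 0.05,
                           min_alt = 3L, error_rate = NULL,
                           mode = c("strict", "permissive"), rescue = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "pooling_scheme"),
            inherits(amplicons, "amplicon_set"))
  pools <- names(counts)
  axes <- substr(pools, 1L, 1L)
  if (!all(c("R", "C", "D") %in% axes))
    stop("`counts` must cover pools on all three axes (R, C, D); missing: ",
         paste(setdiff(c("R", "C", "D"), axes), collapse = ", "), call. = FALSE)
  mask <- mask_divergent_sites(amplicons)
  err <- if (is.null(error_rate)) {
    estimate_error_rate(counts, amplicons, mask)
  } else {
    setNames(rep_len(error_rate, length(amplicons)), names(amplicons))
  }
  n_tests <- sum(vapply(amplicons, `[[`, 0L, "length") -
                   lengths(mask)) * 3L
  thr_comb <- alpha / (n_tests * scheme$cube_dim)
  bases <- c("A", "C", "G", "T")

  cand_rows <- list()
  call_rows <- list()
  for (id in names(amplicons)) {
    a <- amplicons[[id]]
    L <- a$length
    refv <- strsplit(a$seq_a, "")[[1]]
    refi <- match(refv, bases)
    masked <- mask[[id]] + 1L
    cnt <- array(0L, dim = c(length(pools), 4L, L))
    for (pi in seq_along(pools)) cnt[pi, , ] <- counts[[pools[pi]]][[id]]
    depth <- apply(cnt, c(1L, 3L), sum)          # pools x positions
    p_err <- err[[id]] / 3

    for (b in 1:4) {
      altc <- cnt[, b, , drop = FALSE]
      dim(altc) <- dim(depth)
      is_alt <- refi != b
      # prefilter: a site is worth testing only if some pool reaches min_alt
      hit_pos <- which(is_alt & apply(altc, 2L, max) >= min_alt)
      if (!length(hit_pos)) next
      for (pos in hit_pos) {
        if (pos %in% masked) next
        ac <- altc[, pos]
        dp <- depth[, pos]
        tp <- test_position(ac, dp, err[[id]], alpha = alpha,
                            min_alt = min_alt, n_tests = 1L)
        screened <- which(tp$pass & tp$p_value < alpha)
        if (length(screened))
          call_rows[[length(call_rows) + 1L]] <- data.frame(
            pool_id = pools[screened], amplicon_id = id, position = pos - 1L,
            ref_base = refv[pos], alt_base = bases[b],
            alt_count = ac[screened], depth = dp[screened],
            vaf = ac[screened] / pmax(dp[screened], 1L),
            p_value = tp$p_value[screened],
            ems_flag = ems_canonical(refv[pos], bases[b]),
            stringsAsFactors = FALSE)
        if (!ems_canonical(refv[pos], bases[b])) next

        ax_of <- axes[screened]
        have <- unique(ax_of)
        low_conf <- FALSE
        chosen <- integer(0)
        if (length(have) == 3L) {
          for (axx in c("R", "C", "D")) {
            ss <- screened[ax_of == axx]
            chosen <- c(chosen, ss[which.max(ac[ss])])
          }
        } else if (length(have) == 2L && rescue && mode == "strict") {
          miss <- setdiff(c("R", "C", "D"), have)
          in_ax <- which(axes == miss)
          best <- in_ax[which.max(ac[in_ax])]
          if (ac[best] < min_alt - 1L || dp[best] == 0L) next
          for (axx in have) {
            ss <- screened[ax_of == axx]
            chosen <- c(chosen, ss[which.max(ac[ss])])
          }
          chosen <- c(chosen, best)
        } else if (length(have) == 2L && mode == "permissive") {
          for (axx in have) {
            ss <- screened[ax_of == axx]
            chosen <- c(chosen, ss[which.max(ac[ss])])
          }
          low_conf <- TRUE
        } else next

        pv <- pbinom(ac[chosen] - 1, dp[chosen], p_err, lower.tail = FALSE)
        p_comb <- pchisq(-2 * sum(log(pmax(pv, 1e-300))), 2L * length(pv),
                         lower.tail = FALSE)
        if (!(p_comb < thr_comb)) next

        # positive set: per-axis picks (with count ties) + independently
        # Bonferroni-significant screened pools
        positive <- chosen
        for (axx in intersect(unique(axes[chosen]), ax_of)) {
          ss <- screened[ax_of == axx]
          top <- max(ac[ss])
          positive <- c(positive, ss[ac[ss] == top])
        }
        strong <- screened[pbinom(ac[screened] - 1, dp[screened], p_err,
                                  lower.tail = FALSE) < thr_comb]
        positive <- sort(unique(c(positive, strong)))
        dec <- deconvolve(scheme, pools[positive])
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          amplicon_id = id, position = pos - 1L,
          ref_base = refv[pos], alt_base = bases[b],
          pools = paste(pools[positive], collapse = ","),
          status = dec$status,
          families = paste(dec$candidate_family_ids, collapse = ","),
          n_axes = length(unique(axes[positive])),
          p_combined = p_comb,
          low_confidence = low_conf,
          support = paste(sprintf("%s:%d/%d", pools[chosen], ac[chosen],
                                  dp[chosen]), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  cand <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(amplicon_id = character(), position = integer(),
               ref_base = character(), alt_base = character(),
               pools = character(), status = character(),
               families = character(), n_axes = integer(),
               p_combined = numeric(), low_confidence = logical(),
               support = character(), stringsAsFactors = FALSE)
  cand <- cand[order(cand$amplicon_id, cand$position, cand$alt_base), ]
  rownames(cand) <- NULL
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else NULL
  structure(cand, class = c("candidate_set", "data.frame"),
            pool_calls = calls, n_tests = n_tests,
            error_rate = err, threshold = thr_comb)
}

#' Per-position VAF matrix for manual review
#'
#' The top non-reference base fraction at every position in every pool -- a
#' rectangular positions x pools table supporting visual inspection of
#' low-VAF signals. Masked (inter-genome divergent) positions are flagged in
#' a sentinel column.
#'
#' @inheritParams call_mutations
#' @return `data.frame`: `amplicon`, `pos` (0-based), `masked`, then one
#'   column per pool with values in `[0, 1]`.
#' @export
export_vaf_matrix <- function(counts, amplicons) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  mask <- mask_divergent_sites(amplicons)
  pools <- names(counts)
  out <- lapply(names(amplicons), function(id) {
    a <- amplicons[[id]]
    refi <- match(strsplit(a$seq_a, "")[[1]], c("A", "C", "G", "T"))
    df <- data.frame(amplicon = id, pos = seq_len(a$length) - 1L,
                     masked = (seq_len(a$length) - 1L) %in% mask[[id]],
                     stringsAsFactors = FALSE)
    for (pool in pools) {
      m <- counts[[pool]][[id]]
      d <- colSums(m)
      # top non-reference count: zero out the reference row per column
      m2 <- m; m2[cbind(refi, seq_len(a$length))] <- 0L
      df[[pool]] <- ifelse(d > 0, apply(m2, 2L, max) / d, 0)
    }
    df
  })
  do.call(rbind, out)
}
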