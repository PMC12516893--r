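---
title: "Pooled TILLING-by-sequencing: models, simulation and detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled TILLING-by-sequencing: models, simulation and detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillseq)
```

## The screening problem

A TILLING-by-sequencing (TbyS) screen looks for chemically induced point
mutations in target genes across a large mutant library. EMS mutagenesis
produces predominantly G:C→A:T transitions; in an M2 family an induced
mutation is typically heterozygous. Sequencing every family individually is
wasteful, so families are arranged on a `d × d × d` grid and pooled along
each axis: every row (R), column (C) and depth (D) layer becomes one DNA
pool. With `d = 8`, 512 families produce 24 pools of 64 families each, and
each family is present in exactly three pools. A mutation carried by one
family appears in exactly one pool per axis, and the intersection of those
three pools identifies the family — *deconvolution* — without any
family-level barcoding.

The price is signal dilution: a heterozygote in a pool of `N` families has
expected variant allele fraction (VAF) `1/(2N)`; at `N = 64` that is
`1/128 ≈ 0.78%`, a few-fold above the raw error rate of short-read
sequencing. The package implements the full in-silico pipeline around this
design: pooling and deconvolution, a read simulator that reproduces the
screen's conditions, dual-reference read assignment, a pooled
low-VAF caller restricted to the EMS spectrum, codon-level effect
annotation, platform statistics, and conversion of confirmed SNPs to
allele-specific PCR (PACE/KASP) markers.

## Study conditions and the synthetic-data generator

The generator's defaults are the screen's conditions, fixed in
`tbys_config()`:

| parameter | default | meaning |
|---|---|---|
| `n_families`, `cube_dim` | 512, 8 | 512 M2 families on an 8×8×8 cube (24 pools of 64) |
| `n_amplicons`, `length_range` | 17, 452–704 bp | target amplicons from 13 genes |
| `divergence` | 0.005 | substitution-only divergence between the two parental genomes, never inside primers |
| `freq_kb` | 320 | one EMS mutation per 320 kb screened (Poisson spiking over ~4,474 kb total) |
| `het_fraction` | 1.0 | induced mutations enter as heterozygotes |
| `coverage` | 11.3× | per-family, per-pool coverage |
| `error_rate` | 0.002 | i.i.d. per-base substitution error |
| `read_length` | 150 bp | single-end reads |
| `genome_mix` | 0.5 | probability a family haplotype derives from parental genome B |

Design choices worth stating explicitly:

* **Equimolar pooling.** Each family contributes a deterministic number of
  reads per pool (`coverage × effective span / read length`), emulating
  perfectly normalized DNA input; the haplotype behind each read is an
  independent coin flip. How the real platform normalized per-family input
  is not public, so the idealization is exposed as the `coverage`
  parameter rather than hidden behind an arbitrary noise model.
* **Coverage-uniform tiling.** Read starts are tiled on an evenly spaced
  grid extending one read length minus one seed length beyond both amplicon
  ends, with reads clipped to the amplicon. Plain within-amplicon tiling
  would leave every position within a read length of either end at reduced
  depth — nearly half the target space for 452–704 bp amplicons at 150 bp
  reads — which no amplicon protocol intends. With clipped tiling,
  per-position depth is within a few percent of `coverage × pool size`
  everywhere except a mild (~13%) dip in the terminal 21 bp.
* **Spiking sites.** Mutations land on uniformly chosen G/C sites at which
  the two parental genomes agree. Divergent sites are masked from calling
  (they are genotype, not mutagenesis), so spiking them would only create
  unscoreable truth records.
* **Read naming.** Names encode pool and amplicon, never the family:
  recovering the family is the pipeline's job, and the truth sidecar is the
  only place the assignment exists.
* **What is not simulated.** PCR bias and chimeras, indels, quality-score
  profiles (a constant Phred score consistent with `error_rate` is
  written), and per-pool coverage dispersion (the real screen's coverage
  "varied widely"; a dispersion model is deliberately left out so that
  power statements are interpretable). Passing tests therefore demonstrate
  correctness of the statistical machinery under the stated error model,
  not robustness to every artefact of real amplicon data.

## Read assignment

Reads are anchored by exact lookup of their leading 21-mer in a dictionary
of all 21-mers of all amplicons in both parental genomes, then scored by
full-length Hamming distance against both genomes at the anchored offset;
the winner (ties to genome A) is kept if the mismatch fraction is at most
`max_mismatch_frac` (default 0.1). When the leading seed finds no hit, the
trailing 21-mer is tried, then both anchors of the reverse complement.
The fallback matters: a read whose *leading* seed spans a true mutation has
no exact match in either genome, so a single-anchor mapper silently drops
~14% of mutation-covering reads (21/150) and biases pool VAFs low. With
both anchors, only reads with errors in both terminal seeds are lost
(≈0.2% of reads at the default error rate), and mapping efficiency on
simulated platform-scale data is ≈99.7%, comfortably above the >94% the real
platform reports. Gapped alignment is out of scope because the simulator is
substitution-only and EMS does not induce indels at appreciable rates.

## The pooled caller

At every unmasked position and alternate base, pool counts are tested
against an error-only null: alternate reads arise as binomial draws with
per-alternate probability `error_rate / 3` (`test_position()` exposes the
exact upper-tail test). The error rate is estimated per amplicon as the
*mean* non-reference fraction across all pools at unmasked positions,
floored at `1e-4`. A median would be the more conventional robust choice,
but at per-pool depth ≈723 the per-site non-reference counts are small
discrete numbers (mean ≈1.4) whose median underestimates the rate by
~30%; plugging that into the null inflates false calls by two orders of
magnitude, while the handful of genuine mutation sites shifts the mean
negligibly. Robustness is retained by excluding masked sites.

Calling proceeds hierarchically:

1. **Screen.** A pool supports a site when its alternate count reaches
   `min_alt` (default 3) and its per-pool binomial p-value is below
   `alpha` (default 0.05), uncorrected. At 11.3× per family, the carrier
   pool's expected alternate count is only ~5.6 reads, so any per-pool
   threshold strict enough to control the family-wise error rate across
   ~30,000 position×alternate tests (≥6 reads) would miss most per-pool
   signals; conversely the screen alone passes pure-error pools at ~1.3%
   per site. Neither is acceptable on its own — the screen is deliberately
   lenient and the control comes from the next stage.
2. **Confirm.** The best-supported pool on each axis is selected, and the
   three per-pool p-values are combined with Fisher's method. The
   combined p-value must clear `alpha / (N × cube_dim)`, where
   `N = unmasked positions × 3` is the Bonferroni family and the extra
   `cube_dim` factor charges for selecting the supporting pool within each
   axis. Requiring a coincident signal in three independent pools is the
   design's real specificity engine: three pools of pure error reaching
   the screen at the same site and alternate occur at ~`10⁻³` per site,
   and the Fisher confirmation rejects the diffuse (3,3,3)- and
   (4,4,4)-read patterns that survive it. When exactly one axis has no
   screened pool, the best pool there with `min_alt − 1` reads is admitted
   (*rescue*) and the same corrected threshold applies; Monte-Carlo checks
   show rescued error patterns (e.g. 5,5,2 reads) still fail the
   threshold, while rescue recovers the common case of a single carrier
   pool falling one read short.
3. **Filter and deconvolve.** Candidates must be EMS-canonical (G→A or
   C→T on the reference-forward strand) and off the divergence mask. The
   positive-pool set — the per-axis selections, count ties included, plus
   any further pool that alone clears the corrected threshold — is
   deconvolved by set intersection. Ambiguous and incomplete patterns are
   reported with all candidate families rather than dropped; with
   per-pool error what it is, occasional extra positive pools are
   expected, and silently discarding them would misstate the evidence.

Under the default conditions this caller recovers ≈92% of spiked
heterozygous mutations with a unique, correct family assignment, at
≈0–0.05 false candidates per mutation-free run (measured over 20-seed
batches by the acceptance tests and `scripts/acceptance.R`). The two
figures trade off through the confirmation threshold; the
`cube_dim` selection factor was fixed from count-level Monte-Carlo before
the pipeline was assembled, not fitted to its output. A caller required to
apply the full Bonferroni correction *within each pool separately* cannot
reach these operating points at 11.3× coverage: per-pool evidence of ~5.6
expected reads simply does not support a `~10⁻⁶` per-pool threshold, which
is why confirmation is pooled across the three axes.

## Effect annotation and platform statistics

Positions are mapped through the exon model to codons and translated with
the standard genetic code; minus-strand models are complemented first.
Intronic positions within 2 bp of an exon boundary are splice-site
(the essential GT/AG dinucleotides); exonic classification wins over splice
proximity; primer-region positions, positions outside the gene span, and
exonic positions whose codon is not fully contained in the amplicon are
noncoding. The platform statistics follow fixed rounding conventions so the
published values reproduce exactly: `detection_accuracy()` rounds to an
integer percent (14 confirmed / 17 clean traces → 82), `affecting_fraction()`
to one decimal (134 / 3,935 → 3.4), and `mutation_frequency()` reports the
raw kb-per-mutation plus a label rounded to the nearest 10 kb
(4,474 kb / 14 → "1/320 kb"). The screened total is computed as
`Σ amplicon lengths × families / 1000` kb; the source material prints the
same number with an Mbp unit, which is inconsistent with its own 1/320 kb
figure — the package treats the total as 4,474 kb, the only reading under
which the arithmetic closes.

## Marker conversion and segregation

`design_pace()` converts a confirmed SNP into a competitive allele-specific
PCR assay: two allele primers ending exactly at the SNP (differing only in
the 3'-terminal base and their universal FAM/HEX tails, which are excluded
from Tm calculation) and one common reverse-strand primer downstream.
Melting temperatures use two-state nearest-neighbor thermodynamics with the
unified duplex parameter set at 50 mM monovalent salt and 200 nM primer;
defaults (Tm 57–63 °C, length 18–30 nt, product 60–120 bp) follow common
PACE/KASP practice and are config-exposed, since the real assays' primer
sequences are not public. The design search is deterministic: allele
primers grow 5'-ward until the Tm enters the window; the common primer is
scanned product-size-first, then length. `segregation_test()` is a plain
Pearson chi-square with df = 1 and no continuity correction against the
1:1 heterozygous : homozygous-wild-type expectation for backcross progeny
of a heterozygous mutant; 13:12 gives χ² = 0.04, p ≈ 0.84.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere in memory; GFF3 and VCF
exports convert to their 1-based standards. Family ids are 0-based and map
to cube cells row-major (`i = r·d² + c·d + d`), a convention chosen for
deterministic invertibility. Zero-depth positions are untestable (p-value
`NA`, never a pass). Empty read sets yield mapping efficiency `NaN`, not
zero. Zero confirmed mutations yield the frequency label "none detected"
rather than a division. Ties in per-axis pool selection are kept, which can
only widen a candidate's family set (reported as ambiguous). Reads longer
than an amplicon are truncated with a warning. All randomness flows from
user-supplied seeds; per-pool seeds are derived so any subset of pools
reproduces bit-for-bit.

## Problem sizes used by the test-suite

The module tests run on small cubes (8–64 families, 1–3 amplicons) where
every oracle can be enumerated; the acceptance-level checks run the full
platform-scale configuration (512 families, 17 amplicons, ~1.35 million reads
per replicate) over 20 seeded replicates for sensitivity and 20
mutation-free replicates for specificity — sizes chosen so the whole suite
completes on a single CPU in well under half an hour while keeping the
per-batch Monte-Carlo error on the sensitivity estimate near one percent.

## Known limitations

* The caller's operating characteristics are stated under the simulator's
  error model (i.i.d. substitutions, equimolar pools); real amplicon data
  add PCR errors concentrated at specific cycles, strand bias and coverage
  dispersion, all of which would push the false-candidate rate up and
  argue for the VAF-matrix export (`export_vaf_matrix()`) as a manual
  review step — which is exactly the role the original platform gave its
  visualization approach.
* Two mutations in different families at the same position and alternate
  are reported as one candidate site whose deconvolution may be ambiguous;
  at 1/320 kb this affects well under 1% of sites but is worth knowing
  when interpreting family counts that exceed mutation counts.
* Indels, gapped alignment and FreeBayes-style haplotype assembly are out
  of scope by design.
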