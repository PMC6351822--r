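---
title: "Models and methods behind cffrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cffrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffrag)
```

# The scientific setting

Plasma cell-free DNA (cfDNA) is released mainly by apoptotic cells, whose
caspase-activated nuclease cleaves chromatin in the linker between
nucleosomes. Fragment lengths therefore peak at the chromatosome footprint
(~166-175 bp), local fragment density reflects nucleosome occupancy in the
cells of origin, and the spatial periodicity of cleavage downstream of
transcription start sites carries a tissue-of-origin signature: strongly
expressed genes have disorganised (weakly phased) nucleosome arrays, so
phasing intensity anti-correlates with expression in the contributing
tissue.

`cffrag` implements the downstream analyses of such libraries:

* read filtering, deduplication, downsampling, and anchor masking;
* fragment-length histograms and the modal (chromatosome) length;
* 100-kb bin signals annotated with Hi-C subcompartments (A1, A2, B1, B2,
  B3), compared across sample groups by median-of-ratios log2 fold
  changes, Kruskal-Wallis/Dunn rank tests, Brown-Forsythe variance tests,
  and a Gibbs-sampled random-intercept model with credible intervals;
* strand-aware metaprofiles around TSS, TTS and CTCF anchors with ±1,500 bp
  window summaries and replicate CVs;
* coverage of repeat consensus sequences (e.g. the L1HS 5'UTR, dimeric
  AluY) combining uniquely mapped fragments projected from genomic copies
  with fractionally weighted (1/k) multi-mapped fragments;
* window protection score (WPS) tracks, periodograms, the 193-199 bp
  phasing band, tissue correlations and group rank-shift tests.

Because the analyses were designed for human whole-genome cfDNA data,
the package also ships a cohort simulator that generates fragment
libraries with exactly the statistical structure the analyses assume,
along with a ground-truth record, so every stage can be validated by
parameter recovery.

# The generative model

`protection_profile()` builds a per-base expected-coverage ("protection")
track per chromosome as a product of independent factors:

* **Compartment baseline.** Each 100-kb bin carries one subcompartment
  label; the baseline equals the group's `compartment_weights[label]`.
  The default young-group weights order the signal as B1 > A1 > A2 >
  B2 > B3, the enrichment order seen in both cfDNA and MNase digestion;
  with age the defaults raise B2/B3 and lower A1/B1, emulating the
  redistribution of signal from euchromatin and facultative
  heterochromatin toward lamina-associated heterochromatin.
* **Nucleosome-depleted regions.** Gaussian dips of relative depth
  `ndr_depth` (σ = 300 bp at TSS/TTS, σ = 100 bp at CTCF sites). At
  `ndr_depth = 1` the track is exactly zero at the anchor.
* **Phased nucleosome arrays.** A cosine of period `spacing` (default
  196 bp, chosen inside the 193-199 bp band analysed downstream) over the
  10 kb downstream of each TSS, with amplitude
  `phasing_amplitude * (1 - x_g)` where `x_g` is the mixture-weighted
  expression of gene *g* normalised to [0, 1]: the most expressed gene has
  no periodic component, silent genes phase at full amplitude. CTCF sites
  get the same oscillation on both flanks (±2 kb), unstranded.
* **Repeat 5' attenuation.** The genomic footprint of consensus positions
  below 668 bp (the L1HS 5'UTR, which contains its internal promoter) is
  scaled by `repeat_5p_weight`.

`simulate_fragments()` samples fragment midpoints proportionally to the
track (dyad positions), jitters them uniformly by ±10 bp, and draws
lengths from a truncated normal (mean 170, sd 10, clipped to [100, 400]),
which puts the modal mass in 166-175 bp. This midpoint-at-dyad scheme is
the simplest model that produces a WPS oscillation at the planted
spacing. Exactly `depth` fragments are emitted; per-sample seeds are
derived deterministically from the top-level seed so cohorts are
reproducible to the byte.

What the simulator does **not** model: sequence content and alignment
error (fragments are intervals, not reads), GC and mappability bias,
copy-number variation, the mixture of fragment length modes from
sub-chromatosomal particles, methylation, and biological covariance
between the planted effects. Passing recovery tests therefore show that
the analysis code measures what it claims to measure under its own
assumptions — not that those assumptions exhaust real plasma data.

# Statistical kernels

All rank statistics use mid-ranks and tie corrections:
Kruskal-Wallis H with the `1 - Σ(t³-t)/(N³-N)` correction and a
chi-square tail on k-1 df; Dunn's pairwise
`z = (R̄i - R̄j) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))` with
`T = Σ(t³-t)/(12(N-1))` and two-sided normal p; Brown-Forsythe
(median-centred Levene) F; Benjamini-Hochberg step-up FDR. Degenerate
cases are resolved deterministically (all-equal data give H = 0, p = 1;
zero within-group deviation spread with positive between-group spread
gives W = ∞, p = 0). Tail probabilities come from R's standard
distribution functions. BH is deliberately *not* claimed to be
idempotent — the step-up adjustment is not, in general.

The bin-signal group comparison re-implements the random-intercept animal
model as a conjugate Gibbs sampler on
`y = log2(normalized count + 0.5)`:
group means β_g (normal priors, variance 1e8), bin intercepts
u_i ~ N(0, σu²), residuals ~ N(0, σe²), inverse-gamma(0.001, 0.001)
priors on both variances. Defaults are 13,000 iterations, 3,000 burn-in,
thinning 10 (1,000 retained draws), a fixed seed, and a split-chain R-hat
check (warning above 1.1). Group contrasts are posterior differences of
the β_g draws; a contrast is significant when the central 95% credible
interval excludes zero. Because median-of-ratios size factors are anchored
at the median bin, a shift planted in a minority of bins is recovered in
full, while broader shifts are partially absorbed into normalization —
the same behaviour as count-model fold changes on real data.

# Numerical choices

* Coordinates are 0-based half-open throughout (BED convention); fragment
  midpoint is `floor((start + end) / 2)`; bin assignment is by midpoint
  with terminal partial bins dropped rather than rescaled.
* The WPS at position p counts fragments spanning the whole window
  `[p - w/2, p + w/2)` minus *fragments* (not endpoints) with an endpoint
  inside the window; a fragment shorter than the window with both
  endpoints inside counts once. The default w = 120 bp is the
  long-fragment window of the published score.
* Detrending subtracts a running median (default span 1001) before the
  FFT; the median track is extended as a constant over the first and last
  half-window, which is 20x cheaper than shrinking edge windows and
  irrelevant to the 120-280 bp band. The residual mean is also removed.
* Periodograms use a rectangular taper. Squared FFT magnitudes |X_k|²/N²
  are mapped to periods N/k and averaged into integer period bins over
  120-280 bp; the Parseval sum is kept as an attribute. At the 10-kb
  track length used for genes, k = 51 falls at 196.08 bp, within 0.1 bp
  of the planted spacing; profile-level checks that need this resolution
  use a 5-kb flank for the same reason.
* Tissues are ranked by *ascending* Pearson correlation between per-gene
  phasing-band intensity and `log2(expression + 1)`: the strongest
  contributor is the most negative correlation, because phasing intensity
  anti-correlates with expression in the cells of origin. The convention
  is flippable (`rank_sign`). Expression is log-transformed because
  RPKM-scale values are heavy-tailed.
* Dunn post hoc calls are gated on the tissue's omnibus Kruskal-Wallis
  test (p < 0.05): the omnibus test identifies tissues whose ranking
  changes, the pairwise test attributes the change. Without the gate,
  tissues passively displaced by one rank when another tissue climbs the
  ranking are flagged spuriously in a noticeable fraction of cohorts.
* The soft-clip retention rule keeps clipped records only when the
  aligned span is at least 75 bp (configurable); the alternative reading
  (clip length below 75 bp) is noted in the function documentation as an
  ambiguity of the original processing description.

# The reference recovery studies

The acceptance suite runs fixed study designs, each sized to finish in
minutes on one CPU while leaving wide statistical margins:

* **Periodicity**: 20 cohorts of one sample (2-Mb genome, 20 genes, 30k
  fragments); the gene-averaged periodogram must peak inside 193-199 bp.
* **Compartment redistribution**: 4 groups x 3 replicates, 6 Mb in 60
  bins (12 per subcompartment), 60k fragments/sample; old-vs-young log2
  fold changes must be positive in B2/B3 and negative in A1/B1, with
  Gibbs credible intervals excluding zero in the planted directions.
  A2 sits at the size-factor anchor, as in the data it emulates.
* **NDR ordering**: four groups differing only in `ndr_depth`
  (0.2/0.4/0.6/0.8); TSS window means must decrease strictly and all six
  Dunn pairs reject. Steps of 0.1 are only partially resolved by the
  rank test at this depth — fragment-length smoothing fills the dip and
  per-million renormalisation moves the off-dip baseline in the opposite
  direction — so the study uses the wider spacing.
* **Tissue rank shift** (`rank_shift_study()`): 5 tissues, 4 groups x 3
  samples, with the old group doubling the weight of the tissue whose
  baseline weight is 2/3 of the others' — the ratio that maximises the
  rank-crossing margin on both sides. The design isolates the mixture
  effect: one chromosome, 150 genes of identical 15-kb length placed on
  separate slots (variable gene lengths put TTS dips inside some FFT
  windows and give otherwise-exchangeable tissues a consistent
  seed-specific ordering), two CTCF sites, equal group parameters
  elsewhere, and a binary marker-panel expression table
  (`background_sdlog = 0`, marker factor 50, fraction 0.19) under which
  the non-planted tissues are exactly exchangeable. The planted tissue
  must be flagged for old-vs-young in at least 18 of 20 cohorts and no
  other tissue in more than one.

# Known limitations

With a realistic log-normal expression background (sdlog 0.5), the
per-cohort *structural* correlation between the expression table and the
per-gene band intensities dominates the small shift produced by doubling
one mixture weight: tissues displaced in rank by the planted tissue are
then flagged in a material fraction of cohorts. This is the same
sensitivity limit the rank-shift method has on real data — the per-gene
correlation between nucleosome phasing and expression is weak, so
specificity degrades as tissue profiles become less distinguishable. The
recovery study therefore uses the idealised marker panel; conclusions
about real tissue panels should be correspondingly cautious.

The Gibbs model assumes homoscedastic residuals on the log2 scale and
bins exchangeable within a subcompartment; long-range autocorrelation of
real bin signals (replication timing, large-scale copy number) is not
modelled. The Levene/Brown-Forsythe comparisons inherit the usual caveat
that group "spread" mixes biological and technical variance.

# Reproducibility

Every stochastic entry point takes a seed and restores the caller's RNG
state; per-sample and per-stage seeds are derived from the top-level seed
with a fixed integer map, so a single integer reproduces a full cohort,
its analysis, and the acceptance report (`scripts/acceptance.R`).
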