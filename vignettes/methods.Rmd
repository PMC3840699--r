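---
title: "Models and methods: T-RFLP fingerprints, water-mass structure and distance-decay succession"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflptools)
```

## The scientific problem

Deep ocean water masses are long-lived, physically coherent bodies of
water. A narrow conduit such as an equatorial fracture zone funnels them
between basins over months, which raises a testable question: does the
prokaryotic community *inside* a water mass change along the flow path
(succession), or is it a passive, fixed assemblage? The classical assay is
T-RFLP: a 16S rRNA amplicon pool is end-labelled during PCR, digested with
a 4-cutter, and only the labelled terminal fragment of each template is
sized on a capillary sequencer. Each distinct terminal-fragment (T-RF)
length acts as an operational taxonomic unit, and peak heights act as
relative abundances.

This package re-implements that analysis chain as testable code, and —
because the original electropherograms of any given study are rarely
deposited — pairs it with a synthetic transect generator whose ground
truth exercises every statistical claim the chain makes.

## In-silico digestion

An amplicon is the template substring from the first exact match of the
forward primer through the first downstream match of the reverse
complement of the reverse primer (degenerate IUPAC codes expand to
character classes; no mismatches). The forward-channel T-RF length is the
0-based position of the first enzyme site on the top strand plus the cut
offset (HhaI: site `GCGC`, offset 3); the reverse channel applies the same
rule to the reverse-complement strand. Amplicons without a site are kept
as full-length pseudo-T-RFs and flagged, since practice varies on whether
to drop them. Only the first site matters: T-RFLP detects labelled
termini, never internal fragments.

Numerical conventions in `bin_and_standardize()`: bins are half-open
`[lower, lower + width)` anchored at `size_min` (default window 34–966 bp,
the span of observed bacterial T-RFs; width 1 bp), so edge ties cannot
occur; per sample, heights become fractions of the retained total;
fractions below `rel_threshold` (default 0 — no threshold is assumed) are
zeroed and the row renormalized; all-zero bins are dropped. Rows of the
resulting fingerprint matrix sum to 1 or are all zero. The forward (FAM)
channel is the analysis default; the reverse (JOE) channel is computed but
never merged into the same matrix, because the dyes are read on separate
wavelengths.

## OTUs and alpha diversity

Clone sequences are clustered at a p-distance cutoff of 0.02 ("differing
by < 2%"), implemented as *merge while linkage distance ≤ 0.02* with
average linkage — the inclusive reading matches the cutoff semantics of
mothur-era workflows; nearest/furthest linkage are options. Ties merge the
lexicographically smallest pair, making the clustering deterministic.
p-distance excludes columns with gaps or ambiguity codes from the
denominator.

Shannon H′ uses natural logarithms (the magnitudes reported for clone
libraries of ~160 sequences, H′ up to ≈ 4.5, are only consistent with
nats); Margalef SR = (S−1)/ln N; Chao1 uses the bias-corrected form
S + n₁(n₁−1)/(2(n₂+1)) so that zero doubletons stay finite. Rarefaction is
the exact hypergeometric expectation, not Monte Carlo. For fingerprint
input (continuous relative heights) only H′ is computed: SR and Chao1
require genuine individuals, and how a fingerprint's "N" was defined in
historical analyses is unrecoverable, so they are gated behind
integer-count input.

Incidence percentages round half away from zero, mirroring printed integer
percentages (21/116 → 18%, 26/116 → 22%).

## Resemblance, clustering and matrix correlation

Bray–Curtis similarity is stored as percent (0–100) to match how
fingerprint studies plot it; distances (100 − S) are derived only for
clustering. UPGMA is group-average agglomeration with the same
deterministic tie-break as the OTU clustering. The RELATE statistic is the
Spearman rank correlation between lower-triangle entries of two
resemblance matrices; significance comes from jointly permuting rows and
columns of one matrix, with p = (1 + #{ρ\* ≥ ρ})/(1 + n_perm) so the
observed configuration is always counted and p can never be 0.
Environmental matrices use per-variable centering and scaling with the
n−1 standard deviation (documented because worked examples depend on the
convention), then Euclidean distance; an optional log10(x+1) transform is
exposed for biological variables such as cell abundances, since the
historical choice of transform is unstated.

## Succession: distance decay and its two slope tests

For one water mass, each station contributes the Bray–Curtis similarity of
its community to the *reference* station (the western entrance), paired
with the along-path distance. Water masses with several depth sub-layers
per station (upper/middle/lower NADW) are pooled by averaging the
per-sub-layer similarities per station — published succession figures show
one pooled deep-water series — with a per-sub-layer mode retained for
sensitivity analysis. The reference's self-comparison (100% at 0 km) is
excluded from regressions by default: it is an identity, not an
observation (a flag restores it, since published practice is unstated).

Every point shares the single reference sample, so the points are not
independent. Two complementary tests address this:

1. **Station bootstrap** (default 10 000 replicates): stations are
   resampled with replacement as whole units, the OLS slope is refit per
   replicate (replicates with < 3 distinct distances are redrawn), and a
   percentile 95% CI plus a two-sided p for H₀: slope = 0 are reported.
   Percentile rather than BCa intervals are the default because the
   interval type in the motivating description is unspecified.
2. **ANCOVA against a permutation null**: similarity values are shuffled
   across distance labels (n_null replicates), the observed series is
   pooled with the ensemble under a group factor, and homogeneity of
   slopes is tested by the F-test on the distance × group interaction.

The description that motivated this pair — "randomly generated slopes by
bootstrapping" compared to the observed slope by ANCOVA — is ambiguous
between resampled-data slopes and a permutation null; implementing both
and reporting them side by side covers either reading without asserting
the original construction.

Off-path stations (the continuation beyond the conduit's eastern exit) are
kept as a separate region and regressed separately, with distances
continuing the along-path coordinate.

## The synthetic transect generator

`generate_scenario()` states a world and the tests live in it:

- **Layout**: 18 stations across a 2000-km transect plus 9 off-path
  stations continuing at the same spacing; seven to eight depth layers
  (Subsurface, SACW-OMZ, SACW, AAIW, uNADW, mNADW, lNADW, AABW).
- **Environment**: each sample's temperature, salinity, oxygen and
  nutrients are drawn uniformly inside its layer's published envelope
  (e.g. AABW silicate 82.74–94.47 µmol kg⁻¹); "below detection" bounds are
  coded 0. The two biological variables (cell abundance, leucine
  incorporation) are *invented realism*: exponential depth attenuation
  with lognormal scatter, orders of magnitude typical of open-ocean
  profiles; they exist so the environmental-matrix machinery has
  biological columns, not to reproduce any published profile.
- **OTU pool**: 116 T-RF types (bacterial default; 25 for an archaeal
  analogue). Of these, round(0.18 × 116) = 21 are ubiquitous across the
  four water-mass groups and round(0.22 × 116) = 26 are confined to one
  group; the remainder occupy 2–3 groups at random. Relative abundances
  are lognormal (σ = 1), reproducing the low-evenness rank-abundance shape
  of deep-water communities with a single knob; a log-series option
  exists. The published record gives richness and sharing fractions but
  not evenness, so the generator is calibrated only to the former — a
  green test establishes correct *mechanics*, not that diversity index
  values match any table.
- **Succession**: within each NADW sub-layer the present OTUs are split
  into a base set (always containing the ubiquitous OTUs) and a
  disjoint-support replacement set; the community at distance d is
  (1−f)·base + f·replacement with f = min(1, rate·d). For disjoint
  supports this gives *exactly* S(d) = 100(1 − f): expected decay slope
  −100·rate %/km, linear until saturation, richness roughly constant. The
  default rate 3×10⁻⁴ per km yields ≈ 60% turnover across the transect —
  similarity falling from ~100 to ~40%, the range seen in deep-conduit
  fingerprint series. One shared trajectory covers the three NADW
  sub-layers, since succession figures pool them. All other layers are
  homogeneous along the path.
- **Noise**: multiplicative lognormal peak-height noise with unit mean and
  CV 0.2 (a typical fingerprint replicate variability), renormalized so
  rows still sum to 1.
- **Sequences**: each OTU gets a primer-flanked amplicon whose forward
  T-RF is placed at a distinct integer in [34, 966] by inserting the
  enzyme site at the required position and mutating away any upstream
  spurious site; this makes every OTU resolvable, so the noise-free
  fingerprint equals the abundance matrix exactly (the recovery oracle
  used in tests).
- **Reproducibility**: one scenario seed; every sub-draw (roles,
  communities, metadata, noise, sequences) uses a sub-seed derived from it
  in fixed order, so scenarios are identical across platforms and the full
  pipeline is byte-deterministic.

What the generator does **not** emulate: PCR/primer bias, dye mobility
shifts, partial digestion, co-migration of distinct taxa (except when
T-RFs genuinely collide), pseudo-T-RFs from incomplete denaturation,
spatial autocorrelation of the environment beyond the layer envelopes, and
any hydrodynamics. Conclusions from green tests are therefore about the
statistical chain, not about instrument physics.

## Design choices where the ground was open

- **Unique-OTU count**: the stated fraction 0.22 rounds to 26 of 116,
  while the motivating count was 25; both print as 22%, and the generator
  follows the stated fraction.
- **Binning width, size window and channel policy** are decisions (1 bp,
  34–966 bp, forward-only), not recovered facts; all are exposed as
  parameters.
- **RELATE orientation**: the pipeline correlates community
  *dissimilarity* with environmental distance so concordance is a
  positive ρ.
- **JSON run configuration** (not YAML): equally structured, and a parser
  is guaranteed present.
- **Statistical budgets in tests**: level studies use 500 replicates with
  199-permutation RELATE, 399-replicate bootstrap and 99-replicate ANCOVA
  nulls; the power study uses 200 replicates at n_boot = 1000. Replicate
  counts follow the stated design; inner replication is scaled to CPU
  budget and the p-value granularity each count implies is respected by
  the rejection rules.

## Known limitations

- Published headline values computed on undeposited fingerprint data
  (succession R², RELATE ρ, diversity tables) are *not* reproduction
  targets; the pipeline's claims are mechanical correctness against
  oracles and calibrated error rates on synthetic truth.
- `find_amplicon()` is exact-match; degenerate positions expand, but
  mismatch-tolerant priming (and hence primer-bias simulation) is out of
  scope.
- T-RFLP-based SR/Chao1 are intentionally NA: defining "individuals" for
  continuous peak heights has no recoverable convention.
- The ANCOVA test shares residual-variance information between the
  observed series and a large permutation ensemble; with very short series
  its F-statistic is conservative relative to the bootstrap, which is why
  both are reported.
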