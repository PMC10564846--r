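---
title: "Methods: tracing marine viruses from the sea surface into aerosols and rain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing marine viruses from the sea surface into aerosols and rain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerovirome)
```

## The scientific problem

Viruses are the most abundant biological entities in seawater and accumulate
in the sea-surface microlayer (SML, the uppermost <1 mm) and in floating sea
foams — the habitat of the *virioneuston*. From there, bubble bursting and
wind can aerosolize them into the atmospheric boundary layer, and wet
deposition can return them to Earth in rain and snow. `aerovirome`
implements the quantitative machinery needed to trace such cross-ecosystem
dispersal from shotgun metagenomes and accompanying field measurements:

1. **Presence detection** of viral scaffolds and metagenome-assembled
   genomes (MAGs) from read coverage,
2. **Dispersal synthesis**: which viruses occur in which ecosystems, which
   are exclusive to rain, what fraction of the catalog is shared between
   precipitation and the sea surface, and how rain/aerosol abundances
   compare to marine ones,
3. **Virus-host linkage** by background-corrected oligonucleotide
   composition (d2\*) and by CRISPR spacer-protospacer matching,
4. **Variant overlap** between samples of the same virus, as direct
   evidence of transfer,
5. **Air-mass trajectory scoring** (time over sea, marine loading
   conditions) to explain event-to-event differences in marine-virus
   delivery,
6. **Ice-nucleating-particle (INP) spectra** from droplet-freezing assays,
7. **Station field statistics**: enrichment factors, virus-host ratios,
   correlations, and interaction linear models on flow-cytometry counts.

Because the raw sequencing data of such studies are far too large for
routine testing, the package carries a first-class synthetic-data module
that generates every input with known ground truth.

## Detection model

Reads are mapped to a dereplicated catalog of >10 kb viral scaffolds.
The package does not align reads; it consumes identity-annotated alignment
spans (or `samtools depth`-style per-base tables) and makes the filtering
explicit:

* **Read identity** = (aligned length − edit distance) / aligned length,
  over the aligned portion with soft clips excluded. The viral mapping
  contract keeps reads with identity ≥ 0.90 (inclusive — "at least 90%
  identical"). MAG mapping uses a 2% error allowance, i.e. identity ≥ 0.98.
* **Breadth** = fraction of genome positions covered by ≥1 surviving read.
* **Presence**: a viral scaffold is present in a sample if breadth ≥ 0.75;
  a MAG if breadth ≥ 0.90. Both thresholds are inclusive, and presence is
  monotone in coverage by construction.
* Reads that also map to sequencing/handling controls are removed before
  any of this.

Identity enforcement through a mapper's score function (as the original
workflows do) and an explicit edit-distance filter are approximately, not
exactly, equivalent; the explicit filter is inspectable and is what the
package defines. Abundances are mean coverages sum-normalized per sample
to a per-million scale; every downstream ratio pairs samples under the
same convention, so results are invariant to the scale choice (verified
in the tests at 10³ vs 10⁶).

## Dispersal statistics

Per-ecosystem occupancy is the OR over a virus's presence calls across the
ecosystem's samples (controls never contribute). From the occupancy matrix
the package derives Venn region counts over any ≤6 ecosystems (checked
against full subset enumeration), ecosystem-exclusive virus sets ("detected
only in rain" means no other ecosystem reached the presence criterion),
and shared fractions of the scaffold catalog; the denominator defaults to
the full dereplicated catalog and is configurable, since a catalog can be
counted before or after per-sample presence filtering.

Rain/aerosol enrichment uses the maximum sum-normalized coverage of a
virus across an ecosystem as its highest plausible abundance there, and
forms the ratios rain/foam, rain/SML, aerosol/foam, aerosol/SML with the
denominator split by size fraction (5–0.2 µm vs virome). Ratios are
undefined — not zero — when the virus was not detected in either side.

G/C base content (ambiguity codes excluded from numerator and denominator)
is compared across detection groups with a tie-corrected Kruskal-Wallis
test and Dunn's post hoc z tests (Bonferroni-adjusted by default; the
adjustment is capped at 1 and other `p.adjust` methods are selectable).
Dunn's test is implemented in the package because no post hoc package is
assumed; the Kruskal-Wallis statistic itself comes from `stats`. Alpha
diversity is the Shannon–Wiener index with natural logarithm; beta
diversity uses Bray-Curtis dissimilarities (both via `vegan`). The
PERMANOVA pseudo-F and its permutation p value are computed in-package
from within-/total sums of squared distances with 999 label permutations,
and the tests cross-check the statistic against `vegan::adonis2`.

## d2\* virus-host linkage

Viruses and their hosts share oligonucleotide usage beyond what a
low-order background predicts. For word length $k$ and Markov order $r$,
each sequence's profile holds observed counts $X_w$ (over the sequence and
its reverse complement) and expected counts $E_w = N\,P(w)$ under an
order-$r$ chain fitted to the same sequence, with a pseudocount of 0.5 on
transition counts so expectations stay positive on short sequences. With
centred counts $\tilde X_w = X_w - E_w$:

$$D_2^* = \sum_w \frac{\tilde X_w \tilde Y_w}{\sqrt{E^A_w E^B_w}}, \qquad
d_2^* = \frac12\left(1 - \frac{D_2^*}
 {\sqrt{\sum_w \tilde X_w^2/E^A_w}\,\sqrt{\sum_w \tilde Y_w^2/E^B_w}}\right)$$

clamped to [0, 1]. Self-dissimilarity is 0, unrelated i.i.d. sequences
score near 0.5, and hosts are assigned where $d_2^* \le 0.3$, the
customary cutoff of k-mer host matching. Defaults are $k = 6$, $r = 2$,
both-strand counting — the conventional parameters of this method family;
none are restated by typical study methods, so all are exposed as
arguments. Ties between equidistant hosts break lexicographically on host
id, documented and tested.

## CRISPR spacer linkage

Direct repeats (DRs, ≥16 bp) from externally discovered arrays guide
spacer extraction from raw reads: every DR occurrence with ≤3 Hamming
mismatches (no indels, mirroring the extraction tool's mismatch
parameter) is located on both strands, and substrings between consecutive
hits of length ≤60 bp are emitted. DRs that occur verbatim (100% identity,
either strand) in any viral scaffold are discarded first, as likely
virus-encoded repeats. Spacers are then length-filtered to 20–60 bp and
homopolymer-filtered — the rule is made explicit here as "any single base
≥90% of the sequence, or a single-base run ≥15" — and clustered greedily
longest-first at 99% identity (matches over the shorter length at the
best ungapped offset).

Protospacer matching is an exhaustive ungapped scan of both strands of
every scaffold, reporting hits with identity (matches / spacer length)
≥ 0.80 inclusive: a 30-bp spacer with exactly 6 mismatches is reported.
At desk scale the exhaustive scan is exact and reproducible; a short-read
BLAST heuristic, as used in the original workflows, could admit
borderline gapped hits that the ungapped definition excludes — a
deliberate simplification, stated here. The resulting bipartite network
annotates each edge with the ecosystems of the spacer's source array and
of the matched virus and flags edges that cross the marine/atmospheric
boundary, the signature of past virus-host encounters across ecosystems.

## Variant overlap

Substitution variants are called from per-position base counts at columns
with depth ≥10, emitting every non-reference base with frequency ≥0.1 and
count ≥4; the reference base comes from the scaffold sequence, never the
pileup majority. The original analyses used a desktop GUI's unpublished
defaults, so these floors are explicit, conservative and configurable,
and equivalence is not claimed. Sites are shared between samples when
position *and* alternate base coincide; overlaps are reported as Venn
regions plus a per-site membership table. Indels are out of scope.

## Trajectory scoring

Five-day hourly backward trajectories arrive above the sampling site;
each point carries reanalysis annotations (boundary-layer height BLH,
10-m wind, land mask) attached by nearest grid cell (Euclidean in
lat/lon degrees, ties to the lowest cell index). A point is *over sea*
if the land mask is false, and satisfies *loading conditions* — uptake of
generic marine particles — when it lies within the mixing layer
(altitude ≤ BLH) and surface wind strictly exceeds 3 m s⁻¹. The two
stated criteria do not include a sea mask at the loading point, so the
default applies them literally; `loading_requires_sea = TRUE` adds the
sea requirement for sensitivity analyses. Fractions are computed per
trajectory over the first 96 h (the "first four days"; the full 120 h
window remains available) and averaged unweighted per rain event.

## INP spectra

In the freezing assay, filter punches (1 mm diameter, from 47 mm
membranes) sit in 50 µL wells cooled at a constant rate while a camera
records the cumulative number of frozen wells every 0.1 K. Assuming INP
counts per well are Poisson, the cumulative concentration per mL of well
suspension at temperature $T$ is $-\ln(1 - f(T))/V_{well}$ with $f$ the
frozen fraction. Scaling to the source water divides by the filtered
volume times the punch/filter area ratio $(d_{punch}/d_{filter})^2$ —
this geometric reconstruction is the package's own, as assay
descriptions typically omit the formula. When all wells freeze the
estimator diverges; such rows are flagged censored and reported as lower
bounds with a half-count continuity correction $(n-\tfrac12)/n$, never
silently dropped.

## Station field statistics

Enrichment factors are SML/SSW concentration ratios (EF > 1: enrichment
at the interface); displayed values round half-up to one decimal,
matching table presentation. Virus-host ratios divide VLP by prokaryote
concentrations. Correlations report the coefficient, $t = r\sqrt{n-2}/
\sqrt{1-r^2}$, df = n − 2 and the two-sided p; with `method = "auto"` the
Pearson/Spearman choice is gated on Shapiro-Wilk normality of both
variables (both p > 0.05 → Pearson), and callers can force a method —
published method choices are taken as given when reproducing reported
tables. The interaction model is OLS on $[1, a, b, ab]$, reporting
adjusted R², the overall F test and AIC under the Gaussian convention
that includes the $2\pi$ constant and counts the error variance as a
parameter (`stats::AIC`); published AICs of this model family follow the
same convention.

Printed station tables carry two-significant-figure inputs, so
recomputing display values from them can differ from printed cells by one
unit in the last decimal (EFs) or about 2% (ratios); the tests encode
exactly these bands.

## The synthetic study

The generators produce a complete miniature study with known truth, under
seed-deterministic control (one global seed expands into per-stage seeds
by a fixed derivation, so stages re-run in isolation).

* **Genomes** (`sim_genomes`): hosts are order-3 Markov chains whose
  every conditional distribution carries a fixed G+C mass, so realized
  G/C concentrates within ±0.02 of target while within-class splits
  (controlled by `k_signal`) give each host a distinctive word signature.
  Viruses are sampled from their host's chain and perturbed with
  G/C-preserving point mutations (A↔T, C↔G at 5%). Generating from chains
  one order *above* the d2\* background (order 3 vs background order 2)
  is essential: a pure order-2 sample is fully explained by its own
  order-2 background, leaving no shared signal for d2\* to detect —
  matching the generating order to the background order would destroy the
  very structure the statistic measures. Virus classes mirror the study
  design: a marine core occupying foam/SML/SSW at G/C 0.35–0.47, a small
  subset additionally shared with aerosols and rain, and a rain-only
  subset at G/C 0.60. Lengths are uniform on 10–50 kb, respecting the
  >10 kb catalog rule.
* **Coverage** (`sim_coverage_design`, `sim_read_coverage`): present
  pairs get a contiguous covered block of exactly round(breadth × length)
  positions — so realized breadth is exact — tiled by 150 bp pseudo-reads
  with identities drawn in [0.90, 1]; decoys pin the inclusive threshold
  semantics at breadth 0.74 (high identity) and identity 0.85 (ample
  breadth). Edit-distance rounding keeps every read on the designed side
  of the 0.90 floor, including clipped tile ends. Optional contaminant
  reads carry ids listed in a control set. No quality scores, error
  models or insert sizes are simulated: coverage realism lives at the
  span/identity level only.
* **CRISPR** (`sim_crispr_reads`): DR-spacer-DR cassettes with spacers
  copied from the viruses at divergences {0, 0.1, 0.2} — 30-bp spacers
  make these exact identities {1.0, 0.9, 0.8}, the last sitting on the
  inclusive protospacer boundary — plus DR-free negative reads.
* **Trajectories** (`sim_trajectories`): 120 hourly points per
  trajectory; within the 96 h window the counts of over-sea and loading
  points equal the prescriptions exactly (integer-rounded), with
  non-loading points kept unambiguous (calm wind, above the mixing
  layer). Event set-points of 72%/35% and 64%/10% emulate contrasting
  marine-influence events.
* **Freezing assays** (`sim_freezing_assay`): each unfrozen well freezes
  per 0.1 K step with probability $1 - e^{-\Delta\lambda}$ from the
  prescribed cumulative spectrum, with 24 wells per assay.
* **Count tables** (`sim_count_table`): log-normal VLP/prokaryote/
  eukaryote concentrations whose raw-scale Pearson targets are mapped
  exactly onto the latent Gaussian correlation via the log-normal moment
  formula (eigendecomposition of the latent matrix, so exactly collinear
  targets remain representable; infeasible structures error).

What passing tests show — and what they do not: with noise off, every
stage reproduces its truth table exactly (zero false calls), and with the
designed noise on, d2\* host recovery stays ≥90% and the rain-only G/C
contrast is detected at p < 0.01 in ≥95% of seeded replicates. Real data
add everything the generators leave out: uneven coverage, strain
mixtures, chimeric assemblies, amplification bias, shared composition
between unrelated taxa, and trajectory model error. Green tests therefore
certify the *machinery*, not field conclusions.

## Numerical choices and problem sizes

Display rounding is half-up (half-to-even would flip table cells);
equidistant grid cells and equidistant hosts resolve to the lowest
index/lexicographic order; permutation p values use the (x+1)/(n+1)
convention; the d2\* result is clamped to [0, 1] against floating-point
excursions; report TSVs use '.' decimals and shortest-round-trip numeric
formatting, making re-runs byte-identical.

The shipped test and acceptance runs use a 20-virus, 4-host community
over a 16-sample sheet, 10 trajectories per event, 24-well assays with
200 replicates for estimator calibration, 10,000 Kruskal-Wallis null
replicates and 1,000 PERMANOVA null replicates (999 permutations each) —
sizes chosen so the whole suite exercises every stage in a few minutes on
one core while keeping Monte-Carlo error well inside the tested bands.

## Known limitations

No alignment, assembly, viral identification, binning or taxonomy — those
stages are consumed as inputs, as in the original workflows. Protospacer
matching is ungapped; DR matching tolerates no indels. Variant calling is
substitution-only with explicit thresholds, not a likelihood model.
Trajectory scoring assumes reanalysis-style BLH input and does not model
trajectory uncertainty. The INP source-water scaling assumes punches
sample the filter uniformly. File-based (non-synthetic) studies are
assembled from the exported stage functions rather than the one-call
pipeline wrapper.
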