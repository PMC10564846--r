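# aerovirome

Cross-ecosystem dispersal analysis of marine viruses along the natural
water cycle: from sea foams and the sea-surface microlayer (SML), through
boundary-layer aerosols, into rain and snow — and back.

## What it does, and for whom

Viruses accumulate at the air-sea interface (the *virioneuston*), become
aerosolized, and can return to Earth in precipitation. `aerovirome` is an
R toolkit for microbial ecologists who want to quantify that exchange
from shotgun metagenomes and accompanying field measurements. It covers:

- **Presence detection** — a viral scaffold counts as present in a sample
  when ≥ 75% of its genome is covered at ≥ 1x by reads ≥ 90% identical
  (MAGs: ≥ 90% breadth at a 2% error allowance), after subtracting reads
  that hit negative controls.
- **Dispersal synthesis** — per-ecosystem occupancy, Venn regions,
  rain-exclusive virus sets, shared catalog fractions, and rain/aerosol
  over foam/SML enrichment ratios from max sum-normalized coverage.
- **Virus-host linkage** — the Markov-background-corrected
  oligonucleotide dissimilarity
  d2\* = ½(1 − D₂\*/√(Σ X̃²/Eᴬ)·√(Σ Ỹ²/Eᴮ)), with
  D₂\* = Σ X̃ᵥᵥỸᵥᵥ/√(EᴬEᴮ) over k-mers (k = 6, order-2 background, both
  strands), hosts assigned at d2\* ≤ 0.3; plus CRISPR direct-repeat-guided
  spacer extraction (≤ 3 mismatches, 20–60 bp, homopolymer-filtered,
  99% clustering) and ungapped protospacer matching at ≥ 80% identity.
- **Variant overlap** — frequency-based substitution calls per sample and
  their (position, alternate-base) intersections across ecosystems.
- **Trajectory scoring** — time over sea and marine "loading conditions"
  (within the mixing layer, surface wind > 3 m s⁻¹) over the first 96 h
  of 5-day backward trajectories, summarized per rain event.
- **INP spectra** — cumulative ice-nucleating-particle concentrations
  from frozen-fraction assays via Poisson statistics,
  c(T) = −ln(1 − f(T))/V.
- **Field statistics** — SML/SSW enrichment factors, virus-host ratios,
  correlation tests with t and df, and wind × salinity-style interaction
  linear models with adjusted R², F and AIC.

A seed-deterministic synthetic-data module (`sim_*` functions) generates
genomes, coverage, CRISPR cassettes, trajectories, freezing assays and
count tables with known ground truth, so the entire pipeline is testable
offline.

## Worked example

Enrichment factor of virus-like particles in the SML over subsurface
water at one station, and the shared-virome arithmetic:

```r
library(aerovirome)

enrichment_factor(3.4e7, 1.9e7)
#> # A tibble: 1 × 3
#>      ef ef_display undefined
#>   <dbl>      <dbl> <lgl>
#> 1  1.79        1.8 FALSE
```

VLPs are 1.8-fold enriched at the interface. Correlating small
phototrophic eukaryotes with VLPs across the packaged station table
(`inst/extdata/station_counts.csv`):

```r
counts <- read_station_counts(
  system.file("extdata", "station_counts.csv", package = "aerovirome"))
correlate(counts, euk_sml, vlp_sml, method = "pearson")
#> # A tibble: 1 × 8
#>   method  estimate     t    df      p     n ...
#> 1 pearson    0.732  3.04     8 0.0160    10
```

Eukaryote and VLP abundances in the SML co-vary (r ≈ 0.73, p ≈ 0.016,
n = 10 stations) — the tight virus-host association expected in the
neuston. If 112 of an 1813-scaffold catalog occur in both precipitation
and seawater:

```r
occ <- tibble::tibble(target_id = paste0("v", 1:112), rain = TRUE, SML = TRUE)
shared_fraction(occ, "rain", "SML", total = 1813)
#> # A tibble: 1 × 4
#>   shared total percent percent_display
#> 1    112  1813    6.18             6.2
```

6.2% of the virome is shared across the air-sea boundary. A full
synthetic study — generation, detection, dispersal, linkage, variants,
trajectories, INP, field statistics — runs in one call:

```r
report <- run_virome_pipeline(virome_config(seed = 1))
report$trajectories$summary$events   # per-event sea-time and loading %
write_virome_report(report, "results/")
```

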