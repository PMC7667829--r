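---
title: "Detecting DNA transduction from paired metagenome and virome coverage"
author: "transductr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DNA transduction from paired metagenome and virome coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transductr)
```

## The measurement

Bacteriophages and phage-like particles move host DNA between cells
(transduction). When a microbial community sample is split into a
whole-community DNA fraction and an ultra-purified virus-like-particle (VLP)
fraction, and both read sets are mapped onto the same assembled contigs, the
*shape* of the VLP coverage along each contig reveals which DNA is being
packaged and by what mechanism:

* **Prophage/island induction** — a sharply bounded high-coverage plateau
  over the element: particles carry the element's own genome.
* **Specialized transduction** — the same plateau plus low, declining
  coverage over the host DNA immediately flanking it: rare imprecise
  excision packages a capsid's worth of DNA shifted across one prophage
  edge.
* **Generalized transduction** — coverage peaks that rise vertically at
  packaging-initiation (*pac*-like) sequences and decline in a staircase of
  fixed-size steps: processive headful packaging continues past the first
  capsid with per-headful probability *q*, so expected coverage at distance
  *d* downstream of a site with initiation rate *r* is
  `r` &middot; `q^floor(d/H)` for headful size *H*.
* **Lateral transduction** — in-situ headful packaging starting at the edge
  of a still-integrated prophage: an induction plateau with a
  high-frequency, strictly one-sided, log-linearly decaying flank spanning
  hundreds of kbp.
* **GTA-like packaging** — gene-transfer-agent-like particles packaging
  fixed-size quasi-random fragments: mildly uneven coverage with no sharp
  edges.

The package automates what was originally a visual inspection task: it bins
and normalizes coverage, segments the VLP track, classifies each contig,
estimates transducing-particle frequencies, *pac* positions and headful
sizes, and screens candidates for cellular-DNA contamination. A mechanistic
packaging simulator generates ground-truthed inputs for every one of those
claims.

## Coverage tracks

Depth is computed per contig as the mean per-base depth in fixed bins
(default 100 bp; the last, possibly partial, bin is averaged over its true
width). Contigs shorter than 40 kbp are discarded — shorter sequences cannot
expose plateau-plus-flank or multi-headful patterns. The boundary is
inclusive: exactly 40,000 bp is kept. Multi-mapped reads placed once at a
random location by the aligner carry mapping quality 0 and are counted by
default (`min_mapq` raises the bar); whether to filter them is exposed to
the user because repeat-heavy elements otherwise lose coverage.

Tracks are normalized to depth per million mapped reads
(`norm = depth * 1e6 / total_mapped`) so the two differently sequenced
samples are comparable. All *fold*-type thresholds operate on normalized
depth; all *coverage gates* operate on raw depth. The division is
deliberate: jointly rescaling a sample (same library, more lanes) changes no
classification, while subsampling reads leaves every fold unchanged but
pushes raw depth below the gates — which is exactly how detection degrades
with sequencing depth in practice.

## The packaging simulator

`genome_model()` composes inducible prophages (`prophage_element`),
chromosomal islands (`island_element`), *pac* sites (`pac_site`) and GTA
parameters (`gta_params`) on one linear or circular replicon.
`simulate_fragments()` draws each particle as one packaged interval;
`expected_coverage()` gives the exact closed-form expectation of the same
process, and the two agree bin-by-bin within Monte-Carlo error (this is
tested, at 100,000 particles, to 5 standard errors per bin).

Modeling choices worth knowing:

* **Specialized flank law.** The observed signal fixes the flank span and
  its declining shape, not the underlying excision law. We use the least
  informative choice: flank extent uniform on (0, G − m], where G is the
  capsid capacity and m the minimum retained phage DNA. This yields a
  linearly declining expected flank of maximal extent G − m (25 kbp in the
  lambda-like preset).
* **Headful continuation.** The first headful is always packaged; each
  subsequent one continues with fixed probability q (memoryless). A
  particle's headful index is therefore 1 + Geometric(1 − q), and an
  initiation rate r corresponds to r/(1 − q) particles.
* **Lateral packaging** reuses the headful machinery with the initiation
  site pinned at a prophage edge, strictly unidirectional, with the capsid
  capacity as the headful size.
* **Geometry.** Fragments truncate at linear contig ends and wrap on
  circular replicons. Truncation matters: fixed-size fragment packaging on
  a linear replicon depresses coverage over one fragment length at each
  end, which is why the GTA presets are circular.
* **Whole-community tracks** are flat or carry a log-linear
  origin-of-replication gradient, with optional per-bin Poisson noise.

### Fixture presets

`make_fixture()` (parameters in `inst/extdata/fixtures.yaml`) reproduces the
magnitudes of the characterized packaging systems: a temperate-phage contig
with a 1:10,000 specialized frequency and ~25 kbp flanks; a generalized
transducer with six *pac*-like sites, a 44 kbp headful and q = 0.6; a
quasi-random packager with low (&le; 10-fold) unevenness; a GTA packaging
13 kbp fragments whose bias field is calibrated so the smoothed expected
coverage has exactly a 30-fold max/min ratio; a lateral transducer at
1:240; and a mixed community of &ge; 50 contigs (40–800 kbp) spanning all
modes plus seeded cellular-contamination contigs.

Simulated coverage levels are design choices of the generator, set so that
every seeded signature clears the detector's raw-depth gates: e.g. the
lambda-like plateau is 2&times;10^6 particles so its 1:10,000 flank sits
near 200&times;, above the 150&times; flank gate; community
specialized/lateral elements use frequencies of 1:50 and 1:40 — the
high-efficiency end of what has been observed for chromosomal-island-
adjacent lateral transfer — so flanks are measurable at community-scale
plateau depths. The PBSX-like preset simulates 600,000 particles: the
max/min unevenness estimator is upward-biased by noise at its extremes, and
the deeper sample keeps the measured ratio within a few percent of the
configured 30-fold.

What the simulator does *not* emulate: read-level error and mappability,
strain mixtures, chimeric assemblies beyond the evenness flag, and
recombination into recipients. Passing on fixtures therefore demonstrates
correct recovery of the modeled signal shapes at realistic depths, not
robustness to every artifact of real assemblies.

## The detector

Per contig, on the normalized VLP track:

1. **Baseline** — median of bins at or below the 25th percentile (the lower
   coverage envelope). A higher quantile is unsafe: a lateral flank
   legitimately covers most of a contig and would inflate its own
   reference level.
2. **Segmentation** — penalized binary segmentation of
   log2(norm + pseudocount). The penalty is
   max(4&sigma;&#770;&sup2; log n, 1) with &sigma;&#770; from successive
   differences; the absolute floor of one log2 unit protects zero-inflated
   tracks, where the noise estimate collapses, from being shredded. Ties
   resolve toward fewer segments; segments always tile the contig.
3. **Features** — per-segment mean, fold over baseline, edge sharpness
   (ratio of 500 bp means across the boundary, floored at the pseudocount,
   with a one-bin guard band so a breakpoint placed one bin off does not
   dilute the fold), and a log-linear decay fit (slope per 10 kbp, R&sup2;).
4. **Cascade** — induction requires a 5–200 kbp plateau &ge; 10-fold over
   baseline with sharp (&ge; 5-fold) rising/falling edges and raw depth
   &ge; 20&times;; specialized adds flanks &ge; 3-fold over baseline, below
   a tenth of the plateau, shorter than 100 kbp, with smoothed raw depth
   &ge; 150&times;; lateral replaces the extent condition with a one-sided,
   decaying flank &ge; 100 kbp; generalized requires no plateau, &ge; 1
   *pac* call and &ge; 5-fold smoothed unevenness; GTA-like covers 2–5-fold
   unevenness without sharp edges; flat tracks (or tracks whose smoothed
   raw depth never reaches 5&times; — below that, max/min ratios measure
   shot noise) are standard; the rest is unknown. Contig-level mode takes
   the highest-precedence element call.

*pac* sites are segmentation boundaries with a sharp edge followed by a
sustained log-linear decline over two headful scales; a candidate is
rejected if a second sharp edge lies inside its decay window (a staircase
declines only through gentle 1/q steps — a cliff means a plateau), and
calls within one headful deduplicate to the strongest. Headful size is
estimated from the strong negative steps of the smoothed log track: lagged
differences are thresholded into a step-impulse train, the dominant
autocorrelation lag of that train gives the period, and the median
consecutive step spacing refines it. The raw autocorrelation of unthresholded
first differences, though conceptually equivalent, is numerically swamped
by per-bin noise at realistic depths.

The transducing-particle frequency is the plateau-to-flank coverage ratio,
reported as 1:N to two significant figures, with the flank maximum taken
from a lightly smoothed track two bins clear of the plateau edge.

### Numerical choices

* **Pseudocount 0.01 normalized units.** In per-million units the
  normalized height of a specialized flank is determined by its *share* of
  the sample's reads, not by sequencing depth: for a 1:10,000 element the
  flank can never exceed a few tenths of a unit. A pseudocount of 1 would
  therefore erase exactly the faint signals the method exists to find;
  0.01 keeps them three folds above the floor while still suppressing
  empty-track jitter.
* **Coverage gates** (20&times; induction, 150&times; flank, 5&times;
  signal floor) reflect where the respective patterns stop being
  distinguishable from noise as reads are subsampled; below a gate the
  detector refuses to upgrade the call and flags `low_coverage`.
* **Contig ends.** Patterns touching an end are flagged
  `truncated_at_end`; truncated edges are evaluated over the available bins
  only.
* **Degenerate inputs** (all-zero tracks, single-segment contigs) fall
  through to standard with flags rather than erroring.

Known limitations: a GTA-like element with very strong (&ge; 5-fold)
packaging bias but no sharp edges lands in `unknown`, as does any strongly
uneven track without *pac*-like edges; prophages and chromosomal islands
cannot be distinguished without gene annotation and both report as
induction; minus-strand staircases are supported but mixed-orientation
overlapping staircases closer than one headful will merge.

## The contamination rank screen

Cellular DNA that survives VLP purification produces coverage whose
*composition* mirrors the whole-community sample. Each contig's share of
summed mean coverage is computed per sample and ranked (1 = highest; ties
broken lexicographically by contig id so ranks are a deterministic
permutation). A candidate whose VLP rank is numerically worse than its
whole-community rank is flagged `contamination_suspect`; equal or better
ranks are `consistent`. The screen is advisory — flags annotate calls, they
do not delete them, since a low-efficiency genuine element can also rank
worse. Zero-coverage contigs take the worst ranks deterministically.

## Worked example

```{r example, eval = FALSE}
library(transductr)

fx <- make_fixture("lambda_like", seed = 1)
call <- call_patterns(fx$pairs[[1]])
call
#> <pattern_call> lambda_contig  mode=specialized  primary=[125000,173500)  freq=1:9700
vapply(call$flanks, function(f) f$extent, numeric(1))
#>  left right
#> 23300 23100
```

The scanner (`cmd_scan()`, or `inst/cli/transductr.R` from a shell) runs
the same steps over SAM/BAM, per-base depth TSV or bedGraph inputs and
writes BED calls, a per-contig TSV report, the rank table, bedGraph tracks
and a run log; outputs are byte-identical across re-runs with the same
inputs.

## Validation scale

The shipped tests and the acceptance script run entirely on simulated
fixtures: single-replicon presets of 0.3–2 Mbp and a 62-contig community
(~15 Mbp total, ~10^6 particles), sizes at which the full suite completes
in well under a minute while every statistical check retains comfortable
margins. The acceptance script reports: Monte-Carlo/closed-form agreement,
recovery of the 1:10,000 specialized and 1:240 lateral frequencies, 6/6
*pac* localization and the 44 kbp headful, the 30-fold (GTA) and
&le; 10-fold (quasi-random) unevenness magnitudes, community per-mode
recall/precision, the downsampling detection-limit ordering, and the rank
screen's hit/false-flag rates.
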