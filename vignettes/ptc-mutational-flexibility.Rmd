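---
title: "Methods: scoring mutational flexibility of the ribosomal PTC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring mutational flexibility of the ribosomal PTC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcflex)
library(dplyr)
```

This vignette is the package's own account of the models, parameter
choices and numerical conventions behind each analysis stage, and of what
the synthetic-data tests do and do not demonstrate.

## The study design

The package analyses saturation single-point mutagenesis of three 23S
rRNA regions around the peptidyl transferase center, in *E. coli*
numbering:

```{r}
ptc_regions()
```

The PTC-ring comprises 43 nucleotides, the A-loop 13 (U2548–A2560) and
the P-loop 5 (G2250–C2254): 61 positions, each admitting three
substitutions, hence 183 mutants. The panel size often quoted for this
design is 180; that figure cannot be reconciled with the stated ranges
(which enumerate 61 × 3 = 183), and which three mutants were excluded is
not documented. The package deliberately enumerates all 183 and leaves
sub-setting to the caller.

Wild-type identities for the 61 positions ship as a bundled table
(`ptc_reference_bases()`). Identities follow the standard mutant
nomenclature of the field (A2451, U2585, G2553, …) where positions are
named in the literature; the handful of interior positions that are
rarely named carry the *E. coli* 23S reference identity. The table is an
argument, not a constant — pass your own `ref_bases` for another organism
or numbering.

## Conservation: per-column Shannon entropy

For an alignment column, `column_entropy()` evaluates
$H = -\sum_{i \in \{A,U,G,C\}} p_i \ln p_i$, where $p_i$ is the count of
base $i$ divided by the number of *retained* sequences. The natural
logarithm is used — the ceiling for four equiprobable bases is then
$\ln 4 \approx 1.386$ nats — and values are reported in nats throughout.

Two conventions matter:

- **Exclusion rule.** By default every character outside `{A,C,G,U}`
  after uppercasing and T→U mapping (gaps `-`/`.`, ambiguity codes such
  as N, R, Y) is removed from the column before computing probabilities.
  This generalizes the strict gap-only rule; `exclude = "gap_only"`
  restores the stricter behaviour and errors on ambiguity codes so the
  difference is auditable. Exclusion counts are always reported.
- **Degenerate columns.** A column where every sequence is excluded has
  *undefined* entropy and raises an error; it is never silently reported
  as 0, because 0 means perfect conservation.

Alignment columns are indexed 1-based, matching R convention; the mapping
from ungapped reference positions to columns
(`map_reference_positions()`) guarantees that the reference character at
the mapped column equals the reference's ungapped character.

## Activity and the flexibility score

Reporter fluorescence (RFU) converts to protein concentration (μM)
through a linear standard curve fit by ordinary least squares
(`fit_standard_curve()`); conversions that come out negative — noise near
the blank — are floored at 0 with a warning. Replicate traces (the
generators default to n = 3) are averaged pointwise *after* conversion,
with the tail standard deviation propagated.

Three summary statistics per sample:

- **Bulk rate** (μM protein/h): the OLS slope of concentration vs time
  over a window, default 0–2 h. The early-window slope approximates the
  initial rate; for a saturating trace it is biased low by curvature
  (about 10% at the default generator settings), which is why the
  parameter-recovery tests assert a 10% tolerance rather than equality.
  The window is an argument.
- **Endpoint yield** (μM): mean signal over the final 10% of the time
  axis, a plateau estimate robust to noise in traces monitored for
  16–20 h; `method = "last"` takes the final point instead. Which of the
  two feeds the published notion of "yield" is not documented anywhere we
  could verify, so the choice is a switch and the default (plateau) is
  the noise-robust one.
- **Relative activity**: mutant yield / wild-type yield, wild type ≡ 1
  exactly (the wild type is pushed through the identical pipeline).
  Relative activities are *not* capped at 1: a hyperactive mutant can
  exceed it, and consequently a position's score can exceed 3. The 0–3
  framing assumes mutants never beat wild type; the package reports what
  the data say.

The **mutational flexibility score** of a position is the sum of its
three mutants' relative activities (`flexibility_scores()`), which
requires exactly three distinct mutants per position and fails loudly on
duplicates or gaps. Two flags follow the study's annotation conventions:
`flag_flex_ge_1` (score ≥ 1) and `flag_any_ge_75pct` (best mutant ≥ 0.75).

## Readthrough normalization

Relative readthrough is mutant signal / wild-type signal computed *per
construct* (stop codon × amino-acid position), so the wild type is 1 on
every construct and construct-specific differences in absolute signal
cancel. Normalized readthrough divides by the mutant's relative
activity — the literal reading of "normalized by translation activity";
the alternative reading (multiplying by a reciprocal yield measure) is
algebraically the same here. Below an activity floor (default 0.02, i.e.
2% of wild type) the division amplifies noise without bound, so such
records return `NA` with a `below_activity_floor` flag and the raw ratio
retained — never infinity. No codon-specific correction for RF1/RF2
recognition is applied; release-factor effects are an interpretation, not
a computation.

## Gradient quantification

`correct_trace()` subtracts a blank-sucrose baseline and a no-operon
background (each linearly interpolated onto the sample grid;
extrapolation is refused) and clips negatives at 0, logging the clip
count — A254 cannot be negative. The background trace is taken to be
already baseline-corrected; the synthetic generator emits it that way.

`integrate_species()` uses a left-endpoint rectangle rule on the measured
grid — the closest literal reading of summing "between each x-axis
coordinate" — over half-open windows $[start, end)$, so adjacent windows
never double-count a grid point and areas are exactly additive. A
trapezoidal rule is available via `rule = "trapezoid"`. Default windows
(30S 13–21 mm, 50S 22–28 mm, 70S 30–40 mm, polysomes 42–59 mm) are
instrument-dependent approximations and overridable. Signal falling in
the gaps between windows (e.g. 28–30 mm) is attributed to no species; it
is reported as the `unassigned_area` attribute so nothing is silently
lost. The two assembly ratios are invariant under global scaling of the
trace, which the tests assert.

## Structure mapping

- **Heavy atoms only**: hydrogens are excluded everywhere; crystal
  structures at ribosome resolutions do not place them reliably. Alternate
  locations keep the highest-occupancy atom. Author residue numbering is
  used throughout so 23S positions address residues directly.
- **Reference points**: the unweighted mean of the selected heavy atoms.
  For tRNA reference points, select A76 together with the attached
  amino-acid moiety by passing both residue numbers to
  `reference_point()`; passing A76 alone restricts the reference.
- **Superposition**: `kabsch_superpose()` implements the SVD form of the
  Kabsch least-squares rigid fit with the reflection guard, refusing
  fewer than three or collinear points. `superpose()` pairs atoms across
  structures by (chain, residue, atom name), defaulting to phosphorus
  atoms — a sparse, robust selection for placing tRNAs from one ribosome
  structure into another's frame. The published distance span (4 Å to the
  nearest A-loop nucleotide, 36 Å to the farthest loop nucleotide) is
  sensitive at the ±1 Å level to the superposition protocol, which is not
  documented in the source study; the shared selection is therefore an
  argument.
- **Shells**: quantile (equal-count) binning of flexibility scores into
  four ordered shells, ties broken toward the lower shell so equal scores
  always share a shell. Published color thresholds are unavailable, so
  equal counts is the default and explicit `thresholds` are accepted.
- **Attribute maps**: `write_attribute_pdb()` writes scores into the
  B-factor field (2-decimal PDB precision, sentinel −1 for unmapped
  residues) so any viewer can render the heat map; the file round-trips
  through `load_structure()`.

## Regression

`linear_regression()` is ordinary least squares with a two-sided *t* test
on the slope (n − 2 df). No multiple-testing correction is applied,
matching per-comparison reporting. A constant response returns slope 0,
$R^2 = 0$, p = 1 exactly rather than floating-point noise. The testthat
suite calibrates the test's type-I error on 1000 seeded null replicates
at n = 20 and requires the rejection rate at α = 0.05 to fall in
[0.03, 0.07].

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed, and
returns its generating truth alongside the data.

- **Kinetics**: single-exponential saturation
  $c(t) = P\,(1 - e^{-(r/P)t})$ with initial slope exactly the bulk rate
  $r$ — the simplest curve matching rise-to-plateau reporter traces.
  sfGFP maturation delay is deliberately omitted. Defaults: wild-type
  rate 1.03 μM/h, plateau 10 μM, 20 h horizon sampled every 15 min.
  Mutant traces scale both rate and plateau by the activity truth, so all
  samples share one saturation constant and noiseless relative activities
  equal the truth exactly — that is what lets the end-to-end test demand
  3-decimal recovery.
- **Noise**: multiplicative Gaussian, CV-parameterized, floored at 0, on
  fluorescence and A254 alike.
- **Alignment**: columns drawn independently from specified base
  frequencies (default panel: probability concentrated on the wild-type
  base more strongly at less flexible positions), gaps at a fixed rate,
  and a gap-free majority-base reference record.
- **Gradients**: four Gaussian peaks (centers 17/25/35/50 mm, σ
  1.2/1.2/1.5/2.5 mm) whose areas are the species truth, plus linear
  drift (blank) and a stray background peak. The five default samples
  span wild-type-like assembly (subunit ratio ≈ 1.4, 70S:polysomes
  ≈ 0.54) to a severely assembly-defective profile built to a subunit
  ratio of ≈ 16.8 — at 10% noise the recovered defective ratio is
  systematically below its construction value because noise leaves
  residual mass in the small 70S/polysome windows of that sample.
- **Structure**: each toy nucleotide is a four-atom cluster whose
  symmetric offsets make the heavy-atom mean exact. Loop nucleotides sit
  at prescribed radii from their cognate tRNA reference (G2553 at 4 Å
  from the A site; the span reaching 36 Å from the P site), in the plane
  perpendicular to the axis joining the two references so the distance to
  the other reference is known in closed form. PTC-ring radii are drawn
  uniformly — the default truth gives the loops a distance-tied
  flexibility gradient and the ring distance-independent mixture classes,
  mirroring the qualitative structure such scans report.
- **Panel**: 61 positions × 3 mutants + wild type, three replicates, four
  UAG readthrough constructs (amino acids 50/100/116/216), five gradient
  samples, one toy structure. Panel alignments use 400 records for speed;
  the acceptance script's entropy-bound checks use 1614-record alignments
  (the size of the reference LSU alignment).

### What passing tests show — and what they do not

Parameter-recovery tests demonstrate that the pipeline is an unbiased,
correctly-plumbed estimator *of its own generating model*: noiseless
bundles recover flexibility exactly; 10%-CV bundles recover the ranking
(Spearman ≥ 0.9); readthrough ranking survives noise (Kendall τ ≥ 0.9);
gradient fractions return within 2% when peaks sit inside their windows.
They do not validate the biochemical assumptions (single-exponential
kinetics, Gaussian peaks, linear standard curve) against real traces, nor
the accuracy of any wet-lab measurement. Real data add features the
generators omit by design: maturation lag, correlated replicate error,
peak overlap and tailing, alignment phylogenetic structure.

## Problem sizes and runtime

The default test suite runs full 184-sample panels (one noiseless, one at
CV 10% with 3 replicates), 2000-record alignments for sampling-tolerance
checks, and 1000-replicate null simulations; the whole suite completes in
well under a minute on one core, and `scripts/acceptance.R` in a few
seconds. These sizes were chosen as the smallest that keep sampling error
comfortably inside the asserted tolerances.

## Known limitations

- Conservation ignores phylogenetic relatedness; entropy treats each
  sequence as independent.
- Overlapping gradient species are not deconvolved; windowed integration
  under-counts peaks whose tails cross window edges.
- The readthrough assay design cannot separate miscoding from
  termination-fidelity defects, so the package computes a single
  readthrough quantity and leaves interpretation to the analyst.
- Distances computed from superposed structures inherit ±1 Å-scale
  sensitivity to the shared-atom selection.
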