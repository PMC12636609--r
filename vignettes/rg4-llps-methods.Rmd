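---
title: "Models and methods: quantifying rG4 control of FUS phase separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying rG4 control of FUS phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4llps)
```

RNA G-quadruplexes (rG4s) — four-stranded structures of stacked G-quartets —
can inhibit, reverse, or (at high repeat number) nucleate the liquid–liquid
phase separation (LLPS) of the RNA-binding protein FUS. `rg4llps` implements
the quantitative analyses such a study needs as one tested pipeline: rG4
motif scanning, transcriptome-interval enrichment with permutation nulls,
binding and melting curve fits, turbidity kinetics, and condensate image
quantification. Every stage has a synthetic-data generator with known ground
truth, so the whole pipeline is testable without any external download.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology left
genuine freedom. No empirical claim is made here beyond what the package's
own tests and acceptance script compute.

## rG4 motif scanning

`find_candidates()` enumerates every placement of four equal-length G-runs
(`g >= min_group` tetrads) separated by three loops, under the standard
QGRS-mapper parameter set for short RNA panels: maximum motif span 30 nt,
minimum G-group size 2, loop lengths 0–36 nt (`scan_params()`). The
enumeration is exhaustive within the constraints — a G-run longer than `g`
yields candidates at every register, and overlapping candidates are all
reported — because the consumed signal downstream is presence/absence, not a
non-redundant annotation.

The G-score constants of the original mapper are not public, so ranking uses
a surrogate implementing the same ordering principles (more tetrads, shorter
span, more equal loops):

$$\mathrm{score} = 10\,(g - g_{\min}) + (L_{\max} - L) -
  (\max_i l_i - \min_i l_i).$$

The surrogate affects only which candidate is reported as "best" per
sequence; classification (`classify_panel()`) depends only on whether any
candidate exists. The scanner is alphabet-agnostic on loops (any base) and
counts G-runs on the uppercased U/T-normalised sequence, so DNA and RNA
inputs classify identically.

## Interval enrichment of rG4 regions in the FUS interactomes

All interval arithmetic uses the BED convention (0-based, half-open) and is
delegated to `GenomicRanges`; strand is carried through IO but ignored,
since phase-interactome overlap is a transcript-level question. "Occurrence"
of a region in an interactome is the **count of overlapping interactome
intervals** (`bedtools intersect -c` semantics) at a minimum overlap of
1 bp; base-pair coverage and read counts are plausible alternative readings,
but interval counts are the simplest reading consistent with an
intersect-based workflow.

Regions scored with a G4 probability (the fraction of reads with reverse
transcription stops in an rG4-seq experiment) are split by
`stratify_by_probability()` into three groups of near-equal size — sizes
differ by at most one, extras go to the lower strata, ties keep input order
— labelled low/medium/high. The imaging-independent enrichment score of a
region shared between phases is

$$E = \frac{\text{occurrences in the soluble FUS interactome}}
           {\text{occurrences in the droplet FUS interactome}},$$

defined only when the droplet count is positive; soluble-exclusive regions
(droplet count zero) are the strongest soluble bias and rank ahead of all
shared regions in `select_candidates()`.

`permutation_test()` evaluates overlap specificity: the observed statistic
is the number of query intervals with any overlap; the null re-places one
set uniformly in the genome (`shuffle_intervals()`, bedtools-shuffle
semantics: chromosome drawn proportional to length among those that fit,
start uniform, overlaps permitted) 100 times by default, in either
direction. The empirical p-value uses the pseudocount estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(N+1)$, which is
conservative, never zero, and standard for permutation tests. Shuffling is
genome-wide; restricting placement to transcribed regions would sharpen the
null but requires an annotation the pipeline deliberately does not depend
on.

The generator `simulate_enrichment_dataset()` emulates this structure: 300
non-overlapping 30-bp scored regions in a 2 × 1 Mbp genome, uniform G4
probabilities, and 100-bp interactome intervals planted to overlap each
region with probability 0.8/0.55/0.3 (high/medium/low strata) for the
soluble set and 0.3 throughout for the droplet set. The high/low defaults
bracket a strong but not deterministic association; the medium value is
their midpoint (the generative law is not constrained further by the
analysis). One region is planted soluble-exclusive: its droplet probability
is forced to 0 *and* its soluble overlap is forced on, because a region
that merely lacks a droplet draw could also miss its soluble draw and
become unrecoverable. Interactome intervals are 100 bp against 30-bp
regions to create the many-to-one overlap structure of interactome
fragments against rG4-seq windows.

One numerical subtlety: `shuffle_intervals()` and `permutation_test()`
scramble their seed with a Lehmer step before seeding the RNG. Both the
data generator and the shuffler draw chromosome-then-start sequences, so
seeding both with the same integer would make the null shuffles replay the
generator's placement draws and stack null intervals on top of the
original regions, biasing the null upward. The scramble decouples the two
streams while keeping every result deterministic per seed.

A genuine null configuration sets all plant probabilities to zero and adds
uniformly placed background intervals (`n_background`); with planted
overlaps at *any* nonzero rate, a genome-shuffle null is not uniform by
construction, so calibration checks use the zero-plant configuration and,
independently, a query set that is itself a shuffled copy of the subject.
Type-I error at $\alpha = 0.05$ is verified to sit in $[0.02, 0.10]$.

## Binding isotherm

Fluorescence anisotropy titrations are fitted to the exact (ligand
depletion) solution of 1:1 binding, required because the labelled RNA
concentration ($L_t = 8$ nM) is not negligible against nanomolar $K_d$:

$$y = a_0 + \Delta A_{\max}\,
  \frac{(x + L_t + K_d) - \sqrt{(x + L_t + K_d)^2 - 4 x L_t}}{2 L_t}.$$

The bracketed ratio is the bound fraction of the RNA, so $y$ runs from
$a_0$ to $a_0 + \Delta A_{\max}$. Fitting (`fit_binding()`) is
Levenberg–Marquardt with $K_d$ initialised at the half-maximal $x$,
amplitude at the data range, positivity bounds on $K_d$ and
$\Delta A_{\max}$, parameter tolerance $10^{-10}$, and a 10,000-evaluation
cap. An additive offset $a_0$ is fitted by default — raw anisotropy data
then work unchanged — and pinned to zero with `fit_offset = FALSE` for
baseline-subtracted data. Replicates are pooled into one fit. A fitted
amplitude within twice the residual noise is flagged `"flat"` rather than
reported as a binder.

## CD spectra and two-state melts

Spectra are smoothed with the means-movement method — a centred moving
average, width 15 points by default; the vendor algorithm is specified only
by name and width, and a plain centred mean reproduces its behaviour on
smooth spectra. At the edges the window shrinks symmetrically rather than
padding, so no phantom values enter. Buffer blanks are subtracted pointwise
on an identical grid. A parallel rG4 call (`is_parallel_g4()`) requires a
positive smoothed peak at 265 ± 5 nm and a negative trough at 240 ± 5 nm.

Melts at 265 nm are fitted to the two-state van't Hoff model with sloping
baselines, with temperature in Kelvin (the exponential's $1/X$ is only
physical on an absolute scale):

$$Y = \frac{(m_f X + b_f) + (m_u X + b_u)\,Q}{1 + Q},\qquad
  Q = \exp\!\left[\frac{\Delta H}{R}\left(\frac{1}{T_m} -
  \frac{1}{X}\right)\right].$$

$\Delta H > 0$ is enforced (unfolding is endothermic; $Q$ must increase
with temperature). Initialisation: $T_m$ at the steepest point of the
smoothed curve, $\Delta H = 150$ kJ/mol, baselines from linear fits to the
outer 20% of points. A fit whose transition amplitude is under 5% of the
signal range, or whose $T_m$ lands more than 20 K outside the data, is
flagged `no_transition`. On the standard instrument grid (15–85 °C at 1 °C)
with 0.1 mdeg noise and a ~5 mdeg transition, the $T_m$ estimator is
unbiased with a sampling sd of ≈ 0.4 °C — the information limit once the
baseline slopes are free parameters, not an optimizer artefact.

## Turbidity kinetics

Inhibition assays: the pointwise mean of the buffer blanks is subtracted
per trial, then every trace is divided by the maximum of that trial's
single zero-RNA control. Reversal assays: each trace is divided by its own
pre-RNA level, taken as the mean of the last 5 points before addition — a
window, rather than the final point, to resist single-point noise. AUC is
the trapezoidal integral on the native 1-minute grid (no resampling;
endpoints interpolate linearly), normalised against the matched zero-RNA
control when one is supplied. Sedimentation gives pellet/supernatant
fractions that sum to one exactly.

The turbidity generator models LLPS as a logistic rise; reversal
multiplies the post-addition signal by an exponential decay toward the
floor $1 - s$ for inhibitor strength $s \in [0,1]$, so $s = 0$ is a flat
null and AUC is monotone non-increasing in $s$; an enhancement multiplier
above 1 reproduces the low-concentration turbidity increase seen when many
small droplets scatter more light.

## Droplet and cell images

`segment_droplets()` applies a lower-bound threshold (Otsu by default,
numeric override for parity with manual analyses), labels 8-connected
components, and discards components under 4 px. Because Otsu always splits
*something*, a guard refuses segmentations whose foreground/background
class means are separated by less than three pooled within-class standard
deviations — a noise-only frame yields zero droplets, not percolating
noise clusters. "Size" is reported as the equivalent diameter
$2\sqrt{A/\pi}$. Per-droplet enrichment divides mean intensity inside by
the mean background, where the background excludes all droplets plus a
2-px halo (Chebyshev neighbourhood, so rim corners are excluded too) to
keep partial-volume rim pixels out of the denominator. Phase diagrams
average droplet counts per image and pool enrichment within each
(condition, time) cell; passing the full image inventory lets droplet-free
images pull the mean count down.

The stress-granule colocalization pipeline mirrors the standard
CellProfiler recipe: channels are speckle-enhanced with a white top-hat
(disc diameter 20 px), thresholded; nuclei are thresholded and eroded by
5 px so peri-nuclear foci survive; the shrunken nuclei are inversely
masked onto the foci. Pearson correlation of the raw intensities is then
computed over the **union** of the two channels' cytoplasmic foci masks —
the exact pixel population is a genuinely open choice (per-object and
whole-cytoplasm are defensible); the union is symmetric in the channels
and sensitive to both co-occurrence and anti-occurrence.

The image generators plant non-overlapping disks with per-focus
brightnesses drawn once and shared between channels for colocalized foci —
coincident-but-flat foci would carry no correlated signal and Pearson r
would be meaninglessly near zero even at full colocalization. Nuclear foci
are planted interior to the nuclei (8 px inside the rim) to model nuclear
speckles; the peri-nuclear zone is exactly where the 5-px shrink
deliberately classifies foci as cytoplasmic.

## What the synthetic data do and do not show

The generators reproduce the statistical structure the analyses assume —
stratum-dependent overlap rates, the printed fit equations plus
homoscedastic Gaussian noise (the simplest model consistent with
plate-reader and CCD noise at these scales), logistic turbidity, hard-disk
droplets on flat backgrounds. They do not reproduce read-level rG4-seq
counts, spatially correlated optical noise, droplet coalescence dynamics,
or fibril-vs-droplet morphology. Passing tests therefore demonstrate the
*correctness of the computations* and the recoverability of planted effects
at realistic noise, not the biological claims themselves on real data.

Problem sizes used by the test-suite and acceptance runs (chosen to give
stable statistics at desk scale): 120–300 regions per enrichment dataset,
100-shuffle permutation nulls, 50-seed fit-recovery sweeps, 128–192 px
images.

## Known limitations

- The scanner reports all motif registers; it does not model two-tetrad
  thermodynamic stability or bulged topologies.
- Enrichment counts intervals, not reads; with fragment-level data the
  ratio's variance properties differ.
- The melt model is strictly two-state; intermediates bias $\Delta H$.
- Segmentation is 2-D, single-threshold, and does not track droplets over
  time.
- The turbidity generator's decay law is phenomenological; it is meant to
  order inhibitor strengths, not to model nucleation kinetics.
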