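---
title: "Models and measurement rules in knockintools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement rules in knockintools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

knockintools implements the quantitative arms of a CRISPR knock-in tagging
workflow: measuring cytokinesis dynamics from live movies of endogenously
tagged cells, screening 96-well plates for clonal colonies, and genotyping
clones from barcoded long-read amplicon pools. Because raw microscopy
movies, plate scans and sequencing runs of this kind are rarely shareable at
development scale, every analysis stage is paired with a seeded simulator
that produces the same kind of data with a known ground truth. This
vignette explains the models behind both sides — what the simulators
generate, what the estimators measure, and where the package had to commit
to an operational rule that the underlying experimental practice leaves
informal.

## The dividing-cell movie model

`simulate_division_movie()` renders a mitotic cell as the union of two
circles of radius $r$ whose centre separation encodes furrow ingression.
The furrow (neck) width $w(t)$ follows a piecewise-linear law: constant at
$2r$ until `furrow_onset_min`, then decreasing at
`ingression_rate_um_per_min` until closure. This law was chosen over
sigmoidal alternatives because it makes the expected ingression duration
analytically exact, which is what a parameter-recovery test needs. Given a
target width the centre separation is $d = 2\sqrt{r^2 - (w/2)^2}$, so the
neck width is a genuine geometric observable of the rendered mask, not an
annotation.

The tagged-protein channel is a sum of three components: a constant
cytosol, a cortical shell of apparent thickness `cortex_thickness_um`, and
a Gaussian equatorial band. Band intensity along the cortex is

$$ I(s) \propto 1 + (\rho - 1)\, e^{-s^2 / 2\sigma^2}, $$

where $s$ is arc distance from the equator, $\rho$ = `cortical_ratio` and
$\sigma$ = `band_sigma_um`. The full width at half maximum of the band is
therefore $2\sqrt{2\ln 2}\,\sigma$ in closed form, which is the oracle
against which the breadth estimator is validated. Two rendering details
matter for that oracle:

* arc distance is measured at the shell centre-line radius, where the
  linescan path runs; measuring it on the outer circle would compress
  measured breadths by the ratio of the two radii;
* the shell is rendered 1.4 um thick — the apparent (optically blurred)
  cortex width — so that a five-pixel-wide sampling line centred in the
  shell never averages in cytosol or background.

The camera chain is bleach → Poisson → Gaussian read noise → integer
clipping at zero, matching the physical order of a fluorescence camera.
Expected photon counts are `exposure_gain` times the scene, so matched
low/high-exposure pairs (`simulate_exposure_pair()`) obey the shot-noise
scaling $\mathrm{SNR} \propto \sqrt{g}$ on Poisson-dominated regions, which
the tests check by Monte Carlo. Bleaching multiplies the whole scene by
$(1-\beta)^t$. The chromatin channel renders one metaphase plate before
anaphase and two segregating masses after it; it is provided for context
and is not used by the estimators (anaphase onset is user-supplied, as it
was scored manually in practice).

Default conditions: a 7 um radius cell at 0.2 um/pixel, 9 z-slices at 1 um
(most measurements project the two central slices), one frame per minute,
anaphase at 4 min, equatorial accumulation at 8 min, furrow onset at 9 min,
closure rate 0.65 um/min. Under the onset/completion rule described below
these conditions give a rule-based ingression duration of 18 min, matching
the ~19 min scale over which such cells complete ingression. The band SD
default of 1.74 um corresponds to a 4.1 um FWHM (a narrowly banded
scaffold protein); a broader 2.80 um SD (6.6 um FWHM) emulates a GTPase
activity zone.

## Linescan quantification

The measurement pipeline mirrors manual linescan practice: project the two
central z-slices, subtract background, correct bleaching by rescaling each
frame to the first frame's reference-region mean (simple ratio
normalization — the minimal method consistent with "bleach correction"),
trace a five-pixel-wide line along the cortex from pole to pole, and
express positions relative to the midplane.

`extract_cortex_path()` automates the manual trace: the cell mask boundary
(Otsu threshold, hole filling, largest component) is extracted as an
ordered contour, smoothed with a 2 px Gaussian to undo rasterization,
offset outward by half a pixel (pixel-centre contours sit half a pixel
inside the true boundary), optionally inset toward the shell centre-line,
and resampled at a fixed arc step. A manually traced coordinate list is
accepted through `manual_cortex_path()` for exact reproduction of hand
measurements. The midplane defaults to the perpendicular bisector of the
pole–pole chord and must cross the path exactly once; the crossing defines
position zero. Coordinates are 0-based with a pixel-centre convention.

`sample_linescan()` reads `line_width_px` bilinear samples perpendicular to
the local tangent at every arc step and averages them, reproducing a
wide-line profile off-grid.

**Breadth.** After peak normalization, the breadth is the number of samples
above 50% of the peak in the contiguous run containing the global maximum,
times the arc spacing. Above-cutoff samples in other runs are excluded and
only counted; ties for the maximum break toward the sample nearest the
midplane. One preprocessing step is essential and easy to overlook: the
off-peak profile floor (cytosol plus unenriched cortex) must be subtracted
(`subtract_profile_baseline()`, median over the outer thirds of the path)
before normalizing. Without it the half-maximum cutoff can sit below the
floor for moderate enrichment and the breadth becomes the whole profile;
with it, a Gaussian band of SD $\sigma$ measures
$2\sqrt{2\ln 2}\,\sigma$ within one sampling step. Breadth is reported at
furrow initiation (the last frame before the neck visibly deforms, or the
first band-positive frame if accumulation comes later); once the neck
invaginates, the path detours around the saddle and stretches apparent
arc distances by up to ~10%.

**SNR.** `measure_snr()` implements
$(\bar I_\mathrm{signal} - \bar I_\mathrm{background}) / \mathrm{SD}_\mathrm{signal}$
with the sample SD ($n-1$); whether the original computation used $n$ or
$n-1$ is not documented anywhere we could check, and for the ROI sizes in
routine use the difference is far below measurement noise. The statistic is
invariant to affine intensity transforms, which the tests assert exactly.

**Cortical/cytosolic ratio.** The cortical mean is the mean of the full
linescan; the cytosolic mean comes from a user ROI inside the cell. On
simulated metaphase cells with a uniformly enriched shell the true ratio is
recovered within 5% provided the sampling line is centred in the shell
(`inset_px` about half the shell thickness; the pipeline default is 3 px).

**Ingression timing.** The furrow width at each frame is the minimal mask
column count (perpendicular to the pole axis) within a small window around
the mask centroid. The onset/completion rule is an invented
operationalization, exposed as configuration: onset is the first frame at
or below 95% of the median pre-anaphase width sustained for 2 frames;
completion is the first frame at or below 1.0 um. Both thresholds are
reported alongside the duration so that alternative conventions (e.g.
timing from anaphase rather than furrow initiation) can be derived from the
same trace. On the default generator the rule recovers the true (analytic)
rule-based duration within one frame across seeds at default noise.

**Accumulation onset.** Enrichment is declared when the mean intensity
within ±2 um of the midplane exceeds 1.2 times the mean over the outer
thirds of the path, sustained for 2 profiles. The window, threshold and
persistence are invented defaults, chosen to be insensitive to shot noise
at the default photon budget while still detecting a 1.5-fold band in a
single frame.

## Colony screening

The screen reproduces an ImageJ-style macro contract: crop the well edge
(pixels beyond 0.9 of the well radius leave all statistics), subtract the
median of the retained pixels, blur with a 4 px Gaussian, threshold at
mean + 3 SD of the blurred masked image, label connected components, and
call each well positive (exactly one colony, no debris), excluded
(multiple colonies or debris) or negative. Components of at least 300 px
are colonies; 15–300 px are debris; smaller excursions are ignored as
noise. The colony floor is larger than the 200 px one might first pick
because the threshold is self-referential — it rises and falls with the
well's own content — so the suprathreshold area of a fixed object varies
several-fold between an empty and a two-colony well, and the
colony/debris separation must hold across that whole range. The 300 px
floor leaves a two-sided margin: the dimmest colony measures ≥ ~370 px at
the highest threshold it can face, and the brightest debris ≤ ~240 px at
the lowest.

The generator (`simulate_plate_montage()`) draws a colony count per well
from a user distribution (defaults sized so that about 61% of wells hold
a single clean colony, a realistic clonal recovery), places Gaussian-profile colonies (16–20 px
radius, amplitude 15 over background) and bright 4 px debris specks with a
minimum pairwise separation — two overlapping colonies would be one
connected component by construction, making the truth ill-defined — over a
gentle illumination gradient inside a dark well edge, and adds Gaussian
noise at SD 3 (blob SNR 5). Under these conditions noise-free calls equal
the truth exactly, noisy accuracy stays above 95%, and pure-noise wells
essentially never produce a colony-sized component at k = 3.

## Amplicon genotyping

Reads are filtered on read-level quality (the Phred transform of the mean
per-base error probability; reads strictly below Q10 are dropped),
demultiplexed by barcode presence, classified per read against the
wild-type and knock-in references, and summarized either as population
allele fractions or as diploid clone genotypes.

The knock-in reference is the wild-type amplicon with a 57-nt insertion at
the cut site: a 9-nt triple-glycine linker followed by a 48-nt tag coding
sequence (16 codons). The default tag sequence in the package is a
synthetic stand-in with the correct length and structure.

**Demultiplexing** scans the whole read in both orientations for
gene-specific barcodes (population mode: either of the two; clone mode:
additionally exactly one clone barcode). The default is exact matching;
the batch driver and the recovery analyses allow one mismatch with indels,
mirroring alignment-based demultiplexers, without which ~20% of reads at
5% error are discarded for a barcode-spanning error. Barcode sets are
validated to be substring-free in both orientations before any processing.

**Classification** aligns each read (better orientation, chosen by score)
to both references with semi-global affine-gap alignment (match +2,
mismatch −4, gap open 6, extend 2). A read favouring the knock-in
reference is HDR when the tag region is fully covered with no internal
indels and at most 2 substitutions, and HDR-mutant otherwise; population
reporting merges the two, as one cannot reliably distinguish a mutated tag
from sequencing error in a single long read. A read favouring the
wild-type reference is an indel allele when the summed insertion or
deletion gap width overlapping the cut site ±10 bp reaches 2 nt — summing
(rather than requiring one long run) keeps edits that an adjacent
sequencing error has split into two short gaps, while isolated single-base
sequencing indels stay below the floor. Reads shorter than twice the
barcode length, or whose best alignment scores below half the maximal
per-base score, are ambiguous rather than errors. Edits are extracted from
the alignment's vectorized indel and mismatch accessors in reference
coordinates, not by walking gapped strings, which is what makes
$10^4$-read runs take seconds rather than minutes.

At zero simulated error, classification reproduces the generator truth for
every read of all four classes; at 5% error, each mixture fraction is
recovered within three binomial standard errors at $n = 10^4$ reads. The
read-level limit is real, though: 1–2 bp edits are not reliably separable
from sequencing indels in single reads at that error rate, so the default
simulated edit spectrum uses sizes ≥ 3 nt and the limitation is inherited
by any downstream consumer. Likewise, at 5% error a true intact-tag read
carries on average ~2 substitutions and a ~20% chance of an indel inside
the 48-nt tag, so clone-mode separation of HDR from HDR-mutant alleles is
only trustworthy near zero error or after per-clone consensus — consistent
with that call having been made by eye on alignment pileups rather than
per read.

**Clone genotypes** take every class reaching a 20% read fraction as a
candidate allele: one candidate means homozygous, two heterozygous,
anything else (or fewer than 50 classified reads) ambiguous.

## Statistics

Group summaries report the box-plot five-number summary with
linear-interpolation quartiles (R type 7; the plotting-tool convention the
numbers might be compared against is not documented, so the convention is
stated rather than assumed). Welch's t test uses `stats::t.test` with
Satterthwaite degrees of freedom; Welch's ANOVA uses `stats::oneway.test`;
the Brown-Forsythe adjusted F statistic

$$ F^* = \frac{\sum_i n_i(\bar x_i - \bar x)^2}{\sum_i (1 - n_i/N)\, s_i^2} $$

with Satterthwaite denominator degrees of freedom is implemented directly,
as no installed package provides it. Dunnett's T3 all-pairs comparisons
refer pairwise Welch statistics to the studentized maximum modulus
distribution, evaluated through the independence form
$1-(2\,\Phi_t(|t|;\nu)-1)^m$ for $m$ comparisons; a seeded permutation
approximation (family-scaled, capped at 1) is available as a cross-check,
and the adjusted p is floored at the raw Welch p so the multiplicity
penalty can never be negative. Significance labels follow the conventional
ns / * / ** / *** / **** thresholds at 0.05, 0.01, 0.001 and 0.0001, with
boundary values significant.

Degenerate inputs have documented conventions: two zero-variance groups
with equal means give p = 1; with unequal means the statistic is undefined
and an error is raised.

## What the simulations do and do not show

The generators reproduce the features the estimators depend on — geometry
with closed-form observables, Poisson–Gaussian camera statistics, barcode
layout and an error process with substitutions and short indels — and the
test suite shows the estimators recover known truth under those
conditions. They deliberately omit much of what makes real data hard:
cell crowding and neighbour contacts, z-dependent optics beyond a Gaussian
envelope, blinking and chromatic effects, focus drift, colony morphology
variation, context-dependent Nanopore error (homopolymers), and structural
read artefacts such as chimeras. Passing recovery tests therefore
demonstrates correctness of the measurement rules, not robustness to every
failure mode of real acquisitions; the configurable thresholds exist
precisely because real data will need them re-examined.

Problem sizes in the tests and the acceptance analysis were chosen to keep
a full run in the few-minute range on one core: movies use 3 of the 9
z-slices (the pipeline projects the two central slices either way), plate
robustness uses 10 plates of 96 wells, mixture recovery uses $10^4$ reads
per seed with 8 seeds, and the type-I-error checks use $10^4$ replicates.
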