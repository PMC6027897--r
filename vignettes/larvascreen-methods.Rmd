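---
title: "Methods: an image-based larval-size modifier screen, end to end"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an image-based larval-size modifier screen, end to end}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvascreen)
```

## The assay and its statistical skeleton

`larvascreen` re-implements, as tested and reusable code, the analysis
pipeline of a whole-organism chemical-modifier screen for a *Drosophila*
model of NGLY1 deficiency (*Pngl* loss of function). Homozygous mutant
larvae are markedly smaller than their heterozygous siblings; the screen
cultures three larvae per well of a 96-well plate, floats them to a fixed
focal plane, photographs whole plates, and measures total larval area per
well. A compound that restores mutant size is a candidate suppressor.

The fixed plate design carries the statistics:

* column 1 — negative controls: homozygotes on 0.1% v/v DMSO vehicle;
* columns 2–11 — 80 test wells: homozygotes, one compound each at 10 µM in
  0.1% DMSO;
* A12–F12 — positive control group 1: heterozygotes on vehicle;
* G12–H12 — positive control group 2: homozygotes without DMSO.

DMSO matters twice. The mutants are hypersensitive to it (size effects
begin at 0.025% v/v; the homozygote maximum tolerated dose is 0.1% v/v),
so 0.1% vehicle acts as a sensitiser that widens the assay window: the
in-plate homozygote/heterozygote mean-area ratio is about 0.5, versus 0.75
on untreated food. The flip side is an artifact class — any well that
received less DMSO than intended grows larger larvae for reasons that have
nothing to do with the compound.

Per plate, quality control is the Z′ factor
$Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$
with positive control group 1 as the default positive group (selectable).
Per test well, the effect statistic is
$Z = (x - \mu_{NEG})/\sigma_{NEG}$ against the eight same-plate negative
wells. A library well is a *pre-hit* when $Z > 2$ (strictly) in at least
two of the three biological replicates; pre-hits then pass through
artifact triage (high image background; low/absent DMSO) and manual
inspection before any retest.

## The synthetic-data generator defines the study conditions

No images or tables from the original screen are deposited beyond what is
printed, so every downstream stage is exercised against a generator with
full ground truth. Its defaults are the study conditions and are not
tuning knobs.

**Larval areas.** Per-larva areas are lognormal — sizes are positive and
right-skewed, and only means plus "some variation" are reported — with
mean 250 px² for heterozygotes and coefficient of variation `cv = 0.15`.
The CV is the one free noise parameter and was fixed by a consistency
argument: the well readout is a 3-larva total (CV $\approx 0.15/\sqrt3$),
and with the standard three-sigma Z′ the observed plate quality (roughly
three quarters of plates with Z′ > 0) is only attainable when
$3\sqrt3\,\mathrm{cv} \lesssim 1$; cv = 0.15 reproduces that plate-quality
regime, while 0.25 would force almost every plate below Z′ = 0.

**Genotype and DMSO.** Homozygote mean area is 0.75× the heterozygote mean
untreated, declining multiplicatively with DMSO dose along a Hill curve
that is flat up to the 0.025% onset, reaches the anchor value
$0.5/0.75$ at the 0.1% maximum tolerated dose (its half-effect point,
Hill slope 2), and saturates at twice that decline. Homozygote lethality
ramps linearly from 0 at the MTD to 100% at 0.4% v/v. The functional form
is the package's choice; onset, MTD, the two ratios and the lethality
ceiling are the reported biology. Heterozygotes are treated as insensitive
over the screened range (their adverse-effect threshold is far higher).

**True hits.** A hit restores a fraction `hit_rescue` of the
homozygote-to-heterozygote deficit. Screen-level simulations plant about
1% hits with rescues spread over 0.3–0.9, mirroring a realistic mixture of
weak and strong modifiers.

**Artifacts.** Two processes, each with a per-well accident component and
a compound-level component expressed with 95% penetrance per replicate:

* *uneaten food* raises a well's image background (rendered as a broad,
  smooth dark blob) and inflates the measured area (area-level default
  ×1.6, with lognormal compound-to-compound severity);
* *low/absent DMSO* de-sensitises the larvae, boosting their true size by
  up to ×1.5 (full loss of vehicle).

The compound-level component (1.5% of compounds for uneaten food, 0.5%
for faulty DMSO dispensing) is essential: a compound that sickens larvae
leaves food uneaten in *every* replicate, and a faulty library source
well under-dispenses in every replicate. Purely well-level artifacts are
independent across replicates and could neither produce the observed
dominance of high-background wells among replicated pre-hits nor the
jump in replicate correlation inside the extreme-|Z| subset; both emerge
naturally once artifact propensity follows the compound. These rates were
calibrated once against the screen's published triage composition and
then frozen.

**Rendering.** A larva is a curved capsule: a quadratic Bézier centreline
of arc length L (rescaled after bending so arc length is exact), thickened
to width W = L/4, darker than the well background by a 45% contrast (the
gut dye makes larvae dark on a bright well). Rasterisation samples a 4×4
subpixel lattice per pixel; the binary mask keeps pixels with ≥ 1/2
coverage and the ground-truth area is the coverage sum, which matches the
analytic capsule area $LW + \pi W^2/4$ (curvature-independent by the tube
formula) to well under 1%. Plates are an 8×12 grid of bright well discs
(radius 50 px, pitch 110 px) with dark rims on a darker backdrop,
optional linear illumination gradient, and Gaussian sensor noise
(SD 0.008 of full scale). Larvae are placed uniformly in the well disc
with rejection of overlaps (50 attempts); at the default sizes three
larvae cover ~10% of a well and overlap acceptance is essentially never
reached — this matters because overlapping masks would truncate union
areas and bias genotype ratios upward. Resolution is a free parameter of
the imager; the defaults keep a plate near one megapixel.

**Determinism.** Every output is a pure function of configuration and one
master seed. Per-plate/replicate streams derive from the master seed by a
counter scheme (`substream_seed`, MINSTD multiplier modulo $2^{31}-1$), so
any single plate regenerates in isolation.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optics of sucrose flotation (meniscus, defoamer,
glare), out-of-focus larvae, plate-seal reflections, instance-level
larva–larva touching (real larvae do clump), dispenser miscounts (wells
always get three larvae), edge/evaporation plate effects, and any
compound mechanism beyond a mean-size shift.

## The detection algorithm

The measurement chain mirrors the screen's published description —
estimate what each well would look like empty, subtract, and call
high-difference areas larvae — with all unstated operators made explicit:

1. **Grid location.** The 96-well grid is rigid, so location reduces to a
   translation search: a rim-darkness map is convolved with a one-ring
   kernel at the nominal radius, and the integer offset maximising the
   summed response over all 96 nominal centres wins. If the best score
   does not stand out from the offset-score distribution (robust z ≥ 8)
   the image is declared rim-free and an error is raised.
2. **Empty-well background.** "Areas near edges are probably larvae":
   pixels whose gradient magnitude exceeds median + 5·MAD (computed over
   the well's analysis disc) are excluded, after dilation by 3 px so thin
   bodies are swallowed whole. The background is then a least-squares
   quadratic surface fit to the remaining pixels, refined once after
   dropping residuals beyond 4·MAD. A surface fit rather than pure infill
   is deliberate: infill copies the observed image wherever nothing is
   excluded, which would make the difference image identically zero
   outside detections — diffuse artifacts like uneaten food (too smooth
   to trip the gradient rule) would vanish from both detection and
   flagging, contradicting how the artifact actually corrupted the
   screen. The quadratic reproduces constant and planar illumination
   exactly, is idempotent, and leaves smooth blobs in the difference
   image where they belong.
3. **Segmentation.** Pixels with |observed − estimate| above a threshold
   are labelled into connected components; components under `min_area`
   (default 30 px, about a quarter of the smallest simulated larva) are
   discarded; total area per well is the readout. The default threshold is
   5× the MAD of the difference image, pooled across all 96 wells of a
   plate so that a single artifact-dominated well cannot inflate its own
   threshold. Detections are equivariant under joint rescaling of image
   and threshold. Components touching the well wall are kept (larvae rest
   against walls); only the outer 5% rim ring is masked out.
4. **Artifact metric.** Each well reports the 90th percentile of
   |observed − estimate| over non-excluded pixels. An upper-quantile
   scale, not a MAD: the food blob covers roughly 40% of a well, enough
   to corrupt detection yet below the 50% breakdown a MAD would need.
   Wells are flagged high-background when the metric strictly exceeds a
   cutoff calibrated as the 99th percentile of clean simulated wells
   (ties are not flagged).

Coordinates are image pixels, well A1 top-left, rows A–H down, columns
1–12 across; well measurements are written as CSV with one row per well.

## Screening statistics, triage and validation analyses

Z-scores use the mean/SD of the eight same-plate negative wells; a
median/MAD variant exists behind a flag but is not the default, since the
original scale is unspecified. With only eight denominators the per-plate
SD of null Z-scores is right-skew inflated (the $1/s$ tail), so the null
calibration summary is the *median* per-plate SD, which sits near 1.

Replicate merging keys rows by library well, never by substance: a
substance present in two wells keeps two rows (the screen's library had
thioguanine twice). Missing replicates stay missing; pre-hit calling then
evaluates whichever replicate pairs exist. The pre-hit rule is strict
(Z = 2 exactly does not qualify), and a compound exceeding the threshold
in all three replicates appears in all three pair rows — which is exactly
why per-pair counts double-count triple-qualifiers relative to the unique
compound list, and why the published per-pair totals exceed the unique
pre-hit count by twice the number of triples.

Artifact triage is subtractive per pair row: a pre-hit is removed as
high-background if either qualifying well carries that flag, otherwise as
low-DMSO; high background takes precedence when both flags are present so
that clean = pre-hits − high-bg − low-DMSO holds row by row. Manual
inspection is out of computational scope; the written report carries a
free-text pass column defaulting to pass. Replicate-correlation analysis
(squared Pearson) runs in full mode and in extreme mode; whether the
original extreme subset required one or both members beyond |Z| = 2 is
not stated, so both rules are implemented with "either" as the default.

Validation analyses are deliberately plain: survivor-normalised
cumulative timecourses (curves end at 1 by construction; median event day
quantifies delay), eclosion fold changes on per-vial fractions with the
classical equal-variance Student's t-test (Welch behind a flag; zero
within-arm variance short-circuits to an exact-equality fast path), size
ratios with the same test, and a four-parameter logistic
$y = b + (t-b)/(1+(x/\mathrm{IC}_{50})^{s})$ fitted by
Levenberg–Marquardt. The 4PL initialises from data quantiles (plateaus
from the extreme-dose means, IC50 from the dose nearest half-response,
slope 1), flags IC50s outside the positive tested range as extrapolated,
and flags the whole fit as unreliable when per-dose means are not
monotone in dose (|Spearman ρ| < 0.5) — a flat response is the canonical
case. Paired fits report the IC50 ratio between genotypes, the statistic
behind the "~10× more sensitive to bortezomib" readout.

## Problem sizes and numerical choices

The packaged analyses and tests run at the screen's own scale where that
is cheap (area-level simulations: 32 plates × 3 replicates, 2,560 test
wells) and at single-plate scale where rendering is involved (a rendered
plate is ~1.2 Mpx; detection-oracle checks use 200+ rendered wells;
ratio-recovery experiments use one 96-well plate with 48 wells per
genotype, three larvae each). Monte-Carlo oracles for null tail rates use
$10^5$ draws. All stochastic tests fix their seeds.

Degenerate inputs are errors, not warnings: empty control groups, equal
control means (Z′ undefined), zero negative-control spread, non-positive
detection thresholds, exclusion masks covering a whole well, zero
survivors in a normalisation, and fold changes against a zero-mean
control arm all stop with a message.

## Known limitations

* The background model is quadratic; illumination structure above second
  order inside a single well would leak into the difference image.
* Touching larvae merge into one component; only total area per well is
  reliable, not larva counts (the assay readout is total area, so this is
  by design, and per-component tables are still reported).
* The artifact-flag ground truth in area-level simulations is the
  generator's own flag, standing in for flags a reader would assign from
  images by eye.
* Whether per-well area should be a total or a per-larva mean is not
  specified by the assay's description; the package adopts total area per
  well and exposes per-component areas for anyone preferring the mean.
* The low-DMSO artifact boost is capped at full vehicle loss (×1.5);
  partial hydration gradients across a plate are not modelled.
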