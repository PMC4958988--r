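---
title: "Birth-death decomposition and single-cell phenotyping from HCS images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth-death decomposition and single-cell phenotyping from HCS images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsquant)
```

# The model

`hcsquant` treats a well of cells as a linear birth-death process:
each live cell divides with per-capita rate $b$ (1/hour) and dies with
per-capita rate $d$ (1/hour), both constant over the assay window. Two
consequences drive everything downstream:

* the expected live population grows exponentially,
  $\mathbb{E}[N(t)] = N_0 e^{rt}$ with net growth rate $r = b - d$;
* dead cells accumulate as the integral of the death hazard over the
  live population,
  $\mathbb{E}[D(T)] = d \int_0^T N_0 e^{rt}\,dt
                    = d\,N_0\,\frac{e^{rT}-1}{r}.$

Estimation is sequential and closed-form, in the order the data
support it: $r$ and $N_0$ from ordinary least squares of $\ln N$ on
$t$ (all replicate wells pooled into one regression, which weights
unbalanced replication correctly); then
$d = D(T)\,r / (N_0 (e^{rT}-1))$, using the *fitted* $N_0$ rather than
the measured seed count to damp seeding noise; finally $b = r + d$ as
an exact identity. When $|r| < 10^{-9}$ the death formula switches to
its analytic limit $d = D(T)/(N_0 T)$; when $D(T) = 0$, $d = 0$; $d$
is clipped at zero. A negative implied $b$ is flagged rather than
silently truncated — under the model it is impossible, so it signals a
model violation in the inputs.

The decomposition is the point: a perturbation that lowers $b$ at
constant $d$ is cytostatic, one that raises $d$ is cytotoxic, and a
"percent viability" endpoint cannot tell them apart.

## When the fit is trusted

Exponential growth only holds in a seeding window — too few or too
many cells and growth becomes sub-exponential. `checkExponentiality`
passes a series when the log-linear fit's $R^2$ reaches a floor
(default 0.95) and, when at least eight distinct time points exist,
the per-time mean residuals show no systematic sign pattern
(one-sided Wald–Wolfowitz runs test at $\alpha = 0.05$, normal
approximation, written in-package). The runs test uses *per-time mean*
residuals deliberately: lack of fit is a function of time, and
averaging replicates first keeps replicate scatter (and exact ties at
$t=0$, where all wells share the seeded count) from masquerading as a
pattern. With the standard 4-point design ($t \in \{0,24,48,72\}$ h)
the runs test has no power and only the $R^2$ floor decides; 2-point
series cannot be falsified at all and pass with an
`insufficient_points` flag.

# Image quantitation

## Segmentation

Nuclear foreground is an Otsu threshold on the nuclear channel after a
1 px Gaussian blur (a fixed-threshold override exists for fluorescence
setups where Otsu is inappropriate). De-clumping runs a watershed on
the distance transform of a 2x nearest-neighbour upsampled mask:
touching nuclei meet in a saddle whose depth can be a fraction of a
pixel, and halving the discretization error of the distance map lets a
0.25 px tolerance (stated in original pixels) split pairs that a
single-resolution watershed merges. Nuclei failing the size window
(default 50–2000 µm²) or touching the field border are kept in the
record table with `qc_pass = FALSE` and excluded from all counts;
partial border objects would bias both counts and morphology.

Whole cells grow from qc-passing nuclear seeds by `EBImage::propagate`
over the cytoplasm-tracker channel, confined to above-background
cytoplasm signal (the nucleus always belongs to its cell). Cells on
the border, without surrounding cytoplasm signal, or with implausible
nucleus-to-cell geometry are flagged, not dropped.

## Viability

Two rules, both strict inequalities:

* **absolute**: dead iff nuclear dead-stain mean $>$ threshold —
  suited to propidium iodide;
* **ratio** (default): dead iff nuclear mean / background-ring mean
  $> 1.2$ — suited to far-red stains, where the local annulus
  normalizes illumination. The ring is the annulus from
  (offset − halfwidth) to (offset + halfwidth) px outside the nuclear
  boundary, excluding pixels of any nucleus; defaults 30 ± 15 px, read
  as a per-cell-type offset in 15–45 px.

A cell sitting exactly at the boundary is live. Records whose ring
mean is missing or non-positive are *unclassifiable* and excluded from
both counts, so `live + dead + unclassifiable` always equals the
number of qc-passing records. The nuclear statistic is the mean over
the nucleus mask (mirroring the ring statistic); a `sum` switch
exists because some platforms gate on total rather than mean nuclear
intensity.

## Morphology

Area is pixel count × pixel size²; roundness is $4\pi A / P^2$ with
the perimeter measured along the 8-connected boundary chain, diagonal
steps weighted $\sqrt 2$ (Moore tracing, compiled): plain edge
counting overestimates $P$ for diagonal boundaries and biases
compactness low. Width-to-length is the minor/major axis ratio of the
second-moment ellipse. Compactness formulas differ between analysis
platforms, so absolute roundness values are comparable only within
this package; orderings (disk rounder than rectangle) are what the
tests pin down. Objects under 8 px are excluded as segmentation
debris.

# Subpopulation classification

Fluorescence gating assigns the channel whose nuclear mean exceeds its
threshold, with `ambiguous` (both) and `unlabeled` (neither) kept
explicit rather than forced into a class.

The trained classifier is a least-squares multiclass linear
discriminant: candidate features are ranked by absolute standardized
mean difference between classes (maximum over class pairs when there
are more than two), the top $k$ (default 5) are standardized and
regressed on class indicators, and cells take the argmax score, ties
breaking in class order (reported). Least squares on indicators was
chosen over logistic regression or `lda` because it is closed-form,
deterministic, and exposes exactly the "linear coefficients per
class" a user can audit; on the well-separated populations this
classifier targets, the three agree almost everywhere (the test suite
cross-checks against an independent `MASS::lda` fit). Features are
standardized so classification is invariant to affine rescaling of
any input — intensity units vary across instruments. The training
subsample (default 100 cells per class) is drawn with a recorded
seed, and the model serializes to JSON with its standardization
moments, so application is bit-reproducible. A trained model is
accepted only if it classifies at least 90% of held-out pure-control
cells correctly; `evaluateOnControls` computes that number.

# The synthetic-data generator

The generator exists so that every stage has ground truth. It
emulates: anti-aliased elliptical nuclei (axis ratio 0.8–1) with
per-type size heterogeneity; circular cytoplasm halos; a dead-stain
channel where dead nuclei carry an elevated plateau (defaults: live
110, dead 200 over background 100, i.e. ratios 1.1 vs 2.0 around the
1.2 cut); per-type fluorescence label channels; touching pairs at
centre distance 1.2–1.6 nuclear radii (the de-clump stressor);
additive Gaussian noise (sd 5) as a shot-noise stand-in; and flat
background. The default field — 75 cells of two types in 512² px at
~30% cell-body coverage, 20% dead — represents a non-confluent
co-culture well within the exponential seeding window.

It deliberately does **not** emulate optics (PSF, vignetting, depth),
photobleaching, debris, staining heterogeneity within a class, or 3D
spheroids. Passing tests therefore demonstrate the pipeline's
correctness against its own model of the data, not robustness to every
real-microscopy artifact; on real images the segmentation
parameters (blur, size window, watershed tolerance, ring offset) are
the knobs to re-tune.

Touching pairs at the extreme 1.2-radius end occasionally survive
de-clumping as a single object (a few percent of pairs); these count
against the segmentation error budget, and when a mixed live/dead pair
merges, its diluted stain ratio can fall on either side of the cut.
The count-accuracy and viability tests use majority-pixel-overlap
matching against the ground-truth label map, so ambiguous merges are
charged to segmentation rather than to the stain rule.

The stochastic simulator is exact (event-driven Gillespie, compiled;
populations here stay ≤ ~10^5 so tau-leaping is unnecessary), draws
from R's RNG stream so one `set.seed` governs a whole run, and records
cumulative births alongside deaths so the conservation identity
births − deaths = N(t) − N₀ is auditable per trajectory. Dead counts
are reported cumulatively, matching endpoint-stained plates where all
accumulated dead cells remain; an opt-in running-maximum repair exists
for count tables whose dead column is noisy around monotonicity.

# Problem sizes and numerical choices

Test and acceptance workloads were sized to run comfortably on a
laptop-class single core: 20 rendered fields for the
segmentation/viability oracle; 50 Gillespie replicates per cell of the
3×3 $(b, d)$ grid ($b \in \{0.02, 0.04, 0.06\}$,
$d \in \{0, 0.01, 0.03\}$/h, $N_0 = 2000$, samples at 0/24/48/72 h)
for rate recovery within 0.005/h; 10 seeds × 200 cells/class for the
classifier gate; the dead-fraction convergence check pools 2500
generated cells. Other fixed numerics: the $r \to 0$ switch at
$|r| < 10^{-9}$; strict inequalities at both viability boundaries;
zero live counts excluded (with a flag) from log fits rather than
pseudo-counted; zero-variance features dropped with a warning before
selection; classifier ties broken deterministically in class order.

# Limitations

Rates are constant per condition — no time-varying hazards, cell-cycle
structure, or confluence correction beyond the exponentiality flag.
The de-clumping filter exposes only a size window and a declump
toggle. The morphology catalogue is a documented subset (≥10
features); arbitrary extra numeric columns pass through to the
classifier untouched, so platform-specific features can be supplied
externally. Composition analysis assumes each cell is classified
independently; no spatial statistics are computed.
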