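---
title: "Quantifying single-cell NF-kB nuclear translocation: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell NF-kB nuclear translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

When cells are stimulated with lipopolysaccharide (LPS), the
transcription factor NF-kB (its p65/RelA subunit) translocates from the
cytoplasm into the nucleus. In live-cell imaging this is followed with
two fluorescent channels: a constitutive nuclear marker (an H2B fusion)
used only to find and follow nuclei, and a p65 reporter fusion whose
redistribution carries the signal. The per-cell readout is the
*relative nuclear localization*

\[
I(t) \;=\; \frac{\bar{R}_{\mathrm{nuc}}(t)}
{\langle \bar{R}_{\mathrm{cyto}} \rangle_{\mathrm{pre}}},
\]

the mean reporter intensity over the cell's nuclear pixels divided by
its mean cytoplasmic intensity averaged over the pre-stimulus frames
(background subtracted from both). From each trace four statistics are
taken: an **active** flag, the **peak amplitude** (maximum of $I$ after
stimulation), the **time to peak** (minutes from stimulation to that
maximum), and the **peak width** (duration above the level halfway
between the post-stimulus minimum and maximum). Conditions are compared
at the population level through the fraction of active cells as a
function of concentration, per-condition averages of the active-cell
time courses, and cosine distances between those averages.

The raw microscopy behind these quantities is not publicly deposited,
so this package pairs the analysis pipeline with a synthetic-movie
generator whose ground truth is exported alongside every rendered
frame. All tests are parameter-recovery tests: the pipeline must
re-measure, from noisy rendered movies, the statistics the generator
put in.

## The single-cell response model

No generative trace model is defined by the imaging literature the
package follows; the pulse family here was chosen as the minimal form
whose parameters map one-to-one onto the four measured statistics. A
trace is

\[
I(t) = b + A\,(t/\tau)^{s} e^{s(1 - t/\tau)}
     + P\,(1 - e^{-t/\tau_p}) + S(t), \qquad t \ge 0,
\]

with $I(t) = b$ before stimulation. The gamma-shaped primary term
attains its maximum $b + A$ exactly at $t = \tau$; the shape $s$
controls the width at half-max independently of $\tau$ and is solved
numerically from a requested width (`solve_shape_for_width()`, a
deterministic bisection on $\log s$; the width of the pure pulse is
itself found by root bracketing of the half level on each side of the
peak). The saturating plateau $P(1 - e^{-t/\tau_p})$ is carried by
*persistent* responders; *transient* responders have $P = 0$. The
secondary term $S(t) = A_2 u^2 e^{2(1-u)}$, $u = (t - t_2)/r$ for
$t > t_2$, is a smooth delayed bump peaking at $A_2$ at $t_2 + r$,
representing the late re-activations seen in a subset of cells. A
discontinuous step-and-decay form was considered for $S$ and rejected:
trace continuity is a model invariant (and jump discontinuities would
create spurious width crossings).

Cell-to-cell heterogeneity is lognormal and mean-preserving: each
cell's amplitude, time-to-peak and baseline are the central values
multiplied by $\exp(\sigma Z - \sigma^2/2)$ with
$\sigma^2 = \log(1 + \mathrm{cv}^2)$, so population means equal the
central parameters by construction. Default CVs are 0.25 for amplitude
and time-to-peak and 0.05 for baseline: single-cell NF-kB studies
consistently report ~25% amplitude variability, while the normalized
baseline is tightly centred at 1 by the definition of $I(t)$.

Whether a cell responds at all is Bernoulli with Hill probability
$p(c) = p_{\max} c^h / (c^h + K^h)$. Responder classes (transient /
persistent / secondary) are drawn from a per-preparation mixture.
Soluble TNF receptor II (sTNFRII), which sequesters secreted TNF and
thereby blocks the paracrine reinforcement that sustains persistent
nuclear localization, is modelled as two multiplicative factors:
persistent-class probability x0.1 (renormalized) and plateau amplitude
x0.2.

## Preparation presets

The three shipped presets (`Sigma`, `EB`, `UP`) encode the measured
cross-preparation population statistics as ratios of central
parameters, anchored at the 0.5 ug/mL reference concentration:

| quantity (central)        | Sigma  | EB            | UP            |
|---------------------------|--------|---------------|---------------|
| amplitude above baseline  | 1.00   | 0.49 (51% lower) | 1.17 (17% higher) |
| time to peak (min)        | 47.59  | 142.76 (3.0x) | 69.0 (1.45x)  |
| peak width (min)          | 89.98  | 61.0 (Sigma = 1.475x EB) | 61.0 |

Notes on interpretation, both genuinely open choices:

* "lower-intensity activation" is read as a ratio of amplitudes *above
  baseline*, and the longer "average localization" of Sigma-stimulated
  cells is read as the peak-width statistic, fixed at the midpoint
  (47.5%) of the reported 40-55% range. A duration metric other than
  width-at-half-max could have been meant; width is the one the trace
  featurization defines, so it is the one anchored.
* The UP time-to-peak series 52 / 69 / 129 minutes is pinned to 5, 0.5
  and 0.05 ug/mL respectively, log-linearly interpolated in
  concentration between anchors and clamped outside. Only the
  endpoints of the concentration range are certain; the middle
  assignment is a preset choice, recorded here, not a measured fact.

Dose-response parameters were chosen once to reproduce each
preparation's qualitative potency window: Sigma
($p_{\max} = 0.95$, $K = 10^{-4}$ ug/mL, $h = 1$) is near-maximal by
$5\cdot10^{-3}$ ug/mL; UP ($K = 0.15$, $h = 1.2$) only saturates at
0.5-5 ug/mL and is essentially inert at the lowest simulated doses; EB
($K = 10^{-8}$, $h = 0.7$) activates almost every cell even at
$5\cdot10^{-7}$ ug/mL. Class mixtures follow the qualitative
descriptions: Sigma high-dose responses split 50/50 transient/
persistent; EB is dominated by the secondary-activation phenotype
(60%); UP is transient-dominated (80/20). All preset fields live in a
versioned YAML file and are overridable.

Two known consequences of these choices, visible in end-to-end
estimates: the persistent plateau adds a few percent to measured Sigma
amplitudes (the plateau is part of the measured maximum), nudging the
EB-vs-Sigma amplitude reduction slightly above its central 51%; and
discrete 5-minute sampling quantizes per-cell time-to-peak without
biasing condition means appreciably.

## The synthetic movies

`render_movie()` draws each cell as a rotated ellipse nucleus
(semi-axes 5-7 px) with an annular cytoplasm of fixed 8-px extent —
true cell boundaries are not modelled, matching the ring-based
measurement. The nuclear-marker channel is constant per-cell
brightness; the reporter channel moves a **conserved** reporter amount
between the nuclear and cytoplasmic compartments so that
$\bar{R}_{\mathrm{nuc}}(t)/\bar{R}_{\mathrm{cyto}}(\mathrm{pre})$
equals the cell's ground-truth trace at every frame, with compartment
concentrations computed against the per-frame rasterized pixel areas
(conservation is then exact by construction, and the noiseless
measurement model is exact to rasterization). Poisson shot noise at
the photon scale (default: 150 photons cytoplasmic brightness over a
20-photon background) and Gaussian read noise (sd 3) are applied last,
and intensities are quantized to 1/16 photon so that 16-bit TIFF round
trips are bitwise lossless.

Acquisition defaults mirror the imaging setup the pipeline targets:
120 frames at 5-minute cadence with three pre-stimulus frames. A
single fixed cadence keeps all time grids directly comparable (the
real acquisitions varied between 5 and 6 minutes; resampling to a
common 5-minute grid is built into the population averaging for inputs
that need it). Field size, magnification and per-field cell counts are
not reported for the original data; the defaults (512x512 px, 60 cells
per field) are stated assumptions giving the per-field density implied
by ~100 analyzed cells over at least three fields. Placement uses dart
throwing with a 22-px minimum center separation — adherent nuclei do
not interpenetrate — and motion is a reflected random walk (default
0.75 px/frame). Nuclei are rasterized hard-edged at pixel centers by
default: partial-coverage edge pixels would bias the nuclear mean by
more than the renderer's own fidelity contract (traces within 2% of
truth at every frame), so edge anti-aliasing is available as an option
(`edge_width`) but off by default.

Not emulated: photobleaching, illumination shading, cell division and
death, defocus, the microscope point-spread function, and nucleoli
(which the original manual curation used as a visual cue). Passing
recovery tests on these movies therefore demonstrates the pipeline's
correctness on clean, well-posed single-field data — not robustness to
the full range of real-microscopy artifacts.

## Image analysis

*Segmentation* (per frame, nuclear channel): Gaussian smoothing
(sigma 1) -> global Otsu threshold (fixed-value override available for
unattended runs on atypical backgrounds) -> hole filling -> connected
components, with a distance-transform watershed (tolerance 1) invoked
when a component is large enough to be touching nuclei -> area filter
(40-200 px, bracketing single nuclei of the default 5-7 px semi-axes).
Regions are 8-connected; labels are compacted in raster order, making
label images bit-reproducible. One practical limit found while
validating the watershed contract: for typical 6-px nuclei the
discrete distance map of two ellipses closer than ~1.2 semi-axes has
no saddle left after pixel quantization, so such pairs merge; the
split contract is exercised at 10-px radius where it is well-posed,
and default-size merges are handled by quality control instead (below).

*Curation surrogate (quality control)*: the original workflow relied
on visual curation to keep only cleanly measurable cells. Because
abutting cells contribute additively to each other's pixels, three
automated checks stand in for it, each turning a compromised frame
into a measurement gap rather than a biased number: (i) the area
ceiling rejects two-nucleus merges the watershed cannot split; (ii)
*proximity exclusion* flags any nucleus with foreign thresholded
foreground within 16 px of its centroid (one cytoplasm extent plus a
nuclear semi-axis) — including neighbours the area filter removed;
(iii) *marker-brightness exclusion* flags labels whose mean
nuclear-marker intensity exceeds 1.08x the frame median: the marker is
constitutive, so a heavily overlapped pair segmented as one blob is
at least ~11% brighter, while Poisson variation of a clean nucleus
mean is far below 8%. Finally, an *identity guard* discards a track's
measurements after more than two consecutive invalid frames, because
nearest-centroid linking cannot guarantee the same cell re-emerges
from a long close-encounter episode (every identity swap observed in
validation was embedded in one). Without these checks, close
encounters at realistic densities produce false-active flat cells and
spurious late peak times.

*Cytoplasmic rings*: the band of background pixels at distance
$(r_{\mathrm{in}}, r_{\mathrm{out}}] = (2, 8]$ px from the nearest
nuclear pixel, excluding all nuclei, with contested pixels claimed by
the nucleus with the nearest centroid. A representative cytoplasmic
mean is all the normalization needs; full-cell segmentation is
deliberately avoided.

*Tracking*: greedy nearest-centroid linking, assignments accepted in
ascending distance order, rejected beyond 10 px, gaps bridged up to 2
frames, ties broken by smaller label id then track id — fully
deterministic.

*Trace extraction and features*: as defined above. Choices worth
stating: the half level uses the post-stimulus *minimum* (not the
pre-stimulus baseline) — a literal reading of the statistic's
definition; the alternative is one argument away. Ties at the maximum
take the earliest frame. Width crossings are located by linear
interpolation; a trace that never re-descends below the half level is
right-censored and flagged (and excluded from width means by default)
rather than dropped. Gap frames are excluded from extrema and break
activity runs; they are never interpolated. The automated activity
criterion — $I$ at least 0.2 above the pre-stimulus baseline for 3
consecutive valid post-stimulus frames — replaces the original visual
curation ("nuclei uniformly brighter than before stimulation"); theta
and the run length are configuration, not constants.

*Population readouts*: average time courses use active cells only;
cosine distances are computed on the raw averages (no baseline
subtraction or z-scoring — no preprocessing is part of the statistic's
definition; alternatives can be applied upstream). Similarity matrices
are ordered by preparation block, then descending concentration.
Conditions with no active cells produce a flagged empty marker that
propagates to the TNF-blocking comparison as a non-numeric result
rather than an error, since an average of zero cells supports no
distance.

## Numerical and reproducibility choices

* One global seed expands into per-(preset, concentration, arm, movie)
  seeds through a small string hash below $2^{31}$, so adding
  conditions never shifts existing streams; every stage is
  deterministic given its inputs.
* The pipeline persists TIFF/CSV/JSON intermediates per stage and
  skips stages whose outputs exist: deleting one downstream artifact
  recomputes exactly that artifact, byte-identically.
* The width solver brackets $s \in [10^{-3}, 10^4]$ and reports the
  achievable width range when asked for an impossible width; the left
  half-level root is solved in log space to survive extreme shapes.
* Degenerate inputs are contracts, not crashes: blank frames segment
  to zero labels; cells without usable pre-stimulus cytoplasm are
  excluded with a logged reason; all-gap traces raise a feature error.

## Problem sizes used in the shipped checks

The test suite and the acceptance script scale the study design down
to run comfortably on one CPU: recovery fixtures use 256-384 px fields
at the default cell density (the 512-px, 60-cell default is exercised
once, for segmentation/tracking recovery), six replicate 40-cell
movies per condition for the end-to-end statistics (~180-230 active
cells per 0.5 ug/mL arm; the UP preset at 0.05 ug/mL activates only
~20% of cells, so six movies yield ~45 active cells there), and
10,000-draw binomial checks for the dose-response calibration. Sizes
were set from standard-error arithmetic against each tolerance: with
a 0.25 amplitude CV, a cross-preparation amplitude ratio needs ~200
active cells per arm before its standard error (~3 percentage points)
sits comfortably inside a +-5-point band, and time-to-peak means need
only ~40 cells for a +-10-minute band.

## Known limitations

* The trace model is phenomenological; it reproduces measured
  statistics, not IKK/IkB kinetics, and no mechanistic claim attaches
  to its parameters. Receptor-level (TLR2/TLR4) discrimination between
  preparations is out of scope.
* Overlapping cells contaminate each other's measurements additively;
  at the default density this affects a small minority of cells
  (visible as rare large time-to-peak outliers in persistent cells),
  and there is no curation step to remove them — condition means are
  used as-is.
* Fitting the response model to real movies is not implemented; the
  package's direction is generator -> pipeline, not inference.
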