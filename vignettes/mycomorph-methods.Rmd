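---
title: "Quantifying pellet morphology and metabolite enhancement in microparticle-amended cultivations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pellet morphology and metabolite enhancement in microparticle-amended cultivations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomorph)
```

## The problem

Filamentous microorganisms such as *Streptomyces rimosus* grow in
submerged culture as a mixture of morphological forms — dense pellets,
loose clumps, free hyphae and (at inoculation) spores — and the balance
between these forms strongly affects secondary-metabolite productivity.
Microparticle-enhanced cultivation (MPEC) adds inert microparticles
(here talc, nominal mean diameter 10 µm) to steer that balance.
`mycomorph` implements the quantitative read-outs such experiments
need: per-object shape descriptors from phase-contrast micrographs,
area-based classification into morphological groups, group statistics,
enhancement factors for metabolites measured across replicate flasks,
and substrate uptake rates from spline-differentiated concentration
curves. Because raw micrographs from such studies are rarely deposited,
the package ships a seeded synthetic-data generator that reproduces the
*statistical structure* of the experiment with known ground truth, so
every stage is testable end to end.

## Shape descriptors and the morphology number

For a segmented object represented as a set of pixels with calibration
$c$ (µm/pixel):

* **Projected area** $A = n_\mathrm{px}\, c^2$ (µm²).
* **Elongation** $E = (\sigma_L/\sigma_T)^2$: the squared ratio of the
  standard deviations of the pixel coordinates projected on and across
  the orthogonal-regression (major principal) axis. $E = 1$ for a
  disk; a filled $a \times b$ rectangle gives $E \approx (a/b)^2$.
* **Solidity** $S = A / A_\mathrm{hull}$ (identical to the roughness
  descriptor $R$): object area over convex-hull area, in $(0, 1]$.
* **Maximum diameter** $D$: the Feret maximum, the largest distance
  between any two corner points of the object's pixel squares, times
  $c$.
* **Morphology number**
  $$\mathrm{Mo} = \frac{2\sqrt{A}\,S}{\sqrt{\pi}\,D\,E},$$
  a dimensionless composite equal to 1 for a perfect circle and
  decreasing for elongated or irregular objects. The upper bound
  follows from the isodiametric inequality ($A_\mathrm{hull} \le \pi
  D^2/4$) together with $S \le 1$ and $E \ge 1$, so a value above
  $1 + \mathrm{tol}$ can only come from a computational defect; the
  package raises an error there instead of clamping.

Two conventions deserve a note. First, the "deviation along the
regression line" in the elongation definition is interpreted as a
standard deviation over *all* object pixels (not a maximum extent),
because the definition explicitly sums over the whole pixel set.
Second, the convex hull is taken over the corner points of the pixel
*squares*, not the pixel centres: the numerator of $S$ counts whole
pixels, so the denominator must measure area in the same convention;
centre-point hulls systematically understate hull area for thin
objects and can push $S$ above 1. With the corner convention a single
pixel has $D = c\sqrt{2}$.

All descriptors are exactly equivariant under calibration changes
($A \propto c^2$, $D \propto c$; $E$, $S$, Mo invariant) and are
verified in the tests against brute-force recomputation from the raw
pixel sets (closed-form second moments, all-corner hull with shoelace
area, all-pairs distances) to $10^{-9}$ relative.

## Segmentation

The image pipeline is: exact median filter (default 3×3, symmetric
reflect padding) → intensity threshold → Sobel edge-band refinement →
hole filling → 8-connected labeling → minimum-area filter → border
policy. Choices behind that order:

* **Threshold.** The default is a 256-bin Otsu (bimodal) threshold on
  the median-filtered intensity, with a polarity flag
  (`dark_on_bright` by default, matching phase-contrast-like images of
  dark mycelium on a bright field). A fixed numeric threshold is
  available for exactly reproducible segmentations in analyses where
  the automatic threshold is not wanted. A uniform image has no
  bimodal structure and yields an empty segmentation rather than an
  error.
* **Sobel refinement.** The Sobel magnitude (3×3 kernels, weights
  1–2–1, reflect padding) identifies an edge band; pixels in that band
  are added to an object only if they are 8-contiguous with an already
  thresholded region *and* their intensity lies on the object side of
  the midpoint between the threshold and the background level. The
  second condition keeps the refinement from annexing the bright
  outer ring of every boundary (which would bias areas upward by
  roughly one perimeter's worth of pixels); on noise-free synthetic
  scenes the refinement is a no-op and areas are recovered within the
  rasterization error.
* **Connectivity.** 8-connectivity throughout, because hyphal strands
  are thin and frequently connect diagonally. Hole filling labels the
  background 4-connectedly and fills components that do not touch the
  image border.
* **Area floor and talc.** The default minimum object area of 20 µm²
  suppresses noise specks while retaining small hyphal fragments. Talc
  distractors of 10 µm diameter project ≈ 78.5 µm²; raising the floor
  to 100 µm² removes them while keeping all mycelial objects of
  interest — how the original measurements excluded talc is not
  recorded, so this is a declared decision of this package.
* **Border objects** are excluded by default since their $A$, $D$ and
  $E$ are censored by the frame; a flag-only mode keeps them marked.

The median filter, Sobel magnitude, labeling and hole filling are
implemented in the package (the filter and labeling in C++): the
segmentation contract requires exact window medians with reflect
padding and 8-connected components, which the otherwise natural
off-the-shelf image operators in the installed stack do not provide
under exactly these conventions (4-connected labeling, quantized
medians). An independent labeling implementation is still used as a
cross-check in the tests.

## Classification and group statistics

Observed morphological groups in talc-amended *S. rimosus* runs are
widely separated in area: clumps and free hyphae stay below ~164 µm²,
pellets span 10⁴–10⁶ µm², and spores appear only at 0 h. No explicit
decision rule accompanies those ranges, so the package declares one:
objects below 20 µm² are debris; at 0 h objects up to 300 µm² are
spores; otherwise the pellet/clump boundary sits at 1000 µm²
(inclusive on the clump side), inside the two-orders-of-magnitude gap
between the group ranges. All three thresholds are configurable.

Group summaries report, per descriptor and (class, time, condition)
group: $n$, mean, SD (with $n-1$ denominator) and the Student-t band
$\bar{x} \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}$ at $\alpha = 0.05$,
plus a flag marking groups with at least 30 objects — the customary
floor for reporting mean morphological parameters. Two-sample
comparisons use the Welch (unequal-variance) two-sided t-test: the
source procedure says only "t-test", and group sizes and variances
differ across conditions, so the variant that does not assume equal
variances is the safer default (a pooled option exists). Degenerate
zero-variance pairs follow a documented convention (equal means → p =
1, different means → p = 0).

## Enhancement factors

For each metabolite, time and talc dose,
$$\mathrm{EF} = \frac{\text{mean amount, talc run}}{\text{mean amount, control run}}.$$
EF is exactly scale-invariant, so it applies equally to absolute
concentrations (oxytetracycline, mg/L) and to arbitrary-unit ion peak
areas. The confidence band uses the delta method on
$\log \mathrm{EF}$ — $\mathrm{se}^2 = \widehat{cv}_t^2/n_t +
\widehat{cv}_c^2/n_c$ — with Student-t quantiles at
$\min(n_t, n_c) - 1$ degrees of freedom: the source reports EF with
error bars but no formula, and with four replicates per arm a
conservative df choice is preferable to a Welch–Satterthwaite
approximation of doubtful accuracy at $n = 4$. The p-value reported
alongside is the Welch test on the replicate amounts themselves.

## Glucose uptake rates

Replicate glucose concentrations are averaged per time point, fitted
with a cubic spline, and the volumetric uptake rate is reported as
$q(t) = -\mathrm{d}c/\mathrm{d}t$ (positive for consumption). Three
modes exist:

* `"cubic"` (default): interpolating cubic spline whose end conditions
  come from an exact cubic fit through the four points nearest each
  end. This reproduces any cubic polynomial sampled at the data times
  exactly — the natural correctness benchmark for a "cubic spline
  approximation followed by differentiation".
* `"natural"`: zero second derivative at both ends. Natural end
  conditions are sometimes preferred when no end-slope information
  exists, but they impose $c'' = 0$ where the data may be curved and
  therefore cannot reproduce even a cubic near the boundaries (the
  boundary error is $O(h^2)$); this is why they are not the default.
* `"smooth"`: penalised regression spline (`stats::smooth.spline`)
  for visibly noisy series.

With knots at all five sampling times a least-squares cubic B-spline
degenerates to interpolation anyway, so interpolation of replicate
means is both the reproducible choice and the closest reading of the
stated procedure; fitting the mean curve (rather than per-replicate
splines averaged afterwards) is the declared default. By construction
$\int q\,\mathrm{d}t$ over the fitted range equals the total
concentration drop of the means (verified to $10^{-6}$ relative in the
tests). For convex monotone decays the rate is non-negative at the
knots; between knots a cubic interpolant of steeply sigmoidal data can
overshoot slightly (a well-known property of interpolating splines),
which is why rates are reported at the sampling grid by default and
interior oscillation is documented rather than asserted.

## The synthetic-data generator

The generator emulates, with known ground truth, the two data streams
of an MPEC experiment.

**Images.** Objects are rendered dark on a bright background (default
background 0.85, objects 0.05–0.35 on a [0, 1] scale) and corrupted
with additive Gaussian noise (default sd 0.02) clipped to [0, 1] —
the simplest model that stresses the median filter. Pellets are
radial shapes $r(\theta) = r_0 (1 + a \sum_k w_k \cos(k\theta +
\varphi_k))$ with random harmonics $k = 2..6$ normalised so the
perturbation never exceeds the roughness amplitude $a < 1$ (smooth,
connected, seed-reproducible outlines), stretched by an
area-preserving transform to a target aspect ratio; their true area is
the analytic polygon area of the generating boundary. Filaments are
capsules around smooth bounded-curvature paths (end-to-end distance ≥
80 % of length) with up to three straight side branches; their true
area comes from 3× supersampled rasterization. Spores are small
low-aspect pellets; talc distractors are high-contrast 10 µm disks
that appear in the ground truth as class `talc` so filtering can be
scored. Rasterization is hard (no anti-aliasing) so that on noise-free
scenes segmentation can be scored against the truth without a
rendering-model confound. Default shape ranges keep the classes
inside the observed group ranges: clump parameters (length 8–30 µm,
width 1.5–2.5 µm, branch fraction 0.15–0.30) bound the true area below
164 µm², and pellet radii of 60–120 µm put pellet areas in
1.1×10⁴–5×10⁴ µm², inside the observed 10⁴–10⁶ µm² band.

**Time series.** Five sampling times (0–96 h every 24 h), four
replicates per condition, talc doses {0, 0.5, 5, 10, 12} g/L. Each
amount is `control mean × true EF × lognormal noise`, with the
lognormal scaled to unit mean and a given CV (amounts are positive, so
multiplicative noise is the natural model); the expected
treatment/control ratio therefore equals the true EF exactly. The
default true-EF table ramps from 1 at inoculation to its peak by 72 h
with peak values shaped after the reported effect structure (strong
oxytetracycline and 2-acetyl-2-decarboxamido-oxytetracycline
enhancement at 5 g/L, moderate milbemycin A₃+4[O] enhancement at
10 g/L, mild enhancement of rimocidin CE108, suppression of rimocidin
(27-ethyl) and milbemycin β₁₁+4[O], no effect on rimocidin). Glucose
follows a stretched-exponential consumption ramp,
$c(t) = c_0 - (c_0 - c_{96})\,
\frac{1 - e^{-(t/\tau)^p}}{1 - e^{-(96/\tau)^p}}$,
with $c_0 = 22$ g/L (the medium recipe) and per-condition 96 h values
matching the reported finals (7.45 / 7.47 / 10.56 / 10.95 / 11.44 g/L
for 0 / 0.5 / 5 / 10 / 12 g/L talc), $\tau = 55$ h and $p = 2$ (slow
initial uptake, consistent with the reported low early uptake rates),
plus Gaussian noise (sd 0.3 g/L) clipped at zero. The curve is
non-increasing before noise by construction and hits the reported
final concentration exactly in the noiseless limit.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: optical realism (phase halos, focus
gradients, uneven illumination), touching or overlapping objects
(watershed splitting is out of scope), growth kinetics linking object
sizes across time points, within-flask correlation of metabolites, and
LC–MS peak integration. Results on real micrographs will depend on
imaging conditions the synthetic scenes deliberately idealise.

## Numerical choices and degenerate inputs

* Reflect (symmetric) padding for all window operations — no
  artificial edges at the frame.
* Otsu threshold on 256 bins over the observed intensity range;
  degenerate (constant) images yield an empty segmentation.
* Elongation requires ≥ 3 pixels and raises a degenerate-object error
  when the transversal variance is below 10⁻⁹ (e.g. a 1-pixel-wide
  straight line); the measurement table records `NA` descriptors for
  such objects instead of failing wholesale.
* Mo values above 1 + 2 % (the rasterization tolerance) raise an
  error by design — they cannot arise from a correct descriptor chain.
* Spline fitting refuses fewer than 4 distinct times and duplicate
  times with conflicting values (replicates must be averaged
  upstream); equal-valued duplicates collapse.
* All generator randomness is a pure function of (spec, seed); the
  pipeline derives per-stage seeds from a single master seed so that
  stages stay reproducible in isolation.

## Problem sizes in the shipped tests

The test-suite simulations are sized for quick, repeatable runs while
keeping every estimate well inside its tolerance: 512² px scenes with
2–7 objects for segmentation scoring, 500 random masks for the Mo
bound sweep, 200 seeded series for EF bias (4 replicates, CV 0.1),
10,000 null simulations for test-size and band-coverage calibration,
and a 2-condition × 3-time demo pipeline for byte-identical
reproducibility. Larger studies only change the `n` in these checks,
not the code paths.

## Known limitations

* 2-D morphology only; no compactness layering of pellet interiors,
  no 3-D reconstruction, no tracking of individual objects over time.
* Touching pellets are segmented as one object (no watershed split).
* The semiautomatic, operator-guided steps of vendor software are not
  reproduced; the pipeline is fully automatic by design, so absolute
  descriptor values on real images may differ where an operator would
  have intervened.
* The classification thresholds are declared defaults for this
  package, chosen inside the wide empirical gap between the observed
  group ranges — they are not a community standard.
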