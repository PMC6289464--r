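---
title: "Relative-entropy thresholding of EFTEM elemental maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative-entropy thresholding of EFTEM elemental maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(entropymap)
```

## The problem

Energy-filtered transmission electron microscopy (EFTEM) produces elemental
maps of ultrathin cell sections: per-pixel, background-subtracted intensities
proportional to the local abundance of an element such as phosphorus or
nitrogen. Microalgae and cyanobacteria store P and N in discrete reserve
bodies — polyphosphate granules (P-rich inclusions, PRIs) and cyanophycin or
related deposits (N-rich inclusions, NRIs). Quantifying these inclusions on a
map requires separating their signal from two confounders: shot noise, and
element-containing cell structures (thylakoids, ribosome-rich cytosol,
nucleic acids) that are not reserves.

`entropymap` implements a histogram-based separation. The map is quantized to
256 grey levels; the observed grey-level histogram $H(g)$ is treated as the
*a posteriori* evidence about which levels carry signal, and is compared with
a Gaussian *a priori* noise model $G(g)$ of equal mean, variance and total
pixel count:

$$\bar g = \frac{1}{P}\sum_g g\,H(g), \qquad
  \sigma^2 = \frac{1}{P-1}\sum_g (g-\bar g)^2 H(g),$$

$$G(g) = \frac{P}{\sqrt{2\pi\sigma^2}}\,
         e^{-(g-\bar g)^2/2\sigma^2}, \qquad
  R(g) = \ln\frac{H(g)}{G(g)}, \qquad
  q = \frac{1}{P}\sum_g R(g)\,H(g).$$

$R(g) > 0$ flags grey levels where more pixels sit than pure Gaussian noise
would put there. Element-rich pixel classes appear as *contiguous groups* of
positive-$R$ levels on the bright side of the histogram, which yields binary
thresholds:

* **Workflow A** (maps with few inclusions, roughly up to ten per section):
  the threshold $g_0$ is one level below the onset of the first group of
  positive-$R$ levels that begins strictly above $\bar g$; white pixels are
  $g > g_0$.
* **Workflow B** (maps with many inclusions): negative map values are zeroed
  *before* quantization, which piles roughly half of the background noise
  into level 0 and makes moderately element-rich structures form a distinct
  first peak on the curve $R(g)H(g)$ above $g_0$. The threshold $g_1$ is the
  end of that first peak (the structures are not the inclusions of interest);
  white pixels are $g > g_1$.

White pixels are then segmented into connected components, assigned to cell
compartments, and summarized per section as the relative reserve area
$S_R = 100\,S_{TI}/S_{cell}$, where $S_{TI}$ is the total inclusion pixel
area and $S_{cell}$ the cell-section pixel area.

## Worked example

```{r example}
spec <- simulation_spec(shape = c(256, 256), n_inclusions = 5,
                        contrast = "high", seed = 7)
sim <- generate_net_map(spec)
res <- run_analysis(sim$map, sim$region, workflow = "auto")
res
sim$truth$true_S_R
plot_entropy(res$analysis, g0 = res$g0)
```

The detected relative area matches the planted geometry because at this
contrast every inclusion pixel clears the threshold and essentially no noise
pixel does.

## Design choices, and why

**Quantization.** Grey levels are
$g = \mathrm{round}\!\big(255\,(x - x_{min})/(x_{max} - x_{min})\big)$ with
round-half-away-from-zero, so the full dynamic range is used ($g_{min}=0$,
$g_{max}=255$) and the mapping is deterministic and affine-invariant. No
outlier clipping is applied before scaling. A constant map is rejected rather
than mapped to a single level: on real data it indicates an acquisition
failure.

**The positive-run rule and `min_run`.** The decisive detail of $g_0$ is that
the qualifying group of positive-$R$ levels must *begin* strictly above
$\bar g$. The noise bulk always straddles the mean, and within it $H(g)$
fluctuates around $G(g)$, so individual levels just above $\bar g$ have
$R > 0$ about half the time; they belong to a positive block that starts
below the mean and therefore never qualify. What remains are (i) genuine
signal classes, which occupy long contiguous blocks of high levels, and
(ii) short spurious sign-runs from counting noise. Treating each occupied
level above the mean as exceeding its Gaussian expectation independently with
probability about $1/2$, the expected number of spurious runs of length at
least $k$ among the ~128 levels above the mean is about
$128 \cdot 2^{-(k+1)}$. The default `min_run = 12` therefore bounds the
expected spurious detection rate near 1.6% of noise-only maps, while a
genuine inclusion class of any substance spans far more than 12 of the 256
levels. The parameter is exposed: for very small maps, or sections whose
inclusions cover only tens of pixels smeared over a wide grey range (so that
their histogram block contains empty levels, which break runs), a smaller
`min_run` is appropriate — at the cost of admitting isolated noisy levels.

**$g_1$ peak-end detection.** "End of the first peak" of $R(g)H(g)$ is
formalized as: find the first level above $g_0$ with $R(g)H(g) > 0$; the peak
ends at the last positive level before the curve first returns to $\le 0$.
Only when the curve never returns to $\le 0$ (two classes merged by a shallow
dip) does the fallback apply: the first local minimum after the first local
maximum. The order matters — scanning for local extrema first would truncate
the peak at any noise wiggle on its flank. No smoothing is applied by
default; `smooth_window` (odd width, centered moving average) exists for
curves with very ragged peaks.

**Empty bins.** Levels with $H(g) = 0$ contribute $R(g) = R(g)H(g) = 0$ (the
$x \ln x \to 0$ limit); the variance uses the $P-1$ denominator; logarithms
are natural (the base scales $R$ but cannot change its sign, so thresholds do
not depend on it). The Gaussian prior is normalized to carry the full pixel
count $P$ — the prior describes the same number of electrons incident on the
same number of pixels, only noise-distributed.

**Workflow selection.** `workflow = "auto"` analyzes the map with workflow A
and switches to B when more than 10 labeled inclusions are found; exactly 10
stays with A (the boundary count is assigned to the few-inclusion regime).
Explicit `"A"`/`"B"` are honored as given. With many inclusions amid
element-rich structures, components can merge under workflow A, so auto
selection based on the A-pass count is conservative; when the inclusion load
is known (e.g. from survey images), set the workflow explicitly.

**Morphometry.** Manual outlining of inclusion regions is replaced by
8-connected component labeling (configurable to 4) restricted to the cell
mask, or to an analyst-supplied ROI mask that reproduces manual selection
exactly. `min_area = 1` by default, so $S_{TI}$ equals the raw white-pixel
count within the counting region; raising it suppresses single-pixel noise
at the price of missing the smallest genuine granules. Compartment
assignment uses a strict majority (> 50%) of inclusion pixels; anything
else — ties, mostly-unlabeled pixels, no compartment image — is
`not_determined`. Inclusions touching the cell-mask boundary are counted for
the pixels that lie inside it.

**Three-window background subtraction.** Two pre-edge images determine the
power law $I(E) = A E^{-r}$ exactly per pixel
($r = \ln(I_1/I_2)/\ln(E_2/E_1)$, $A = I_1 E_1^{r}$); the net map is the
post-edge image minus the extrapolated background. This is the unique power
law through two points, not a least-squares fit — with two pre-edge windows
the fit is fully determined. Pixels with a non-positive pre-edge intensity
have no defined logarithm; they are flagged invalid, contribute net 0, and
are counted in the map's `invalid_pixels` field rather than poisoning the
array with NaNs. Negative net values are preserved — zeroing them is
workflow B's preprocessing step, not a property of the subtraction. Image
alignment is assumed done upstream in acquisition software.

**File formats.** Float TIFF (read exactly, including negative values),
integer TIFF (read as raw counts) and delimited text matrices are accepted.
Net maps are *written* as text matrices at full precision; TIFF output is
used for 8-bit grey images and masks. Multi-channel images are rejected.

## The synthetic generator

`generate_net_map()` emulates exactly what the thresholding consumes: a
background-subtracted map whose background fluctuates around zero with
Gaussian noise of sd `sigma_n`, an elliptical cell section, optional
mid-intensity elliptical structures (the "element-containing structures that
are not inclusions" class), and disk-shaped inclusions — reserve granules are
roundish bodies. Contrast presets set the inclusion signal to $20\sigma_n$
("high") or $5\sigma_n$ ("low"). `generate_window_triplet()` builds the
upstream three-window images from planted $(A, r)$ fields, with optional
Poisson shot noise, adding the inclusion signal to the post-edge image only.
Everything is bit-reproducible per seed, and the caller's RNG stream is left
untouched.

What the generator does *not* emulate: organelle texture, correlated noise,
drift or misalignment between windows, thickness gradients, and inclusions of
graded density. Passing tests on synthetic maps therefore demonstrate the
correctness and statistical behavior of the algorithm under its own model
assumptions — not performance on any particular instrument's data. In
particular, real maps with strong textured backgrounds may need an explicit
workflow choice, a ROI mask, or a nonzero `min_area`.

## Validation at the package's study conditions

The test suite validates, among others (sizes chosen to keep a full run
around twenty seconds):

* formula-level agreement of the entropy analysis with an independent
  scalar-loop implementation on 200 random 32×32 images (≤ 1e−10 relative);
* exact recovery of planted signals by the three-window chain on noiseless
  64×64 triplets with spatially varying $(A, r)$ (≤ 1e−9 relative);
* relative-area recovery within 15% and exact inclusion counts on ≥ 18 of 20
  high-contrast 512×512 maps with 3–8 disks;
* on 100 pure-noise 256×256 maps, ≥ 95 report no threshold or a white area
  below 0.5% of pixels;
* on two-class maps (structures + 15 inclusions, 10 seeds), workflow B
  excludes ≥ 90% of structure pixels while retaining ≥ 80% of inclusion
  pixels, whereas workflow A leaves the structure class white;
* three repeated runs of one section give identical $S_R$ and byte-identical
  artifact files (the method has no manual step left, so repeat variability
  is exactly zero).

`scripts/acceptance.R` recomputes these quantities from scratch against
freshly generated ground truth.

## Known limitations

* The run-length guard trades noise robustness against sensitivity to
  inclusion classes covering very few pixels; see the `min_run` discussion.
* $S_R$ is a per-section area fraction; no stereological correction toward
  volume fractions is attempted, and inclusion density/brightness is not
  quantified — a dim and a saturated granule of equal area count equally.
* Auto workflow selection counts components found by workflow A and can
  under-count when inclusions merge with bright structures.
* The Gaussian prior assumes the noise histogram is unimodal and symmetric;
  maps dominated by strongly non-Gaussian backgrounds violate the model.
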