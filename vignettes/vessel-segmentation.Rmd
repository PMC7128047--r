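---
title: "Centerline-seeded random walks for retinal vessel segmentation"
author: "retwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-seeded random walks for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(retwalk)
```

## The problem and the model

Retinal blood vessels appear in fundus photographs as dark, elongated,
tree-structured valleys on a brighter textured background, confined to the
circular camera aperture (the field of view, FOV). `retwalk` segments them
in four stages.

**1. Working image and FOV.** The green channel carries the strongest
vessel/background contrast and is normalized to $[0,1]$ at load time; every
parameter below is interpreted on that scale. The FOV disc is recovered by
thresholding the red channel at 15% of its maximum, keeping the largest
4-connected component, opening with a 3-px disc and filling holes. Before
any filtering, pixels outside the FOV are replaced by the mean interior
intensity; otherwise the artificial step at the aperture rim dominates
every derivative filter near the boundary.

**2. Multiscale vesselness.** At each scale $\sigma$ the Hessian
$H = \begin{pmatrix} g_{xx} & g_{xy} \\ g_{xy} & g_{yy}\end{pmatrix}$
is computed by convolution with analytic Gaussian-derivative kernels and
scale-normalized by $\sigma^2$ (without normalization the multiscale
maximum degenerates to the smallest scale). With signed eigenvalue
ordering $\lambda_1 \le \lambda_2$, a dark tube has $\lambda_1 \approx 0$
along its axis and $\lambda_2 \gg 0$ across it. Writing
$s^2 = \lambda_1^2 + \lambda_2^2$ and the fractional anisotropy
$\mathrm{FAH} = |\lambda_1 - \lambda_2| / s$ (clipped to $[0,1]$), the
per-scale response is

$$\nu(\sigma) = \begin{cases}
0 & \lambda_1 > 0,\\
\bigl(1 - e^{-s^2 / 2c^2}\bigr)\, e^{\mathrm{FAH} - 1} & \lambda_1 \le 0,
\end{cases}$$

and the enhancement map is the pixelwise maximum
$\nu_{\max} = \max_\sigma \nu(\sigma)$ over $\sigma = 0.2m$,
$m = 1,\dots,25$. The scale achieving the maximum and the cross-vessel
eigenvector at that scale are retained; the eigenvector later orients the
seed placement. The anisotropy factor $e^{\mathrm{FAH}-1}$ equals 1 at the
line-like limit $\mathrm{FAH}=1$; an alternative form $e^{-1/\mathrm{FAH}}$
is available (`exponent_form = "inverse"`), as is classic magnitude
eigenvalue ordering.

**3. Centerlines.** Two independent detectors are fused.

*Divergence candidates.* The normalized gradient field
$\mathrm{NF} = \nabla g / |\nabla g|$ of the smoothed image expands away
from a dark axis, so a positive divergence marks centerline pixels. For
each pair $(\theta, \sigma)$ the angle-weighted score
$\mathrm{NG}(\theta) = \cos\theta\, \partial_x \mathrm{NF}_x +
\sin\theta\, \partial_y \mathrm{NF}_y$ (central differences) is
thresholded at $\varphi = 0.45$ and 8-connected components smaller than
$\delta = 50$ px are discarded; the candidate mask $C_\mathrm{can}$ is the
union over 8 angles and all 25 scales. The angle-weighted form takes at
most one full-strength noise term per angle, which keeps the per-map
false-positive rate below the site-percolation threshold of the 8-connected
lattice ($\approx 0.41$); the full divergence of the rotated field (two
summed noise terms, available as `divergence_form = "rotated"`) crosses
that threshold on noisy images, after which spurious responses merge into
components larger than any $\delta$ and the size filter is inert. Because
the field is normalized, this detector is contrast-blind: it finds shallow
valleys as readily as deep ones, and relies entirely on the next detector
to reject them.

*Morphological skeleton.* A sum of bottom-hat transforms (closing minus
image) with 1-px-wide linear elements of lengths 2–12 px (step 2) in 8
orientations responds to dark structures narrower than the element. The
sum, rescaled by its maximum, is binarized by Otsu's threshold computed
over in-FOV pixels and thinned (Zhang–Suen) to the skeleton
$C_\mathrm{skel}$. This detector is contrast-sensitive — it is the
pipeline's only gate against low-contrast clutter — but its summed
response is width-biased: a 12-px vessel excites only the longest elements
at near-perpendicular orientations, at roughly half depth.

*Fusion.* Both masks are split into 4-connected regions; a region survives
when more than 40% of its pixels lie in the agreement set
$C_\mathrm{skel} \wedge C_\mathrm{can}$, and 8-connected components of the
union shorter than $L = 50$ px are removed. The length threshold matches
$\delta$: on noisy images, measured noise-coincidence components reach
$\sim$45 px while true centerline components exceed 100 px, so a
materially smaller $L$ cannot perform its role of removing isolated short
branches.

**4. Random walker.** In-FOV pixels form an 8-connected lattice whose
edges carry weights $w_{ij} = e^{-\beta (\nu_i - \nu_j)^2}$, $\beta = 90$,
where $\nu$ is the enhancement map rescaled to a maximum of 1. The
rescaling matters: with $\sigma^2$-normalized Hessians on $[0,1]$
intensities the raw ridge response is $\approx 0.39 \times$ the vessel
contrast (typically $\sim 0.1$), and $\beta = 90$ applied to per-edge
differences of a few hundredths would leave every weight near 1; on the
normalized guide the vessel wall becomes a genuine low-conductance
barrier. Every centerline pixel is a foreground seed. Candidate background
seeds sit at $\pm d$ along the cross-vessel eigenvector, where
$d = R_\mathrm{mid} + 1 = 8$ px in DENSE areas (several vessels inside the
$2R_\mathrm{mid}$ window around the pixel, judged on the
$R_\mathrm{mid}$-dilated centerlines) and $d = R_\mathrm{max} + 1 = 13$ px
in SPARSE areas. A candidate is rejected if it leaves the FOV, falls
within 1 px of a centerline, or lands on a pixel whose guide value exceeds
the guide's own FOV-Otsu threshold — a background label is a hard boundary
condition, and planting one on a vessel-like pixel (typically a wide
vessel whose centerline was missed) would contradict the enhancement
evidence. The walker probabilities fix $u = 1$ at foreground and $u = 0$
at background seeds and minimize the Dirichlet energy
$E(u) = \tfrac12 \sum_{ij} w_{ij} (u_i - u_j)^2$; the reduced sparse
linear system is solved exactly by sparse Cholesky factorization
(`Matrix`), which is simpler and at least as accurate as an iterative
solver at tolerance $10^{-8}$ — `solver_tol` is retained in the interface
for compatibility. FOV components containing no seed get probability 0
with a warning. A pixel is vessel when $u \ge 0.5$ (per-pixel maximum of
the two label probabilities; ties to vessel).

**Evaluation.** Inside the FOV only:
$Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$,
$Acc = (TP+TN)/(TP+FN+TN+FP)$, plus the Dice overlap
$2|A \cap B| / (|A| + |B|)$. Batch mode averages per-image metrics
arithmetically.

## Parameters

| key | default | units | role |
|---|---|---|---|
| `sigmas` | $0.2m,\, m=1..25$ | px | Gaussian scale grid (all derivative filters) |
| `c` | 0.2 | intensity | vesselness contrast sensitivity |
| `thetas` | $n\pi/8,\, n=0..7$ | rad | divergence detector angles |
| `phi` | 0.45 | — | divergence threshold |
| `delta` | 50 | px | minimum candidate component |
| `se_lengths` | 2..12 step 2 | px | bottom-hat element lengths |
| `se_angles` | $0..7\pi/8$ step $\pi/8$ | rad | bottom-hat orientations |
| `overlap_frac` | 0.40 | — | region agreement fraction |
| `min_length` | 50 | px | minimum centerline branch |
| `r_min`, `r_mid`, `r_max` | 2, 7, 12 | px | vessel radius range; seed offsets |
| `beta` | 90 | — | walker edge-weight sharpness |
| `solver_tol` | 1e-8 | — | interface compatibility (direct solve is exact) |

The eight angles pair with the 25 scales to give the 200 candidate maps
whose union forms $C_\mathrm{can}$.

## The phantom generator

`generate_phantom()` renders a brighter shaded background (level 0.72,
smooth shading amplitude 0.05) inside a FOV disc of radius
$0.46\min(H,W)$, carrying dark vessel polylines with Gaussian
cross-profiles, optional bright lesion-like blobs, and additive noise —
with exact vessel, axis, FOV and lesion masks as ground truth. Its
modeling choices:

* **Width is FWHM.** A vessel of full width $w$ has profile standard
  deviation $w/2.355$, so the truth mask edge sits at the half-depth
  point — the standard caliber convention in fundus photometry.
* **Contrast follows caliber.** Default axis depth is
  $0.35\,(1 - e^{-w/4})$: absorption through the blood column saturates
  for large vessels and leaves capillary-scale vessels faint, as in real
  photographs. Equal contrast across calibers would be unrealistic and
  lets thin vessels dominate the summed bottom-hat by an order of
  magnitude.
* **Overlapping branches combine by max**, the deepest local blood
  column. Summing profiles would render junctions as isotropic dark
  blobs, which the $\lambda_1 \le 0$ gate scores as non-vessel.
* **Noise is band-limited** (Gaussian point-spread $\sigma = 0.8$ px,
  then scaled to per-pixel sd 0.02). A photograph digitized through an
  optical system cannot carry noise that is white at the Nyquist limit,
  and pixel-iid noise is uniquely pathological for grayscale closings
  (one pixel's downward spike enters every bottom-hat term) and for
  normalized-gradient direction fields (directions decorrelate at the
  pixel scale and the divergence percolates). Set `noise_psf = 0` to
  study that regime deliberately.

`default_test_suite_specs()` fixes five scenarios on a 160×160 canvas: a
single straight tube, a Y-bifurcation, two parallel tubes $3R_\mathrm{mid}$
apart (exercising DENSE seeding), a curved tube with three bright lesions,
and a tree with a tapering trunk spanning the full 2–12 px width range.
The sizes keep a full 25-scale end-to-end run in a few seconds, so the
whole suite (and the acceptance script) completes in minutes on one CPU.

What the phantoms do **not** emulate: the optic disc and fovea, central
light reflexes inside large vessels, arteriole/venule color differences,
JPEG blocking, and the illumination falloff of real fundus cameras.
Passing on phantoms therefore demonstrates internal correctness and
robustness to the modeled effects, not benchmark performance on clinical
data; a batch mode is provided for users who hold a real annotated
dataset.

## Numerical choices

* Convolutions use sampled analytic Gaussian-derivative kernels of radius
  $\lceil 4\sigma \rceil$, normalized so polynomial responses are exact
  (order 0 sums to 1, order 1 has unit ramp response, order 2 responds
  with 2 to $x^2$), applied with reflective boundaries via FFT.
* The eigenvector of $\lambda_2$ falls back across two closed-form
  candidates to remain defined at isotropic pixels.
* Grayscale closings for the bottom-hat are computed exactly as max/min
  over the structuring element's offsets, with the conventional
  $\pm\infty$ border convention.
* Otsu's threshold searches 256 histogram-bin edges but evaluates class
  statistics exactly from raw pixel values; ties break toward the lower
  threshold; constant images are an error.
* Zhang–Suen thinning deletes simultaneously per sub-iteration; one pixel
  of any component that would vanish entirely is exempted (the classic
  2×2-square failure), so 8-connected component counts are preserved.
* Vectors with gradient magnitude below `eps = 1e-8` normalize to exactly
  zero.
* Divergences use central differences (one-sided at borders).

## Known limitations

* **Boundary width bias.** The walker's 0.5-level set tracks the steepest
  cliff of the normalized enhancement map, which sits near one profile
  standard deviation from the axis, while background seeds sit at fixed
  offsets (8 or 13 px) regardless of the true local caliber. The result
  is a systematic $\sim$1 px over-segmentation of capillary-scale vessels
  and $\sim$1 px under-segmentation of the widest trunks. On compact
  high-perimeter structures this costs Dice: the tapered-tree phantom
  stabilizes near 0.75 even though every caliber is recovered (per-vessel
  sensitivity 0.74–1.0), whereas the straight-tube and bifurcation
  phantoms exceed 0.8. Caliber-adaptive seed offsets would remove the
  bias but are outside the fixed-offset design.
* **Wide, faint vessels.** A 12-px vessel's summed bottom-hat response is
  marginal against the global Otsu threshold when thin high-response
  vessels share the scene; its skeleton fragments, and recovery then
  depends on the candidate regions carrying it through the fusion rule.
* The contrast-blind candidate detector needs the skeleton's contrast
  gate; on scenes whose noise passes both detectors at the same pixels
  (heavy white noise), the fusion admits clutter.
* Single FOV component assumed per image for seeding; multi-aperture
  montages would need per-component seeds.

## Reproducing the numbers

`scripts/acceptance.R` regenerates the phantom suite from a seed, runs the
full pipeline at default settings, and writes the Dice scores, centerline
precision/coverage, lesion false-label fraction, mean pixelwise metrics
and solver/threshold oracle checks to JSON. The test suite
(`testthat::test_dir("tests/testthat")`) covers the same ground plus
per-operation oracles: dense linear-algebra solutions for the walker,
exhaustive-search agreement for Otsu, `base::eigen` for the Hessian
eigensystem, and closed-form kernels for every convolution.
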