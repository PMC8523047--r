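---
title: "Sarcomere segmentation, tracking and contractile mechanics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sarcomere segmentation, tracking and contractile mechanics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, numerical choices and
known limitations of the package. It is the design record: wherever a
step admitted more than one reasonable definition, the choice made here
is stated as such.

# The problem

Movies of beating human induced pluripotent stem cell-derived
cardiomyocytes (hiPSC-CMs) with fluorescently labeled z-discs contain
hundreds of sarcomeres per frame over 100+ frames. Because hiPSC-CM
sarcomere chains are disordered and beat out of sync, useful
quantification needs individual sarcomeres segmented *and* tracked, not
one filter response per image. The pipeline is: ingest → per-frame
z-disc segmentation → procedural sarcomere linking → independent
tracking of z-discs and sarcomeres → Gaussian-process time-series
reconstruction → average-deformation and orientation metrics → spatial
graph analysis.

# Segmentation model

z-discs appear as bright, roughly elliptical blobs a few pixels across.
The detector computes the image Laplacian (4-neighbor stencil,
replicated boundary), negates it so blob interiors give positive
response, smooths with an isotropic Gaussian of standard deviation
`gaussian_filter_size`, and extracts iso-contours of the response at the
Otsu threshold using marching squares. Contours that touch the border
without closing are discarded, as are contours with fewer than 4
distinct vertices (no principled lower bound exists; the cutoff is
exposed as `min_points`). Working on the Laplacian rather than the raw
image is what lets a single global threshold work: slowly varying
background has nearly zero Laplacian, so only blob-scale structure
crosses the threshold and constant offsets change nothing.

Per-disc properties follow fixed definitions: the center is the mean of
the contour vertices, the endpoints are the two contour points realizing
the maximum pairwise distance (exact O(k²) search, ties broken by first
occurrence), and the disc length is that distance. Coordinates are
x = column, y = row, origin top-left, sub-pixel positions allowed; all
lengths are in pixels and all times in frames. Frames are indexed from 1.

`gaussian_filter_size = 1` is the default and appropriate for clean
movies; 2 suppresses strongly fluctuating background at the cost of
merging close discs.

## Sarcomere linking

Sarcomeres are z-disc pairs. The linker: (1) computes each disc's
nearest-neighbor center distance; (2) takes `median_neigh`, the median
of those; (3) places two *ghost points* per disc at `median_neigh/2`
along the unit vector perpendicular to the disc's endpoint axis — i.e.
where the partner discs of an idealized chain would sit; (4) finds each
ghost point's nearest neighbor among ghost points of *other* discs
(ties broken by smaller distance, then lower disc id, for determinism);
(5) turns mutual nearest-neighbor ghost pairs into sarcomeres, collapsing
duplicate disc pairs. Each disc has two ghosts, so it joins at most two
sarcomeres — one per side — which is exactly the chain topology.
"Approximately parallel" is deliberately not enforced beyond mutuality;
no extra rejection criterion is applied by default. Sarcomere length is
the distance between disc centers, width the mean of the two disc
lengths, and angle the direction of the center-connecting vector taken
modulo π.

# Tracking

z-discs and sarcomeres are tracked independently (both identities are
needed to assemble the spatial graph). Linking between frames is a
per-frame-pair optimal assignment: candidate links are all
(track, detection) pairs displaced at most `tp_depth` pixels per elapsed
frame, and the assignment minimizing total squared displacement —
computed by the Hungarian method — is kept. Optimal assignment rather
than greedy matching keeps the result deterministic and order-invariant.
A track unmatched for more than `memory` consecutive frames is closed;
during a gap of g frames the allowed radius scales to `g * tp_depth`, so
the displacement bound is per elapsed frame. Defaults: `tp_depth = 4`
(use 3 for low-resolution movies), `memory = 5`. The memory default is a
package choice — gap closure must be long enough that the downstream
interpolation has gaps to fill, and 5 frames spans the transient signal
loss seen around rapid contraction peaks in practice; it is exposed in
the configuration.

Tracks present in more than `min_presence = 0.10` of frames receive
global ids, assigned in a deterministic order (first frame, then x, then
y at first observation).

# Time-series reconstruction

Only tracks present in at least `keep_thresh` of the frames are
processed; 0.75 is the default for quantitative work, and anything above
1/k (k = number of beats in the movie) is only appropriate for
visualization. For each kept track, five series — length, width, angle,
x, y — are reconstructed at every frame by Gaussian-process regression
with kernel

$$k(t,t') = \sigma_f^2 \exp\!\left(-\frac{(t-t')^2}{2\ell^2}\right)
          + \sigma_n^2\,\delta_{tt'}$$

Values are standardized before fitting (a package choice; the length
scale is kept in frame units). Hyperparameters are fitted by maximizing
the log marginal likelihood with L-BFGS-B from three length-scale starts
(3, 10, 30 frames; bounds [1, 100], noise variance init 1e-2 in
[1e-6, 1], signal variance in [1e-3, 1e3]); the restarts guard against
local optima that oversmooth sharp beats. Only the posterior mean is
used downstream; posterior uncertainty is not propagated. Angles live
modulo π and are unwrapped before smoothing so that no artificial π
jumps enter the GP.

Normalized length is computed *after* reconstruction as
y = (L − L̄)/L̄ with L̄ the mean of the dense reconstructed series —
a gap-robust choice, and it makes every y series zero-mean by
construction.

# Average deformation and functional metrics

Tracked sarcomere centers act as fiducial markers (z-discs would serve
equally well). For m markers, the 2 × n matrices Λ₀ and Λ collect the
vectors joining every unordered pair (n = m(m−1)/2, fixed lexicographic
order) in the reference and current frame; unordered rather than ordered
pairs because antipodal duplicates cancel in the normal equations. The
least-squares deformation gradient is F = Λ Λ₀ᵀ (Λ₀ Λ₀ᵀ)⁻¹, computed by
a stable 2 × 2 solve with a condition-number guard at 1e8 (collinear
markers are a hard error, not a warning). At the reference frame F is
the identity. Polar decomposition uses the SVD (F = WΣVᵀ, R = WVᵀ,
U = VΣVᵀ), robust near singular F; principal stretches are reported
λ₁ ≤ λ₂ and eigenvector signs are fixed so the first nonzero component
is positive.

Reference-frame selection is a two-pass rule: det F is computed with
frame 1 as reference, the maximizing frame (most relaxed cell) becomes
the reference, det F is recomputed, and the minimizing frame is the most
contracted. Ties break to the earliest frame, so a static movie uses
frame 1.

Scalar metrics: s = (y_max − y_min)/(y_max + 1) per sarcomere
(identically (L_max − L_min)/L_max); s̃ = median over sarcomeres
(median, not mean — robust to segmentation outliers); s_avg = s of the
pointwise mean series, which additionally encodes synchrony; the
structural tensor T = ⟨2rrᵀ − I⟩ over unit orientations at the
contracted frame, OOP its largest eigenvalue, v_max the dominant
orientation; C_iso = 1 − det(F)^(1/dim) with dim = 2 (the 3D extension
is out of scope); C_∥ = (|F⁻¹v_max| − 1)/|F⁻¹v_max|. Lower values of
s̃, s_avg, C_iso, C_∥ all mean less contraction. Sarcomeres are not
weighted by width anywhere; an explicit limitation shared with the
analysis-design this follows.

# Spatial graph and timing analyses

The graph has tracked z-discs as nodes and sarcomeres as edges; each
frame in which a tracked sarcomere is observed increments its edge
weight, and observations whose endpoint discs were never globally
tracked are skipped with a log message. The network distance between
sarcomeres is 0 for the same edge and otherwise the minimum endpoint
shortest-path length plus one, which makes adjacent sarcomeres (sharing
a disc) distance 1; for path graphs this coincides with line-graph
distance. The "normalized cross-correlation score" between contraction
series is the zero-lag Pearson correlation — bounded, scale-invariant,
and the package's explicit interpretation since no standard definition
exists; constant series are excluded.

Clustering of normalized-length series uses average-linkage hierarchical
clustering on either Euclidean distances or classic unconstrained
dynamic-time-warping distances (squared local cost, unit steps, square
root of the optimal path cost — hence never exceeding the Euclidean
distance).

Timing parameters have no standard algorithmic definitions; the
package's own are: contraction events are local minima of the series
with prominence at least 25% of the series range (`prominence_frac`,
exposed); contraction time runs from the preceding local maximum (last
point attaining the running maximum) to the minimum; relaxation time
from the minimum to the first point attaining the following maximum;
period is the median inter-minimum spacing; flat time is the period
minus mean contraction and relaxation times; offset is the first
minimum's frame. The same conventions applied to J(t) = det F(t) yield
beat counts and periods for the whole-cell deformation signal.

# Synthetic data generator

The generator exists so that every downstream stage can be validated
against known ground truth. A chain is a smooth 3D path — parametric
sinusoid (in-plane amplitude/period, out-of-plane slope `tilt_z`) or an
arbitrary control-point polyline — decorated with n+1 z-discs whose
consecutive 3D distances equal `rest_length * (1 + g_k(t))` *exactly*
(the disc placement walks the path by chords, solving each step's
intersection analytically). The contraction program g is arbitrary
per-sarcomere; the built-in beat program uses Gaussian pulses of depth
`peak` repeating every `period` frames with optional per-sarcomere phase
lag, because only the peak depth and timing — not the exact pulse shape
— are constrained by the quantities being validated, and users supply
their own program matrix when the shape matters.

Rendering voxelizes each disc as an oriented cylinder (axis along the
local chain tangent, so the projected blob is elongated perpendicular to
the chain) on a grid with `xy_res` voxels per pixel in-plane and coarser
z sampling, slices a slab of half-width `slab_half` around the focal
plane, projects by maximum intensity (preserves blob brightness for thin
slabs), block-averages to pixel resolution (anti-aliasing of the uniform
cylinder profile), applies Gaussian blur at pixel resolution, normalizes
the frame to [0, 1], and adds Perlin noise:
`clip(image + magnitude * field, 0, 1)`. The noise field is classic
2D lattice gradient noise, octave i with period `base_period / 2^i` and
weight 0.5^i, summed without renormalization so added octaves add
high-frequency content; it is zero-mean and deterministic given the
seed. Each frame draws an independent field (seed offset per frame):
the background fluctuates, so spurious blob-like noise does not persist
across frames — persistent background would instead be tracked like a
real structure, which is not what fluorescence background does.

Ground truth is computed from the *prescribed* geometry, never the
rendered images: normalized-length series from the prescribed lengths
give s, s̃ and s_avg; projected sarcomere centers act as noiseless
markers for F, reference/contracted frame selection, C_iso and C_∥; and
projected orientations at the contracted frame give the OOP. Because
the ground-truth metrics are produced by the package's own metric
definitions applied to exact inputs, ground-truth self-consistency is a
tested invariant rather than an assumption.

The baseline validation scene is a single sinusoidal chain of 20
sarcomeres (rest length 10 px — about the apparent sarcomere scale of
100× acquisitions — amplitude 10 px over a 200 px period, no tilt),
80 frames of homogeneous 15% beating at 40 frames/beat, Perlin magnitude
0.1 with 3 octaves, rendered at 128 × 256 px. Validation uses this
scene and stressor variants (tilt 0/0.05/0.15; amplitude-to-period
ratio 0.05/0.2/0.4; Perlin magnitude 0.05/0.4/0.8 at 4 octaves; octaves
1/3/6 at magnitude 0.5, 30 frames each) — sizes chosen to exercise the
full pipeline at realistic density while keeping the whole validation
suite in the minutes range on one core. What the generator does *not*
emulate: photobleaching, shot noise and camera statistics, z-disc shape
irregularity, and neighboring non-sarcomeric fluorescent structure. A
pipeline that is exact on these movies is therefore validated for
geometry, tracking and inference logic, not for photophysical
robustness.

# Degenerate inputs and numerical edge cases

Constant frames segment to nothing (the Otsu threshold is undefined and
guarded). A single disc yields no sarcomeres. Fewer than 3 markers, or
collinear markers, abort deformation estimation with a named error — a
straight untracked chain is the common cause. det F ≤ 0 (frame flip) is
a hard error. GP reconstruction refuses series with fewer than 3
observations. Empty focal slabs render as flagged all-zero frames.
Movie ingestion rescales by the global (not per-frame) min/max so
intensity dynamics across the beat are preserved, and converts color
input with ITU-R BT.601 luma weights.

# Known limitations

All metrics are kinematic; nothing here measures force, and bending or
buckling chains contribute only their visible length changes. The
deformation gradient is 2D; out-of-plane motion appears as apparent
shortening. Sarcomeres invisible to the eye will not be segmented, and
partially tracked populations can be biased — `compare_tracked_untracked()`
exists to check exactly that. Exact reproduction of any particular
published synthetic example requires its (unpublished) geometry
parameters; the package validates the qualitative behavior instead:
full recovery under baseline conditions, weakly monotone degradation
under geometric and noise stressors, and s_avg falling below s̃ under
desynchronized contraction.
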