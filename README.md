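# sarcokinetics

Quantitative analysis of beating human induced pluripotent stem
cell-derived cardiomyocytes (hiPSC-CMs) from fluorescence movies of
z-disc labeled cells. hiPSC-CM sarcomere chains are immature and
disordered, so frameworks built for well-aligned adult myocytes (FFT
line profiles, texture metrics on still images) miss most of the
information in a movie. This package segments every z-disc in every
frame, procedurally links z-disc pairs into sarcomeres, tracks both
across frames, reconstructs per-sarcomere contraction time series, and
condenses the motion of the whole tracked population into an average
deformation gradient and a small set of scalar functional metrics. A
ground-truthed synthetic movie generator makes the entire pipeline
testable without any experimental data.

It is intended for cell mechanics and cardiac tissue-engineering labs
that have movies of z-disc labeled beating cells (order 100+ frames,
hundreds of sarcomeres per frame) and want per-sarcomere and whole-cell
contraction statistics without manual annotation.

## Method

**Segmentation.** z-discs are bright elongated blobs. The frame's
Laplacian (negated, so blob interiors score positive) is smoothed with a
Gaussian (σ = `gaussian_filter_size`, default 1 px) and thresholded at
the Otsu level; closed iso-contours of the response are the z-discs.
Because the threshold acts on the Laplacian, a single global level
suffices and a constant background offset changes nothing. Sarcomeres
are found with a ghost-point rule: each disc casts two auxiliary points
at half the median nearest-neighbor distance along its perpendicular,
and a mutual nearest-neighbor match between ghost points of two discs
links them into a sarcomere of length |**c**₂ − **c**₁| (disc centers),
width equal to the mean disc length, and angle in [0, π).

**Tracking and time series.** Detections are linked frame to frame by
optimal assignment (minimum total squared displacement) restricted to
moves below `tp_depth` px per elapsed frame (default 4), with gap
closure over up to `memory` frames (default 5). Tracks present in more
than 10% of frames get global ids; tracks present in at least
`keep_thresh` (default 0.75) of frames are reconstructed at every frame
by Gaussian-process regression (RBF + white-noise kernel, hyperparameters
by marginal-likelihood maximization), giving dense length, width, angle
and position series plus the normalized length y = (L − L̄)/L̄.

**Average deformation.** Tracked sarcomere centers are fiducial
markers. With Λ₀ and Λ the 2 × n matrices of vectors connecting every
unordered marker pair in the reference and current frames, the
least-squares average deformation gradient is

    F_avg = Λ Λ₀ᵀ (Λ₀ Λ₀ᵀ)⁻¹

Polar decomposition F = R·U yields principal stretches λ₁ ≤ λ₂ and
J = det F (area change, < 1 under contraction). The reference frame is
the frame maximizing det F (first pass referenced to frame 1), the
contracted frame the one minimizing det F after re-referencing.

**Functional metrics.** Per sarcomere s = (y_max − y_min)/(y_max + 1)
≡ (L_max − L_min)/L_max; s̃ is the population median and s_avg the value
of s on the pointwise-mean series (equal to s̃ for synchronous beating,
smaller under desynchrony). The structural tensor T = ⟨2 r rᵀ − I⟩ over
unit orientations gives the orientational order parameter OOP = a_max
(1 = perfectly aligned, 0 = random) and dominant direction v_max.
C_iso = 1 − det(F)^(1/2) is the equivalent isotropic line shortening and
C_∥ = (|F⁻¹v_max| − 1)/|F⁻¹v_max| the shortening along v_max.

**Spatial graph.** z-discs are nodes, sarcomeres edges (weight = frames
observed), so the network distance between sarcomere pairs (same edge 0,
sharing a disc 1, otherwise min endpoint path + 1) and
correlation-vs-distance analyses come from standard graph algorithms.

**Synthetic movies.** Chains of z-discs (oriented cylinders spaced one
sarcomere rest length ≈ 10 px apart) follow prescribed per-sarcomere
fractional length-change programs; frames are produced by voxelizing the
cylinders, slicing a focal slab, maximum-intensity projection, Gaussian
blur and multi-octave Perlin background noise. Ground-truth positions,
lengths, orientations and all scalar metrics are emitted alongside.

## Worked example

```r
library(sarcokinetics)

scene <- baseline_scene(seed = 1)   # 20-sarcomere sinusoidal chain,
                                    # 80 frames, 15% homogeneous beat
res <- run_all(run_config(scene = scene, seed = 1))
length(res$timeseries$ids)
print(res$metrics)
```

prints

```
[1] 20
Functional metrics (20 tracked sarcomeres)
  s_med = 0.1516, s_avg = 0.1481
  OOP = 0.9295 (v_max = [0.998, 0.058])
  C_iso = 0.2208, C_par = 0.146
  reference frame 41, contracted frame 60
```

All 20 prescribed sarcomeres are segmented and tracked. The median
sarcomere shortening s̃ = 0.152 and mean-series shortening
s_avg = 0.148 recover the prescribed 15% peak shortening (they nearly
coincide because the beat is synchronous). OOP = 0.93 reflects the
gently curved, nearly aligned chain; the reference frame falls in
diastole and the contracted frame on a beat peak. C_iso exceeds s̃ here
because a single chain contracts along one axis, so area change
concentrates in that direction.

The same pipeline runs from a shell:

```sh
inst/scripts/sarcokinetics synth --scene scene.json --seed 1 --out data/
inst/scripts/sarcokinetics all --folder data/movie.tif --seed 1 --out out/
```

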