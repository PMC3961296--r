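# dtseg — adaptive distance-metric learning for DTI segmentation

`dtseg` segments diffusion tensor images (DTI) with graph-based
semi-supervised label propagation, for researchers who need to delineate
anatomical structures (e.g. white-matter tracts) from a handful of seed
strokes. Its distinguishing feature: instead of committing to a fixed
tensor metric, it **learns a Mahalanobis kernel metric per segmentation
task**, jointly with the voxel labels.

## The model

Each voxel pair is compared by a 4-component distance vector

d<sub>ij</sub> = ( |ΔMD|, |ΔFA|, |ΔVR|, arccos|e<sub>i</sub>·e<sub>j</sub>| / (π/2) )

— min-max-normalized differences of mean diffusivity, fractional
anisotropy and volume ratio, plus the normalized rotation angle between
principal axes. Face-adjacent voxels form a graph with edge weights
w<sub>ij</sub> = exp(−d<sub>ij</sub>ᵀ M d<sub>ij</sub>), M a symmetric
positive semi-definite 4×4 kernel matrix. Seed labels y ∈ {+1, −1} are
hard constraints, and scores f minimize the normalized-Laplacian
smoothness fᵀ L(M) f. Labels and metric are optimized alternately:

1. exact hard-constrained solve of f at fixed M (reduced linear system);
2. projected gradient descent on M at fixed f — each trial step
   M ← Π<sub>PSD</sub>(M − α ∇J) is accepted and α doubled when the cost
   drops, otherwise reverted and α halved —

until a full alternation improves the cost by less than ε (defaults:
α₀ = 0.01, ε = 0.1, M₀ = I). Classical baselines (Euclidean, J-divergence,
geodesic tensor metrics under a Gaussian kernel) run in the same
propagation framework. Accuracy is reported as the Dice similarity
coefficient DSC = 2TP / (2TP + FP + FN).

The package also ships the full synthetic validation protocol: a 15×15
tensor-lattice phantom whose region of interest shares one eigenvalue
triple but mixes principal orientations, Stejskal–Tanner synthesis of 12
diffusion-weighted images at b = 1000 s/mm² (+ b = 0 baseline), Rician
noise at fixed SNR, and linear least-squares tensor re-estimation.

## Worked example

```r
library(dtseg)

ph <- make_phantom()   # 15x15 lattice, 81-voxel ROI, 3 seed strokes

for (m in c("euclidean", "jdivergence", "geodesic")) {
  res <- segment_field(ph$field, ph$labels, method = m)
  cat(sprintf("%-12s DSC = %.4f\n", m, dice(res$seg, ph$truth)))
}
#> euclidean    DSC = 0.8000
#> jdivergence  DSC = 0.8000
#> geodesic     DSC = 0.8000

fit <- learn_metric(ph$field, ph$labels)
fit
#> dtseg_fit: 2 iterations, final cost 0.0160351, converged = TRUE
#> learned kernel diagonal: 1.4672, 1.4672, 1.4672, 0.6697
cat(sprintf("learned DSC = %.4f\n", dice(fit$seg, ph$truth)))
#> learned DSC = 1.0000
```

All three fixed metrics cut the region of interest at its internal
orientation boundary and stop at DSC 0.80; the learned kernel down-weights
the orientation component (last diagonal entry 0.67 vs 1.47 for the
geometry components) and recovers the full region. The same holds on noisy
re-estimated tensors:

```r
fld15 <- noisy_field(ph$field, snr = 15, seed = 1)
res15 <- segment_field(fld15, ph$labels, method = "learned")
dice(res15$seg, ph$truth)
#> [1] 1
```

A thin command-line front end covers the same workflow
(`system.file("scripts", "dtseg", package = "dtseg")` with subcommands
`segment`, `simulate`, `evaluate`, `distances`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the learned-metric
DSC on the clean phantom (`t1`), the median learned-metric DSC over 10
noise seeds at SNR 15 and 20 through the full DWI-synthesis /
Rician-noise / least-squares pipeline (`t2`), and the number of
alternating-optimization iterations at the stated parameters (`t3`).

## Further reading

The methods vignette (`vignettes/metric-learning.Rmd`) documents the model
assumptions, the optimizer's staging and stopping rules, the bandwidth
heuristic for the classical baselines, what the phantom does and does not
emulate, and the handling of degenerate inputs.
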