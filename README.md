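# ieegloc

Semi-automatic localization, numbering and anatomical labeling of
intracranial EEG electrodes (subdural grids, strips and depth arrays) from
a co-registered post-implantation CT and a brain mask, with brain-shift
correction for grids — plus a synthetic CT phantom generator and the
validation statistics needed to quantify the method's accuracy and
reliability without patient data.

**Who it is for.** Epilepsy-surgery and cognitive-neuroscience groups who
record iEEG and need every contact's coordinates in a standard (e.g. MNI)
or native space: a platinum contact leaves a bright, compact artifact in
CT (≫ 1,000 HU), so a thresholded CT inside the brain mask carries enough
information to localize all contacts in minutes rather than hours of manual
clicking. Pre-processing (DICOM conversion, CT–MRI co-registration,
normalization, brain extraction) stays in the usual neuroimaging tools;
this package starts from co-registered NIfTI volumes.

## The method

For each electrode array:

1. **Mask + threshold.** The brain mask is dilated/eroded with a 3×3×3
   cube (`morph_adjust`) — outward for surface grids, inward to shed bright
   skull — and the CT is thresholded at ≥ 1,800 HU by default
   (`threshold_ct`), yielding a voxel cloud (a tibble: voxel index, world
   mm, intensity).
2. **Select.** The array's voxels are isolated programmatically
   (`select_near_points`, `select_box`, `remove_components` with
   26-connected component ids or a minimum size) — the scripted counterpart
   of interactive 3-D lassoing.
3. **Cluster + localize.** K-means (k-means++ seeding, ≥ 10 restarts, best
   within-cluster sum of squares, Lloyd fixpoint) splits the cloud into
   `K = rows × cols` clusters; each contact is its cluster's
   intensity-weighted center of mass:
   `L_k = Σ w_i x_i / Σ w_i`, weights `w_i` the CT intensities.
4. **Number + name.** Depth/strip arrays: order along the first principal
   component, index 1 at the deep tip. Grids: project to the top-2 PCA
   plane, take the convex hull, mark the 4 largest transition angles as
   corners, build an ideal rows × cols grid from the corners (bilinear),
   radially project it onto the least-squares sphere through the contacts,
   assign indices greedily from short to long distances, then refine by
   permuting lattice-adjacent index pairs. Names are `prefix + index`
   ("G1" … "G20"), with `flip_rotate()` for the diagram-determined
   orientation.
5. **Label.** Nearest-voxel lookup in a 4-D probabilistic atlas
   (FSL-layout NIfTI + TSV), ranked probabilities reported as sampled.
6. **Correct brain shift.** Grids are projected to a smoothed cortical
   envelope (mask closing with an 8 mm ball, voxel-face surface, Laplacian
   smoothing) by minimizing
   `Σ_k ||L_k − L_k0||² + Σ_{i<j} a_ij (d_ij − d_ij0)²`
   with every contact constrained to a mesh node; depth contacts follow via
   the Gaussian displacement field
   `F_j = Σ_k w_jk w′_jk D_k / Σ_k w_jk`.

`krippendorff_alpha()` (interval), `gold_standard()`,
`localization_errors()` and `paired_permutation_test()` (sign-flip null)
quantify accuracy and inter-rater reliability.

## Worked example

Simulate a realistic phantom (an 8×8 grid on the 80 mm brain sphere plus a
10-contact depth array, 1 mm CT, noise sd 100 HU), run the pipeline, and
compare against the built-in ground truth:

```r
library(ieegloc)

ph <- standard_phantom(seed = 11, noise_sd = 100)
ph
#> <iel_phantom> 124 x 124 x 128, 2 arrays, 74 contacts, seed 11

arrays <- localize_phantom(ph, threshold = 1800, seed = 11)
arrays$D
#> <iel_electrodes> depth 1x10 ('D'), 10 contacts
#> # A tibble: 10 × 5
#>   index name       x      y     z
#>   <int> <chr>  <dbl>  <dbl> <dbl>
#> 1     1 D1    -15.4   5.78  -49.5
#> 2     2 D2     -8.46  3.23  -42.9
#> 3     3 D3     -1.45  0.471 -36.4
#> 4     4 D4      5.63 -2.09  -29.8
#> # i 6 more rows

tt <- subset(ph$truth, array == "D")
mm <- match_coordinates(el_coords(arrays$D), cbind(tt$x, tt$y, tt$z))
summarize_errors(mm$distance)
#> # A tibble: 1 × 5
#>    mean     sd median   max     n
#>   <dbl>  <dbl>  <dbl> <dbl> <int>
#> 1 0.106 0.0527 0.0871 0.211    10
```

Contact `D1` is the deep tip (the mask's distance transform orients the
array), and the localized coordinates land ~0.1 mm from the true contact
centers despite the noise — the intensity-weighted centroid averages over
~10 voxels per artifact.

Reliability across analysis choices, on one fixed phantom re-analyzed under
five configurations (thresholds 1,200–2,200 HU, mask iterations varied):

```r
rob <- run_robustness_study(seed = 7)
rob$mean_error   # mean distance of each run's coordinates to the run mean
#> [1] 0.097
rob$alpha        # Krippendorff's interval alpha, configurations as raters
#> [1] 0.999993
```

Real CT + mask volumes go through the same functions (`load_volume`,
`load_mask`, `threshold_ct`, `localize_array`, `number_electrodes`,
`label_set`, `project_grid`, `displacement_field`), or declaratively via a
YAML config and `run_pipeline()` / the `exec/ieegloc` command line
(`ieegloc pipeline --config run.yaml`; `ieegloc simulate --seed 3 --out d/`
writes a phantom to disk).

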