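# fluoroshape

Patient-specific 3-D bone reconstruction from **single-plane 2-D projection
sequences**, for researchers in medical image analysis and orthopaedic
biomechanics who want both the bone surface and its per-frame rigid motion
(e.g. during a deep knee bend) without prior CT/MRI.

A single fluoroscopic view cannot be inverted directly: it constrains
in-plane motion and the projected contour well, out-of-plane translation
only through scale, and 3-D shape not at all without a prior.  The package
therefore fits a **nonlinear statistical shape model** to the whole
sequence:

* **Shape prior — kernel PCA.**  Corresponded training meshes
  `x_i ∈ R^{3M}` are mapped implicitly into the feature space of the
  Gaussian kernel `k(a,b) = exp(−‖a−b‖² / 2σ²)`; PCA is performed there by
  solving the eigenproblem of the double-centered kernel matrix `K̄`, with
  dual vectors normalized so `λ_k (α_k·α_k) = 1`.  A shape is encoded by
  `m` nonlinear coordinates `θ`, and decoded by a **preimage
  approximation**: feature-space distances to the training images are
  inverted through the kernel (`d² = −2σ² log[(K_ii+K_jj−d̃²)/2]`) and the
  `n = 10` nearest neighbors give a local least-squares embedding
  (`ẑ = −½ Λ⁻¹ V′ (d² − d0²)`, `x̂ = U ẑ + x̄`).  A linear-PCA baseline is
  included for comparison.
* **Observation model.**  An ideal point-source camera projects a
  candidate mesh; the model image is a per-pixel ray **thickness render**,
  its contour the silhouette boundary; observed edges come from a
  bilateral filter plus Canny detector.
* **Similarity — hybrid energy.**
  `E = −[c₁·Ee + c₂·Er − c₃·Eh − c₄·Ec]`, combining an edge-overlap score,
  a local-cross-correlation region score, a contour homogeneity score and
  a femur/tibia collision penalty (paired condyle–plateau vertex heights
  over the tibial bottom plane).
* **Optimization.**  Derivative-free pattern search in a two-stage
  alternation: per-frame rigid pose with the shape fixed, then one shared
  shape over all frames, with morphotype-aware multi-start and a joint
  shape/pose-offset refinement.  Multi-view (biplane) and multi-body
  (femur + tibia) fitting are supported.

A synthetic **phantom module** generates corresponded, two-cluster,
genuinely nonlinear bone populations and ground-truthed projection
sequences, so every claim above is testable end to end.

## Worked example

```r
library(fluoroshape)

# a corresponded, pose-normalized synthetic population of 20 femora
pop   <- rigid_align_set(sample_population(phantom_config(n_shapes = 20, seed = 1)))
model <- kpca_ssm(pop)
model
#> Kernel-PCA statistical shape model
#>   N = 20 training shapes, 2358 coordinates
#>   sigma = 50.69 mm, m = 9 components

# encode a shape in feature space and decode it again
theta <- predict(model, pop$shapes[[7]])
round(theta, 2)
#>      theta1 theta2 theta3 theta4 theta5 theta6 theta7 theta8 theta9
#> [1,]  -2.49   0.73   0.42   0.43   0.28  -0.65   0.14  -0.49   0.31
xhat <- reconstruct_shape(model, theta)
rms_error(xhat, flatten_shape(pop$shapes[[7]]))
#> 0.241   # mm: the model reproduces one of its own shapes to ~0.2 mm

# a ground-truthed projection sequence, and a fit from a perturbed init
seqn <- simulate_sequence(pop$shapes[[7]],
                          trajectory_config(n_frames = 2, flexion = c(20, 40)),
                          noise_sd = 0.01, seed = 5)
init <- lapply(seqn$true_poses, function(p)
  pose(p$alpha, p$beta, p$gamma + 3, p$tx - 3, p$ty + 3, p$tz))
fit  <- reconstruct_sequence(model, seqn, init,
                             opt = optimizer_config(max_eval = 150,
                                                    max_alternations = 1))
pose_error_stats(fit$poses, seqn$true_poses)
#>    dof   mae        sd
#> Tx  Tx 0.000 0.0000000
#> Ty  Ty 0.000 0.0000000
#> Tz  Tz 0.875 0.1767767
#> Rx  Rx 1.750 1.0606602
#> Ry  Ry 3.000 2.1213203
#> Rz  Rz 1.125 0.1767767
```

The table is the package's standard registration report: mean absolute
error and spread per degree of freedom, translations in mm, rotations in
degrees.  In-plane translation (Tx, Ty) is recovered essentially exactly;
flexion (Rz) to about a degree; the out-of-plane axes (Tz, Ry) are the
weakly observable ones in a single view, exactly as projective geometry
predicts.

A command-line front-end wrapping the same functions lives at
`inst/scripts/fluoroshape.R`
(`train` / `simulate` / `reconstruct` / `evaluate`).

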