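# dhreg — dual-hierarchical patch-based deformable registration of 3D brain volumes

`dhreg` registers 3D grayscale volumes — the motivating case is whole
mouse-brain micro-optical imagery (PI-channel cytoarchitecture), isotropically
downsampled to a 25 µm atlas working resolution and linearly pre-aligned — by
predicting a dense nonlinear displacement field with a patch-based
convolutional network, trained with supervision from known deformation
fields.

## The method

For a fixed (reference) volume $F$ and moving volume $M$, registration seeks
$\phi$ with $F = M\circ\phi$, represented as a per-voxel displacement field
$u$ (voxel units, pull convention: the registered value at voxel $v$ samples
$M$ at $v+u(v)$). Three ideas define the method:

1. **Patch regression.** A dual-branch CNN (InputConv 5³ + PReLU; encoder
   units of 3³ conv + PReLU + stride-2 pooling with feature doubling; branch
   concatenation with dropout; per-component decoder chains and a linear
   OutConn head) maps co-located $w^3$ fixed/moving patches to the central
   $o^3$ displacement block. Dense fields are assembled by sliding-window
   traversal at stride $o$ with **overlap averaging**: block sums $\phi_{temp}$
   divided by superposition counts $W$, then mean-filtered.
2. **Self-feedback sampling.** After pretraining on a fixed grid, the model
   predicts its own training volumes; the per-voxel error
   $\mathrm{DMap}(v)=\lVert G(v)-P(v)\rVert$ is binned to integers, and a
   budget of $A$ extra patches per volume is allocated to bins
   $\propto (1/N(i))^{\alpha}$ — hard, rare error levels get oversampled —
   then the model is fine-tuned on old + new samples.
3. **Two levels.** A coarse model $G$ learns large deformations; its
   predictions on a second training group define residual fields from which
   a fine model $H$ learns; inference applies $M' = H(G(M))$.

Evaluation: Dice overlap of warped region labels, endpoint-error statistics,
correlation-point export, and the Jacobian determinant
$\det(I+\nabla u)$ per voxel — positive everywhere means the deformation is
fold-free (diffeomorphic).

A synthetic module generates textured nested-ellipsoid phantoms, region
labels, and smooth fold-free ground-truth fields (large for level 1, small
residuals for level 2), so the entire pipeline trains and evaluates with no
external data. See `vignettes/methods.Rmd` for modelling choices and limits.

## Worked example

```r
library(dhreg)

# a small synthetic world: 6 coarse-training pairs, 1 validation pair
corpus <- make_dataset(6, 0, 1,
                       phantom = phantom_spec(c(64, 64, 64), seed = 1),
                       large  = field_spec(max_magnitude = 4, smoothness = 10),
                       small  = field_spec(max_magnitude = 1, smoothness = 10),
                       seed = 7)

triples <- lapply(corpus$train1, function(v) {
  v$moving <- histogram_match(v$moving, v$fixed); v
})
samples <- build_training_set(triples, w = 16, o = 9, step = 8, min_sd = 0.04)
cfg <- train_config(epochs = 20, batch_size = 16, learning_rate = 1e-3,
                    step = 8, seed = 1, smooth_radius = 3)
net <- network_config(window = 16, output = 9, base_features = 2,
                      n_encoders = 2, dropout_rate = 0.2, seed = 1)
fit <- pretrain(samples, cfg, net = net)    # 1854 patch pairs, ~7 min on 1 CPU

v <- corpus$val[[1]]
P <- predict_field(fit$model, v$fixed, histogram_match(v$moving, v$fixed),
                   smooth_radius = 3)
mask <- v$fixed$data > 0.02                 # evaluate inside the phantom
round(unlist(endpoint_error_stats(v$gt_field, P, mask))[1:3], 3)
round(unlist(endpoint_error_stats(v$gt_field, zero_field(c(64, 64, 64)),
                                  mask))[1:3], 3)
jacobian_report(P)$n_nonpositive
```

With the seeds above this prints:

```
#>   mean median    max
#>  1.445  1.390  3.230      # registered endpoint error (voxels)
#>   mean median    max
#>  1.893  1.851  4.003      # unregistered baseline
#> [1] 0                     # no folded voxels in the predicted field
```

a ~24 % mean endpoint-error reduction from a seven-minute single-level
toy run (error reduction grows steadily with training budget and corpus
size — the desk-scale pipeline in `tests/testthat/test-acceptance.R`,
20 pairs at 96³ with two levels + self-feedback, reaches ~40-50 %; see
the methods vignette for the compute/accuracy trade-off).

## Command line

```sh
Rscript inst/cli/dhreg simulate     --out corpus/ --seed 7
Rscript inst/cli/dhreg train-level1 --corpus corpus/ --out run/l1 --seed 1
Rscript inst/cli/dhreg feedback     --corpus corpus/ --model run/l1/model_level1.rds --out run/fb
Rscript inst/cli/dhreg train-level2 --corpus corpus/ --model run/fb/model_level1_feedback.rds --out run/l2
Rscript inst/cli/dhreg predict      --model-l1 run/fb/model_level1_feedback.rds \
                                    --model-l2 run/l2/model_level2.rds \
                                    --fixed corpus/val_18/fixed.nii.gz \
                                    --moving corpus/val_18/moving.nii.gz --out-dir run/pred
Rscript inst/cli/dhreg evaluate     --pred-field run/pred/field_level1.nii.gz \
                                    --true-field corpus/val_18/gt_field.nii.gz --out run/eval.json
```

Presets: `desk` (CPU-budget profile used by the tests) and `paper`
(full-scale recipe: window 64 / output 9, step 32, batch 64, lr 1e-4,
200 + 200 epochs, ~2000 feedback pairs per volume at step 48).

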