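# voxelrep

Self-supervised voxel-level representation learning and unsupervised 3D
segmentation for volume microscopy, in R.

## The problem

Volume electron microscopy (FIB-SEM) images whole cells at nanometer
resolution — hundreds of millions of voxels, essentially unannotated.
Subcellular structures have plastic shapes but stereotypical *local
texture*: a small patch of mitochondrial cristae resembles any other, up to
rotation, scale, and intensity changes. `voxelrep` exploits this: it learns,
without any labels, a latent vector for **every voxel** by encoding a small
3D patch centered on it, and clusters those vectors into an unsupervised
segmentation in which major structures (nucleus-like, granule-like,
mitochondria-like textures) emerge as separate classes.

## The method

1. **Sampling** — anchor patches are drawn at random positions and physical
   sizes (4–12 voxels, resampled onto a fixed 16^3 lattice); each anchor
   gets `n_pos` *positives*: patches at the same location (within a 2-voxel
   ball) under random rotation, deformation, size jitter, and photometric
   augmentation.
2. **Model** — a 3D convolutional VAE encodes patches to a Gaussian latent
   `(mu_z, sigma_z)` of dimension `d`; the first `d_MS` dimensions form the
   *semantic subspace*.
3. **Loss** — reconstruction (normalized by batch and patch volume
   `1/(b a^3) ||x - mu_x||^2`) + weighted KL to the standard normal
   (normalized `1/(b d)`) + a **multi-similarity metric loss** applied only
   to the semantic dimensions of `mu_z`, pulling each anchor toward its own
   positives and away from all other patches in the batch:
   positives are weighted by `exp(-alpha (S - lambda))`, negatives by
   `exp(beta (S - lambda))`, with `S` the cosine similarity.
   Restricting the metric signal to a subspace disentangles semantics
   (transformation-invariant, used for clustering) from transformation
   information (kept for reconstruction).
4. **Inference** — every voxel is encoded from its fixed-size (edge 8)
   axis-aligned patch; only `mu_z[1..d_MS]` is kept.
5. **Clustering** — mini-batch k-means over all voxel vectors gives the
   segmentation.
6. **Evaluation** — against a reference labeling: confusion matrix `C`,
   Dice matrix `D_ij = 2 C_ij / (row_i + col_j)`, optimal one-to-one
   matching of clusters to classes by the Hungarian algorithm on cost `-D`,
   reported as the mean Dice over the `min(n_clusters, n_classes)` matched
   pairs.

Everything is testable without external data: a synthetic phantom generator
produces volumes with labeled regions of distinct texture (oriented stripes,
dark blobs, smooth fields, speckle).

## Worked example

```r
library(voxelrep)

# a 64^3 phantom: smooth background, striped tube, blob-filled and
# speckled ellipsoids (labels 0..3)
phantom <- generate_phantom(default_phantom_spec(seed = 7))

# train the patch VAE at desk scale (a few minutes on one CPU)
fit <- train(phantom$volume,
             train_config(anchors_per_stack = 20000,
                          vae = vae_config(latent_dim = 16, semantic_dim = 8),
                          seed = 1))

# is the semantic subspace more transformation-invariant than the rest?
pairs <- generate_transformed_pairs(phantom$volume, phantom$labels,
                                    n_per_class = 4, seed = 2)
subspace_invariance_score(fit$model, pairs, dims_a = 1:8, dims_b = 9:16)
#>   score_a   score_b
#> 0.4302180 0.7345036

# dense per-voxel inference, clustering, evaluation
latent <- encode_volume(fit$model, phantom$volume)
seg <- cluster_latent(latent, cluster_config(k = 4), seed = 3)
evaluate_segmentation(seg, phantom$labels)$match
#> <vxr_match 4 pairs, mean Dice 0.6866>
#>   pred 1 -> ref 1  Dice 0.9246
#>   pred 2 -> ref 2  Dice 0.7549
#>   pred 3 -> ref 4  Dice 0.8082
#>   pred 4 -> ref 3  Dice 0.2588
```

The invariance scores are scale-normalized mean latent displacements under
random rotation/scale/translation of the same physical patch — the semantic
subspace (dims 1–8, trained with the metric loss) moves *less* than the
untouched subspace (dims 9–16), which is the disentanglement the loss is
designed to produce. The `vxr_match` prints the optimal cluster-to-class
assignment and its mean Dice. In this run the background, stripe and
speckle textures are recovered cleanly (Dice 0.75–0.92) while the
blob-field region is the weak class — typical for short desk-scale
training, where run-to-run variation concentrates in one texture class;
see the vignette for what drives this variance and which knobs control it.

A command-line interface wrapping the same functions (subcommands
`simulate`, `train`, `infer`, `cluster`, `evaluate`, `pipeline`) is
installed at `inst/cli/voxelrep.R`, driven by a single YAML configuration
(see `read_pipeline_config()`).

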