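# Shared fixtures: small phantoms, tiny model configs, and a cache of
# desk-scale trained models reused across acceptance checks.

tiny_vae <- function(latent_dim = 8, semantic_dim = 4, seed = 1) {
  vae_init(vae_config(latent_dim = latent_dim, semantic_dim = semantic_dim,
                      encoder_channels = c(2, 3, 4, 5)), seed = seed)
}

# a one-ellipsoid phantom with a smooth noise-free interior
one_region_spec <- function(noise_sd = 0, kind = "smooth", seed = 5, ...) {
  phantom_spec(
    shape = c(32, 32, 32),
    regions = list(
      list(geometry = "background", label = 0L,
           texture = texture_spec("smooth", intensity_mean = 0.6,
                                  intensity_contrast = 0, noise_sd = noise_sd)),
      list(geometry = "ellipsoid", label = 1L, semiaxes = c(10, 9, 8),
           center = c(16, 16, 16),
           texture = texture_spec(kind, intensity_mean = 0.4,
                                  intensity_contrast = 0.3,
                                  noise_sd = noise_sd, ...))
    ),
    seed = seed
  )
}

# desk-scale study conditions: 64^3 four-texture phantom, 20k anchors,
# b = 128, n_pos = 4, d = 16 with 8 semantic dimensions
desk_phantom <- function(seed) {
  generate_phantom(default_phantom_spec(seed = derive_seed(seed, 11)))
}

desk_config <- function(seed) {
  train_config(anchors_per_stack = 20000, batch_anchors = 128, n_pos = 4,
               vae = vae_config(latent_dim = 16, semantic_dim = 8),
               seed = derive_seed(seed, 21))
}

.desk_cache <- new.env(parent = emptyenv())

# train (once per session) the desk-scale model for a given seed; returns
# list(phantom, model, latent, seg4, eval4)
desk_fit <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  ph <- desk_phantom(seed)
  fit <- train(ph$volume, desk_config(seed))
  latent <- encode_volume(fit$model, ph$volume)
  seg <- cluster_latent(latent, cluster_config(4), seed = derive_seed(seed, 41))
  ev <- evaluate_segmentation(seg, ph$labels)
  out <- list(phantom = ph, model = fit$model, log = fit$log, latent = latent,
              seg = seg, eval = ev)
  .desk_cache[[key]] <- out
  out
}
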