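#' Build a pipeline configuration
#'
#' One configuration drives simulate -> train -> infer -> cluster -> evaluate.
#' All stage seeds derive from the single `seed` through fixed offsets, so one
#' integer reproduces the whole run. Unknown fields in `...` override the
#' defaults of the nested configs.
#'
#' @param seed global seed.
#' @param phantom a [phantom_spec()], or `NULL` when training volumes are
#'   supplied directly.
#' @param volumes character vector of volume TIFF paths (alternative to
#'   `phantom`).
#' @param reference path to a reference label TIFF for evaluation (the phantom
#'   supplies its own).
#' @param train a [train_config()].
#' @param ks integer vector of cluster counts to evaluate.
#' @param cluster_batch mini-batch size for clustering.
#' @param chunk inference chunk shape.
#' @return a `vxr_pipeline_config`.
#' @export
pipeline_config <- function(seed = 7, phantom = default_phantom_spec(),
                            volumes = NULL, reference = NULL,
                            train = train_config(), ks = 4,
                            cluster_batch = 10000, chunk = c(16, 16, 16)) {
  structure(list(seed = as.integer(seed), phantom = phantom,
                 volumes = volumes, reference = reference, train = train,
                 ks = as.integer(ks), cluster_batch = cluster_batch,
                 chunk = chunk),
            class = "vxr_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file. Recognized top-level keys: `seed`, `phantom`
#'   (`shape`, `seed`, `noise_sd` for the default four-texture phantom),
#'   `volumes`, `reference`, `ks`, `train` (any [train_config()] argument,
#'   with nested `vae`, `loss`, `augment` blocks).
#' @return a `vxr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 7
  phantom <- NULL
  if (!is.null(y$phantom)) {
    phantom <- default_phantom_spec(
      shape = unlist(y$phantom$shape) %||% c(64, 64, 64),
      seed = y$phantom$seed %||% derive_seed(seed, 11),
      noise_sd = y$phantom$noise_sd %||% 0.02
    )
  } else if (is.null(y$volumes)) {
    phantom <- default_phantom_spec(seed = derive_seed(seed, 11))
  }
  tr <- y$train %||% list()
  vae <- do.call(vae_config, tr$vae %||% list())
  loss <- do.call(loss_config, tr$loss %||% list())
  aug <- do.call(augmentation_config, tr$augment %||% list())
  tr[c("vae", "loss", "augment")] <- NULL
  train <- do.call(train_config, c(tr, list(vae = vae, loss = loss,
                                            augment = aug,
                                            seed = derive_seed(seed, 21))))
  pipeline_config(seed = seed, phantom = phantom,
                  volumes = unlist(y$volumes), reference = y$reference,
                  train = train, ks = unlist(y$ks) %||% 4L)
}

write_meta <- function(path, hash) {
  jsonlite::write_json(list(config_hash = hash), paste0(path, ".meta.json"),
                       auto_unbox = TRUE)
}

meta_matches <- function(path, hash) {
  mp <- paste0(path, ".meta.json")
  file.exists(path) && file.exists(mp) &&
    identical(jsonlite::read_json(mp)$config_hash, hash)
}

#' Run the full pipeline
#'
#' Executes simulate (if a phantom is configured), train, dense inference,
#' clustering at each requested `k`, and evaluation; writes intermediate
#' artifacts and a JSON report to `out_dir`. Every artifact carries a sidecar
#' recording the hash of the configuration that produced it; a stage is
#' re-used on rerun only when its hash matches, which makes every stage
#' resumable and refuses mismatched resumption.
#'
#' @param config a `vxr_pipeline_config` or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param skip_train reuse an existing checkpoint regardless of budget (it
#'   must still match the model configuration hash).
#' @param verbose print stage progress.
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, out_dir, skip_train = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  report <- list(seed = config$seed)

  # --- simulate / load --------------------------------------------------
  ref_labels <- NULL
  if (!is.null(config$phantom)) {
    vol_path <- file.path(out_dir, "phantom.tif")
    lab_path <- file.path(out_dir, "labels.tif")
    h <- rlang::hash(config$phantom)
    if (!meta_matches(vol_path, h)) {
      say("[simulate] generating phantom")
      ph <- tryCatch(generate_phantom(config$phantom),
                     error = function(e) stop("stage 'simulate' failed: ",
                                              conditionMessage(e)))
      write_volume(ph$volume, vol_path)
      write_labels(ph$labels, lab_path)
      write_meta(vol_path, h); write_meta(lab_path, h)
    } else say("[simulate] reusing phantom")
    volumes <- list(read_volume(vol_path))
    ref_labels <- read_labels(lab_path)
  } else {
    volumes <- lapply(config$volumes, read_volume)
    if (!is.null(config$reference)) ref_labels <- read_labels(config$reference)
  }

  # --- train ------------------------------------------------------------
  ckpt <- file.path(out_dir, "model.rds")
  th <- rlang::hash(config$train)
  if (meta_matches(ckpt, th) || (skip_train && file.exists(ckpt))) {
    say("[train] reusing checkpoint")
    model <- load_checkpoint(ckpt)
  } else {
    say("[train] training (%d steps)",
        (config$train$anchors_per_stack * length(volumes)) %/%
          config$train$batch_anchors)
    fit <- tryCatch(train(volumes, config$train, verbose = verbose),
                    error = function(e) stop("stage 'train' failed: ",
                                             conditionMessage(e)))
    model <- fit$model
    save_checkpoint(model, ckpt)
    write_meta(ckpt, th)
    utils::write.csv(fit$log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
    report$final_loss <- as.list(fit$log[nrow(fit$log), ])
  }

  # --- invariance scores (phantom runs only) ----------------------------
  if (!is.null(ref_labels)) {
    dms <- model$config$semantic_dim
    if (model$config$latent_dim >= 2 * dms) {
      pairs <- generate_transformed_pairs(volumes[[1]], ref_labels,
                                          n_per_class = 4,
                                          seed = derive_seed(config$seed, 31))
      sc <- subspace_invariance_score(model, pairs, dims_a = seq_len(dms),
                                      dims_b = dms + seq_len(dms))
      report$invariance <- list(semantic = unname(sc[1]),
                                residual = unname(sc[2]))
      say("[invariance] semantic %.3f vs residual %.3f", sc[1], sc[2])
    }
  }

  # --- infer ------------------------------------------------------------
  lat_path <- file.path(out_dir, "latent.rds")
  ih <- rlang::hash(list(th, config$chunk))
  if (meta_matches(lat_path, ih)) {
    say("[infer] reusing latent volume")
    latent <- readRDS(lat_path)
  } else {
    say("[infer] dense inference")
    latent <- tryCatch(encode_volume(model, volumes[[1]], chunk = config$chunk),
                       error = function(e) stop("stage 'infer' failed: ",
                                                conditionMessage(e)))
    saveRDS(latent, lat_path)
    write_meta(lat_path, ih)
  }

  # --- cluster + evaluate ----------------------------------------------
  report$segmentation <- list()
  for (k in config$ks) {
    say("[cluster] k = %d", k)
    seg <- tryCatch(
      cluster_latent(latent, cluster_config(k, batch_size = config$cluster_batch),
                     seed = derive_seed(config$seed, 41 + k)),
      error = function(e) stop("stage 'cluster' failed: ", conditionMessage(e)))
    write_labels(seg, file.path(out_dir, sprintf("segmentation_k%d.tif", k)))
    entry <- list(k = k)
    if (!is.null(ref_labels)) {
      ev <- evaluate_segmentation(seg, ref_labels)
      entry$mean_dice <- ev$match$mean_dice
      entry$n_matched <- ev$match$n_matched
      entry$matched_dice <- as.numeric(ev$match$dice)
      say("[evaluate] k = %d  mean Dice %.4f", k, ev$match$mean_dice)
    }
    report$segmentation[[as.character(k)]] <- entry
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
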