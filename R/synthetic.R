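#' Texture specification for phantom regions
#'
#' Four texture archetypes mirror the local appearance classes the method is
#' designed to separate in electron microscopy: oriented `stripes`
#' (mitochondria-like cristae), dark `blobs` on a bright surround
#' (granule-like), near-constant `smooth` fields (cytosol-like), and
#' high-frequency `speckle` (nucleus-like chromatin). Each texture is
#' generated with zero mean inside its region and shifted to `intensity_mean`,
#' so with `noise_sd = 0` the mean intensity of a region equals its
#' `intensity_mean` exactly.
#'
#' @param kind one of `"stripes"`, `"blobs"`, `"smooth"`, `"speckle"`.
#' @param period stripe period in voxels (>= 2).
#' @param blob_radius blob radius in voxels (>= 1).
#' @param intensity_mean mean intensity in `[0, 1]`.
#' @param intensity_contrast peak-to-peak texture amplitude as a fraction of
#'   the intensity range, in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param orientation optional unit 3-vector `(z, y, x)` fixing the stripe
#'   normal; `NULL` draws a random orientation per region.
#' @return a `vxr_texture` spec.
#' @export
texture_spec <- function(kind = c("stripes", "blobs", "smooth", "speckle"),
                         period = 4, blob_radius = 2.5, intensity_mean = 0.5,
                         intensity_contrast = 0.3, noise_sd = 0.02,
                         orientation = NULL) {
  kind <- match.arg(kind)
  stopifnot(period >= 2, blob_radius >= 1,
            intensity_mean >= 0, intensity_mean <= 1,
            intensity_contrast >= 0, intensity_contrast <= 1, noise_sd >= 0)
  structure(list(kind = kind, period = period, blob_radius = blob_radius,
                 intensity_mean = intensity_mean,
                 intensity_contrast = intensity_contrast,
                 noise_sd = noise_sd, orientation = orientation),
            class = "vxr_texture")
}

#' Phantom specification
#'
#' Describes a synthetic labeled volume: a background texture (label 0) plus
#' textured regions of simple geometry. Regions are painted in order, so later
#' regions overwrite earlier ones where geometries overlap (documented
#' precedence); random placement uses rejection sampling to avoid overlap.
#'
#' @param shape integer 3-vector `(depth, height, width)`, each `>= 32`.
#' @param regions list of region specs, each a list with fields:
#'   `geometry` (`"ellipsoid"`, `"tube"`, or `"background"`), `texture`
#'   (a [texture_spec()]), `label` (small positive integer; background is 0),
#'   and geometry parameters: `semiaxes` (ellipsoid, 3-vector), `radius` and
#'   `axis` (tube; axis 1=depth, 2=height, 3=width), optional `center`
#'   (explicit placement, 0-based voxel coordinates).
#' @param seed integer seed; all placement and texture randomness derives from
#'   it through fixed per-region offsets.
#' @return a `vxr_phantom_spec`.
#' @export
phantom_spec <- function(shape, regions, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 32))
  labs <- vapply(regions, function(r) as.integer(r$label), integer(1))
  bg <- vapply(regions, function(r) identical(r$geometry, "background"), logical(1))
  if (sum(bg) != 1 || labs[bg] != 0L) stop("exactly one background region with label 0 is required")
  fg <- sort(labs[!bg])
  if (length(fg) > 0 && !identical(fg, seq_along(fg))) {
    stop("foreground labels must be unique and contiguous from 1")
  }
  structure(list(shape = as.integer(shape), regions = regions,
                 seed = as.integer(seed)),
            class = "vxr_phantom_spec")
}

#' Default four-texture phantom
#'
#' A 64^3 volume with a smooth background and three textured regions: a
#' striped tube (mitochondrion-like), a blob-filled ellipsoid (granule
#' field-like) and a speckled ellipsoid (nucleus-like). Intensity means are
#' distinct per class (0.35-0.65) so the segmentation task is well posed while
#' textures, not just intensity, carry class identity.
#'
#' @param shape volume shape, default `c(64, 64, 64)`.
#' @param seed integer seed.
#' @param noise_sd additive Gaussian noise level for all regions.
#' @return a [phantom_spec()].
#' @export
default_phantom_spec <- function(shape = c(64, 64, 64), seed = 7,
                                 noise_sd = 0.02) {
  s <- shape
  regions <- list(
    list(geometry = "background", label = 0L,
         texture = texture_spec("smooth", intensity_mean = 0.55,
                                intensity_contrast = 0, noise_sd = noise_sd)),
    list(geometry = "tube", label = 1L, radius = 0.16 * min(s), axis = 3L,
         center = c(0.75 * s[1], 0.25 * s[2], 0.5 * s[3]),
         texture = texture_spec("stripes", period = 4, intensity_mean = 0.45,
                                intensity_contrast = 0.35, noise_sd = noise_sd)),
    list(geometry = "ellipsoid", label = 2L,
         semiaxes = c(0.22, 0.20, 0.19) * min(s),
         center = c(0.23 * s[1], 0.24 * s[2], 0.32 * s[3]),
         texture = texture_spec("blobs", blob_radius = 2.5,
                                intensity_mean = 0.65,
                                intensity_contrast = 0.4, noise_sd = noise_sd)),
    list(geometry = "ellipsoid", label = 3L,
         semiaxes = c(0.30, 0.27, 0.25) * min(s),
         center = c(0.36 * s[1], 0.63 * s[2], 0.63 * s[3]),
         texture = texture_spec("speckle", intensity_mean = 0.35,
                                intensity_contrast = 0.3, noise_sd = noise_sd))
  )
  phantom_spec(shape, regions, seed = seed)
}

coord_grids <- function(shape) {
  list(z = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]), shape),
       x = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape))
}

ellipsoid_mask <- function(grids, center, semiaxes) {
  ((grids$z - center[1]) / semiaxes[1])^2 +
    ((grids$y - center[2]) / semiaxes[2])^2 +
    ((grids$x - center[3]) / semiaxes[3])^2 <= 1
}

tube_mask <- function(grids, center, radius, axis) {
  ax <- c("z", "y", "x")[setdiff(1:3, axis)]
  ((grids[[ax[1]]] - center[setdiff(1:3, axis)[1]])^2 +
     (grids[[ax[2]]] - center[setdiff(1:3, axis)[2]])^2) <= radius^2
}

place_region <- function(region, grids, shape, occupied, seed) {
  geom <- region$geometry
  make_mask <- function(center) {
    if (geom == "ellipsoid") ellipsoid_mask(grids, center, region$semiaxes)
    else tube_mask(grids, center, region$radius, region$axis)
  }
  fits <- function(center) {
    if (geom == "ellipsoid") {
      all(center - region$semiaxes >= 0) && all(center + region$semiaxes <= shape - 1)
    } else {
      idx <- setdiff(1:3, region$axis)
      all(center[idx] - region$radius >= 0) && all(center[idx] + region$radius <= shape[idx] - 1)
    }
  }
  if (!is.null(region$center)) {
    if (!fits(region$center)) stop("region geometry out of bounds")
    return(make_mask(region$center))
  }
  with_seed(seed, {
    for (attempt in seq_len(1000)) {
      center <- runif(3, 0, shape - 1)
      if (!fits(center)) next
      mask <- make_mask(center)
      if (!any(mask & occupied)) return(mask)
    }
  })
  stop("could not place region (label ", region$label,
       ") without overlap in 1000 attempts")
}

texture_fill <- function(texture, mask, grids, shape, seed) {
  n <- sum(mask)
  if (n == 0) return(numeric(0))
  tx <- with_seed(seed, {
    switch(texture$kind,
      smooth = rep(0, n),
      stripes = {
        u <- texture$orientation %||% {
          v <- rnorm(3); v / sqrt(sum(v^2))
        }
        phase <- (grids$z[mask] * u[1] + grids$y[mask] * u[2] +
                    grids$x[mask] * u[3]) / texture$period
        (texture$intensity_contrast / 2) * sin(2 * pi * phase)
      },
      speckle = runif(n, -texture$intensity_contrast / 2,
                      texture$intensity_contrast / 2),
      blobs = {
        # dark spheres on a bright surround, ~25% volume fraction
        r <- texture$blob_radius
        vol_frac <- 0.25
        bb <- apply(cbind(grids$z[mask], grids$y[mask], grids$x[mask]), 2, range)
        bb_vol <- prod(bb[2, ] - bb[1, ] + 1)
        n_blobs <- max(1, round(vol_frac * bb_vol / (4 / 3 * pi * r^3)))
        cz <- runif(n_blobs, bb[1, 1], bb[2, 1])
        cy <- runif(n_blobs, bb[1, 2], bb[2, 2])
        cx <- runif(n_blobs, bb[1, 3], bb[2, 3])
        val <- rep(texture$intensity_contrast / 2, n)
        pz <- grids$z[mask]; py <- grids$y[mask]; px <- grids$x[mask]
        for (i in seq_len(n_blobs)) {
          inside <- (pz - cz[i])^2 + (py - cy[i])^2 + (px - cx[i])^2 <= r^2
          val[inside] <- -texture$intensity_contrast / 2
        }
        val
      }
    )
  })
  tx <- tx - mean(tx)                     # exact region mean = intensity_mean
  v <- texture$intensity_mean + tx
  if (texture$noise_sd > 0) {
    v <- v + with_seed(derive_seed(seed, 999), rnorm(n, 0, texture$noise_sd))
  }
  v
}

#' Generate a synthetic textured phantom
#'
#' Produces an intensity volume in `[0, 1]` and a matching integer label
#' volume. Each region is filled with its texture plus additive Gaussian
#' noise; output is deterministic for a fixed spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([vxr_volume]) and `labels`
#'   ([vxr_labels]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "vxr_phantom_spec"))
  shape <- spec$shape
  grids <- coord_grids(shape)
  labels <- array(0L, shape)
  fg <- Filter(function(r) r$geometry != "background", spec$regions)
  fg <- fg[order(vapply(fg, function(r) r$label, integer(1)))]
  for (r in fg) {
    mask <- place_region(r, grids, shape, labels > 0, derive_seed(spec$seed, r$label))
    labels[mask] <- r$label                 # later regions overwrite earlier
  }
  vol <- array(0, shape)
  for (r in spec$regions) {
    mask <- labels == r$label
    vol[mask] <- texture_fill(r$texture, mask, grids, shape,
                              derive_seed(spec$seed, 100 + r$label))
  }
  vol <- clamp01(vol)
  cn <- c("background", vapply(fg, function(r) {
    r$name %||% paste0("region", r$label)
  }, character(1)))
  list(volume = vxr_volume(vol), labels = vxr_labels(labels, class_names = cn))
}

#' Sample original/transformed patch pairs per class
#'
#' For evaluating transformation invariance of a learned representation: from
#' each class, patches are sampled at voxels whose full patch support lies
#' inside the volume, then resampled at the same physical location under a
#' random rotation, scale jitter and small translation (the training
#' augmentation ranges).
#'
#' @param volume a [vxr_volume].
#' @param labels matching [vxr_labels].
#' @param n_per_class number of pairs per class.
#' @param seed integer seed.
#' @param config an [augmentation_config()] giving rotation family, scale
#'   jitter and translation radius (`r_pos`). With `rotation = "none"`,
#'   `scale_jitter = c(1, 1)` and `r_pos = 0` the transform is the identity.
#' @param size physical patch edge in voxels (default 8, the inference size).
#' @param classes integer labels to sample from; default all present. A
#'   requested class absent from `labels` is an error.
#' @return list of pairs, each `list(original, transformed, class)` where the
#'   patches are 16^3 arrays.
#' @export
generate_transformed_pairs <- function(volume, labels, n_per_class = 4,
                                       seed = 1, config = augmentation_config(),
                                       size = 8, classes = NULL) {
  vol <- as_volume_array(volume)
  lab <- as_label_array(labels)
  present <- sort(unique(as.vector(lab)))
  classes <- classes %||% present
  absent <- setdiff(classes, present)
  if (length(absent) > 0) {
    stop("class(es) absent from labels: ", paste(absent, collapse = ", "))
  }
  shape <- dim(vol)
  margin <- ceiling(size / 2 * sqrt(3)) + 1  # rotated support stays inside
  pairs <- list()
  with_seed(seed, {
    for (cls in classes) {
      idx <- which(lab == cls)
      zz <- (idx - 1) %% shape[1]
      yy <- ((idx - 1) %/% shape[1]) %% shape[2]
      xx <- (idx - 1) %/% (shape[1] * shape[2])
      ok <- zz >= margin & zz < shape[1] - margin &
        yy >= margin & yy < shape[2] - margin &
        xx >= margin & xx < shape[3] - margin
      if (!any(ok)) {
        stop("class ", cls, " has no voxel with full patch support inside the volume")
      }
      pick <- sample(which(ok), n_per_class, replace = sum(ok) < n_per_class)
      centers <- cbind(zz[pick], yy[pick], xx[pick])
      orig <- extract_patches(vol, centers, A = identity_rows(n_per_class),
                              sizes = rep(size, n_per_class))
      A <- switch(config$rotation,
                  none = identity_rows(n_per_class),
                  axis90 = {
                    g <- rot90_group()
                    g[sample(nrow(g), n_per_class, replace = TRUE), , drop = FALSE]
                  },
                  uniform = random_rotations(n_per_class))
      sizes_t <- size * runif(n_per_class, config$scale_jitter[1], config$scale_jitter[2])
      offs <- sample_ball(n_per_class, config$r_pos)
      trans <- extract_patches(vol, centers + offs, A = A, sizes = sizes_t)
      for (i in seq_len(n_per_class)) {
        pairs[[length(pairs) + 1]] <- list(
          original = array(orig[, i], c(16, 16, 16)),
          transformed = array(trans[, i], c(16, 16, 16)),
          class = cls
        )
      }
    }
  })
  pairs
}
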