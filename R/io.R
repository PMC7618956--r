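#' Construct a volume object
#'
#' A `vxr_volume` is a 3D scalar field in `(depth, height, width)` axis order
#' with isotropic voxel spacing. Intensities are expected in `[0, 1]`; use
#' [normalize_volume()] to map arbitrary scales there.
#'
#' @param data a 3D numeric array `(depth, height, width)`.
#' @param spacing physical size per voxel (isotropic), default 1.
#' @param normalize if `TRUE`, min-max normalize to `[0, 1]`.
#' @return a `vxr_volume` object.
#' @export
vxr_volume <- function(data, spacing = 1, normalize = FALSE) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  if (normalize) data <- normalize_volume(data)
  structure(list(data = data, spacing = spacing), class = "vxr_volume")
}

#' @export
print.vxr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vxr_volume %d x %d x %d (depth x height x width), range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vxr_volume <- function(x) dim(x$data)

#' Min-max normalize intensities to [0, 1]
#'
#' Maps the input minimum to 0 and maximum to 1. A constant input maps to all
#' zeros (the decoder's output range must match the input range, so every
#' volume entering training or inference is normalized this way).
#'
#' @param x numeric array.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_volume <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) return(array(0, dim(x)))
  (x - lo) / (hi - lo)
}

#' Construct a label volume
#'
#' Integer labels per voxel. Label 0 is reserved for "unrecognized" (the
#' residual class); `class_names[1]` therefore names label 0.
#'
#' @param data a 3D integer-valued array.
#' @param class_names optional character vector; `class_names[i]` names label
#'   `i - 1`.
#' @return a `vxr_labels` object.
#' @export
vxr_labels <- function(data, class_names = NULL) {
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (any(data < 0)) stop("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  structure(list(data = data, class_names = class_names), class = "vxr_labels")
}

#' @export
print.vxr_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vxr_labels %d x %d x %d, %d distinct labels>\n",
              d[1], d[2], d[3], length(unique(as.vector(x$data)))))
  if (!is.null(x$class_names)) cat(" classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.vxr_labels <- function(x) dim(x$data)

as_volume_array <- function(volume) {
  if (inherits(volume, "vxr_volume")) volume$data else volume
}

as_label_array <- function(labels) {
  if (inherits(labels, "vxr_labels")) labels$data else labels
}

#' Read a 3D grayscale volume from a multi-page TIFF
#'
#' Pages become the depth axis, giving axis order `(depth, height, width)`.
#' Intensities are min-max normalized to `[0, 1]` on load by default.
#'
#' @param path path to a `.tif`/`.tiff` stack.
#' @param normalize normalize intensities on load (default `TRUE`).
#' @param spacing voxel spacing to record, default 1.
#' @return a [vxr_volume].
#' @export
read_volume <- function(path, normalize = TRUE, spacing = 1) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) {
    stop("unsupported volume format '.", ext, "'; supported formats: .tif, .tiff")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L) {
    stop("non-3D data: TIFF pages must be single-channel 2D images")
  }
  d <- c(length(pages), dim(pages[[1]]))
  vol <- array(0, d)
  for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
  vxr_volume(vol, spacing = spacing, normalize = normalize)
}

#' Write a volume as a 32-bit float multi-page TIFF
#'
#' @param volume a [vxr_volume] or 3D array with values in `[0, 1]`.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  x <- as_volume_array(volume)
  pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read / write integer label volumes as 8-bit TIFF
#'
#' Labels are stored as 8-bit samples (0..255).
#'
#' @param path TIFF path.
#' @param class_names optional class names to attach on read.
#' @return [vxr_labels] for `read_labels`; `path` invisibly for `write_labels`.
#' @export
read_labels <- function(path, class_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  lab <- array(0L, d)
  for (i in seq_along(pages)) lab[i, , ] <- as.integer(round(pages[[i]] * 255))
  vxr_labels(lab, class_names = class_names)
}

#' @param labels a [vxr_labels] or integer array with values in 0..255.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  x <- as_label_array(labels)
  if (max(x) > 255) stop("8-bit label TIFF supports labels 0..255")
  pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Merge per-class binary reference masks into one label volume
#'
#' Reference segmentations often come as one binary mask per class with
#' overlaps (e.g. a manual annotation overlapping an automatic one). Overlaps
#' are resolved by `priority`: a voxel covered by several masks takes the class
#' earliest in `priority` (curated annotation should prevail). Voxels covered
#' by no mask become class `"unrecognized"` with label 0.
#'
#' @param masks named list of binary 3D arrays (one per class), all the same
#'   shape. Names are the class names.
#' @param priority character vector ordering all provided class names from
#'   most to least authoritative.
#' @return a [vxr_labels]; label `i` is the class `names(masks)[i]`, label 0 is
#'   `"unrecognized"`.
#' @export
merge_reference_masks <- function(masks, priority = names(masks)) {
  if (is.null(names(masks)) || any(names(masks) == "")) {
    stop("masks must be a named list")
  }
  shp <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), shp)) stop("mask shape mismatch")
  }
  missing <- setdiff(names(masks), priority)
  if (length(missing) > 0) {
    stop("priority is missing provided classes: ", paste(missing, collapse = ", "))
  }
  out <- array(0L, shp)
  # apply lowest priority first so the earliest-priority class wins overlaps
  for (cls in rev(intersect(priority, names(masks)))) {
    lab <- match(cls, names(masks))
    out[masks[[cls]] != 0] <- lab
  }
  vxr_labels(out, class_names = c("unrecognized", names(masks)))
}

#' Merge minor classes into the unrecognized class
#'
#' Keeps the classes in `major` and relabels every other class to 0
#' ("unrecognized"). With the default protocol of three major organelle
#' classes this yields a 4-class reference (major classes plus unrecognized).
#'
#' @param labels a [vxr_labels] with `class_names`.
#' @param major character vector of class names to keep.
#' @return a [vxr_labels] with labels `0..length(major)`; label `i` is
#'   `major[i]`.
#' @export
coarsen_labels <- function(labels, major) {
  if (length(major) == 0) stop("`major` must name at least one class")
  cn <- labels$class_names
  if (is.null(cn)) stop("labels must carry class_names")
  if (!all(major %in% cn)) {
    stop("unknown class(es): ", paste(setdiff(major, cn), collapse = ", "))
  }
  # map old label value (index into cn minus 1) -> new label
  map <- integer(length(cn))           # default 0 = unrecognized
  for (i in seq_along(major)) map[match(major[i], cn)] <- i
  new <- array(map[labels$data + 1L], dim(labels$data))
  vxr_labels(new, class_names = c("unrecognized", major))
}
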