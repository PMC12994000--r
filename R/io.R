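#' Construct a voxel series
#'
#' @param values `V x N` matrix of voxel time courses.
#' @param coords Optional `V x 3` integer grid coordinates (1-based
#'   internally; written 0-based in tables).
#' @param mask_dim Dimensions of the reference volume.
#' @param reference Optional NIfTI header/image the series was read from.
#' @return A `venc_voxels` object.
#' @export
voxel_series <- function(values, coords = NULL, mask_dim = NULL, reference = NULL) {
  values <- as.matrix(values)
  check_finite(values, "values")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(values)) stop_venc("one coordinate row per voxel required")
    if (anyDuplicated(coords)) stop_venc("duplicate voxel coordinates")
  }
  structure(list(values = values, coords = coords, mask_dim = mask_dim,
                 reference = reference),
            class = "venc_voxels")
}

#' @export
print.venc_voxels <- function(x, ...) {
  cat(sprintf("<venc_voxels> %d voxels x %d volumes\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

binarize_mask <- function(mask, threshold = 0.5) {
  array(as.array(mask) > threshold, dim(mask))
}

same_affine <- function(a, b, tol = 1e-4) {
  xa <- try(RNifti::xform(a), silent = TRUE)
  xb <- try(RNifti::xform(b), silent = TRUE)
  if (inherits(xa, "try-error") || inherits(xb, "try-error")) return(TRUE)
  max(abs(unclass(xa) - unclass(xb))) < tol
}

#' Read a 4-D BOLD NIfTI into a voxel series
#'
#' @param path Path to a 4-D NIfTI-1 file.
#' @param mask Optional path to (or array of) a 3-D mask; values are
#'   binarized at 0.5. Without a mask all voxels are read.
#' @param n_volumes If given, error unless the file holds this many volumes.
#' @return A `venc_voxels` with voxels in rows (mask order, column-major).
#' @export
read_bold <- function(path, mask = NULL, n_volumes = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop_venc("expected a 4-D BOLD image, got %d-D", length(d))
  if (!is.null(n_volumes) && d[4] != n_volumes) {
    stop_venc("file has %d volumes but configuration expects %d", d[4], n_volumes)
  }
  if (!is.null(mask)) {
    if (is.character(mask)) {
      mimg <- RNifti::readNifti(mask)
      if (!same_affine(img, mimg)) {
        stop_venc("affine mismatch between BOLD '%s' and mask '%s'", path, mask)
      }
      mask <- mimg
    }
    mask <- binarize_mask(mask)
    if (!identical(as.integer(dim(mask)), as.integer(d[1:3]))) {
      stop_venc("mask dimensions do not match the BOLD grid")
    }
  } else {
    mask <- array(TRUE, d[1:3])
  }
  idx <- which(mask)
  mat <- matrix(img, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  voxel_series(mat, coords = which(mask, arr.ind = TRUE), mask_dim = d[1:3],
               reference = img)
}

#' Write a voxel-wise map as a 3-D NIfTI volume
#'
#' @param values Per-voxel values, aligned with `coords`.
#' @param coords `V x 3` grid coordinates (1-based), e.g. from a
#'   `venc_voxels` or `venc_rois`.
#' @param dim Volume dimensions.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param reference Optional NIfTI image supplying the header/affine.
#' @param background Fill value outside the map (default 0).
#' @return `path`, invisibly.
#' @export
write_map <- function(values, coords, dim, path, reference = NULL, background = 0) {
  vol <- array(background, dim)
  vol[as.matrix(coords)] <- values
  img <- if (!is.null(reference)) RNifti::asNifti(vol, reference = reference)
  else RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a mask volume
#' @param mask Logical 3-D array.
#' @param path Output path.
#' @return `path` (write) or logical array (read).
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) binarize_mask(RNifti::readNifti(path))

#' Write / read motion parameters as plain text
#'
#' Six columns (three translations, three rotations), one row per volume,
#' whitespace-delimited, no header.
#'
#' @param motion `6 x N` matrix.
#' @param path File path.
#' @return `path` (write) or a `6 x N` matrix (read).
#' @export
write_motion <- function(motion, path) {
  utils::write.table(t(motion), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  t(as.matrix(utils::read.table(path, header = FALSE)))
}

# Versioned single-file array stores for frame and feature series. RDS-backed
# with an explicit layout header so files are self-describing.
STORE_VERSION <- 1L

#' Write / read a frame-sequence store
#' @param x A `venc_frames` (write).
#' @param path File path.
#' @return `path` (write) or the restored object (read).
#' @export
write_frames <- function(x, path) {
  stopifnot(inherits(x, "venc_frames"))
  saveRDS(list(store = "venc_frames", version = STORE_VERSION,
               layout = "frames[H,W,T]; logs length T",
               frames = x$frames, terminal_flags = x$terminal_flags,
               actions = x$actions, rewards = x$rewards, rate_hz = x$rate_hz),
          path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  s <- readRDS(path)
  if (!identical(s$store, "venc_frames")) stop_venc("'%s' is not a frame store", path)
  frame_sequence(s$frames, s$terminal_flags, s$actions, s$rewards, s$rate_hz)
}

#' Write / read a feature-series store
#' @param x A `venc_features` (write).
#' @param path File path.
#' @return `path` (write) or the restored object (read).
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "venc_features"))
  saveRDS(list(store = "venc_features", version = STORE_VERSION,
               layout = "values[U,T]; unit_layer/unit_index length U",
               values = x$values, unit_layer = x$unit_layer,
               unit_index = x$unit_index, rate_hz = x$rate_hz),
          path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  s <- readRDS(path)
  if (!identical(s$store, "venc_features")) stop_venc("'%s' is not a feature store", path)
  feature_series(s$values, s$unit_layer, s$unit_index, s$rate_hz)
}
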