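# Readers and writers: 8/16-bit gray PNG/TIFF and NIfTI volumes (slice-wise).

.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Load a grayscale image
#'
#' Reads an 8/16-bit gray PNG or TIFF, or one slice of a NIfTI volume, and
#' rescales intensities to \eqn{[0, 1]} by \eqn{(v - \min)/(\max - \min)}.
#' All model parameter defaults are interpreted on that scale. A constant
#' image passes through as 0.5 everywhere with a warning.
#'
#' @param path File path (\code{.png}, \code{.tif(f)}, \code{.nii},
#'   \code{.nii.gz}).
#' @param slice For volumes: 1-based slice index along \code{axis}.
#' @param axis Slice axis for volumes (1, 2 or 3; default 3 = axial for
#'   standard orientation).
#' @param channel For multi-channel rasters: which channel to take; an error
#'   is raised for multi-channel input when unset.
#' @return Numeric matrix in \eqn{[0, 1]}.
#' @export
loadImage <- function(path, slice = NULL, axis = 3L, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- if (.isNifti(path)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) arr
    else {
      if (is.null(slice)) stop("NIfTI volume: a 'slice' index is required")
      .extractSlice(arr, slice, axis)
    }
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    .collapseChannels(png::readPNG(path), channel, "PNG")
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    .collapseChannels(tiff::readTIFF(path), channel, "TIFF")
  } else stop("unsupported image format: ", path)
  v <- matrix(as.numeric(v), nrow(v), ncol(v))
  if (any(!is.finite(v))) stop("image contains non-finite values")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image; returning 0.5 everywhere")
    return(matrix(0.5, nrow(v), ncol(v)))
  }
  (v - rng[1]) / (rng[2] - rng[1])
}

.collapseChannels <- function(a, channel, fmt) {
  if (length(dim(a)) == 2L) return(a)
  if (is.null(channel))
    stop(fmt, " image has ", dim(a)[3],
         " channels; pass 'channel' to select one")
  a[, , channel]
}

.extractSlice <- function(arr, slice, axis) {
  nd <- length(dim(arr))
  if (nd != 3L) stop("expected a 3-D volume, got ", nd, " dimensions")
  if (slice < 1L || slice > dim(arr)[axis]) stop("slice index out of range")
  switch(as.integer(axis),
         arr[slice, , ], arr[, slice, ], arr[, , slice])
}

#' Write a grayscale image
#'
#' PNG at 8 or 16 bits, TIFF at 16 bits, or NIfTI. Values are clipped to
#' \eqn{[0, 1]} for raster formats.
#'
#' @param image Numeric matrix.
#' @param path Output path; the extension selects the format.
#' @param bits Bit depth for raster output (8 or 16).
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(image, path, bits = 8L) {
  v <- pmin(pmax(image, 0), 1)
  if (.isNifti(path)) RNifti::writeNifti(RNifti::asNifti(image), path)
  else if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(v, path, dpi = NULL)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(v, path, bits.per.sample = as.integer(bits))
  else stop("unsupported output format: ", path)
  invisible(path)
}

#' Write / read integer label maps
#'
#' Labels are stored in gray PNGs as \code{value = label/255} (exact for up
#' to 255 labels) or in NIfTI as integers. \code{loadLabels} inverts the
#' encoding.
#'
#' @param labels Integer matrix (or logical mask, stored as 0/1).
#' @param path Output path (\code{.png}, \code{.nii}, \code{.nii.gz}).
#' @return \code{saveLabels}: \code{path} invisibly; \code{loadLabels}: an
#'   integer matrix.
#' @export
saveLabels <- function(labels, path) {
  lab <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(lab < 0L) || any(lab > 255L)) stop("labels must be in 0..255")
  if (.isNifti(path)) RNifti::writeNifti(RNifti::asNifti(lab), path)
  else if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(lab / 255, path, dpi = NULL)
  else stop("unsupported label format: ", path)
  invisible(path)
}

#' @rdname saveLabels
#' @export
loadLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (.isNifti(path)) {
    v <- as.array(RNifti::readNifti(path))
    if (length(dim(v)) != 2L) stop("expected a 2-D label map")
    return(matrix(as.integer(round(v)), nrow(v), ncol(v)))
  }
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}
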