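fileExt <- function(path) tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))

#' Read an emission-count image
#'
#' Reads PNG, TIFF or NIfTI (.nii / .nii.gz) grayscale data into a
#' [ScintiImage-class]. PNG and TIFF samples are returned by their readers
#' normalized to [0, 1] and are rescaled by \code{scale} to recover counts;
#' NIfTI voxel values are used as stored. Multi-channel rasters use the
#' first channel; a 3-D NIfTI yields the first slice (use
#' [readScintiVolume()] for stacks).
#'
#' @param path input file.
#' @param scale count value of a full-intensity PNG/TIFF sample
#'   (default 255).
#' @param pixelSpacing pixel spacing in mm (PNG/TIFF only; NIfTI uses the
#'   header).
#' @return A [ScintiImage-class].
#' @export
readScintiImage <- function(path, scale = 255, pixelSpacing = 1) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- fileExt(path)
  if (ext %in% c("png", "tif", "tiff")) {
    v <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    return(scintiImage(v * scale, pixelSpacing = pixelSpacing))
  }
  if (ext == "nii") {
    v <- RNifti::readNifti(path)
    sp <- tryCatch(RNifti::pixdim(v)[1], error = function(e) 1)
    a <- as.array(v)
    a <- array(as.numeric(a), dim(a))
    if (length(dim(a)) == 3L) a <- a[, , 1]
    return(scintiImage(a, pixelSpacing = if (is.finite(sp) && sp > 0) sp else 1))
  }
  stop("unsupported image format: .", ext,
       " (supported: png, tif/tiff, nii/nii.gz)")
}

#' Read a slice stack
#'
#' Reads a 3-D NIfTI file as a [ScintiVolume-class] (third axis = slices,
#' posterior first), or stacks several 2-D files given as a character
#' vector of paths.
#'
#' @param path a 3-D NIfTI file, or a vector of 2-D image paths.
#' @param sliceSpacing slice spacing in mm (taken from the NIfTI header
#'   when available).
#' @inheritParams readScintiImage
#' @return A [ScintiVolume-class].
#' @export
readScintiVolume <- function(path, scale = 255, sliceSpacing = 10) {
  if (length(path) > 1L) {
    return(scintiVolume(lapply(path, readScintiImage, scale = scale),
                        sliceSpacing = sliceSpacing))
  }
  if (fileExt(path) != "nii")
    stop("a single volume file must be NIfTI; give a vector of paths otherwise")
  v <- RNifti::readNifti(path)
  a <- as.array(v)
  a <- array(as.numeric(a), dim(a))
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  sp <- tryCatch(RNifti::pixdim(v)[3], error = function(e) NA_real_)
  if (!is.finite(sp) || sp <= 0) sp <- sliceSpacing
  scintiVolume(lapply(seq_len(dim(a)[3]), function(k) scintiImage(a[, , k])),
               sliceSpacing = sp)
}

#' Write a binary mask
#'
#' Writes a logical mask as an 8-bit PNG (0/255) or a NIfTI volume (0/1),
#' chosen by the file extension.
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output file ending in .png or .nii / .nii.gz.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- (mask != 0) * 1
  ext <- fileExt(path)
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(m), path)
  } else {
    stop("unsupported mask format: .", ext, " (supported: png, nii/nii.gz)")
  }
  invisible(path)
}
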