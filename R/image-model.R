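#' Construct an emission-count image
#'
#' @param values numeric matrix of non-negative counts (rows = image rows,
#'   origin top-left).
#' @param pixelSpacing in-plane pixel spacing in millimetres.
#' @return A [ScintiImage-class] object.
#' @examples
#' img <- scintiImage(matrix(rpois(100, 5), 10, 10))
#' dim(img)
#' @export
scintiImage <- function(values, pixelSpacing = 1) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ScintiImage", values = values, pixelSpacing = as.numeric(pixelSpacing))
}

#' Construct a slice stack
#'
#' @param slices list of [ScintiImage-class] objects (or numeric matrices)
#'   with identical dimensions; slice 1 is the posterior-most slice.
#' @param sliceSpacing spacing between slice centres in millimetres.
#' @return A [ScintiVolume-class] object.
#' @export
scintiVolume <- function(slices, sliceSpacing = 10) {
  slices <- lapply(slices, function(s)
    if (is(s, "ScintiImage")) s else scintiImage(s))
  new("ScintiVolume", slices = slices, sliceSpacing = as.numeric(sliceSpacing))
}

#' Split the image domain into segmentation and model regions
#'
#' Divides the image domain M into phi_s (the part containing the kidney(s),
#' on which the labeling is optimized) and its complement phi_s-bar (the
#' "safety" tissue whose intensity distribution defines the background
#' model). Single-kidney choices use a vertical dividing line; the
#' two-kidneys choice uses a horizontal line, with phi_s the band holding
#' both kidneys.
#'
#' Orientation is a single documented convention: side choices name the
#' patient's anatomical side, and images are assumed displayed in the
#' standard radiological orientation where the patient's left appears on
#' the viewer's right. "left_kidney" therefore selects the right half of
#' the displayed image and "right_kidney" the left half. Set
#' \code{flip = TRUE} for data stored in the mirrored orientation.
#'
#' @param image a [ScintiImage-class].
#' @param sideChoice "left_kidney", "right_kidney" or "two_kidneys".
#' @param splitIndex optional 1-based coordinate of the first column (or row,
#'   for "two_kidneys") of the second block; defaults to the midline.
#' @param kidneyBand for "two_kidneys": which horizontal band contains the
#'   kidneys, "lower" (default; matches the pelvic presets) or "upper".
#' @param flip flip the left/right naming convention.
#' @return A [DomainPartition-class].
#' @examples
#' img <- scintiImage(matrix(1, 10, 10))
#' p <- splitDomain(img, "right_kidney")
#' sum(phiS(p))  # 50: columns 1-5 (patient right = viewer left)
#' @export
splitDomain <- function(image,
                        sideChoice = c("left_kidney", "right_kidney",
                                       "two_kidneys"),
                        splitIndex = NULL,
                        kidneyBand = c("lower", "upper"),
                        flip = FALSE) {
  stopifnot(is(image, "ScintiImage"))
  sideChoice <- match.arg(sideChoice)
  kidneyBand <- match.arg(kidneyBand)
  d <- dim(image@values)
  horizontal <- sideChoice == "two_kidneys"
  extent <- if (horizontal) d[1] else d[2]
  if (is.null(splitIndex)) splitIndex <- extent %/% 2L + 1L
  splitIndex <- as.integer(splitIndex)
  if (splitIndex <= 1L || splitIndex > extent)
    stop("invalid partition: split line must lie strictly inside the image")
  firstBlock <- matrix(FALSE, d[1], d[2])
  if (horizontal) firstBlock[seq_len(splitIndex - 1L), ] <- TRUE
  else            firstBlock[, seq_len(splitIndex - 1L)] <- TRUE
  phiSisFirst <- switch(sideChoice,
    left_kidney  = flip,
    right_kidney = !flip,
    two_kidneys  = kidneyBand == "upper")
  phi <- if (phiSisFirst) firstBlock else !firstBlock
  new("DomainPartition", phiS = phi, phiSbar = !phi,
      splitKind = if (horizontal) "horizontal" else "vertical",
      splitIndex = splitIndex, sideChoice = sideChoice)
}
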