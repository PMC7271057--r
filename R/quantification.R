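#' Background-noise correction of a renal ROI count
#'
#' Subtracts the per-pixel background rate, estimated from a background
#' ROI, scaled to the size of the renal ROI:
#' Q_BC = Q_b - N_Qb * (Q_F / N_QF). The raw value may be negative on noisy
#' inputs; set \code{clamp = TRUE} to clamp at zero (a warning is issued).
#'
#' @param qb total count inside the renal ROI.
#' @param nqb pixel count of the renal ROI (>= 1).
#' @param qf total count inside the background ROI.
#' @param nqf pixel count of the background ROI (>= 1).
#' @param clamp clamp negative corrected counts to zero.
#' @return The corrected count.
#' @examples
#' backgroundCorrect(1000, 100, 200, 100)  # 800
#' @export
backgroundCorrect <- function(qb, nqb, qf, nqf, clamp = FALSE) {
  if (nqb < 1 || nqf < 1)
    stop("ROI pixel counts must be >= 1")
  if (qb < 0 || qf < 0) stop("counts must be non-negative")
  out <- qb - nqb * qf / nqf
  if (clamp && out < 0) {
    warning("negative background-corrected count clamped to 0")
    out <- 0
  }
  out
}

#' Attenuation correction of paired anterior/posterior counts
#'
#' Default mode combines the two views by the geometric-mean method:
#' Q_AC = sqrt(C_ant * C_post) * exp(mu * T / 2), which exactly recovers
#' the source count under the symmetric exponential model
#' C_post = C0 exp(-mu d), C_ant = C0 exp(-mu (T - d)). Mode "literal"
#' instead evaluates C_ant * C_post * exp(mu d) (a dimensionally
#' inconsistent form kept only for reproduction of legacy reports).
#'
#' @param cAnt,cPost anterior and posterior counts (>= 0).
#' @param mu linear attenuation coefficient, 1/cm.
#' @param depth kidney depth from the posterior surface, cm (used by the
#'   "literal" mode only).
#' @param thickness anteroposterior body thickness, cm (used by the
#'   geometric-mean mode).
#' @param mode "geometric_mean" (default) or "literal".
#' @return The corrected count.
#' @examples
#' c0 <- 1000; mu <- 0.15; d <- 7; T <- 20
#' attenuationCorrect(c0 * exp(-mu * (T - d)), c0 * exp(-mu * d),
#'                    mu, thickness = T)  # 1000
#' @export
attenuationCorrect <- function(cAnt, cPost, mu, depth = NULL,
                               thickness = NULL,
                               mode = c("geometric_mean", "literal")) {
  mode <- match.arg(mode)
  if (cAnt < 0 || cPost < 0) stop("counts must be non-negative")
  if (mu < 0) stop("mu must be non-negative")
  if (mode == "geometric_mean") {
    if (is.null(thickness) || thickness <= 0)
      stop("geometric-mean correction needs a positive body thickness")
    sqrt(cAnt * cPost) * exp(mu * thickness / 2)
  } else {
    if (is.null(depth) || depth <= 0)
      stop("the literal form needs a positive kidney depth")
    cAnt * cPost * exp(mu * depth)
  }
}

#' Relative renal function split
#'
#' Each kidney's percentage share of the total corrected counts; the two
#' percentages sum to 100 exactly.
#'
#' @param qRight,qLeft corrected per-side counts (>= 0, not both zero).
#' @return Named numeric(2): \code{right} and \code{left} percentages.
#' @examples
#' relativeFunction(600, 400)  # 60 / 40
#' @export
relativeFunction <- function(qRight, qLeft) {
  if (qRight < 0 || qLeft < 0) stop("corrected counts must be non-negative")
  tot <- qRight + qLeft
  if (tot <= 0)
    stop("relative function undefined: both corrected counts are zero")
  rfr <- qRight / tot * 100
  c(right = rfr, left = 100 - rfr)
}

# Coerce per-side masks to a list of per-slice logical matrices.
sliceMasks <- function(masks, nSlices, d) {
  if (is.array(masks) && length(dim(masks)) == 3L)
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) != nSlices)
    stop("mask list length must equal the number of slices")
  lapply(masks, function(m) {
    if (!identical(dim(m), d)) stop("mask dimensions must match the slices")
    m != 0
  })
}

#' Tomographic relative renal function
#'
#' Sums raw reconstructed counts inside per-side kidney masks across all
#' slices and converts the two totals into a relative-function split. No
#' background or attenuation correction is applied: the segmentation
#' excludes surrounding background, and the reconstruction is assumed to
#' be attenuation-corrected upstream.
#'
#' @param volume a [ScintiVolume-class] (a [ScintiImage-class] is treated
#'   as a single-slice volume).
#' @param rightMasks,leftMasks per-side masks: a logical matrix, a list of
#'   per-slice matrices, or a 3-D array.
#' @return A [QuantReport-class] with method "tomographic".
#' @export
tomographicRF <- function(volume, rightMasks, leftMasks) {
  if (is(volume, "ScintiImage"))
    volume <- scintiVolume(list(volume), sliceSpacing = 1)
  d <- dim(volume@slices[[1]]@values)
  ns <- length(volume@slices)
  rm_ <- sliceMasks(rightMasks, ns, d)
  lm_ <- sliceMasks(leftMasks, ns, d)
  sumSide <- function(ms) sum(vapply(seq_len(ns), function(k)
    sum(volume@slices[[k]]@values[ms[[k]]]), numeric(1)))
  qr <- sumSide(rm_); ql <- sumSide(lm_)
  if (all(!vapply(rm_, any, logical(1))) && all(!vapply(lm_, any, logical(1))))
    stop("relative function undefined: both side masks are empty")
  rf <- relativeFunction(qr, ql)
  new("QuantReport", qBC = numeric(0),
      qAC = c(right = qr, left = ql),
      rfRight = rf[["right"]], rfLeft = rf[["left"]],
      method = "tomographic", flags = character(0))
}

#' Kidney depth estimate from a segmented volume
#'
#' Distance, along the posterior-to-anterior stack axis, from the posterior
#' body surface (the outer face of slice 1) to the centre of mass of the
#' kidney mask, in cm. Slice centres lie at (k - 0.5) * spacing from the
#' posterior surface.
#'
#' @param volume a [ScintiVolume-class].
#' @param masks kidney mask per slice (matrix, list or 3-D array).
#' @return Depth in cm.
#' @export
estimateDepth <- function(volume, masks) {
  ns <- length(volume@slices)
  d <- dim(volume@slices[[1]]@values)
  ms <- sliceMasks(masks, ns, d)
  vox <- vapply(ms, sum, numeric(1))
  if (sum(vox) == 0) stop("degenerate mask: no kidney voxels")
  com <- sum(seq_len(ns) * vox) / sum(vox)
  (com - 0.5) * volume@sliceSpacing / 10
}

#' Construct a planar anterior/posterior study
#'
#' @param anterior,posterior [ScintiImage-class] count images (the anterior
#'   view on the same, unmirrored pixel grid as the posterior view).
#' @param roiRight,roiLeft per-side kidney ROI masks.
#' @param bgRight,bgLeft per-side background ROI masks, disjoint from the
#'   kidney ROIs.
#' @param depthRight,depthLeft kidney depths from the posterior surface, cm.
#' @param thickness anteroposterior body thickness, cm.
#' @param mu linear attenuation coefficient, 1/cm. The default 1.43 is the
#'   value used in the clinical-routine protocol this mirrors; note it is
#'   far above soft-tissue attenuation at 140 keV (about 0.15/cm), so
#'   physical simulations should pass mu explicitly.
#' @return A [PlanarStudy-class].
#' @export
planarStudy <- function(anterior, posterior, roiRight, roiLeft,
                        bgRight, bgLeft, depthRight, depthLeft,
                        thickness, mu = 1.43) {
  new("PlanarStudy", anterior = anterior, posterior = posterior,
      roiRight = roiRight != 0, roiLeft = roiLeft != 0,
      bgRight = bgRight != 0, bgLeft = bgLeft != 0,
      depthRight = as.numeric(depthRight), depthLeft = as.numeric(depthLeft),
      thickness = as.numeric(thickness), mu = as.numeric(mu))
}

#' Clinical-routine planar relative renal function
#'
#' The standard planar pipeline: per side and per view, the ROI count is
#' background-corrected from the paired background ROI; the corrected
#' anterior and posterior counts are then combined by the geometric-mean
#' attenuation correction (or the literal legacy form), and the two
#' corrected totals yield the relative-function split.
#'
#' @param study a [PlanarStudy-class].
#' @param mode attenuation mode, see [attenuationCorrect()].
#' @param clamp clamp negative background-corrected counts to zero
#'   (default TRUE; flagged in the report).
#' @return A [QuantReport-class] with method "planar".
#' @export
planarRF <- function(study, mode = c("geometric_mean", "literal"),
                     clamp = TRUE) {
  mode <- match.arg(mode)
  views <- list(ant = study@anterior@values, post = study@posterior@values)
  rois <- list(right = study@roiRight, left = study@roiLeft)
  bgs <- list(right = study@bgRight, left = study@bgLeft)
  depths <- c(right = study@depthRight, left = study@depthLeft)
  qbc <- numeric(0)
  flags <- character(0)
  qac <- c(right = NA_real_, left = NA_real_)
  for (side in c("right", "left")) {
    cc <- numeric(2); names(cc) <- names(views)
    for (vw in names(views)) {
      v <- views[[vw]]
      raw <- backgroundCorrect(sum(v[rois[[side]]]), sum(rois[[side]]),
                               sum(v[bgs[[side]]]), sum(bgs[[side]]))
      if (raw < 0 && clamp) {
        raw <- 0
        flags <- unique(c(flags, "negative_counts_clamped"))
      }
      cc[vw] <- raw
      qbc[paste(side, vw, sep = "_")] <- raw
    }
    qac[side] <- attenuationCorrect(cc["ant"], cc["post"], study@mu,
                                    depth = depths[[side]],
                                    thickness = study@thickness, mode = mode)
  }
  rf <- relativeFunction(qac[["right"]], qac[["left"]])
  new("QuantReport", qBC = qbc, qAC = qac,
      rfRight = rf[["right"]], rfLeft = rf[["left"]],
      method = "planar", flags = flags)
}
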