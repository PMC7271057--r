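#' @import methods
NULL

#' Emission-count image
#'
#' A 2-D grid of non-negative photon counts as acquired by a gamma camera.
#' Values are stored as a numeric matrix in row/column (y/x) order with the
#' origin at the top-left of the displayed image.
#'
#' @slot values numeric matrix of non-negative, finite counts.
#' @slot pixelSpacing numeric(1), in-plane pixel spacing in millimetres.
#'
#' @seealso [scintiImage()] for the user constructor, [splitDomain()],
#'   [optimizeLabeling()].
#' @export
setClass("ScintiImage",
  representation(values = "matrix", pixelSpacing = "numeric"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 2L || ncol(v) < 2L) return("image must be at least 2x2")
    if (any(!is.finite(v))) return("all counts must be finite")
    if (any(v < 0)) return("counts must be non-negative")
    if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
        object@pixelSpacing <= 0)
      return("'pixelSpacing' must be a single positive number")
    TRUE
  })

#' Stack of emission-count slices
#'
#' An ordered stack of equally sized [ScintiImage-class] slices, as produced
#' by a tomographic acquisition. Slice 1 is taken to lie at the posterior
#' body surface and the stack axis runs posterior to anterior.
#'
#' @slot slices list of [ScintiImage-class] objects with common dimensions.
#' @slot sliceSpacing numeric(1), spacing between slice centres in
#'   millimetres.
#' @export
setClass("ScintiVolume",
  representation(slices = "list", sliceSpacing = "numeric"),
  validity = function(object) {
    if (length(object@slices) < 1L) return("volume needs at least one slice")
    ok <- vapply(object@slices, is, logical(1), class2 = "ScintiImage")
    if (!all(ok)) return("all slices must be ScintiImage objects")
    d <- vapply(object@slices, function(s) dim(s@values), integer(2))
    if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
      return("all slices must share the same dimensions")
    if (length(object@sliceSpacing) != 1L || object@sliceSpacing <= 0)
      return("'sliceSpacing' must be a single positive number")
    TRUE
  })

#' Segmentation domain partition
#'
#' The split of the image domain M into the region to segment (phi_s, which
#' contains the kidney(s)) and the complement model region (phi_s-bar, the
#' surrounding "safety" tissue whose intensity distribution defines the
#' background model). The two masks are disjoint, jointly cover M, and are
#' both non-empty.
#'
#' @slot phiS logical matrix, TRUE on the region to be segmented.
#' @slot phiSbar logical matrix, TRUE on the model region.
#' @slot splitKind "vertical" or "horizontal".
#' @slot splitIndex integer(1), first column (vertical) or row (horizontal)
#'   of the second block of the split.
#' @slot sideChoice one of "left_kidney", "right_kidney", "two_kidneys".
#' @export
setClass("DomainPartition",
  representation(phiS = "matrix", phiSbar = "matrix", splitKind = "character",
                 splitIndex = "integer", sideChoice = "character"),
  validity = function(object) {
    a <- object@phiS; b <- object@phiSbar
    if (!is.logical(a) || !is.logical(b)) return("masks must be logical")
    if (!identical(dim(a), dim(b))) return("mask dimensions differ")
    if (any(a & b)) return("phiS and phiSbar must be disjoint")
    if (!all(a | b)) return("phiS and phiSbar must cover the whole domain")
    if (!any(a) || !any(b)) return("both parts of the partition must be non-empty")
    if (!object@splitKind %in% c("vertical", "horizontal"))
      return("splitKind must be 'vertical' or 'horizontal'")
    if (!object@sideChoice %in% c("left_kidney", "right_kidney", "two_kidneys"))
      return("unknown sideChoice")
    TRUE
  })

#' Intensity kernel specification
#'
#' The kernel used for density estimation over intensities: a Gaussian of
#' bandwidth \code{sigma}, or a Dirac kernel which reduces the estimate to a
#' normalized histogram. \code{sigma = NA} requests the default bandwidth of
#' twice the bin width, resolved when the kernel is applied to a binning.
#'
#' @slot kind "gaussian" or "dirac".
#' @slot sigma numeric(1) bandwidth in intensity units (Gaussian only);
#'   NA means "auto" (2 x bin width).
#' @export
setClass("KernelSpec",
  representation(kind = "character", sigma = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("gaussian", "dirac"))
      return("kind must be 'gaussian' or 'dirac'")
    if (object@kind == "gaussian" && !is.na(object@sigma) &&
        object@sigma <= 0)
      return("sigma must be > 0 for a gaussian kernel")
    TRUE
  })

#' Discrete intensity distribution
#'
#' A proper probability distribution over intensity bins: strictly
#' increasing bin centers and non-negative probabilities summing to one
#' (within 1e-9).
#'
#' @slot binCenters numeric, strictly increasing intensity values.
#' @slot probabilities numeric, non-negative, one per bin, summing to 1.
#' @export
setClass("IntensityDistribution",
  representation(binCenters = "numeric", probabilities = "numeric"),
  validity = function(object) {
    z <- object@binCenters; p <- object@probabilities
    if (length(z) != length(p)) return("lengths of centers and probabilities differ")
    if (length(z) < 1L) return("at least one bin required")
    if (length(z) > 1L && any(diff(z) <= 0))
      return("bin centers must be strictly increasing")
    if (any(p < 0)) return("probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1 (within 1e-9)")
    TRUE
  })

#' Segmentation energy parameters
#'
#' Tunables of the distribution-matching energy C(L) = -B(P_E, D) +
#' gamma * E(L) and of its bound optimizer.
#'
#' @slot gamma numeric(1) >= 0, smoothness weight; NA means "auto",
#'   resolved at run time to 0.5 / |phi_s| so the boundary-length prior is
#'   commensurate with the [-1, 0] matching term.
#' @slot kernel a [KernelSpec-class].
#' @slot connectivity 4 or 8 neighbours; diagonal pairs are weighted
#'   1/sqrt(2) (inverse Euclidean distance).
#' @slot epsilon numeric(1) > 0, convergence tolerance on the energy
#'   decrease.
#' @slot maxIter integer(1) >= 1, ceiling on optimizer iterations.
#' @slot nBins integer(1), number of intensity bins.
#' @export
setClass("EnergyParams",
  representation(gamma = "numeric", kernel = "KernelSpec",
                 connectivity = "integer", epsilon = "numeric",
                 maxIter = "integer", nBins = "integer"),
  validity = function(object) {
    if (!is.na(object@gamma) && object@gamma < 0) return("gamma must be >= 0")
    if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
    if (object@epsilon <= 0) return("epsilon must be > 0")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    if (object@nBins < 1L) return("nBins must be >= 1")
    TRUE
  })

#' Segmentation result
#'
#' The output of [optimizeLabeling()]: the final binary labeling over
#' phi_s (1 = background-matching region E, 0 = kidney candidate), the
#' extracted kidney mask (complement of E within phi_s), the energy trace
#' of the descent, and the final values of both energy terms.
#'
#' @slot labels integer matrix over the image domain; 0/1 on phi_s pixels
#'   and NA elsewhere.
#' @slot kidneyMask logical matrix over the image domain, a subset of phi_s.
#' @slot energyTrace numeric, C(L) per iteration (non-increasing).
#' @slot iterations integer(1), number of descent iterations performed.
#' @slot matchingTerm numeric(1), final value of -B(P_E, D).
#' @slot smoothnessTerm numeric(1), final boundary-length prior E(L).
#' @slot converged logical(1).
#' @slot shrinkMonotone logical(1), TRUE when every iterate removed pixels
#'   from E only (always the case for the shrink optimizer; recorded from
#'   the actual label history).
#' @slot flags character, diagnostic flags such as "empty_kidney_mask".
#' @export
setClass("SegmentationResult",
  representation(labels = "matrix", kidneyMask = "matrix",
                 energyTrace = "numeric", iterations = "integer",
                 matchingTerm = "numeric", smoothnessTerm = "numeric",
                 converged = "logical", shrinkMonotone = "logical",
                 flags = "character"),
  validity = function(object) {
    tr <- object@energyTrace
    if (length(tr) >= 2L && any(diff(tr) > 1e-9))
      return("energy trace must be non-increasing")
    if (any(object@kidneyMask & is.na(object@labels)))
      return("kidney mask must lie inside phi_s")
    TRUE
  })

#' Paired anterior/posterior planar study
#'
#' Inputs of the clinical-routine planar quantification: anterior and
#' posterior count images, per-side kidney and background ROIs (applied to
#' both views), per-side kidney depths, body thickness, and the linear
#' attenuation coefficient.
#'
#' @slot anterior,posterior [ScintiImage-class] views with common
#'   dimensions. The anterior view is stored unmirrored, i.e. on the same
#'   pixel grid as the posterior view.
#' @slot roiRight,roiLeft logical matrices, kidney ROIs per side.
#' @slot bgRight,bgLeft logical matrices, background ROIs per side,
#'   disjoint from the kidney ROIs.
#' @slot depthRight,depthLeft numeric(1), kidney depth from the posterior
#'   surface in cm.
#' @slot thickness numeric(1), anteroposterior body thickness in cm.
#' @slot mu numeric(1), linear attenuation coefficient in 1/cm.
#' @export
setClass("PlanarStudy",
  representation(anterior = "ScintiImage", posterior = "ScintiImage",
                 roiRight = "matrix", roiLeft = "matrix",
                 bgRight = "matrix", bgLeft = "matrix",
                 depthRight = "numeric", depthLeft = "numeric",
                 thickness = "numeric", mu = "numeric"),
  validity = function(object) {
    d <- dim(object@anterior@values)
    masks <- list(object@roiRight, object@roiLeft, object@bgRight, object@bgLeft)
    if (!identical(d, dim(object@posterior@values)))
      return("anterior and posterior views must share dimensions")
    for (m in masks) {
      if (!is.logical(m) || !identical(dim(m), d))
        return("ROI masks must be logical matrices matching the image")
    }
    if (any(object@roiRight & object@bgRight) || any(object@roiLeft & object@bgLeft))
      return("kidney and background ROIs must be disjoint within each side")
    if (object@mu <= 0) return("mu must be > 0")
    if (object@thickness <= 0) return("thickness must be > 0")
    if (object@depthRight <= 0 || object@depthLeft <= 0)
      return("depths must be > 0")
    if (object@depthRight > object@thickness || object@depthLeft > object@thickness)
      return("depth cannot exceed body thickness")
    TRUE
  })

#' Relative renal function report
#'
#' Corrected per-side counts and the relative function split. The two
#' percentages sum to 100 by construction.
#'
#' @slot qBC numeric, background-corrected counts (planar: named per
#'   side/view; tomographic: empty).
#' @slot qAC named numeric(2), attenuation-corrected (planar) or raw
#'   in-mask (tomographic) counts, names "right" and "left".
#' @slot rfRight,rfLeft numeric(1), relative function percentages.
#' @slot method "planar" or "tomographic".
#' @slot flags character, e.g. "negative_counts_clamped".
#' @export
setClass("QuantReport",
  representation(qBC = "numeric", qAC = "numeric", rfRight = "numeric",
                 rfLeft = "numeric", method = "character", flags = "character"),
  validity = function(object) {
    if (!object@method %in% c("planar", "tomographic"))
      return("method must be 'planar' or 'tomographic'")
    if (abs(object@rfRight + object@rfLeft - 100) > 1e-9)
      return("relative function percentages must sum to 100")
    if (object@rfRight < 0 || object@rfRight > 100 ||
        object@rfLeft < 0 || object@rfLeft > 100)
      return("relative function percentages must lie in [0, 100]")
    TRUE
  })

#' Method-agreement statistics
#'
#' Bland-Altman bias and limits of agreement, two-way random-effects
#' absolute-agreement intraclass correlation (single and average measures,
#' with F-based 95% confidence intervals), and the Pearson fit of one
#' series on the other.
#'
#' @slot bias mean difference a - b.
#' @slot loaLow,loaHigh limits of agreement (bias -/+ 1.96 sd).
#' @slot iccSingle,iccAverage intraclass correlation coefficients.
#' @slot ciSingle,ciAverage numeric(2) 95% confidence bounds.
#' @slot pearsonR,slope,intercept Pearson correlation and OLS fit of b on a.
#' @slot flags character, e.g. "degenerate_variance".
#' @export
setClass("AgreementResult",
  representation(bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 iccSingle = "numeric", iccAverage = "numeric",
                 ciSingle = "numeric", ciAverage = "numeric",
                 pearsonR = "numeric", slope = "numeric",
                 intercept = "numeric", flags = "character"),
  validity = function(object) {
    if (is.finite(object@bias) &&
        (object@loaLow > object@bias + 1e-12 ||
         object@loaHigh < object@bias - 1e-12))
      return("limits of agreement must bracket the bias")
    if (is.finite(object@iccSingle) && object@iccSingle > 1 + 1e-12)
      return("ICC cannot exceed 1")
    TRUE
  })

#' Synthetic phantom specification
#'
#' Geometry, emission rates and acquisition parameters of a seeded
#' scintigraphy phantom. Kidneys are elliptical high-count regions over a
#' low-count Poisson background; presets emulate normal anatomy, a pelvic
#' (ectopic) kidney with depth/thickness asymmetry and a posterior bone
#' insert, and a hydronephrotic kidney (ring-shaped uptake with a cold
#' centre and an elevated peri-renal background patch).
#'
#' @slot preset "normal", "ectopic" or "hydronephrotic".
#' @slot size integer(1), image side length in pixels.
#' @slot seed integer(1), RNG seed; every generator path is deterministic
#'   given the seed.
#' @slot backgroundRate numeric(1), background counts/pixel.
#' @slot kidneyRateLeft,kidneyRateRight numeric(1), additional counts/pixel
#'   inside each kidney (right rate is solved from \code{trueSplit}).
#' @slot trueSplit named numeric(2), ground-truth relative-function split
#'   in percent (right, left), summing to 100.
#' @slot centers 2x2 numeric matrix (rows: right, left) of ellipse centres
#'   (row, col).
#' @slot axes 2x2 numeric matrix (rows: right, left) of ellipse semi-axes
#'   (row, col) in pixels.
#' @slot ringInner numeric(1), inner-to-outer radius ratio of the
#'   hydronephrotic ring (0 for filled kidneys).
#' @slot depths named numeric(2), kidney depth from the posterior surface
#'   in cm (right, left).
#' @slot thickness numeric(1), nominal anteroposterior body thickness in cm.
#' @slot effThickness named numeric(2), effective per-side thickness in cm
#'   (differs from \code{thickness} for the pelvic side of ectopic presets).
#' @slot boneAtten named numeric(2), extra attenuation exponent (mu_bone x
#'   bone thickness, dimensionless) added to the posterior path per side.
#' @slot noise logical(1), Poisson noise on (FALSE gives expected counts,
#'   for closed-form checks).
#' @export
setClass("PhantomSpec",
  representation(preset = "character", size = "integer", seed = "integer",
                 backgroundRate = "numeric", kidneyRateLeft = "numeric",
                 kidneyRateRight = "numeric", trueSplit = "numeric",
                 centers = "matrix", axes = "matrix", ringInner = "numeric",
                 depths = "numeric", thickness = "numeric",
                 effThickness = "numeric", boneAtten = "numeric",
                 noise = "logical"),
  validity = function(object) {
    if (!object@preset %in% c("normal", "ectopic", "hydronephrotic"))
      return("unknown preset")
    if (object@size < 16L) return("size must be >= 16 pixels")
    if (object@backgroundRate <= 0) return("background rate must be > 0")
    if (object@kidneyRateLeft <= 0 || object@kidneyRateRight <= 0)
      return("kidney rates must be > 0 (contrast above background)")
    if (abs(sum(object@trueSplit) - 100) > 1e-9)
      return("trueSplit must sum to 100")
    if (object@ringInner < 0 || object@ringInner >= 1)
      return("ringInner must lie in [0, 1)")
    for (s in c("right", "left")) {
      ctr <- object@centers[s, ]; ax <- object@axes[s, ]
      if (ctr[1] - ax[1] < 1 || ctr[1] + ax[1] > object@size ||
          ctr[2] - ax[2] < 1 || ctr[2] + ax[2] > object@size)
        return(sprintf("%s kidney ellipse exceeds the image bounds", s))
    }
    if (any(object@depths <= 0) || object@thickness <= 0)
      return("depths and thickness must be > 0")
    if (any(object@depths > object@effThickness))
      return("depth cannot exceed the effective body thickness")
    TRUE
  })
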