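#' Kernel specification constructor
#'
#' @param kind "gaussian" (default) or "dirac". The Dirac kernel reduces the
#'   density estimate to a normalized histogram.
#' @param sigma Gaussian bandwidth in intensity units; \code{NA} (default)
#'   resolves to twice the bin width when the kernel is applied.
#' @return A [KernelSpec-class].
#' @export
kernelSpec <- function(kind = c("gaussian", "dirac"), sigma = NA_real_) {
  kind <- match.arg(kind)
  new("KernelSpec", kind = kind, sigma = as.numeric(sigma))
}

#' Equal-width intensity binning
#'
#' Builds the binning used by all density estimates: \code{nBins}
#' equal-width bins spanning the full intensity range of the input. A
#' degenerate (constant-intensity) input falls back to a single bin
#' centred on that value.
#'
#' @param x a [ScintiImage-class] or numeric vector of intensities.
#' @param nBins number of bins (default 256).
#' @return list with elements \code{centers} (bin centres) and \code{width}
#'   (common bin width; 1 for the degenerate single-bin case).
#' @export
intensityBins <- function(x, nBins = 256L) {
  v <- if (is(x, "ScintiImage")) x@values else x
  v <- as.numeric(v)
  if (!length(v) || any(!is.finite(v))) stop("intensities must be finite")
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0)
    return(list(centers = lo, width = 1))
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1")
  w <- (hi - lo) / nBins
  list(centers = lo + (seq_len(nBins) - 0.5) * w, width = w)
}

#' Gaussian kernel function
#'
#' The Gaussian density kernel K_x(y) = exp(-(x-y)^2 / (2 sigma^2)) /
#' sqrt(2 pi sigma^2), symmetric in its arguments and maximal at x = y.
#'
#' @param x,y intensities (vectorized).
#' @param sigma bandwidth, > 0.
#' @return Kernel density values.
#' @examples
#' gaussianKernel(0, 0, 1)  # 1/sqrt(2*pi)
#' @export
gaussianKernel <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  exp(-(x - y)^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
}

# Resolve a KernelSpec against a binning: returns list(kind, sigma).
resolveKernel <- function(kernel, bins) {
  sigma <- kernel@sigma
  if (kernel@kind == "gaussian" && is.na(sigma)) sigma <- 2 * bins$width
  list(kind = kernel@kind, sigma = sigma)
}

# Kernel evaluation matrix: rows = bin centers, cols = distinct values.
kernelMatrix <- function(centers, values, kern) {
  if (kern$kind == "dirac") {
    idx <- binIndex(values, centers)
    m <- matrix(0, length(centers), length(values))
    m[cbind(idx, seq_along(values))] <- 1
    m
  } else {
    outer(centers, values, gaussianKernel, sigma = kern$sigma)
  }
}

# Bin membership for each value: equal-width bins with edges at
# center - w/2; values exactly on an edge belong to the upper bin.
binIndex <- function(values, centers) {
  if (length(centers) == 1L) return(rep(1L, length(values)))
  w <- centers[2] - centers[1]
  lo <- centers[1] - w / 2
  pmin(pmax(as.integer(floor((values - lo) / w)) + 1L, 1L),
       length(centers))
}

#' Kernel density estimate of an intensity distribution
#'
#' Estimates the distribution of a pixel intensity sample on a fixed
#' binning: each bin centre z receives the mean kernel response
#' sum_i K_z(I_i) / A, and the resulting bin vector is renormalized to sum
#' exactly to one so that Bhattacharyya overlaps retain their [0, 1]
#' semantics on the discrete grid. With a Dirac kernel this is the
#' normalized histogram.
#'
#' @param values numeric vector of pixel intensities (non-empty).
#' @param kernel a [KernelSpec-class]; default Gaussian with automatic
#'   bandwidth (2 x bin width).
#' @param bins binning from [intensityBins()]; defaults to 256 bins over
#'   the range of \code{values}.
#' @return An [IntensityDistribution-class].
#' @examples
#' d <- kdeEstimate(c(1, 1, 2, 2), kernelSpec("dirac"), intensityBins(c(1, 2), 2))
#' probabilities(d)  # 0.5 0.5
#' @export
kdeEstimate <- function(values, kernel = kernelSpec(), bins = NULL) {
  if (is(values, "ScintiImage")) values <- values@values
  values <- as.numeric(values)
  if (!length(values))
    stop("degenerate region: cannot estimate a distribution from no pixels")
  if (is.null(bins)) bins <- intensityBins(values)
  kern <- resolveKernel(kernel, bins)
  tab <- valueTable(values)
  raw <- as.numeric(kernelMatrix(bins$centers, tab$values, kern) %*% tab$counts)
  raw <- raw / length(values)
  tot <- sum(raw)
  if (tot <= 0)
    stop("binning error: sample has no mass on the supplied bins")
  new("IntensityDistribution", binCenters = bins$centers,
      probabilities = raw / tot)
}

# Distinct values with multiplicities (keeps kernel sums O(#distinct x bins)).
valueTable <- function(values) {
  vs <- sort(unique(values))
  counts <- as.numeric(tabulate(match(values, vs), nbins = length(vs)))
  list(values = vs, counts = counts)
}

#' Bhattacharyya coefficient
#'
#' Overlap between two distributions on the same bins:
#' B(f, g) = sum_z sqrt(f(z) g(z)), in [0, 1]; 1 iff f = g bin-wise and 0
#' iff the supports are disjoint.
#'
#' @param f,g [IntensityDistribution-class] objects on identical bins.
#' @return The coefficient, a number in [0, 1].
#' @examples
#' b <- intensityBins(c(0, 1), 2)
#' f <- kdeEstimate(c(0, 1), kernelSpec("dirac"), b)
#' bhattacharyya(f, f)  # 1
#' @export
bhattacharyya <- function(f, g) {
  stopifnot(is(f, "IntensityDistribution"), is(g, "IntensityDistribution"))
  if (length(f@binCenters) != length(g@binCenters) ||
      max(abs(f@binCenters - g@binCenters)) >
        1e-8 * max(1, max(abs(f@binCenters))))
    stop("binning error: distributions are defined on different bins")
  min(1, sum(sqrt(f@probabilities * g@probabilities)))
}

#' @describeIn kdeEstimate serialize a distribution to a data frame
#'   (columns \code{bin_center}, \code{probability}), e.g. for CSV export.
#' @param x an [IntensityDistribution-class].
#' @param row.names,optional,... passed on conventions of
#'   [base::as.data.frame()]; unused.
#' @export
as.data.frame.IntensityDistribution <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(bin_center = x@binCenters, probability = x@probabilities)
}
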