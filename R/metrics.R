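asMask <- function(m) {
  if (is(m, "ScintiImage")) m <- m@values
  m != 0
}

#' Dice similarity coefficient
#'
#' 2 |A intersect M| / (|A| + |M|) between an automatic and a reference
#' mask; 1 iff the masks are identical as sets, 0 iff disjoint.
#'
#' @param maskA,maskM binary masks of equal dimensions, at least one
#'   non-empty.
#' @return Dice coefficient in [0, 1].
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' diceCoef(a, a)  # 1
#' @export
diceCoef <- function(maskA, maskM) {
  a <- asMask(maskA); m <- asMask(maskM)
  if (!identical(dim(a), dim(m))) stop("mask dimensions differ")
  va <- sum(a); vm <- sum(m)
  if (va + vm == 0) stop("undefined metric: both masks are empty")
  2 * sum(a & m) / (va + vm)
}

#' Jaccard index
#'
#' |A intersect M| / |A union M|; related to Dice by J = D / (2 - D).
#'
#' @inheritParams diceCoef
#' @return Jaccard index in [0, 1].
#' @export
jaccardCoef <- function(maskA, maskM) {
  a <- asMask(maskA); m <- asMask(maskM)
  if (!identical(dim(a), dim(m))) stop("mask dimensions differ")
  u <- sum(a | m)
  if (u == 0) stop("undefined metric: both masks are empty")
  sum(a & m) / u
}

#' Segmentation overlap summary
#'
#' @inheritParams diceCoef
#' @return list with \code{dice}, \code{jaccard}, and the region pixel
#'   counts \code{vA}, \code{vM}, \code{vAM}.
#' @export
segMetrics <- function(maskA, maskM) {
  a <- asMask(maskA); m <- asMask(maskM)
  list(dice = diceCoef(a, m), jaccard = jaccardCoef(a, m),
       vA = sum(a), vM = sum(m), vAM = sum(a & m))
}

#' Pearson correlation and least-squares line
#'
#' @param x,y numeric series of equal length >= 3; \code{x} must not be
#'   constant.
#' @return list with \code{r}, \code{slope}, \code{intercept} of the OLS
#'   fit of y on x.
#' @export
pearsonFit <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("degenerate fit: x is constant")
  slope <- stats::cov(x, y) / stats::var(x)
  list(r = stats::cor(x, y), slope = slope,
       intercept = mean(y) - slope * mean(x))
}

#' Bland-Altman agreement
#'
#' Bias (mean difference a - b) and 1.96-SD limits of agreement, with the
#' per-pair means and differences for plotting. The SD uses the n-1
#' denominator.
#'
#' @param a,b numeric series of equal length >= 2.
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh}, \code{sd},
#'   and plot data \code{means}, \code{diffs}.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 2L) stop("need at least 2 observations")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       sd = s, means = (a + b) / 2, diffs = d)
}

#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' ICC for two raters (methods) measuring the same subjects, under the
#' two-way random-effects, absolute-agreement model: the single-measures
#' form ICC(A,1) and the average-measures form ICC(A,k), with F-based 95%
#' confidence intervals (Satterthwaite degrees of freedom for the single
#' form; the average-measure bounds are the Spearman-Brown transform of
#' the single-measure bounds).
#'
#' @param a,b numeric series of equal length >= 3 (one per rater).
#' @param conf confidence level (default 0.95).
#' @return list with \code{single}, \code{average}, \code{ciSingle},
#'   \code{ciAverage}, the mean squares \code{msr}, \code{msc}, \code{mse},
#'   and \code{flags}.
#' @export
iccAgreement <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("series lengths differ")
  n <- length(a)
  if (n < 3L) stop("need at least 3 subjects")
  k <- 2
  dat <- cbind(a, b)
  subjMeans <- rowMeans(dat)
  raterMeans <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * stats::var(subjMeans)
  msc <- n * sum((raterMeans - grand)^2) / (k - 1)
  sse <- sum((dat - outer(subjMeans, rep(1, k)) -
                outer(rep(1, n), raterMeans) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  flags <- character(0)
  denomS <- msr + (k - 1) * mse + k * (msc - mse) / n
  denomA <- msr + (msc - mse) / n
  if (denomS <= 0 || (msr == 0 && mse == 0)) {
    flags <- "degenerate_variance"
    single <- average <- NaN
  } else if (mse == 0 && msc == 0) {
    # identical raters on varying subjects: perfect agreement
    flags <- "degenerate_variance"
    single <- average <- 1
  } else {
    single <- (msr - mse) / denomS
    average <- (msr - mse) / denomA
  }
  alpha <- 1 - conf
  ciS <- c(NA_real_, NA_real_)
  if (is.finite(single) && mse > 0) {
    fj <- msc / mse
    nu <- (k - 1) * (n - 1) *
      ((k * single * fj + n * (1 + (k - 1) * single) - k * single)^2) /
      ((n - 1) * k^2 * single^2 * fj^2 +
         (n * (1 + (k - 1) * single) - k * single)^2)
    fl <- stats::qf(1 - alpha / 2, n - 1, nu)
    fu <- stats::qf(1 - alpha / 2, nu, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ciS <- c(lower, upper)
  } else if (is.finite(single)) {
    ciS <- c(single, single)
  }
  sb <- function(r) r * k / (1 + (k - 1) * r)
  list(single = unname(single), average = unname(average),
       ciSingle = ciS, ciAverage = sb(ciS),
       msr = msr, msc = msc, mse = mse, flags = flags)
}

#' Full method-agreement summary
#'
#' Combines [blandAltman()], [iccAgreement()] and [pearsonFit()] into one
#' [AgreementResult-class].
#'
#' @param a,b numeric series of equal length >= 3.
#' @param conf confidence level for the ICC intervals.
#' @return An [AgreementResult-class].
#' @export
agreementStats <- function(a, b, conf = 0.95) {
  ba <- blandAltman(a, b)
  icc <- iccAgreement(a, b, conf)
  pf <- tryCatch(pearsonFit(a, b),
                 error = function(e) list(r = NA_real_, slope = NA_real_,
                                          intercept = NA_real_))
  new("AgreementResult", bias = ba$bias, loaLow = ba$loaLow,
      loaHigh = ba$loaHigh, iccSingle = icc$single,
      iccAverage = icc$average, ciSingle = icc$ciSingle,
      ciAverage = icc$ciAverage, pearsonR = pf$r, slope = pf$slope,
      intercept = pf$intercept, flags = icc$flags)
}
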