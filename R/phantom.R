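# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generator calls do not perturb it.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Synthetic scintigraphy phantom specification
#'
#' Builds a validated [PhantomSpec-class]. Presets place two elliptical
#' kidneys in the lower half of the image (so the upper band is kidney-free
#' "safety" tissue): "normal" puts both at normal abdominal height and
#' equal depth geometry; "ectopic" displaces the right kidney toward the
#' pelvic (inferior) region, makes it shallower-bodied (smaller effective
#' anteroposterior thickness) and adds a posterior bone insert over it;
#' "hydronephrotic" additionally hollows the right kidney's uptake into a
#' ring (radiotracer stasis: cold centre, elevated peri-renal background).
#'
#' The right kidney's uptake rate is solved from \code{trueSplit} so that
#' the ground-truth relative function - the split of expected
#' kidney-specific (background-free) emissions - equals the requested
#' percentages exactly.
#'
#' @param preset "normal", "ectopic" or "hydronephrotic".
#' @param size image side length in pixels (default 128).
#' @param seed integer seed; all generator output is deterministic given it.
#' @param backgroundRate background counts/pixel (default 10).
#' @param kidneyRate additional counts/pixel inside the left kidney
#'   (default 20, i.e. in-kidney/background contrast ratio 3 at the
#'   defaults); the right rate is solved from \code{trueSplit}.
#' @param trueSplit named ground-truth relative function in percent,
#'   c(right = , left = ), summing to 100.
#' @param thickness nominal anteroposterior body thickness, cm.
#' @param depths optional named kidney depths (cm from the posterior
#'   surface); preset defaults otherwise.
#' @param effThickness optional named per-side effective thickness (cm);
#'   preset defaults (the ectopic side is thinner).
#' @param boneAtten optional named extra posterior attenuation exponents;
#'   preset defaults (0.3 over the ectopic kidney).
#' @param centers,axes optional 2x2 matrices (rows "right", "left") of
#'   ellipse centres/semi-axes in pixels; preset defaults otherwise.
#' @param ringInner inner/outer radius ratio of the hydronephrotic ring.
#' @param noise draw Poisson counts (TRUE) or return expected counts.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec("ectopic", seed = 7)
#' spec
#' @export
phantomSpec <- function(preset = c("normal", "ectopic", "hydronephrotic"),
                        size = 128L, seed = 1L, backgroundRate = 10,
                        kidneyRate = 20,
                        trueSplit = c(right = 50, left = 50),
                        thickness = 20, depths = NULL, effThickness = NULL,
                        boneAtten = NULL, centers = NULL, axes = NULL,
                        ringInner = NULL, noise = TRUE) {
  preset <- match.arg(preset)
  size <- as.integer(size)
  sidesOf <- function(x, default) {
    if (is.null(x)) x <- default
    stopifnot(all(c("right", "left") %in% names(x)))
    x[c("right", "left")]
  }
  px <- function(f) round(f * size)
  if (is.null(centers)) {
    centers <- switch(preset,
      normal = rbind(right = c(px(0.72), px(0.30)),
                     left  = c(px(0.72), px(0.70))),
      rbind(right = c(px(0.84), px(0.38)),
            left  = c(px(0.66), px(0.70))))
  }
  if (is.null(axes))
    axes <- rbind(right = c(px(0.11), px(0.07)),
                  left  = c(px(0.11), px(0.07)))
  ectopicLike <- preset %in% c("ectopic", "hydronephrotic")
  depths <- sidesOf(depths,
                    if (ectopicLike) c(right = 9, left = 6)
                    else c(right = 6.5, left = 6))
  effThickness <- sidesOf(effThickness,
                          if (ectopicLike) c(right = 16, left = thickness)
                          else c(right = thickness, left = thickness))
  boneAtten <- sidesOf(boneAtten,
                       if (ectopicLike) c(right = 0.3, left = 0)
                       else c(right = 0, left = 0))
  if (is.null(ringInner))
    ringInner <- if (preset == "hydronephrotic") 0.5 else 0
  trueSplit <- trueSplit[c("right", "left")]
  # solve the right uptake rate so expected kidney emissions split as asked
  g <- phantomGeometry(size, centers, axes, ringInner)
  krL <- kidneyRate
  krR <- (trueSplit[["right"]] / trueSplit[["left"]]) * krL *
    sum(g$uptakeLeft) / sum(g$uptakeRight)
  new("PhantomSpec", preset = preset, size = size, seed = as.integer(seed),
      backgroundRate = backgroundRate, kidneyRateLeft = krL,
      kidneyRateRight = krR, trueSplit = trueSplit,
      centers = centers, axes = axes, ringInner = ringInner,
      depths = depths, thickness = thickness, effThickness = effThickness,
      boneAtten = boneAtten, noise = noise)
}

# Pixel geometry shared by all generator paths: full-ellipse masks, uptake
# regions (ring for hydronephrotic kidneys) and the peri-renal patch.
phantomGeometry <- function(size, centers, axes, ringInner, scale = c(1, 1)) {
  rw <- matrix(seq_len(size), size, size)
  cl <- t(rw)
  inEll <- function(side, f = 1) {
    sc <- scale[if (side == "right") 1 else 2]
    if (sc <= 0) return(matrix(FALSE, size, size))
    a <- axes[side, ] * f * sc
    if (any(a < 0.5)) return(matrix(FALSE, size, size))
    ((rw - centers[side, 1]) / a[1])^2 + ((cl - centers[side, 2]) / a[2])^2 <= 1
  }
  maskR <- inEll("right"); maskL <- inEll("left")
  upR <- if (ringInner > 0) maskR & !inEll("right", ringInner) else maskR
  patch <- if (ringInner > 0) inEll("right", 1.5) & !maskR & !maskL
           else matrix(FALSE, size, size)
  list(maskRight = maskR, maskLeft = maskL,
       uptakeRight = upR, uptakeLeft = maskL, patch = patch)
}

# Expected emission-rate images for one slice: background field (with any
# peri-renal patch) and per-side kidney-specific rates.
sliceRates <- function(spec, scale = c(1, 1), krR = spec@kidneyRateRight,
                       krL = spec@kidneyRateLeft) {
  g <- phantomGeometry(spec@size, spec@centers, spec@axes, spec@ringInner,
                       scale)
  bg <- matrix(spec@backgroundRate, spec@size, spec@size)
  bg[g$patch] <- 1.5 * spec@backgroundRate
  kidR <- g$uptakeRight * krR
  kidL <- g$uptakeLeft * krL
  list(bg = bg, kidRight = kidR, kidLeft = kidL, geom = g)
}

#' Generate one phantom slice
#'
#' Draws a single emission-count image: Poisson counts with rate equal to
#' the background rate plus the per-kidney uptake rate inside the kidney
#' shapes (ring-shaped for the hydronephrotic preset). Background and
#' kidney emissions are drawn separately and summed, so the realized
#' kidney-specific counts are known exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{image} ([ScintiImage-class]), \code{masks}
#'   (full-ellipse ground-truth masks, \code{right}/\code{left}),
#'   \code{uptake} (uptake-region masks), \code{expected} (expected
#'   kidney-specific totals per side), \code{realized} (realized
#'   kidney-specific totals), \code{inMask} (realized in-mask totals,
#'   background included), and \code{trueRF} (the ground-truth split).
#' @export
makeSlice <- function(spec) {
  sr <- sliceRates(spec)
  draw <- function(rate) {
    if (!spec@noise) return(rate)
    matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
  }
  res <- withSeed(spec@seed, {
    bgI <- draw(sr$bg); kR <- draw(sr$kidRight); kL <- draw(sr$kidLeft)
    list(bg = bgI, kR = kR, kL = kL)
  })
  img <- scintiImage(res$bg + res$kR + res$kL)
  total <- res$bg + res$kR + res$kL
  list(image = img,
       masks = list(right = sr$geom$maskRight, left = sr$geom$maskLeft),
       uptake = list(right = sr$geom$uptakeRight, left = sr$geom$uptakeLeft),
       expected = c(right = sum(sr$kidRight), left = sum(sr$kidLeft)),
       realized = c(right = sum(res$kR), left = sum(res$kL)),
       inMask = c(right = sum(total[sr$geom$maskRight]),
                  left = sum(total[sr$geom$maskLeft])),
       trueRF = spec@trueSplit)
}

#' Generate a phantom slice stack
#'
#' Stacks coronal-equivalent slices along the posterior-to-anterior axis
#' (slice 1 posterior): each kidney's in-plane extent follows an elliptical
#' axial profile centred at its specified depth, with half-extent
#' \code{axialExtent} cm, so the stack centre of mass sits at the
#' ground-truth depth. The per-side uptake rate is re-solved against the
#' realized multi-slice uptake volumes so the expected kidney-specific
#' split still equals \code{trueSplit} exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @param nSlices number of slices (>= 1); slice spacing is
#'   thickness / nSlices.
#' @param axialExtent kidney half-extent along the stack axis, cm.
#' @return list with \code{volume} ([ScintiVolume-class]), per-slice mask
#'   lists \code{masksRight}/\code{masksLeft}, \code{expected},
#'   \code{realized}, \code{inMask} totals as in [makeSlice()], and
#'   \code{trueRF}.
#' @export
makeVolume <- function(spec, nSlices = 5L, axialExtent = 4) {
  nSlices <- as.integer(nSlices)
  if (nSlices < 1L) stop("nSlices must be >= 1")
  spacingCm <- spec@thickness / nSlices
  if (nSlices == 1L) {
    scales <- matrix(1, 1, 2)
  } else {
    zc <- spec@depths / spacingCm + 0.5
    hs <- axialExtent / spacingCm
    k <- seq_len(nSlices)
    scales <- cbind(sqrt(pmax(0, 1 - ((k - zc[["right"]]) / hs)^2)),
                    sqrt(pmax(0, 1 - ((k - zc[["left"]]) / hs)^2)))
  }
  prelim <- lapply(seq_len(nSlices), function(k)
    sliceRates(spec, scale = scales[k, ]))
  upR <- sum(vapply(prelim, function(p) sum(p$geom$uptakeRight), numeric(1)))
  upL <- sum(vapply(prelim, function(p) sum(p$geom$uptakeLeft), numeric(1)))
  if (upR == 0 || upL == 0)
    stop("geometry error: a kidney has no voxels in the stack")
  krL <- spec@kidneyRateLeft
  krR <- (spec@trueSplit[["right"]] / spec@trueSplit[["left"]]) * krL *
    upL / upR
  rates <- lapply(seq_len(nSlices), function(k)
    sliceRates(spec, scale = scales[k, ], krR = krR, krL = krL))
  out <- withSeed(spec@seed, lapply(rates, function(sr) {
    draw <- function(rate) {
      if (!spec@noise) return(rate)
      matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
    }
    list(bg = draw(sr$bg), kR = draw(sr$kidRight), kL = draw(sr$kidLeft))
  }))
  slicesImg <- mapply(function(r) scintiImage(r$bg + r$kR + r$kL), out,
                      SIMPLIFY = FALSE)
  vol <- scintiVolume(slicesImg, sliceSpacing = spacingCm * 10)
  tot <- function(f) colSums(do.call(rbind, lapply(seq_len(nSlices), f)))
  list(volume = vol,
       masksRight = lapply(rates, function(r) r$geom$maskRight),
       masksLeft = lapply(rates, function(r) r$geom$maskLeft),
       expected = c(right = sum(vapply(rates, function(r) sum(r$kidRight),
                                       numeric(1))),
                    left = sum(vapply(rates, function(r) sum(r$kidLeft),
                                      numeric(1)))),
       realized = c(right = sum(vapply(out, function(o) sum(o$kR), numeric(1))),
                    left = sum(vapply(out, function(o) sum(o$kL), numeric(1)))),
       inMask = tot(function(k) {
         v <- out[[k]]$bg + out[[k]]$kR + out[[k]]$kL
         c(right = sum(v[rates[[k]]$geom$maskRight]),
           left = sum(v[rates[[k]]$geom$maskLeft]))
       }),
       trueRF = spec@trueSplit)
}

#' Attenuated planar projections of a phantom
#'
#' Computes the expected anterior and posterior planar views of a phantom
#' under exponential attenuation: each kidney's emissions are attenuated by
#' exp(-mu d) toward the posterior detector and exp(-mu (T_eff - d)) toward
#' the anterior detector (per-side effective thickness), with the bone
#' insert adding its extra exponent to the posterior path of the affected
#' side; background emissions are distributed uniformly through the body
#' column, giving the depth-averaged factor (1 - exp(-mu T)) / (mu T) on
#' both views. Poisson noise is then applied unless the spec disables it.
#'
#' @param spec a [PhantomSpec-class].
#' @param mu soft-tissue linear attenuation coefficient, 1/cm
#'   (default 0.15, the physical value near 140 keV).
#' @param noise override the spec's noise flag.
#' @return list with \code{anterior}, \code{posterior}
#'   ([ScintiImage-class]), the 2-D kidney \code{masks} and background-ring
#'   ROIs \code{bgRois}, and \code{truth}: unattenuated kidney-specific
#'   totals \code{c0}, their attenuated view components \code{kidneyAnt},
#'   \code{kidneyPost}, the ground-truth split \code{trueRF}, and the
#'   geometry (\code{depths}, \code{effThickness}, \code{boneAtten},
#'   \code{thickness}).
#' @export
projectPlanar <- function(spec, mu = 0.15, noise = NULL) {
  if (is.null(noise)) noise <- spec@noise
  if (mu < 0) stop("mu must be non-negative")
  sr <- sliceRates(spec)
  g <- sr$geom
  d <- spec@depths; te <- spec@effThickness; bone <- spec@boneAtten
  fBg <- if (mu == 0) 1 else
    (1 - exp(-mu * spec@thickness)) / (mu * spec@thickness)
  postF <- c(right = exp(-mu * d[["right"]] - bone[["right"]]),
             left = exp(-mu * d[["left"]] - bone[["left"]]))
  antF <- c(right = exp(-mu * (te[["right"]] - d[["right"]])),
            left = exp(-mu * (te[["left"]] - d[["left"]])))
  post <- sr$bg * fBg + sr$kidRight * postF[["right"]] +
    sr$kidLeft * postF[["left"]]
  ant <- sr$bg * fBg + sr$kidRight * antF[["right"]] +
    sr$kidLeft * antF[["left"]]
  if (noise) {
    drawn <- withSeed(spec@seed + 104729L, list(
      ant = matrix(stats::rpois(length(ant), ant), spec@size, spec@size),
      post = matrix(stats::rpois(length(post), post), spec@size, spec@size)))
    ant <- drawn$ant; post <- drawn$post
  }
  ring <- function(side) {
    ctr <- spec@centers[side, ]; ax <- spec@axes[side, ]
    rw <- matrix(seq_len(spec@size), spec@size, spec@size); cl <- t(rw)
    rr <- function(f) ((rw - ctr[1]) / (ax[1] * f))^2 +
      ((cl - ctr[2]) / (ax[2] * f))^2 <= 1
    rng <- rr(1.6) & !rr(1.2) & !g$maskRight & !g$maskLeft & !g$patch
    rng
  }
  c0 <- c(right = sum(sr$kidRight), left = sum(sr$kidLeft))
  list(anterior = scintiImage(ant), posterior = scintiImage(post),
       masks = list(right = g$maskRight, left = g$maskLeft),
       bgRois = list(right = ring("right"), left = ring("left")),
       truth = list(c0 = c0,
                    kidneyAnt = c0 * antF, kidneyPost = c0 * postF,
                    trueRF = spec@trueSplit, depths = d,
                    effThickness = te, boneAtten = bone,
                    thickness = spec@thickness))
}
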