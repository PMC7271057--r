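# Independent reference implementations used as oracles. These are kept
# deliberately naive (double loops, exhaustive enumeration) and do not
# share code with the package internals they check.

# Naive KDE: per-bin double loop over pixels, then renormalization.
naiveKDE <- function(values, centers, sigma = NULL) {
  raw <- numeric(length(centers))
  width <- if (length(centers) > 1) centers[2] - centers[1] else 1
  lo <- centers[1] - width / 2
  for (zi in seq_along(centers)) {
    for (v in values) {
      raw[zi] <- raw[zi] + if (is.null(sigma)) {
        # dirac: bin membership (edges belong to the upper bin)
        bz <- min(max(floor((v - lo) / width) + 1, 1), length(centers))
        as.numeric(bz == zi)
      } else {
        exp(-(centers[zi] - v)^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
      }
    }
  }
  raw <- raw / length(values)
  unname(raw / sum(raw))
}

# Naive boundary length: all-pairs enumeration with Euclidean distances.
naiveSmoothness <- function(labels, connectivity = 8L) {
  idx <- which(!is.na(labels), arr.ind = TRUE)
  tot <- 0
  if (nrow(idx) < 2) return(0)
  for (p in seq_len(nrow(idx) - 1)) {
    for (q in seq((p + 1), nrow(idx))) {
      dr <- abs(idx[p, 1] - idx[q, 1]); dc <- abs(idx[p, 2] - idx[q, 2])
      neigh <- if (connectivity == 4L) dr + dc == 1 else max(dr, dc) == 1
      if (neigh && labels[idx[p, 1], idx[p, 2]] != labels[idx[q, 1], idx[q, 2]])
        tot <- tot + 1 / sqrt(dr^2 + dc^2)
    }
  }
  unname(tot)
}

# Exhaustive minimum of the segmentation energy over all labelings of
# phi_s with non-empty E. Fully vectorized over the 2^n labelings; energy
# recomputed from first principles (naive KDE model, renormalized region
# density, Bhattacharyya, pairwise boundary sum).
exhaustiveMinEnergy <- function(image, partition, params) {
  v <- imgValues(image)
  phi <- phiS(partition)
  n <- sum(phi)
  stopifnot(n <= 16)
  bins <- intensityBins(image, params@nBins)
  centers <- bins$centers
  sigma <- if (params@kernel@kind == "dirac") NULL else {
    s <- params@kernel@sigma
    if (is.na(s)) 2 * bins$width else s
  }
  D <- naiveKDE(v[phiSbar(partition)], centers, sigma)
  gamma <- if (is.na(params@gamma)) 0.5 / n else params@gamma
  vals <- v[phi]
  # per-pixel kernel columns
  w <- if (length(centers) > 1) centers[2] - centers[1] else 1
  loEdge <- centers[1] - w / 2
  K <- sapply(vals, function(x) {
    if (is.null(sigma)) {
      col <- numeric(length(centers))
      col[min(max(floor((x - loEdge) / w) + 1, 1), length(centers))] <- 1
      col
    } else {
      exp(-(centers - x)^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
    }
  })
  K <- matrix(K, nrow = length(centers))
  nlab <- 2^n
  bitm <- sapply(seq_len(n), function(i) bitwAnd(0:(nlab - 1), 2^(i - 1)) > 0)
  nz <- bitm %*% t(K)                  # labelings x bins (unnormalized)
  Ntot <- rowSums(nz)
  B <- rowSums(sqrt(sweep(nz, 1, Ntot, "/") *
                      matrix(D, nlab, length(D), byrow = TRUE)))
  # pairwise boundary term
  pos <- which(phi, arr.ind = TRUE)
  S <- numeric(nlab)
  for (p in seq_len(n - 1)) {
    for (q in seq((p + 1), n)) {
      dr <- abs(pos[p, 1] - pos[q, 1]); dc <- abs(pos[p, 2] - pos[q, 2])
      neigh <- if (params@connectivity == 4L) dr + dc == 1 else
        max(dr, dc) == 1
      if (neigh)
        S <- S + (bitm[, p] != bitm[, q]) / sqrt(dr^2 + dc^2)
    }
  }
  e <- -pmin(B, 1) + gamma * S
  ok <- rowSums(bitm) >= 1
  list(minEnergy = min(e[ok]), energies = e, keepMatrix = bitm, valid = ok)
}

# A small two-valued test instance: phi_s holds a contiguous block of
# "kidney" pixels (value hi) over background (value lo); phi_s-bar is all
# background.
twoValuedInstance <- function(seed, nrow = 4, lo = 0, hi = 10) {
  set.seed(seed)
  m <- matrix(lo, nrow, nrow * 2)
  r0 <- sample(seq_len(nrow - 1), 1)
  c0 <- sample(seq_len(nrow - 1), 1)
  m[r0:(r0 + 1), c0:(c0 + 1)] <- hi
  img <- scintiImage(m)
  part <- splitDomain(img, "right_kidney", splitIndex = nrow + 1L)
  list(image = img, partition = part,
       truthMask = (m == hi) & phiS(part))
}

# Phantom conditions for the quantification experiments: high cortical
# uptake over a faint background (DMSA-like), physical attenuation.
quantSpec <- function(preset, seed, split = c(right = 50, left = 50), ...) {
  phantomSpec(preset, seed = seed, backgroundRate = 2, kidneyRate = 30,
              trueSplit = split, ...)
}

segmentPhantom <- function(ph, params = energyParams()) {
  part <- splitDomain(ph$image, "two_kidneys")
  seg <- optimizeLabeling(ph$image, part, params)
  list(seg = seg, kidneys = extractKidneys(seg, "two_kidneys"),
       partition = part)
}

planarFromPhantom <- function(spec, mu = 0.15) {
  pr <- projectPlanar(spec, mu = mu)
  st <- planarStudy(pr$anterior, pr$posterior, pr$masks$right,
                    pr$masks$left, pr$bgRois$right, pr$bgRois$left,
                    spec@depths[["right"]], spec@depths[["left"]],
                    spec@thickness, mu = mu)
  planarRF(st)
}
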