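#' Segmentation energy parameters
#'
#' @param gamma smoothness weight, >= 0. The default \code{NA} ("auto")
#'   resolves at run time to \code{0.5 / |phi_s|}: the matching term is
#'   bounded in [-1, 0] while the boundary-length prior grows with the
#'   region perimeter, so the weight is expressed per phi_s pixel to keep
#'   the two terms commensurate across image sizes.
#' @param kernel a [KernelSpec-class] (default Gaussian, auto bandwidth).
#' @param connectivity 4 or 8 (default) neighbours; diagonal pairs weighted
#'   by inverse Euclidean distance 1/sqrt(2).
#' @param epsilon convergence tolerance on the absolute energy decrease.
#' @param maxIter iteration ceiling.
#' @param nBins number of intensity bins for all density estimates.
#' @return An [EnergyParams-class].
#' @export
energyParams <- function(gamma = NA_real_, kernel = kernelSpec(),
                         connectivity = 8L, epsilon = 1e-6, maxIter = 50L,
                         nBins = 256L) {
  new("EnergyParams", gamma = as.numeric(gamma), kernel = kernel,
      connectivity = as.integer(connectivity), epsilon = as.numeric(epsilon),
      maxIter = as.integer(maxIter), nBins = as.integer(nBins))
}

resolveGamma <- function(params, phiS) {
  if (is.na(params@gamma)) 0.5 / sum(phiS) else params@gamma
}

# Neighbour pairs within a mask. Returns positions (into the vector of
# TRUE pixels of `mask`, in column-major order) and inverse-distance
# weights. Pairs with an endpoint outside the mask are dropped: the
# labeling is defined on phi_s only.
neighborPairs <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- matrix(0L, nr, nc)
  pos[mask] <- seq_len(sum(mask))
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L, 1 / sqrt(2)), c(-1L, 1L, 1 / sqrt(2))))
  pi <- integer(0); pj <- integer(0); w <- numeric(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- pos[r1, c1, drop = FALSE]
    b <- pos[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) {
      pi <- c(pi, a[sel]); pj <- c(pj, b[sel])
      w <- c(w, rep(o[3], sum(sel)))
    }
  }
  list(i = pi, j = pj, w = w)
}

#' Distribution-matching term
#'
#' The negative Bhattacharyya overlap -B(P_E, D) between the kernel density
#' estimate of a region's intensities and a model distribution; lies in
#' [-1, 0], with -1 at a perfect match.
#'
#' @param values intensities of the region E (non-empty).
#' @param model an [IntensityDistribution-class], the background model D.
#' @param kernel a [KernelSpec-class] used for P_E.
#' @return A number in [-1, 0].
#' @export
matchingTerm <- function(values, model, kernel = kernelSpec()) {
  if (is(values, "ScintiImage")) values <- values@values
  values <- as.numeric(values)
  if (!length(values))
    stop("degenerate region: the matching term needs a non-empty region")
  w <- if (length(model@binCenters) > 1L)
    model@binCenters[2] - model@binCenters[1] else 1
  pe <- kdeEstimate(values, kernel,
                    bins = list(centers = model@binCenters, width = w))
  -bhattacharyya(pe, model)
}

#' Boundary-length smoothness term
#'
#' E(L) = sum over neighbouring pixel pairs within phi_s that carry
#' different labels of the inverse Euclidean distance between them (1 for
#' axial, 1/sqrt(2) for diagonal neighbours). Zero for constant labelings.
#'
#' @param labels integer/logical matrix: 0/1 on phi_s pixels, NA outside.
#' @param connectivity 4 or 8.
#' @return Non-negative boundary length.
#' @export
smoothnessTerm <- function(labels, connectivity = 8L) {
  mask <- !is.na(labels)
  if (!any(mask)) stop("label map is empty")
  pr <- neighborPairs(mask, connectivity)
  lv <- as.integer(labels[mask])
  sum(pr$w[lv[pr$i] != lv[pr$j]])
}

#' Total segmentation energy
#'
#' C(L) = -B(P_E, D) + gamma * E(L), where E = {x in phi_s : L_x = 1} and D
#' is the model distribution of phi_s-bar. Lower is better.
#'
#' @param labels label matrix as in [smoothnessTerm()] (1 = region E).
#' @param image the [ScintiImage-class] being segmented.
#' @param partition the [DomainPartition-class].
#' @param params an [EnergyParams-class].
#' @param model optional precomputed model distribution; built from
#'   phi_s-bar when NULL.
#' @return The energy value.
#' @export
evaluateEnergy <- function(labels, image, partition, params = energyParams(),
                           model = NULL) {
  bins <- intensityBins(image, params@nBins)
  if (is.null(model))
    model <- kdeEstimate(image@values[partition@phiSbar], params@kernel, bins)
  ev <- image@values[partition@phiS][labels[partition@phiS] == 1L]
  if (!length(ev))
    stop("degenerate region: E is empty")
  gamma <- resolveGamma(params, partition@phiS)
  matchingTerm(ev, model, params@kernel) +
    gamma * smoothnessTerm(labels, params@connectivity)
}

# ---- optimizer internals ----------------------------------------------

# Precomputed segmentation state. All per-pixel quantities are ordered by
# the column-major position of phi_s pixels.
makeSegState <- function(image, partition, params) {
  phiS <- partition@phiS
  bins <- intensityBins(image, params@nBins)
  kern <- resolveKernel(params@kernel, bins)
  model <- kdeEstimate(image@values[partition@phiSbar], params@kernel, bins)
  vals <- image@values[phiS]
  tab <- valueTable(vals)
  Kmat <- kernelMatrix(bins$centers, tab$values, kern)
  pairs <- neighborPairs(phiS, params@connectivity)
  st <- new.env(parent = emptyenv())
  st$phiS <- phiS
  st$bins <- bins
  st$kern <- kern
  st$model <- model
  st$D <- model@probabilities
  st$vals <- vals
  st$valIdx <- match(vals, tab$values)
  st$Kmat <- Kmat
  st$sv <- colSums(Kmat)
  st$pairs <- pairs
  st$gamma <- resolveGamma(params, phiS)
  st$keep <- rep(TRUE, length(vals))
  refreshDensity(st)
  st
}

# Recompute the kept-region density summaries n(z), N, B from scratch.
refreshDensity <- function(st) {
  tally <- as.numeric(tabulate(st$valIdx[st$keep], nbins = ncol(st$Kmat)))
  st$n <- as.numeric(st$Kmat %*% tally)
  st$N <- sum(st$n)
  st$B <- min(1, sum(sqrt(st$D * st$n / st$N)))
  invisible(st)
}

currentEnergy <- function(st) {
  lab <- as.integer(st$keep)
  -st$B + st$gamma * sum(st$pairs$w[lab[st$pairs$i] != lab[st$pairs$j]])
}

# Per-pixel removal costs of the auxiliary (majorizing) objective at the
# current labeling. For x in E the bound is
#   -B(E') <= -B(E) + sum_{x in E \ E'} m_x,
#   m_x = (3/2) c_x - B s_x / (2N),
#   c_x = (1/N) sum_z sqrt(D(z)/P_E(z)) K_z(I_x),  s_x = sum_z K_z(I_x),
# derived from sqrt(p - d) >= sqrt(p) - d/sqrt(p), the area-renormalization
# bound (1-t)^(-1/2) >= 1 + t/2, and a modular bound of the bilinear cross
# term. Tight at E' = E and valid for every shrink-reachable labeling.
boundCosts <- function(st) {
  r <- ifelse(st$n > 0, sqrt(st$D * st$N / st$n), 0)
  cv <- as.numeric(crossprod(st$Kmat, r)) / st$N
  mv <- 1.5 * cv - st$B * st$sv / (2 * st$N)
  mv[st$valIdx]
}

# One min-cut shrink move on the auxiliary objective. Returns TRUE if any
# pixel was removed from E.
cutMove <- function(st) {
  keepIdx <- which(st$keep)
  nv <- length(keepIdx)
  if (nv <= 1L) return(FALSE)
  m <- boundCosts(st)[keepIdx]
  node <- integer(length(st$keep)); node[keepIdx] <- seq_len(nv)
  lab <- as.integer(st$keep)
  # gamma-weighted pairwise terms
  pi <- st$pairs$i; pj <- st$pairs$j; w <- st$gamma * st$pairs$w
  bothKeep <- st$keep[pi] & st$keep[pj]
  oneKeep <- xor(st$keep[pi], st$keep[pj])
  # cost of label 1 from frozen label-0 neighbours
  cost1 <- numeric(nv)
  if (any(oneKeep)) {
    vpix <- ifelse(st$keep[pi[oneKeep]], pi[oneKeep], pj[oneKeep])
    agg <- rowsum(w[oneKeep], node[vpix])
    cost1[as.integer(rownames(agg))] <- agg[, 1]
  }
  s <- nv + 1L; t <- nv + 2L
  capS <- pmax(m, 0)            # cut when x takes label 0
  capT <- pmax(-m, 0) + cost1   # cut when x keeps label 1
  maxCap <- max(capS, capT, if (any(bothKeep)) max(w) else 0)
  if (maxCap <= 0 || all(capT == 0)) return(FALSE)
  # integer capacities: igraph's min-cut is much faster on them, and the
  # exact energy recomputation below keeps the descent exact regardless
  scale <- 1e9 / maxCap
  capS <- round(capS * scale); capT <- round(capT * scale)
  ef <- rbind(
    cbind(s, seq_len(nv))[capS > 0, , drop = FALSE],
    cbind(seq_len(nv), t)[capT > 0, , drop = FALSE])
  caps <- c(capS[capS > 0], capT[capT > 0])
  if (any(bothKeep)) {
    a <- node[pi[bothKeep]]; b <- node[pj[bothKeep]]
    pw <- round(w[bothKeep] * scale)
    sel <- pw > 0
    ef <- rbind(ef, cbind(a, b)[sel, , drop = FALSE],
                cbind(b, a)[sel, , drop = FALSE])
    caps <- c(caps, pw[sel], pw[sel])
  }
  if (!length(caps)) return(FALSE)
  g <- igraph::make_empty_graph(n = t, directed = TRUE)
  g <- igraph::add_edges(g, t(ef))
  fl <- igraph::max_flow(g, source = s, target = t, capacity = caps)
  srcSide <- rep(FALSE, t)
  srcSide[as.integer(fl$partition1)] <- TRUE
  newKeepLocal <- srcSide[seq_len(nv)]
  if (!any(newKeepLocal)) {
    # a cut emptying E is disallowed: retain the pixel costliest to remove
    newKeepLocal[which.max(m)] <- TRUE
  }
  if (all(newKeepLocal)) return(FALSE)
  st$keep[keepIdx[!newKeepLocal]] <- FALSE
  refreshDensity(st)
  TRUE
}

# Greedy exact single-pixel shrink moves until no single removal strictly
# decreases the energy. Returns TRUE if any pixel was removed.
polishShrink <- function(st) {
  changed <- FALSE
  # per-pixel gamma-weighted neighbour mass by current neighbour label
  lab <- as.integer(st$keep)
  w1 <- numeric(length(st$keep)); w0 <- numeric(length(st$keep))
  addPair <- function(acc, at, wt) {
    agg <- rowsum(wt, at)
    acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg[, 1]
    acc
  }
  pi <- st$pairs$i; pj <- st$pairs$j; w <- st$pairs$w
  for (end in 1:2) {
    at <- if (end == 1) pi else pj
    ot <- if (end == 1) pj else pi
    sel1 <- lab[ot] == 1L; sel0 <- !sel1
    if (any(sel1)) w1 <- addPair(w1, at[sel1], w[sel1])
    if (any(sel0)) w0 <- addPair(w0, at[sel0], w[sel0])
  }
  adj <- NULL  # built lazily on first removal
  repeat {
    if (sum(st$keep) <= 1L) break
    tally <- tabulate(st$valIdx[st$keep], nbins = ncol(st$Kmat))
    present <- which(tally > 0L)
    M <- st$n - st$Kmat[, present, drop = FALSE]
    M[M < 0] <- 0
    Bnew <- colSums(sqrt(st$D * M)) / sqrt(st$N - st$sv[present])
    Bnew <- pmin(Bnew, 1)
    dMatch <- st$B - Bnew                       # change in -B on removal
    dmByVal <- rep(Inf, ncol(st$Kmat)); dmByVal[present] <- dMatch
    kx <- which(st$keep)
    dC <- dmByVal[st$valIdx[kx]] + st$gamma * (w1[kx] - w0[kx])
    best <- which.min(dC)
    if (!(dC[best] < -1e-12)) break
    x <- kx[best]
    st$keep[x] <- FALSE
    v <- st$valIdx[x]
    st$n <- pmax(st$n - st$Kmat[, v], 0)
    st$N <- st$N - st$sv[v]
    st$B <- min(1, sum(sqrt(st$D * st$n / st$N)))
    if (is.null(adj)) {
      adj <- split(data.frame(o = c(pj, pi), w = c(w, w)), f = c(pi, pj))
      names(adj) <- as.character(as.integer(names(adj)))
    }
    nb <- adj[[as.character(x)]]
    if (!is.null(nb)) {
      w1[nb$o] <- w1[nb$o] - nb$w
      w0[nb$o] <- w0[nb$o] + nb$w
    }
    changed <- TRUE
  }
  changed
}

#' Segment the kidney region by bound-optimized distribution matching
#'
#' Minimizes C(L) = -B(P_E, D) + gamma E(L) over binary labelings of phi_s,
#' starting from E = phi_s (everything labeled "background-matching") and
#' iterating shrink moves: each iteration majorizes the matching term by a
#' per-pixel (modular) removal cost that upper-bounds the energy on every
#' labeling reachable by removing pixels from E and is tight at the current
#' labeling, then minimizes the resulting modular + pairwise objective
#' exactly with a binary min-cut. When cut moves stall, exact greedy
#' single-pixel removals run to exhaustion, so at convergence no single
#' 1-to-0 flip strictly decreases the energy. The energy is recomputed
#' exactly each iteration and is non-increasing by construction; the kidney
#' mask is the complement of the final E within phi_s.
#'
#' @param image a [ScintiImage-class].
#' @param partition a [DomainPartition-class]; the model D is estimated
#'   from phi_s-bar, which must be non-empty.
#' @param params an [EnergyParams-class].
#' @param optimizer "bound" (min-cut bound optimization, default) or
#'   "sweep" (exact greedy single-pixel shrink only; the slow reference
#'   path).
#' @return A [SegmentationResult-class].
#' @examples
#' set.seed(1)
#' v <- matrix(rpois(32 * 32, 5), 32, 32); v[8:16, 20:28] <- rpois(81, 30)
#' img <- scintiImage(v)
#' p <- splitDomain(img, "right_kidney")
#' res <- optimizeLabeling(img, p)
#' sum(kidneyMask(res))
#' @export
optimizeLabeling <- function(image, partition, params = energyParams(),
                             optimizer = c("bound", "sweep")) {
  optimizer <- match.arg(optimizer)
  stopifnot(is(image, "ScintiImage"), is(partition, "DomainPartition"))
  if (!any(partition@phiSbar))
    stop("cannot build the model: phi_s_bar is empty")
  if (sum(partition@phiS) < 2L)
    stop("phi_s must contain at least 2 pixels")
  st <- makeSegState(image, partition, params)
  trace <- currentEnergy(st)
  iter <- 0L
  converged <- FALSE
  shrinkOK <- TRUE
  prevKeep <- st$keep
  while (iter < params@maxIter) {
    iter <- iter + 1L
    changed <- if (optimizer == "bound") cutMove(st) else FALSE
    if (!changed) changed <- polishShrink(st)
    if (any(st$keep & !prevKeep)) shrinkOK <- FALSE
    prevKeep <- st$keep
    e <- currentEnergy(st)
    if (e > trace[length(trace)] + 1e-9)
      stop("internal error: energy increased during descent")
    e <- min(e, trace[length(trace)])
    trace <- c(trace, e)
    dec <- trace[length(trace) - 1L] - e
    if (!changed || dec < params@epsilon) { converged <- TRUE; break }
  }
  labels <- matrix(NA_integer_, nrow(image@values), ncol(image@values))
  labels[partition@phiS] <- 0L
  labels[partition@phiS][st$keep] <- 1L
  km <- matrix(FALSE, nrow(image@values), ncol(image@values))
  km[partition@phiS][!st$keep] <- TRUE
  lab <- as.integer(st$keep)
  flags <- character(0)
  if (!any(km)) flags <- c(flags, "empty_kidney_mask")
  new("SegmentationResult", labels = labels, kidneyMask = km,
      energyTrace = trace, iterations = iter,
      matchingTerm = -st$B,
      smoothnessTerm = sum(st$pairs$w[lab[st$pairs$i] != lab[st$pairs$j]]),
      converged = converged, shrinkMonotone = shrinkOK, flags = flags)
}

#' Extract labeled kidney masks from a segmentation
#'
#' Single-kidney modes return the largest connected component of the kidney
#' mask; the two-kidneys mode returns the two largest components, assigned
#' to sides by centroid column under the display convention (patient left
#' on viewer right, so the smaller-column component is the right kidney;
#' set \code{flip = TRUE} to reverse).
#'
#' @param result a [SegmentationResult-class].
#' @param sideChoice the choice used for the domain split.
#' @param flip flip the left/right naming convention.
#' @return Named list of logical masks ("left" and/or "right").
#' @export
extractKidneys <- function(result,
                           sideChoice = c("left_kidney", "right_kidney",
                                          "two_kidneys"),
                           flip = FALSE) {
  sideChoice <- match.arg(sideChoice)
  km <- result@kidneyMask
  if (!any(km)) stop("empty segmentation: no kidney component found")
  cc <- as.matrix(EBImage::bwlabel(km * 1L))
  sizes <- tabulate(cc[cc > 0])
  ord <- order(sizes, decreasing = TRUE)
  compMask <- function(k) cc == k
  centroidCol <- function(m) mean(which(m, arr.ind = TRUE)[, 2])
  if (sideChoice != "two_kidneys") {
    out <- list(compMask(ord[1]))
    names(out) <- sub("_kidney", "", sideChoice)
    return(out)
  }
  if (length(ord) < 2L) {
    warning("missing kidney: expected two components, found one")
    m <- compMask(ord[1])
    viewerLeft <- centroidCol(m) <= ncol(km) / 2
    side <- if (xor(viewerLeft, flip)) "right" else "left"
    out <- list(m); names(out) <- side
    return(out)
  }
  m1 <- compMask(ord[1]); m2 <- compMask(ord[2])
  if (centroidCol(m1) > centroidCol(m2)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  m1 <- as.matrix(m1) != 0; m2 <- as.matrix(m2) != 0
  if (flip) list(right = m2, left = m1) else list(right = m1, left = m2)
}
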