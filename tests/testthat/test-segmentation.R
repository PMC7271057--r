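test_that("matching term is the negative Bhattacharyya overlap", {
  model <- new("IntensityDistribution", binCenters = c(0, 1),
               probabilities = c(0.9, 0.1))
  expect_equal(matchingTerm(c(0, 0, 1, 1), model, kernelSpec("dirac")),
               -(sqrt(0.5 * 0.9) + sqrt(0.5 * 0.1)))
  # sample drawn from the model itself approaches a perfect match
  set.seed(5)
  big <- sample(c(0, 1), 20000, replace = TRUE, prob = c(0.9, 0.1))
  expect_lt(matchingTerm(big, model, kernelSpec("dirac")), -0.999)
  # disjoint support gives zero overlap
  model2 <- new("IntensityDistribution", binCenters = c(0, 10),
                probabilities = c(1, 0))
  expect_equal(matchingTerm(c(10, 10), model2, kernelSpec("dirac")), 0)
  expect_error(matchingTerm(numeric(0), model), "degenerate")
})

test_that("smoothness term counts cut neighbour pairs by inverse distance", {
  lab <- matrix(c(1L, 1L, 0L, 0L), 2, 2)  # column-major: [[1,0],[1,0]]
  expect_equal(smoothnessTerm(lab, 4L), 2)
  expect_equal(smoothnessTerm(lab, 8L), 2 + 2 / sqrt(2))
  chk <- matrix(c(1L, 0L, 0L, 1L), 2, 2)  # checkerboard [[1,0],[0,1]]
  expect_equal(smoothnessTerm(chk, 8L), 4)  # diagonals agree
  expect_equal(smoothnessTerm(matrix(1L, 3, 3), 8L), 0)
  expect_equal(smoothnessTerm(matrix(0L, 3, 3), 4L), 0)
  # random label maps against the all-pairs oracle
  set.seed(21)
  for (rep in 1:10) {
    lab <- matrix(sample(0:1, 20, TRUE), 4, 5)
    lab[sample(20, 4)] <- NA  # pixels outside phi_s are ignored
    for (conn in c(4L, 8L)) {
      if (all(is.na(lab))) next
      expect_equal(smoothnessTerm(lab, conn), naiveSmoothness(lab, conn))
    }
  }
})

test_that("total energy equals its independently recomputed parts", {
  set.seed(13)
  for (rep in 1:50) {
    m <- matrix(rpois(32, 8), 4, 8)
    img <- scintiImage(m)
    part <- splitDomain(img, "right_kidney")
    params <- energyParams(gamma = runif(1, 0, 0.2),
                           kernel = kernelSpec("dirac"), nBins = 16L)
    lab <- matrix(NA_integer_, 4, 8)
    lab[phiS(part)] <- sample(0:1, 16, TRUE)
    if (!any(lab[phiS(part)] == 1L)) lab[phiS(part)][1] <- 1L
    e <- evaluateEnergy(lab, img, part, params)
    model <- naiveKDE(m[phiSbar(part)], intensityBins(img, 16L)$centers, NULL)
    pe <- naiveKDE(m[phiS(part)][lab[phiS(part)] == 1L],
                   intensityBins(img, 16L)$centers, NULL)
    eRef <- -sum(sqrt(pe * model)) +
      params@gamma * naiveSmoothness(lab, params@connectivity)
    expect_equal(e, eRef, tolerance = 1e-10)
  }
})

test_that("constant labeling has zero smoothness in the energy", {
  set.seed(2)
  img <- scintiImage(matrix(rpois(64, 5), 8, 8))
  part <- splitDomain(img, "left_kidney")
  lab <- matrix(NA_integer_, 8, 8); lab[phiS(part)] <- 1L
  params <- energyParams(gamma = 100, kernel = kernelSpec("dirac"))
  e <- evaluateEnergy(lab, img, part, params)
  model <- kdeEstimate(imgValues(img)[phiSbar(part)], kernelSpec("dirac"),
                       intensityBins(img, 256L))
  expect_equal(e, matchingTerm(imgValues(img)[phiS(part)], model,
                               kernelSpec("dirac")))
})

test_that("the per-pixel bound majorizes the energy on all shrink labelings", {
  set.seed(31)
  for (rep in 1:6) {
    inst <- twoValuedInstance(rep, nrow = 3)
    m <- imgValues(inst$image) + rpois(length(imgValues(inst$image)), 2)
    img <- scintiImage(m)
    part <- inst$partition
    params <- energyParams(gamma = 0.05, kernel = kernelSpec("dirac"),
                           nBins = 16L)
    st <- renoscint:::makeSegState(img, part, params)
    for (stage in 1:2) {
      keepIdx <- which(st$keep)
      mcost <- renoscint:::boundCosts(st)[keepIdx]
      e0 <- renoscint:::currentEnergy(st)
      n <- length(keepIdx)
      phi <- phiS(part)
      for (code in 0:(2^n - 1)) {
        sub <- bitwAnd(code, 2^(seq_len(n) - 1)) > 0  # TRUE = removed
        if (all(sub)) next  # E must stay non-empty
        lab <- matrix(NA_integer_, nrow(m), ncol(m))
        lab[phi] <- 0L
        keepNew <- st$keep; keepNew[keepIdx[sub]] <- FALSE
        lab[phi][keepNew] <- 1L
        exact <- evaluateEnergy(lab, img, part, params)
        smoothNew <- smoothnessTerm(lab, params@connectivity)
        smoothOld <- st$gamma * 0 # aux carries the pairwise term exactly
        aux <- e0 -
          st$gamma * smoothnessTerm({
            l0 <- matrix(NA_integer_, nrow(m), ncol(m))
            l0[phi] <- 0L; l0[phi][st$keep] <- 1L; l0
          }, params@connectivity) +
          sum(mcost[sub]) + st$gamma * smoothNew
        # (a) upper bound on every shrink-reachable labeling
        expect_gte(aux, exact - 1e-12)
        # (b) tight at the current labeling
        if (!any(sub)) expect_equal(aux, exact, tolerance = 1e-12)
      }
      # advance one cut move and re-check at the new labeling
      if (!renoscint:::cutMove(st)) break
    }
  }
})

test_that("bound optimization reaches the exhaustive minimum on tiny instances", {
  # noise-free two-valued inputs make the smoothness term degenerate (every
  # all-background E matches the model perfectly, so any gamma > 0 favours
  # the shortest boundary, not the kidney complement); the matching-driven
  # optimum is checked at gamma = 0 where the ground truth is the argmin
  for (seed in 1:20) {
    inst <- twoValuedInstance(seed)
    params <- energyParams(gamma = 0, kernel = kernelSpec("dirac"),
                           nBins = 16L)
    res <- optimizeLabeling(inst$image, inst$partition, params)
    oracle <- exhaustiveMinEnergy(inst$image, inst$partition, params)
    expect_equal(energyTrace(res)[length(energyTrace(res))],
                 oracle$minEnergy, tolerance = 1e-6)
    expect_equal(kidneyMask(res) & phiS(inst$partition), inst$truthMask)
  }
})

test_that("descent is monotone and shrink-only with a non-increasing trace", {
  set.seed(17)
  for (seed in 1:8) {
    spec <- phantomSpec(c("normal", "ectopic")[seed %% 2 + 1], seed = seed,
                        size = 64L)
    ph <- makeSlice(spec)
    part <- splitDomain(ph$image, "two_kidneys")
    res <- optimizeLabeling(ph$image, part)
    expect_true(all(diff(energyTrace(res)) <= 1e-9))
    expect_true(res@shrinkMonotone)
    expect_true(res@converged)
    expect_lte(res@iterations, 50L)
  }
})

test_that("no single shrink flip improves the energy at convergence", {
  set.seed(23)
  for (seed in 1:5) {
    m <- matrix(rpois(48, 6), 6, 8)
    m[2:4, 6:8] <- rpois(9, 40)
    img <- scintiImage(m)
    part <- splitDomain(img, "left_kidney")
    params <- energyParams(gamma = 0.01, kernel = kernelSpec("dirac"),
                           nBins = 24L)
    res <- optimizeLabeling(img, part, params)
    lab <- segLabels(res)
    eFinal <- evaluateEnergy(lab, img, part, params)
    phi <- phiS(part)
    kept <- which(phi & lab == 1L)
    if (length(kept) <= 1L) next
    for (x in kept) {
      lab2 <- lab; lab2[x] <- 0L
      if (!any(lab2[phi] == 1L)) next
      expect_gte(evaluateEnergy(lab2, img, part, params), eFinal - 1e-9)
    }
  }
})

test_that("a uniform phi_s yields an empty or near-empty kidney mask", {
  set.seed(4)
  img <- scintiImage(matrix(rpois(512, 10), 16, 32))
  part <- splitDomain(img, "right_kidney")
  res <- optimizeLabeling(img, part,
                          energyParams(kernel = kernelSpec("dirac")))
  expect_lte(sum(kidneyMask(res)), 8)  # nothing real to segment
  expect_lte(energyTrace(res)[length(energyTrace(res))], energyTrace(res)[1])
})

test_that("stronger smoothness never lengthens the mask boundary", {
  spec <- phantomSpec("normal", seed = 19, size = 64L)
  ph <- makeSlice(spec)
  part <- splitDomain(ph$image, "two_kidneys")
  boundaryLen <- function(gamma) {
    res <- optimizeLabeling(ph$image, part, energyParams(gamma = gamma))
    lab <- segLabels(res)
    pr <- renoscint:::neighborPairs(phiS(part), 8L)
    lv <- lab[phiS(part)]
    sum(lv[pr$i] != lv[pr$j])
  }
  lens <- vapply(c(0, 0.1, 1, 10), boundaryLen, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("the sweep reference optimizer agrees with the bound path", {
  for (seed in 1:5) {
    inst <- twoValuedInstance(seed)
    params <- energyParams(gamma = 0, kernel = kernelSpec("dirac"),
                           nBins = 16L)
    a <- optimizeLabeling(inst$image, inst$partition, params, "bound")
    b <- optimizeLabeling(inst$image, inst$partition, params, "sweep")
    expect_equal(energyTrace(a)[length(energyTrace(a))],
                 energyTrace(b)[length(energyTrace(b))], tolerance = 1e-9)
  }
})

test_that("kidney extraction picks components and names sides correctly", {
  km <- matrix(FALSE, 20, 40)
  km[5:14, 3:9] <- TRUE      # 70-pixel blob, viewer left
  km[16:17, 20] <- TRUE      # 2-pixel speck
  res <- new("SegmentationResult", labels = matrix(0L, 20, 40),
             kidneyMask = km, energyTrace = c(-0.5), iterations = 1L,
             matchingTerm = -0.5, smoothnessTerm = 0, converged = TRUE,
             shrinkMonotone = TRUE, flags = character(0))
  one <- extractKidneys(res, "right_kidney")
  expect_named(one, "right")
  expect_equal(sum(one$right), 70)
  # two blobs: viewer-left component is the anatomical right kidney
  km2 <- matrix(FALSE, 20, 40); km2[5:10, 3:8] <- TRUE; km2[5:10, 30:36] <- TRUE
  res2 <- res; res2@kidneyMask <- km2
  two <- extractKidneys(res2, "two_kidneys")
  expect_lt(mean(which(two$right, arr.ind = TRUE)[, 2]),
            mean(which(two$left, arr.ind = TRUE)[, 2]))
  flipped <- extractKidneys(res2, "two_kidneys", flip = TRUE)
  expect_identical(flipped$left, two$right)
  # degenerate cases
  res3 <- res; res3@kidneyMask <- matrix(FALSE, 20, 40)
  expect_error(extractKidneys(res3, "left_kidney"), "empty segmentation")
  km4 <- matrix(FALSE, 20, 40); km4[5:10, 3:8] <- TRUE  # single component
  res4 <- res; res4@kidneyMask <- km4
  expect_warning(one4 <- extractKidneys(res4, "two_kidneys"),
                 "missing kidney")
  expect_named(one4, "right")  # viewer-left centroid = anatomical right
})

test_that("an empty model region or tiny phi_s is rejected", {
  img <- scintiImage(matrix(1:16 * 1.0, 4, 4))
  part <- splitDomain(img, "right_kidney")
  bad <- part
  expect_error(optimizeLabeling(img, new("DomainPartition",
    phiS = matrix(TRUE, 4, 4) , phiSbar = matrix(FALSE, 4, 4),
    splitKind = "vertical", splitIndex = 2L, sideChoice = "right_kidney")),
    "non-empty")
})
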