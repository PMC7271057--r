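# renoscint

Kidney segmentation and relative renal function (RF) quantification for
static renal scintigraphy (99mTc-DMSA), with a particular focus on
ectopic (pelvic) kidneys, where the clinical-routine planar method is
biased.

## Who this is for

Nuclear-medicine image analysts and methods researchers who want (i) an
automatic, training-free kidney ROI extraction from emission-count
images, (ii) both RF estimators — the planar anterior/posterior routine
with background and attenuation corrections, and the tomographic
segmented-ROI count method — and (iii) the agreement statistics
(Dice/Jaccard, Pearson fits, Bland–Altman, ICC) needed to compare them.
A seeded phantom generator with full ground truth makes every step
testable without clinical data.

## The model

The image domain is split by a straight line into the region to segment,
Φs (containing the kidneys), and a kidney-free complement Φ̄s whose
intensity kernel density estimate D is the background model. A binary
labeling L on Φs defines a region E = {x : L_x = 1} intended to match
the background; the kidney is its complement within Φs. Segmentation
minimizes

    C(L) = −B(P_E, D) + γ · E(L)

where P_E is the kernel density estimate of intensities in E,
B(f, g) = Σ_z √(f(z) g(z)) is the Bhattacharyya overlap, and E(L) is a
boundary-length prior (inverse-distance-weighted disagreeing neighbour
pairs). The optimizer starts from E = Φs and iterates shrink moves:
each iteration builds a per-pixel (modular) upper bound of the matching
term — tight at the current labeling and valid for every
removal-reachable labeling — and minimizes bound + smoothness exactly by
a binary min-cut, followed by exact single-pixel polishing. The energy
is recomputed exactly each iteration, so the trace is non-increasing;
convergence takes a handful of iterations.

RF is then quantified two ways:

* **planar** (clinical routine): per-view background correction
  Q_BC = Q_b − N_Qb·(Q_F/N_QF), geometric-mean attenuation correction
  Q_AC = √(C_ant·C_post)·e^{μT/2}, and RF_right = 100·Q_AC^R/(Q_AC^R+Q_AC^L);
* **tomographic**: raw counts summed inside the segmented per-side masks
  (no corrections — the segmentation excludes background and the
  reconstruction is assumed attenuation-corrected).

See `vignettes/renoscint-methods.Rmd` for assumptions, parameter
defaults, the bound derivation, and what the phantoms do and do not
emulate.

## Worked example

Segment an ectopic phantom and quantify RF both ways:

```r
library(renoscint)

spec <- phantomSpec("ectopic", seed = 42)          # 128x128, contrast 3:1
ph   <- makeSlice(spec)
part <- splitDomain(ph$image, "two_kidneys")       # model band is kidney-free
seg  <- optimizeLabeling(ph$image, part)
seg
#> SegmentationResult: 753 kidney pixels, 4 iteration(s), C = -0.976632
#>   (matching -0.998596, smoothness 359.847763)

kidneys <- extractKidneys(seg, "two_kidneys")
diceCoef(kidneys$right, ph$masks$right)            # 0.9725
diceCoef(kidneys$left,  ph$masks$left)             # 0.9792

# DMSA-like contrast for quantification; truth split 45/55
qspec <- phantomSpec("ectopic", seed = 42, backgroundRate = 2,
                     kidneyRate = 30, trueSplit = c(right = 45, left = 55))
proj  <- projectPlanar(qspec, mu = 0.15)           # attenuated ant/post views
study <- planarStudy(proj$anterior, proj$posterior,
                     proj$masks$right, proj$masks$left,
                     proj$bgRois$right, proj$bgRois$left,
                     depthRight = 9, depthLeft = 6, thickness = 20, mu = 0.15)
planarRF(study)
#> QuantReport (planar): RF right 48.46% / left 51.54%

phq  <- makeSlice(qspec)
segq <- optimizeLabeling(phq$image, splitDomain(phq$image, "two_kidneys"))
kq   <- extractKidneys(segq, "two_kidneys")
tomographicRF(phq$image, kq$right, kq$left)
#> QuantReport (tomographic): RF right 45.31% / left 54.69%
```

The matching term near −1 says the retained region matches the
background model almost perfectly; Dice ≈ 0.97 scores the extracted
masks against the generator's ground truth. With a true split of 45/55,
the planar estimate is off by ~3.5 points — the ectopic kidney's bone
shadow and thinner body section violate the geometric-mean assumptions —
while the tomographic estimate lands within ~0.3 points.

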