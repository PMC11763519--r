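test_that("generators are deterministic given spec and seed", {
  s1 <- genFamily(familySpec(nBackground = 15, nForeground = 3, length = 40,
                             seed = 21))
  s2 <- genFamily(familySpec(nBackground = 15, nForeground = 3, length = 40,
                             seed = 21))
  expect_identical(alignmentMatrix(s1$alignment),
                   alignmentMatrix(s2$alignment))
  expect_identical(s1$truth, s2$truth)
  s3 <- genFamily(familySpec(nBackground = 15, nForeground = 3, length = 40,
                             seed = 22))
  expect_false(identical(alignmentMatrix(s1$alignment),
                         alignmentMatrix(s3$alignment)))
  c1 <- genCounts(countSpec(nGenes = 100, nOr = 10, nOrLike = 10, downOr = 4,
                            downOrLike = 4, downOther = 10, seed = 5))
  c2 <- genCounts(countSpec(nGenes = 100, nOr = 10, nOrLike = 10, downOr = 4,
                            downOrLike = 4, downOther = 10, seed = 5))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth, c2$truth)
  p1 <- genPlate(plateSpec(seed = 6))
  p2 <- genPlate(plateSpec(seed = 6))
  expect_identical(p1$plate, p2$plate)
})

test_that("family generator honors the conservation model", {
  # radius 0: only the anchor qualifies -> monomorphic foreground
  fam <- genFamily(familySpec(nBackground = 20, nForeground = 5, length = 30,
                              plantedSites = c(4, 17), radius = 0,
                              gapRate = 0, seed = 2))
  M <- alignmentMatrix(fam$alignment)
  fg <- fam$truth$foregroundIds
  for (k in seq_along(fam$truth$plantedSites)) {
    col <- M[fg, fam$truth$plantedSites[k]]
    expect_identical(unname(unique(col)), fam$truth$anchors[k])
  }
  # positive radius: every foreground residue lies within it
  G <- granthamMatrix()
  fam2 <- genFamily(familySpec(nBackground = 20, nForeground = 5,
                               length = 30, plantedSites = 9, radius = 60,
                               gapRate = 0, seed = 3))
  col <- alignmentMatrix(fam2$alignment)[fam2$truth$foregroundIds, 9]
  expect_true(all(G[col, fam2$truth$anchors] <= 60))
  # reference record is gap-free even at high gap rates
  fam3 <- genFamily(familySpec(nBackground = 10, nForeground = 3,
                               length = 80, gapRate = 0.4, seed = 4))
  M3 <- alignmentMatrix(fam3$alignment)
  expect_false(any(M3["REF", ] == "-"))
  expect_gt(sum(M3 == "-"), 0)
  # decoys never collide with planted sites
  expect_length(intersect(fam3$truth$decoySites,
                          fam3$truth$plantedSites), 0L)
})

test_that("family specs reject impossible settings", {
  expect_error(familySpec(nForeground = 1), "at least 2")
  expect_error(familySpec(gapRate = 0.6), "0.5")
  expect_error(familySpec(radius = -1), "non-negative")
  expect_error(familySpec(length = 10, plantedSites = 11), "within")
  expect_error(familySpec(plantedSites = c(3, 3)), "duplicate")
  expect_error(familySpec(plantedSites = 3, anchors = c("A", "C")),
               "one anchor per")
  expect_error(familySpec(backgroundProbs = rep(1, 19)), "20")
})

test_that("count generator plants class-labelled down-regulation", {
  spec <- countSpec(nGenes = 400, nOr = 40, nOrLike = 40, downOr = 10,
                    downOrLike = 10, downOther = 20, seed = 7)
  sim <- genCounts(spec)
  expect_identical(dim(sim$counts), c(400L, 8L))
  expect_identical(levels(sim$groups), c("control", "treatment"))
  expect_identical(as.vector(table(sim$annotation$class)[c("OR", "OR-like")]),
                   c(40L, 40L))
  ann <- sim$annotation
  expect_true(all(ann$class[match(sim$truth$downOr, ann$gene_id)] == "OR"))
  # planted genes are down in treatment on average
  trt <- sim$groups == "treatment"
  planted <- rownames(sim$counts) %in% sim$truth$downOr
  expect_lt(mean(sim$counts[planted, trt]) / mean(sim$counts[planted, !trt]),
            0.5)
  # dispersion 0 is the Poisson limit: variance tracks the mean
  pois <- genCounts(countSpec(nGenes = 3000, nPerGroup = 4, dispersion = 0,
                              downOr = 0, downOrLike = 0, downOther = 0,
                              seed = 8))
  v <- apply(pois$counts, 1, var)
  expect_equal(mean(v), 100, tolerance = 0.05)
  nb <- genCounts(countSpec(nGenes = 3000, nPerGroup = 4, dispersion = 0.1,
                            downOr = 0, downOrLike = 0, downOther = 0,
                            seed = 8))
  expect_gt(mean(apply(nb$counts, 1, var)), 5 * mean(v))
})

test_that("plate generator: noise model and degenerate noise-free case", {
  # cv = 0 and flat profiles: all normalized responses exactly equal
  pl <- genPlate(plateSpec(constructs = list(a = c(1, 1, 1)), cv = 0,
                           seed = 1))
  norm <- normalizeWells(pl$plate)
  expect_identical(length(unique(norm$response)), 1L)
  # fold activation moves the mean response proportionally
  pl2 <- genPlate(plateSpec(constructs = list(a = c(1, 2, 4)), cv = 0,
                            seed = 1))
  norm2 <- normalizeWells(pl2$plate)
  m <- tapply(norm2$response, norm2$concentration_uM, mean)
  expect_equal(as.numeric(m[c("100", "200")] / m[["0"]]), c(2, 4))
  # multiplicative noise has roughly the requested CV
  pl3 <- genPlate(plateSpec(constructs = list(a = c(1, 1, 1)),
                            replicates = 400, cv = 0.1, seed = 9))
  ff <- pl3$plate$firefly
  expect_equal(sd(ff) / mean(ff), 0.1, tolerance = 0.15)
  expect_error(plateSpec(constructs = list(a = c(1, 1))), "per concentration")
  expect_error(plateSpec(concentrations = c(100, 200),
                         constructs = list(a = c(1, 2))), "no-odor")
  expect_error(plateSpec(constructs = list(a = c(0, 1, 1))), "positive")
})
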