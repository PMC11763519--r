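test_that("site pairwise distances enumerate all unordered pairs", {
  G <- granthamMatrix()
  expect_identical(sitePairwiseDistances(c("L", "L", "L"), G), c(0, 0, 0))
  d <- sitePairwiseDistances(c("L", "I", "L"), G)
  expect_identical(sort(round(d)), c(0, 5, 5))
  expect_equal(mean(d), 2 * oracle_dist("L", "I") / 3)
  expect_identical(sitePairwiseDistances("L", G), numeric(0))
  expect_identical(sitePairwiseDistances(character(0), G), numeric(0))
  expect_length(sitePairwiseDistances(rep("A", 6), G), choose(6, 2))
  expect_error(sitePairwiseDistances(c("L", "-"), G), "gaps")
})

test_that("screen agrees with literal brute-force enumeration on small alignments", {
  G <- granthamMatrix()
  set.seed(20)
  for (k in 1:10) {
    nseq <- sample(3:5, 1)
    width <- sample(2:5, 1)
    seqs <- random_small_alignment(nseq, width)
    aln <- ReceptorAlignment(seqs)
    fg <- sample(names(seqs), sample(2:nseq, 1))
    panel <- sitePanel(seq_len(width))
    res <- screenSites(aln, panel, "REF", fg, G = G)
    M <- alignmentMatrix(aln)
    for (i in seq_len(width)) {
      bs <- brute_site_means(M, res$column[i], fg, names(seqs))
      expect_equal(res$fgMean[i], bs$fgMean)
      expect_equal(res$bgMean[i], bs$bgMean)
      expect_identical(res$nFgPairs[i], bs$nFgPairs)
      expect_identical(res$nBgPairs[i], bs$nBgPairs)
    }
  }
})

test_that("results are invariant to record order and relabeling", {
  fam <- genFamily(familySpec(nBackground = 25, nForeground = 4,
                              length = 30, seed = 3))
  aln <- fam$alignment
  panel <- sitePanel(c(fam$truth$plantedSites,
                       setdiff(c(5, 9, 13), fam$truth$plantedSites)))
  fg <- fam$truth$foregroundIds
  res <- screenSites(aln, panel, "REF", fg)
  # shuffle record order
  set.seed(1)
  perm <- sample(length(aln))
  aln2 <- ReceptorAlignment(setNames(
    as.character(alignmentMatrix(aln)[perm, ] |>
                   apply(1, paste0, collapse = "")), names(aln)[perm]))
  res2 <- screenSites(aln2, panel, "REF", fg)
  expect_equal(as.data.frame(res), as.data.frame(res2))
  # relabel every receptor
  ids3 <- setNames(paste0("id_", seq_along(names(aln))), names(aln))
  aln3 <- ReceptorAlignment(setNames(
    apply(alignmentMatrix(aln), 1, paste0, collapse = ""),
    ids3[names(aln)]))
  res3 <- screenSites(aln3, panel, ids3[["REF"]], unname(ids3[fg]))
  expect_equal(res3$fgMean, res$fgMean)
  expect_equal(res3$pValue, res$pValue)
})

test_that("rescaling rho shifts means proportionally but not rank-test calls", {
  fam <- genFamily(familySpec(nBackground = 20, nForeground = 5,
                              length = 25, seed = 8))
  panel <- sitePanel(c(fam$truth$plantedSites,
                       setdiff(c(2, 4, 6), fam$truth$plantedSites)))
  fg <- fam$truth$foregroundIds
  G1 <- granthamMatrix()
  G3 <- granthamMatrix(granthamParams(rho = 3 * 50.723))
  r1 <- screenSites(fam$alignment, panel, "REF", fg, G = G1)
  r3 <- screenSites(fam$alignment, panel, "REF", fg, G = G3)
  expect_equal(r3$fgMean, 3 * r1$fgMean)
  expect_equal(r3$bgMean, 3 * r1$bgMean)
  expect_equal(r3$pValue, r1$pValue)          # Mann-Whitney is rank-based
  expect_identical(r3$conserved, r1$conserved)
})

test_that("degenerate sites are reported, never dropped, and bad input errors", {
  aln <- ReceptorAlignment(c(REF = "MKT", a = "-KT", b = "-RT", c = "MKT",
                             d = "MRT"))
  fg <- c("a", "b")
  res <- screenSites(aln, sitePanel(1:3), "REF", fg)
  expect_identical(nrow(res), 3L)
  # site 1: both foreground residues are gaps -> no test, row retained
  expect_identical(res$nFgUsable[1], 0L)
  expect_true(is.na(res$pValue[1]) && is.na(res$fgMean[1]))
  expect_false(res$conserved[1])
  expect_false(anyNA(res$pValue[2:3]))
  expect_error(screenSites(aln, sitePanel(1), "REF", "a"), "at least two")
  expect_error(screenSites(aln, sitePanel(1), "ZZ", fg), "ZZ")
  expect_error(screenSites(aln, sitePanel(9), "REF", fg), "beyond")
  expect_error(screenSites(aln, sitePanel(1, residues = "W"), "REF", fg),
               "mismatch")
})

test_that("permutation null is reproducible, extreme for monomorphic foregrounds", {
  aln <- genFamily(familySpec(nBackground = 40, nForeground = 5, length = 10,
                              plantedSites = 4, radius = 0, gapRate = 0,
                              seed = 5))
  fg <- aln$truth$foregroundIds
  pn <- permutationNull(aln$alignment, 4, fg, nPerm = 500, seed = 9)
  expect_identical(pn$observed, 0)
  # monomorphic foreground in a polymorphic background: near-minimal p
  expect_lte(pn$p, 1 / 501 + 0.02)
  pn2 <- permutationNull(aln$alignment, 4, fg, nPerm = 500, seed = 9)
  expect_identical(pn$p, pn2$p)
  expect_error(permutationNull(aln$alignment, 4, fg, nPerm = 0), "positive")
  # insufficient usable background
  tiny <- ReceptorAlignment(c(REF = "MK", a = "MK", b = "MR", c = "-K"))
  expect_warning(
    p <- permutationNull(tiny, 1, c("a", "b", "c"), c("REF", "c"),
                         nPerm = 100),
    "insufficient")
  expect_true(is.na(p$p))
})

test_that("Benjamini-Hochberg adjustment drives the conserved flag when enabled", {
  fam <- genFamily(familySpec(nBackground = 50, nForeground = 5,
                              length = 40, seed = 12))
  panel <- sitePanel(sort(c(fam$truth$plantedSites, fam$truth$decoySites)))
  raw <- screenSites(fam$alignment, panel, "REF", fam$truth$foregroundIds)
  adj <- screenSites(fam$alignment, panel, "REF", fam$truth$foregroundIds,
                     config = screenConfig(adjust = "BH"))
  expect_equal(adj$pValue, raw$pValue)
  expect_equal(adj$pAdjusted, p.adjust(raw$pValue, "BH"))
  expect_true(all(adj$conserved <= (adj$pAdjusted <= 0.05), na.rm = TRUE))
  # adjustment can only lose calls, never add them
  expect_true(all(!adj$conserved | raw$conserved))
})
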