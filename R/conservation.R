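#' All pairwise Grantham distances within one alignment column
#'
#' Given the usable residues observed at a site in a set of receptors
#' (gaps and `X` already removed by the caller), returns the distances of
#' all C(n,2) unordered residue pairs.  Fewer than two residues yield an
#' empty vector.
#'
#' @param residues Character vector of one-letter residue codes, one per
#'   receptor (repeats allowed; this is a multiset).
#' @param G Distance matrix from [granthamMatrix()].
#' @return Numeric vector of length `choose(length(residues), 2)`.
#' @examples
#' round(sitePairwiseDistances(c("L", "I", "L")))  # 5, 5, 0
#' sitePairwiseDistances("L")                       # empty
#' @export
sitePairwiseDistances <- function(residues, G = granthamMatrix()) {
  residues <- as.character(residues)
  n <- length(residues)
  if (n < 2L) {
    return(numeric(0))
  }
  bad <- setdiff(unique(residues), rownames(G))
  if (length(bad) > 0L) {
    stop("residues not present in the distance matrix: ",
         paste(sQuote(bad), collapse = ", "),
         " (remove gaps and ambiguity codes first)")
  }
  D <- G[residues, residues, drop = FALSE]
  D[upper.tri(D)]
}

# usable residues (gaps and X dropped) of a set of rows at one column of a
# character alignment matrix
.usable <- function(M, ids, column) {
  ch <- M[ids, column]
  ch[!ch %in% c(.GAP, "X")]
}

# mean pairwise distance from a residue-count vector: with counts n over the
# matrix rows, sum over unordered pairs is n'Gn/2 (zero diagonal), pair
# count is choose(N,2)
.mean_pairwise <- function(counts, G) {
  N <- sum(counts)
  if (N < 2L) {
    return(NA_real_)
  }
  as.numeric(counts %*% G %*% counts) / 2 / choose(N, 2)
}

#' Empirical permutation null for a foreground's mean pairwise distance
#'
#' Statistically sounder alternative to the two-sample tests: pairwise
#' distances within a receptor set share sequences and are not independent
#' observations, so the permutation test resamples receptor subsets, not
#' pairs.  It draws `nPerm` random subsets of the background residues at
#' the column, of the same size as the usable foreground, and compares
#' their mean pairwise Grantham distance with the observed foreground mean:
#' `p = (1 + #\{permuted means <= observed\}) / (1 + nPerm)`.
#'
#' @param x A [ReceptorAlignment-class].
#' @param column 1-based alignment column.
#' @param foregroundIds Foreground receptor ids.
#' @param backgroundIds Background receptor ids (default: all records).
#' @param nPerm Number of permutations (>= 1).
#' @param seed Integer seed; the draw is reproducible under a fixed seed.
#' @param G Distance matrix from [granthamMatrix()].
#' @return A list with `p` (empirical p-value, `NA` when the site is
#'   degenerate), `observed` (foreground mean pairwise distance), `nUsable`
#'   (usable foreground residues) and `nPerm`.
#' @export
permutationNull <- function(x, column, foregroundIds,
                            backgroundIds = names(x), nPerm = 1000L,
                            seed = 1L, G = granthamMatrix()) {
  stopifnot(methods::is(x, "ReceptorAlignment"))
  nPerm <- as.integer(nPerm)
  if (is.na(nPerm) || nPerm < 1L) {
    stop("nPerm must be a positive integer")
  }
  M <- alignmentMatrix(x)
  fg <- .usable(M, foregroundIds, column)
  bg <- .usable(M, backgroundIds, column)
  out <- .perm_p(fg, bg, nPerm, seed, G)
  c(out, list(nPerm = nPerm))
}

.perm_p <- function(fg, bg, nPerm, seed, G) {
  m <- length(fg)
  obs <- .mean_pairwise(table(factor(fg, levels = rownames(G))), G)
  if (m < 2L || length(bg) < m) {
    if (length(bg) < m) {
      warning("insufficient usable background residues (", length(bg),
              ") for a foreground of size ", m, "; p unavailable")
    }
    return(list(p = NA_real_, observed = obs, nUsable = m))
  }
  bgi <- match(bg, rownames(G))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  pairs <- utils::combn(m, 2L)
  i1 <- pairs[1L, ]
  i2 <- pairs[2L, ]
  perm <- vapply(seq_len(nPerm), function(k) {
    s <- bgi[sample.int(length(bgi), m)]
    mean(G[cbind(s[i1], s[i2])])
  }, numeric(1))
  list(p = (1 + sum(perm <= obs)) / (1 + nPerm), observed = obs,
       nUsable = m)
}

#' Screen cavity sites for foreground-specific conservation
#'
#' The core computation: for each site of the panel (given in ungapped
#' reference coordinates and mapped to alignment columns via the reference
#' record), compute all pairwise Grantham distances within the foreground
#' receptors and within the background repertoire at that column, and test
#' whether the foreground mean is lower -- i.e. whether the site is
#' relatively conserved among the co-responsive receptors.  A site is
#' flagged `conserved` when its (optionally BH-adjusted) p-value is at most
#' `alpha` *and* the foreground mean is below the background mean.
#'
#' Sites with fewer than `minUngapped` usable foreground residues are
#' reported with `pValue = NA`, never dropped.  Gap and `X` characters are
#' removed residue-wise (pairwise deletion); usable counts are reported per
#' site.
#'
#' @param x A [ReceptorAlignment-class].
#' @param panel Site panel from [sitePanel()] / [readSitePanel()].
#' @param referenceId Id of the reference receptor whose coordinates the
#'   panel uses.
#' @param foregroundIds Ids of the foreground (co-responsive) receptors; at
#'   least two.
#' @param backgroundIds Ids of the background repertoire (default: all
#'   records; by convention this includes the foreground unless
#'   `excludeForeground` is set in `config`).
#' @param config A [ScreenConfig-class] from [screenConfig()].
#' @param G Distance matrix from [granthamMatrix()].
#' @return A [S4Vectors::DataFrame] with one row per panel site and columns
#'   `position`, `column`, `refResidue`, `label`, `fgMean`, `bgMean`,
#'   `nFgUsable`, `nBgUsable`, `nFgPairs`, `nBgPairs`, `statistic`,
#'   `pValue`, `pAdjusted`, `conserved`.  `metadata()` carries the
#'   configuration and ids used.
#' @examples
#' fam <- genFamily(familySpec(nBackground = 30, nForeground = 5,
#'                             length = 40, nPlanted = 2, seed = 1))
#' panel <- sitePanel(sort(c(fam$truth$plantedSites, 10, 20)))
#' screenSites(fam$alignment, panel, fam$truth$referenceId,
#'             fam$truth$foregroundIds)
#' @export
screenSites <- function(x, panel, referenceId, foregroundIds,
                        backgroundIds = names(x), config = screenConfig(),
                        G = granthamMatrix()) {
  stopifnot(methods::is(x, "ReceptorAlignment"),
            methods::is(config, "ScreenConfig"))
  methods::validObject(config)
  foregroundIds <- unique(as.character(foregroundIds))
  backgroundIds <- unique(as.character(backgroundIds))
  if (length(foregroundIds) < 2L) {
    stop("at least two foreground receptors are required")
  }
  missing <- setdiff(c(foregroundIds, backgroundIds, referenceId), names(x))
  if (length(missing) > 0L) {
    stop("id(s) not in alignment: ", paste(missing, collapse = ", "))
  }
  if (config@excludeForeground) {
    backgroundIds <- setdiff(backgroundIds, foregroundIds)
  }
  if (length(backgroundIds) < 2L) {
    stop("background must contain at least two receptors")
  }
  pmap <- positionMap(x, referenceId)
  unmapped <- setdiff(panel$position, pmap$position)
  if (length(unmapped) > 0L) {
    stop("panel position(s) beyond the reference's ungapped length (",
         max(pmap$position), "): ", paste(unmapped, collapse = ", "))
  }
  cols <- pmap$column[match(panel$position, pmap$position)]
  refRes <- pmap$residue[match(panel$position, pmap$position)]
  if (!is.null(panel$residue)) {
    stated <- !is.na(panel$residue)
    off <- stated & panel$residue != refRes
    if (any(off)) {
      stop("expected residue mismatch at reference position(s) ",
           paste(sprintf("%d (stated %s, reference has %s)",
                         panel$position[off], panel$residue[off],
                         refRes[off]), collapse = "; "))
    }
  }
  M <- alignmentMatrix(x)

  one_site <- function(i) {
    fg <- .usable(M, foregroundIds, cols[i])
    bg <- .usable(M, backgroundIds, cols[i])
    fgd <- sitePairwiseDistances(fg, G)
    bgd <- sitePairwiseDistances(bg, G)
    row <- list(fgMean = if (length(fgd)) mean(fgd) else NA_real_,
                bgMean = if (length(bgd)) mean(bgd) else NA_real_,
                nFgUsable = length(fg), nBgUsable = length(bg),
                nFgPairs = length(fgd), nBgPairs = length(bgd),
                statistic = NA_real_, pValue = NA_real_)
    if (length(fg) < config@minUngapped || length(bgd) < 1L) {
      return(row)
    }
    alt <- if (config@alternative == "less") "less" else "two.sided"
    if (config@test == "mann_whitney") {
      ht <- tryCatch(suppressWarnings(
        stats::wilcox.test(fgd, bgd, alternative = alt)),
        error = function(e) NULL)
      if (!is.null(ht)) {
        row$statistic <- unname(ht$statistic)
        row$pValue <- ht$p.value
      }
    } else if (config@test == "t_test") {
      ht <- tryCatch(stats::t.test(fgd, bgd, alternative = alt),
                     error = function(e) NULL)
      if (!is.null(ht)) {
        row$statistic <- unname(ht$statistic)
        row$pValue <- ht$p.value
      }
    } else {
      pr <- .perm_p(fg, bg, config@permutations,
                    seed = config@seed + i, G = G)
      row$statistic <- pr$observed
      row$pValue <- if (config@alternative == "less") pr$p else {
        if (is.na(pr$p)) NA_real_ else min(1, 2 * min(pr$p, 1 - pr$p))
      }
    }
    row
  }

  rows <- lapply(seq_len(nrow(panel)), one_site)
  num <- function(f) vapply(rows, function(r) as.numeric(r[[f]]), numeric(1))
  int <- function(f) vapply(rows, function(r) as.integer(r[[f]]), integer(1))
  res <- S4Vectors::DataFrame(
    position = panel$position, column = cols, refResidue = refRes,
    label = if (is.null(panel$label)) NA_character_ else panel$label,
    fgMean = num("fgMean"), bgMean = num("bgMean"),
    nFgUsable = int("nFgUsable"), nBgUsable = int("nBgUsable"),
    nFgPairs = int("nFgPairs"), nBgPairs = int("nBgPairs"),
    statistic = num("statistic"), pValue = num("pValue"))
  res$pAdjusted <- if (config@adjust == "none") res$pValue else {
    stats::p.adjust(res$pValue, method = config@adjust)
  }
  res$conserved <- !is.na(res$pAdjusted) & res$pAdjusted <= config@alpha &
    !is.na(res$fgMean) & !is.na(res$bgMean) & res$fgMean < res$bgMean
  S4Vectors::metadata(res) <- list(
    config = config, referenceId = referenceId,
    foregroundIds = foregroundIds, backgroundIds = backgroundIds)
  res
}

#' Write screen results as TSV with a JSON sidecar
#'
#' Writes the per-site table to `path` and, when the `jsonlite` package is
#' available, a `<path>.json` sidecar recording the test configuration,
#' seed and receptor sets for provenance.
#'
#' @param res Result of [screenSites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeScreenResults <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- S4Vectors::metadata(res)
  if (length(meta) > 0L && requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- meta$config
    side <- list(
      test = cfg@test, alternative = cfg@alternative, alpha = cfg@alpha,
      permutations = cfg@permutations, seed = cfg@seed,
      minUngapped = cfg@minUngapped,
      excludeForeground = cfg@excludeForeground, adjust = cfg@adjust,
      referenceId = meta$referenceId, foregroundIds = meta$foregroundIds,
      nBackground = length(meta$backgroundIds))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}
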