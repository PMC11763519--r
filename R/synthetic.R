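#' Specification of a synthetic receptor family
#'
#' Describes the alignment generator of [genFamily()]: a background
#' repertoire whose columns are drawn i.i.d. from a background residue
#' distribution, plus a small foreground of co-responsive receptors that is
#' generated by the same process except at planted "conserved" sites, where
#' foreground residues are drawn uniformly from the pool of residues within
#' a Grantham radius of an anchor residue.  Radius 0 makes the foreground
#' monomorphic at a planted site; large radii dilute the planted signal to
#' nothing.  Gaps are inserted independently per cell except in the
#' designated gap-free reference record.
#'
#' @param nBackground Number of background receptors, including the
#'   reference record (default 200, a desk-scale stand-in for a full OR
#'   repertoire).
#' @param nForeground Number of foreground receptors (default 5; at least
#'   2).
#' @param length Ungapped sequence length / alignment width (default 310,
#'   a typical OR length).
#' @param nPlanted Number of planted conserved sites (default 3); ignored
#'   when `plantedSites` is given.
#' @param plantedSites Optional integer vector of planted positions; drawn
#'   uniformly at generation time when `NULL`.
#' @param anchors Optional anchor residues for the planted sites; drawn
#'   uniformly when `NULL`.
#' @param radius Grantham radius of the planted conservation pool
#'   (default 50).
#' @param gapRate Per-cell gap probability outside the reference record
#'   (default 0.02; must be < 0.5).
#' @param backgroundProbs Optional length-20 probability vector over the
#'   residues of `aaProperties()` (default uniform).
#' @param dirichlet Optional positive concentration parameter; when set,
#'   each column's background distribution is an independent
#'   Dirichlet(`dirichlet`) perturbation instead of `backgroundProbs`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A validated list of class `"FamilySpec"`.
#' @export
familySpec <- function(nBackground = 200L, nForeground = 5L, length = 310L,
                       nPlanted = 3L, plantedSites = NULL, anchors = NULL,
                       radius = 50, gapRate = 0.02, backgroundProbs = NULL,
                       dirichlet = NULL, seed = 1L) {
  spec <- list(nBackground = as.integer(nBackground),
               nForeground = as.integer(nForeground),
               length = as.integer(length), nPlanted = as.integer(nPlanted),
               plantedSites = if (!is.null(plantedSites))
                 as.integer(plantedSites),
               anchors = if (!is.null(anchors)) toupper(anchors),
               radius = radius, gapRate = gapRate,
               backgroundProbs = backgroundProbs, dirichlet = dirichlet,
               seed = as.integer(seed))
  if (spec$nForeground < 2L) stop("nForeground must be at least 2")
  if (spec$nBackground < 2L) stop("nBackground must be at least 2")
  if (spec$length < 1L) stop("length must be positive")
  if (!(gapRate >= 0 && gapRate < 0.5)) {
    stop("gapRate must lie in [0, 0.5)")
  }
  if (radius < 0) stop("radius must be non-negative")
  if (!is.null(spec$plantedSites)) {
    if (any(spec$plantedSites < 1L | spec$plantedSites > spec$length)) {
      stop("planted sites must lie within the sequence length")
    }
    if (anyDuplicated(spec$plantedSites)) stop("duplicate planted sites")
    spec$nPlanted <- length(spec$plantedSites)
  } else if (spec$nPlanted > spec$length) {
    stop("more planted sites than columns")
  }
  if (!is.null(spec$anchors)) {
    .check_residues(spec$anchors, aaProperties(), "anchor")
    if (length(spec$anchors) != spec$nPlanted) {
      stop("need one anchor per planted site")
    }
  }
  if (!is.null(backgroundProbs)) {
    if (length(backgroundProbs) != 20L || any(backgroundProbs < 0) ||
        sum(backgroundProbs) <= 0) {
      stop("backgroundProbs must be 20 non-negative values, ordered as ",
           "aaProperties()$residue")
    }
  }
  if (!is.null(dirichlet) && dirichlet <= 0) {
    stop("dirichlet concentration must be positive")
  }
  structure(spec, class = "FamilySpec")
}

#' Generate a synthetic receptor family alignment
#'
#' See [familySpec()] for the model.  The first background record, named
#' `"REF"`, is kept gap-free so that alignment columns coincide with its
#' ungapped positions and any panel stated in reference coordinates maps
#' one-to-one onto columns.
#'
#' @param spec A [familySpec()].
#' @return A list with `alignment` (a [ReceptorAlignment-class]) and
#'   `truth`: `foregroundIds`, `backgroundIds` (all records, foreground
#'   included, matching the repertoire-wide background convention),
#'   `referenceId`, `plantedSites`, `anchors`, `radius`, and `decoySites`
#'   (20 non-planted positions, or fewer on short alignments, for
#'   false-positive accounting).
#' @examples
#' fam <- genFamily(familySpec(nBackground = 20, nForeground = 3,
#'                             length = 50, seed = 42))
#' fam$alignment
#' fam$truth$plantedSites
#' @export
genFamily <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  set.seed(spec$seed)
  res20 <- aaProperties()$residue
  G <- granthamMatrix()
  L <- spec$length
  nBg <- spec$nBackground
  nFg <- spec$nForeground
  n <- nBg + nFg
  planted <- spec$plantedSites
  if (is.null(planted)) {
    planted <- sort(sample.int(L, spec$nPlanted))
  }
  anchors <- spec$anchors
  if (is.null(anchors) && spec$nPlanted > 0L) {
    anchors <- sample(res20, spec$nPlanted, replace = TRUE)
  }
  probs <- spec$backgroundProbs
  if (is.null(probs)) probs <- rep(1 / 20, 20)
  probs <- probs / sum(probs)

  M <- matrix("", nrow = n, ncol = L)
  if (is.null(spec$dirichlet)) {
    M[] <- sample(res20, n * L, replace = TRUE, prob = probs)
  } else {
    for (j in seq_len(L)) {
      w <- stats::rgamma(20, shape = spec$dirichlet)
      M[, j] <- sample(res20, n, replace = TRUE, prob = w / sum(w))
    }
  }
  fgRows <- nBg + seq_len(nFg)
  for (k in seq_along(planted)) {
    pool <- res20[G[, anchors[k]] <= spec$radius]
    if (length(pool) == 0L) {
      stop("conservation radius admits no residues at planted site ",
           planted[k])
    }
    M[fgRows, planted[k]] <- sample(pool, nFg, replace = TRUE)
  }
  if (spec$gapRate > 0) {
    gap <- matrix(stats::runif(n * L) < spec$gapRate, nrow = n)
    gap[1L, ] <- FALSE  # the reference record stays gap-free
    M[gap] <- .GAP
  }
  ids <- c("REF", sprintf("BG%03d", seq_len(nBg - 1L) + 1L),
           sprintf("FG%02d", seq_len(nFg)))
  aln <- ReceptorAlignment(stats::setNames(
    apply(M, 1L, paste0, collapse = ""), ids))
  nonPlanted <- setdiff(seq_len(L), planted)
  decoys <- sort(sample(nonPlanted, min(20L, length(nonPlanted))))
  list(alignment = aln,
       truth = list(foregroundIds = ids[fgRows], backgroundIds = ids,
                    referenceId = "REF", plantedSites = planted,
                    anchors = anchors, radius = spec$radius,
                    decoySites = decoys))
}

#' Specification of a synthetic two-group count matrix
#'
#' Emulates a two-group olfactory-epithelium RNA-seq design (default 4
#' samples per group, i.e. two animals sampled left and right) with
#' negative-binomial counts and planted down-regulated receptor genes.
#'
#' @param nGenes Total genes (default 2000).
#' @param nPerGroup Samples per group (default 4).
#' @param baselineMean Negative-binomial mean of unperturbed genes
#'   (default 100).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts (default 0.1).
#' @param nOr,nOrLike Number of genes labelled `OR` / `OR-like` (defaults
#'   60 and 80); the rest are `other`.
#' @param downOr,downOrLike,downOther Number of planted down-regulated
#'   genes per class (defaults 15, 49, 100, mirroring a candidate screen
#'   in which most down-regulated genes are not receptors).
#' @param foldChange Planted fold-change (treatment mean =
#'   baseline / foldChange; default 4).
#' @param seed Integer seed.
#' @return A validated list of class `"CountSpec"`.
#' @export
countSpec <- function(nGenes = 2000L, nPerGroup = 4L, baselineMean = 100,
                      dispersion = 0.1, nOr = 60L, nOrLike = 80L,
                      downOr = 15L, downOrLike = 49L, downOther = 100L,
                      foldChange = 4, seed = 1L) {
  spec <- list(nGenes = as.integer(nGenes), nPerGroup = as.integer(nPerGroup),
               baselineMean = baselineMean, dispersion = dispersion,
               nOr = as.integer(nOr), nOrLike = as.integer(nOrLike),
               downOr = as.integer(downOr), downOrLike = as.integer(downOrLike),
               downOther = as.integer(downOther), foldChange = foldChange,
               seed = as.integer(seed))
  if (spec$nPerGroup < 2L) stop("nPerGroup must be at least 2")
  if (baselineMean <= 0) stop("baselineMean must be positive")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (foldChange <= 0) stop("foldChange must be positive")
  if (spec$nOr + spec$nOrLike > spec$nGenes) {
    stop("more labelled receptor genes than genes")
  }
  if (spec$downOr > spec$nOr || spec$downOrLike > spec$nOrLike ||
      spec$downOther > spec$nGenes - spec$nOr - spec$nOrLike) {
    stop("more planted down-regulated genes than genes in a class")
  }
  structure(spec, class = "CountSpec")
}

#' Generate a synthetic two-group count matrix
#'
#' @param spec A [countSpec()].
#' @return A list with `counts` (genes x samples integer matrix), `groups`
#'   (factor, levels `control` then `treatment`), `annotation` (gene_id /
#'   class data.frame usable by [intersectCandidates()]) and `truth`
#'   (planted down-regulated ids per class and the fold change).
#' @examples
#' sim <- genCounts(countSpec(nGenes = 500, seed = 9))
#' dim(sim$counts)
#' @export
genCounts <- function(spec) {
  stopifnot(inherits(spec, "CountSpec"))
  set.seed(spec$seed)
  ng <- spec$nGenes
  npg <- spec$nPerGroup
  ids <- sprintf("g%05d", seq_len(ng))
  cls <- rep("other", ng)
  cls[seq_len(spec$nOr)] <- "OR"
  cls[spec$nOr + seq_len(spec$nOrLike)] <- "OR-like"
  downIds <- c(sample(ids[cls == "OR"], spec$downOr),
               sample(ids[cls == "OR-like"], spec$downOrLike),
               sample(ids[cls == "other"], spec$downOther))
  mu <- matrix(spec$baselineMean, nrow = ng, ncol = 2L * npg)
  trtCols <- npg + seq_len(npg)
  mu[ids %in% downIds, trtCols] <- spec$baselineMean / spec$foldChange
  counts <- if (spec$dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), nrow = ng)
  } else {
    matrix(stats::rnbinom(length(mu), size = 1 / spec$dispersion, mu = mu),
           nrow = ng)
  }
  dimnames(counts) <- list(ids, c(sprintf("Ctl_%d", seq_len(npg)),
                                  sprintf("Trt_%d", seq_len(npg))))
  list(counts = counts,
       groups = factor(rep(c("control", "treatment"), each = npg),
                       levels = c("control", "treatment")),
       annotation = data.frame(gene_id = ids, class = cls,
                               stringsAsFactors = FALSE),
       truth = list(downOr = downIds[seq_len(spec$downOr)],
                    downOrLike = downIds[spec$downOr +
                                           seq_len(spec$downOrLike)],
                    downOther = downIds[spec$downOr + spec$downOrLike +
                                          seq_len(spec$downOther)],
                    foldChange = spec$foldChange))
}

#' Specification of a synthetic dual-luciferase plate
#'
#' Each construct has a true fold-activation profile over the odor
#' concentrations (1 = non-responder).  Firefly luminescence is
#' baseline x fold-activation x mean-one lognormal noise; renilla is an
#' independent baseline x mean-one lognormal noise, so the noise is
#' multiplicative as in real reporter assays.
#'
#' @param constructs Named list; one numeric vector of fold activations per
#'   construct, aligned with `concentrations`.  Default: a responder
#'   (`OR7D4`, folds 1/2/3 at 0/100/200 µM) and a flat no-receptor control
#'   (`NoOR`).
#' @param concentrations Odor concentrations in µM (default `c(0, 100,
#'   200)`; the first must be the no-odor control, 0).
#' @param replicates Wells per (construct, concentration) (default 6).
#' @param cv Coefficient of variation of the multiplicative noise, applied
#'   independently to firefly and renilla (default 0.1).
#' @param fireflyBaseline,renillaBaseline Baseline luminescence (defaults
#'   1000 and 500).
#' @param seed Integer seed.
#' @return A validated list of class `"PlateSpec"`.
#' @export
plateSpec <- function(constructs = list(OR7D4 = c(1, 2, 3),
                                        NoOR = c(1, 1, 1)),
                      concentrations = c(0, 100, 200), replicates = 6L,
                      cv = 0.1, fireflyBaseline = 1000,
                      renillaBaseline = 500, seed = 1L) {
  spec <- list(constructs = constructs, concentrations = concentrations,
               replicates = as.integer(replicates), cv = cv,
               fireflyBaseline = fireflyBaseline,
               renillaBaseline = renillaBaseline, seed = as.integer(seed))
  if (length(constructs) == 0L || is.null(names(constructs)) ||
      any(!nzchar(names(constructs)))) {
    stop("constructs must be a non-empty named list")
  }
  folds <- unlist(constructs)
  if (any(folds <= 0)) stop("fold activations must be positive")
  if (any(lengths(constructs) != length(concentrations))) {
    stop("each construct needs one fold activation per concentration")
  }
  if (concentrations[1L] != 0) {
    stop("the first concentration must be the no-odor control (0)")
  }
  if (cv < 0) stop("cv must be non-negative")
  if (spec$replicates < 1L) stop("replicates must be positive")
  if (fireflyBaseline <= 0 || renillaBaseline <= 0) {
    stop("baselines must be positive")
  }
  structure(spec, class = "PlateSpec")
}

#' Generate a synthetic dual-luciferase plate
#'
#' @param spec A [plateSpec()].
#' @return A list with `plate` (a well-level `data.frame` with columns
#'   `construct`, `concentration_uM`, `replicate`, `firefly`, `renilla`)
#'   and `truth` (the fold-activation profiles).
#' @examples
#' sim <- genPlate(plateSpec(seed = 11))
#' head(sim$plate)
#' @export
genPlate <- function(spec) {
  stopifnot(inherits(spec, "PlateSpec"))
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  meanlog <- -sdlog^2 / 2  # mean-one lognormal noise
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      concentration_uM = spec$concentrations,
                      construct = names(spec$constructs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("construct", "concentration_uM", "replicate")]
  fold <- mapply(function(cn, cc) {
    spec$constructs[[cn]][match(cc, spec$concentrations)]
  }, grid$construct, grid$concentration_uM)
  nw <- nrow(grid)
  noise <- function() {
    if (spec$cv == 0) rep(1, nw)
    else stats::rlnorm(nw, meanlog = meanlog, sdlog = sdlog)
  }
  grid$firefly <- spec$fireflyBaseline * fold * noise()
  grid$renilla <- spec$renillaBaseline * noise()
  rownames(grid) <- NULL
  list(plate = grid, truth = list(constructs = spec$constructs,
                                  concentrations = spec$concentrations))
}
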