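#' Read a differential-expression results table
#'
#' Expects a TSV with header columns `gene_id`, `log2fc`, `p_value`
#' (extra columns are kept).  Validates uniqueness of gene ids, finiteness
#' of fold changes and the p-value range.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame`.
#' @export
readDETable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p_value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("DE table is missing column(s): ", paste(miss, collapse = ", "))
  }
  .validate_de(tab)
  tab
}

.validate_de <- function(de) {
  if (anyDuplicated(de$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(de$gene_id[duplicated(de$gene_id)]), collapse = ", "))
  }
  badFc <- !is.na(de$log2fc) & !is.finite(de$log2fc)
  if (any(badFc)) {
    stop("non-finite log2fc for gene(s): ",
         paste(de$gene_id[badFc], collapse = ", "))
  }
  badP <- !is.na(de$p_value) & (de$p_value < 0 | de$p_value > 1)
  if (any(badP)) {
    stop("p-value outside [0, 1] for gene(s): ",
         paste(de$gene_id[badP], collapse = ", "))
  }
  invisible(TRUE)
}

#' Filter differentially expressed genes by fold change and p-value
#'
#' Applies the standard cutoffs for calling DEGs from a results table:
#' `|log2fc| >= lfcCutoff` (boundary included) and `p < pCutoff` (boundary
#' excluded).  Genes with `NA` p-values (e.g. untestable all-zero genes)
#' are never selected.
#'
#' @param de A DE table (`data.frame` with `gene_id`, `log2fc`, `p_value`).
#' @param lfcCutoff Absolute log2 fold-change cutoff (default 1).
#' @param pCutoff Raw p-value cutoff (default 0.05).
#' @param direction `"down"` (log2fc <= -cutoff), `"up"` (>= +cutoff), or
#'   `"both"` (their union).
#' @return Character vector of gene ids passing the filter.
#' @examples
#' de <- data.frame(gene_id = c("g1", "g2"), log2fc = c(-1.5, -0.5),
#'                  p_value = c(0.01, 0.001))
#' filterDEGs(de)  # g1 only: g2 fails the fold-change cutoff
#' @export
filterDEGs <- function(de, lfcCutoff = 1, pCutoff = 0.05,
                       direction = c("down", "up", "both")) {
  direction <- match.arg(direction)
  stopifnot(lfcCutoff >= 0, pCutoff > 0, pCutoff <= 1)
  .validate_de(de)
  sig <- !is.na(de$p_value) & !is.na(de$log2fc) & de$p_value < pCutoff
  down <- sig & de$log2fc <= -lfcCutoff
  up <- sig & de$log2fc >= lfcCutoff
  keep <- switch(direction, down = down, up = up, both = down | up)
  de$gene_id[keep]
}

#' Partition down-regulated genes by receptor annotation
#'
#' Intersects a filtered gene set with an OR annotation, splitting it into
#' candidate OR genes, candidate OR-like genes and other genes.  Genes
#' absent from the annotation are treated as class `"other"` with a
#' warning.
#'
#' @param genes Character vector of gene ids (e.g. the down-regulated set
#'   from [filterDEGs()]).
#' @param annotation A `data.frame` with columns `gene_id` and `class`
#'   (values `"OR"`, `"OR-like"` or `"other"`), each gene classified once.
#' @return A list with `or`, `orLike`, `other` (character vectors) and
#'   `counts` (named integer vector).
#' @examples
#' ann <- data.frame(gene_id = c("a", "b", "c"),
#'                   class = c("OR", "OR-like", "other"))
#' intersectCandidates(c("a", "b", "c"), ann)
#' @export
intersectCandidates <- function(genes, annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "class") %in% names(annotation)))
  if (anyDuplicated(annotation$gene_id)) {
    stop("gene(s) classified more than once: ",
         paste(unique(annotation$gene_id[duplicated(annotation$gene_id)]),
               collapse = ", "))
  }
  badClass <- setdiff(unique(annotation$class), c("OR", "OR-like", "other"))
  if (length(badClass) > 0L) {
    stop("unknown annotation class(es): ", paste(badClass, collapse = ", "))
  }
  genes <- unique(as.character(genes))
  cls <- annotation$class[match(genes, annotation$gene_id)]
  unannotated <- is.na(cls)
  if (any(unannotated)) {
    warning(sum(unannotated), " gene(s) absent from the annotation, ",
            "treated as class 'other'")
    cls[unannotated] <- "other"
  }
  out <- list(or = genes[cls == "OR"], orLike = genes[cls == "OR-like"],
              other = genes[cls == "other"])
  out$counts <- c(OR = length(out$or), `OR-like` = length(out$orLike),
                  other = length(out$other))
  out
}

#' Read a two-column gene annotation TSV
#'
#' @param path TSV with header columns `gene_id` and `class`.
#' @return A `data.frame`.
#' @export
readGeneAnnotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class") %in% names(tab))) {
    stop("annotation must have columns gene_id and class")
  }
  tab
}

#' Simple two-group differential-expression test for synthetic counts
#'
#' A deliberately plain DE test so the synthetic pipeline runs end-to-end
#' without external DE software; it is not a negative-binomial model and is
#' no substitute for edgeR/DESeq2 on real data (whose results tables this
#' package consumes directly).  Counts are normalized to counts-per-million
#' with a pseudocount of 0.5 added to every count (library sizes from the
#' raw counts); the reported `log2fc` is the log2 ratio of treatment to
#' control mean CPM, and the p-value is a two-sided Welch t-test on the
#' per-sample log2 CPM values.  All-zero genes get `log2fc = 0` and an
#' `NA` p-value, so they can never enter a DEG set.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param groups Two-level factor (or character) of length `ncol(counts)`;
#'   the *first* level is the control/reference, the second the treatment.
#'   Each group needs at least two samples.
#' @param pseudocount Added to every count before CPM normalization
#'   (default 0.5).
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `p_value`.
#' @examples
#' spec <- countSpec(nGenes = 200, seed = 3)
#' sim <- genCounts(spec)
#' de <- simpleDETest(sim$counts, sim$groups)
#' head(de)
#' @export
simpleDETest <- function(counts, groups, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(counts)) {
    stop("groups must be a two-level factor of length ncol(counts)")
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least two samples")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  cpm <- sweep(counts + pseudocount, 2L, lib, "/") * 1e6
  lcpm <- log2(cpm)
  i1 <- which(groups == levels(groups)[1L])  # control
  i2 <- which(groups == levels(groups)[2L])  # treatment
  n1 <- length(i1)
  n2 <- length(i2)
  log2fc <- log2(rowMeans(cpm[, i2, drop = FALSE]) /
                   rowMeans(cpm[, i1, drop = FALSE]))
  rowVar <- function(m) {
    rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
  }
  m1 <- rowMeans(lcpm[, i1, drop = FALSE])
  m2 <- rowMeans(lcpm[, i2, drop = FALSE])
  v1 <- rowVar(lcpm[, i1, drop = FALSE])
  v2 <- rowVar(lcpm[, i2, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate variance: identical groups are untestable, separated
  # constant groups are maximally significant
  zeroSe <- se2 == 0
  flat <- abs(m2 - m1) < .Machine$double.eps^0.5
  p[zeroSe & flat] <- NA_real_
  p[zeroSe & !flat] <- 0
  allZero <- rowSums(counts) == 0
  log2fc[allZero] <- 0
  p[allZero] <- NA_real_
  data.frame(gene_id = rownames(counts), log2fc = unname(log2fc),
             p_value = unname(p), stringsAsFactors = FALSE)
}
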