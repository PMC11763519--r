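#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom Biostrings AAStringSet
NULL

.GAP <- "-"
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' ReceptorAlignment: a validated protein multiple sequence alignment
#'
#' Thin wrapper around a [Biostrings::AAStringSet] holding aligned receptor
#' protein sequences.  Validity enforces what every downstream operation
#' assumes: all records have identical width, ids are unique and non-empty,
#' and the alphabet is restricted to the 20 standard residues, the gap
#' character `-`, and (flagged, tolerated) `X` for ambiguous residues.
#' On construction sequences are upper-cased and `.` gaps are normalized to
#' `-`.
#'
#' @slot seqs An `AAStringSet` of equal-width aligned sequences.
#' @seealso [readAlignment()], [positionMap()], [extractColumn()]
#' @export
setClass("ReceptorAlignment", representation(seqs = "AAStringSet"))

setValidity("ReceptorAlignment", function(object) {
  s <- object@seqs
  if (length(s) == 0L) {
    return("alignment contains no sequences")
  }
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) {
    return("all records must have non-empty ids")
  }
  if (anyDuplicated(ids)) {
    return(paste0("duplicate record id(s): ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    off <- ids[w != w[1L]]
    return(paste0("ragged alignment: record(s) ",
                  paste(off, collapse = ", "),
                  " differ in width from record ", ids[1L]))
  }
  af <- Biostrings::alphabetFrequency(s, collapse = TRUE)
  allowed <- c(.AA20, .GAP, "X")
  bad <- setdiff(names(af)[af > 0], allowed)
  if (length(bad) > 0L) {
    return(paste0("disallowed character(s) in alignment: ",
                  paste(sQuote(bad), collapse = ", "),
                  " (alphabet is the 20 standard residues, '-' and 'X')"))
  }
  TRUE
})

#' Construct a ReceptorAlignment
#'
#' @param seqs A named character vector of aligned sequences or an
#'   `AAStringSet`.  Case is normalized to upper and `.` to `-`.
#' @return A [ReceptorAlignment-class] object.
#' @examples
#' aln <- ReceptorAlignment(c(refA = "M-KT", seqB = "MAKT"))
#' alignmentWidth(aln)
#' @export
ReceptorAlignment <- function(seqs) {
  if (methods::is(seqs, "AAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (!is.character(seqs)) {
    stop("'seqs' must be a named character vector or an AAStringSet")
  }
  seqs <- chartr(".", .GAP, toupper(seqs))
  methods::new("ReceptorAlignment", seqs = Biostrings::AAStringSet(seqs))
}

#' @describeIn ReceptorAlignment-class number of records
#' @param x A `ReceptorAlignment`.
#' @export
setMethod("length", "ReceptorAlignment", function(x) length(x@seqs))

#' @describeIn ReceptorAlignment-class record ids
#' @export
setMethod("names", "ReceptorAlignment", function(x) names(x@seqs))

#' Alignment width (number of columns)
#'
#' @param x A [ReceptorAlignment-class].
#' @return Integer scalar.
#' @export
alignmentWidth <- function(x) {
  stopifnot(methods::is(x, "ReceptorAlignment"))
  Biostrings::width(x@seqs)[1L]
}

#' Alignment as a character matrix
#'
#' @param x A [ReceptorAlignment-class].
#' @return A character matrix, rows named by record id, one column per
#'   alignment column.
#' @export
alignmentMatrix <- function(x) {
  stopifnot(methods::is(x, "ReceptorAlignment"))
  as.matrix(x@seqs)
}

setMethod("show", "ReceptorAlignment", function(object) {
  nx <- sum(Biostrings::alphabetFrequency(object@seqs, collapse = TRUE)["X"])
  cat("ReceptorAlignment with", length(object), "records x",
      alignmentWidth(object), "columns",
      if (nx > 0) sprintf("(%d 'X' residues flagged)", nx) else "", "\n")
  ids <- names(object)
  shown <- utils::head(ids, 5L)
  cat("  ids:", paste(shown, collapse = ", "),
      if (length(ids) > 5L) "..." else "", "\n")
})

#' Configuration of the per-site conservation screen
#'
#' Collects the statistical choices of [screenSites()]: which two-sample
#' test compares foreground against background pairwise Grantham distances,
#' sidedness, the significance level, permutation count and seed, the
#' minimum number of usable (non-gap, non-X) foreground residues a site
#' needs before a test is attempted, whether the background should exclude
#' the foreground receptors, and an optional multiplicity correction.
#'
#' @slot test `"mann_whitney"`, `"t_test"` or `"permutation"`.
#' @slot alternative `"less"` (one-sided: foreground more conserved) or
#'   `"two_sided"`.
#' @slot alpha Significance level in (0, 1).
#' @slot permutations Number of subset permutations (used when
#'   `test = "permutation"`; must be at least 100).
#' @slot seed Integer seed for permutation draws.
#' @slot minUngapped Minimum usable foreground residues per site.
#' @slot excludeForeground If `TRUE`, foreground ids are removed from the
#'   background set before computing background pairs.
#' @slot adjust `"none"` (raw p-values, the default) or `"BH"`.
#' @export
setClass("ScreenConfig",
         representation(test = "character", alternative = "character",
                        alpha = "numeric", permutations = "integer",
                        seed = "integer", minUngapped = "integer",
                        excludeForeground = "logical", adjust = "character"))

setValidity("ScreenConfig", function(object) {
  if (!object@test %in% c("mann_whitney", "t_test", "permutation")) {
    return("test must be one of mann_whitney, t_test, permutation")
  }
  if (!object@alternative %in% c("less", "two_sided")) {
    return("alternative must be 'less' or 'two_sided'")
  }
  if (!(object@alpha > 0 && object@alpha < 1)) {
    return("alpha must lie strictly between 0 and 1")
  }
  if (object@test == "permutation" && object@permutations < 100L) {
    return("permutations must be at least 100")
  }
  if (object@minUngapped < 2L) {
    return("minUngapped must be at least 2 (pairs need two residues)")
  }
  if (!object@adjust %in% c("none", "BH")) {
    return("adjust must be 'none' or 'BH'")
  }
  TRUE
})

#' @rdname ScreenConfig-class
#' @param test,alternative,alpha,permutations,seed,minUngapped,excludeForeground,adjust
#'   See the class slots.
#' @return A `ScreenConfig` object.
#' @examples
#' screenConfig()
#' screenConfig(test = "permutation", permutations = 1000, seed = 7)
#' @export
screenConfig <- function(test = c("mann_whitney", "t_test", "permutation"),
                         alternative = c("less", "two_sided"),
                         alpha = 0.05, permutations = 1000L, seed = 1L,
                         minUngapped = 2L, excludeForeground = FALSE,
                         adjust = c("none", "BH")) {
  methods::new("ScreenConfig",
               test = match.arg(test), alternative = match.arg(alternative),
               alpha = alpha, permutations = as.integer(permutations),
               seed = as.integer(seed), minUngapped = as.integer(minUngapped),
               excludeForeground = isTRUE(excludeForeground),
               adjust = match.arg(adjust))
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig:", object@test,
      sprintf("(%s), alpha=%g", object@alternative, object@alpha))
  if (object@test == "permutation") {
    cat(sprintf(", %d permutations, seed=%d", object@permutations,
                object@seed))
  }
  if (object@excludeForeground) cat(", background excludes foreground")
  if (object@adjust != "none") cat(", ", object@adjust, " adjusted", sep = "")
  cat("\n")
})
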