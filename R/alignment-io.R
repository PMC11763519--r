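#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal (`.aln`) file into a validated
#' [ReceptorAlignment-class].  Sequences are upper-cased and `.` gaps
#' normalized to `-`.  Ragged FASTA records are reported by id; duplicate
#' ids and empty files are errors.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A [ReceptorAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">refA", "M-KT", ">seqB", "MAKT"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  seqs <- switch(format,
    fasta = {
      s <- Biostrings::readAAStringSet(path, format = "fasta")
      if (length(s) == 0L) stop("empty alignment file: ", path)
      s
    },
    clustal = {
      msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
      if (nrow(msa) == 0L) stop("empty alignment file: ", path)
      methods::as(msa, "AAStringSet")
    })
  ReceptorAlignment(seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param x A [ReceptorAlignment-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(x, path) {
  stopifnot(methods::is(x, "ReceptorAlignment"))
  Biostrings::writeXStringSet(x@seqs, filepath = path)
  invisible(path)
}

#' Map ungapped reference positions to alignment columns
#'
#' Residue positions of cavity sites are given in the ungapped coordinates
#' of a reference receptor (e.g. F178 of OR7D4); the screen needs them as
#' alignment columns.  For every non-gap character of the reference record
#' this returns one (position, column) pair; the mapping is strictly
#' increasing in both coordinates and position -> column -> position is the
#' identity.  Columns where the reference itself has a gap are never
#' assigned to a reference position.
#'
#' @param x A [ReceptorAlignment-class].
#' @param referenceId Id of the reference record.
#' @return A `data.frame` with columns `position` (1-based ungapped),
#'   `column` (1-based alignment column) and `residue`.
#' @examples
#' aln <- ReceptorAlignment(c(ref = "M-KT", other = "MAKT"))
#' positionMap(aln, "ref")  # residue 2 (K) sits in column 3
#' @export
positionMap <- function(x, referenceId) {
  stopifnot(methods::is(x, "ReceptorAlignment"))
  if (!referenceId %in% names(x)) {
    stop("reference id ", sQuote(referenceId), " not found in alignment")
  }
  chars <- strsplit(as.character(x@seqs[[referenceId]]), "", fixed = TRUE)[[1L]]
  cols <- which(chars != .GAP)
  if (length(cols) == 0L) {
    stop("reference record ", sQuote(referenceId),
         " is all gaps (zero-length ungapped reference)")
  }
  data.frame(position = seq_along(cols), column = cols,
             residue = chars[cols], stringsAsFactors = FALSE)
}

#' Extract one alignment column as a residue multiset
#'
#' Returns the residues of the selected records at a column, with gaps and
#' `X` separated out and counted rather than mixed into the residue tally.
#'
#' @param x A [ReceptorAlignment-class].
#' @param column 1-based column index.
#' @param ids Record ids to include (default: all records).
#' @return A list with `residues` (named integer vector of counts over the
#'   standard residues observed), `nGap`, `nX`, and `chars` (the per-record
#'   characters, named by id, gaps and X included).
#' @examples
#' aln <- ReceptorAlignment(c(a = "LAK", b = "-AK", c = "LAK"))
#' extractColumn(aln, 1)
#' @export
extractColumn <- function(x, column, ids = names(x)) {
  stopifnot(methods::is(x, "ReceptorAlignment"))
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) || column < 1L ||
      column > alignmentWidth(x)) {
    stop("column must be a single index in [1, ", alignmentWidth(x), "]")
  }
  missing <- setdiff(ids, names(x))
  if (length(missing) > 0L) {
    stop("id(s) not in alignment: ", paste(missing, collapse = ", "))
  }
  if (length(ids) == 0L) {
    return(list(residues = stats::setNames(integer(0), character(0)),
                nGap = 0L, nX = 0L,
                chars = stats::setNames(character(0), character(0))))
  }
  ch <- as.character(Biostrings::subseq(x@seqs[ids], start = column,
                                        width = 1L))
  names(ch) <- ids
  plain <- ch[!ch %in% c(.GAP, "X")]
  counts <- table(factor(plain, levels = sort(unique(plain))))
  list(residues = stats::setNames(as.integer(counts), names(counts)),
       nGap = sum(ch == .GAP), nX = sum(ch == "X"), chars = ch)
}

#' Site panels: cavity residue positions of the reference receptor
#'
#' A site panel lists the ligand-binding-cavity positions to screen, in
#' 1-based ungapped reference coordinates, optionally with the expected
#' reference residue (checked against the alignment when screening) and a
#' free-text label such as the structural element (TM5, ECL2, ...).
#'
#' @param positions Integer vector of 1-based ungapped reference positions.
#' @param residues Optional expected reference residues (one-letter codes,
#'   `NA` for unspecified).
#' @param labels Optional free-text labels.
#' @return A `data.frame` with columns `position`, `residue`, `label`.
#' @examples
#' sitePanel(c(178, 203), residues = c("F", "T"), labels = c("ECL2", "TM5"))
#' @export
sitePanel <- function(positions, residues = NA_character_,
                      labels = NA_character_) {
  positions <- as.integer(positions)
  if (length(positions) == 0L || anyNA(positions) || any(positions < 1L)) {
    stop("positions must be 1-based positive integers")
  }
  if (anyDuplicated(positions)) {
    stop("duplicate panel position(s): ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  }
  residues <- toupper(rep_len(as.character(residues), length(positions)))
  known <- is.na(residues) | residues %in% .AA20
  if (!all(known)) {
    stop("invalid expected residue code(s): ",
         paste(unique(residues[!known]), collapse = ", "))
  }
  data.frame(position = positions, residue = residues,
             label = rep_len(as.character(labels), length(positions)),
             stringsAsFactors = FALSE)
}

#' Read a site panel from TSV
#'
#' Expects 1-3 columns: position, optional expected residue, optional
#' label.  A header line is detected by a non-numeric first field.
#'
#' @param path Path to the TSV file.
#' @return A site-panel `data.frame` as from [sitePanel()].
#' @export
readSitePanel <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             colClasses = "character")
  header <- is.na(suppressWarnings(as.numeric(first[[1L]])))
  tab <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(tab) < 1L) stop("site panel file has no columns: ", path)
  sitePanel(positions = as.integer(tab[[1L]]),
            residues = if (ncol(tab) >= 2L) tab[[2L]] else NA_character_,
            labels = if (ncol(tab) >= 3L) tab[[3L]] else NA_character_)
}
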