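#' Read a dual-luciferase plate table
#'
#' Expects a TSV with header columns `construct`, `concentration_uM`,
#' `replicate`, `firefly`, `renilla`.  Replicate indices must be unique
#' within each (construct, concentration) cell and luminescence values
#' finite.
#'
#' @param path Path to the TSV file.
#' @return A validated plate `data.frame`.
#' @export
readPlate <- function(path) {
  plate <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_plate(plate)
  plate
}

.validate_plate <- function(plate) {
  need <- c("construct", "concentration_uM", "replicate", "firefly",
            "renilla")
  miss <- setdiff(need, names(plate))
  if (length(miss) > 0L) {
    stop("plate is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(plate$firefly)) || !all(is.finite(plate$renilla))) {
    stop("non-finite luminescence values in plate")
  }
  key <- paste(plate$construct, plate$concentration_uM, plate$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate replicate index within (construct, concentration): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  invisible(TRUE)
}

#' Normalize reporter wells by the renilla internal control
#'
#' Per-well response is the ratio of firefly to renilla luminescence,
#' which cancels well-to-well transfection-efficiency and cell-number
#' variation.  Wells with `renilla <= 0` cannot be normalized; they are
#' flagged invalid (`valid = FALSE`, `response = NA`) with a warning and
#' excluded by downstream tests.  A plate with no valid well is an error.
#'
#' @param plate A plate `data.frame` (see [readPlate()]).
#' @return The plate with `response` and `valid` columns appended.
#' @examples
#' plate <- data.frame(construct = "OR7D4", concentration_uM = 0,
#'                     replicate = 1:2, firefly = c(5000, 0),
#'                     renilla = c(1000, 1000))
#' normalizeWells(plate)$response  # 5.0, 0.0
#' @export
normalizeWells <- function(plate) {
  .validate_plate(plate)
  valid <- plate$renilla > 0
  if (!any(valid)) {
    stop("no valid wells: all renilla readings are <= 0")
  }
  if (!all(valid)) {
    warning(sum(!valid), " well(s) with renilla <= 0 flagged invalid ",
            "and excluded from analysis")
  }
  plate$response <- ifelse(valid, plate$firefly / plate$renilla, NA_real_)
  plate$valid <- valid
  plate
}

.two_group_p <- function(a, b, test, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) {
    return(NA_real_)
  }
  ht <- switch(test,
    t_test = tryCatch(stats::t.test(a, b, alternative = alternative),
                      error = function(e) NULL),
    mann_whitney = tryCatch(suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative)),
      error = function(e) NULL))
  if (is.null(ht)) NA_real_ else ht$p.value
}

.sig_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Odor response of each construct against its no-odor control
#'
#' For every (construct, concentration) cell, summarizes the normalized
#' responses (mean, SEM) and tests stimulated wells (concentration > 0)
#' against the no-odor wells (concentration 0) of the same construct.
#' Zero-concentration rows are included with `pValue = NA` (they are the
#' reference).  Cells with fewer than two replicates on either side get
#' `pValue = NA` but their means are still reported.
#'
#' @param plate A plate `data.frame`; normalized on the fly if the
#'   `response` column is absent.
#' @param test `"t_test"` (Welch, the default) or `"mann_whitney"`.
#' @return A `data.frame` with columns `construct`, `concentration_uM`,
#'   `n`, `meanResponse`, `sem`, `pValue`, `signif` (`"ns"`, `"*"` for
#'   p < 0.05, `"**"` for p < 0.01).
#' @examples
#' sim <- genPlate(plateSpec(seed = 2))
#' responseTest(sim$plate)
#' @export
responseTest <- function(plate, test = c("t_test", "mann_whitney")) {
  test <- match.arg(test)
  if (is.null(plate$response)) {
    plate <- normalizeWells(plate)
  }
  plate <- plate[plate$valid, , drop = FALSE]
  if (all(plate$concentration_uM == 0)) {
    stop("no stimulated wells (all concentrations are 0)")
  }
  cells <- unique(plate[, c("construct", "concentration_uM")])
  cells <- cells[order(cells$construct, cells$concentration_uM), ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cn <- cells$construct[i]
    cc <- cells$concentration_uM[i]
    y <- plate$response[plate$construct == cn &
                          plate$concentration_uM == cc]
    ref <- plate$response[plate$construct == cn &
                            plate$concentration_uM == 0]
    p <- if (cc == 0) NA_real_ else .two_group_p(y, ref, test)
    data.frame(construct = cn, concentration_uM = cc, n = length(y),
               meanResponse = mean(y),
               sem = if (length(y) > 1L) stats::sd(y) / sqrt(length(y))
                     else NA_real_,
               pValue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$signif <- .sig_tier(out$pValue)
  rownames(out) <- NULL
  out
}

#' Mutant responses relative to the wild-type receptor
#'
#' At a single odor concentration, expresses every construct's normalized
#' responses relative to the mean of a no-receptor (or otherwise negative)
#' control group, then tests each mutant against the wild-type construct.
#' The control group's relative mean is 1 by construction; the wild-type
#' row is tested against the control group.
#'
#' @param plate A plate `data.frame`; normalized on the fly if needed.
#' @param wildtype Construct label of the wild-type receptor.
#' @param control Construct label of the negative-control group.
#' @param concentration Odor concentration (µM) at which to compare; may be
#'   omitted when the plate has exactly one non-zero concentration.
#' @param test `"t_test"` (Welch, the default) or `"mann_whitney"`.
#' @return A `data.frame` with columns `construct`, `n`, `relMean`
#'   (mean response / control mean), `sem`, `pValue` (vs wild-type for
#'   mutants, vs control for the wild-type row, `NA` for the control row)
#'   and `signif`.
#' @examples
#' spec <- plateSpec(constructs = list(
#'   NoOR = c(1, 1, 1), OR7D4 = c(1, 2, 3), OR7D4_F178A = c(1, 1.2, 1.4)),
#'   seed = 5)
#' relativeResponse(genPlate(spec)$plate, wildtype = "OR7D4",
#'                  control = "NoOR", concentration = 200)
#' @export
relativeResponse <- function(plate, wildtype, control, concentration = NULL,
                             test = c("t_test", "mann_whitney")) {
  test <- match.arg(test)
  if (is.null(plate$response)) {
    plate <- normalizeWells(plate)
  }
  plate <- plate[plate$valid, , drop = FALSE]
  nz <- sort(unique(plate$concentration_uM[plate$concentration_uM > 0]))
  if (is.null(concentration)) {
    if (length(nz) != 1L) {
      stop("plate has ", length(nz), " non-zero concentrations; ",
           "state which one to compare at")
    }
    concentration <- nz
  }
  sel <- plate[plate$concentration_uM == concentration, , drop = FALSE]
  for (lbl in c(wildtype, control)) {
    if (!lbl %in% sel$construct) {
      stop("construct ", sQuote(lbl), " has no wells at ", concentration,
           " µM")
    }
  }
  resp <- function(cn) sel$response[sel$construct == cn]
  if (length(resp(control)) < 2L || length(resp(wildtype)) < 2L) {
    stop("control and wild-type each need at least two replicates")
  }
  ctlMean <- mean(resp(control))
  if (ctlMean <= 0) {
    stop("control-group mean response is <= 0; cannot form ratios")
  }
  constructs <- unique(c(control, wildtype,
                         setdiff(sel$construct, c(control, wildtype))))
  wtRel <- resp(wildtype) / ctlMean
  rows <- lapply(constructs, function(cn) {
    rel <- resp(cn) / ctlMean
    p <- if (cn == control) NA_real_
         else if (cn == wildtype) .two_group_p(rel, resp(control) / ctlMean,
                                               test)
         else .two_group_p(rel, wtRel, test)
    data.frame(construct = cn, n = length(rel), relMean = mean(rel),
               sem = if (length(rel) > 1L) stats::sd(rel) / sqrt(length(rel))
                     else NA_real_,
               pValue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$signif <- .sig_tier(out$pValue)
  rownames(out) <- NULL
  out
}
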