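#' Build a reverse-decoy database
#'
#' Reverses every template sequence of the database (per record, full
#' sequence, translated-stop marks travelling with their positions) and
#' tags the genome id with a `decoy_` prefix so exported headers mark the
#' records as decoys. Record count is preserved.
#'
#' @param db a [ChimericPeptideDB-class].
#' @return A [ChimericPeptideDB-class] of decoy templates.
#' @export
makeDecoyDb <- function(db) {
  tpl <- db@templates
  tpl$peptide <- vapply(strsplit(tpl$peptide, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""), "")
  new("ChimericPeptideDB",
    genomeId = paste0("decoy_", db@genomeId),
    genomeLength = db@genomeLength, k = db@k, segCodons = db@segCodons,
    codeId = db@codeId, templates = tpl)
}

#' Target-decoy q-values
#'
#' Simple target-decoy competition estimator on a mixed score list. At a
#' score threshold `s`, `FDR(s) = #(decoy >= s) / max(1, #(target >= s))`;
#' the q-value of a hit is the minimum FDR over all observed thresholds at
#' or below its score, capped at 1. Higher scores are better; ties share a
#' q. Vendor scores are taken as given -- no re-scoring is performed.
#'
#' @param score numeric vector of hit scores (finite).
#' @param isDecoy logical vector, same length.
#' @return numeric vector of q-values aligned with the input.
#' @examples
#' targetDecoyQvalues(c(10, 8, 9), c(FALSE, FALSE, TRUE))
#' # 0.0 0.5 0.5
#' @export
targetDecoyQvalues <- function(score, isDecoy) {
  stopifnot(length(score) == length(isDecoy), all(is.finite(score)))
  isDecoy <- as.logical(isDecoy)
  if (!any(!isDecoy)) stop("no target hits", call. = FALSE)
  thr <- sort(unique(score), decreasing = TRUE)
  ord <- order(score, decreasing = TRUE)
  ## cumulative counts at each threshold
  cumD <- cumsum(isDecoy[ord])
  cumT <- cumsum(!isDecoy[ord])
  last <- cumsum(tabulate(match(score[ord], thr), nbins = length(thr)))
  fdr <- pmin(1, cumD[last] / pmax(1, cumT[last]))
  ## q at threshold i = min FDR over thresholds i..n (scores <= thr[i])
  q <- rev(cummin(rev(fdr)))
  q[match(score, thr)]
}
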