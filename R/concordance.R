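#' Concordance between eDNA and dip-net survey methods
#'
#' Reduces each sampling event to one site-level eDNA call (positive if at
#' least one non-discarded replicate is positive) and one dip-net call, and
#' cross-tabulates them.  Agreement with positive dip-net results is
#' E+D+ / (E+D+ + E-D+); agreement with negative dip-net results is
#' E-D- / (E+D- + E-D-).  Percentages follow the package's reporting
#' convention (see [roundPercent()]).  Events whose replicates are all
#' discarded/missing are excluded from the counts.
#'
#' @param events list of [SamplingEvent-class] with calls and dip-net results
#'   attached.
#' @param species species code.
#' @return object of class `"concordance"`: a list with `counts` (named
#'   vector `EpDp`, `EpDn`, `EnDp`, `EnDn`), `posAgreement`, `negAgreement`
#'   (percentages; `NA` when undefined) and `nEvents`.
#' @seealso [concordanceFromCounts()] for working directly from a published
#'   2x2 panel.
#' @export
concordanceSummary <- function(events, species) {
  counts <- c(EpDp = 0L, EpDn = 0L, EnDp = 0L, EnDn = 0L)
  for (e in events) {
    if (!species %in% names(e@calls))
      stop("event ", e@eventId, " lacks eDNA calls for ", species)
    calls <- e@calls[[species]]
    informative <- calls %in% c("positive", "negative")
    if (!any(informative)) next
    ednaPos <- any(calls == "positive")
    dipPos <- isTRUE(unname(e@dipnet[species]))
    cell <- paste0(if (ednaPos) "Ep" else "En", if (dipPos) "Dp" else "Dn")
    counts[cell] <- counts[cell] + 1L
  }
  concordanceFromCounts(counts["EpDp"], counts["EpDn"],
                        counts["EnDp"], counts["EnDn"])
}

#' Concordance summary from a published 2x2 panel
#'
#' @param EpDp,EpDn,EnDp,EnDn counts of events by eDNA (E) and dip-net (D)
#'   call: both positive, eDNA-only positive, dip-net-only positive, both
#'   negative.
#' @return a `"concordance"` object; see [concordanceSummary()].  Agreement
#'   with positive dip-net results is `NA` (undefined, not 0) when there are
#'   no dip-net positives, and likewise for negatives.
#' @examples
#' concordanceFromCounts(22, 0, 4, 26)$posAgreement  # 85
#' concordanceFromCounts(5, 3, 3, 2)$posAgreement    # 62.5
#' @export
concordanceFromCounts <- function(EpDp, EpDn, EnDp, EnDn) {
  counts <- c(EpDp = as.integer(EpDp), EpDn = as.integer(EpDn),
              EnDp = as.integer(EnDp), EnDn = as.integer(EnDn))
  nPos <- unname(counts["EpDp"] + counts["EnDp"])
  nNeg <- unname(counts["EpDn"] + counts["EnDn"])
  structure(class = "concordance", list(
    counts = counts,
    posAgreement = if (nPos > 0) roundPercent(counts[["EpDp"]] / nPos)
                   else NA_real_,
    negAgreement = if (nNeg > 0) roundPercent(counts[["EnDn"]] / nNeg)
                   else NA_real_,
    nEvents = sum(counts)))
}

#' @export
print.concordance <- function(x, ...) {
  cat("eDNA vs dip-net concordance (", x$nEvents, " events)\n", sep = "")
  m <- matrix(x$counts[c("EpDp", "EpDn", "EnDp", "EnDn")], 2, 2,
              byrow = TRUE,
              dimnames = list(c("eDNA+", "eDNA-"),
                              c("dip-net+", "dip-net-")))
  print(m)
  fmt <- function(v) if (is.na(v)) "undefined" else paste0(v, "%")
  cat("agreement with positive dip-net:", fmt(x$posAgreement), "\n")
  cat("agreement with negative dip-net:", fmt(x$negAgreement), "\n")
  invisible(x)
}
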