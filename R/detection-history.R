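#' Construct a DetectionHistory directly
#'
#' Low-level constructor used by tests and simulations; most analyses build
#' the object from sampling events with [buildDetectionHistory()].
#'
#' @param y observation matrix coded \{0, 1, 2, NA\}.
#' @param siteIds site identifiers (defaults to row numbers).
#' @param siteCovs per-site covariate `data.frame`.
#' @param obsCovs named list of per-replicate covariate matrices.
#' @param knownOccupied logical per-site flags (defaults to sites holding a
#'   certain detection).
#' @return a [DetectionHistory-class] object.
#' @examples
#' makeDetectionHistory(rbind(c(1, 0, 0), c(0, 0, 0)))
#' @export
makeDetectionHistory <- function(y, siteIds = NULL, siteCovs = NULL,
                                 obsCovs = list(), knownOccupied = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (is.null(siteIds)) siteIds <- as.character(seq_len(nrow(y)))
  if (is.null(siteCovs)) siteCovs <- data.frame()[seq_len(nrow(y)), , drop = FALSE]
  if (is.null(knownOccupied))
    knownOccupied <- rowSums(y == 2, na.rm = TRUE) > 0
  new("DetectionHistory", y = y, siteIds = as.character(siteIds),
      siteCovs = siteCovs, obsCovs = obsCovs,
      knownOccupied = knownOccupied)
}

#' @rdname obsMatrix
setMethod("obsMatrix", "DetectionHistory", function(object) object@y)

#' @rdname obsMatrix
setMethod("siteCovs", "DetectionHistory", function(object) object@siteCovs)

#' @rdname obsMatrix
setMethod("obsCovs", "DetectionHistory", function(object) object@obsCovs)

#' @rdname obsMatrix
setMethod("knownOccupied", "DetectionHistory",
          function(object) object@knownOccupied)

#' @rdname nSites
setMethod("nSites", "DetectionHistory", function(object) nrow(object@y))

setMethod("show", "DetectionHistory", function(object) {
  y <- object@y
  cat(sprintf("DetectionHistory: %d sites x %d replicates\n",
              nrow(y), ncol(y)))
  cat(sprintf("  detections: %d uncertain, %d certain; %d NA cells\n",
              sum(y == 1, na.rm = TRUE), sum(y == 2, na.rm = TRUE),
              sum(is.na(y))))
  cat(sprintf("  known-occupied sites: %d\n", sum(object@knownOccupied)))
  if (ncol(object@siteCovs))
    cat("  site covariates:", paste(names(object@siteCovs), collapse = ", "),
        "\n")
  if (length(object@obsCovs))
    cat("  replicate covariates:",
        paste(names(object@obsCovs), collapse = ", "), "\n")
})

#' Build a detection history from called sampling events
#'
#' Reduces per-replicate eDNA calls for one species, together with the
#' event's dip-net outcome, to the coded sites-by-replicates matrix that the
#' occupancy models consume.  With `certainFromDipnet = TRUE`, eDNA-positive
#' replicates at dip-net-positive events are coded 2 (certain) and positives
#' at dip-net-negative events are coded 1 (uncertain); otherwise all
#' positives are coded 1.  Dip-net-positive events are flagged known
#' occupied.  Discarded or missing replicates are coded `NA`; events whose
#' replicates are all `NA` are dropped and counted in the QC summary.
#'
#' Each sampling event is one site, even for repeat visits to the same pool;
#' the per-site covariates `avgVolume` (mean volume filtered across the
#' event's replicates, mL) and `poolArea` (m2), and per-replicate covariates
#' `volume` (mL) and `protocol` (0 = field, 1 = lab) are carried along.
#'
#' @param events list of [SamplingEvent-class] with calls and dip-net results
#'   attached.
#' @param species species code to extract.
#' @param certainFromDipnet use the certain/uncertain coding (default).
#' @return a [DetectionHistory-class]; attribute `"qc"` summarizes discarded
#'   replicates and dropped events.
#' @seealso [attachCalls()], [attachDipnet()], [occuFit()], [occuFPFit()]
#' @export
buildDetectionHistory <- function(events, species, certainFromDipnet = TRUE) {
  events <- events[order(vapply(events, function(e) e@eventId, ""))]
  keep <- vapply(events, function(e) species %in% names(e@calls), TRUE)
  if (!all(keep))
    stop("event(s) without eDNA calls for species ", species, ": ",
         paste(vapply(events[!keep], function(e) e@eventId, ""),
               collapse = ", "))
  J <- max(vapply(events, function(e) nrow(e@replicates), 1L))
  n <- length(events)
  y <- matrix(NA_integer_, n, J)
  vol <- matrix(NA_real_, n, J)
  prot <- matrix(NA_real_, n, J)
  known <- logical(n)
  nDiscarded <- 0L
  for (i in seq_len(n)) {
    e <- events[[i]]
    dip <- isTRUE(unname(e@dipnet[species]))
    known[i] <- dip
    calls <- e@calls[[species]]
    nDiscarded <- nDiscarded + sum(calls == "discarded")
    code <- ifelse(calls == "positive",
                   if (certainFromDipnet && dip) 2L else 1L,
                   ifelse(calls == "negative", 0L, NA_integer_))
    jj <- seq_along(code)
    y[i, jj] <- code
    vol[i, jj] <- e@replicates$volumeMl
    prot[i, jj] <- as.numeric(e@replicates$protocol == "lab")
  }
  allNA <- rowSums(!is.na(y)) == 0
  droppedEvents <- vapply(events[allNA], function(e) e@eventId, "")
  sel <- !allNA
  sc <- data.frame(
    avgVolume = vapply(events, function(e) mean(e@replicates$volumeMl), 0),
    poolArea = vapply(events, function(e) e@poolAreaM2, 0)
  )[sel, , drop = FALSE]
  rownames(sc) <- NULL
  dh <- makeDetectionHistory(
    y[sel, , drop = FALSE],
    siteIds = vapply(events, function(e) e@eventId, "")[sel],
    siteCovs = sc,
    obsCovs = list(volume = vol[sel, , drop = FALSE],
                   protocol = prot[sel, , drop = FALSE]),
    knownOccupied = known[sel])
  attr(dh, "qc") <- list(nDiscardedReplicates = nDiscarded,
                         droppedEvents = droppedEvents)
  dh
}

#' Collapse certain/uncertain codes to a binary detection history
#'
#' @param history a [DetectionHistory-class].
#' @return the same object with codes \{1, 2\} collapsed to 1.
#' @export
collapseBinary <- function(history) {
  y <- history@y
  y[y == 2L] <- 1L
  initialize(history, y = y)
}
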