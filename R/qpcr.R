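#' Single-assay qPCR plate
#'
#' One physical plate: every well tests for the same target species.  Wells
#' carry a role — `sample`, `ntc` (no-template control), `positive_control`,
#' `extraction_blank` or `field_negative` — and a Cq (`NA` = never crossed
#' threshold within the 50-cycle protocol).  Field-negative wells carry the
#' event ID of the sampling event whose filtration they accompanied as their
#' `sample_id`, so that QC can discard the event when they amplify.
#'
#' @slot plateId plate identifier.
#' @slot assay species code tested by the plate.
#' @slot wells `data.frame` with columns `well`, `role`, `sample_id`, `cq`.
#' @export
setClass("QpcrPlate",
  representation(plateId = "character", assay = "character",
                 wells = "data.frame"))

setValidity("QpcrPlate", function(object) {
  msg <- character()
  need <- c("well", "role", "sample_id", "cq")
  if (!all(need %in% names(object@wells)))
    msg <- c(msg, paste("wells must have columns:", paste(need, collapse = ", ")))
  else {
    roles <- c("sample", "ntc", "positive_control", "extraction_blank",
               "field_negative")
    if (!all(object@wells$role %in% roles))
      msg <- c(msg, paste("well roles must be one of:",
                          paste(roles, collapse = ", ")))
    cq <- object@wells$cq
    if (any(!is.na(cq) & (cq <= 0 | cq > 50)))
      msg <- c(msg, "cq values must lie in (0, 50]")
  }
  if (length(object@assay) != 1)
    msg <- c(msg, "exactly one assay per plate")
  if (length(msg)) msg else TRUE
})

#' @rdname QpcrPlate-class
#' @param plateId plate identifier.
#' @param assay species code.
#' @param wells `data.frame` with columns `well`, `role`, `sample_id`, `cq`.
#' @return a `QpcrPlate` object.
#' @export
QpcrPlate <- function(plateId, assay, wells) {
  new("QpcrPlate", plateId = as.character(plateId),
      assay = as.character(assay), wells = wells)
}

setMethod("show", "QpcrPlate", function(object) {
  cat(sprintf("QpcrPlate %s (%s): %d wells, %d amplified\n",
              object@plateId, object@assay, nrow(object@wells),
              sum(!is.na(object@wells$cq))))
})

#' Read a long-format qPCR results CSV
#'
#' Expects columns `plate_id`, `well`, `assay`, `sample_id`, `role`, `cq`
#' (empty cell = no amplification).
#'
#' @param path CSV file path.
#' @return list of [QpcrPlate-class], one per plate, in plate-ID order.
#' @export
readQpcrLong <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "assay", "sample_id", "role", "cq")
  if (!all(need %in% names(df)))
    stop("qPCR table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$cq <- suppressWarnings(as.numeric(df$cq))
  plates <- lapply(split(df, df$plate_id), function(g) {
    if (length(unique(g$assay)) != 1)
      stop("plate ", g$plate_id[1], " mixes assays")
    QpcrPlate(g$plate_id[1], g$assay[1],
              g[, c("well", "role", "sample_id", "cq")])
  })
  plates[order(names(plates))]
}

#' Call one well amplified or not
#'
#' A well counts as amplified when it reports a Cq at or before `maxCycle`.
#' For eDNA samples the default counts any reported Cq within the 50-cycle
#' protocol; tighter cutoffs apply only to tissue identification
#' ([classifySpecimen()]).
#'
#' @param cq quantification cycle, or `NA` for no amplification (vectorized).
#' @param maxCycle latest cycle that counts as amplified (<= 50).
#' @return logical vector.
#' @examples
#' callWell(c(18.4, NA, 31), maxCycle = 30)
#' @export
callWell <- function(cq, maxCycle = 50) {
  if (maxCycle > 50) stop("maxCycle must be <= 50 (protocol length)")
  if (any(!is.na(cq) & cq <= 0)) stop("cq values must be positive")
  !is.na(cq) & cq <= maxCycle
}

#' Call a sample from its quadruplicate wells
#'
#' Applies the 2-of-4 calling rule: two or more amplified wells make the
#' sample positive; zero make it negative; exactly one triggers a re-run,
#' after which a single amplified well suffices for a positive and none
#' makes it negative.
#'
#' @param firstRun logical vector of 4 well amplification flags.
#' @param rerun optional logical vector of re-run well flags.
#' @return list with `nAmplified` (first run), `status` one of `"positive"`,
#'   `"negative"`, `"rerun_needed"`, and `rerunApplied`.
#' @examples
#' callSample(c(TRUE, TRUE, FALSE, FALSE))$status             # positive
#' callSample(c(TRUE, FALSE, FALSE, FALSE))$status            # rerun_needed
#' callSample(c(TRUE, FALSE, FALSE, FALSE), rep(FALSE, 4))$status # negative
#' @export
callSample <- function(firstRun, rerun = NULL) {
  if (length(firstRun) != 4)
    stop("exactly 4 first-run wells required")
  n <- sum(firstRun)
  if (n >= 2 || n == 0) {
    if (!is.null(rerun))
      warning("first run was conclusive (", n, "/4); re-run ignored")
    return(list(nAmplified = n,
                status = if (n >= 2) "positive" else "negative",
                rerunApplied = FALSE))
  }
  if (is.null(rerun))
    return(list(nAmplified = n, status = "rerun_needed",
                rerunApplied = FALSE))
  list(nAmplified = n,
       status = if (any(rerun)) "positive" else "negative",
       rerunApplied = TRUE)
}

#' Quality-control a qPCR plate
#'
#' Flags no-template-control amplification, positive-control failure (a
#' positive-control sample with no amplifying well), and extraction-blank or
#' field-negative amplification.  A field negative that amplifies discards
#' all water replicates of the sampling event it accompanied (its
#' `sample_id`).
#'
#' @param plate a [QpcrPlate-class].
#' @return list with logical flags `ntcAmplified`, `positiveControlFailed`,
#'   `blankAmplified`, overall `valid`, character vector `discardEvents` of
#'   event IDs whose field negative amplified, and `missingControls`.
#' @export
qcPlate <- function(plate) {
  w <- plate@wells
  amp <- callWell(w$cq)
  ntc <- w$role == "ntc"
  pc <- w$role == "positive_control"
  missing <- character()
  if (!any(ntc)) missing <- c(missing, "ntc")
  if (!any(pc)) missing <- c(missing, "positive_control")
  if (length(missing))
    warning("plate ", plate@plateId, " lacks control(s): ",
            paste(missing, collapse = ", "), "; calls still emitted")
  pcFailed <- FALSE
  if (any(pc)) {
    perPc <- tapply(amp[pc], w$sample_id[pc], any)
    pcFailed <- !all(perPc)
  }
  blanks <- w$role %in% c("extraction_blank", "field_negative")
  fneg <- w$role == "field_negative"
  discard <- unique(w$sample_id[fneg & amp])
  res <- list(
    plateId = plate@plateId,
    ntcAmplified = any(amp[ntc]),
    positiveControlFailed = pcFailed,
    blankAmplified = any(amp[blanks]),
    discardEvents = discard,
    missingControls = missing)
  res$valid <- !res$ntcAmplified && !pcFailed && length(missing) == 0
  res
}

#' Classify a tissue specimen from quadruplicate Cq values
#'
#' For high-concentration tissue-derived DNA, a specimen is called the
#' target when the median Cq (non-amplifying wells counted as the 50-cycle
#' run length) falls at or below the assay's target cutoff (20 cycles; 30
#' for BRLY), a non-target when nothing amplifies before the off-target
#' floor (30 cycles; 42 for BRLY), and indeterminate otherwise.
#'
#' @param cq numeric vector of well Cqs (`NA` = no amplification).
#' @param assay an [Assay-class].
#' @return one of `"target"`, `"non_target"`, `"indeterminate"`.
#' @examples
#' classifySpecimen(c(17.2, 17.5, 16.9, 17.8), vernalAssays()$BRME)
#' @export
classifySpecimen <- function(cq, assay) {
  stopifnot(is(assay, "Assay"))
  if (!any(!is.na(cq) & cq < assay@offtargetFloorCycle))
    return("non_target")
  cqFull <- ifelse(is.na(cq), 50, cq)
  if (median(cqFull) <= assay@positiveCallMaxCycle) "target"
  else "indeterminate"
}

#' Call all eDNA samples across a set of plates
#'
#' Groups sample wells by assay and sample ID, treats the
#' earliest plate (by plate ID) holding a sample's quadruplicate as its
#' first run and any later plate as its re-run, applies [callSample()], and
#' applies plate QC: events whose field negative amplified have all their
#' replicates' calls forced to `"discarded"`.
#'
#' @param plates list of [QpcrPlate-class] (e.g. from [readQpcrLong()]).
#' @param maxCycle Cq ceiling for counting a well amplified (default: any
#'   reported Cq within the 50-cycle protocol).
#' @param replicateEvents optional named character vector mapping replicate
#'   (sample) IDs to event IDs, used to propagate field-negative discards;
#'   when `NULL`, a field negative discards samples sharing its `sample_id`
#'   prefix up to the last underscore.
#' @return `data.frame` with columns `sample_id`, `species`, `n_amplified`,
#'   `status` (positive/negative/rerun_needed/discarded), `rerun_applied`;
#'   plate QC reports attached as attribute `"qc"`.
#' @export
callQpcrSamples <- function(plates, maxCycle = 50, replicateEvents = NULL) {
  qc <- lapply(plates, qcPlate)
  discardEvents <- unique(unlist(lapply(qc, `[[`, "discardEvents")))
  rows <- do.call(rbind, lapply(plates, function(p) {
    w <- p@wells[p@wells$role == "sample", , drop = FALSE]
    if (!nrow(w)) return(NULL)
    data.frame(plate_id = p@plateId, species = p@assay,
               sample_id = w$sample_id, cq = w$cq,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) stop("no sample wells found on any plate")
  out <- do.call(rbind, lapply(
    split(rows, list(rows$species, rows$sample_id), drop = TRUE),
    function(g) {
      g <- g[order(g$plate_id), ]
      runs <- split(callWell(g$cq, maxCycle), g$plate_id)
      call <- callSample(runs[[1]],
                         rerun = if (length(runs) > 1) runs[[2]] else NULL)
      data.frame(sample_id = g$sample_id[1], species = g$species[1],
                 n_amplified = call$nAmplified, status = call$status,
                 rerun_applied = call$rerunApplied,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  if (length(discardEvents)) {
    ev <- if (!is.null(replicateEvents)) unname(replicateEvents[out$sample_id])
          else sub("_[^_]*$", "", out$sample_id)
    out$status[!is.na(ev) & ev %in% discardEvents] <- "discarded"
  }
  attr(out, "qc") <- qc
  out
}
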