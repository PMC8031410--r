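#' Construct a SamplingEvent
#'
#' @param eventId unique event (collection) identifier.
#' @param poolId vernal pool identifier.
#' @param replicates `data.frame` with columns `replicateId`, `volumeMl`,
#'   `protocol` ("field"/"lab"), `filterType`.
#' @param property property name.
#' @param date sampling date (`Date` or ISO-8601 string).
#' @param poolAreaM2 pool surface area, square meters.
#' @param latitude,longitude decimal degrees.
#' @param calls optional `data.frame` (replicates x species) of eDNA calls.
#' @param dipnet named logical vector of per-species dip-net detections.
#' @return a [SamplingEvent-class] object.
#' @export
SamplingEvent <- function(eventId, poolId, replicates, property = "",
                          date = Sys.Date(), poolAreaM2 = 1,
                          latitude = NA_real_, longitude = NA_real_,
                          calls = data.frame(), dipnet = logical()) {
  new("SamplingEvent", eventId = as.character(eventId),
      poolId = as.character(poolId), property = as.character(property),
      date = as.Date(date), poolAreaM2 = as.numeric(poolAreaM2),
      latitude = as.numeric(latitude), longitude = as.numeric(longitude),
      replicates = replicates, calls = calls, dipnet = dipnet)
}

setMethod("show", "SamplingEvent", function(object) {
  cat(sprintf("SamplingEvent %s: pool %s, %s, %d replicate(s), %.0f m2\n",
              object@eventId, object@poolId, format(object@date),
              nrow(object@replicates), object@poolAreaM2))
  if (length(object@dipnet))
    cat("  dip-net:",
        paste(names(object@dipnet), ifelse(object@dipnet, "+", "-"),
              sep = "", collapse = " "), "\n")
})

# canonical sample-sheet columns; matching of input headers is
# case-insensitive and ignores separators
.sheetCols <- c(collection_id = "collection_id", pool_id = "pool_id",
                property = "property", filter_type = "filter_type",
                protocol = "protocol", date = "date",
                pool_area_m2 = "pool_area_m2", volume_ml = "volume_ml",
                latitude = "latitude", longitude = "longitude")

.normHeader <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a field sample sheet
#'
#' Reads a comma-separated sample sheet with one row per water replicate and
#' the standard column set: a unique collection ID, vernal pool ID, property,
#' filter type, filtration protocol (field/lab), sampling date (ISO-8601),
#' pool area in square meters, water volume filtered per replicate in
#' milliliters, and latitude/longitude in decimal degrees.  Header matching
#' is case-insensitive.  Rows are grouped into one [SamplingEvent-class] per
#' pool visit (same pool ID and date).
#'
#' @param path CSV file path.
#' @return list of [SamplingEvent-class] objects, named by event ID; rows
#'   that failed to parse are reported in attribute `"badRows"`.
#' @seealso [writeSampleSheet()] for the inverse.
#' @export
readSampleSheet <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hdr <- .normHeader(names(raw))
  idx <- match(.normHeader(.sheetCols), hdr)
  missing_cols <- .sheetCols[is.na(idx)]
  if (length(missing_cols))
    stop("sample sheet is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- raw[, idx]
  names(df) <- names(.sheetCols)
  if (anyDuplicated(df$collection_id))
    stop("duplicate collection ID(s): ",
         paste(unique(df$collection_id[duplicated(df$collection_id)]),
               collapse = ", "))
  if (nrow(df) == 0) return(structure(list(), badRows = integer()))

  df$volume_ml <- suppressWarnings(as.numeric(df$volume_ml))
  df$pool_area_m2 <- suppressWarnings(as.numeric(df$pool_area_m2))
  df$protocol <- tolower(trimws(df$protocol))
  bad <- which(is.na(df$volume_ml) | is.na(df$pool_area_m2) |
                 !(df$protocol %in% c("field", "lab")))
  if (length(bad)) {
    warning(length(bad), " unparseable row(s) dropped (rows ",
            paste(bad, collapse = ", "), ")")
    df <- df[-bad, , drop = FALSE]
  }

  key <- paste(df$pool_id, df$date, sep = "@")
  events <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
    function(ii) {
      g <- df[ii, , drop = FALSE]
      SamplingEvent(
        eventId = paste0(g$pool_id[1], "_", g$date[1]),
        poolId = g$pool_id[1], property = g$property[1], date = g$date[1],
        poolAreaM2 = g$pool_area_m2[1],
        latitude = suppressWarnings(as.numeric(g$latitude[1])),
        longitude = suppressWarnings(as.numeric(g$longitude[1])),
        replicates = data.frame(
          replicateId = g$collection_id, volumeMl = g$volume_ml,
          protocol = g$protocol, filterType = g$filter_type,
          stringsAsFactors = FALSE))
    })
  names(events) <- vapply(events, function(e) e@eventId, "")
  structure(events[order(names(events))], badRows = bad)
}

#' Write sampling events back to a sample sheet
#'
#' Inverse of [readSampleSheet()]: one CSV row per water replicate.
#'
#' @param events list of [SamplingEvent-class].
#' @param path output CSV path.
#' @return invisibly, the `data.frame` written.
#' @export
writeSampleSheet <- function(events, path) {
  rows <- do.call(rbind, lapply(events, function(e) {
    r <- e@replicates
    data.frame(collection_id = r$replicateId, pool_id = e@poolId,
               property = e@property, filter_type = r$filterType,
               protocol = r$protocol, date = format(e@date),
               pool_area_m2 = e@poolAreaM2, volume_ml = r$volumeMl,
               latitude = e@latitude, longitude = e@longitude,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

#' Attach dip-net survey results to sampling events
#'
#' @param events list of [SamplingEvent-class].
#' @param dipnet `data.frame` with columns `event_id`, `species`, `detected`
#'   (logical or 0/1); the schema of the dip-net CSV.
#' @return the events, each with its `dipnet` slot filled (species absent
#'   from the table are recorded as not detected).
#' @export
attachDipnet <- function(events, dipnet) {
  need <- c("event_id", "species", "detected")
  if (!all(need %in% names(dipnet)))
    stop("dipnet table must have columns: ", paste(need, collapse = ", "))
  species <- sort(unique(as.character(dipnet$species)))
  lapply(events, function(e) {
    d <- dipnet[dipnet$event_id == e@eventId, , drop = FALSE]
    flags <- setNames(rep(FALSE, length(species)), species)
    if (nrow(d)) flags[as.character(d$species)] <- as.logical(d$detected)
    e@dipnet <- flags
    e
  })
}

#' Attach replicate-level eDNA calls to sampling events
#'
#' @param events list of [SamplingEvent-class].
#' @param calls `data.frame` with columns `event_id`, `replicate_id`,
#'   `species`, `status` (positive/negative/discarded/missing); the calls CSV
#'   emitted by the qPCR calling stage.
#' @return the events with their `calls` slot filled; replicates without a
#'   row for a species are recorded as `"missing"`.
#' @export
attachCalls <- function(events, calls) {
  need <- c("event_id", "replicate_id", "species", "status")
  if (!all(need %in% names(calls)))
    stop("calls table must have columns: ", paste(need, collapse = ", "))
  species <- sort(unique(as.character(calls$species)))
  lapply(events, function(e) {
    m <- matrix("missing", nrow(e@replicates), length(species),
                dimnames = list(NULL, species))
    d <- calls[calls$event_id == e@eventId, , drop = FALSE]
    if (nrow(d)) {
      ri <- match(d$replicate_id, e@replicates$replicateId)
      ok <- !is.na(ri)
      m[cbind(ri[ok], match(d$species[ok], species))] <- d$status[ok]
    }
    e@calls <- as.data.frame(m, stringsAsFactors = FALSE)
    e
  })
}
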