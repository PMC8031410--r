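makeSheet <- function(path, rows) {
  hdr <- paste("Collection_ID,Pool_ID,Property,Filter_Type,Protocol,Date,",
               "Pool_Area_m2,Volume_mL,Latitude,Longitude", sep = "")
  writeLines(c(hdr, rows), path)
}

test_that("sample sheet rows map to replicates and group into events", {
  f <- withr::local_tempfile(fileext = ".csv")
  makeSheet(f, c(
    "C1,VP1,PropA,CN,lab,2017-02-01,350,500,38.5,-121.7",
    "C2,VP1,PropA,CN,lab,2017-02-01,350,n/a,38.5,-121.7",
    "C3,VP1,PropA,CN,lab,2017-02-01,350,450,38.5,-121.7",
    "C4,VP2,PropA,CN,field,2017-02-01,900,200,38.6,-121.8"))
  # row C2 above has a non-numeric volume and is reported + dropped
  expect_warning(events <- readSampleSheet(f), "unparseable")
  expect_length(events, 2)
  e1 <- events[["VP1_2017-02-01"]]
  expect_s4_class(e1, "SamplingEvent")
  expect_equal(nrow(e1@replicates), 2)
  expect_equal(e1@replicates$volumeMl, c(500, 450))
  expect_equal(e1@replicates$protocol, c("lab", "lab"))
  expect_equal(events[["VP2_2017-02-01"]]@poolAreaM2, 900)
})

test_that("three rows sharing a pool and date form one three-replicate event", {
  f <- withr::local_tempfile(fileext = ".csv")
  makeSheet(f, sprintf(
    "C%d,VP9,PropB,CN,field,2017-03-10,500,%d,38.1,-121.2", 1:3,
    c(500, 350, 410)))
  events <- readSampleSheet(f)
  expect_length(events, 1)
  expect_equal(nrow(events[[1]]@replicates), 3)
})

test_that("sheet errors: missing column, duplicate ID; empty sheet is empty", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("collection_id,pool_id,property,date", f)
  expect_error(readSampleSheet(f), "volume_ml")
  makeSheet(f, rep("C1,VP1,P,CN,lab,2017-02-01,350,500,38.5,-121.7", 2))
  expect_error(readSampleSheet(f), "duplicate")
  makeSheet(f, character())
  expect_length(readSampleSheet(f), 0)
})

test_that("write/read round-trips all sample-sheet fields", {
  study <- simulateStudy(nSites = 5, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSampleSheet(study$events, f)
  back <- readSampleSheet(f)
  expect_length(back, length(study$events))
  for (nm in names(study$events)) {
    a <- study$events[[nm]]
    key <- paste0(a@poolId, "_", format(a@date))
    b <- back[[key]]
    expect_equal(b@replicates$volumeMl, a@replicates$volumeMl)
    expect_equal(b@replicates$protocol, a@replicates$protocol)
    expect_equal(b@poolAreaM2, a@poolAreaM2)
    expect_equal(b@latitude, a@latitude, tolerance = 1e-12)
  }
})

test_that("detection history codes certain/uncertain positives from dip-net", {
  events <- list(
    toyEvent("E1", c("positive", "positive", "negative"), TRUE),
    toyEvent("E2", c("positive", "negative", "negative"), FALSE),
    toyEvent("E3", c("negative", "negative", "negative"), FALSE))
  dh <- buildDetectionHistory(events, "BRLY")
  expect_equal(obsMatrix(dh),
               matrix(c(2L, 1L, 0L, 2L, 0L, 0L, 0L, 0L, 0L), 3))
  expect_equal(knownOccupied(dh), c(TRUE, FALSE, FALSE))
  # binary coding on request
  dhb <- buildDetectionHistory(events, "BRLY", certainFromDipnet = FALSE)
  expect_true(all(obsMatrix(dhb) <= 1))
})

test_that("discarded replicates are NA-coded and all-NA events dropped", {
  events <- list(
    toyEvent("E1", c("positive", "discarded", "negative"), FALSE),
    toyEvent("E2", c("discarded", "discarded", "discarded"), FALSE))
  dh <- buildDetectionHistory(events, "BRLY")
  expect_equal(nSites(dh), 1)
  expect_equal(obsMatrix(dh)[1, ], c(1L, NA_integer_, 0L))
  qc <- attr(dh, "qc")
  expect_equal(qc$nDiscardedReplicates, 4L)
  expect_equal(qc$droppedEvents, "E2")
})

test_that("detection history is permutation-equivariant in event order", {
  events <- list(
    toyEvent("E1", c("positive", "negative", "negative"), TRUE),
    toyEvent("E2", c("negative", "negative", "negative"), FALSE),
    toyEvent("E3", c("positive", "positive", "negative"), FALSE))
  a <- buildDetectionHistory(events, "BRLY")
  b <- buildDetectionHistory(events[c(3, 1, 2)], "BRLY")
  expect_equal(obsMatrix(a), obsMatrix(b))
  expect_equal(a@siteIds, b@siteIds)
})

test_that("concordance arithmetic, rounding and undefined cells", {
  cc <- concordanceFromCounts(22, 0, 4, 26)
  expect_equal(cc$posAgreement, 85)
  expect_equal(cc$negAgreement, 100)
  expect_equal(cc$nEvents, 52)
  expect_equal(concordanceFromCounts(5, 3, 3, 2)$posAgreement, 62.5)
  none <- concordanceFromCounts(0, 0, 0, 12)
  expect_true(is.na(none$posAgreement))
  expect_equal(none$negAgreement, 100)
})

test_that("event-level concordance counts all informative events once", {
  events <- list(
    toyEvent("E1", c("positive", "negative", "negative"), TRUE),
    toyEvent("E2", c("negative", "negative", "negative"), TRUE),
    toyEvent("E3", c("positive", "positive", "negative"), FALSE),
    toyEvent("E4", c("negative", "negative", "negative"), FALSE),
    toyEvent("E5", c("discarded", "discarded", "discarded"), FALSE))
  cc <- concordanceSummary(events, "BRLY")
  expect_equal(unname(cc$counts), c(1L, 1L, 1L, 1L))
  expect_equal(cc$nEvents, 4)  # E5 uninformative, excluded
})
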