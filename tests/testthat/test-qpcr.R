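test_that("well calls respect the cycle ceiling and reject bad Cq", {
  expect_true(callWell(18.4, 50))
  expect_false(callWell(NA_real_, 50))
  expect_false(callWell(31.0, 30))  # just past the 30-cycle floor
  expect_true(callWell(30.0, 30))
  expect_error(callWell(-1, 50), "positive")
  expect_error(callWell(25, 60), "maxCycle")
})

test_that("2-of-4 sample rule is exhaustive over first-run outcomes", {
  amp <- function(k) c(rep(TRUE, k), rep(FALSE, 4 - k))
  expect_equal(callSample(amp(0))$status, "negative")
  expect_equal(callSample(amp(1))$status, "rerun_needed")
  for (k in 2:4) expect_equal(callSample(amp(k))$status, "positive")
  # re-run resolution: any amplification is positive, none is negative
  expect_equal(callSample(amp(1), rerun = amp(1))$status, "positive")
  expect_equal(callSample(amp(1), rerun = amp(4))$status, "positive")
  expect_equal(callSample(amp(1), rerun = amp(0))$status, "negative")
  expect_true(callSample(amp(1), rerun = amp(1))$rerunApplied)
  expect_warning(res <- callSample(amp(3), rerun = amp(0)), "conclusive")
  expect_equal(res$status, "positive")
})

test_that("adding an amplified well never flips a call toward negative", {
  rank <- c(negative = 0, rerun_needed = 1, positive = 2)
  amp <- function(k) c(rep(TRUE, k), rep(FALSE, 4 - k))
  for (k in 0:3) {
    a <- rank[callSample(amp(k))$status]
    b <- rank[callSample(amp(k + 1))$status]
    expect_gte(b, a)
  }
  for (k in 0:3) {
    a <- rank[callSample(amp(1), rerun = amp(k))$status]
    b <- rank[callSample(amp(1), rerun = amp(k + 1))$status]
    expect_gte(b, a)
  }
})

test_that("plate QC flags controls and discards field-negative events", {
  wells <- function(role, sid, cq) data.frame(
    well = paste0(sid, "_", seq_along(cq)), role = role, sample_id = sid,
    cq = cq, stringsAsFactors = FALSE)
  clean <- rbind(
    wells("sample", "E1_R1", c(33, 34, NA, 33.5)),
    wells("ntc", "NTC", rep(NA_real_, 4)),
    wells("positive_control", "PC1", c(34, 34, 35, 34)),
    wells("field_negative", "E1", rep(NA_real_, 4)))
  qc <- qcPlate(QpcrPlate("P1", "BRLY", clean))
  expect_true(qc$valid)
  expect_length(qc$discardEvents, 0)

  dirty <- clean
  dirty$cq[dirty$role == "field_negative"][1:2] <- c(38, 39)
  qc2 <- qcPlate(QpcrPlate("P2", "BRLY", dirty))
  expect_equal(qc2$discardEvents, "E1")

  deadPc <- clean
  deadPc$cq[deadPc$role == "positive_control"] <- NA_real_
  qc3 <- qcPlate(QpcrPlate("P3", "BRLY", deadPc))
  expect_true(qc3$positiveControlFailed)
  expect_false(qc3$valid)

  expect_warning(
    qc4 <- qcPlate(QpcrPlate("P4", "BRLY",
                             wells("sample", "E1_R1", c(33, 34, NA, 33)))),
    "lacks control")
  expect_false(qc4$valid)
})

test_that("tissue specimens classify by median Cq against assay cutoffs", {
  assays <- vernalAssays()
  expect_equal(classifySpecimen(c(17.1, 17.4, 16.9, 17.6), assays$BRME),
               "target")
  expect_equal(classifySpecimen(c(43.2, 44.0, NA, 43.5), assays$BRLY),
               "non_target")
  expect_equal(classifySpecimen(c(25.0, 25.3, 24.8, 25.1), assays$BRCO),
               "indeterminate")
  # one aberrant late well does not break a clear target call
  expect_equal(classifySpecimen(c(17.1, 17.4, 16.9, 49), assays$BRME),
               "target")
  expect_equal(classifySpecimen(rep(NA_real_, 4), assays$LEPA), "non_target")
})

test_that("pipeline calls reproduce the simulated latent detections", {
  study <- simulateStudy(nSites = 30, seed = 21)
  plates <- lapply(split(study$qpcr, study$qpcr$plate_id), function(g)
    QpcrPlate(g$plate_id[1], g$assay[1],
              g[, c("well", "role", "sample_id", "cq")]))
  calls <- callQpcrSamples(plates)
  expect_true(all(calls$status %in% c("positive", "negative")))
  det <- study$truth$detected
  for (r in seq_len(nrow(calls))) {
    id <- calls$sample_id[r]
    i <- as.integer(sub("^E(\\d+)_R\\d+$", "\\1", id))
    j <- as.integer(sub("^E\\d+_R(\\d+)$", "\\1", id))
    expect_equal(calls$status[r] == "positive", det[i, j])
  }
  expect_true(any(calls$rerun_applied))  # both re-run branches exercised
})

test_that("field-negative contamination discards the whole event", {
  study <- simulateStudy(nSites = 4, contaminationRate = 1, seed = 3)
  plates <- lapply(split(study$qpcr, study$qpcr$plate_id), function(g)
    QpcrPlate(g$plate_id[1], g$assay[1],
              g[, c("well", "role", "sample_id", "cq")]))
  calls <- callQpcrSamples(plates)
  expect_true(all(calls$status == "discarded"))
})
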