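# exact CV construction: wells at conc cc with back-calculated copies
# cc*(1 +/- d) in alternating pairs give sample CV = 2d/sqrt(3); choosing d
# per concentration pins the CV profile exactly (on the true curve)
cvWells <- function(conc, cvTargets, slope = -3.4, intercept = 38.7) {
  d <- cvTargets * sqrt(3) / 2
  copies <- unlist(mapply(function(cc, dd)
    cc * c(1 - dd, 1 + dd, 1 - dd, 1 + dd), conc, d, SIMPLIFY = FALSE))
  StandardPanel(copies = rep(conc, each = 4),
                cq = slope * log10(copies) + intercept)
}

test_that("noiseless panels recover the generating line exactly", {
  pan <- simulateStandardPanel(slope = -3.3219, intercept = 38, sdCq = 0,
                               detect95 = 0.01, seed = 4)
  fit <- suppressWarnings(fitCurve(pan))
  expect_equal(fit@slope, -3.3219, tolerance = 1e-10)
  expect_equal(fit@intercept, 38, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-10)
  expect_equal(fit@efficiency, 10^(1 / 3.3219) - 1, tolerance = 1e-10)
})

test_that("regression coefficients equal an independent normal-equations solve", {
  set.seed(7)
  copies <- rep(c(1, 2, 5, 10, 100), each = 5)
  cq <- -3.5 * log10(copies) + 39 + rnorm(length(copies), 0, 0.4)
  drop <- sample(length(cq), 4)
  cq[drop] <- NA  # non-amplifying wells excluded from the regression
  fit <- fitCurve(StandardPanel(copies, cq))
  ok <- !is.na(cq)
  X <- cbind(1, log10(copies[ok]))
  beta <- solve(t(X) %*% X, t(X) %*% cq[ok])
  expect_equal(fit@intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit@slope, beta[2], tolerance = 1e-10)
})

test_that("efficiency follows from the slope alone", {
  pan <- simulateStandardPanel(slope = -3.609, intercept = 38.664,
                               sdCq = 0, detect95 = 0.01, seed = 5)
  fit <- fitCurve(pan)
  expect_equal(fit@efficiency, 0.893, tolerance = 1e-3)
  # intercept shifts leave efficiency untouched
  pan2 <- simulateStandardPanel(slope = -3.609, intercept = 45, sdCq = 0,
                                detect95 = 0.01, seed = 5)
  expect_equal(fitCurve(pan2)@efficiency, fit@efficiency, tolerance = 1e-12)
})

test_that("Low95 picks the lowest standard with >=95% amplification", {
  mk <- function(fracs, conc = c(1, 2, 5, 10, 100)) {
    nAmp <- round(fracs * 8)
    cq <- unlist(lapply(seq_along(conc), function(i)
      c(rep(35, nAmp[i]), rep(NA_real_, 8 - nAmp[i]))))
    StandardPanel(rep(conc, each = 8), cq)
  }
  expect_equal(low95(mk(c(6 / 8, 7 / 8, 1, 1, 1))), 5)  # 7/8 = 87.5% < 95%
  expect_equal(low95(mk(rep(1, 5))), 1)
  expect_equal(low95(mk(rep(6 / 8, 5))), Inf)
  expect_equal(estimateLod(mk(c(6 / 8, 7 / 8, 1, 1, 1)), "discrete"), 5)
  # all-or-nothing: 0% below 10 copies, 100% at and above
  expect_equal(estimateLod(mk(c(0, 0, 0, 1, 1)), "discrete"), 10)
})

test_that("curve-fit LOD recovers a known 95% crossing and clamps at 1", {
  lods <- vapply(1:8, function(r)
    estimateLod(simulateStandardPanel(concentrations = c(1, 2, 3, 5, 10, 100),
                                      replicates = 24, detect95 = 3,
                                      seed = 400 + r)), 0)
  expect_equal(mean(lods), 3.0, tolerance = 0.15)
  # fully saturated detection: LOD is the smallest tested concentration
  full <- simulateStandardPanel(detect95 = 0.01, seed = 6)
  expect_equal(estimateLod(full), 1)
})

test_that("LOQ rules: noiseless floor, discrete threshold, exact crossing", {
  # CV = 0 everywhere: LOQ is the smallest tested concentration
  noiseless <- simulateStandardPanel(sdCq = 0, detect95 = 0.01, seed = 8)
  expect_equal(estimateLoq(noiseless), 1)
  # CV crosses 0.35 between 10 and 100: discrete LOQ = 100
  pan <- cvWells(c(1, 10, 100), c(0.60, 0.45, 0.20))
  expect_equal(estimateLoq(pan, method = "discrete"), 100)
  # collinear CV profile crossing 0.35 at 24 copies: curvefit pins it;
  # oracle = closed-form crossing of the least-squares line through the
  # back-calculated CVs, computed here from first principles
  pan24 <- cvWells(c(1, 10, 100), 0.5 - 0.108674 * log10(c(1, 10, 100)))
  fit <- fitCurve(pan24)
  back <- quantifyCopies(pan24@cq, fit)
  cv <- vapply(c(1, 10, 100), function(cc) {
    v <- back[pan24@copies == cc]; sd(v) / mean(v)
  }, 0)
  X <- cbind(1, log10(c(1, 10, 100)))
  ab <- solve(t(X) %*% X, t(X) %*% cv)
  oracle <- 10^((0.35 - ab[1]) / ab[2])
  expect_equal(estimateLoq(pan24, method = "curvefit"), oracle,
               tolerance = 1e-8)
  expect_equal(oracle, 24, tolerance = 0.03 * 24)
  # nothing under threshold anywhere: above-max sentinel
  high <- cvWells(c(1, 10, 100), c(0.9, 0.8, 0.7))
  expect_equal(estimateLoq(high, method = "discrete"), Inf)
})

test_that("quantification inverts the calibration line", {
  fit <- new("CurveFit", assay = "BRCO", slope = -3.609, intercept = 38.664,
             rSquared = 0.970, efficiency = 10^(1 / 3.609) - 1)
  expect_equal(quantifyCopies(38.664, fit), 1)
  expect_equal(quantifyCopies(38.664 - 3.609, fit), 10)
  expect_equal(quantifyCopies(38.664 - 3.609 * 2, fit), 100)
  # identity on noiseless simulated wells
  pan <- simulateStandardPanel(sdCq = 0, detect95 = 0.01, seed = 10)
  f <- fitCurve(pan)
  ok <- !is.na(pan@cq)
  expect_equal(quantifyCopies(pan@cq[ok], f), pan@copies[ok],
               tolerance = 1e-8)
})

test_that("full calibration assembles a sensitivity-report row", {
  pan <- simulateStandardPanel(assay = "BRLY", seed = 12)
  fit <- calibrateAssay(pan)
  expect_s4_class(fit, "CurveFit")
  expect_true(fit@slope < 0)
  expect_true(fit@low95 %in% c(1, 2, 5, 10, 100))
  tab <- curveReport(list(fit))
  expect_named(tab, c("assay", "r_squared", "slope", "intercept", "low95",
                      "lod", "loq"))
  # replicate-adjusted LOD can only improve on the single-replicate LOD
  lod3 <- estimateLod(pan, nReplicates = 3)
  expect_lte(lod3, estimateLod(pan))
})

test_that("standards CSV round-trips through panels", {
  pan <- simulateStandardPanel(assay = "BRME", seed = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(assay = "BRME",
                   copies_per_reaction = c(pan@copies, rep(0, 8)),
                   cq = c(pan@cq, rep(NA, 8)))
  write.csv(df, f, row.names = FALSE)
  back <- readStandardsCsv(f)$BRME
  expect_equal(back@copies, pan@copies)
  expect_equal(back@cq, pan@cq)
  expect_length(back@ntcCq, 8)
})
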