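test_that("likelihood matches hand arithmetic on one-site histories", {
  h1 <- makeDetectionHistory(matrix(1L, 1, 1))
  expect_equal(occuNegLogLik(c(0, 0), h1), -log(0.25), tolerance = 1e-12)
  h2 <- makeDetectionHistory(matrix(c(0L, 0L), 1, 2))
  expect_equal(occuNegLogLik(c(0, 0), h2), -log(0.625), tolerance = 1e-12)
  # known-occupied site drops the unoccupied branch
  h3 <- makeDetectionHistory(matrix(c(0L, 0L), 1, 2),
                             knownOccupied = TRUE)
  expect_equal(occuNegLogLik(c(0, 0), h3), -log(0.125), tolerance = 1e-12)
})

test_that("likelihood equals brute-force enumeration on random toys", {
  for (r in 1:40) {
    h <- randomToyHistory(1000 + r)
    psi <- runif(1, 0.2, 0.8)
    p <- runif(1, 0.2, 0.9)
    y <- obsMatrix(h)
    expect_equal(
      occuNegLogLik(qlogis(c(psi, p)), h),
      oracleNegLogLik(psi, matrix(p, nrow(y), ncol(y)), y,
                      knownOccupied(h)),
      tolerance = 1e-10)
  }
})

test_that("likelihood with a replicate covariate matches the oracle", {
  for (r in 1:10) {
    h <- randomToyHistory(2000 + r)
    y <- obsMatrix(h)
    set.seed(r)
    vol <- matrix(runif(length(y), -1, 1), nrow(y))
    h2 <- makeDetectionHistory(y, obsCovs = list(volume = vol),
                               knownOccupied = knownOccupied(h))
    beta <- c(0.3, -0.8)
    psi <- 0.55
    pmat <- plogis(beta[1] + beta[2] * vol)
    expect_equal(
      occuNegLogLik(c(qlogis(psi), beta), h2, detFormula = ~volume),
      oracleNegLogLik(psi, pmat, y, knownOccupied(h2)),
      tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to site and replicate permutation", {
  h <- randomToyHistory(31)
  y <- obsMatrix(h)
  params <- qlogis(c(0.6, 0.7))
  base <- occuNegLogLik(params, h)
  ip <- sample(nrow(y)); jp <- sample(ncol(y))
  hp <- makeDetectionHistory(y[ip, jp, drop = FALSE],
                             knownOccupied = knownOccupied(h)[ip])
  expect_equal(occuNegLogLik(params, hp), base, tolerance = 1e-12)
})

test_that("no-covariate MLE agrees with a dense grid search", {
  set.seed(44)
  y <- matrix(rbinom(18, 1, 0.45), 6, 3)
  y[1, ] <- c(1L, 0L, 1L)  # ensure a detection
  h <- makeDetectionHistory(y, knownOccupied = rep(FALSE, 6))
  fit <- occuFit(h)
  grid <- oracleGridMLE(y, known = rep(FALSE, 6))
  expect_lt(abs(psiHat(fit) - grid$psi), 1e-3 + 1e-9)
  expect_lt(abs(pHat(fit) - grid$p), 1e-3 + 1e-9)
  expect_lte(-fit@loglik, grid$value + 1e-6)
})

test_that("fit recovers simulation truth within 3 standard errors", {
  h <- simulateDetectionHistory(500, 3, psi = 0.6, p = 0.75, seed = 99)
  fit <- occuFit(h)
  expect_true(fit@converged)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[1] - qlogis(0.6)), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - qlogis(0.75)), 3 * se[2])
})

test_that("all-detection data drive both rates to a flagged boundary", {
  h <- makeDetectionHistory(matrix(1L, 8, 3), knownOccupied = rep(FALSE, 8))
  fit <- suppressWarnings(occuFit(h))
  expect_gt(psiHat(fit), 0.999)
  expect_gt(pHat(fit), 0.999)
  expect_true(fit@boundary)
})

test_that("known-occupied-only data reduce to Bernoulli detection", {
  set.seed(5)
  y <- matrix(rbinom(60, 1, 0.7), 20, 3)
  h <- makeDetectionHistory(y, knownOccupied = rep(TRUE, 20))
  fit <- suppressWarnings(occuFit(h))
  expect_equal(pHat(fit), mean(y), tolerance = 1e-3)
  expect_gt(psiHat(fit), 0.999)  # psi unidentified, pushed to boundary
})

test_that("collapsing certain codes reproduces the binary fit exactly", {
  h <- simulateDetectionHistory(120, 3, psi = 0.6, p = 0.7,
                                dipnetSensitivity = 0.8, seed = 17)
  f1 <- occuFit(h)
  f2 <- occuFit(collapseBinary(h))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-9)
})

test_that("model enumeration covers every covariate subset", {
  h <- simulateDetectionHistory(60, 3, psi = 0.6, p = 0.7, seed = 23)
  tab <- enumerateModels(h, starts = 1)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$deltaAIC[1], 0)
  expect_true(all(diff(tab$AIC) >= 0))
  base <- enumerateModels(h, covariatePool = character(), starts = 1)
  expect_equal(nrow(base), 1)
  expect_equal(base$model, "~1")
})

test_that("a strong protocol effect is selected by AIC", {
  hits <- 0L
  for (r in 1:8) {
    h <- simulateDetectionHistory(150, 3, psi = 0.65, p = 0.45,
                                  detCoefs = c(protocol = 2.5),
                                  seed = 5000 + r)
    tab <- enumerateModels(h, covariatePool = c("protocol", "poolArea"),
                           starts = 2, seed = r)
    hits <- hits + grepl("protocol", attr(tab, "best"))
  }
  expect_gte(hits, 7L)
})

test_that("detection predictions back-transform a delta-method interval", {
  h <- simulateDetectionHistory(200, 3, psi = 0.6, p = 0.7, seed = 41)
  fit <- occuFit(h)
  pr <- predictDetection(fit)
  expect_true(pr$lower <= pr$estimate && pr$estimate <= pr$upper)
  expect_true(pr$lower >= 0 && pr$upper <= 1)
  # Monte-Carlo oracle on the linear predictor
  idx <- length(coef(fit))
  eta <- coef(fit)[idx]; se <- sqrt(vcov(fit)[idx, idx])
  set.seed(1)
  draws <- plogis(rnorm(1e6, eta, se))
  qs <- quantile(draws, c(0.025, 0.975))
  expect_equal(unname(pr$lower), unname(qs[1]), tolerance = 1e-3)
  expect_equal(unname(pr$upper), unname(qs[2]), tolerance = 1e-3)
  # degenerate interval when the SE is zero
  fit0 <- fit
  fit0@vcov[] <- 0
  pr0 <- predictDetection(fit0)
  expect_equal(pr0$lower, pr0$estimate, tolerance = 1e-12)
  expect_equal(pr0$upper, pr0$estimate, tolerance = 1e-12)
})

test_that("per-replicate scale anchors pass through prediction untouched", {
  # an intercept-only fit with beta0 = logit(0.7564) predicts p = 0.7564
  h <- makeDetectionHistory(matrix(c(1L, 0L), 1, 2))
  fit <- suppressWarnings(occuFit(h, starts = 1))
  fit@estimates[2] <- qlogis(0.7564)
  fit@vcov[] <- 0
  expect_equal(predictDetection(fit)$estimate, 0.7564, tolerance = 1e-12)
})

test_that("goodness-of-fit statistic matches exhaustive enumeration", {
  # 4 sites x 2 replicates; expected frequencies enumerated by hand
  y <- rbind(c(1L, 0L), c(0L, 0L), c(1L, 1L), c(0L, 1L))
  h <- makeDetectionHistory(y, knownOccupied = rep(FALSE, 4))
  fit <- occuFit(h)
  psi <- psiHat(fit); p <- pHat(fit)
  tExp <- 0
  for (i in 1:4) {
    for (h1 in 0:1) for (h2 in 0:1) {
      pr <- psi * p^(h1 + h2) * (1 - p)^(2 - h1 - h2) +
        (1 - psi) * (h1 + h2 == 0)
      obs <- as.integer(all(c(h1, h2) == y[i, ]))
      tExp <- tExp + (obs - pr)^2 / pr
    }
  }
  d <- ednaOccu:::.occuDesign(h, ~1, ~1, scaling = fit@scaling)
  expect_equal(ednaOccu:::.gofStatistic(coef(fit), d), tExp,
               tolerance = 1e-8)
})

test_that("perfect-fit degenerate case gives T close to its floor, p near 1", {
  # all sites known occupied with every replicate detected: model fits the
  # observed frequencies exactly and T collapses to 0
  y <- matrix(1L, 5, 2)
  h <- makeDetectionHistory(y, knownOccupied = rep(TRUE, 5))
  fit <- suppressWarnings(occuFit(h, starts = 1))
  g <- suppressWarnings(gofMB(fit, B = 60, seed = 2))
  expect_lt(g@tObs, 1e-3)
  expect_gt(g@pValue, 0.9)
})

test_that("bootstrap p-value and c-hat are well-formed", {
  h <- simulateDetectionHistory(50, 3, psi = 0.6, p = 0.7,
                                dipnetSensitivity = 0, seed = 77)
  fit <- occuFit(h, starts = 2)
  expect_warning(g <- gofMB(fit, B = 40, seed = 5), "unstable")
  expect_true(g@pValue >= 0 && g@pValue <= 1)
  expect_gt(g@cHat, 0)
  expect_length(g@tStar, 40)
})
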