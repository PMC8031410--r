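# Independent brute-force oracles, deliberately written as plain loops over
# the two-branch site likelihood so they share no code with the package.

# binary occupancy negative log-likelihood by direct enumeration
oracleNegLogLik <- function(psi, pmat, y, known) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    occ <- psi
    unocc <- 1 - psi
    sawDet <- FALSE
    for (j in seq_len(ncol(y))) {
      yij <- y[i, j]
      if (is.na(yij)) next
      pij <- pmat[i, j]
      occ <- occ * (if (yij >= 1) pij else 1 - pij)
      if (yij >= 1) sawDet <- TRUE
    }
    if (sawDet) unocc <- 0
    li <- if (known[i]) occ else occ + unocc
    total <- total - log(li)
  }
  total
}

# false-positive model negative log-likelihood by direct enumeration
oracleNegLogLikFP <- function(psi, p11mat, p10, b, y, known) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    occ <- psi
    unocc <- 1 - psi
    for (j in seq_len(ncol(y))) {
      yij <- y[i, j]
      if (is.na(yij)) next
      p11 <- p11mat[i, j]
      occ <- occ * switch(yij + 1, 1 - p11, p11 * (1 - b), p11 * b)
      unocc <- unocc * switch(yij + 1, 1 - p10, p10, 0)
    }
    li <- if (known[i]) occ else occ + unocc
    total <- total - log(li)
  }
  total
}

# binomial tail by exhaustive enumeration of all 2^n outcome vectors
oracleCumulative <- function(p, n, k) {
  total <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}

# dense grid search over (psi, p) for the no-covariate binary model
oracleGridMLE <- function(y, known, res = 1e-3) {
  grid <- seq(res, 1 - res, by = res)
  ndet <- rowSums(y >= 1, na.rm = TRUE)
  nobs <- rowSums(!is.na(y))
  best <- c(NA, NA); bestVal <- Inf
  for (psi in grid) {
    # profile over p vectorized for speed
    cp <- outer(grid, seq_len(nrow(y)), function(p, i)
      p^ndet[i] * (1 - p)^(nobs[i] - ndet[i]))
    li <- sweep(cp, 2, rep(psi, nrow(y)), "*")
    add <- ifelse(ndet == 0 & !known, 1 - psi, 0)
    li <- sweep(li, 2, add, "+")
    nll <- -rowSums(log(li))
    w <- which.min(nll)
    if (nll[w] < bestVal) {
      bestVal <- nll[w]
      best <- c(psi, grid[w])
    }
  }
  list(psi = best[1], p = best[2], value = bestVal)
}

# random toy detection history generator for oracle-equivalence sweeps
randomToyHistory <- function(seed, fp = FALSE) {
  set.seed(seed)
  n <- sample(2:8, 1)
  J <- sample(2:4, 1)
  y <- matrix(sample(0:1, n * J, replace = TRUE, prob = c(0.6, 0.4)), n, J)
  known <- runif(n) < 0.3
  if (fp) {
    certain <- matrix(runif(n * J) < 0.5, n, J)
    y[y == 1 & certain & matrix(known, n, J)] <- 2L
  }
  # sprinkle NAs but keep every site partly observed
  nas <- matrix(runif(n * J) < 0.15, n, J)
  for (i in seq_len(n)) if (all(nas[i, ])) nas[i, J] <- FALSE
  y[nas] <- NA_integer_
  known <- known | rowSums(y == 2, na.rm = TRUE) > 0
  makeDetectionHistory(y, knownOccupied = known)
}

# events fixture: three replicates each, calls and dip-net set directly
toyEvent <- function(id, calls, dipnet, species = "BRLY",
                     volumes = c(500, 500, 500), protocol = "field") {
  e <- SamplingEvent(
    eventId = id, poolId = paste0("VP_", id), date = "2017-02-01",
    poolAreaM2 = 400,
    replicates = data.frame(
      replicateId = paste0(id, "_R", seq_along(calls)),
      volumeMl = volumes[seq_along(calls)],
      protocol = rep(protocol, length(calls))[seq_along(calls)],
      filterType = "CN", stringsAsFactors = FALSE))
  e@calls <- setNames(data.frame(calls, stringsAsFactors = FALSE), species)
  e@dipnet <- setNames(dipnet, species)
  e
}
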