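# ---- design-matrix machinery ------------------------------------------------

# observation-level data frame: site covariates replicated over replicates,
# per-replicate covariates flattened column-major (site index fastest), so
# obs index = i + (j-1) * n aligns with as.vector(y)
.obsData <- function(history) {
  n <- nrow(history@y); J <- ncol(history@y)
  df <- data.frame(row.names = seq_len(n * J))
  for (nm in names(history@siteCovs))
    df[[nm]] <- rep(history@siteCovs[[nm]], times = J)
  for (nm in names(history@obsCovs))
    df[[nm]] <- as.vector(history@obsCovs[[nm]])
  df
}

# build a model matrix, imputing covariate NAs only where the response is
# masked; errors on non-finite covariates at observed cells
.modelMatrix <- function(formula, data, maskObserved = NULL) {
  for (nm in names(data)) {
    bad <- !is.finite(as.numeric(data[[nm]]))
    if (!is.null(maskObserved) && any(bad & maskObserved))
      stop("non-finite covariate '", nm, "' at observed replicates")
    if (any(bad)) data[[nm]][bad] <- 0
  }
  model.matrix(formula, data)
}

# z-standardize non-binary, non-intercept columns; returns matrix + scaling
.standardizeMat <- function(X, scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- list()
    for (j in seq_len(ncol(X))) {
      nm <- colnames(X)[j]
      v <- X[, j]
      binary <- all(v %in% c(0, 1))
      if (nm == "(Intercept)" || binary || sd(v) == 0)
        scaling[[nm]] <- c(center = 0, scale = 1)
      else
        scaling[[nm]] <- c(center = mean(v), scale = sd(v))
    }
  }
  for (j in seq_len(ncol(X))) {
    sc <- scaling[[colnames(X)[j]]]
    X[, j] <- (X[, j] - sc["center"]) / sc["scale"]
  }
  list(X = X, scaling = scaling)
}

# full design bundle for a fit (binary-collapsed response)
.occuDesign <- function(history, detFormula, occFormula, scaling = NULL) {
  y <- history@y
  y[y == 2L] <- 1L
  n <- nrow(y); J <- ncol(y)
  yv <- as.vector(y)
  observed <- !is.na(yv)
  obsdf <- .obsData(history)
  detX0 <- .modelMatrix(detFormula, obsdf, maskObserved = observed)
  occX0 <- .modelMatrix(occFormula, history@siteCovs)
  sdet <- .standardizeMat(detX0, scaling$det)
  socc <- .standardizeMat(occX0, scaling$occ)
  list(y = y, yv = yv, n = n, J = J, observed = observed,
       detX = sdet$X, occX = socc$X,
       scaling = list(det = sdet$scaling, occ = socc$scaling),
       known = history@knownOccupied)
}

# ---- likelihood -------------------------------------------------------------

# negative log-likelihood of the binary single-season model on a design
# bundle; params = (alpha | beta) on the logit scale
.negloglikBinary <- function(params, d) {
  pocc <- ncol(d$occX)
  alpha <- params[seq_len(pocc)]
  beta <- params[-seq_len(pocc)]
  etaPsi <- drop(d$occX %*% alpha)
  logPsi <- plogis(etaPsi, log.p = TRUE)
  log1mPsi <- plogis(-etaPsi, log.p = TRUE)
  etaP <- drop(d$detX %*% beta)
  logP <- plogis(etaP, log.p = TRUE)
  log1mP <- plogis(-etaP, log.p = TRUE)
  lf <- ifelse(d$yv == 1, logP, log1mP)
  lf[!d$observed] <- 0
  logCP <- rowSums(matrix(lf, d$n, d$J))
  ydet <- rowSums(matrix(d$yv == 1 & d$observed, d$n, d$J)) > 0
  logOcc <- logPsi + logCP
  logUnocc <- ifelse(ydet, -Inf, log1mPsi)
  ll <- ifelse(d$known, logOcc, logSumExp2(logOcc, logUnocc))
  -sum(ll)
}

#' Negative log-likelihood of the single-season occupancy model
#'
#' For site i with replicate observations y_ij (codes 2 collapsed to 1,
#' `NA` replicates contributing no factor), the site likelihood is
#' psi_i * prod_j p_ij^y (1-p_ij)^(1-y) + (1 - psi_i) * I\[all y_ij = 0\],
#' where p_ij and psi_i are logit-linear in the detection and occupancy
#' covariates.  For known-occupied sites (dip-net capture) the unoccupied
#' branch is dropped.  Returns the negative sum of log site likelihoods.
#'
#' Parameters are packed occupancy block first, then detection, on the logit
#' scale; with `standardize = FALSE` (the default here) covariates enter as
#' supplied, which makes hand-computed checks transparent.
#'
#' @param params numeric vector (alpha | beta) on the logit scale.
#' @param history a [DetectionHistory-class].
#' @param detFormula,occFormula covariate formulas (default intercept-only).
#' @param standardize z-standardize covariates as [occuFit()] does.
#' @return scalar negative log-likelihood.
#' @examples
#' h <- makeDetectionHistory(matrix(c(0, 0), 1))
#' occuNegLogLik(c(0, 0), h)  # -log(0.5 * 0.25 + 0.5)
#' @export
occuNegLogLik <- function(params, history, detFormula = ~1,
                          occFormula = ~1, standardize = FALSE) {
  d <- .occuDesign(history, detFormula, occFormula)
  if (!standardize) {
    d$detX <- .modelMatrix(detFormula, .obsData(history),
                           maskObserved = d$observed)
    d$occX <- .modelMatrix(occFormula, history@siteCovs)
  }
  .negloglikBinary(params, d)
}

# ---- fitting ----------------------------------------------------------------

# quasi-Newton MLE with multiple jittered starts over a design bundle and a
# negative log-likelihood closure
.mleMultiStart <- function(negll, start, starts, seed, jitterSd = 0.5) {
  best <- NULL
  for (s in seq_len(starts)) {
    par0 <- start
    if (s > 1) {
      set.seed(deriveSeed(seed, s))
      par0 <- start + rnorm(length(start), 0, jitterSd)
    }
    opt <- tryCatch(
      suppressWarnings(optim(par0, negll, method = "BFGS",
                             control = list(maxit = 500))),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best))
    return(list(par = start, value = negll(start), convergence = 1L,
                hessian = matrix(NA_real_, length(start), length(start))))
  hess <- tryCatch(
    suppressWarnings(optim(best$par, negll, method = "BFGS", hessian = TRUE,
                           control = list(maxit = 200))),
    error = function(e) NULL)
  if (!is.null(hess) && hess$value <= best$value + 1e-9) best <- hess
  best
}

.vcovFromHessian <- function(hessian) {
  v <- tryCatch(solve(hessian), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v)))
    return(matrix(NA_real_, nrow(hessian), ncol(hessian)))
  (v + t(v)) / 2
}

# naive starting values from the observed data
.naiveStarts <- function(d) {
  ydet <- rowSums(matrix(d$yv >= 1 & d$observed, d$n, d$J)) > 0
  psi0 <- clampProb(mean(ydet | d$known), 0.05)
  obsAtDet <- d$observed & rep(ydet, times = d$J)
  p0 <- if (any(obsAtDet)) clampProb(mean(d$yv[obsAtDet] >= 1), 0.05) else 0.5
  c(qlogis(psi0), rep(0, ncol(d$occX) - 1),
    qlogis(p0), rep(0, ncol(d$detX) - 1))
}

# assemble an OccupancyFit from an optimizer result
.makeOccuFit <- function(class, opt, d, detFormula, occFormula, extra = list()) {
  pocc <- ncol(d$occX)
  nm <- c(paste0("psi_", colnames(d$occX)), paste0("p_", colnames(d$detX)),
          extra$names)
  est <- setNames(opt$par, nm)
  vc <- .vcovFromHessian(opt$hessian)
  dimnames(vc) <- list(nm, nm)
  k <- length(est)
  args <- list(class,
    detFormula = detFormula, occFormula = occFormula,
    estimates = est, vcov = vc, loglik = -opt$value,
    aic = 2 * k + 2 * opt$value,
    converged = opt$convergence == 0,
    boundary = any(abs(opt$par) > 10),
    nSites = d$n, nParams = as.integer(k),
    scaling = d$scaling, history = extra$history)
  do.call(new, c(args, extra$slots))
}

#' Fit the single-season occupancy model by maximum likelihood
#'
#' Maximizes the likelihood of [occuNegLogLik()] by quasi-Newton (BFGS)
#' optimization with multiple jittered starts.  Covariates are z-standardized
#' internally (binary 0/1 covariates such as filtration protocol are left as
#' coded); coefficients are reported on the standardized scale, with
#' [naturalCoefs()] recovering the data scale.  The coefficient covariance
#' matrix is the inverse numerical Hessian at the optimum.  Estimates with
#' |logit| > 10 are flagged as boundary cases.
#'
#' @param history a [DetectionHistory-class] (codes 2 are collapsed to 1).
#' @param detFormula detection covariate formula, e.g. `~ volume + protocol`;
#'   names resolve against the history's site and replicate covariates.
#' @param occFormula occupancy covariate formula (default intercept-only, as
#'   in surveys that vary detection conditions only).
#' @param starts number of optimizer starts (first from data-driven values,
#'   the rest jittered).
#' @param seed seed for the jittered starts.
#' @return an [OccupancyFit-class].
#' @examples
#' set.seed(1)
#' h <- simulateDetectionHistory(nSites = 100, psi = 0.6, p = 0.75, seed = 1)
#' fit <- occuFit(h)
#' psiHat(fit); pHat(fit)
#' @export
occuFit <- function(history, detFormula = ~1, occFormula = ~1,
                    starts = 5, seed = 1L) {
  d <- .occuDesign(history, detFormula, occFormula)
  anyDet <- any(d$yv == 1 & d$observed)
  if (!anyDet && ncol(d$detX) > 0)
    warning("no detections in the data; detection parameters are weakly ",
            "identified")
  opt <- .mleMultiStart(function(p) .negloglikBinary(p, d),
                        .naiveStarts(d), starts, seed)
  .makeOccuFit("OccupancyFit", opt, d, detFormula, occFormula,
               extra = list(history = history))
}

# refit on the same design with a new response (parametric bootstrap)
.refitBinary <- function(d, yNew, start, starts = 1, seed = 1L) {
  d$y <- yNew
  d$yv <- as.vector(yNew)
  opt <- .mleMultiStart(function(p) .negloglikBinary(p, d),
                        start, starts, seed)
  opt
}

# ---- accessors and methods --------------------------------------------------

.occIdx <- function(fit) seq_along(fit@scaling$occ)
.detIdx <- function(fit)
  length(fit@scaling$occ) + seq_along(fit@scaling$det)

#' @rdname psiHat
setMethod("psiHat", "OccuFitBase", function(object, ...) {
  unname(plogis(object@estimates[.occIdx(object)[1]]))
})

#' @rdname pHat
setMethod("pHat", "OccuFitBase", function(object, ...) {
  unname(plogis(object@estimates[.detIdx(object)[1]]))
})

#' @rdname nSites
setMethod("nSites", "OccuFitBase", function(object) object@nSites)

#' Log-likelihood and AIC of occupancy fits
#'
#' @param object a fitted occupancy model.
#' @param ... ignored.
#' @return `logLik` returns the maximized natural-log likelihood with a
#'   `df` attribute; `AIC` returns 2k - 2 logLik.
#' @export
setMethod("logLik", "OccuFitBase", function(object, ...) {
  structure(object@loglik, df = object@nParams, class = "logLik")
})

#' @rdname logLik-OccuFitBase-method
#' @param k penalty per parameter (2 for AIC).
#' @export
setMethod("AIC", "OccuFitBase", function(object, ..., k = 2) {
  k * object@nParams - 2 * object@loglik
})

#' Coefficient covariance matrix of a fit
#'
#' @param object a fitted occupancy model.
#' @return covariance matrix of the (standardized-scale) coefficients.
#' @export
setMethod("vcov", "OccuFitBase", function(object) object@vcov)

#' Coefficients of a fit (standardized scale)
#'
#' @param object a fitted occupancy model.
#' @return named coefficient vector on the logit scale with covariates as
#'   standardized internally; see [naturalCoefs()] for the data scale.
#' @export
setMethod("coef", "OccuFitBase", function(object) object@estimates)

setMethod("show", "OccupancyFit", function(object) {
  cat("Single-season occupancy model fit\n")
  cat("  detection:", deparse(object@detFormula),
      " occupancy:", deparse(object@occFormula), "\n")
  cat(sprintf("  %d sites, %d parameters; logLik %.3f, AIC %.3f\n",
              object@nSites, object@nParams, object@loglik, object@aic))
  cat(sprintf("  psi-hat %.4f, p-hat %.4f%s%s\n", psiHat(object),
              pHat(object),
              if (!object@converged) " [NOT CONVERGED]" else "",
              if (object@boundary) " [boundary]" else ""))
  print(round(object@estimates, 4))
})

#' Coefficients on the natural (unstandardized) covariate scale
#'
#' Back-transforms the internally standardized logit-scale coefficients to
#' the scale of the covariates as supplied.
#'
#' @param fit a fitted occupancy model.
#' @return list with components `occ` and `det`, each a named vector.
#' @export
naturalCoefs <- function(fit) {
  unscale <- function(est, scaling) {
    ctr <- vapply(scaling, `[[`, 0, "center")
    scl <- vapply(scaling, `[[`, 0, "scale")
    out <- est / scl
    icpt <- which(names(scaling) == "(Intercept)")
    if (length(icpt))
      out[icpt] <- est[icpt] - sum((est * ctr / scl)[-icpt])
    setNames(out, names(scaling))
  }
  list(occ = unscale(unname(fit@estimates[.occIdx(fit)]), fit@scaling$occ),
       det = unscale(unname(fit@estimates[.detIdx(fit)]), fit@scaling$det))
}

# linear predictor + delta-method CI on the link scale, back-transformed
.predictLink <- function(X, est, V, level) {
  eta <- drop(X %*% est)
  se <- sqrt(pmax(0, rowSums((X %*% V) * X)))
  z <- -qnorm((1 - level) / 2)
  data.frame(estimate = plogis(eta),
             se = se,
             lower = plogis(eta - z * se),
             upper = plogis(eta + z * se))
}

#' Predict per-replicate detection probability at given covariate values
#'
#' Evaluates the fitted detection model at new covariate values, with a 95%
#' (by default) confidence interval computed by the delta method on the
#' linear-predictor scale and back-transformed through the logistic — so the
#' interval always lies inside \[0, 1\].  Values outside the range observed
#' during fitting are flagged as extrapolation.
#'
#' @param fit an [OccupancyFit-class] or [FPOccupancyFit-class].
#' @param newdata `data.frame` supplying every covariate in the detection
#'   formula; defaults to a single row at the training covariate means.
#' @param level confidence level.
#' @return `data.frame` with columns `estimate`, `se`, `lower`, `upper`,
#'   `extrapolated`.
#' @examples
#' h <- simulateDetectionHistory(nSites = 150, psi = 0.6, p = 0.75, seed = 7)
#' predictDetection(occuFit(h))
#' @export
predictDetection <- function(fit, newdata = NULL, level = 0.95) {
  tt <- delete.response(terms(fit@detFormula))
  if (is.null(newdata)) {
    X <- matrix(c(1, rep(0, length(fit@scaling$det) - 1)), 1,
                dimnames = list(NULL, names(fit@scaling$det)))
    extra <- FALSE
  } else {
    X0 <- model.matrix(tt, newdata)
    X <- .standardizeMat(X0, fit@scaling$det)$X
    # standardized training columns span roughly [-3, 3]; binary exact
    extra <- apply(X, 1, function(r) any(abs(r[-1]) > 3.5))
    if (any(extra))
      warning("prediction at covariate values outside the observed range")
  }
  idx <- .detIdx(fit)
  out <- .predictLink(X, fit@estimates[idx],
                      fit@vcov[idx, idx, drop = FALSE], level)
  out$extrapolated <- extra
  out
}

#' Predict occupancy probability
#'
#' @inheritParams predictDetection
#' @return `data.frame` with columns `estimate`, `se`, `lower`, `upper`.
#' @export
predictOccupancy <- function(fit, newdata = NULL, level = 0.95) {
  if (is.null(newdata)) {
    X <- matrix(c(1, rep(0, length(fit@scaling$occ) - 1)), 1,
                dimnames = list(NULL, names(fit@scaling$occ)))
  } else {
    X0 <- model.matrix(delete.response(terms(fit@occFormula)), newdata)
    X <- .standardizeMat(X0, fit@scaling$occ)$X
  }
  idx <- .occIdx(fit)
  .predictLink(X, fit@estimates[idx], fit@vcov[idx, idx, drop = FALSE],
               level)
}

# ---- AIC model enumeration --------------------------------------------------

#' Fit every detection-covariate subset and rank by AIC
#'
#' Fits the single-season model for all 2^m subsets of the covariate pool as
#' detection covariates (16 models for the standard pool of four: volume per
#' replicate, average volume, pool area, filtration protocol) and ranks them
#' by AIC.  Among models within 2 AIC units of the best, the one with fewest
#' parameters is selected (parsimony convention).
#'
#' @param history a [DetectionHistory-class].
#' @param covariatePool character vector of covariate names to enumerate
#'   over.
#' @param occFormula occupancy formula shared by all models.
#' @param starts,seed passed to [occuFit()].
#' @return `data.frame` with columns `model`, `nParams`, `logLik`, `AIC`,
#'   `deltaAIC`, `converged`, sorted by AIC; the fitted models are in
#'   attribute `"fits"` (named by model string) and the selected model name
#'   in attribute `"best"`.  A model whose fit fails is recorded with `NA`
#'   rather than aborting the table.
#' @examples
#' h <- simulateDetectionHistory(nSites = 80, psi = 0.6, p = 0.7, seed = 3)
#' enumerateModels(h, covariatePool = character())
#' @export
enumerateModels <- function(history,
                            covariatePool = c("volume", "avgVolume",
                                              "poolArea", "protocol"),
                            occFormula = ~1, starts = 5, seed = 1L) {
  subsets <- list(character())
  for (m in seq_along(covariatePool))
    subsets <- c(subsets,
                 combn(covariatePool, m, simplify = FALSE))
  fits <- list(); rows <- list()
  for (s in subsets) {
    f <- if (length(s)) as.formula(paste("~", paste(s, collapse = " + ")))
         else ~1
    label <- paste(deparse(f), collapse = "")
    fit <- tryCatch(occuFit(history, detFormula = f,
                            occFormula = occFormula,
                            starts = starts, seed = seed),
                    error = function(e) NULL)
    fits[[label]] <- fit
    rows[[label]] <- if (is.null(fit))
      data.frame(model = label, nParams = NA_integer_, logLik = NA_real_,
                 AIC = NA_real_, converged = FALSE)
    else
      data.frame(model = label, nParams = fit@nParams, logLik = fit@loglik,
                 AIC = fit@aic, converged = fit@converged)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  tab$deltaAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  near <- which(!is.na(tab$deltaAIC) & tab$deltaAIC <= 2)
  best <- tab$model[near[which.min(tab$nParams[near])]]
  attr(tab, "fits") <- fits
  attr(tab, "best") <- best
  tab
}
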