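# design bundle keeping the certain/uncertain codes {0, 1, 2}
.fpDesign <- function(history, detFormula, occFormula, scaling = NULL) {
  d <- .occuDesign(history, detFormula, occFormula, scaling = scaling)
  d$yv <- as.vector(history@y)       # un-collapsed codes
  d$y <- history@y
  d
}

# negative log-likelihood with false positives; params on the logit scale:
# (alpha | beta for p11 | p10 | b-unless-fixed)
.negloglikFP <- function(params, d, bFixed = NULL) {
  pocc <- ncol(d$occX); pdet <- ncol(d$detX)
  alpha <- params[seq_len(pocc)]
  beta <- params[pocc + seq_len(pdet)]
  lp10 <- params[pocc + pdet + 1]
  b <- if (is.null(bFixed)) plogis(params[pocc + pdet + 2]) else bFixed
  etaPsi <- drop(d$occX %*% alpha)
  logPsi <- plogis(etaPsi, log.p = TRUE)
  log1mPsi <- plogis(-etaPsi, log.p = TRUE)
  etaP <- drop(d$detX %*% beta)
  logP11 <- plogis(etaP, log.p = TRUE)
  log1mP11 <- plogis(-etaP, log.p = TRUE)
  logP10 <- plogis(lp10, log.p = TRUE)
  log1mP10 <- plogis(-lp10, log.p = TRUE)
  logB <- log(b); log1mB <- log1p(-b)

  y <- d$yv
  lf1 <- ifelse(y == 0, log1mP11,
         ifelse(y == 1, logP11 + log1mB, logP11 + logB))
  lf0 <- ifelse(y == 0, log1mP10,
         ifelse(y == 1, logP10, -Inf))
  lf1[!d$observed] <- 0
  lf0[!d$observed] <- 0
  logOcc <- logPsi + rowSums(matrix(lf1, d$n, d$J))
  logUnocc <- log1mPsi + rowSums(matrix(lf0, d$n, d$J))
  ll <- ifelse(d$known, logOcc, logSumExp2(logOcc, logUnocc))
  -sum(ll)
}

#' Negative log-likelihood of the false-positive occupancy model
#'
#' Site likelihood for certain/uncertain detection data (codes 0, 1, 2): the
#' occupied branch multiplies f1(0) = 1 - p11, f1(1) = p11 (1 - b),
#' f1(2) = p11 b over replicates; the unoccupied branch multiplies
#' f0(0) = 1 - p10, f0(1) = p10, f0(2) = 0; the site contributes
#' psi * occupied + (1 - psi) * unoccupied (the unoccupied branch is
#' dropped at known-occupied sites).  p11 may carry logit-linear covariates;
#' p10 is a scalar with no covariates; b is the probability that a true
#' detection is recorded as certain.
#'
#' Parameters are packed (alpha | beta | logit p10 | logit b), the last
#' omitted when `bFixed` is supplied.
#'
#' @param params numeric parameter vector on the logit scale.
#' @param history a [DetectionHistory-class] with codes \{0, 1, 2\}.
#' @param detFormula,occFormula covariate formulas for p11 and psi.
#' @param bFixed optionally fix b to a probability instead of estimating it.
#' @param standardize z-standardize covariates as [occuFPFit()] does.
#' @return scalar negative log-likelihood.
#' @examples
#' h <- makeDetectionHistory(matrix(1L, 1, 1), knownOccupied = FALSE)
#' # psi = 0.5, p11 = 0.8, p10 = 0.1, b = 0.5: -log(0.5*0.4 + 0.5*0.1)
#' occuFPNegLogLik(qlogis(c(0.5, 0.8, 0.1, 0.5)), h)
#' @export
occuFPNegLogLik <- function(params, history, detFormula = ~1,
                            occFormula = ~1, bFixed = NULL,
                            standardize = FALSE) {
  d <- .fpDesign(history, detFormula, occFormula)
  if (!standardize) {
    d$detX <- .modelMatrix(detFormula, .obsData(history),
                           maskObserved = d$observed)
    d$occX <- .modelMatrix(occFormula, history@siteCovs)
  }
  .negloglikFP(params, d, bFixed = bFixed)
}

#' Fit the false-positive occupancy model
#'
#' Maximum-likelihood fit of [occuFPNegLogLik()] with multiple jittered
#' starts, estimating occupancy psi, true-positive per-replicate detection
#' p11 (optionally covariate-dependent), the constant false-positive
#' probability p10, and the certainty probability b (estimated by default;
#' fix it with `bFixed`).  The headline false-positive estimate is `p10Hat`.
#' Data with no uncertain detections drive p10 to its 0 boundary — the fit
#' is flagged, not an error.
#'
#' @param history a [DetectionHistory-class] with certain/uncertain codes.
#' @param detFormula covariates of p11 (false positives carry none).
#' @param occFormula covariates of psi (default intercept-only).
#' @param starts,seed optimizer starts as in [occuFit()].
#' @param bFixed optionally fix the certainty probability.
#' @return an [FPOccupancyFit-class].
#' @examples
#' h <- simulateDetectionHistory(nSites = 300, psi = 0.6, p = 0.8,
#'                               p10 = 0.09, dipnetSensitivity = 0.8,
#'                               seed = 5)
#' fit <- occuFPFit(h)
#' p10Hat(fit)
#' @export
occuFPFit <- function(history, detFormula = ~1, occFormula = ~1,
                      starts = 5, seed = 1L, bFixed = NULL) {
  d <- .fpDesign(history, detFormula, occFormula)
  yv <- d$yv[d$observed]
  if (!any(yv > 0)) stop("data contain no detections; model unidentifiable")
  if (is.null(bFixed) && !any(yv == 2))
    warning("no certain detections in the data; b is not identifiable")
  nPos <- sum(yv > 0)
  bStart <- clampProb(sum(yv == 2) / max(1, nPos), 0.05)
  start <- c(.naiveStarts(d), qlogis(0.05),
             if (is.null(bFixed)) qlogis(bStart))
  opt <- .mleMultiStart(function(p) .negloglikFP(p, d, bFixed = bFixed),
                        start, starts, seed)
  pocc <- ncol(d$occX); pdet <- ncol(d$detX)
  extraNames <- c("logit_p10", if (is.null(bFixed)) "logit_b")
  fit <- .makeOccuFit("FPOccupancyFit", opt, d, detFormula, occFormula,
    extra = list(history = history, names = extraNames,
      slots = list(
        p10 = unname(plogis(opt$par[pocc + pdet + 1])),
        b = if (is.null(bFixed)) unname(plogis(opt$par[pocc + pdet + 2]))
            else bFixed,
        bFixed = !is.null(bFixed))))
  fit
}

#' @rdname p10Hat
setMethod("p10Hat", "FPOccupancyFit", function(object) object@p10)

setMethod("show", "FPOccupancyFit", function(object) {
  cat("False-positive occupancy model fit (certain/uncertain detections)\n")
  cat("  p11:", deparse(object@detFormula),
      " psi:", deparse(object@occFormula), "\n")
  cat(sprintf("  %d sites, %d parameters; logLik %.3f, AIC %.3f\n",
              object@nSites, object@nParams, object@loglik, object@aic))
  cat(sprintf("  psi-hat %.4f, p11-hat %.4f, p10-hat %.3g, b-hat %.4f%s%s%s\n",
              psiHat(object), pHat(object), object@p10, object@b,
              if (object@bFixed) " (b fixed)" else "",
              if (!object@converged) " [NOT CONVERGED]" else "",
              if (object@boundary) " [boundary]" else ""))
})
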