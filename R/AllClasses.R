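setOldClass("formula")

#' Species-specific qPCR assay description
#'
#' Holds the primer/probe sequences and cycle cutoffs of one TaqMan assay
#' targeting a single branchiopod species.  The two cycle cutoffs encode the
#' specificity window established on tissue-derived DNA: target specimens
#' amplify at or before `positiveCallMaxCycle`, while off-target congeners
#' never amplify before `offtargetFloorCycle`.
#'
#' @slot speciesCode four-letter species code (e.g. "BRCO", "BRLY", "BRME",
#'   "LEPA").
#' @slot gene marker gene label.
#' @slot primerF,primerR,probe IUPAC DNA strings.
#' @slot annealTempC annealing/elongation temperature in Celsius.
#' @slot positiveCallMaxCycle latest Cq at which a tissue-derived specimen is
#'   called the target.
#' @slot offtargetFloorCycle earliest cycle at which an off-target has ever
#'   been observed to amplify; no amplification before this cycle supports a
#'   non-target call.
#' @seealso [vernalAssays()] for the four assays shipped with the package.
#' @export
setClass("Assay",
  representation(
    speciesCode = "character",
    gene = "character",
    primerF = "character",
    primerR = "character",
    probe = "character",
    annealTempC = "numeric",
    positiveCallMaxCycle = "numeric",
    offtargetFloorCycle = "numeric"
  )
)

setValidity("Assay", function(object) {
  msg <- character()
  iupac <- "^[ACGTRYSWKMBDHVN]+$"
  for (s in c("primerF", "primerR", "probe")) {
    seq <- slot(object, s)
    if (!length(seq) || !nzchar(seq) || !grepl(iupac, toupper(seq)))
      msg <- c(msg, sprintf("'%s' must be a nonempty IUPAC DNA string", s))
  }
  if (object@positiveCallMaxCycle >= object@offtargetFloorCycle)
    msg <- c(msg, "positiveCallMaxCycle must be < offtargetFloorCycle")
  if (object@offtargetFloorCycle > 50)
    msg <- c(msg, "offtargetFloorCycle must be <= 50 (protocol length)")
  if (length(msg)) msg else TRUE
})

#' One pool visit: covariates, water replicates and dip-net outcomes
#'
#' A sampling event is a single visit to a vernal pool, comprising (usually
#' three) replicate water samples plus an immediately following dip-net
#' survey.  Events are the "site" unit of all occupancy models in this
#' package, even when the same pool is visited more than once; `poolId` is
#' retained for reporting only.
#'
#' @slot eventId unique collection identifier.
#' @slot poolId vernal pool identifier.
#' @slot property name of the property sampled.
#' @slot date sampling date.
#' @slot poolAreaM2 pool area in square meters (positive, finite).
#' @slot latitude,longitude decimal degrees (may be `NA`).
#' @slot replicates `data.frame` with one row per water replicate: columns
#'   `replicateId`, `volumeMl` (0 to 1000), `protocol` ("field" or "lab") and
#'   `filterType`.
#' @slot calls `data.frame` (replicates x species) of eDNA sample calls, each
#'   one of "positive", "negative", "discarded", "missing"; may have zero
#'   columns before qPCR calling has been run.
#' @slot dipnet named logical vector of per-species dip-net detections.
#' @export
setClass("SamplingEvent",
  representation(
    eventId = "character",
    poolId = "character",
    property = "character",
    date = "Date",
    poolAreaM2 = "numeric",
    latitude = "numeric",
    longitude = "numeric",
    replicates = "data.frame",
    calls = "data.frame",
    dipnet = "logical"
  )
)

setValidity("SamplingEvent", function(object) {
  msg <- character()
  if (!is.finite(object@poolAreaM2) || object@poolAreaM2 <= 0)
    msg <- c(msg, "poolAreaM2 must be finite and positive")
  rep <- object@replicates
  need <- c("replicateId", "volumeMl", "protocol", "filterType")
  if (!all(need %in% names(rep)))
    msg <- c(msg, paste("replicates must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(rep) < 1) msg <- c(msg, "at least one water replicate required")
    if (any(!is.na(rep$volumeMl) & (rep$volumeMl < 0 | rep$volumeMl > 1000)))
      msg <- c(msg, "volumeMl must lie in [0, 1000]")
    if (!all(rep$protocol %in% c("field", "lab")))
      msg <- c(msg, "protocol must be 'field' or 'lab'")
  }
  if (ncol(object@calls) > 0) {
    ok <- c("positive", "negative", "discarded", "missing")
    if (!all(unlist(object@calls) %in% ok))
      msg <- c(msg, "calls must be positive/negative/discarded/missing")
    if (nrow(object@calls) != nrow(rep))
      msg <- c(msg, "calls must have one row per replicate")
  }
  if (length(msg)) msg else TRUE
})

#' Coded detection-history matrix for occupancy modelling
#'
#' Sites-by-replicates matrix of coded observations: 0 = no detection, 1 =
#' uncertain detection (eDNA positive without a dip-net capture), 2 = certain
#' detection (eDNA positive at a dip-net-positive event), `NA` = missing or
#' discarded replicate.  Certain detections may only occur at sites flagged
#' `knownOccupied`.
#'
#' @slot y integer observation matrix with codes \{0, 1, 2, NA\}.
#' @slot siteIds character site (sampling event) identifiers, row order of
#'   `y`.
#' @slot siteCovs `data.frame` of per-site covariates (one row per site).
#' @slot obsCovs named list of numeric sites-by-replicates matrices of
#'   per-replicate covariates.
#' @slot knownOccupied logical; `TRUE` where the dip-net survey captured the
#'   target, making occupancy certain at that site.
#' @seealso [makeDetectionHistory()], [buildDetectionHistory()]
#' @export
setClass("DetectionHistory",
  representation(
    y = "matrix",
    siteIds = "character",
    siteCovs = "data.frame",
    obsCovs = "list",
    knownOccupied = "logical"
  )
)

setValidity("DetectionHistory", function(object) {
  msg <- character()
  y <- object@y
  if (!all(y[!is.na(y)] %in% c(0, 1, 2)))
    msg <- c(msg, "observation codes must be 0, 1, 2 or NA")
  n <- nrow(y)
  if (length(object@siteIds) != n)
    msg <- c(msg, "siteIds length must equal nrow(y)")
  if (length(object@knownOccupied) != n)
    msg <- c(msg, "knownOccupied length must equal nrow(y)")
  else {
    certain <- rowSums(y == 2, na.rm = TRUE) > 0
    if (any(certain & !object@knownOccupied))
      msg <- c(msg, "code 2 may only appear at knownOccupied sites")
  }
  if (nrow(object@siteCovs) > 0 && nrow(object@siteCovs) != n)
    msg <- c(msg, "siteCovs must have one row per site")
  for (nm in names(object@obsCovs)) {
    oc <- object@obsCovs[[nm]]
    if (!is.matrix(oc) || !all(dim(oc) == dim(y)))
      msg <- c(msg, sprintf("obsCovs$%s must be a matrix of dim(y)", nm))
  }
  if (any(rowSums(!is.na(y)) == 0))
    msg <- c(msg, "every site must have at least one non-missing replicate")
  if (length(msg)) msg else TRUE
})

#' Dilution-series panel for qPCR calibration
#'
#' Well-level results of a standard-curve run: known template concentrations
#' (copies per reaction) against observed quantification cycles, with `NA`
#' for wells that never amplified, plus the no-template-control wells.
#'
#' @slot assay species code of the assay.
#' @slot copies numeric vector of known copies/reaction per standard well.
#' @slot cq numeric vector of observed Cq per well (`NA` = no amplification).
#' @slot ntcCq numeric vector of NTC well Cqs (`NA` = clean, the expectation).
#' @export
setClass("StandardPanel",
  representation(
    assay = "character",
    copies = "numeric",
    cq = "numeric",
    ntcCq = "numeric"
  )
)

setValidity("StandardPanel", function(object) {
  msg <- character()
  if (length(object@copies) != length(object@cq))
    msg <- c(msg, "copies and cq must have equal length")
  if (any(object@copies <= 0))
    msg <- c(msg, "copies must be strictly positive")
  if (length(unique(object@copies)) < 2)
    msg <- c(msg, "at least two distinct concentrations required")
  if (any(!is.na(object@cq) & (object@cq <= 0 | object@cq > 50)))
    msg <- c(msg, "cq values must lie in (0, 50]")
  if (length(msg)) msg else TRUE
})

#' Fitted standard curve and assay sensitivity metrics
#'
#' The log-linear calibration fit Cq = slope * log10(copies) + intercept over
#' amplifying wells, with amplification efficiency 10^(-1/slope) - 1, plus
#' the sensitivity metrics computed from the same panel: Low95 (lowest tested
#' standard with >= 95% of replicates amplifying), LOD (lowest concentration
#' detected with 95% confidence) and LOQ (lowest concentration quantified
#' with back-calculated CV below threshold).
#'
#' @slot assay species code.
#' @slot slope cycles per log10(copies); negative for a valid assay.
#' @slot intercept cycles at 1 copy/reaction.
#' @slot rSquared coefficient of determination of the calibration regression.
#' @slot efficiency amplification efficiency as a fraction (1 = perfect
#'   doubling per cycle).
#' @slot low95 copies/reaction; `Inf` when no tested concentration reaches
#'   95% amplification.
#' @slot lod,loq copies/reaction; `Inf` for above-max-tested.
#' @slot details list of method settings and per-concentration summaries.
#' @export
setClass("CurveFit",
  representation(
    assay = "character",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    efficiency = "numeric",
    low95 = "numeric",
    lod = "numeric",
    loq = "numeric",
    details = "list"
  ),
  prototype(low95 = NA_real_, lod = NA_real_, loq = NA_real_,
            details = list())
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# shared slots of maximum-likelihood occupancy fits
setClass("OccuFitBase",
  representation(
    "VIRTUAL",
    detFormula = "formula",
    occFormula = "formula",
    estimates = "numeric",
    vcov = "matrix",
    loglik = "numeric",
    aic = "numeric",
    converged = "logical",
    boundary = "logical",
    nSites = "integer",
    nParams = "integer",
    scaling = "list",
    history = "DetectionHistory"
  )
)

#' Fitted single-season occupancy model
#'
#' Maximum-likelihood fit of the single-season site-occupancy model with
#' imperfect detection: occupancy probability psi on a logit link (optionally
#' with site covariates) and per-replicate detection probability p on a logit
#' link with detection covariates.  Sites flagged known-occupied (dip-net
#' capture) contribute only the occupied branch of the likelihood.
#'
#' @slot detFormula,occFormula model formulas for detection and occupancy.
#' @slot estimates named coefficient vector on the logit scale (occupancy
#'   block first, then detection), covariates internally standardized.
#' @slot vcov coefficient covariance matrix (inverse numerical Hessian).
#' @slot loglik maximized natural-log likelihood.
#' @slot aic 2k - 2 loglik.
#' @slot converged optimizer convergence flag.
#' @slot boundary `TRUE` when any coefficient sits at a logit boundary
#'   (|estimate| > 10), where Wald inference is unreliable.
#' @slot nSites,nParams dimensions of the fit.
#' @slot scaling centering/scaling used for covariates, for prediction and
#'   natural-scale reporting.
#' @slot history the [DetectionHistory-class] the model was fitted to.
#' @seealso [occuFit()], [predictDetection()], [gofMB()]
#' @export
setClass("OccupancyFit", contains = "OccuFitBase")

#' Fitted false-positive occupancy model (certain/uncertain detections)
#'
#' Maximum-likelihood fit of the occupancy model that accommodates false
#' positives by exploiting detections of two kinds: certain (code 2,
#' corroborated by a dip-net capture) and uncertain (code 1).  Estimates
#' occupancy psi, true-positive per-replicate detection p11 (optionally with
#' covariates), a constant false-positive probability p10 at unoccupied
#' sites, and the probability b that a detection at an occupied site is
#' recorded as certain.
#'
#' @slot p10 estimated false-positive probability (response scale).
#' @slot b estimated (or fixed) certainty probability (response scale).
#' @slot bFixed `TRUE` when b was supplied rather than estimated.
#' @seealso [occuFPFit()]
#' @export
setClass("FPOccupancyFit",
  contains = "OccuFitBase",
  representation(
    p10 = "numeric",
    b = "numeric",
    bFixed = "logical"
  )
)

#' Parametric-bootstrap goodness-of-fit result
#'
#' MacKenzie-Bailey chi-square goodness-of-fit for a fitted occupancy model:
#' the observed statistic, its parametric-bootstrap reference distribution,
#' the bootstrap p-value and the overdispersion ratio c-hat.
#'
#' @slot tObs observed chi-square statistic.
#' @slot tStar bootstrap replicates of the statistic.
#' @slot pValue (1 + #\{T* >= T_obs\}) / (B + 1).
#' @slot cHat tObs / mean(tStar); ~1 indicates adequate fit.
#' @slot nBoot number of bootstrap datasets B.
#' @seealso [gofMB()]
#' @export
setClass("GofResult",
  representation(
    tObs = "numeric",
    tStar = "numeric",
    pValue = "numeric",
    cHat = "numeric",
    nBoot = "integer"
  )
)

setValidity("GofResult", function(object) {
  msg <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (is.finite(object@cHat) && object@cHat <= 0)
    msg <- c(msg, "cHat must be positive")
  if (length(msg)) msg else TRUE
})

#' Replicate-number survey-design curve
#'
#' Cumulative probability of calling a site positive (>= k positive water
#' replicates out of n) as a function of n, with confidence limits propagated
#' from the per-replicate detection estimate, and — when a false-positive
#' probability is supplied — the probability that the same k-of-n rule calls
#' an unoccupied site positive.
#'
#' @slot table `data.frame` with columns `n`, `k`, `p`, `cumulative`, `lower`,
#'   `upper` and (optionally) `fpRule`.
#' @slot k number of positive replicates required.
#' @slot p10 per-replicate false-positive probability used for `fpRule`
#'   (`NA` when not supplied).
#' @seealso [designCurve()], [cumulativeDetection()]
#' @export
setClass("DesignCurve",
  representation(
    table = "data.frame",
    k = "integer",
    p10 = "numeric"
  )
)
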