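#' @import methods
#' @importFrom stats AIC as.formula coef dbinom delete.response glm lm
#'   logLik median model.matrix optim pbinom plogis qlogis qnorm rbinom
#'   rlnorm rnorm runif sd setNames terms var vcov
#' @importFrom utils read.csv write.csv head combn
NULL

#' Detection-history observation matrix
#'
#' Accessors for the central detection-history container: the coded
#' sites-by-replicates observation matrix, the per-site and per-replicate
#' covariates, and the known-occupancy flags derived from dip-net captures.
#'
#' @param object a [DetectionHistory-class] object.
#' @return `obsMatrix` returns an integer matrix with codes 0 (no
#'   detection), 1 (uncertain detection), 2 (certain detection) and `NA`
#'   (replicate missing or discarded); `siteCovs` a `data.frame` of per-site
#'   covariates; `obsCovs` a named list of sites-by-replicates matrices;
#'   `knownOccupied` a logical vector.
#' @aliases obsMatrix siteCovs obsCovs knownOccupied
#' @export
setGeneric("obsMatrix", function(object) standardGeneric("obsMatrix"))

#' @rdname obsMatrix
#' @export
setGeneric("siteCovs", function(object) standardGeneric("siteCovs"))

#' @rdname obsMatrix
#' @export
setGeneric("obsCovs", function(object) standardGeneric("obsCovs"))

#' @rdname obsMatrix
#' @export
setGeneric("knownOccupied", function(object) standardGeneric("knownOccupied"))

#' Number of sites (sampling events) in an object
#'
#' @param object a detection history or model fit.
#' @return integer count of sites.
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' Extract estimated occupancy probability
#'
#' @param object a fitted occupancy model.
#' @param ... further arguments for methods.
#' @return occupancy probability on the response scale (at mean covariates
#'   for models with occupancy covariates).
#' @export
setGeneric("psiHat", function(object, ...) standardGeneric("psiHat"))

#' Extract the estimated per-replicate detection probability
#'
#' @param object a fitted occupancy model.
#' @param ... further arguments for methods.
#' @return detection probability on the response scale at the covariate
#'   values implied by the method (the intercept, i.e. covariate means,
#'   by default).
#' @export
setGeneric("pHat", function(object, ...) standardGeneric("pHat"))

#' Extract the estimated false-positive probability
#'
#' @param object a fitted false-positive occupancy model.
#' @return the scalar probability of a positive call at an unoccupied site.
#' @export
setGeneric("p10Hat", function(object) standardGeneric("p10Hat"))
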