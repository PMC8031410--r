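# covariate generators: a site-level turbidity latent couples replicate
# volumes (turbid pools clog filters early), making average volume a
# meaningful site covariate; volumes are capped at the 1000 mL protocol max
.simCovariates <- function(nSites, J) {
  turbidity <- rnorm(nSites)
  vol <- matrix(pmin(1000, rlnorm(nSites * J,
                                  meanlog = rep(6.2 - 0.8 * turbidity, J),
                                  sdlog = 0.35)),
                nSites, J)
  list(turbidity = turbidity,
       volume = vol,
       avgVolume = rowMeans(vol),
       poolArea = rlnorm(nSites, meanlog = log(500), sdlog = 1),
       protocol = matrix(rep(rbinom(nSites, 1, 0.5), J), nSites, J))
}

# standardized covariate effects entering the detection linear predictor;
# reference point (coefs = 0) is a 500 mL replicate in a 500 m2 pool under
# field filtration
.detLinpred <- function(cov, pIntercept, detCoefs, nSites, J) {
  volZ <- (cov$volume - 500) / 250
  avgZ <- matrix((cov$avgVolume - 500) / 250, nSites, J)
  areaZ <- matrix((log(cov$poolArea) - log(500)) / 1, nSites, J)
  qlogis(pIntercept) + detCoefs["volume"] * volZ +
    detCoefs["avgVolume"] * avgZ + detCoefs["poolArea"] * areaZ +
    detCoefs["protocol"] * cov$protocol
}

.fullDetCoefs <- function(detCoefs) {
  full <- c(volume = 0, avgVolume = 0, poolArea = 0, protocol = 0)
  if (length(detCoefs)) {
    bad <- setdiff(names(detCoefs), names(full))
    if (length(bad)) stop("unknown detection coefficient(s): ",
                          paste(bad, collapse = ", "))
    full[names(detCoefs)] <- detCoefs
  }
  full
}

#' Simulate a detection history from the occupancy process
#'
#' Draws site occupancy z ~ Bernoulli(psi), per-replicate eDNA detections
#' (Bernoulli(p11) at occupied sites, Bernoulli(p10) at unoccupied sites),
#' and dip-net detections Bernoulli(dipnetSensitivity) at occupied sites.
#' Detections at dip-net-positive sites are coded certain (2), all others
#' uncertain (1); dip-net-positive sites are flagged known occupied.
#' Detection may depend on the standard covariate set through logit-scale
#' coefficients applied to internally standardized covariates, with `p` the
#' per-replicate detection probability at the reference covariates (500 mL
#' replicate, 500 m2 pool, field filtration).
#'
#' @param nSites number of sampling events.
#' @param replicatesPerSite water replicates per event (default 3).
#' @param psi occupancy probability.
#' @param p per-replicate true-positive detection probability at reference
#'   covariates.
#' @param detCoefs named logit-scale coefficients, any of `volume`,
#'   `avgVolume`, `poolArea`, `protocol` (default all 0: the base model).
#' @param p10 per-replicate false-positive probability at unoccupied sites.
#' @param dipnetSensitivity probability a dip-net survey detects the target
#'   at an occupied site (certainty is then assigned at the event level:
#'   every detection at a dip-net-positive event is certain).
#' @param b when supplied, certainty is instead drawn per detection: each
#'   detection at an occupied site is recorded certain with probability b,
#'   independently — the data-generating process assumed by the
#'   false-positive model itself.  Known-occupied flags are then the sites
#'   holding at least one certain detection.
#' @param seed RNG seed (required: simulations are reproducible by
#'   construction).
#' @return a [DetectionHistory-class] with covariates `volume`, `protocol`
#'   (replicate level) and `avgVolume`, `poolArea` (site level); the latent
#'   truth (`z`, `p11`, parameters) is in attribute `"truth"`.
#' @seealso [simulateStudy()] for the full pipeline including qPCR wells.
#' @export
simulateDetectionHistory <- function(nSites, replicatesPerSite = 3,
                                     psi = 0.5, p = 0.7564,
                                     detCoefs = c(), p10 = 0,
                                     dipnetSensitivity = 0.85, b = NULL,
                                     seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(deriveSeed(seed, 0L))
  J <- replicatesPerSite
  cov <- .simCovariates(nSites, J)
  detCoefs <- .fullDetCoefs(detCoefs)
  p11 <- plogis(.detLinpred(cov, p, detCoefs, nSites, J))
  z <- rbinom(nSites, 1, psi)
  zmat <- matrix(z, nSites, J)
  probs <- ifelse(zmat == 1, p11, p10)
  det <- matrix(rbinom(nSites * J, 1, probs), nSites, J)
  y <- det
  if (is.null(b)) {
    dipnet <- rbinom(nSites, 1, dipnetSensitivity * z) == 1
    y[det == 1 & matrix(dipnet, nSites, J)] <- 2L
    known <- dipnet
  } else {
    certain <- matrix(rbinom(nSites * J, 1, b), nSites, J)
    y[det == 1 & zmat == 1 & certain == 1] <- 2L
    dipnet <- rowSums(y == 2) > 0
    known <- dipnet
  }
  dh <- makeDetectionHistory(
    y,
    siteIds = sprintf("E%04d", seq_len(nSites)),
    siteCovs = data.frame(avgVolume = cov$avgVolume,
                          poolArea = cov$poolArea),
    obsCovs = list(volume = cov$volume, protocol = cov$protocol),
    knownOccupied = known)
  attr(dh, "truth") <- list(z = z, p11 = p11, dipnet = dipnet,
                            params = list(psi = psi, p = p,
                                          detCoefs = detCoefs, p10 = p10,
                                          dipnetSensitivity = dipnetSensitivity,
                                          b = b),
                            seed = seed)
  dh
}

# quadruplicate well Cqs for one run: nAmp amplifying wells with Cqs from
# the latent concentration through the curve truth, the rest NA
.runWells <- function(nAmp, curve) {
  copies <- rlnorm(1, meanlog = log(10), sdlog = 1)
  cq <- curve$slope * log10(copies) + curve$intercept +
    rnorm(4, 0, curve$sdCq)
  cq <- pmin(pmax(cq, 1), 50)
  amp <- sample(c(rep(TRUE, nAmp), rep(FALSE, 4 - nAmp)))
  ifelse(amp, cq, NA_real_)
}

#' Simulate a complete eDNA survey study
#'
#' Generates the full raw-data bundle of a side-by-side eDNA/dip-net survey
#' for one species: sampling events (pools, covariates, water replicates),
#' a dip-net results table, and a long-format qPCR well table in which each
#' latently detected replicate yields quadruplicate wells with at least two
#' amplifications or a 1-of-4 first run followed by a positive re-run, and
#' each undetected replicate yields either a clean quadruplicate or a 1-of-4
#' first run whose re-run is clean — exercising every branch of the 2-of-4
#' calling rule.  Each event gets its own plate with a quadruplicate NTC,
#' two quadruplicate positive controls and a quadruplicate field negative.
#'
#' Defaults mirror the study design: 98 sampling events (89 pools visited
#' once plus 3 pools visited three times), three replicates per event.
#'
#' @inheritParams simulateDetectionHistory
#' @param species assay/species code for the tables.
#' @param curve list with `slope`, `intercept`, `sdCq`: the Cq-generating
#'   calibration truth for amplifying wells.
#' @param rerunRatePositive probability a detected replicate presents as a
#'   1-of-4 first run resolved positive on re-run.
#' @param rerunRateNegative probability an undetected replicate presents as
#'   a 1-of-4 first run whose re-run is clean.
#' @param contaminationRate probability a field negative amplifies (2 of 4
#'   wells), discarding its event in QC.
#' @return list with `events` (list of [SamplingEvent-class]), `qpcr`
#'   (long-format well `data.frame`), `dipnet` (`data.frame`), and `truth`
#'   (latent states and parameters).
#' @examples
#' study <- simulateStudy(nSites = 6, seed = 42)
#' head(study$qpcr)
#' @export
simulateStudy <- function(nSites = 98, replicatesPerSite = 3, psi = 0.5,
                          p = 0.7564, detCoefs = c(), p10 = 0.091,
                          dipnetSensitivity = 0.85, species = "BRLY",
                          curve = list(slope = -3.4, intercept = 38.7,
                                       sdCq = 0.3),
                          rerunRatePositive = 0.15,
                          rerunRateNegative = 0.08,
                          contaminationRate = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  dh <- simulateDetectionHistory(nSites, replicatesPerSite, psi, p,
                                 detCoefs, p10, dipnetSensitivity,
                                 seed = seed)
  truth <- attr(dh, "truth")
  det <- obsMatrix(dh) >= 1
  vol <- obsCovs(dh)$volume
  prot <- obsCovs(dh)$protocol
  sc <- siteCovs(dh)
  J <- replicatesPerSite

  set.seed(deriveSeed(seed, 1L))
  events <- vector("list", nSites)
  qpcr <- list()
  season <- as.Date("2017-01-15")
  nPools <- max(1, nSites - 2 * min(3, nSites %/% 10))
  poolOf <- c(seq_len(nPools),
              rep(seq_len(min(3, nPools)), length.out = max(0, nSites - nPools)))
  for (i in seq_len(nSites)) {
    eid <- sprintf("E%04d", i)
    repIds <- sprintf("%s_R%d", eid, seq_len(J))
    events[[i]] <- SamplingEvent(
      eventId = eid, poolId = sprintf("VP%03d", poolOf[i]),
      property = sprintf("Property%d", 1 + (poolOf[i] - 1) %% 5),
      date = season + i, poolAreaM2 = sc$poolArea[i],
      latitude = 38.5 + rnorm(1, 0, 0.2),
      longitude = -121.7 + rnorm(1, 0, 0.2),
      replicates = data.frame(
        replicateId = repIds, volumeMl = vol[i, ],
        protocol = ifelse(prot[i, ] == 1, "lab", "field"),
        filterType = "CN 0.22um", stringsAsFactors = FALSE))

    wells <- list()
    addRun <- function(sampleId, role, nAmp, plateSuffix = "") {
      cq <- if (nAmp > 0) .runWells(nAmp, curve) else rep(NA_real_, 4)
      data.frame(plate_id = paste0("P_", eid, plateSuffix),
                 well = paste0(sampleId, "_w", 1:4), assay = species,
                 sample_id = sampleId, role = role, cq = cq,
                 stringsAsFactors = FALSE)
    }
    for (j in seq_len(J)) {
      if (det[i, j]) {
        if (runif(1) < rerunRatePositive) {
          wells[[length(wells) + 1]] <- addRun(repIds[j], "sample", 1)
          wells[[length(wells) + 1]] <- addRun(repIds[j], "sample",
                                               sample(1:4, 1), "_rerun")
        } else {
          wells[[length(wells) + 1]] <- addRun(repIds[j], "sample",
                                               sample(2:4, 1))
        }
      } else {
        if (runif(1) < rerunRateNegative) {
          wells[[length(wells) + 1]] <- addRun(repIds[j], "sample", 1)
          wells[[length(wells) + 1]] <- addRun(repIds[j], "sample", 0,
                                               "_rerun")
        } else {
          wells[[length(wells) + 1]] <- addRun(repIds[j], "sample", 0)
        }
      }
    }
    eventPlates <- unique(vapply(wells, function(w) w$plate_id[1], ""))
    for (pl in eventPlates) {
      suffix <- sub(paste0("^P_", eid), "", pl)
      wells[[length(wells) + 1]] <- addRun(paste0(eid, "_NTC"), "ntc", 0,
                                           suffix)
      for (pcIdx in 1:2)
        wells[[length(wells) + 1]] <-
          addRun(paste0(eid, "_PC", pcIdx), "positive_control", 4, suffix)
    }
    wells[[length(wells) + 1]] <-
      addRun(eid, "field_negative",
             if (runif(1) < contaminationRate) 2 else 0)
    qpcr[[i]] <- do.call(rbind, wells)
  }
  qpcr <- do.call(rbind, qpcr)
  rownames(qpcr) <- NULL
  dipnet <- data.frame(
    event_id = sprintf("E%04d", seq_len(nSites)), species = species,
    detected = truth$dipnet,
    voucher_confirmed = truth$dipnet,
    stringsAsFactors = FALSE)
  events <- setNames(events, vapply(events, function(e) e@eventId, ""))
  events <- attachDipnet(events, dipnet)
  list(events = events, qpcr = qpcr, dipnet = dipnet,
       truth = c(truth, list(detected = det)))
}

#' Simulate a standard-curve dilution panel
#'
#' Per-well amplification is Bernoulli in a logistic dose-response of
#' log10(concentration) — parameterized by the concentration detected 95% of
#' the time and a slope — and amplifying wells draw
#' Cq = slope * log10(copies) + intercept + Normal(0, sdCq).  The default
#' geometry is five concentrations spanning 1 to 100 copies/reaction with
#' eight replicates each and eight clean NTCs.
#'
#' @param slope,intercept calibration-line truth (cycles per log10(copies);
#'   cycles).
#' @param sdCq Cq noise standard deviation (0 gives exact recovery).
#' @param concentrations copies/reaction levels.
#' @param replicates wells per concentration.
#' @param nNtc no-template-control wells.
#' @param detect95 concentration detected with probability 0.95.
#' @param detectSlope logistic slope of detection vs log10(copies).
#' @param assay species code label.
#' @param seed RNG seed (required).
#' @return a [StandardPanel-class].
#' @examples
#' p <- simulateStandardPanel(sdCq = 0, detect95 = 0.01, seed = 1)
#' fitCurve(p)  # recovers slope and intercept exactly
#' @export
simulateStandardPanel <- function(slope = -3.4, intercept = 38.7,
                                  sdCq = 0.3,
                                  concentrations = c(1, 2, 5, 10, 100),
                                  replicates = 8, nNtc = 8,
                                  detect95 = 2, detectSlope = 6,
                                  assay = "", seed) {
  if (missing(seed)) stop("a seed is required")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  set.seed(deriveSeed(seed, 2L))
  copies <- rep(concentrations, each = replicates)
  a <- qlogis(0.95) - detectSlope * log10(detect95)
  pDetect <- plogis(a + detectSlope * log10(copies))
  amp <- rbinom(length(copies), 1, pDetect) == 1
  cq <- ifelse(amp,
               pmin(pmax(slope * log10(copies) + intercept +
                           rnorm(length(copies), 0, sdCq), 1), 50),
               NA_real_)
  StandardPanel(copies = copies, cq = cq, assay = assay,
                ntcCq = rep(NA_real_, nNtc))
}
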