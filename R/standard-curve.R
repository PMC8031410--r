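#' Construct a StandardPanel
#'
#' @param copies known copies/reaction per standard well.
#' @param cq observed Cq per well (`NA` = no amplification).
#' @param assay species code label.
#' @param ntcCq NTC well Cqs (`NA` = clean).
#' @return a [StandardPanel-class].
#' @export
StandardPanel <- function(copies, cq, assay = "", ntcCq = rep(NA_real_, 8)) {
  new("StandardPanel", assay = as.character(assay),
      copies = as.numeric(copies), cq = as.numeric(cq),
      ntcCq = as.numeric(ntcCq))
}

setMethod("show", "StandardPanel", function(object) {
  tab <- detectionFractions(object)
  cat(sprintf("StandardPanel (%s): %d wells over %d concentrations\n",
              if (nzchar(object@assay)) object@assay else "unlabelled",
              length(object@copies), nrow(tab)))
  print(tab, row.names = FALSE)
})

#' Per-concentration amplification summary of a standard panel
#'
#' @param panel a [StandardPanel-class].
#' @return `data.frame` with columns `copies`, `n`, `nAmplified`, `fraction`,
#'   ordered by concentration.
#' @export
detectionFractions <- function(panel) {
  conc <- sort(unique(panel@copies))
  amp <- !is.na(panel@cq)
  data.frame(
    copies = conc,
    n = vapply(conc, function(cc) sum(panel@copies == cc), 0L),
    nAmplified = vapply(conc, function(cc) sum(amp[panel@copies == cc]), 0L),
    fraction = vapply(conc, function(cc) mean(amp[panel@copies == cc]), 0))
}

#' Fit the log-linear calibration curve
#'
#' Ordinary least squares of Cq on log10(copies/reaction) over amplifying
#' wells.  Non-amplifying wells are excluded from the regression (they still
#' count toward detection fractions for LOD/Low95).  Amplification
#' efficiency is 10^(-1/slope) - 1.
#'
#' @param panel a [StandardPanel-class].
#' @return a [CurveFit-class] with slope, intercept, R-squared and
#'   efficiency filled; sensitivity metrics are added by [calibrateAssay()].
#'   A non-negative slope is flagged in `details$positiveSlope` with a
#'   warning.
#' @examples
#' p <- StandardPanel(copies = rep(c(1, 10, 100), each = 2),
#'                    cq = 38 - 3.3219 * log10(rep(c(1, 10, 100), each = 2)))
#' fitCurve(p)
#' @export
fitCurve <- function(panel) {
  ok <- !is.na(panel@cq)
  if (!any(ok)) stop("no amplifying wells; cannot fit a standard curve")
  x <- log10(panel@copies[ok])
  if (length(unique(x)) < 2)
    stop("need amplifying wells at >= 2 distinct concentrations")
  fit <- lm(panel@cq[ok] ~ x)
  m <- unname(coef(fit)[2]); c0 <- unname(coef(fit)[1])
  sst <- sum((panel@cq[ok] - mean(panel@cq[ok]))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  pos <- m >= 0
  if (pos) warning("standard curve slope is non-negative; assay suspect")
  new("CurveFit", assay = panel@assay, slope = m, intercept = c0,
      rSquared = r2, efficiency = 10^(-1 / m) - 1,
      details = list(positiveSlope = pos, nWells = sum(ok)))
}

#' Lowest standard with at least 95% of replicates amplifying
#'
#' @param panel a [StandardPanel-class].
#' @return copies/reaction of the smallest tested concentration whose
#'   amplification fraction is >= 0.95, or `Inf` (above max tested) when no
#'   concentration reaches it.
#' @examples
#' p <- StandardPanel(copies = rep(c(2, 5), each = 8),
#'                    cq = c(36, rep(NA, 1), 36, 36, 36, 36, 36, 36,
#'                           rep(35, 8)))
#' low95(p)  # 5: 7/8 = 87.5% at 2 copies falls short
#' @export
low95 <- function(panel) {
  tab <- detectionFractions(panel)
  hit <- tab$copies[tab$fraction >= 0.95]
  if (length(hit)) min(hit) else Inf
}

#' Estimate the limit of detection
#'
#' The LOD is the lowest concentration reliably distinguished from blank at
#' 95% confidence.  The `"discrete"` method applies the Low95 rule directly
#' to the tested concentrations.  The `"curvefit"` method fits a
#' two-parameter logistic dose-response of per-well detection against
#' log10(copies) and solves for the 95%-detection concentration, clamped to
#' no less than the smallest tested concentration; it falls back to the
#' discrete rule (with a warning) when the detection pattern gives a
#' non-increasing dose-response.
#'
#' @param panel a [StandardPanel-class].
#' @param method `"curvefit"` (default) or `"discrete"`.
#' @param nReplicates report the LOD attained by `nReplicates` water/qPCR
#'   replicates jointly (detection 1 - (1 - d)^r >= 0.95); default 1,
#'   matching single-replicate reporting.
#' @return copies/reaction (`Inf` = above max tested, discrete method only).
#' @export
estimateLod <- function(panel, method = c("curvefit", "discrete"),
                        nReplicates = 1) {
  method <- match.arg(method)
  target <- 1 - 0.05^(1 / nReplicates)
  tab <- detectionFractions(panel)
  discrete <- function() {
    hit <- tab$copies[1 - (1 - tab$fraction)^nReplicates >= 0.95]
    if (length(hit)) min(hit) else Inf
  }
  if (method == "discrete") return(discrete())
  if (all(tab$fraction >= target)) return(min(tab$copies))
  amp <- as.integer(!is.na(panel@cq))
  lx <- log10(panel@copies)
  gfit <- tryCatch(
    suppressWarnings(glm(amp ~ lx, family = binomial())),
    error = function(e) NULL)
  if (is.null(gfit) || coef(gfit)[2] <= 0) {
    warning("non-monotone detection pattern; falling back to discrete LOD")
    return(discrete())
  }
  a <- coef(gfit)[1]; b <- coef(gfit)[2]
  conc <- unname(10^((qlogis(target) - a) / b))
  max(conc, min(tab$copies))
}

#' Estimate the limit of quantitation
#'
#' Back-calculates copies for every amplifying well through the fitted
#' calibration curve and computes the per-concentration coefficient of
#' variation of those back-calculated copy numbers.  The `"discrete"` LOQ is
#' the lowest tested concentration (with >= 3 amplifying replicates) whose
#' CV is at or below `cvThreshold`; the `"curvefit"` variant fits a
#' monotone-decreasing linear model of CV against log10(copies) and solves
#' the threshold crossing, clamped to the tested range.
#'
#' @param panel a [StandardPanel-class].
#' @param cvThreshold CV threshold as a fraction (default 0.35).
#' @param method `"curvefit"` (default) or `"discrete"`.
#' @param fit optional pre-computed [CurveFit-class]; refitted otherwise.
#' @return copies/reaction (`Inf` = no tested concentration meets the
#'   threshold).
#' @export
estimateLoq <- function(panel, cvThreshold = 0.35,
                        method = c("curvefit", "discrete"), fit = NULL) {
  method <- match.arg(method)
  if (is.null(fit)) fit <- fitCurve(panel)
  ok <- !is.na(panel@cq)
  back <- quantifyCopies(panel@cq[ok], fit)
  conc <- panel@copies[ok]
  levels <- sort(unique(conc))
  cv <- vapply(levels, function(cc) {
    v <- back[conc == cc]
    if (length(v) < 3) return(NA_real_)
    sd(v) / mean(v)
  }, 0)
  usable <- !is.na(cv)
  discrete <- function() {
    hit <- levels[usable & cv <= cvThreshold]
    if (length(hit)) min(hit) else Inf
  }
  if (method == "discrete") return(discrete())
  if (sum(usable) < 2) return(discrete())
  if (all(cv[usable] <= cvThreshold)) return(min(levels[usable]))
  lfit <- lm(cv[usable] ~ log10(levels[usable]))
  b <- unname(coef(lfit)[2])
  if (b >= 0) {
    warning("CV does not decrease with concentration; discrete LOQ used")
    return(discrete())
  }
  x <- (cvThreshold - unname(coef(lfit)[1])) / b
  out <- 10^x
  if (out > max(levels)) return(Inf)
  max(out, min(levels))
}

#' Back-calculate copies/reaction from a Cq
#'
#' Inverse of the calibration line: copies = 10^((cq - intercept) / slope).
#'
#' @param cq quantification cycle(s).
#' @param fit a [CurveFit-class] with negative slope.
#' @return estimated copies/reaction.
#' @examples
#' f <- new("CurveFit", assay = "BRCO", slope = -3.609, intercept = 38.664,
#'          rSquared = 0.97, efficiency = 10^(1 / 3.609) - 1)
#' quantifyCopies(38.664 - 3.609 * 2, f)  # 100
#' @export
quantifyCopies <- function(cq, fit) {
  if (fit@slope >= 0) stop("calibration slope must be negative")
  10^((cq - fit@intercept) / fit@slope)
}

#' Full assay calibration: curve fit plus sensitivity metrics
#'
#' Runs [fitCurve()], [low95()], [estimateLod()] and [estimateLoq()] on a
#' panel and returns the completed [CurveFit-class] — one row of an assay
#' sensitivity report.
#'
#' @param panel a [StandardPanel-class].
#' @param cvThreshold LOQ CV threshold (default 0.35).
#' @param lodMethod,loqMethod estimation method, `"curvefit"` (default) or
#'   `"discrete"`.
#' @param nReplicates replicate count for LOD reporting (default 1).
#' @return a [CurveFit-class] with all metrics filled.
#' @seealso [curveReport()]
#' @export
calibrateAssay <- function(panel, cvThreshold = 0.35,
                           lodMethod = "curvefit", loqMethod = "curvefit",
                           nReplicates = 1) {
  fit <- fitCurve(panel)
  fit@low95 <- low95(panel)
  fit@lod <- estimateLod(panel, method = lodMethod,
                         nReplicates = nReplicates)
  fit@loq <- estimateLoq(panel, cvThreshold = cvThreshold,
                         method = loqMethod, fit = fit)
  fit@details <- c(fit@details,
                   list(cvThreshold = cvThreshold, lodMethod = lodMethod,
                        loqMethod = loqMethod, nReplicates = nReplicates,
                        fractions = detectionFractions(panel)))
  fit
}

setMethod("show", "CurveFit", function(object) {
  cat(sprintf("CurveFit %s: Cq = %.3f log10(copies) + %.3f (R2 = %.3f)\n",
              if (nzchar(object@assay)) object@assay else "",
              object@slope, object@intercept, object@rSquared))
  cat(sprintf("  efficiency %.1f%%", 100 * object@efficiency))
  fmt <- function(v) if (!length(v) || is.na(v)) "NA"
                     else if (is.infinite(v)) ">max tested"
                     else format(signif(v, 4))
  cat(sprintf("; Low95 %s, LOD %s, LOQ %s copies/reaction\n",
              fmt(object@low95), fmt(object@lod), fmt(object@loq)))
})

#' Tabulate assay calibrations
#'
#' @param fits list of completed [CurveFit-class] objects.
#' @return `data.frame` with columns `assay`, `r_squared`, `slope`,
#'   `intercept`, `low95`, `lod`, `loq` — the layout of a published assay
#'   sensitivity table.
#' @export
curveReport <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(assay = f@assay, r_squared = f@rSquared, slope = f@slope,
               intercept = f@intercept, low95 = f@low95, lod = f@lod,
               loq = f@loq, stringsAsFactors = FALSE)))
}

#' Read a standards CSV into panels
#'
#' Expects columns `assay`, `copies_per_reaction`, `cq` (empty = no
#' amplification); NTC wells are rows with `copies_per_reaction` 0 or empty.
#'
#' @param path CSV file path.
#' @return named list of [StandardPanel-class], one per assay.
#' @export
readStandardsCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay", "copies_per_reaction", "cq")
  if (!all(need %in% names(df)))
    stop("standards table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$cq <- suppressWarnings(as.numeric(df$cq))
  df$copies_per_reaction <- suppressWarnings(as.numeric(df$copies_per_reaction))
  lapply(split(df, df$assay), function(g) {
    ntc <- is.na(g$copies_per_reaction) | g$copies_per_reaction == 0
    StandardPanel(copies = g$copies_per_reaction[!ntc], cq = g$cq[!ntc],
                  assay = g$assay[1], ntcCq = g$cq[ntc])
  })
}
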