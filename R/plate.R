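#' Percentage tumour growth inhibition from plate controls
#'
#' Converts mean luminescence counts to percentage growth inhibition using
#' the plate's medium-only (MO, 0% inhibition) and maximum-inhibitor (MI,
#' 100% inhibition) controls:
#' \deqn{\%I = \left(1 - \frac{Test - MI}{MO - MI}\right) \times 100}
#' The raw (unclipped) value is returned by default; noise can push test
#' counts above MO or below MI, giving values outside \[0, 100\].
#'
#' @param testCounts numeric vector of mean test-well counts.
#' @param moCounts mean counts of the medium-only control wells.
#' @param miCounts mean counts of the maximum-inhibitor control wells.
#' @param clip if `TRUE`, clip the result to \[0, 100\].
#' @return numeric vector of percent inhibition, same length as
#'   `testCounts`.
#' @examples
#' computeInhibition(250, moCounts = 1000, miCounts = 0)  # 75
#' @export
computeInhibition <- function(testCounts, moCounts, miCounts, clip = FALSE) {
  if (any(c(testCounts, moCounts, miCounts) < 0, na.rm = TRUE))
    stop("luminescence counts must be non-negative")
  if (!is.finite(moCounts) || !is.finite(miCounts) || moCounts <= miCounts)
    stop("control failure: MO mean must exceed MI mean (assay invalid)")
  inh <- (1 - (testCounts - miCounts) / (moCounts - miCounts)) * 100
  if (clip) pmin(pmax(inh, 0), 100) else inh
}

#' Fit an ATP standard curve
#'
#' Ordinary least-squares line (free intercept) through pairs of known ATP
#' amount and measured luminescence, run before each plate read.
#'
#' @param atp numeric, ATP amounts (e.g. pmol).
#' @param counts numeric, luminescence counts at those amounts.
#' @return A [StandardCurve-class] object.
#' @examples
#' sc <- standardCurve(atp = c(0, 5, 10), counts = c(0, 500, 1000))
#' calibrateAtp(sc, 750)
#' @export
standardCurve <- function(atp, counts) {
  fit <- stats::lm(counts ~ atp)
  new("StandardCurve", atp = as.numeric(atp), counts = as.numeric(counts),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]))
}

#' Map luminescence counts to ATP amounts
#'
#' Inverts the fitted standard line: `amount = (counts - intercept) /
#' slope`. Counts outside the calibrated count range are still mapped (the
#' line is extended) but flagged out-of-range, with a warning.
#'
#' @param curve a [StandardCurve-class].
#' @param counts numeric vector of luminescence counts.
#' @return A data.frame with columns `counts`, `atp`, and logical
#'   `outOfRange`.
#' @export
calibrateAtp <- function(curve, counts) {
  stopifnot(is(curve, "StandardCurve"))
  validObject(curve)
  atp <- (counts - curve@intercept) / curve@slope
  rng <- range(curve@counts)
  oor <- counts < rng[1L] | counts > rng[2L]
  if (any(oor))
    warning(sum(oor), " count value(s) outside the calibrated range [",
            rng[1L], ", ", rng[2L], "]; extrapolated")
  data.frame(counts = counts, atp = atp, outOfRange = oor)
}

setMethod("show", "StandardCurve", function(object) {
  cat("ATP StandardCurve:", length(object@atp), "points; counts =",
      signif(object@slope, 4), "* atp +", signif(object@intercept, 4), "\n")
})

#' Read a per-well plate table
#'
#' Reads the delimited plate format: a header row and columns `plate_id`,
#' `well` (e.g. `"A1"`), `condition` (a drug/combination label, `"MO"` or
#' `"MI"`), `dilution_step` (1-6, empty for control wells), `replicate`
#' (1-based) and `counts`.
#'
#' @param path path to a comma-separated file.
#' @return A data.frame with the columns above; `dilution_step` and
#'   `replicate` integer, `counts` numeric.
#' @export
readPlateTable <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "condition", "dilution_step", "replicate",
            "counts")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("plate table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  wells$dilution_step <- as.integer(wells$dilution_step)
  wells$replicate <- as.integer(wells$replicate)
  wells$counts <- as.numeric(wells$counts)
  validateWellTable(wells)
  wells
}

#' Validate a per-well table
#'
#' Checks the structural invariants of a well table: non-negative counts,
#' well coordinates A1-H12, and `dilution_step` present exactly for
#' non-control wells.
#'
#' @param wells a well data.frame as returned by [readPlateTable()] or
#'   [simulatePlate()].
#' @return `wells`, invisibly; errors describe the first violation found.
#' @export
validateWellTable <- function(wells) {
  if (any(!is.finite(wells$counts) | wells$counts < 0))
    stop("counts must be finite and non-negative")
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", wells$well)
  if (!all(ok))
    stop("malformed well coordinate(s): ",
         paste(unique(wells$well[!ok]), collapse = ", "))
  ctrl <- wells$condition %in% c("MO", "MI")
  if (any(!is.na(wells$dilution_step[ctrl])))
    stop("control wells must not carry a dilution step")
  if (any(is.na(wells$dilution_step[!ctrl])))
    stop("non-control wells must carry a dilution step")
  if (any(!is.na(wells$dilution_step) &
          (wells$dilution_step < 1L | wells$dilution_step > 6L)))
    stop("dilution_step must be in 1..6")
  invisible(wells)
}

# Mean of control wells after dropping outliers beyond `nsd` standard
# deviations. Each well is judged against the mean and sd of the other
# control wells (leave-one-out), so a single extreme well cannot mask
# itself by inflating the pooled sd; drops are reported via warning.
.controlMean <- function(counts, label, plateId, nsd = 3) {
  if (length(counts) >= 3L) {
    keep <- vapply(seq_along(counts), function(i) {
      rest <- counts[-i]
      abs(counts[i] - mean(rest)) <= nsd * stats::sd(rest)
    }, logical(1))
    if (!all(keep)) {
      warning(sum(!keep), " outlier ", label, " control well(s) dropped ",
              "on plate ", plateId)
      counts <- counts[keep]
    }
  }
  mean(counts)
}

#' Summarize one condition on a plate into an inhibition profile
#'
#' Aggregates the replicate wells of one condition: per dilution step, the
#' replicate-mean count is converted to percent inhibition against the
#' plate's mean MO and MI controls, and the replicate coefficient of
#' variance (sd/mean, in percent) is computed on the raw replicate counts
#' (or, optionally, on per-replicate inhibition values). Control wells
#' beyond 3 sd of the control mean are dropped with a warning. Steps with
#' fewer than 2 replicates are kept but carry their replicate count for
#' downstream QC flagging.
#'
#' @param wells a well data.frame (one plate).
#' @param series the [DoseSeries-class] or [CombinationDesign-class] the
#'   condition was tested on.
#' @param condition condition label to summarize; defaults to the drug id
#'   of `series`.
#' @param cvOn `"counts"` (default) computes replicate CV on raw counts;
#'   `"inhibition"` computes it on per-replicate inhibition values.
#' @return An [InhibitionProfile-class] object.
#' @export
summarizeCondition <- function(wells, series, condition = NULL,
                               cvOn = c("counts", "inhibition")) {
  cvOn <- match.arg(cvOn)
  if (is.null(condition))
    condition <- if (is(series, "CombinationDesign"))
      paste0(series@drugA@drugId, "+", series@drugB@drugId)
    else series@drugId
  cond <- wells[wells$condition == condition, , drop = FALSE]
  if (!nrow(cond))
    stop("no wells found for condition '", condition, "'")
  plateId <- unique(cond$plate_id)
  if (length(plateId) != 1L)
    stop("condition '", condition, "' spans multiple plates; summarize ",
         "one plate at a time")
  mo <- wells$counts[wells$plate_id == plateId & wells$condition == "MO"]
  mi <- wells$counts[wells$plate_id == plateId & wells$condition == "MI"]
  if (!length(mo) || !length(mi))
    stop("control failure on plate ", plateId, ": missing ",
         if (!length(mo)) "MO" else "MI", " control wells")
  if (length(mo) < 3L || length(mi) < 3L)
    warning("fewer than 3 MO/MI control wells on plate ", plateId)
  moMean <- .controlMean(mo, "MO", plateId)
  miMean <- .controlMean(mi, "MI", plateId)
  if (moMean <= miMean)
    stop("control failure on plate ", plateId,
         ": MO mean must exceed MI mean")

  conc <- if (is(series, "CombinationDesign"))
    series@drugA@concentrations else series@concentrations
  inh <- cv <- rep(NA_real_, 6L)
  n <- integer(6L)
  for (k in 1:6) {
    rep_counts <- cond$counts[cond$dilution_step == k]
    n[k] <- length(rep_counts)
    if (!n[k]) stop("condition '", condition, "' has no wells at step ", k)
    inh[k] <- computeInhibition(mean(rep_counts), moMean, miMean)
    cv[k] <- if (n[k] >= 2L) {
      if (cvOn == "counts")
        100 * stats::sd(rep_counts) / mean(rep_counts)
      else {
        ri <- computeInhibition(rep_counts, moMean, miMean)
        if (abs(mean(ri)) < .Machine$double.eps) 0
        else abs(100 * stats::sd(ri) / mean(ri))
      }
    } else NA_real_
  }
  new("InhibitionProfile", condition = condition, concentrations = conc,
      inhibition = inh, cv = cv, nReplicates = n, series = series)
}

#' @describeIn inhibition raw or clipped mean percent inhibition, ordered
#'   from the 200% step down to the 6.25% step.
#' @export
setMethod("inhibition", "InhibitionProfile", function(x, clipped = FALSE) {
  if (clipped) pmin(pmax(x@inhibition, 0), 100) else x@inhibition
})

#' Inhibition values of a profile
#'
#' @param x an [InhibitionProfile-class].
#' @param clipped if `TRUE`, clip to \[0, 100\] (the form consumed by
#'   [indexSum()] and [estimateICF()]).
#' @return numeric(6) percent inhibition.
#' @name inhibition
NULL

#' @rdname accessors
#' @export
setMethod("concentrations", "InhibitionProfile", function(x) x@concentrations)

#' @rdname accessors
#' @export
setMethod("condition", "InhibitionProfile", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("replicateCV", "InhibitionProfile", function(x) x@cv)

setMethod("show", "InhibitionProfile", function(object) {
  cat("InhibitionProfile for", object@condition, "\n")
  print(data.frame(step = dilutionLabels(),
                   conc_uM = signif(object@concentrations, 4),
                   inhibition = round(object@inhibition, 2),
                   cv_pct = round(object@cv, 2),
                   n = object@nReplicates))
})

#' Quality-control report for an inhibition profile
#'
#' Flags dilution steps whose replicate coefficient of variance exceeds
#' the limit (the assay's typical replicate CV is below 10%, the default
#' limit) or which had fewer than 2 replicates. The profile passes iff no
#' step is flagged.
#'
#' @param profile an [InhibitionProfile-class].
#' @param cvLimit CV limit in percent (default 10).
#' @return A list with elements `condition`, `cv`, `nReplicates`,
#'   `flagged` (logical(6)), `pass` (logical(1)) and `cvLimit`.
#' @export
qcProfile <- function(profile, cvLimit = 10) {
  stopifnot(is(profile, "InhibitionProfile"))
  flagged <- (is.na(profile@cv) & profile@nReplicates < 2L) |
    (!is.na(profile@cv) & profile@cv > cvLimit)
  list(condition = profile@condition, cv = profile@cv,
       nReplicates = profile@nReplicates, flagged = flagged,
       pass = !any(flagged), cvLimit = cvLimit)
}
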