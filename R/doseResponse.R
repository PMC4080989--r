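#' IndexSUM sensitivity statistic
#'
#' Sums `100 - inhibition` (clipped to \[0, 100\]) over the six dilution
#' steps (200% .. 6.25% of the TDC), giving a plate-level sensitivity
#' index in \[0, 600\]: 0 = complete inhibition at every step, 600 = no
#' inhibition at any step, and 300 corresponds to 50% inhibition across
#' the tested range. Values below 300 define an active agent.
#'
#' @param x an [InhibitionProfile-class], or a numeric vector of 6 percent
#'   inhibition values (clipped internally).
#' @param ... unused.
#' @return single numeric index in \[0, 600\].
#' @examples
#' indexSum(rep(100, 6))  # complete inhibition -> 0
#' indexSum(rep(0, 6))    # no inhibition -> 600
#' @export
setMethod("indexSum", "InhibitionProfile", function(x, ...)
  indexSum(inhibition(x, clipped = TRUE)))

#' @rdname indexSum
#' @export
setMethod("indexSum", "numeric", function(x, ...) {
  if (length(x) != 6L)
    stop("IndexSUM is defined over exactly 6 dilution steps; got ",
         length(x))
  if (any(!is.finite(x)))
    stop("non-finite inhibition values")
  sum(100 - pmin(pmax(x, 0), 100))
})

#' Classify an agent as active from its IndexSUM
#'
#' An agent is active iff its IndexSUM is strictly below 300 (at least
#' 50% inhibition on average across the tested concentration range); an
#' index of exactly 300 is inactive.
#'
#' @param indexSum numeric index in \[0, 600\].
#' @return logical, `TRUE` for active.
#' @export
classifyActivity <- function(indexSum) {
  stopifnot(all(indexSum >= 0 & indexSum <= 600))
  indexSum < 300
}

# Core ICF search on ascending-concentration vectors. Scans from the
# lowest to the highest concentration for the first crossing of the
# target effect, interpolating inhibition linearly against
# log2(concentration) between the bracketing steps.
.icfSearch <- function(conc, inh, effect) {
  stopifnot(length(conc) == length(inh), effect > 0, effect < 1)
  if (any(!is.finite(inh)))
    stop("non-finite inhibition values")
  o <- order(conc)
  x <- log2(conc[o])
  y <- pmin(pmax(inh[o], 0), 100)
  target <- 100 * effect
  if (y[1L] >= target)
    return(new("ICFEstimate", concentration = conc[o][1L],
               censored = "below", effect = effect))
  hit <- which(y >= target)
  if (!length(hit))
    return(new("ICFEstimate", concentration = conc[o][length(conc)],
               censored = "above", effect = effect))
  j <- hit[1L]
  frac <- (target - y[j - 1L]) / (y[j] - y[j - 1L])
  new("ICFEstimate",
      concentration = 2^(x[j - 1L] + frac * (x[j] - x[j - 1L])),
      censored = "none", effect = effect)
}

#' Estimate the concentration giving a fractional effect (IC50, IC90, ...)
#'
#' Finds the first crossing of the target effect, scanning from the
#' lowest to the highest tested concentration, by linear interpolation of
#' (clipped) inhibition against log2(concentration) between the
#' bracketing dilution steps — the natural axis for a doubling-dilution
#' design. If the effect is never reached the estimate is censored above
#' the top concentration; if the lowest concentration already meets it,
#' censored below the bottom one.
#'
#' @param x an [InhibitionProfile-class], or a numeric vector of percent
#'   inhibition values (then `conc` must be given).
#' @param effect effect fraction F in (0, 1); 0.5 for IC50, 0.9 for IC90.
#' @param conc concentrations matching `x` when `x` is numeric, uM.
#' @param ... unused.
#' @return An [ICFEstimate-class] object.
#' @examples
#' p <- rep(c(40, 60), each = 3)              # crosses 50% once
#' cc <- 2 / 2^(0:5)                          # 2 .. 0.0625 uM, descending
#' estimateICF(rev(p), effect = 0.5, conc = cc)
#' @export
setMethod("estimateICF", "InhibitionProfile",
  function(x, effect = 0.5, ...)
    .icfSearch(x@concentrations, x@inhibition, effect))

#' @rdname estimateICF
#' @export
setMethod("estimateICF", "numeric",
  function(x, effect = 0.5, conc, ...) .icfSearch(conc, x, effect))

#' @rdname accessors
#' @export
setMethod("isEstimable", "ICFEstimate", function(x) x@censored == "none")

#' @rdname accessors
#' @export
setMethod("concentrations", "ICFEstimate", function(x) x@concentration)

setMethod("show", "ICFEstimate", function(object) {
  lab <- sprintf("IC%g", 100 * object@effect)
  if (object@censored == "none")
    cat(lab, "=", signif(object@concentration, 4), "uM\n")
  else
    cat(lab, if (object@censored == "above") ">" else "<",
        signif(object@concentration, 4), "uM (censored)\n")
})

#' Fit a Hill model to an inhibition profile
#'
#' Least-squares fit of I(c) = Imax * c^h / (EC50^h + c^h) with Imax
#' constrained to \[0, 100\] and h > 0, by Levenberg-Marquardt. Profiles
#' with no usable signal (maximal inhibition below 5%) are returned as
#' degenerate, unconverged fits rather than silently defaulted; so are
#' optimizer failures.
#'
#' @param x an [InhibitionProfile-class], or numeric percent inhibition
#'   (then `conc` is required).
#' @param conc concentrations matching numeric `x`, uM.
#' @param ... unused.
#' @return A [HillFit-class] with a `converged` flag and residual norm.
#' @export
setMethod("fitHill", "InhibitionProfile", function(x, ...)
  fitHill(inhibition(x, clipped = TRUE), conc = x@concentrations))

#' @rdname fitHill
#' @export
setMethod("fitHill", "numeric", function(x, conc, ...) {
  stopifnot(length(x) == length(conc), all(conc > 0))
  if (sum(is.finite(x)) < 4L)
    stop("at least 4 informative steps are required for a Hill fit")
  y <- pmin(pmax(x, 0), 100)
  if (max(y) < 5)
    return(new("HillFit", imax = NA_real_, ec50 = NA_real_,
               slope = NA_real_, converged = FALSE,
               residualNorm = NA_real_))
  startImax <- min(100, max(y))
  startEc50 <- conc[which.min(abs(y - startImax / 2))]
  df <- data.frame(conc = conc, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ imax * conc^h / (ec50^h + conc^h), data = df,
      start = list(imax = startImax, ec50 = startEc50, h = 1),
      lower = c(imax = 0, ec50 = min(conc) * 1e-6, h = 1e-3),
      upper = c(imax = 100, ec50 = max(conc) * 1e6, h = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("HillFit", imax = NA_real_, ec50 = NA_real_,
               slope = NA_real_, converged = FALSE,
               residualNorm = NA_real_))
  cf <- stats::coef(fit)
  new("HillFit", imax = unname(cf["imax"]), ec50 = unname(cf["ec50"]),
      slope = unname(cf["h"]), converged = TRUE,
      residualNorm = sqrt(sum(stats::resid(fit)^2)))
})

setMethod("show", "HillFit", function(object) {
  if (!object@converged) {
    cat("HillFit: degenerate / not converged\n")
  } else {
    cat(sprintf("HillFit: Imax %.2f%%, EC50 %.4g uM, slope %.3f (rss %.3g)\n",
                object@imax, object@ec50, object@slope,
                object@residualNorm^2))
  }
})

#' Full sensitivity analysis of one condition
#'
#' Computes IC50, IC90, the IndexSUM statistic and the activity call for a
#' condition's inhibition profile. IC values use log-linear interpolation
#' by default; `method = "hill"` instead inverts a fitted Hill curve
#' (censored when the fitted Imax does not reach the effect or the fit is
#' degenerate).
#'
#' @param profile an [InhibitionProfile-class].
#' @param method `"interpolation"` (default) or `"hill"`.
#' @return A [SensitivityResult-class] object.
#' @export
drugSensitivity <- function(profile, method = c("interpolation", "hill")) {
  method <- match.arg(method)
  stopifnot(is(profile, "InhibitionProfile"))
  if (method == "interpolation") {
    e50 <- estimateICF(profile, 0.5)
    e90 <- estimateICF(profile, 0.9)
  } else {
    fit <- fitHill(profile)
    e50 <- .icfFromHill(fit, profile, 0.5)
    e90 <- .icfFromHill(fit, profile, 0.9)
  }
  idx <- indexSum(profile)
  new("SensitivityResult", condition = profile@condition, ic50 = e50,
      ic90 = e90, indexSum = idx, active = idx < 300)
}

.icfFromHill <- function(fit, profile, effect) {
  top <- max(profile@concentrations)
  bottom <- min(profile@concentrations)
  if (!fit@converged || fit@imax <= 100 * effect)
    return(new("ICFEstimate", concentration = top, censored = "above",
               effect = effect))
  conc <- hillInverse(100 * effect, fit@imax, fit@ec50, fit@slope)
  if (conc > top)
    new("ICFEstimate", concentration = top, censored = "above",
        effect = effect)
  else if (conc < bottom)
    new("ICFEstimate", concentration = bottom, censored = "below",
        effect = effect)
  else
    new("ICFEstimate", concentration = conc, censored = "none",
        effect = effect)
}

#' @rdname accessors
#' @export
setMethod("ic50", "SensitivityResult", function(x) x@ic50)

#' @rdname accessors
#' @export
setMethod("ic90", "SensitivityResult", function(x) x@ic90)

#' @rdname accessors
#' @export
setMethod("indexSum", "SensitivityResult", function(x, ...) x@indexSum)

#' @rdname accessors
#' @export
setMethod("isActive", "SensitivityResult", function(x) x@active)

#' @rdname accessors
#' @export
setMethod("condition", "SensitivityResult", function(x) x@condition)

setMethod("show", "SensitivityResult", function(object) {
  fmt <- function(e) {
    if (e@censored == "none") sprintf("%.4g uM", e@concentration)
    else sprintf("%s%.4g uM", if (e@censored == "above") ">" else "<",
                 e@concentration)
  }
  cat("SensitivityResult for", object@condition, "\n")
  cat("  IC50:", fmt(object@ic50), " IC90:", fmt(object@ic90), "\n")
  cat(sprintf("  IndexSUM: %.1f (%s)\n", object@indexSum,
              if (object@active) "active" else "inactive"))
})
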