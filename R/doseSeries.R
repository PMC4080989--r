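#' Construct a doubling-dilution dose series
#'
#' Builds the six-step series used on ATP-TCA plates from the test drug
#' concentration (TDC): concentrations `2*tdc, tdc, tdc/2, tdc/4, tdc/8,
#' tdc/16`, i.e. the 200% down to 6.25% steps. Alternatively an explicit
#' vector of six concentrations can be supplied and is validated against
#' the doubling-dilution invariants.
#'
#' @param drugId single character drug label.
#' @param tdc test drug concentration in uM; the 100% step. Ignored when
#'   `concentrations` is given, in which case `tdc` is taken as half the
#'   top step.
#' @param concentrations optional numeric(6), descending doubling
#'   dilutions in uM.
#' @return A [DoseSeries-class] object.
#' @examples
#' gefitinib <- DoseSeries("gefitinib", tdc = 1)   # 0.0625 - 2 uM
#' concentrations(gefitinib)
#' @export
DoseSeries <- function(drugId, tdc, concentrations = NULL) {
  if (is.null(concentrations)) {
    stopifnot(is.numeric(tdc), length(tdc) == 1L, tdc > 0)
    concentrations <- 2 * tdc / 2^(0:5)
  } else {
    tdc <- concentrations[1L] / 2
  }
  new("DoseSeries", drugId = as.character(drugId),
      concentrations = as.numeric(concentrations), tdc = as.numeric(tdc))
}

#' @rdname accessors
#' @param x an atpTCA object.
#' @export
setMethod("concentrations", "DoseSeries", function(x) x@concentrations)

#' @rdname accessors
#' @export
setMethod("drugId", "DoseSeries", function(x) x@drugId)

#' @rdname accessors
#' @export
setMethod("tdc", "DoseSeries", function(x) x@tdc)

setMethod("show", "DoseSeries", function(object) {
  cat("DoseSeries for", object@drugId, "\n")
  cat("  TDC:", object@tdc, "uM; steps (200%..6.25%):",
      paste(signif(object@concentrations, 4), collapse = ", "), "uM\n")
})

#' Dilution-step percentage labels
#'
#' The conventional labels of the six steps relative to the TDC.
#'
#' @return character(6): `"200%" "100%" "50%" "25%" "12.5%" "6.25%"`.
#' @export
dilutionLabels <- function() c("200%", "100%", "50%", "25%", "12.5%", "6.25%")
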