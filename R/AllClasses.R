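#' @import methods
NULL

#' DoseSeries: a six-step doubling-dilution series for one drug
#'
#' Represents the concentration ladder used on an ATP-TCA plate: six
#' concentrations in descending order, each step half of the one before,
#' spanning 200% down to 6.25% of the test drug concentration (TDC). The
#' top step is therefore `2 * tdc` and the bottom step `tdc / 16`.
#'
#' @slot drugId single character label for the drug.
#' @slot concentrations numeric(6), descending, in uM.
#' @slot tdc test drug concentration in uM (the 100% step).
#'
#' @seealso [DoseSeries()] for the constructor.
#' @export
setClass("DoseSeries",
  representation(drugId = "character", concentrations = "numeric",
                 tdc = "numeric"))

setValidity("DoseSeries", function(object) {
  msg <- character()
  if (length(object@drugId) != 1L || is.na(object@drugId))
    msg <- c(msg, "drugId must be a single non-NA label")
  cc <- object@concentrations
  if (length(cc) != 6L)
    msg <- c(msg, "a dose series has exactly 6 concentrations")
  else {
    if (any(!is.finite(cc)) || any(cc <= 0))
      msg <- c(msg, "concentrations must be finite and positive")
    else {
      if (any(diff(cc) >= 0))
        msg <- c(msg, "concentrations must be strictly decreasing")
      ratios <- cc[-6L] / cc[-1L]
      if (any(abs(ratios - 2) > 1e-9 * 2))
        msg <- c(msg, "successive steps must be doubling dilutions (ratio 2)")
    }
    if (length(object@tdc) != 1L || !is.finite(object@tdc) || object@tdc <= 0)
      msg <- c(msg, "tdc must be a single positive number")
    else if (abs(cc[1L] - 2 * object@tdc) > 1e-9 * 2 * object@tdc)
      msg <- c(msg, "top concentration must equal 2 * tdc (the 200% step)")
  }
  if (length(msg)) msg else TRUE
})

#' StandardCurve: ATP calibration line for a plate read
#'
#' Pairs of known ATP amounts and observed luminescence counts, with the
#' ordinary-least-squares line fitted through them (free intercept). Used
#' to map raw counts back to ATP amounts for QC; the inhibition
#' calculation itself works on raw counts with plate controls.
#'
#' @slot atp numeric, known ATP amounts (e.g. pmol).
#' @slot counts numeric, luminescence counts at those amounts.
#' @slot slope,intercept fitted line coefficients; slope must be positive.
#'
#' @seealso [standardCurve()], [calibrateAtp()]
#' @export
setClass("StandardCurve",
  representation(atp = "numeric", counts = "numeric",
                 slope = "numeric", intercept = "numeric"))

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (length(object@atp) != length(object@counts))
    msg <- c(msg, "atp and counts must have equal length")
  if (length(unique(object@atp)) < 2L)
    msg <- c(msg, "at least 2 distinct ATP amounts are required")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "fitted slope must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' InhibitionProfile: per-condition inhibition across the six dilutions
#'
#' Mean percentage tumour growth inhibition and replicate variability for
#' one condition (a drug or a combination) at each of the six dilution
#' steps. Step 1 is the 200% (top) concentration, step 6 the 6.25%
#' (bottom) one. Inhibition is stored unclipped; the clipped companion in
#' [0, 100] is available through [inhibition()] with `clipped = TRUE` and
#' is what [indexSum()] and [estimateICF()] consume.
#'
#' @slot condition condition label.
#' @slot concentrations numeric(6), descending, in uM. For a combination
#'   profile this is the drug-A component concentration at each step.
#' @slot inhibition numeric(6), raw (unclipped) mean percent inhibition.
#' @slot cv numeric(6), replicate coefficient of variance in percent.
#' @slot nReplicates integer(6), replicates averaged at each step.
#' @slot series the [DoseSeries-class] or [CombinationDesign-class]
#'   the profile was measured on.
#'
#' @seealso [summarizeCondition()], [qcProfile()]
#' @export
setClass("InhibitionProfile",
  representation(condition = "character", concentrations = "numeric",
                 inhibition = "numeric", cv = "numeric",
                 nReplicates = "integer", series = "ANY"))

setValidity("InhibitionProfile", function(object) {
  msg <- character()
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  if (length(object@concentrations) != 6L || length(object@inhibition) != 6L ||
      length(object@cv) != 6L || length(object@nReplicates) != 6L)
    msg <- c(msg, "a profile has exactly 6 dilution steps")
  else {
    if (any(!is.finite(object@concentrations)) ||
        any(object@concentrations <= 0) || any(diff(object@concentrations) >= 0))
      msg <- c(msg, "concentrations must be positive and strictly decreasing")
    if (any(object@cv < 0, na.rm = TRUE))
      msg <- c(msg, "replicate CV must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' ICFEstimate: an IC\\[F\\] concentration, possibly censored
#'
#' Result of locating the concentration giving a fractional effect F
#' (e.g. F = 0.5 for IC50). When the profile never reaches the effect the
#' estimate is censored `"above"` and `concentration` holds the top tested
#' concentration; when the lowest tested concentration already exceeds the
#' effect it is censored `"below"` and `concentration` holds the bottom
#' one.
#'
#' @slot concentration the estimate, or the bounding concentration when
#'   censored, in uM.
#' @slot censored one of `"none"`, `"above"`, `"below"`.
#' @slot effect the effect fraction F in (0, 1).
#'
#' @seealso [estimateICF()], [isEstimable()]
#' @export
setClass("ICFEstimate",
  representation(concentration = "numeric", censored = "character",
                 effect = "numeric"))

setValidity("ICFEstimate", function(object) {
  msg <- character()
  if (!object@censored %in% c("none", "above", "below"))
    msg <- c(msg, "censored must be one of none/above/below")
  if (length(object@effect) != 1L || object@effect <= 0 || object@effect >= 1)
    msg <- c(msg, "effect must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' HillFit: least-squares Hill model fit to an inhibition profile
#'
#' Parameters of the Hill model I(c) = Imax * c^h / (EC50^h + c^h) fitted
#' to the six-step profile, with a convergence flag and the residual norm.
#' Degenerate (flat, signal-free) profiles are returned unconverged rather
#' than silently defaulted.
#'
#' @slot imax maximal inhibition in percent, in \\[0, 100\\].
#' @slot ec50 half-maximal concentration in uM.
#' @slot slope Hill slope h, positive.
#' @slot converged logical convergence flag.
#' @slot residualNorm root-sum-of-squares of the fit residuals.
#'
#' @seealso [fitHill()]
#' @export
setClass("HillFit",
  representation(imax = "numeric", ec50 = "numeric", slope = "numeric",
                 converged = "logical", residualNorm = "numeric"))

#' SensitivityResult: IC50, IC90, IndexSUM and activity for one condition
#'
#' @slot condition condition label.
#' @slot ic50,ic90 [ICFEstimate-class] objects (possibly censored).
#' @slot indexSum IndexSUM sensitivity index in \\[0, 600\\]
#'   (0 = complete inhibition, 600 = no inhibition).
#' @slot active logical; `TRUE` iff `indexSum < 300` (strict).
#'
#' @seealso [drugSensitivity()], [classifyActivity()]
#' @export
setClass("SensitivityResult",
  representation(condition = "character", ic50 = "ICFEstimate",
                 ic90 = "ICFEstimate", indexSum = "numeric",
                 active = "logical"))

setValidity("SensitivityResult", function(object) {
  msg <- character()
  if (!is.finite(object@indexSum) || object@indexSum < 0 ||
      object@indexSum > 600)
    msg <- c(msg, "indexSum must lie in [0, 600]")
  else if (!identical(object@active, object@indexSum < 300))
    msg <- c(msg, "active flag must equal indexSum < 300")
  if (object@ic50@censored == "none" && object@ic90@censored == "none" &&
      object@ic50@concentration > object@ic90@concentration * (1 + 1e-9))
    msg <- c(msg, "estimated ic50 must not exceed estimated ic90")
  if (length(msg)) msg else TRUE
})

#' CombinationDesign: a fixed-ratio ray pairing two dose series
#'
#' Step k of the combination adds step k of drug A's series and step k of
#' drug B's series simultaneously, so the concentration ratio c_A / c_B is
#' constant across the six steps (a fixed-ratio ray).
#'
#' @slot drugA,drugB the component [DoseSeries-class] objects.
#'
#' @seealso [CombinationDesign()], [comboComponentsAtEffect()]
#' @export
setClass("CombinationDesign",
  representation(drugA = "DoseSeries", drugB = "DoseSeries"))

setValidity("CombinationDesign", function(object) {
  ratio <- object@drugA@concentrations / object@drugB@concentrations
  if (any(abs(ratio - ratio[1L]) > 1e-9 * ratio[1L]))
    "component ratio c_A/c_B must be constant across the 6 steps"
  else TRUE
})

#' CombinationResult: a Chou-Talalay combination index at one effect level
#'
#' @slot drugA,drugB component drug labels.
#' @slot effect effect fraction F (0.5 or 0.9).
#' @slot ci the combination index, or `NA` when not estimable.
#' @slot alpha mutual-exclusivity parameter used (0 or 1).
#' @slot classification `"synergy"`, `"additive"`, `"antagonism"`, or
#'   `"not estimable"`.
#' @slot doseAcombo,doseBcombo component doses in the combination at
#'   effect F, uM.
#' @slot doseAsingle,doseBsingle single-agent doses at effect F, uM.
#' @slot estimable logical; `FALSE` when any required dose was censored.
#'
#' @seealso [ciReport()], [combinationIndex()], [classifyCI()]
#' @export
setClass("CombinationResult",
  representation(drugA = "character", drugB = "character", effect = "numeric",
                 ci = "numeric", alpha = "numeric",
                 classification = "character",
                 doseAcombo = "numeric", doseBcombo = "numeric",
                 doseAsingle = "numeric", doseBsingle = "numeric",
                 estimable = "logical"))

setValidity("CombinationResult", function(object) {
  msg <- character()
  if (!object@alpha %in% c(0, 1))
    msg <- c(msg, "alpha must be 0 or 1")
  if (object@estimable && (!is.finite(object@ci) || object@ci <= 0))
    msg <- c(msg, "an estimable CI must be positive")
  if (length(msg)) msg else TRUE
})

#' DrugResponseModel: ground-truth Hill response of one line to one drug
#'
#' @slot cellLine,drugId labels.
#' @slot imax maximal inhibition in percent, at most 100.
#' @slot ec50 half-maximal concentration, uM, positive.
#' @slot hillSlope Hill slope, positive.
#'
#' @seealso [DrugResponseModel()], [SyntheticScenario-class]
#' @export
setClass("DrugResponseModel",
  representation(cellLine = "character", drugId = "character",
                 imax = "numeric", ec50 = "numeric", hillSlope = "numeric"))

setValidity("DrugResponseModel", function(object) {
  msg <- character()
  if (!is.finite(object@imax) || object@imax < 0 || object@imax > 100)
    msg <- c(msg, "imax must lie in [0, 100]")
  if (!is.finite(object@ec50) || object@ec50 <= 0)
    msg <- c(msg, "ec50 must be positive")
  if (!is.finite(object@hillSlope) || object@hillSlope <= 0)
    msg <- c(msg, "hillSlope must be positive")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: ground truth for plate simulation
#'
#' Bundles everything needed to simulate ATP-TCA plates with known
#' dose-response structure: a panel of Hill models per cell line x drug,
#' the dose series for each drug, fixed-ratio combination definitions with
#' a Loewe potency-shift factor rho (1 = additive ground truth, rho < 1 =
#' synergistic), the count emission scale (MO and MI well means), the
#' replicate noise CV, the replicate count, and the seed.
#'
#' @slot models named list of [DrugResponseModel-class], keyed
#'   `"<cellLine>:<drugId>"`.
#' @slot series named list of [DoseSeries-class], one per drug.
#' @slot combinations named list, keyed by combination condition label,
#'   each element `list(drugA =, drugB =, rho =)`.
#' @slot noiseCV replicate coefficient of variance in percent.
#' @slot moMean,miMean mean counts of medium-only and maximum-inhibitor
#'   control wells; `moMean > miMean >= 0`.
#' @slot replicates replicate wells per condition and step.
#' @slot seed integer seed recorded in all outputs.
#'
#' @seealso [SyntheticScenario()], [simulatePlate()],
#'   [scenarioIsogenicPanel()]
#' @export
setClass("SyntheticScenario",
  representation(models = "list", series = "list", combinations = "list",
                 noiseCV = "numeric", moMean = "numeric", miMean = "numeric",
                 replicates = "integer", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (!(object@moMean > object@miMean && object@miMean >= 0))
    msg <- c(msg, "moMean > miMean >= 0 is required")
  if (object@noiseCV < 0)
    msg <- c(msg, "noiseCV must be non-negative")
  if (object@replicates < 1L)
    msg <- c(msg, "at least one replicate is required")
  drugs <- names(object@series)
  for (m in object@models)
    if (!m@drugId %in% drugs)
      msg <- c(msg, sprintf("model drug '%s' has no dose series", m@drugId))
  for (nm in names(object@combinations)) {
    cmb <- object@combinations[[nm]]
    if (!all(c(cmb$drugA, cmb$drugB) %in% drugs))
      msg <- c(msg, sprintf("combination '%s' names an unknown drug", nm))
    if (!is.numeric(cmb$rho) || cmb$rho <= 0)
      msg <- c(msg, sprintf("combination '%s' needs a positive rho", nm))
  }
  if (length(msg)) msg else TRUE
})
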