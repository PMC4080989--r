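#' Construct a fixed-ratio combination design
#'
#' Pairs two drugs' own dose series step-for-step: at dilution step k the
#' combination adds step k of drug A's series and step k of drug B's
#' series simultaneously, so the ratio c_A/c_B is constant across the six
#' steps.
#'
#' @param drugA,drugB [DoseSeries-class] objects for the two components.
#' @return A [CombinationDesign-class] object.
#' @examples
#' d <- CombinationDesign(DoseSeries("gefitinib", 1),
#'                        DoseSeries("ZSTK474", 1.1))
#' comboRatio(d)  # c_A / c_B, constant across steps
#' @export
CombinationDesign <- function(drugA, drugB) {
  stopifnot(is(drugA, "DoseSeries"), is(drugB, "DoseSeries"))
  new("CombinationDesign", drugA = drugA, drugB = drugB)
}

#' Component concentration ratio of a combination design
#'
#' @param design a [CombinationDesign-class].
#' @return single numeric, c_A / c_B.
#' @export
comboRatio <- function(design) {
  stopifnot(is(design, "CombinationDesign"))
  design@drugA@tdc / design@drugB@tdc
}

#' Combination condition label
#'
#' @param design a [CombinationDesign-class].
#' @return character, `"<drugA>+<drugB>"`.
#' @export
comboLabel <- function(design)
  paste0(design@drugA@drugId, "+", design@drugB@drugId)

setMethod("show", "CombinationDesign", function(object) {
  cat("CombinationDesign:", comboLabel(object),
      sprintf("(fixed ratio %.4g)\n", comboRatio(object)))
})

#' Component doses of a combination at a fixed effect
#'
#' Locates the combination mixture's crossing of effect F along the
#' fixed-ratio ray (via [estimateICF()] on the combination profile, whose
#' concentration axis is the drug-A component), then splits the crossing
#' into its A and B components using the design's constant ratio. A
#' censored crossing yields a non-estimable result (no dose pair).
#'
#' @param comboProfile [InhibitionProfile-class] measured along the
#'   design's ray.
#' @param design the [CombinationDesign-class].
#' @param effect effect fraction F in (0, 1).
#' @return list with `doseA`, `doseB` (uM; `NA` when censored) and
#'   logical `estimable`.
#' @export
comboComponentsAtEffect <- function(comboProfile, design, effect) {
  stopifnot(is(comboProfile, "InhibitionProfile"),
            is(design, "CombinationDesign"))
  est <- estimateICF(comboProfile, effect)
  if (!isEstimable(est))
    return(list(doseA = NA_real_, doseB = NA_real_, estimable = FALSE))
  dA <- est@concentration
  list(doseA = dA, doseB = dA / comboRatio(design), estimable = TRUE)
}

#' Chou-Talalay combination index
#'
#' For a fixed effect F, with d_A, d_B the component doses of the
#' combination giving effect F and D_A, D_B the single-agent doses giving
#' the same effect:
#' \deqn{CI = \frac{d_A}{D_A} + \frac{d_B}{D_B} +
#'   \alpha \frac{d_A d_B}{D_A D_B}}
#' `alpha = 0` treats the drugs as mutually exclusive (two-term Loewe
#' sum); `alpha = 1` as mutually non-exclusive (product term added).
#'
#' @param doseAcombo,doseBcombo component doses in the combination at
#'   effect F, uM.
#' @param doseAsingle,doseBsingle single-agent doses at effect F, uM.
#' @param alpha 0 or 1.
#' @return single numeric CI, or `NA` if any dose is non-positive or
#'   missing (e.g. a single agent that never reached effect F).
#' @examples
#' combinationIndex(0.25, 0.25, 1, 1, alpha = 0)  # quarter doses -> 0.5
#' @export
combinationIndex <- function(doseAcombo, doseBcombo, doseAsingle,
                             doseBsingle, alpha = 0) {
  stopifnot(alpha %in% c(0, 1))
  d <- c(doseAcombo, doseBcombo, doseAsingle, doseBsingle)
  if (any(is.na(d)) || any(d <= 0))
    return(NA_real_)
  doseAcombo / doseAsingle + doseBcombo / doseBsingle +
    alpha * (doseAcombo * doseBcombo) / (doseAsingle * doseBsingle)
}

#' Classify a combination index
#'
#' Synergy for CI < 0.8, additivity for 0.8 <= CI <= 1.2 (boundary values
#' fall in the additive band), antagonism for CI > 1.2.
#'
#' @param ci positive combination index (vectorized); `NA` allowed.
#' @return character vector: `"synergy"`, `"additive"`, `"antagonism"` or
#'   `"not estimable"` for `NA`.
#' @examples
#' classifyCI(c(0.23, 1.0, 1.33))
#' @export
classifyCI <- function(ci) {
  stopifnot(all(ci > 0, na.rm = TRUE))
  out <- ifelse(is.na(ci), "not estimable",
                ifelse(ci < 0.8, "synergy",
                       ifelse(ci <= 1.2, "additive", "antagonism")))
  as.character(out)
}

#' Combination-index report at 50% and 90% effect
#'
#' Computes the Chou-Talalay CI at F = 0.5 (from the IC50s) and F = 0.9
#' (from the IC90s) for one combination, classifies each, and records all
#' component doses for audit. Censoring propagates per effect level
#' independently: a CI90 may be estimable when the CI50 is not, and any
#' censored dose yields a non-estimable CI rather than a substituted
#' bound.
#'
#' @param singleA,singleB [SensitivityResult-class] objects for the two
#'   single agents (same cell line / plate batch as the combination).
#' @param combo [SensitivityResult-class] for the combination, analyzed
#'   along the design's ray (drug-A component concentration axis).
#' @param design the [CombinationDesign-class].
#' @param alpha mutual-exclusivity parameter, 0 (default) or 1.
#' @return list with elements `ci50` and `ci90`, each a
#'   [CombinationResult-class].
#' @export
ciReport <- function(singleA, singleB, combo, design, alpha = 0) {
  stopifnot(is(singleA, "SensitivityResult"),
            is(singleB, "SensitivityResult"),
            is(combo, "SensitivityResult"),
            is(design, "CombinationDesign"), alpha %in% c(0, 1))
  one <- function(effect, estA, estB, estC) {
    ratio <- comboRatio(design)
    ok <- isEstimable(estA) && isEstimable(estB) && isEstimable(estC)
    dAc <- if (isEstimable(estC)) estC@concentration else NA_real_
    dBc <- dAc / ratio
    dAs <- if (isEstimable(estA)) estA@concentration else NA_real_
    dBs <- if (isEstimable(estB)) estB@concentration else NA_real_
    ci <- if (ok) combinationIndex(dAc, dBc, dAs, dBs, alpha) else NA_real_
    new("CombinationResult", drugA = design@drugA@drugId,
        drugB = design@drugB@drugId, effect = effect, ci = ci,
        alpha = alpha, classification = classifyCI(ci),
        doseAcombo = dAc, doseBcombo = dBc, doseAsingle = dAs,
        doseBsingle = dBs, estimable = ok && !is.na(ci))
  }
  list(ci50 = one(0.5, ic50(singleA), ic50(singleB), ic50(combo)),
       ci90 = one(0.9, ic90(singleA), ic90(singleB), ic90(combo)))
}

#' @rdname accessors
#' @export
setMethod("ciValue", "CombinationResult", function(x) x@ci)

#' @rdname accessors
#' @export
setMethod("classification", "CombinationResult", function(x)
  x@classification)

#' @rdname accessors
#' @export
setMethod("isEstimable", "CombinationResult", function(x) x@estimable)

setMethod("show", "CombinationResult", function(object) {
  cat(sprintf("CombinationResult %s + %s at F = %g (alpha = %g)\n",
              object@drugA, object@drugB, object@effect, object@alpha))
  if (object@estimable)
    cat(sprintf("  CI = %.3f (%s)\n", object@ci, object@classification))
  else
    cat("  CI not estimable\n")
})
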