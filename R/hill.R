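#' Hill inhibition model
#'
#' Percent inhibition at concentration `conc` under the Hill model
#' I(c) = imax * c^h / (ec50^h + c^h).
#'
#' @param conc concentration(s), uM; non-negative.
#' @param imax maximal inhibition, percent.
#' @param ec50 half-maximal concentration, uM.
#' @param hillSlope Hill slope h, positive.
#' @return numeric percent inhibition, same length as `conc`.
#' @export
hillInhibition <- function(conc, imax, ec50, hillSlope = 1) {
  stopifnot(ec50 > 0, hillSlope > 0, all(conc >= 0))
  imax * conc^hillSlope / (ec50^hillSlope + conc^hillSlope)
}

#' Inverse Hill model
#'
#' Concentration producing a given percent inhibition under the Hill
#' model: D(I) = ec50 * (I / (imax - I))^(1/h). `NA` when the effect is at
#' or above `imax` (unreachable).
#'
#' @param effectPct target percent inhibition.
#' @inheritParams hillInhibition
#' @return numeric concentration, uM; `NA` where unreachable.
#' @export
hillInverse <- function(effectPct, imax, ec50, hillSlope = 1) {
  stopifnot(ec50 > 0, hillSlope > 0)
  out <- rep(NA_real_, length(effectPct))
  ok <- effectPct > 0 & effectPct < imax
  out[ok] <- ec50 * (effectPct[ok] / (imax - effectPct[ok]))^(1 / hillSlope)
  out[effectPct <= 0] <- 0
  out
}

#' Mixture inhibition under Loewe additivity with a potency shift
#'
#' Solves the Loewe equation for the effect I of a simultaneous dose
#' (dA, dB) of two Hill-response drugs:
#' \deqn{\frac{d_A}{D_A(I)} + \frac{d_B}{D_B(I)} = \rho}
#' where `D_X(I)` is each drug's single-agent dose giving effect I. With
#' `rho = 1` this is exact Loewe additivity (the no-interaction null);
#' `rho < 1` shifts mixture potency upward, an explicitly synergistic
#' ground truth (for drugs of equal shape the downstream combination
#' index equals `rho`).
#'
#' @param doseA,doseB component doses, uM, non-negative.
#' @param modelA,modelB [DrugResponseModel-class] objects for the two
#'   drugs.
#' @param rho potency-shift factor, positive; 1 = additive.
#' @return percent inhibition of the mixture; `NA` with a warning if the
#'   solve does not bracket a root (the step should then be treated as
#'   invalid, never imputed). With unequal maximal inhibitions the solve
#'   extends past the weaker drug's ceiling, where that drug's
#'   dose-equivalent contribution is zero (generalized Loewe treatment
#'   of partial agonists).
#' @export
loeweInhibition <- function(doseA, doseB, modelA, modelB, rho = 1) {
  stopifnot(is(modelA, "DrugResponseModel"), is(modelB, "DrugResponseModel"),
            rho > 0, doseA >= 0, doseB >= 0)
  if (doseA == 0 && doseB == 0) return(0)
  if (doseA == 0)
    return(hillInhibition(doseB / rho, modelB@imax, modelB@ec50,
                          modelB@hillSlope))
  if (doseB == 0)
    return(hillInhibition(doseA / rho, modelA@imax, modelA@ec50,
                          modelA@hillSlope))
  upper <- max(modelA@imax, modelB@imax)
  if (upper <= 0) return(0)
  # Beyond a partial agonist's own ceiling its equipotent dose is
  # infinite, so its dose-equivalent contribution vanishes; this extends
  # the Loewe solve continuously up to the stronger drug's maximum.
  term <- function(dose, m, i) {
    if (i >= m@imax) return(0)
    dose / hillInverse(i, m@imax, m@ec50, m@hillSlope)
  }
  f <- function(i)
    term(doseA, modelA, i) + term(doseB, modelB, i) - rho
  lo <- upper * 1e-12
  hi <- upper * (1 - 1e-12)
  if (f(hi) > 0) {
    warning("Loewe solve did not converge: mixture effect exceeds the ",
            "joint maximal inhibition; step marked invalid")
    return(NA_real_)
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
}
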