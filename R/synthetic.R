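#' Construct a ground-truth drug-response model
#'
#' @param cellLine,drugId labels.
#' @param imax maximal inhibition, percent, in \[0, 100\].
#' @param ec50 half-maximal concentration, uM.
#' @param hillSlope Hill slope, positive (default 1).
#' @return A [DrugResponseModel-class] object.
#' @export
DrugResponseModel <- function(cellLine, drugId, imax, ec50, hillSlope = 1) {
  new("DrugResponseModel", cellLine = as.character(cellLine),
      drugId = as.character(drugId), imax = as.numeric(imax),
      ec50 = as.numeric(ec50), hillSlope = as.numeric(hillSlope))
}

setMethod("show", "DrugResponseModel", function(object) {
  cat(sprintf("DrugResponseModel %s x %s: Imax %.1f%%, EC50 %.4g uM, h %.2f\n",
              object@cellLine, object@drugId, object@imax, object@ec50,
              object@hillSlope))
})

#' Construct a synthetic plate scenario
#'
#' @param models list of [DrugResponseModel-class] objects (one per cell
#'   line x drug).
#' @param series named list of [DoseSeries-class], one per drug.
#' @param combinations named list keyed by combination label, each
#'   `list(drugA =, drugB =, rho =)`; `rho = 1` is Loewe-additive ground
#'   truth, `rho < 1` synergistic.
#' @param noiseCV replicate coefficient of variance, percent (default 8,
#'   below the assay's typical sub-10% replicate variability).
#' @param moMean,miMean mean counts of MO and MI control wells.
#' @param replicates replicate wells per condition and step (default 3).
#' @param seed integer seed recorded in all outputs.
#' @return A [SyntheticScenario-class] object.
#' @export
SyntheticScenario <- function(models, series, combinations = list(),
                              noiseCV = 8, moMean = 50000, miMean = 500,
                              replicates = 3L, seed = 1L) {
  names(models) <- vapply(models, function(m)
    paste0(m@cellLine, ":", m@drugId), character(1))
  if (is.null(names(series)))
    names(series) <- vapply(series, drugId, character(1))
  new("SyntheticScenario", models = models, series = series,
      combinations = combinations, noiseCV = as.numeric(noiseCV),
      moMean = as.numeric(moMean), miMean = as.numeric(miMean),
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Cell lines and model lookup in a scenario
#'
#' @param scenario a [SyntheticScenario-class].
#' @return `scenarioCellLines`: character vector of panel cell lines.
#' @export
scenarioCellLines <- function(scenario)
  unique(vapply(scenario@models, function(m) m@cellLine, character(1)))

#' @rdname scenarioCellLines
#' @param cellLine,drugId labels identifying the model.
#' @return `scenarioModel`: the matching [DrugResponseModel-class].
#' @export
scenarioModel <- function(scenario, cellLine, drugId) {
  key <- paste0(cellLine, ":", drugId)
  m <- scenario@models[[key]]
  if (is.null(m))
    stop("no response model for ", key)
  m
}

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", length(scenarioCellLines(object)),
      "cell line(s) x", length(object@series), "drug(s),",
      length(object@combinations), "combination(s)\n")
  cat(sprintf("  noise CV %g%%, MO %g, MI %g counts, %d replicates, seed %d\n",
              object@noiseCV, object@moMean, object@miMean,
              object@replicates, object@seed))
})

# Expected mean inhibition for one condition of a scenario at the six
# dilution steps (descending concentration).
.expectedInhibition <- function(scenario, cellLine, conditionLabel) {
  if (conditionLabel %in% names(scenario@series)) {
    m <- scenarioModel(scenario, cellLine, conditionLabel)
    cc <- scenario@series[[conditionLabel]]@concentrations
    return(hillInhibition(cc, m@imax, m@ec50, m@hillSlope))
  }
  cmb <- scenario@combinations[[conditionLabel]]
  if (is.null(cmb))
    stop("condition '", conditionLabel, "' is neither a drug nor a ",
         "combination of the scenario")
  mA <- scenarioModel(scenario, cellLine, cmb$drugA)
  mB <- scenarioModel(scenario, cellLine, cmb$drugB)
  ccA <- scenario@series[[cmb$drugA]]@concentrations
  ccB <- scenario@series[[cmb$drugB]]@concentrations
  vapply(1:6, function(k)
    loeweInhibition(ccA[k], ccB[k], mA, mB, rho = cmb$rho), numeric(1))
}

# Draw noisy counts: normal with sd = CV * mean, negatives set to 0.
.emitCounts <- function(n, mu, cvPct) {
  if (cvPct == 0) return(rep(mu, n))
  pmax(stats::rnorm(n, mean = mu, sd = cvPct / 100 * mu), 0)
}

#' Simulate one ATP-TCA plate
#'
#' Emits a per-well table for up to four conditions (drugs or
#' combinations) of one cell line. Expected counts follow
#' `MI + (MO - MI) * (1 - I(c)/100)` with I from the scenario's Hill
#' models (mixtures by the Loewe solve with the combination's rho);
#' replicate counts are drawn from a normal law with the scenario's CV,
#' truncated at zero. Conditions occupy three replicate columns each with
#' dilution steps down rows A-F (step 1 = 200% in row A); the control row
#' H holds six MO wells (columns 1-6) and six MI wells (columns 7-12).
#' Fully reproducible from the seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param cellLine panel cell line to simulate.
#' @param conditions character vector (max 4) of drug ids and/or
#'   combination labels; defaults to all drugs of the scenario (up to 4).
#' @param plateId plate label; defaults to `"<cellLine>_p1"`.
#' @param seed integer seed for this plate; defaults to the scenario
#'   seed.
#' @return A well data.frame with columns `plate_id`, `well`,
#'   `condition`, `dilution_step`, `replicate`, `counts`.
#' @export
simulatePlate <- function(scenario, cellLine, conditions = NULL,
                          plateId = paste0(cellLine, "_p1"),
                          seed = scenario@seed) {
  stopifnot(is(scenario, "SyntheticScenario"))
  validObject(scenario)
  if (is.null(conditions))
    conditions <- utils::head(names(scenario@series), 4L)
  if (length(conditions) > 4L)
    stop("a plate holds at most 4 drugs or combinations")
  if (scenario@replicates > 3L)
    stop("the standard plate layout supports at most 3 replicate columns")
  set.seed(seed)
  rows <- LETTERS[1:6]
  out <- vector("list", length(conditions) + 2L)
  for (ci in seq_along(conditions)) {
    inh <- .expectedInhibition(scenario, cellLine, conditions[ci])
    if (any(is.na(inh)))
      stop("invalid (non-convergent) expected inhibition for condition '",
           conditions[ci], "'")
    mu <- scenario@miMean +
      (scenario@moMean - scenario@miMean) * (1 - inh / 100)
    cols <- 3L * (ci - 1L) + seq_len(scenario@replicates)
    recs <- expand.grid(replicate = seq_len(scenario@replicates),
                        dilution_step = 1:6)
    counts <- unlist(lapply(1:6, function(k)
      .emitCounts(scenario@replicates, mu[k], scenario@noiseCV)))
    out[[ci]] <- data.frame(
      plate_id = plateId,
      well = paste0(rows[recs$dilution_step], cols[recs$replicate]),
      condition = conditions[ci],
      dilution_step = recs$dilution_step,
      replicate = recs$replicate,
      counts = counts)
  }
  out[[length(conditions) + 1L]] <- data.frame(
    plate_id = plateId, well = paste0("H", 1:6), condition = "MO",
    dilution_step = NA_integer_, replicate = 1:6,
    counts = .emitCounts(6L, scenario@moMean, scenario@noiseCV))
  out[[length(conditions) + 2L]] <- data.frame(
    plate_id = plateId, well = paste0("H", 7:12), condition = "MI",
    dilution_step = NA_integer_, replicate = 1:6,
    counts = .emitCounts(6L, scenario@miMean, scenario@noiseCV))
  wells <- do.call(rbind, out)
  rownames(wells) <- NULL
  validateWellTable(wells)
  wells
}

#' Simulate a single fixed-ratio combination plate
#'
#' Convenience wrapper around [simulatePlate()] for one combination
#' condition: the mixture inhibition at each step is obtained by solving
#' the Loewe equation `d_A/D_A(I) + d_B/D_B(I) = rho` for the paired
#' doses of the two drugs' series.
#'
#' @inheritParams simulatePlate
#' @param drugA,drugB drug ids present in the scenario.
#' @param rho potency-shift factor; defaults to the scenario's registered
#'   combination, else 1 (Loewe-additive).
#' @return A well data.frame (see [simulatePlate()]).
#' @export
simulateCombination <- function(scenario, drugA, drugB, cellLine,
                                rho = NULL,
                                plateId = paste0(cellLine, "_combo"),
                                seed = scenario@seed) {
  label <- paste0(drugA, "+", drugB)
  if (is.null(rho)) {
    rho <- if (label %in% names(scenario@combinations))
      scenario@combinations[[label]]$rho else 1
  }
  scenario@combinations[[label]] <-
    list(drugA = drugA, drugB = drugB, rho = rho)
  simulatePlate(scenario, cellLine, conditions = label, plateId = plateId,
                seed = seed)
}

#' Simulate every plate of a scenario
#'
#' Lays out all drugs and combinations of the scenario for every cell
#' line, at most four conditions per plate (plates `"<line>_p1"`,
#' `"<line>_p2"`, ...), with per-plate seeds derived from the scenario
#' seed. Identical seeds yield bit-identical tables.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return One well data.frame covering all plates.
#' @export
simulatePanel <- function(scenario) {
  conditions <- c(names(scenario@series), names(scenario@combinations))
  lines <- scenarioCellLines(scenario)
  out <- list()
  plateOrdinal <- 0L
  for (ln in lines) {
    chunks <- split(conditions,
                    ceiling(seq_along(conditions) / 4))
    for (i in seq_along(chunks)) {
      plateOrdinal <- plateOrdinal + 1L
      out[[plateOrdinal]] <- simulatePlate(
        scenario, ln, conditions = chunks[[i]],
        plateId = paste0(ln, "_p", i),
        seed = scenario@seed + plateOrdinal)
    }
  }
  do.call(rbind, out)
}

# Solve the EC50 (imax 100, slope 1) whose noiseless IndexSUM over a
# doubling-dilution series equals a target index; the index is strictly
# increasing in EC50 (less potent -> higher index).
.ec50ForIndex <- function(targetIndex, series, imax = 100, hillSlope = 1) {
  stopifnot(targetIndex > 0, targetIndex < 600)
  cc <- series@concentrations
  f <- function(log10e)
    sum(100 - hillInhibition(cc, imax, 10^log10e, hillSlope)) - targetIndex
  stats::uniroot(f, lower = -9, upper = 9, tol = 1e-12)$root |>
    (\(x) 10^x)()
}

#' Preset isogenic MCF10a-style panel scenario
#'
#' Six isogenic lines (parental plus single knock-in mutants of PIK3CA,
#' EGFR, BRAF and AKT) by four inhibitors (gefitinib and erlotinib
#' against EGFR, ZSTK474 against PI3K, sirolimus against mTOR) with dose
#' series matching clinically achievable ranges (gefitinib 0.06-2 uM,
#' erlotinib 0.2-6.5 uM, ZSTK474 0.07-2.2 uM, sirolimus 0.06-2 uM).
#' Ground-truth potencies (Hill imax 100, slope 1; EC50 solved
#' numerically) encode the panel's characteristic sensitivity pattern:
#' the PIK3CA mutants — E545K ahead of H1047R — are the most sensitive
#' to the EGFR inhibitors (parental most resistant to gefitinib), and
#' BRAF V600E is by far the most resistant line to sirolimus. Four
#' fixed-ratio combinations (each EGFR inhibitor with ZSTK474 and with
#' sirolimus) carry a synergistic potency shift `rho`.
#'
#' @param noiseCV replicate CV in percent (default 8).
#' @param rho ground-truth potency-shift factor for all four preset
#'   combinations (default 0.6, synergistic).
#' @param seed integer seed (default 101).
#' @return A [SyntheticScenario-class] object.
#' @examples
#' sc <- scenarioIsogenicPanel()
#' scenarioCellLines(sc)
#' @export
scenarioIsogenicPanel <- function(noiseCV = 8, rho = 0.6, seed = 101L) {
  series <- list(
    gefitinib = DoseSeries("gefitinib", tdc = 1),
    erlotinib = DoseSeries("erlotinib", tdc = 3.25),
    ZSTK474   = DoseSeries("ZSTK474", tdc = 1.1),
    sirolimus = DoseSeries("sirolimus", tdc = 1))
  lines <- c("Wt", "PI3K_H1047R", "PI3K_E545K", "EGFR_dE746-A750",
             "BRAF_V600E", "AKT_E17K")
  # Target noiseless IndexSUM per line x drug: the panel's sensitivity
  # pattern (low = sensitive, high = resistant).
  targets <- matrix(c(
    # gefitinib erlotinib ZSTK474 sirolimus
      423,      188,      220,    333,   # Wt
      120,      110,      130,    420,   # PI3K_H1047R
       64,       70,      110,    254,   # PI3K_E545K
      280,      150,      215,    272,   # EGFR_dE746-A750
      380,      210,      280,    533,   # BRAF_V600E
      350,      227,      225,    360),  # AKT_E17K
    nrow = length(lines), byrow = TRUE,
    dimnames = list(lines, names(series)))
  models <- list()
  for (ln in lines)
    for (dr in names(series))
      models[[paste0(ln, ":", dr)]] <- DrugResponseModel(
        ln, dr, imax = 100,
        ec50 = .ec50ForIndex(targets[ln, dr], series[[dr]]),
        hillSlope = 1)
  combos <- list(
    "gefitinib+ZSTK474" =
      list(drugA = "gefitinib", drugB = "ZSTK474", rho = rho),
    "erlotinib+ZSTK474" =
      list(drugA = "erlotinib", drugB = "ZSTK474", rho = rho),
    "gefitinib+sirolimus" =
      list(drugA = "gefitinib", drugB = "sirolimus", rho = rho),
    "erlotinib+sirolimus" =
      list(drugA = "erlotinib", drugB = "sirolimus", rho = rho))
  SyntheticScenario(models, series, combos, noiseCV = noiseCV,
                    seed = seed)
}

#' Write the ground truth of a scenario as JSON
#'
#' Sidecar for test harnesses: Hill parameters per cell line x drug, dose
#' series, combination definitions with rho, noise CV, emission scale and
#' seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScenarioTruth <- function(scenario, path) {
  truth <- list(
    models = lapply(scenario@models, function(m)
      list(cell_line = m@cellLine, drug = m@drugId, imax = m@imax,
           ec50 = m@ec50, hill_slope = m@hillSlope)),
    series = lapply(scenario@series, function(s)
      list(drug = s@drugId, tdc = s@tdc,
           concentrations = s@concentrations)),
    combinations = scenario@combinations,
    noise_cv = scenario@noiseCV, mo_mean = scenario@moMean,
    mi_mean = scenario@miMean, replicates = scenario@replicates,
    seed = scenario@seed)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
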