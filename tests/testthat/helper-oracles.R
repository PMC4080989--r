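# Fixtures and independent oracles used across the suite.

# Build an InhibitionProfile directly from inhibition values.
# conc descending (step 1 = top); series defaults to a DoseSeries
# consistent with conc.
makeProfile <- function(inh, conc = 2 / 2^(0:5), condition = "test",
                        cv = rep(0, 6), n = rep(3L, 6), series = NULL) {
  if (is.null(series))
    series <- DoseSeries(condition, concentrations = conc)
  new("InhibitionProfile", condition = condition, concentrations = conc,
      inhibition = inh, cv = cv, nReplicates = as.integer(n),
      series = series)
}

# Noiseless profile sampled from a Hill model on a dose series.
hillProfile <- function(imax, ec50, h, series, condition = drugId(series)) {
  cc <- concentrations(series)
  makeProfile(hillInhibition(cc, imax, ec50, h), conc = cc,
              condition = condition, series = series)
}

# Brute-force ICF oracle: fine grid over the log-linear interpolant,
# first grid point at or past the target effect. Independent of
# estimateICF's bracketing logic.
oracleICF <- function(conc, inh, effect, nGrid = 1e5) {
  o <- order(conc)
  x <- log2(conc[o])
  y <- pmin(pmax(inh[o], 0), 100)
  target <- 100 * effect
  if (y[1] >= target)
    return(list(conc = conc[o][1], censored = "below"))
  grid <- seq(x[1], x[length(x)], length.out = nGrid)
  yg <- approx(x, y, xout = grid)$y
  hit <- which(yg >= target)
  if (!length(hit))
    return(list(conc = max(conc), censored = "above"))
  list(conc = 2^grid[hit[1]], censored = "none")
}

# Numeric Loewe isobole oracle: single-agent equipotent doses of two Hill
# drugs at effect F, and the ray crossing satisfying the Loewe sum = rho,
# solved on the dose axis (independent of loeweInhibition's effect-axis
# solve).
oracleLoeweRayCrossing <- function(mA, mB, ratio, effect, rho = 1) {
  DA <- hillInverse(100 * effect, mA@imax, mA@ec50, mA@hillSlope)
  DB <- hillInverse(100 * effect, mB@imax, mB@ec50, mB@hillSlope)
  # along the ray dB = dA / ratio; Loewe: dA/DA + dA/(ratio*DB) = rho
  dA <- rho / (1 / DA + 1 / (ratio * DB))
  list(doseA = dA, doseB = dA / ratio, DA = DA, DB = DB)
}

# Noiseless combination profile along a design's ray under the Loewe
# potency-shift model.
loeweComboProfile <- function(mA, mB, design, rho = 1,
                              condition = comboLabel(design)) {
  ccA <- concentrations(design@drugA)
  ccB <- concentrations(design@drugB)
  inh <- vapply(1:6, function(k)
    loeweInhibition(ccA[k], ccB[k], mA, mB, rho = rho), numeric(1))
  makeProfile(inh, conc = ccA, condition = condition, series = design)
}

# Random monotone (non-decreasing in concentration) inhibition profile.
randMonotoneProfile <- function() {
  conc <- 2^runif(1, -3, 3) / 2^(0:5)
  inh <- sort(runif(6, 0, 100))   # ascending with concentration
  makeProfile(rev(inh), conc = conc)   # profile stores descending conc
}

# Well table for a hand-built plate: one condition, given per-step
# replicate counts (list of numeric vectors), plus MO/MI control wells.
manualPlate <- function(stepCounts, moCounts, miCounts,
                        condition = "drugX", plateId = "P1") {
  rows <- do.call(rbind, lapply(seq_along(stepCounts), function(k) {
    reps <- stepCounts[[k]]
    data.frame(plate_id = plateId,
               well = paste0(LETTERS[k], seq_along(reps)),
               condition = condition, dilution_step = k,
               replicate = seq_along(reps), counts = reps)
  }))
  ctrlRow <- function(counts, label, offset) {
    if (!length(counts)) return(NULL)
    data.frame(plate_id = plateId,
               well = paste0("H", offset + seq_along(counts)),
               condition = label, dilution_step = NA_integer_,
               replicate = seq_along(counts), counts = counts)
  }
  rbind(rows, ctrlRow(moCounts, "MO", 0), ctrlRow(miCounts, "MI", 6))
}
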