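#' RunConfig: configuration of an end-to-end pipeline run
#'
#' @slot plates character, paths to per-well plate tables.
#' @slot layout path to the YAML layout/config file.
#' @slot outDir output directory (created if absent).
#' @slot alpha mutual-exclusivity parameter (0 or 1); `NA` defers to the
#'   layout file (default 0).
#' @slot cvLimit replicate-CV QC limit in percent; `NA` defers to the
#'   layout file (default 10).
#' @slot method IC estimation backend, `"interpolation"` or `"hill"`.
#' @slot cvOn `"counts"` or `"inhibition"`.
#' @slot seed integer seed recorded in the manifest.
#' @slot logLevel `"info"` or `"quiet"`.
#'
#' @seealso [RunConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
  representation(plates = "character", layout = "character",
                 outDir = "character", alpha = "numeric",
                 cvLimit = "numeric", method = "character",
                 cvOn = "character", seed = "integer",
                 logLevel = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!is.na(object@alpha) && !object@alpha %in% c(0, 1))
    msg <- c(msg, "alpha must be 0 or 1")
  if (!object@method %in% c("interpolation", "hill"))
    msg <- c(msg, "method must be 'interpolation' or 'hill'")
  if (!object@cvOn %in% c("counts", "inhibition"))
    msg <- c(msg, "cvOn must be 'counts' or 'inhibition'")
  if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param plates,layout,outDir,alpha,cvLimit,method,cvOn,seed,logLevel
#'   see the corresponding slots.
#' @return A [RunConfig-class] object; referenced input paths must exist.
#' @export
RunConfig <- function(plates, layout, outDir, alpha = NA_real_,
                      cvLimit = NA_real_, method = "interpolation",
                      cvOn = "counts", seed = 1L, logLevel = "info") {
  missing <- c(plates, layout)[!file.exists(c(plates, layout))]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  new("RunConfig", plates = plates, layout = layout, outDir = outDir,
      alpha = as.numeric(alpha), cvLimit = as.numeric(cvLimit),
      method = method, cvOn = cvOn, seed = as.integer(seed),
      logLevel = logLevel)
}

#' Read a layout/config file
#'
#' The layout is structured YAML naming the drugs with their test drug
#' concentrations (`tdc`, uM), the fixed-ratio combination designs, an
#' optional `groups` map from plate id to analysis group (e.g. cell
#' line), and optional `cv_limit` and `alpha` defaults.
#'
#' @param path YAML file path.
#' @return list with `series` (named [DoseSeries-class] list),
#'   `combinations` (each with `condition`, `drugA`, `drugB`, `design`),
#'   `groups`, `cvLimit`, `alpha`.
#' @export
readLayout <- function(path) {
  lay <- yaml::read_yaml(path)
  if (is.null(lay$drugs) || !length(lay$drugs))
    stop("layout ", path, " names no drugs")
  series <- lapply(names(lay$drugs), function(dr) {
    spec <- lay$drugs[[dr]]
    tdcVal <- if (is.list(spec)) spec$tdc else spec
    if (is.null(tdcVal)) stop("drug '", dr, "' has no tdc in layout")
    DoseSeries(dr, tdc = as.numeric(tdcVal))
  })
  names(series) <- names(lay$drugs)
  combos <- lapply(lay$combinations, function(cmb) {
    for (f in c("drug_a", "drug_b"))
      if (is.null(cmb[[f]])) stop("combination entry lacks ", f)
    if (!all(c(cmb$drug_a, cmb$drug_b) %in% names(series)))
      stop("combination names unknown drug(s): ", cmb$drug_a, ", ",
           cmb$drug_b)
    design <- CombinationDesign(series[[cmb$drug_a]], series[[cmb$drug_b]])
    list(condition = if (is.null(cmb$condition)) comboLabel(design)
                     else cmb$condition,
         drugA = cmb$drug_a, drugB = cmb$drug_b, design = design)
  })
  groups <- if (is.null(lay$groups)) character()
            else unlist(lay$groups)
  list(series = series, combinations = combos, groups = groups,
       cvLimit = if (is.null(lay$cv_limit)) 10 else as.numeric(lay$cv_limit),
       alpha = if (is.null(lay$alpha)) 0 else as.numeric(lay$alpha))
}

.log <- function(config, ...) {
  if (!identical(config@logLevel, "quiet")) message(...)
}

.fmtICF <- function(e, digits = NA) {
  v <- e@concentration
  if (!is.na(digits)) v <- round(v, digits)
  list(value = v, censored = e@censored)
}

#' Run the end-to-end ATP-TCA analysis pipeline
#'
#' Reads per-well plate tables, summarizes every condition into an
#' inhibition profile with QC, computes per-condition sensitivity (IC50,
#' IC90, IndexSUM, activity call), scores every combination defined in
#' the layout against its single agents with Chou-Talalay indices at 50%
#' and 90% effect, and writes result tables (delimited text, 2-decimal
#' human precision), JSON mirrors (full precision), a wide CI matrix (one
#' row per analysis group), and a machine-readable run manifest recording
#' every configurable decision. Stage errors carry plate/condition
#' context; combinations whose doses are censored are reported as not
#' estimable rather than dropped.
#'
#' @param config a [RunConfig-class] object.
#' @return Invisibly, a list with `profiles`, `qc`, `sensitivity`
#'   (data.frame), `combinations` (data.frame), `ciMatrix` and the output
#'   `paths`.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  layout <- readLayout(config@layout)
  alpha <- if (is.na(config@alpha)) layout$alpha else config@alpha
  cvLimit <- if (is.na(config@cvLimit)) layout$cvLimit else config@cvLimit
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)

  wells <- do.call(rbind, lapply(config@plates, readPlateTable))
  comboByCondition <- stats::setNames(
    layout$combinations,
    vapply(layout$combinations, `[[`, character(1), "condition"))
  groupOf <- function(plateId)
    if (plateId %in% names(layout$groups)) layout$groups[[plateId]]
    else plateId

  profiles <- list()
  profRows <- qcRows <- sensRows <- list()
  results <- list()
  for (plateId in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == plateId, , drop = FALSE]
    conds <- setdiff(unique(pw$condition), c("MO", "MI"))
    for (cond in conds) {
      series <- if (cond %in% names(layout$series)) layout$series[[cond]]
                else if (cond %in% names(comboByCondition))
                  comboByCondition[[cond]]$design
                else stop("plate ", plateId, ": condition '", cond,
                          "' is not defined in the layout")
      prof <- tryCatch(
        summarizeCondition(pw, series, condition = cond, cvOn = config@cvOn),
        error = function(e)
          stop("plate ", plateId, ", condition '", cond, "': ",
               conditionMessage(e), call. = FALSE))
      qc <- qcProfile(prof, cvLimit = cvLimit)
      sens <- drugSensitivity(prof, method = config@method)
      grp <- groupOf(plateId)
      key <- paste0(grp, "|", cond)
      profiles[[key]] <- prof
      results[[key]] <- sens
      profRows[[key]] <- data.frame(
        group = grp, plate_id = plateId, condition = cond, step = 1:6,
        dilution = dilutionLabels(),
        concentration = signif(prof@concentrations, 6),
        inhibition = round(inhibition(prof), 2),
        inhibition_clipped = round(inhibition(prof, clipped = TRUE), 2),
        cv = round(prof@cv, 2), n = prof@nReplicates)
      qcRows[[key]] <- data.frame(
        group = grp, plate_id = plateId, condition = cond, step = 1:6,
        cv = round(prof@cv, 2), flagged = qc$flagged, pass = qc$pass,
        cv_limit = cvLimit)
      sensRows[[key]] <- data.frame(
        group = grp, plate_id = plateId, condition = cond,
        ic50 = round(sens@ic50@concentration, 2),
        ic50_censored = sens@ic50@censored,
        ic90 = round(sens@ic90@concentration, 2),
        ic90_censored = sens@ic90@censored,
        index_sum = round(sens@indexSum, 2), active = sens@active)
      .log(config, "analyzed plate ", plateId, " condition ", cond)
    }
  }

  comboRows <- list()
  groups <- unique(vapply(strsplit(names(results), "|", fixed = TRUE),
                          `[[`, character(1), 1L))
  for (grp in groups) {
    for (cmb in layout$combinations) {
      kA <- paste0(grp, "|", cmb$drugA)
      kB <- paste0(grp, "|", cmb$drugB)
      kC <- paste0(grp, "|", cmb$condition)
      if (!all(c(kA, kB, kC) %in% names(results))) next
      rep2 <- ciReport(results[[kA]], results[[kB]], results[[kC]],
                       cmb$design, alpha = alpha)
      for (r in rep2) {
        comboRows[[paste0(grp, "|", cmb$condition, "|", r@effect)]] <-
          data.frame(
            group = grp, combination = cmb$condition,
            effect = r@effect, ci = round(r@ci, 2),
            classification = r@classification, alpha = r@alpha,
            dose_a_combo = round(r@doseAcombo, 4),
            dose_b_combo = round(r@doseBcombo, 4),
            dose_a_single = round(r@doseAsingle, 4),
            dose_b_single = round(r@doseBsingle, 4),
            ci_full = r@ci)
      }
    }
  }

  profTab <- do.call(rbind, unname(profRows))
  qcTab <- do.call(rbind, unname(qcRows))
  sensTab <- do.call(rbind, unname(sensRows))
  comboTab <- if (length(comboRows)) do.call(rbind, unname(comboRows))
              else data.frame()

  # Wide, one row per group: CI50/CI90 and class per combination.
  ciMatrix <- NULL
  if (nrow(comboTab)) {
    ciMatrix <- data.frame(group = groups)
    for (cmb in unique(comboTab$combination)) {
      for (eff in c(0.5, 0.9)) {
        sel <- comboTab[comboTab$combination == cmb &
                          comboTab$effect == eff, , drop = FALSE]
        col <- paste0(cmb, "_CI", eff * 100)
        ciMatrix[[col]] <- sel$ci[match(ciMatrix$group, sel$group)]
        ciMatrix[[paste0(col, "_class")]] <-
          sel$classification[match(ciMatrix$group, sel$group)]
      }
    }
  }

  paths <- list(
    profiles = file.path(config@outDir, "profiles.csv"),
    qc = file.path(config@outDir, "qc.csv"),
    sensitivity = file.path(config@outDir, "sensitivity.csv"),
    sensitivityJson = file.path(config@outDir, "sensitivity.json"),
    combinations = file.path(config@outDir, "combinations.csv"),
    combinationsJson = file.path(config@outDir, "combinations.json"),
    ciMatrix = file.path(config@outDir, "ci_matrix.csv"),
    manifest = file.path(config@outDir, "manifest.json"))
  utils::write.csv(profTab, paths$profiles, row.names = FALSE)
  utils::write.csv(qcTab, paths$qc, row.names = FALSE)
  utils::write.csv(sensTab, paths$sensitivity, row.names = FALSE)
  jsonlite::write_json(
    lapply(unname(results), function(s) list(
      condition = s@condition, ic50 = .fmtICF(s@ic50),
      ic90 = .fmtICF(s@ic90), index_sum = s@indexSum,
      active = s@active)),
    paths$sensitivityJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(comboTab)) {
    out <- comboTab
    out$ci <- out$ci  # human table keeps 2-decimal ci; ci_full dropped
    utils::write.csv(out[setdiff(names(out), "ci_full")],
                     paths$combinations, row.names = FALSE)
    jsonlite::write_json(
      lapply(seq_len(nrow(comboTab)), function(i) as.list(
        transform(comboTab[i, ], ci = ci_full)[
          setdiff(names(comboTab), "ci_full")])),
      paths$combinationsJson, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(ciMatrix, paths$ciMatrix, row.names = FALSE)
  }
  manifest <- list(
    package = "atpTCA",
    version = as.character(utils::packageVersion("atpTCA")),
    inputs = list(plates = config@plates, layout = config@layout),
    seed = config@seed,
    decisions = list(
      alpha = alpha, cv_limit = cvLimit, cv_on = config@cvOn,
      ic_backend = config@method,
      inhibition_clipped_for_index_and_icf = TRUE,
      control_aggregation = "mean after dropping outliers beyond 3 sd",
      interpolation_axis = "log2 concentration",
      censoring_policy = "censored doses propagate as not estimable",
      activity_threshold = "IndexSUM < 300 (strict)",
      ci_classes = "synergy < 0.8 <= additive <= 1.2 < antagonism"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .log(config, "pipeline complete: ", length(results), " condition(s), ",
       nrow(comboTab) / 2, " combination report(s)")
  invisible(list(profiles = profiles, qc = qcTab, sensitivity = sensTab,
                 results = results, combinations = comboTab,
                 ciMatrix = ciMatrix, paths = paths))
}

#' Write a scenario's plates and layout for pipeline consumption
#'
#' Simulates every plate of a scenario (see [simulatePanel()]) and writes
#' the per-well CSV, a matching YAML layout (drugs, combinations, plate
#' groups) and the ground-truth JSON sidecar, producing exactly the
#' inputs [runPipeline()] reads.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory (created if absent).
#' @return list of written paths (`plates`, `layout`, `truth`),
#'   invisibly.
#' @export
writeSimulatedInputs <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wells <- simulatePanel(scenario)
  platePath <- file.path(dir, "plates.csv")
  utils::write.csv(wells, platePath, row.names = FALSE)
  groups <- lapply(unique(wells$plate_id), function(p)
    sub("_p[0-9]+$", "", p))
  names(groups) <- unique(wells$plate_id)
  lay <- list(
    drugs = lapply(scenario@series, function(s) list(tdc = s@tdc)),
    combinations = lapply(names(scenario@combinations), function(nm) {
      cmb <- scenario@combinations[[nm]]
      list(condition = nm, drug_a = cmb$drugA, drug_b = cmb$drugB)
    }),
    groups = groups,
    cv_limit = 10, alpha = 0)
  layoutPath <- file.path(dir, "layout.yaml")
  yaml::write_yaml(lay, layoutPath)
  truthPath <- file.path(dir, "truth.json")
  writeScenarioTruth(scenario, truthPath)
  invisible(list(plates = platePath, layout = layoutPath,
                 truth = truthPath))
}
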