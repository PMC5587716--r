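# Pipeline entry points: design, simulate, quantify, evaluate.
# Each reads/writes plain CSV (RFC-4180, header row) and returns its main
# result invisibly; quantify and evaluate also emit a JSON run report whose
# per-stage counts reconcile (read = used + excluded).

.readCsvChecked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s file %s is missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")))
  df
}

#' Design stage: FASTA in, transition-list CSV out
#'
#' Digests the target proteins, selects proteotypic peptides and writes a
#' paired light/heavy transition list. Deterministic: identical input gives
#' byte-identical output.
#'
#' @param fastaPath Input protein FASTA.
#' @param outPath Output transition CSV.
#' @param nTransitions Per-peptide transition counts (see
#'   [designTransitions()]).
#' @param precursorCharge Precursor charge state, default 2.
#'
#' @return The transition data.frame, invisibly.
#' @export
runDesign <- function(fastaPath, outPath,
                      nTransitions = .DEFAULT_TRANSITIONS,
                      precursorCharge = 2L) {
  targets <- readProteinFasta(fastaPath)
  transitions <- designTransitions(targets, nTransitions = nTransitions,
                                   precursorCharge = precursorCharge)
  writeTransitionList(transitions, outPath)
  invisible(transitions)
}

#' Simulation stage: write calibration, cohort areas, metadata and truth CSVs
#'
#' @param outDir Output directory (created if needed).
#' @param spec A [CohortSpec-class]; defaults to [sepsisCohortSpec()].
#' @param config An [AssayConfig-class].
#' @param seed Integer seed; all randomness funnels through it.
#' @param levelsFmol,replicates Calibration design, defaults 7 levels x 3.
#'
#' @return Named character vector of written file paths, invisibly.
#' @export
runSimulate <- function(outDir, spec = sepsisCohortSpec(),
                        config = AssayConfig(), seed = 1L,
                        levelsFmol = c(0.1, 0.5, 1, 5, 10, 20, 40),
                        replicates = 3L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cal <- simulateCalibrationSeries(levelsFmol, replicates, config,
                                   seed = seed)
  sim <- simulateCohort(spec, config, seed = seed + 1L)
  paths <- c(
    calibration = file.path(outDir, "calibration.csv"),
    areas = file.path(outDir, "areas.csv"),
    metadata = file.path(outDir, "metadata.csv"),
    truth = file.path(outDir, "truth.csv")
  )
  utils::write.csv(cal, paths[["calibration"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$areas, paths[["areas"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$metadata, paths[["metadata"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Quantification stage: areas + calibration + metadata in, concentrations out
#'
#' @param areasPath Long peak-area CSV (`sample_id`, `peptide`, `fragment`,
#'   `light_area`, `heavy_area`).
#' @param calibrationPath Calibration CSV (`level_fmol`, `replicate`,
#'   `peptide`, `fragment`, `light_area`, `heavy_area`).
#' @param metadataPath Metadata CSV (`sample_id`, `group`,
#'   `plasma_protein_ug_per_ml`).
#' @param outDir Output directory.
#' @param config An [AssayConfig-class].
#'
#' @return List with `concentrations` (data.frame) and `report` (RunReport
#'   list), invisibly. Writes `concentrations.csv` and
#'   `quantify_report.json`.
#' @export
runQuantify <- function(areasPath, calibrationPath, metadataPath, outDir,
                        config = AssayConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  areas <- .readCsvChecked(
    areasPath, c("sample_id", "peptide", "fragment", "light_area", "heavy_area"),
    "areas")
  cal <- .readCsvChecked(
    calibrationPath,
    c("level_fmol", "replicate", "peptide", "fragment", "light_area",
      "heavy_area"), "calibration")
  metadata <- .readCsvChecked(
    metadataPath, c("sample_id", "group", "plasma_protein_ug_per_ml"),
    "metadata")

  nRead <- nrow(areas)
  unknown <- !areas$sample_id %in% metadata$sample_id
  if (any(unknown))
    warning(sprintf("%d area rows reference samples absent from metadata; excluded",
                    sum(unknown)))
  used <- areas[!unknown, , drop = FALSE]
  curves <- fitCalibrationCurves(cal, weighting = config@weighting)
  conc <- if (nrow(used)) quantifySamples(used, curves, metadata, config)
          else .emptyQuantFrame()
  if (nrow(used) == 0L) warning("empty areas table: no samples quantified")

  report <- list(
    tool = "histoneMRM",
    version = as.character(utils::packageVersion("histoneMRM")),
    stage = "quantify",
    config = list(
      spike_amount_fmol = config@spikeAmountFmol,
      protein_load_ug = config@proteinLoadUg,
      weighting = config@weighting,
      cv_flag_threshold = config@cvFlagThreshold
    ),
    counts = list(
      area_rows_read = nRead,
      area_rows_used = nrow(used),
      area_rows_excluded = sum(unknown),
      exclusion_reasons = if (any(unknown)) "sample_id absent from metadata"
                          else character(0),
      samples_quantified = length(unique(conc$sample_id))
    ),
    curves = lapply(curves, function(cu) list(
      peptide = cu@peptide, slope = cu@slope, intercept = cu@intercept,
      r_squared = cu@rSquared, range_fmol = cu@rangeFmol,
      weighting = cu@weighting)),
    qc = list(
      flagged_rows = sum(nzchar(conc$flags)),
      unquantifiable = sum(grepl("unquantifiable", conc$flags))
    )
  )
  utils::write.csv(conc, file.path(outDir, "concentrations.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(outDir, "quantify_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(concentrations = conc, report = report))
}

#' Evaluation stage: concentrations in, biomarker statistics out
#'
#' Writes group summaries (mean, SD, 95% CI), pooled-variance t-test
#' comparisons (patients vs controls, non-survivors vs survivors), Pearson
#' correlations between the two histones (per subgroup and pooled), ROC
#' results in a published-table layout, and the ROC coordinates for
#' plotting.
#'
#' @param concentrationsPath Concentrations CSV from [runQuantify()].
#' @param metadataPath Metadata CSV (used when the concentrations file
#'   lacks a `group` column).
#' @param outDir Output directory.
#' @param contrasts Character subset of `c("diagnosis", "prognosis")`.
#'
#' @return List of the computed tables plus a report, invisibly.
#' @export
runEvaluate <- function(concentrationsPath, metadataPath = NULL, outDir,
                        contrasts = c("diagnosis", "prognosis")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  conc <- .readCsvChecked(concentrationsPath,
                          c("sample_id", "histone", "ng_per_ml"),
                          "concentrations")
  if (!"group" %in% names(conc)) {
    if (is.null(metadataPath))
      stop("concentrations lack a 'group' column and no metadata was given")
    md <- .readCsvChecked(metadataPath, c("sample_id", "group"), "metadata")
    conc$group <- md$group[match(conc$sample_id, md$sample_id)]
  }
  res <- evaluateCohort(conc, contrasts = contrasts)
  utils::write.csv(res$group_summaries,
                   file.path(outDir, "group_summaries.csv"), row.names = FALSE)
  utils::write.csv(res$t_tests, file.path(outDir, "t_tests.csv"),
                   row.names = FALSE)
  corr <- if (is.null(res$correlations))
    data.frame(subset = character(0), r = numeric(0), p = numeric(0),
               n = integer(0))
  else res$correlations
  utils::write.csv(corr, file.path(outDir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(res$roc_results, file.path(outDir, "roc_results.csv"),
                   row.names = FALSE)
  utils::write.csv(res$roc_coordinates,
                   file.path(outDir, "roc_coordinates.csv"), row.names = FALSE)
  jsonlite::write_json(res$report, file.path(outDir, "evaluate_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Full biomarker evaluation of a quantified cohort
#'
#' In-memory core of [runEvaluate()].
#'
#' @param conc data.frame with `sample_id`, `group`, `histone`,
#'   `ng_per_ml`.
#' @param contrasts Character subset of `c("diagnosis", "prognosis")`.
#'
#' @return List: `group_summaries`, `t_tests`, `correlations`,
#'   `roc_results`, `roc_coordinates`, `roc_objects` (list of
#'   [RocResult-class]), `report`.
#' @export
evaluateCohort <- function(conc, contrasts = c("diagnosis", "prognosis")) {
  conc <- conc[is.finite(conc$ng_per_ml) & !is.na(conc$group), , drop = FALSE]
  histones <- sort(unique(conc$histone))

  summaries <- do.call(rbind, lapply(histones, function(h) {
    sub <- conc[conc$histone == h, ]
    pooledPatients <- sub$ng_per_ml[sub$group %in% c("survivor", "non_survivor")]
    rows <- lapply(split(sub, sub$group), function(g)
      cbind(histone = h, meanCI(g$ng_per_ml, group = g$group[1])))
    rows <- do.call(rbind, rows)
    if (length(pooledPatients) >= 2)
      rows <- rbind(rows, cbind(histone = h,
                                meanCI(pooledPatients, group = "patient")))
    rows
  }))
  rownames(summaries) <- NULL

  tt <- do.call(rbind, lapply(histones, function(h) {
    sub <- conc[conc$histone == h, ]
    ctl <- sub$ng_per_ml[sub$group == "control"]
    pat <- sub$ng_per_ml[sub$group %in% c("survivor", "non_survivor")]
    sur <- sub$ng_per_ml[sub$group == "survivor"]
    non <- sub$ng_per_ml[sub$group == "non_survivor"]
    out <- NULL
    if (length(ctl) >= 2 && length(pat) >= 2) {
      t1 <- studentsTTest(pat, ctl)
      out <- rbind(out, data.frame(histone = h,
                                   comparison = "patient_vs_control",
                                   t = t1$t, df = t1$df, p = t1$p))
    }
    if (length(sur) >= 2 && length(non) >= 2) {
      t2 <- studentsTTest(non, sur)
      out <- rbind(out, data.frame(histone = h,
                                   comparison = "non_survivor_vs_survivor",
                                   t = t2$t, df = t2$df, p = t2$p))
    }
    out
  }))

  wide <- stats::reshape(
    conc[, c("sample_id", "group", "histone", "ng_per_ml")],
    idvar = c("sample_id", "group"), timevar = "histone",
    direction = "wide")
  names(wide) <- sub("^ng_per_ml\\.", "", names(wide))
  corr <- NULL
  if (all(c("H2B", "H3") %in% names(wide))) {
    sets <- list(
      control = wide[wide$group == "control", ],
      patient = wide[wide$group %in% c("survivor", "non_survivor"), ],
      pooled = wide
    )
    corr <- do.call(rbind, lapply(names(sets), function(nm) {
      s <- sets[[nm]]
      if (nrow(s) < 3) return(NULL)
      pc <- pearsonCorrelation(s$H2B, s$H3)
      data.frame(subset = nm, r = pc$r, p = pc$p, n = pc$n)
    }))
  }

  rocObjects <- list()
  for (h in histones) {
    sub <- conc[conc$histone == h, ]
    for (ct in contrasts) {
      ok <- tryCatch({
        rocObjects[[paste(h, ct, sep = "_")]] <-
          evaluateBiomarker(sub$ng_per_ml, sub$group, contrast = ct,
                            histone = h)
        TRUE
      }, error = function(e) FALSE)
    }
  }
  rocTable <- do.call(rbind, lapply(rocObjects, rocAsRow))
  rownames(rocTable) <- NULL
  rocCoords <- do.call(rbind, lapply(rocObjects, function(r)
    cbind(histone = r@histone, contrast = r@contrast, rocCoordinates(r))))
  rownames(rocCoords) <- NULL

  report <- list(
    tool = "histoneMRM", stage = "evaluate",
    counts = list(
      concentration_rows_read = nrow(conc),
      histones = histones,
      subjects = length(unique(conc$sample_id)),
      per_contrast = lapply(rocObjects, function(r)
        list(n_cases = r@nCases, n_controls = r@nControls))
    )
  )
  list(group_summaries = summaries, t_tests = tt, correlations = corr,
       roc_results = rocTable, roc_coordinates = rocCoords,
       roc_objects = rocObjects, report = report)
}
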