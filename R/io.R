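#' Read a measurement table from CSV
#'
#' Expects the documented schema: columns `time_min`, `species`,
#' `replicate`, `signal` and optional `censored` (0/1). Malformed rows are
#' reported with their line numbers (header = line 1).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A [SweatMeasurements-class] object.
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "species", "replicate", "signal")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(tab)) + 1L
  bad <- !tab$species %in% SPECIES
  if (any(bad))
    stop("unknown species in ", path, " at line(s) ",
         paste(line[bad], collapse = ", "), ": ",
         paste(unique(tab$species[bad]), collapse = ", "))
  badT <- !is.finite(tab$time_min) | tab$time_min < 0
  if (any(badT))
    stop("invalid time_min in ", path, " at line(s) ",
         paste(line[badT], collapse = ", "))
  badS <- !is.finite(tab$signal) | tab$signal < 0
  if (any(badS))
    stop("invalid signal in ", path, " at line(s) ",
         paste(line[badS], collapse = ", "))
  SweatMeasurements(tab)
}

#' Write a measurement table to CSV
#'
#' Inverse of [readMeasurements()]: writes the tidy schema (`time_min`,
#' `species`, `replicate`, `signal`, `censored`); the round trip is
#' lossless.
#'
#' @param x A [SweatMeasurements-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(x, path) {
  tab <- asMeasurementTable(x)
  write.csv(tab[, c("time_min", "species", "replicate", "signal",
                    "censored")],
            path, row.names = FALSE)
  invisible(path)
}

.runMeta <- function(seed, config = list()) {
  cfg <- paste(deparse(config), collapse = "")
  list(package = "sweatPK",
       version = as.character(packageVersion("sweatPK")),
       seed = seed,
       configHash = sprintf("%08x",
                            sum(utf8ToInt(cfg) *
                                  (seq_along(utf8ToInt(cfg)) %% 97 + 1)) %%
                              .Machine$integer.max))
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, loss, adjusted R-squared, confidence intervals (if
#' set), the per-start convergence log, the seed and package version.
#'
#' @param fit A [KineticFit-class] object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "KineticFit"))
  out <- c(.runMeta(fit@seed, fit@params), list(
    rates = as.list(fit@rates),
    initialConcentrations = as.list(fit@init),
    sweatVolumes = as.list(setNames(fit@volumes,
                                    sprintf("t%g", fit@times))),
    loss = fit@loss, alpha = fit@alpha, scale = fit@scale,
    adjR2 = fit@adjR2, nObs = fit@nObs, dfResidual = fit@dfResidual,
    ci = fit@ci, startLog = fit@convergence))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write fitted sweat volumes as tidy CSV
#'
#' @param fit A [KineticFit-class] object.
#' @param path Output path (`.csv`); columns `time_min`, `v_sweat_uL`.
#' @return `path`, invisibly.
#' @export
writeSweatVolumes <- function(fit, path) {
  stopifnot(is(fit, "KineticFit"))
  write.csv(data.frame(time_min = fit@times * 60,
                       v_sweat_uL = unname(fit@volumes)),
            path, row.names = FALSE)
  invisible(path)
}

.cliUsage <- function() {
  cat("usage: sweatpk <simulate|fit|quantify|stats|cohort> [options]\n",
      "  simulate --out DIR [--design A|B|C1|C2] [--seed N] [--n N] [--cv F]\n",
      "  fit      --input FILE.csv --out DIR [--seed N] [--n-starts N]",
      " [--alpha F]\n",
      "  quantify --calibration FILE.csv --out DIR [--blanks FILE.csv]\n",
      "  stats    --input FILE.csv --out DIR [--pre T] [--post T]",
      " [--seed N]\n",
      "  cohort   --input DIR --out DIR [--seed N] [--n-starts N]\n",
      sep = "")
}

.parseArgs <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(argv)) stop("missing value for --", key)
    out[[gsub("-", "_", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Drives the pipeline from a shell: `simulate` writes a synthetic cohort
#' (measurement CSVs plus a ground-truth JSON sidecar), `fit` estimates a
#' profile from a measurement CSV, `quantify` produces a QC report from a
#' calibration CSV (columns `level_pg_per_uL`, `signal`) and optional
#' blanks, `stats` runs paired tests per metabolite on a tidy cohort table
#' (`subject`, `metabolite`, `time`, `value`), and `cohort` fits every
#' profile CSV in a directory and reports the PCA of the conversion
#' constants. A thin wrapper script is installed at
#' `system.file("scripts", "sweatpk", package = "sweatPK")`.
#'
#' @param argv Character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return Integer exit code, invisibly: 0 success, 1 input error,
#'   2 fit/convergence failure.
#' @export
runCLI <- function(argv) {
  if (length(argv) < 1L) { .cliUsage(); return(invisible(1L)) }
  cmd <- argv[1]
  res <- try({
    opts <- .parseArgs(argv[-1])
    seed <- as.integer(opts$seed %||% "1")
    switch(cmd,
      simulate = .cliSimulate(opts, seed),
      fit = .cliFit(opts, seed),
      quantify = .cliQuantify(opts, seed),
      stats = .cliStats(opts, seed),
      cohort = .cliCohort(opts, seed),
      { .cliUsage(); stop("unknown subcommand: ", cmd) })
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    msg <- attr(res, "condition")$message
    message("error: ", msg)
    code <- if (grepl("optimizer|converg", msg)) 2L else 1L
    return(invisible(code))
  }
  invisible(0L)
}

.cliSimulate <- function(opts, seed) {
  if (is.null(opts$out)) stop("simulate needs --out")
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  design <- studyDesign(opts$design %||% "C2")
  n <- as.integer(opts$n %||% "1")
  noise <- noiseModel(cv = as.numeric(opts$cv %||% "0.10"))
  cohort <- generateCohort(n, design, noise, seed = seed)
  gt <- list()
  for (i in seq_along(cohort)) {
    f <- file.path(opts$out, sprintf("profile_%02d.csv", i))
    writeMeasurements(cohort[[i]], f)
    g <- groundTruth(cohort[[i]])
    gt[[sprintf("profile_%02d", i)]] <-
      list(rates = as.list(g$rates), init = as.list(g$init),
           volumes = g$volumes)
  }
  jsonlite::write_json(c(.runMeta(seed, list(design = design$name, n = n)),
                         list(groundTruth = gt)),
                       file.path(opts$out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.cliFit <- function(opts, seed) {
  if (is.null(opts$input) || is.null(opts$out))
    stop("fit needs --input and --out")
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  sm <- readMeasurements(opts$input)
  cfg <- fitConfig(nStarts = as.integer(opts$n_starts %||% "100"),
                   seed = seed,
                   alphaGrid = as.numeric(opts$alpha %||%
                                            c(2, 1, 0.5, 0)))
  fit <- fitProfile(sm, config = cfg)
  writeFitResult(fit, file.path(opts$out, "fit_result.json"))
  writeSweatVolumes(fit, file.path(opts$out, "sweat_volumes.csv"))
}

.cliQuantify <- function(opts, seed) {
  if (is.null(opts$calibration) || is.null(opts$out))
    stop("quantify needs --calibration and --out")
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  cal <- read.csv(opts$calibration, stringsAsFactors = FALSE)
  if (!all(c("level_pg_per_uL", "signal") %in% names(cal)))
    stop("calibration CSV needs columns level_pg_per_uL, signal")
  cc <- fitCalibration(cal$level_pg_per_uL, cal$signal)
  rep <- c(.runMeta(seed), list(
    calibration = list(slope = cc$slope, intercept = cc$intercept,
                       r2 = cc$r2, range = cc$range),
    responseCVpercent = cvPercent(cal$signal / cal$level_pg_per_uL)))
  if (!is.null(opts$blanks)) {
    bl <- read.csv(opts$blanks, stringsAsFactors = FALSE)
    if (!"signal" %in% names(bl)) stop("blanks CSV needs column signal")
    rep$lod <- lod(bl$signal)
    rep$lloq <- lloq(bl$signal)
  }
  jsonlite::write_json(rep, file.path(opts$out, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.cliStats <- function(opts, seed) {
  if (is.null(opts$input) || is.null(opts$out))
    stop("stats needs --input and --out")
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  tab <- read.csv(opts$input, stringsAsFactors = FALSE)
  need <- c("subject", "metabolite", "time", "value")
  if (!all(need %in% names(tab)))
    stop("stats CSV needs columns ", paste(need, collapse = ", "))
  tp <- sort(unique(tab$time))
  preT <- as.numeric(opts$pre %||% tp[1])
  postT <- as.numeric(opts$post %||% tp[length(tp)])
  mets <- sort(unique(tab$metabolite))
  rows <- lapply(mets, function(m) {
    sub <- tab[tab$metabolite == m, ]
    pre <- sub$value[sub$time == preT][order(sub$subject[sub$time == preT])]
    post <- sub$value[sub$time == postT][
      order(sub$subject[sub$time == postT])]
    if (length(pre) != length(post) || length(pre) < 2) return(NULL)
    w <- wilcoxonSignedRank(pre, post)
    t <- pairedT(pre, post)
    data.frame(metabolite = m, n = length(pre), meanDiff = t$meanDiff,
               t = t$t, pT = t$p, wPos = w$wPos, pWilcoxon = w$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  write.csv(res, file.path(opts$out, "paired_tests.csv"), row.names = FALSE)
  jsonlite::write_json(c(.runMeta(seed, list(pre = preT, post = postT))),
                       file.path(opts$out, "stats_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.cliCohort <- function(opts, seed) {
  if (is.null(opts$input) || is.null(opts$out))
    stop("cohort needs --input and --out")
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  files <- sort(list.files(opts$input, pattern = "\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no profile CSVs in ", opts$input)
  cfg <- fitConfig(nStarts = as.integer(opts$n_starts %||% "100"),
                   seed = seed, alphaGrid = 2)
  fits <- lapply(files, function(f) fitProfile(readMeasurements(f),
                                               config = cfg))
  kmat <- kineticConstantMatrix(fits)
  rownames(kmat) <- basename(files)
  write.csv(cbind(profile = rownames(kmat), as.data.frame(kmat),
                  adjR2 = vapply(fits, fitAdjR2, 0)),
            file.path(opts$out, "kinetic_constants.csv"),
            row.names = FALSE)
  pca <- pcaAnalysis(kmat, nComponents = 2, standardScale = TRUE)
  write.csv(data.frame(profile = rownames(kmat), pca$scores),
            file.path(opts$out, "pca_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(.runMeta(seed, list(nStarts = cfg$nStarts)),
      list(explainedVariance = pca$explainedVariance,
           correlations = as.data.frame(kCorrelationSummary(kmat)))),
    file.path(opts$out, "cohort_meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
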