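#' SweatMeasurements: finger-sweat signal table
#'
#' An S4 container for one volunteer profile: internal-standard-normalized
#' signals for the four methylxanthine species, measured at a grid of
#' sampling times with technical replicates. It extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are the four species,
#' columns are collected samples (one per time-point and technical
#' replicate), the `"signal"` assay holds normalized signals and the
#' `"censored"` assay flags below-LOD entries that are excluded from
#' fitting. Column metadata carries `time_h` and `replicate`.
#'
#' A generated profile additionally stores its generating ground truth
#' (rates, baseline, sweat volumes) in `metadata(x)$groundTruth`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases SweatMeasurements-class
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @exportClass SweatMeasurements
setClass("SweatMeasurements",
         contains = "SummarizedExperiment")

setValidity("SweatMeasurements", function(object) {
  msg <- character()
  if (!all(c("signal", "censored") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'signal' and 'censored' are required")
  if (nrow(object) != 4L || !identical(rownames(object), SPECIES))
    msg <- c(msg, "rows must be the four species, in canonical order")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time_h", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain time_h and replicate")
  } else {
    tt <- cd$time_h
    if (any(!is.finite(tt)) || any(tt < 0))
      msg <- c(msg, "time_h must be finite and non-negative")
    if (length(unique(tt)) < 2L)
      msg <- c(msg, "need at least 2 distinct time-points")
  }
  if ("signal" %in% SummarizedExperiment::assayNames(object)) {
    sig <- SummarizedExperiment::assay(object, "signal")
    if (any(!is.finite(sig)) || any(sig < 0))
      msg <- c(msg, "signals must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SweatMeasurements object from a tidy table
#'
#' @param table `data.frame` with columns `time_h` (or `time_min`, converted
#'   on read), `species`, `replicate`, `signal` and optionally `censored`
#'   (0/1 or logical; defaults to all observed).
#' @param groundTruth Optional list of generating parameters, stored in the
#'   object metadata (used by the synthetic-data generator).
#'
#' @return A [SweatMeasurements-class] object.
#' @examples
#' tab <- expand.grid(time_h = c(0, 1, 2), species = SPECIES,
#'                    replicate = 1:2, stringsAsFactors = FALSE)
#' tab$signal <- runif(nrow(tab))
#' sm <- SweatMeasurements(tab)
#' sm
#' @export
SweatMeasurements <- function(table, groundTruth = NULL) {
  stopifnot(is.data.frame(table))
  if (!"time_h" %in% names(table)) {
    if (!"time_min" %in% names(table))
      stop("table needs a time_h or time_min column")
    table$time_h <- table$time_min / 60
  }
  need <- c("time_h", "species", "replicate", "signal")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- !table$species %in% SPECIES
  if (any(bad))
    stop("unknown species at row(s) ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(table$species[bad]), collapse = ", "))
  if (is.null(table$censored)) table$censored <- FALSE
  table$censored <- as.logical(table$censored)

  samp <- unique(table[order(table$time_h, table$replicate),
                       c("time_h", "replicate")])
  rownames(samp) <- NULL
  key <- function(t, r) paste(format(t, digits = 12), r, sep = "@")
  sampKey <- key(samp$time_h, samp$replicate)
  idx <- cbind(match(table$species, SPECIES),
               match(key(table$time_h, table$replicate), sampKey))
  if (anyDuplicated(cbind(idx)) > 0)
    stop("duplicate (time, species, replicate) rows")
  sig <- matrix(NA_real_, 4L, nrow(samp), dimnames = list(SPECIES, NULL))
  cen <- matrix(TRUE, 4L, nrow(samp), dimnames = list(SPECIES, NULL))
  sig[idx] <- table$signal
  cen[idx] <- table$censored
  if (anyNA(sig)) {
    # a species not measured in a sample is treated as censored at 0
    cen[is.na(sig)] <- TRUE
    sig[is.na(sig)] <- 0
  }
  colnames(sig) <- colnames(cen) <-
    sprintf("t%g_r%s", samp$time_h, samp$replicate)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = sig, censored = cen),
    colData = S4Vectors::DataFrame(time_h = samp$time_h,
                                   replicate = samp$replicate,
                                   row.names = colnames(sig))
  )
  md <- if (is.null(groundTruth)) list() else list(groundTruth = groundTruth)
  out <- new("SweatMeasurements", se)
  S4Vectors::metadata(out) <- md
  validObject(out)
  out
}

#' @describeIn SweatMeasurements-accessors distinct sampling times (hours,
#'   increasing)
#' @export
sampleTimes <- function(x) sort(unique(SummarizedExperiment::colData(x)$time_h))

#' Accessors for SweatMeasurements
#'
#' @name SweatMeasurements-accessors
#' @param x A [SweatMeasurements-class] object.
NULL

#' @describeIn SweatMeasurements-accessors signal matrix (species x samples)
#' @export
signalMatrix <- function(x) SummarizedExperiment::assay(x, "signal")

#' @describeIn SweatMeasurements-accessors logical censoring matrix
#' @export
censoredMatrix <- function(x) SummarizedExperiment::assay(x, "censored")

#' @describeIn SweatMeasurements-accessors stored generating ground truth
#'   (or NULL)
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$groundTruth

#' @describeIn SweatMeasurements-accessors back to the tidy table (columns
#'   time_h, time_min, species, replicate, signal, censored)
#' @export
asMeasurementTable <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  sig <- signalMatrix(x)
  cen <- censoredMatrix(x)
  df <- data.frame(
    time_h = rep(cd$time_h, each = 4L),
    time_min = rep(cd$time_h * 60, each = 4L),
    species = rep(SPECIES, times = ncol(x)),
    replicate = rep(cd$replicate, each = 4L),
    signal = as.vector(sig),
    censored = as.integer(as.vector(cen)),
    stringsAsFactors = FALSE
  )
  df[order(df$time_h, df$replicate, match(df$species, SPECIES)), ,
     drop = FALSE]
}

setMethod("show", "SweatMeasurements", function(object) {
  cd <- SummarizedExperiment::colData(object)
  tt <- sort(unique(cd$time_h))
  cat("SweatMeasurements:", ncol(object), "samples,",
      length(tt), "time-points,",
      sprintf("t in [%g, %g] h\n", min(tt), max(tt)))
  ncen <- sum(censoredMatrix(object))
  cat("  censored entries:", ncen, "of", length(censoredMatrix(object)), "\n")
  if (!is.null(groundTruth(object)))
    cat("  carries generating ground truth (synthetic profile)\n")
  invisible(object)
})
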