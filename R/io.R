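## Plain-text and TIFF interchange: per-trial CSV session layout,
## amplitude tables, QC report, 16-bit TIFF stacks.

#' Write / read a session as per-trial CSV files
#'
#' Sessions are stored as a directory with one CSV matrix per trial
#' (\code{<condition>_trial<i>.csv}), a \code{metadata.csv} with the
#' acquisition parameters and a \code{ledger.csv} with the ground-truth
#' ledger.
#'
#' @param session a \linkS4class{GluSession}.
#' @param dir target directory (created if missing).
#' @return \code{writeSessionCsv}: the directory, invisibly;
#'   \code{readSessionCsv}: a \linkS4class{GluSession}.
#' @export
writeSessionCsv <- function(session, dir) {
  stopifnot(is(session, "GluSession"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acq <- session@acq
  meta <- data.frame(field = c("nLines", "nPositions", "stimLine",
                               "lineRate", "kernelTau", "sigma0",
                               "conditions"),
                     value = c(acq@nLines, acq@nPositions, acq@stimLine,
                               acq@lineRate, acq@kernelTau, acq@sigma0,
                               paste(session@conditions, collapse = ";")))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(session@ledger, file.path(dir, "ledger.csv"),
            row.names = FALSE)
  for (cc in session@conditions) {
    mats <- session@trials[[cc]]
    for (i in seq_along(mats))
      write.csv(mats[[i]],
                file.path(dir, sprintf("%s_trial%04d.csv", cc, i)),
                row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeSessionCsv
#' @export
readSessionCsv <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"),
                   colClasses = "character")
  gv <- function(f) meta$value[meta$field == f]
  conditions <- strsplit(gv("conditions"), ";")[[1]]
  ledger <- read.csv(file.path(dir, "ledger.csv"))
  trials <- setNames(lapply(conditions, function(cc) {
    files <- sort(list.files(dir, sprintf("^%s_trial[0-9]+\\.csv$", cc),
                             full.names = TRUE))
    lapply(files, function(f) as.matrix(read.csv(f)))
  }), conditions)
  acq <- acquisitionParams(
    nTrials = length(trials[[1]]), nLines = as.integer(gv("nLines")),
    lineRate = as.numeric(gv("lineRate")),
    nPositions = as.integer(gv("nPositions")),
    stimLine = as.integer(gv("stimLine")),
    kernelTau = as.numeric(gv("kernelTau")),
    sigma0 = as.numeric(gv("sigma0")), artifactRate = 0)
  truth <- if (all(c("condition", "k") %in% names(ledger)) &&
               nrow(ledger))
    gluGroundTruth(nDocked = max(max(ledger$k), 1),
                   pVes = setNames(rep(0.5, length(conditions)),
                                   conditions))
  else gluGroundTruth()
  new("GluSession", conditions = conditions, trials = trials,
      ledger = ledger, acq = acq, truth = truth)
}

#' Write / read an amplitude table as CSV
#'
#' Flat CSV with columns bouton, condition, trial, amplitude, label,
#' reason (and trueK when available).
#'
#' @param ampSet an \linkS4class{AmplitudeSet}.
#' @param file path.
#' @param bouton bouton identifier written into the table.
#' @return \code{writeAmplitudeCsv}: the path, invisibly;
#'   \code{readAmplitudeCsv}: the data.frame.
#' @export
writeAmplitudeCsv <- function(ampSet, file, bouton = "bouton1") {
  tab <- cbind(bouton = bouton, amplitudes(ampSet))
  write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeAmplitudeCsv
#' @export
readAmplitudeCsv <- function(file) read.csv(file)

#' QC report of an amplitude set
#'
#' Summarizes the per-bouton quality-control quantities: baseline noise
#' and FWHM per condition, bleach and template constants, release
#' probability, optional paired-pulse ratio, and the bouton-level QC
#' verdict. Written as JSON when the \pkg{jsonlite} package is
#' available, otherwise returned invisibly.
#'
#' @param ampSet an \linkS4class{AmplitudeSet}.
#' @param file optional JSON path.
#' @return The report list, invisibly.
#' @export
qcReport <- function(ampSet, file = NULL) {
  rep <- list(
    conditions = lapply(setNames(nm = names(ampSet@psyn)), function(cc) {
      nm <- ampSet@noise[[cc]]
      list(sigma0 = if (!is.null(nm)) nm@sigma0 else NA,
           baselineFwhm = if (!is.null(nm)) nm@fwhm else NA,
           qcPass = if (!is.null(nm) && !is.na(nm@fwhm)) qcBouton(nm)
                    else NA,
           pSyn = ampSet@psyn[[cc]],
           ppr = unname(ampSet@ppr[cc]),
           bleachTau = unname(ampSet@bleachTau[cc]),
           nRejected = sum(ampSet@table$condition == cc &
                             ampSet@table$label == "rejected"))
    }),
    templateTau = ampSet@templateTau,
    roi = ampSet@roi)
  if (!is.null(file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing the QC report requires the jsonlite package",
           call. = FALSE)
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rep)
}

#' Write / read a frame-scan stack as multi-page 16-bit TIFF
#'
#' Values are scaled into the 16-bit range; the scale, offset and pixel
#' size are stored in a plain-text sidecar file (\code{<file>.meta}),
#' so \code{readStackTiff} restores the original
#' \eqn{\Delta F/F_0}-scale values.
#'
#' @param stack array (rows x cols x frames) or a
#'   \code{\link{synthesizeFrameScanStack}} result.
#' @param file TIFF path.
#' @return \code{writeStackTiff}: the path, invisibly;
#'   \code{readStackTiff}: the stack array with attribute
#'   \code{"pixelSize"} when stored.
#' @export
writeStackTiff <- function(stack, file) {
  ps <- NA_real_
  if (is.list(stack)) { ps <- stack$pixelSize; stack <- stack$stack }
  hi <- max(stack)
  lo <- min(stack)
  scl <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f)
    (stack[, , f] - lo) / scl)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  writeLines(sprintf("lo=%.8g;scale=%.8g;pixelSize=%.8g", lo, scl, ps),
             paste0(file, ".meta"))
  invisible(file)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  meta <- paste0(file, ".meta")
  info <- if (file.exists(meta)) readLines(meta, n = 1L) else NULL
  lo <- 0; scl <- 1; ps <- NA_real_
  if (!is.null(info)) {
    kv <- strsplit(strsplit(info, ";")[[1]], "=")
    for (p in kv) {
      if (p[1] == "lo") lo <- as.numeric(p[2])
      if (p[1] == "scale") scl <- as.numeric(p[2])
      if (p[1] == "pixelSize") ps <- as.numeric(p[2])
    }
  }
  arr <- simplify2array(lapply(pages, function(p) p * scl + lo))
  attr(arr, "pixelSize") <- ps
  arr
}
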