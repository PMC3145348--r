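## Raster conventions shared by every module: a raster is a plain numeric
## matrix indexed (row, col), 0-based pixel coordinates when exported,
## intensities in [0,1]; a label raster is an integer matrix with background
## 0 and consecutive object labels 1..n.

checkIntensityRaster <- function(x, what = "raster") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (nrow(x) < 1 || ncol(x) < 1)
    stop(what, " must be at least 1x1")
  if (any(!is.finite(x)))
    stop(what, " contains non-finite pixels")
  if (min(x) < 0 || max(x) > 1)
    stop(what, " intensities must lie in [0,1]")
  invisible(x)
}

## Labels run 1..n for primary segmentation outputs; derived compartments
## (e.g. a cytoplasm that collapsed onto its nucleus) may legitimately
## have empty labels, which downstream measurements report as missing — so
## only non-negativity is enforced here.
checkLabelRaster <- function(x, what = "labels") {
  if (!is.matrix(x)) stop(what, " must be a matrix")
  storage.mode(x) <- "integer"
  if (any(is.na(x)) || any(x < 0L)) stop(what, " must be non-negative integers")
  x
}

nObjects <- function(labels) max(0L, max(labels))

#' Normalize control labels
#'
#' Case-insensitive mapping of free-text control annotations onto
#' \code{"positive"}, \code{"negative"} or \code{"sample"}. The default
#' alias map accepts \code{positive/pos/p} and \code{negative/neg/n};
#' anything else is a sample well.
#'
#' @param x character vector of control annotations
#' @param aliases named list with elements \code{positive} and
#'   \code{negative}, each a character vector of accepted aliases
#' @return character vector of normalized labels
#' @export
normalizeControl <- function(x,
    aliases = list(positive = c("positive", "pos", "p"),
                   negative = c("negative", "neg", "n"))) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep("sample", length(lx))
  out[lx %in% tolower(aliases$positive)] <- "positive"
  out[lx %in% tolower(aliases$negative)] <- "negative"
  out
}

#' Load a plate-map metadata table as a ScreenExperiment
#'
#' Reads a CSV plate map with one row per image set and validates it. The
#' table must provide \code{set_id}, one \code{path_<channel>} column per
#' requested channel, and \code{plate}, \code{well}, \code{compound},
#' \code{dose}, \code{control} columns (\code{cell_type} optional).
#' Control annotations are normalized case-insensitively
#' (\code{\link{normalizeControl}}). Control wells with a missing dose get
#' a defaulted dose so dose-series grouping always has endpoints: 0 for
#' negative controls, the maximum observed dose for positive controls;
#' such rows are flagged in the \code{dose_defaulted} column.
#'
#' @param path CSV file path
#' @param channelNames character vector of channel names (first = DNA)
#' @param aliases control alias map passed to \code{\link{normalizeControl}}
#' @return a \code{\linkS4class{ScreenExperiment}}; record order equals row
#'   order in the file
#' @export
loadExperiment <- function(path, channelNames,
    aliases = list(positive = c("positive", "pos", "p"),
                   negative = c("negative", "neg", "n"))) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  # keep dose as text so parse failures can be reported with context
  cc <- if ("dose" %in% hdr) c(dose = "character") else NA
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = cc, check.names = FALSE)
  if (nrow(tab) == 0) stop("metadata table is empty: ", path)
  need <- c("set_id", paste0("path_", channelNames), "plate", "well",
            "compound", "dose", "control")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metadata table lacks required column(s): ",
         paste(miss, collapse = ", "))
  dup <- tab$set_id[duplicated(tab$set_id)]
  if (length(dup))
    stop("duplicate set_id in metadata: ", paste(unique(dup), collapse = ", "))
  doseRaw <- trimws(tab$dose)
  dose <- suppressWarnings(as.numeric(doseRaw))
  bad <- which(!is.na(doseRaw) & doseRaw != "" & is.na(dose))
  if (length(bad))
    stop("unparseable dose at metadata row ", bad[1],
         " (set_id ", tab$set_id[bad[1]], "): '", doseRaw[bad[1]], "'")
  if (any(!is.na(dose) & dose < 0)) {
    bad <- which(!is.na(dose) & dose < 0)[1]
    stop("negative dose at metadata row ", bad, " (set_id ",
         tab$set_id[bad], ")")
  }
  control <- normalizeControl(tab$control, aliases)
  defaulted <- is.na(dose) & control != "sample"
  if (any(is.na(dose) & control == "sample")) {
    bad <- which(is.na(dose) & control == "sample")[1]
    stop("missing dose for sample well at metadata row ", bad,
         " (set_id ", tab$set_id[bad], ")")
  }
  maxDose <- if (all(is.na(dose))) 1 else max(dose, na.rm = TRUE)
  dose[defaulted & control == "negative"] <- 0
  dose[defaulted & control == "positive"] <- maxDose
  rec <- data.frame(set_id = as.character(tab$set_id),
                    plate = as.character(tab$plate),
                    well = as.character(tab$well),
                    compound = as.character(tab$compound),
                    dose = dose, control = control,
                    cell_type = if ("cell_type" %in% names(tab))
                      as.character(tab$cell_type) else NA_character_,
                    dose_defaulted = defaulted,
                    stringsAsFactors = FALSE)
  for (ch in channelNames) {
    p <- as.character(tab[[paste0("path_", ch)]])
    rel <- !is.na(p) & !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(dirname(normalizePath(path)), p[rel])
    rec[[paste0("path_", ch)]] <- p
  }
  new("ScreenExperiment", records = rec, channelNames = channelNames)
}

#' Read a grayscale image as an intensity raster
#'
#' Reads an 8- or 16-bit single-plane grayscale TIFF or PNG and scales
#' integer pixel values by the dtype maximum (255 or 65535) into [0,1].
#' Normalizing by the dtype maximum rather than the observed maximum keeps
#' intensities comparable across images, which illumination correction and
#' every intensity feature rely on.
#'
#' @param path image file path
#' @return numeric matrix in [0,1], indexed (row, col)
#' @export
readImageRaster <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png"))
    stop("unsupported image format '", ext, "' for ", path,
         " (TIFF and PNG are supported)")
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2 && !all(d[-(1:2)] == 1))
    stop("multi-channel or multi-frame image not supported: ", path)
  # EBImage stores images x-by-y; transpose to (row, col)
  m <- t(array(as.numeric(EBImage::imageData(img)), dim = d[1:2]))
  if (any(!is.finite(m))) stop("non-finite pixels in ", path)
  if (min(m) < 0 || max(m) > 1)
    stop("pixel values outside the dtype range in ", path)
  m
}

writeImageRaster <- function(raster, path, bits = 16L) {
  img <- EBImage::Image(t(raster))
  EBImage::writeImage(img, path, type = tolower(tools::file_ext(path)),
                      bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write / read a feature table
#'
#' A feature table is a data.frame whose first column(s) identify the row
#' (per-image tables: \code{set_id}; per-object tables: \code{set_id} and
#' \code{label}) followed by named feature columns. Written as CSV with
#' missing values as empty fields at 17 significant digits, so a read-back
#' reproduces the table bit-for-bit.
#'
#' @param table data.frame feature table, non-empty
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeFeatureTable <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("feature table must be a non-empty data.frame")
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) {
    v <- out[[j]]
    s <- vapply(v, function(x)
      if (is.na(x)) "" else sprintf("%.17g", x), character(1))
    out[[j]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @param idCols names of identifier columns kept as character
#' @export
readFeatureTable <- function(path, idCols = intersect(
    c("set_id", "compartment", "label"), names(utils::read.csv(path, nrows = 1)))) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(tab)) {
    if (nm %in% idCols) tab[[nm]] <- as.character(tab[[nm]])
    else tab[[nm]] <- as.numeric(tab[[nm]])
  }
  if ("label" %in% names(tab)) tab$label <- as.integer(tab$label)
  tab
}

#' Write a quality report as CSV
#'
#' Columns \code{feature}, \code{category}, \code{zprime}, \code{vfactor},
#' \code{band}, \code{rank}, rows in rank order.
#'
#' @param report a \code{\linkS4class{QualityReport}}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "QualityReport"))
  sc <- report@scores
  out <- sc[, c("feature", "category", "zprime", "vfactor", "band", "rank")]
  for (j in c("zprime", "vfactor"))
    out[[j]] <- vapply(out[[j]], function(x)
      if (is.na(x)) "" else sprintf("%.17g", x), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$zprime <- as.numeric(tab$zprime)
  tab$vfactor <- as.numeric(tab$vfactor)
  tab
}
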