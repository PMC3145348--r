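#' @useDynLib assayScreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' ScreenExperiment: an image-set collection with plate metadata
#'
#' Container for the records of a screening experiment: one row per image
#' set, each holding the file path of every channel plus plate, well,
#' compound, dose and control-status metadata.
#'
#' @slot records data.frame with one row per image set; columns
#'   \code{set_id}, one \code{path_<channel>} column per channel,
#'   \code{plate}, \code{well}, \code{compound}, \code{dose} (numeric,
#'   non-negative), \code{control} (one of \code{"positive"},
#'   \code{"negative"}, \code{"sample"}), \code{cell_type} and
#'   \code{dose_defaulted} (logical, TRUE where a missing control dose was
#'   filled in).
#' @slot channelNames character vector of channel names, in order; the
#'   first channel is taken to be the DNA stain.
#'
#' @export
setClass("ScreenExperiment",
  representation(records = "data.frame", channelNames = "character"))

setValidity("ScreenExperiment", function(object) {
  rec <- object@records
  ch <- object@channelNames
  msgs <- character(0)
  if (length(ch) < 1) msgs <- c(msgs, "at least one channel name required")
  if (nrow(rec) < 1) msgs <- c(msgs, "at least one image-set record required")
  need <- c("set_id", paste0("path_", ch), "plate", "well", "compound",
            "dose", "control")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    msgs <- c(msgs, paste("missing record columns:", paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(rec$set_id))
      msgs <- c(msgs, "set_id values must be unique")
    if (!is.numeric(rec$dose) || any(!is.na(rec$dose) & rec$dose < 0))
      msgs <- c(msgs, "dose must be numeric and non-negative")
    if (!all(rec$control %in% c("positive", "negative", "sample")))
      msgs <- c(msgs, "control must be positive/negative/sample")
  }
  if (length(msgs)) msgs else TRUE
})

#' IlluminationFunction: a smooth per-channel shading surface
#'
#' The illumination function of a channel: the median-smoothed average of
#' all of that channel's images, normalized to mean 1. Raw images are
#' divided by this surface before measurement.
#'
#' @slot surface numeric matrix, strictly positive, mean 1
#' @slot channel channel name the surface was estimated for
#' @slot filterSize odd integer, the median-filter window side length
#'
#' @export
setClass("IlluminationFunction",
  representation(surface = "matrix", channel = "character",
                 filterSize = "integer"))

setValidity("IlluminationFunction", function(object) {
  s <- object@surface
  msgs <- character(0)
  if (!is.numeric(s) || length(dim(s)) != 2)
    msgs <- c(msgs, "surface must be a 2-D numeric matrix")
  else {
    if (any(!is.finite(s)) || min(s) <= 0)
      msgs <- c(msgs, "surface must be finite and strictly positive")
    if (abs(mean(s) - 1) > 1e-9)
      msgs <- c(msgs, "surface must have mean 1")
  }
  if (length(object@filterSize) != 1L || object@filterSize %% 2L != 1L)
    msgs <- c(msgs, "filterSize must be a single odd integer")
  if (length(msgs)) msgs else TRUE
})

#' QualityReport: ranked per-feature assay-quality scores
#'
#' One row per screened feature with its Z-prime factor, V factor, the
#' ranking score actually used, the quality band and the rank. Invalid
#' scores (constant or all-missing features, zero control separation) are
#' NA and rank last.
#'
#' @slot scores data.frame with columns \code{feature}, \code{category},
#'   \code{zprime}, \code{vfactor}, \code{score}, \code{band} (one of
#'   \code{"excellent"}, \code{"screenable"}, \code{"not screenable"},
#'   \code{"invalid"}), \code{rank}; rows in rank order.
#' @slot scoreType which statistic ranked the features ("zprime" or
#'   "vfactor")
#'
#' @export
setClass("QualityReport",
  representation(scores = "data.frame", scoreType = "character"))

setValidity("QualityReport", function(object) {
  sc <- object@scores
  need <- c("feature", "category", "zprime", "vfactor", "score", "band", "rank")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    return(paste("missing score columns:", paste(miss, collapse = ", ")))
  if (nrow(sc)) {
    if (is.unsorted(sc$rank)) return("rows must be in rank order")
    fin <- is.finite(sc$score)
    if (any(which(!fin) < max(c(0, which(fin)))))
      return("invalid scores must rank after all finite scores")
    if (!all(sc$band %in% c("excellent", "screenable", "not screenable", "invalid")))
      return("unknown band value")
  }
  TRUE
})

#' @describeIn ScreenExperiment number of image sets
#' @param x,object a \code{ScreenExperiment}
#' @export
setMethod("length", "ScreenExperiment", function(x) nrow(x@records))

setMethod("show", "ScreenExperiment", function(object) {
  rec <- object@records
  cat("ScreenExperiment with", nrow(rec), "image sets,",
      length(object@channelNames), "channels (",
      paste(object@channelNames, collapse = ", "), ")\n")
  cat("  controls:", sum(rec$control == "positive"), "positive,",
      sum(rec$control == "negative"), "negative,",
      sum(rec$control == "sample"), "sample\n")
  cat("  doses:", paste(signif(sort(unique(rec$dose)), 3), collapse = " "), "\n")
})

setMethod("show", "IlluminationFunction", function(object) {
  cat("IlluminationFunction for channel '", object@channel, "': ",
      nrow(object@surface), "x", ncol(object@surface),
      ", median window ", object@filterSize,
      ", range [", signif(min(object@surface), 4), ", ",
      signif(max(object@surface), 4), "]\n", sep = "")
})

setMethod("show", "QualityReport", function(object) {
  sc <- object@scores
  cat("QualityReport:", nrow(sc), "features ranked by", object@scoreType, "\n")
  cat("  bands:", sum(sc$band == "excellent"), "excellent,",
      sum(sc$band == "screenable"), "screenable,",
      sum(sc$band == "not screenable"), "not screenable,",
      sum(sc$band == "invalid"), "invalid\n")
  if (nrow(sc)) {
    top <- utils::head(sc[, c("feature", "category", "zprime", "vfactor", "band")], 5)
    print(top, row.names = FALSE)
  }
})

#' Accessors
#'
#' @param x a \code{ScreenExperiment}, \code{IlluminationFunction} or
#'   \code{QualityReport}
#' @name accessors
NULL

#' @rdname accessors
#' @export
records <- function(x) {
  stopifnot(is(x, "ScreenExperiment"))
  x@records
}

#' @rdname accessors
#' @export
channelNames <- function(x) {
  stopifnot(is(x, "ScreenExperiment"))
  x@channelNames
}

#' @rdname accessors
#' @export
setIds <- function(x) {
  stopifnot(is(x, "ScreenExperiment"))
  x@records$set_id
}

#' @rdname accessors
#' @export
surface <- function(x) {
  stopifnot(is(x, "IlluminationFunction"))
  x@surface
}

#' @rdname accessors
#' @export
scores <- function(x) {
  stopifnot(is(x, "QualityReport"))
  x@scores
}

#' Path of one channel's image for given image sets
#'
#' @param x a \code{ScreenExperiment}
#' @param set_id image-set identifier(s); default all
#' @param channel channel name
#' @return character vector of file paths
#' @export
channelPaths <- function(x, channel, set_id = setIds(x)) {
  stopifnot(is(x, "ScreenExperiment"), channel %in% x@channelNames)
  rec <- x@records[match(set_id, x@records$set_id), , drop = FALSE]
  if (anyNA(rec$set_id)) stop("unknown set_id")
  rec[[paste0("path_", channel)]]
}
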