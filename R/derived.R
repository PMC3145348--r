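#' Per-object ratio feature
#'
#' Adds the per-object ratio of two existing features to a per-object
#' feature table — e.g. cytoplasm over nucleus mean intensity, the classic
#' translocation readout (with that direction, translocation into the
#' nucleus lowers the ratio). A zero or missing denominator yields a
#' missing value, never infinity. The new column is named
#' \code{Derived_Ratio_<numerator>_over_<denominator>}.
#'
#' @param perObj per-object feature table (columns \code{set_id},
#'   \code{label}, features); compartment features of the same cell share
#'   the cell's label, so the ratio joins per object by construction
#' @param numerator,denominator existing feature column names
#' @return \code{perObj} with the new column appended
#' @export
ratioFeature <- function(perObj, numerator, denominator) {
  for (f in c(numerator, denominator))
    if (!f %in% names(perObj)) stop("unknown feature: ", f)
  num <- perObj[[numerator]]
  den <- perObj[[denominator]]
  val <- ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
  perObj[[paste0("Derived_Ratio_", numerator, "_over_", denominator)]] <- val
  perObj
}

#' Per-image classified fraction
#'
#' The fraction of objects in each image whose feature value is strictly
#' above a threshold, among objects with a non-missing value (the fraction
#' of responding cells). Ties at the threshold fall below. Images
#' with no valid object are missing. The result column is named
#' \code{Derived_Classified_<feature>_gt_<threshold>}.
#'
#' @param perObj per-object feature table with a \code{set_id} column
#' @param feature feature column name
#' @param threshold classification threshold
#' @param setIds image sets to report (default: those present); sets with
#'   no objects appear with a missing value
#' @return data.frame with columns \code{set_id} and the classified
#'   fraction
#' @export
classifyFraction <- function(perObj, feature, threshold,
                             setIds = unique(perObj$set_id)) {
  if (!feature %in% names(perObj)) stop("unknown feature: ", feature)
  v <- perObj[[feature]]
  out <- data.frame(set_id = setIds, stringsAsFactors = FALSE)
  frac <- vapply(setIds, function(s) {
    vs <- v[perObj$set_id == s]
    vs <- vs[!is.na(vs)]
    if (!length(vs)) NA_real_ else sum(vs > threshold) / length(vs)
  }, numeric(1))
  out[[sprintf("Derived_Classified_%s_gt_%g", feature, threshold)]] <- frac
  out
}

#' Aggregate per-object features to one row per image
#'
#' For every feature column, records the per-image mean and median over
#' non-missing values (columns \code{Mean_<feature>} and
#' \code{Median_<feature>}), plus an object count. Images listed in
#' \code{setIds} but absent from the table get a row of missing values
#' with count 0.
#'
#' @param perObj per-object feature table (columns \code{set_id},
#'   \code{label}, features)
#' @param setIds image sets to report
#' @param countName name of the object-count column
#' @return per-image feature table, one row per \code{setIds} entry, in
#'   that order
#' @export
aggregatePerImage <- function(perObj, setIds = unique(perObj$set_id),
                              countName = "ObjectCount") {
  featCols <- setdiff(names(perObj),
                      c("set_id", "label", "compartment", "parent"))
  out <- data.frame(set_id = setIds, stringsAsFactors = FALSE)
  out[[countName]] <- vapply(setIds, function(s)
    sum(perObj$set_id == s), numeric(1))
  for (f in featCols) {
    v <- perObj[[f]]
    out[[paste0("Mean_", f)]] <- vapply(setIds, function(s) {
      vs <- v[perObj$set_id == s]
      vs <- vs[!is.na(vs)]
      if (!length(vs)) NA_real_ else mean(vs)
    }, numeric(1))
    out[[paste0("Median_", f)]] <- vapply(setIds, function(s) {
      vs <- v[perObj$set_id == s]
      vs <- vs[!is.na(vs)]
      if (!length(vs)) NA_real_ else stats::median(vs)
    }, numeric(1))
  }
  out
}
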