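#' Z-prime factor
#'
#' Z' = 1 - 3 (s_pos + s_neg) / |m_pos - m_neg| with sample standard
#' deviations: how well separated the positive and negative controls are
#' given the variation in both populations. 1 is perfect separation; values
#' at or below 0 mean overlapping controls. Equal group means make the
#' statistic undefined (NA). The statistic is symmetric in its arguments
#' and invariant under affine transforms of the data.
#'
#' @param pos,neg numeric vectors of the feature over positive and negative
#'   control images, at least 2 finite values each
#' @return Z' factor, or NA when the group means coincide
#' @export
zPrime <- function(pos, neg) {
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 finite values per control group")
  sep <- abs(mean(pos) - mean(neg))
  if (sep == 0) return(NA_real_)
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / sep
}

#' V factor
#'
#' Generalizes the Z-prime factor to a whole dose-response series:
#' V = 1 - 6 * mean_d(s_d) / |m_high - m_low|, where s_d is the sample SD
#' within dose group d and m_high, m_low are the mean responses at the
#' highest and lowest dose. With exactly two dose groups this reduces
#' algebraically to the Z-prime factor of the same data (6 times the mean
#' of two SDs equals 3 times their sum). A variant measuring variability
#' around a fitted four-parameter logistic dose-response curve is available
#' (\code{method = "fit_residual"}; residual SD pooled over all points
#' replaces the per-dose SDs); the per-dose-SD form is the default as it
#' involves no curve-fit convergence edge cases.
#'
#' @param groups named list: dose (coerced numeric from the names) ->
#'   numeric vector of responses; at least 2 groups with at least 2 values
#'   each
#' @param method \code{"per_dose_sd"} (default) or \code{"fit_residual"}
#' @return V factor, or NA when the extreme dose means coincide
#' @export
vFactor <- function(groups, method = c("per_dose_sd", "fit_residual")) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 dose groups")
  doses <- suppressWarnings(as.numeric(names(groups)))
  if (any(is.na(doses))) stop("group names must be numeric doses")
  if (any(vapply(groups, function(g) sum(is.finite(g)), 0L) < 2))
    stop("every dose group needs at least 2 finite values")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  means <- vapply(groups, mean, numeric(1))
  rng <- abs(unname(means[which.max(doses)] - means[which.min(doses)]))
  if (rng == 0) return(NA_real_)
  if (method == "per_dose_sd") {
    sds <- vapply(groups, stats::sd, numeric(1))
    return(1 - 6 * mean(sds) / rng)
  }
  x <- rep(doses, lengths(groups))
  y <- unlist(groups, use.names = FALSE)
  fit <- tryCatch({
    lo0 <- means[which.min(doses)]; hi0 <- means[which.max(doses)]
    ec0 <- max(stats::median(doses[doses > 0]), min(doses[doses > 0]))
    stats::nls(y ~ lo + (hi - lo) * ifelse(x == 0, 0,
                 x^h / (ec^h + x^h)),
               start = list(lo = lo0, hi = hi0, ec = ec0, h = 1),
               control = stats::nls.control(warnOnly = TRUE))
  }, error = function(e) NULL)
  s <- if (is.null(fit)) {
    sds <- vapply(groups, stats::sd, numeric(1))
    mean(sds)
  } else stats::sd(stats::resid(fit))
  1 - 6 * s / rng
}

## Category = second token of the feature-name grammar
## Compartment_Category_Name_Channel[_scale], after stripping a Mean_ or
## Median_ aggregation prefix; Derived features report Ratio / Classified.
featureCategory <- function(feature) {
  base <- sub("^(Mean|Median)_", "", feature)
  parts <- strsplit(base, "_", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], character(1))
}

#' Control and dose-series specification
#'
#' Extracts from an experiment's metadata which image sets are positive and
#' negative controls and how all image sets group into dose series.
#'
#' @param experiment a \code{\linkS4class{ScreenExperiment}}
#' @return list with \code{positive}, \code{negative} (set_id vectors),
#'   \code{dose} (named numeric vector over all set_ids) and
#'   \code{doseGroups} (list: dose value -> set_ids)
#' @export
controlSpec <- function(experiment) {
  rec <- records(experiment)
  pos <- rec$set_id[rec$control == "positive"]
  neg <- rec$set_id[rec$control == "negative"]
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 positive and 2 negative control image sets")
  dose <- stats::setNames(rec$dose, rec$set_id)
  groups <- split(rec$set_id, rec$dose)
  list(positive = pos, negative = neg, dose = dose, doseGroups = groups)
}

#' Screen every feature with Z-prime and V factors
#'
#' Scores each feature column of a per-image feature table: the Z-prime
#' factor from the positive/negative control rows and the V factor from
#' the dose groups (dose groups with fewer than 2 non-missing values are
#' dropped for that feature). Features are banded on the ranking score by
#' the conventional cutoffs — above 0.5 "excellent", above 0 "screenable" — and
#' ranked descending with deterministic name tie-breaks; constant or
#' all-missing features are invalid and rank last.
#'
#' @param table per-image feature table (column \code{set_id} plus feature
#'   columns)
#' @param spec a \code{\link{controlSpec}} result
#' @param score ranking statistic: \code{"auto"} (V factor when at least 3
#'   dose groups exist, else Z-prime), \code{"zprime"} or \code{"vfactor"}
#' @return a \code{\linkS4class{QualityReport}}
#' @export
screenFeatures <- function(table, spec, score = c("auto", "zprime", "vfactor")) {
  score <- match.arg(score)
  if (!"set_id" %in% names(table)) stop("table needs a set_id column")
  ids <- table$set_id
  if (!all(c(spec$positive, spec$negative) %in% ids))
    stop("feature table does not cover all control image sets")
  featCols <- names(table)[vapply(table, is.numeric, logical(1))]
  nGroups <- length(spec$doseGroups)
  scoreType <- switch(score, auto = if (nGroups >= 3) "vfactor" else "zprime",
                      score)
  posI <- ids %in% spec$positive
  negI <- ids %in% spec$negative
  zp <- vf <- rep(NA_real_, length(featCols))
  for (i in seq_along(featCols)) {
    v <- table[[featCols[i]]]
    p <- v[posI]; n <- v[negI]
    if (sum(is.finite(p)) >= 2 && sum(is.finite(n)) >= 2)
      zp[i] <- zPrime(p, n)
    g <- lapply(spec$doseGroups, function(s) {
      x <- v[ids %in% s]
      x[is.finite(x)]
    })
    g <- g[lengths(g) >= 2]
    if (length(g) >= 2) {
      d <- as.numeric(names(g))
      if (abs(mean(g[[which.max(d)]]) - mean(g[[which.min(d)]])) > 0)
        vf[i] <- vFactor(g)
    }
  }
  sc <- data.frame(feature = featCols,
                   category = featureCategory(featCols),
                   zprime = zp, vfactor = vf,
                   stringsAsFactors = FALSE)
  sc$score <- if (scoreType == "vfactor") sc$vfactor else sc$zprime
  sc$band <- ifelse(is.na(sc$score), "invalid",
             ifelse(sc$score > 0.5, "excellent",
             ifelse(sc$score > 0, "screenable", "not screenable")))
  o <- order(is.na(sc$score), -ifelse(is.na(sc$score), -Inf, sc$score),
             sc$feature)
  sc <- sc[o, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  rownames(sc) <- NULL
  new("QualityReport", scores = sc, scoreType = scoreType)
}

#' Best feature per category
#'
#' @param report a \code{\linkS4class{QualityReport}}
#' @return data.frame with the top-ranked feature of every category, in
#'   rank order
#' @export
bestByCategory <- function(report) {
  stopifnot(is(report, "QualityReport"))
  sc <- scores(report)
  sc[!duplicated(sc$category), , drop = FALSE]
}

#' Train/test validation of feature selection
#'
#' Guards against selection overfitting: control image sets are split into
#' a training and a held-out test set (seeded uniform draw, stratified by
#' control class), features are ranked by training-set Z-prime, and the top
#' features' Z-prime is re-evaluated on the held-out controls. A feature
#' whose quality holds up on data that played no part in selecting it is
#' trustworthy; noise-selected features regress toward the mean.
#'
#' @param table per-image feature table
#' @param spec a \code{\link{controlSpec}} result
#' @param holdoutFraction fraction of each control class held out for
#'   testing, in (0,1); both halves must keep at least 2 sets per class
#' @param seed integer seed making the split deterministic
#' @param topK number of top training features to validate
#' @return list with \code{validation} (data.frame: feature, category,
#'   train_zprime, test_zprime), \code{train} and \code{test} (the set_id
#'   splits)
#' @export
splitValidate <- function(table, spec, holdoutFraction = 0.5, seed = 1L,
                          topK = 5L) {
  stopifnot(holdoutFraction > 0, holdoutFraction < 1)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  splitClass <- function(idsAll) {
    nTest <- round(length(idsAll) * holdoutFraction)
    if (nTest < 2 || length(idsAll) - nTest < 2)
      stop("holdout split leaves fewer than 2 controls in a group")
    test <- sort(sample(idsAll, nTest))
    list(train = setdiff(idsAll, test), test = test)
  }
  sp <- splitClass(spec$positive)
  sn <- splitClass(spec$negative)
  ids <- table$set_id
  featCols <- names(table)[vapply(table, is.numeric, logical(1))]
  zOn <- function(posIds, negIds) {
    vapply(featCols, function(f) {
      p <- table[[f]][ids %in% posIds]
      n <- table[[f]][ids %in% negIds]
      if (sum(is.finite(p)) < 2 || sum(is.finite(n)) < 2) return(NA_real_)
      zPrime(p, n)
    }, numeric(1))
  }
  zTrain <- zOn(sp$train, sn$train)
  o <- order(is.na(zTrain), -ifelse(is.na(zTrain), -Inf, zTrain), featCols)
  top <- utils::head(o[!is.na(zTrain[o])], topK)
  zTest <- zOn(sp$test, sn$test)[top]
  list(validation = data.frame(feature = featCols[top],
                               category = featureCategory(featCols[top]),
                               train_zprime = zTrain[top],
                               test_zprime = unname(zTest),
                               stringsAsFactors = FALSE),
       train = c(sp$train, sn$train),
       test = c(sp$test, sn$test))
}
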