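#' Default pipeline configuration
#'
#' The full configuration tree with every tunable of the measurement
#' pipeline. Dilation distances and classification thresholds are lists
#' screened in parallel: every value fans out into its own compartment /
#' feature-name suffix rather than a separate run.
#'
#' @return nested named list
#' @export
defaultConfig <- function() {
  list(
    channels = c("dna", "green"),
    illumination = list(enabled = TRUE, filter_size = 151L),
    nucleus = list(threshold_method = "otsu_global", min_area = 40,
                   max_area = 5000, declump = FALSE, smoothing_sigma = 1,
                   connectivity = 4L, remove_border = TRUE),
    cell = list(method = "propagate", threshold = "otsu",
                regularization = 0.05, distance = 15),
    dilations = c(5, 10, 15),
    texture = list(offsets = c(1L, 3L, 5L), levels = 8L),
    radial = list(bins = 4L, wedges = 8L),
    speckles = list(enabled = FALSE, element_radius = 4L, min_area = 6,
                    max_area = 400, per_object = TRUE,
                    min_threshold = 0.1),
    derived = list(ratios = NULL, classify_thresholds = c(0.5, 1, 2)),
    screen = list(score = "auto", holdout = NULL, top_k = 5L),
    seed = 1L
  )
}

mergeConfig <- function(def, usr, path = "") {
  for (key in names(usr)) {
    kp <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(def))
      stop("unknown configuration key: ", kp)
    if (is.list(def[[key]]) && !is.null(usr[[key]])) {
      if (!is.list(usr[[key]]) && !(key == "derived"))
        stop("configuration key ", kp, " must be a mapping")
      def[[key]] <- mergeConfig(def[[key]], usr[[key]], kp)
    } else {
      def[[key]] <- usr[[key]]
    }
  }
  def
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path, a nested list or NULL, fills every default
#' from \code{\link{defaultConfig}}, rejects unknown keys (naming the key
#' path), and normalizes values: an even illumination filter size is bumped
#' to the next odd value (a median window needs a center pixel) with a
#' message.
#'
#' @param config YAML file path, named list of overrides, or NULL
#' @return fully populated configuration list
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list, YAML path, or NULL")
  cfg <- mergeConfig(defaultConfig(), config)
  cfg$channels <- as.character(unlist(cfg$channels))
  if (length(cfg$channels) < 2)
    stop("configuration needs at least 2 channels (DNA first)")
  fs <- as.integer(cfg$illumination$filter_size)
  if (fs %% 2L == 0L) {
    message("illumination.filter_size ", fs, " is even; using ", fs + 1L)
    fs <- fs + 1L
  }
  if (fs < 3L) stop("illumination.filter_size must be >= 3")
  cfg$illumination$filter_size <- fs
  cfg$dilations <- as.numeric(unlist(cfg$dilations))
  if (any(cfg$dilations < 0)) stop("dilations must be non-negative")
  cfg$texture$offsets <- as.integer(unlist(cfg$texture$offsets))
  if (any(cfg$texture$offsets < 1)) stop("texture.offsets must be >= 1")
  if (cfg$texture$levels < 2) stop("texture.levels must be >= 2")
  if (!cfg$cell$method %in% c("propagate", "dilate"))
    stop("cell.method must be 'propagate' or 'dilate'")
  if (cfg$radial$bins < 1 || cfg$radial$wedges < 2)
    stop("radial.bins must be >= 1 and radial.wedges >= 2")
  cfg$derived$classify_thresholds <-
    as.numeric(unlist(cfg$derived$classify_thresholds))
  cfg
}

nucleusParamsFromConfig <- function(cfg) {
  n <- cfg$nucleus
  segmentationParams(thresholdMethod = n$threshold_method,
                     minArea = n$min_area, maxArea = n$max_area,
                     declump = isTRUE(n$declump),
                     smoothingSigma = n$smoothing_sigma,
                     connectivity = as.integer(n$connectivity),
                     removeBorder = isTRUE(n$remove_border))
}

## Measurement tables are sized by the highest label present; compartments
## with empty trailing objects (e.g. collapsed cytoplasm of the last cell)
## come back short, so pad to the seed count with missing rows.
padRows <- function(df, n) {
  out <- df[match(seq_len(n), df$label), , drop = FALSE]
  out$label <- seq_len(n)
  rownames(out) <- NULL
  out
}

renameStats <- function(df, compartment, category, channel = NULL,
                        scale = NULL) {
  statCols <- setdiff(names(df), "label")
  nm <- gsub("_", "", statCols)  # FracAtD_1 -> FracAtD1
  nm <- paste(compartment, category, nm, sep = "_")
  if (!is.null(channel)) nm <- paste(nm, channel, sep = "_")
  if (!is.null(scale)) nm <- paste(nm, scale, sep = "_")
  names(df)[match(statCols, names(df))] <- nm
  df
}

#' Measure the full feature library on one image set
#'
#' Segments nuclei from the DNA channel, derives the other compartments
#' (propagated or dilated whole cell, cytoplasm, and a dilated
#' nucleus + ring pair per configured dilation distance), then measures
#' shape, per-channel intensity, Haralick texture at every configured
#' offset, radial distribution and channel correlation in every
#' compartment; optionally detects speckles (top-hat + per-object Otsu)
#' and measures them. Feature names follow
#' \code{Compartment_Category_Name_Channel[_scale]}.
#'
#' @param rasters named list of intensity rasters, one per configured
#'   channel (DNA first)
#' @param cfg validated configuration (\code{\link{validateConfig}})
#' @param setId image-set identifier stamped on the rows
#' @return list with \code{cells} (per-object table over all cell
#'   compartments; one row per cell), \code{speckles} (per-speckle table
#'   or NULL) and \code{image} (one-row table of image-level features)
#' @export
measureImageSet <- function(rasters, cfg = validateConfig(), setId = "set1") {
  chans <- cfg$channels
  stopifnot(all(chans %in% names(rasters)))
  dna <- rasters[[chans[1]]]
  green <- rasters[[chans[2]]]
  nuclei <- segmentNuclei(dna, nucleusParamsFromConfig(cfg))
  n <- nObjects(nuclei)
  if (n == 0)
    return(list(cells = NULL, speckles = NULL,
                image = data.frame(set_id = setId, stringsAsFactors = FALSE)))
  cells <- if (cfg$cell$method == "propagate") {
    thr <- cfg$cell$threshold
    if (identical(thr, "otsu")) {
      thr <- otsuOrNA(as.vector(green))
      if (is.na(thr)) thr <- 1
    }
    propagateCells(nuclei, green, thr, cfg$cell$regularization)
  } else {
    dilateObjects(nuclei, cfg$cell$distance)
  }
  comps <- list(Nucleus = nuclei, Cell = cells,
                Cytoplasm = subtractCompartment(cells, nuclei))
  for (d in cfg$dilations) {
    dil <- dilateObjects(nuclei, d)
    comps[[sprintf("Dilated%g", d)]] <- dil
    comps[[sprintf("Ring%g", d)]] <- subtractCompartment(dil, nuclei)
  }
  out <- data.frame(set_id = setId, label = seq_len(n),
                    stringsAsFactors = FALSE)
  for (cn in names(comps)) {
    lab <- comps[[cn]]
    sh <- renameStats(padRows(measureShape(lab), n), cn, "Shape")
    out <- cbind(out, sh[, setdiff(names(sh), "label"), drop = FALSE])
    for (ch in chans) {
      r <- rasters[[ch]]
      it <- renameStats(padRows(measureIntensity(lab, r), n),
                        cn, "Intensity", ch)
      out <- cbind(out, it[, setdiff(names(it), "label"), drop = FALSE])
      for (off in cfg$texture$offsets) {
        tx <- renameStats(padRows(measureTexture(lab, r, off,
                                                 cfg$texture$levels), n),
                          cn, "Texture", ch, off)
        out <- cbind(out, tx[, setdiff(names(tx), "label"), drop = FALSE])
      }
      rd <- renameStats(padRows(measureRadial(lab, r, cfg$radial$bins,
                                              cfg$radial$wedges), n),
                        cn, "RadialDist", ch)
      out <- cbind(out, rd[, setdiff(names(rd), "label"), drop = FALSE])
    }
    co <- measureCorrelation(lab, rasters[[chans[1]]], rasters[[chans[2]]])
    chPair <- paste(chans[1], chans[2], sep = ".")
    cp <- renameStats(padRows(co$perObject, n), cn, "Correlation", chPair)
    out <- cbind(out, cp[, setdiff(names(cp), "label"), drop = FALSE])
  }
  imgRow <- data.frame(set_id = setId, stringsAsFactors = FALSE)
  coImg <- measureCorrelation(comps$Cell, rasters[[chans[1]]],
                              rasters[[chans[2]]])$image
  for (s in names(coImg))
    imgRow[[paste("Image", "Correlation", s,
                  paste(chans[1], chans[2], sep = "."), sep = "_")]] <- coImg[[s]]
  speckles <- NULL
  if (isTRUE(cfg$speckles$enabled)) {
    enh <- tophatEnhance(green, cfg$speckles$element_radius)
    det <- detectSpeckles(enh, cells, cfg$speckles$min_area,
                          cfg$speckles$max_area,
                          isTRUE(cfg$speckles$per_object),
                          cfg$speckles$min_threshold)
    cc <- countChildren(det$parentMap, cells)
    out[["Cell_Counts_SpeckleCount"]] <- cc$perParent$ChildCount
    imgRow[["Image_Counts_SpeckleTotal"]] <- cc$total
    if (nObjects(det$labels) > 0) {
      si <- renameStats(measureIntensity(det$labels, green),
                        "Speckle", "Intensity", chans[2])
      ss <- renameStats(measureShape(det$labels), "Speckle", "Shape")
      speckles <- cbind(data.frame(set_id = setId,
                                   label = si$label,
                                   parent = det$parentMap,
                                   stringsAsFactors = FALSE),
                        si[, setdiff(names(si), "label"), drop = FALSE],
                        ss[, setdiff(names(ss), "label"), drop = FALSE])
    }
  }
  list(cells = out, speckles = speckles, image = imgRow)
}

defaultRatioPairs <- function(cfg) {
  green <- cfg$channels[2]
  den <- paste("Nucleus", "Intensity", "Mean", green, sep = "_")
  nums <- c("Cytoplasm", sprintf("Ring%g", cfg$dilations))
  lapply(paste(nums, "Intensity", "Mean", green, sep = "_"),
         function(nm) c(nm, den))
}

#' Measure an entire experiment
#'
#' Runs \code{\link{measureImageSet}} over every image set of an
#' experiment (optionally after per-channel illumination correction),
#' appends the configured derived ratio features per object, aggregates to
#' one row per image (means and medians of everything, object counts),
#' and appends the per-image classified fractions for every configured
#' threshold. Per-image-set failures are caught, logged and skipped; the
#' run aborts only if no set succeeds.
#'
#' @param experiment a \code{\linkS4class{ScreenExperiment}}
#' @param cfg validated configuration
#' @param illum optional named list of
#'   \code{\linkS4class{IlluminationFunction}}s per channel
#' @param verbose log one line per image set
#' @return list with \code{perImage} (the screened feature table),
#'   \code{cells}, \code{speckles} (per-object tables) and \code{skipped}
#'   (named character vector of failed set_ids -> error message)
#' @export
measureExperiment <- function(experiment, cfg = validateConfig(),
                              illum = NULL, verbose = TRUE) {
  cellsL <- list(); speckL <- list(); imgL <- list()
  skipped <- character(0)
  for (sid in setIds(experiment)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      rasters <- lapply(stats::setNames(nm = channelNames(experiment)),
                        function(ch) {
        r <- readImageRaster(channelPaths(experiment, ch, sid))
        if (!is.null(illum[[ch]])) r <- applyIllumination(r, illum[[ch]])
        r
      })
      measureImageSet(rasters, cfg, sid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[sid] <- conditionMessage(res)
      if (verbose) message("set ", sid, ": SKIPPED (", skipped[sid], ")")
      next
    }
    cellsL[[sid]] <- res$cells
    speckL[[sid]] <- res$speckles
    imgL[[sid]] <- res$image
    if (verbose)
      message(sprintf("set %s: %d cells, %.1fs", sid,
                      if (is.null(res$cells)) 0L else nrow(res$cells),
                      proc.time()[["elapsed"]] - t0))
  }
  done <- setdiff(setIds(experiment), names(skipped))
  if (!length(done)) stop("no image set could be processed")
  cells <- do.call(rbind, cellsL[!vapply(cellsL, is.null, logical(1))])
  if (is.null(cells) || nrow(cells) == 0)
    stop("no objects found in any image set")
  rownames(cells) <- NULL
  ratios <- cfg$derived$ratios
  if (is.null(ratios)) ratios <- defaultRatioPairs(cfg)
  ratioNames <- character(0)
  for (pr in ratios) {
    if (!all(pr[1:2] %in% names(cells))) next
    before <- names(cells)
    cells <- ratioFeature(cells, pr[1], pr[2])
    ratioNames <- c(ratioNames, setdiff(names(cells), before))
  }
  perImage <- aggregatePerImage(cells, setIds = done,
                                countName = "Image_Counts_CellCount")
  for (rn in ratioNames)
    for (thr in cfg$derived$classify_thresholds) {
      cf <- classifyFraction(cells, rn, thr, setIds = done)
      perImage <- merge(perImage, cf, by = "set_id", sort = FALSE)
    }
  speckles <- NULL
  keep <- !vapply(speckL, is.null, logical(1))
  if (any(keep)) {
    speckles <- do.call(rbind, speckL[keep])
    rownames(speckles) <- NULL
    spAgg <- aggregatePerImage(speckles, setIds = done,
                               countName = "Image_Counts_SpeckleObjects")
    perImage <- merge(perImage, spAgg, by = "set_id", sort = FALSE)
  }
  imgFeat <- do.call(rbind, imgL[done])
  perImage <- merge(perImage, imgFeat, by = "set_id", all.x = TRUE,
                    sort = FALSE)
  perImage <- perImage[match(done, perImage$set_id), , drop = FALSE]
  rownames(perImage) <- NULL
  list(perImage = perImage, cells = cells, speckles = speckles,
       skipped = skipped)
}

#' Estimate illumination functions for every channel of an experiment
#'
#' Unreadable images are skipped with a message (they will be reported as
#' skipped again at measurement time); estimation fails only if a channel
#' has no readable image at all.
#'
#' @param experiment a \code{\linkS4class{ScreenExperiment}}
#' @param filterSize odd median-window side
#' @return named list of \code{\linkS4class{IlluminationFunction}}s
#' @export
estimateExperimentIllumination <- function(experiment, filterSize = 151L) {
  lapply(stats::setNames(nm = channelNames(experiment)), function(ch) {
    rasters <- lapply(channelPaths(experiment, ch), function(p)
      tryCatch(readImageRaster(p), error = function(e) {
        message("illumination: skipping unreadable ", p)
        NULL
      }))
    rasters <- rasters[!vapply(rasters, is.null, logical(1))]
    if (!length(rasters))
      stop("no readable image for channel ", ch)
    estimateIllumination(rasters, filterSize, channel = ch)
  })
}

#' Run the full screening pipeline
#'
#' Illumination estimation, segmentation over all compartments and all
#' parallel parameter values, feature measurement, derived features,
#' per-image aggregation, Z-prime / V-factor screening, optional train/test
#' validation — writing every stage's output to \code{outDir}
#' (\code{features.csv}, \code{cells.csv}, \code{report.csv},
#' \code{validation.csv}, \code{skipped.csv}, illumination surfaces as
#' 32-bit float TIFF). Deterministic given inputs, configuration and seed.
#'
#' @param metadataPath plate-map CSV path
#' @param config configuration (path, list or NULL for defaults)
#' @param outDir output directory, created if needed
#' @param verbose log progress
#' @return list with \code{features} (per-image table), \code{report}
#'   (\code{\linkS4class{QualityReport}}), \code{validation} (or NULL) and
#'   \code{skipped}
#' @export
runPipeline <- function(metadataPath, config = NULL, outDir, verbose = TRUE) {
  cfg <- validateConfig(config)
  set.seed(cfg$seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  experiment <- loadExperiment(metadataPath, cfg$channels)
  illum <- NULL
  if (isTRUE(cfg$illumination$enabled)) {
    if (verbose) message("estimating illumination functions")
    illum <- estimateExperimentIllumination(experiment,
                                            cfg$illumination$filter_size)
    for (ch in names(illum))
      tiff::writeTIFF(surface(illum[[ch]]) /
                        max(surface(illum[[ch]])),
                      file.path(outDir, paste0("illum_", ch, ".tiff")),
                      bits.per.sample = 32L)
  }
  meas <- measureExperiment(experiment, cfg, illum, verbose = verbose)
  writeFeatureTable(meas$perImage, file.path(outDir, "features.csv"))
  writeFeatureTable(meas$cells, file.path(outDir, "cells.csv"))
  if (!is.null(meas$speckles))
    writeFeatureTable(meas$speckles, file.path(outDir, "speckles.csv"))
  if (length(meas$skipped))
    utils::write.csv(data.frame(set_id = names(meas$skipped),
                                error = unname(meas$skipped)),
                     file.path(outDir, "skipped.csv"), row.names = FALSE)
  ## screen on the successfully measured sets only (skips are logged)
  recOk <- records(experiment)[setIds(experiment) %in% meas$perImage$set_id,
                               , drop = FALSE]
  spec <- controlSpec(new("ScreenExperiment", records = recOk,
                          channelNames = channelNames(experiment)))
  report <- screenFeatures(meas$perImage, spec, cfg$screen$score)
  writeReport(report, file.path(outDir, "report.csv"))
  validation <- NULL
  if (!is.null(cfg$screen$holdout)) {
    validation <- splitValidate(meas$perImage, spec,
                                holdoutFraction = cfg$screen$holdout,
                                seed = cfg$seed, topK = cfg$screen$top_k)
    utils::write.csv(validation$validation,
                     file.path(outDir, "validation.csv"), row.names = FALSE)
  }
  list(features = meas$perImage, report = report,
       validation = validation, skipped = meas$skipped)
}
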