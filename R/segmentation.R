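#' Segmentation parameter set
#'
#' @param thresholdMethod \code{"otsu_global"} (Otsu on intensities) or
#'   \code{"otsu_log"} (Otsu on log-intensities, for long-tailed stains)
#' @param minArea,maxArea object area bounds in pixels
#' @param declump split touching nuclei by watershed on the negated
#'   distance transform
#' @param smoothingSigma Gaussian pre-smoothing sigma in pixels (0 = none)
#' @param connectivity 4 (default) or 8
#' @param removeBorder drop objects touching the image border (their
#'   compartments would be truncated and bias intensity features)
#' @return a named list of validated parameters
#' @export
segmentationParams <- function(thresholdMethod = c("otsu_global", "otsu_log"),
                               minArea = 40, maxArea = 5000,
                               declump = FALSE, smoothingSigma = 1,
                               connectivity = 4L, removeBorder = TRUE) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(minArea > 0, minArea < maxArea, smoothingSigma >= 0,
            connectivity %in% c(4L, 8L))
  list(thresholdMethod = thresholdMethod, minArea = minArea,
       maxArea = maxArea, declump = declump,
       smoothingSigma = smoothingSigma,
       connectivity = as.integer(connectivity),
       removeBorder = removeBorder)
}

labelComponents <- function(mask, connectivity = 4L) {
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(mask * 1)
    matrix(as.integer(lab), nrow(mask), ncol(mask))
  } else {
    cpp_label_cc(mask, 8L)
  }
}

relabelConsecutive <- function(labels) {
  present <- sort(unique(labels[labels > 0L]))
  if (!length(present)) return(matrix(0L, nrow(labels), ncol(labels)))
  map <- integer(max(present))
  map[present] <- seq_along(present)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

distanceTransform <- function(mask) {
  t(as.matrix(EBImage::distmap(EBImage::Image(t(mask * 1)))))
}

## Declumping seeds: local maxima of the distance transform, greedily
## thinned to a minimum separation; candidates ordered by height then
## raster order so the seed set is deterministic.
declumpSeeds <- function(dt, minSep) {
  nr <- nrow(dt); nc <- ncol(dt)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dt
  isMax <- dt > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & dt >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  idx <- which(isMax)
  if (!length(idx)) return(NULL)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  o <- order(-dt[idx], c, r)
  keep <- integer(0)
  for (i in o) {
    if (!length(keep) ||
        min((r[i] - r[keep])^2 + (c[i] - c[keep])^2) >= minSep^2)
      keep <- c(keep, i)
  }
  cbind(row = r[keep], col = c[keep])
}

#' Segment nuclei from a DNA-channel image
#'
#' Gaussian pre-smoothing, a global Otsu threshold (optionally computed on
#' log-intensities), hole filling, area filtering, optional removal of
#' border-touching objects, and optional declumping of touching nuclei by
#' marker-controlled watershed on the negated distance transform (markers =
#' distance-transform maxima at least \code{sqrt(minArea)/2} apart).
#' Surviving objects are relabeled consecutively in raster order.
#'
#' @param dna corrected DNA-channel intensity raster
#' @param params parameter list from \code{\link{segmentationParams}}
#' @return label raster; an all-background image yields 0 objects, not an
#'   error
#' @export
segmentNuclei <- function(dna, params = segmentationParams()) {
  checkIntensityRaster(dna, "dna")
  x <- dna
  if (params$smoothingSigma > 0)
    x <- t(as.matrix(EBImage::gblur(EBImage::Image(t(x)),
                                    sigma = params$smoothingSigma)))
  tx <- if (params$thresholdMethod == "otsu_log") log1p(x) else x
  rng <- range(tx)
  if (diff(rng) == 0) return(matrix(0L, nrow(dna), ncol(dna)))
  thr <- EBImage::otsu(EBImage::Image(t(tx)), range = rng)
  mask <- tx > thr
  mask <- t(as.matrix(EBImage::fillHull(EBImage::Image(t(mask * 1))))) > 0
  lab <- labelComponents(mask, params$connectivity)
  if (params$declump && nObjects(lab) > 0) {
    dt <- distanceTransform(lab > 0)
    seeds <- declumpSeeds(dt, minSep = sqrt(params$minArea) / 2)
    if (!is.null(seeds) && nrow(seeds) > 1) {
      seedLab <- matrix(0L, nrow(lab), ncol(lab))
      seedLab[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
      lab <- cpp_seeded_watershed(dt, seedLab, lab > 0)
    }
  }
  areas <- tabulate(lab[lab > 0L], nbins = max(1L, nObjects(lab)))
  drop <- which(areas < params$minArea | areas > params$maxArea)
  if (params$removeBorder) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabelConsecutive(lab)
}

#' Dilate labeled objects without merging
#'
#' Expands every object to all pixels within Euclidean distance
#' \code{distance} of it; pixels within reach of several objects go to the
#' nearest one (exact squared-integer distances; ties to the lower label).
#' Input labels are preserved, objects never merge, and \code{distance = 0}
#' is the identity.
#'
#' @param objects label raster
#' @param distance dilation distance in pixels, >= 0
#' @return label raster of the dilated objects
#' @export
dilateObjects <- function(objects, distance) {
  objects <- checkLabelRaster(objects)
  if (length(distance) != 1 || is.na(distance) || distance < 0)
    stop("distance must be a single non-negative number")
  if (distance == 0) return(objects)
  cpp_dilate_labels(objects, as.numeric(distance))
}

#' Subtract an inner compartment from an outer one
#'
#' Per label k, the output object is outer k minus inner k — e.g. the
#' cytoplasmic ring between a dilated nucleus and the nucleus itself. Every
#' inner object must be contained in the same-labeled outer object. Rings
#' may come out empty (zero area); downstream measurements flag them as
#' missing.
#'
#' @param outer,inner label rasters with matching labels
#' @return label raster of the per-label set differences
#' @export
subtractCompartment <- function(outer, inner) {
  outer <- checkLabelRaster(outer, "outer")
  inner <- checkLabelRaster(inner, "inner")
  if (!identical(dim(outer), dim(inner)))
    stop("outer and inner dimensions differ")
  viol <- inner > 0L & outer != inner
  if (any(viol))
    stop("containment violation: inner object ",
         inner[which(viol)[1]], " not inside outer object of the same label")
  out <- outer
  out[inner > 0L] <- 0L
  out
}

#' Propagate cell boundaries from nuclear seeds
#'
#' Identifies whole cells as the region delimited by the marker
#' fluorescence: foreground pixels (green >= threshold, union the seed
#' pixels) are assigned to the seed reachable at minimal geodesic
#' cost, where a step of length L between neighbouring pixels costs
#' sqrt(regularization * L^2 + dI^2) for intensity difference dI. With
#' uniform intensity, or as regularization grows large, the cost is
#' proportional to path length and the assignment reduces to nearest-seed.
#' Foreground not connected to any seed stays background; seed labels are
#' preserved.
#'
#' @param seeds label raster of seed objects (e.g. nuclei), non-empty
#' @param green intensity raster guiding the propagation
#' @param threshold foreground intensity threshold in [0,1]
#' @param regularization non-negative; weight of spatial distance against
#'   intensity steps in the geodesic cost
#' @return label raster of propagated cells
#' @export
propagateCells <- function(seeds, green, threshold, regularization = 0.05) {
  seeds <- checkLabelRaster(seeds, "seeds")
  checkIntensityRaster(green, "green")
  if (!identical(dim(seeds), dim(green)))
    stop("seeds and green dimensions differ")
  if (nObjects(seeds) == 0) stop("no seeds to propagate from")
  stopifnot(threshold >= 0, threshold <= 1, regularization >= 0)
  mask <- green >= threshold
  cpp_propagate(green, seeds, mask, regularization)
}

#' White top-hat speckle enhancement
#'
#' Subtracts the morphological opening with a disk structuring element from
#' the image, leaving bright structures smaller than the element and
#' suppressing everything larger — the standard enhancement step before
#' speckle detection.
#'
#' @param green intensity raster
#' @param elementRadius disk radius in pixels, >= 1
#' @return non-negative raster of enhanced speckles
#' @export
tophatEnhance <- function(green, elementRadius) {
  checkIntensityRaster(green, "green")
  if (elementRadius < 1) stop("elementRadius must be >= 1")
  brush <- EBImage::makeBrush(2L * as.integer(elementRadius) + 1L,
                              shape = "disc")
  opened <- t(as.matrix(EBImage::opening(EBImage::Image(t(green)), brush)))
  pmax(green - opened, 0)
}

otsuOrNA <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  EBImage::otsu(EBImage::Image(matrix(values, ncol = 1)), range = rng)
}

#' Detect speckles by per-object or global thresholding
#'
#' Thresholds a top-hat-enhanced image with Otsu's method — either one
#' global threshold, or (default in speckle pipelines) a separate threshold
#' from the enhanced pixels inside each parent object, which makes the
#' detection robust to per-cell background differences. Parents with fewer
#' than 64 pixels or zero intensity range fall back to the global
#' threshold. Connected components outside [minArea, maxArea] are removed;
#' survivors are relabeled consecutively and assigned to the parent with
#' the largest pixel overlap.
#'
#' @param enhanced top-hat-enhanced intensity raster
#' @param parents label raster of parent objects (cells)
#' @param minArea,maxArea speckle area bounds in pixels, 1 <= min < max
#' @param perObject use per-parent thresholds (speckles are then only
#'   sought inside parents)
#' @param minThreshold lower bound applied to every Otsu threshold. An
#'   unbounded threshold always "finds" a split, so in a cell with no true
#'   speckles it segments noise; the floor encodes the smallest
#'   enhancement a credible speckle produces (a modest fraction of the
#'   marker's aggregate amplitude, well above the noise floor). 0 disables
#'   the bound.
#' @return list with \code{labels} (speckle label raster) and
#'   \code{parentMap} (integer vector: speckle label -> parent label, 0 =
#'   unassigned)
#' @export
detectSpeckles <- function(enhanced, parents, minArea = 6, maxArea = 400,
                           perObject = TRUE, minThreshold = 0) {
  if (min(enhanced) < 0 || any(!is.finite(enhanced)))
    stop("enhanced raster must be finite and non-negative")
  parents <- checkLabelRaster(parents, "parents")
  if (!identical(dim(enhanced), dim(parents)))
    stop("enhanced and parents dimensions differ")
  stopifnot(minArea >= 1, minArea < maxArea)
  np <- nObjects(parents)
  if (perObject && np == 0)
    stop("per-object thresholding needs a non-empty parents raster")
  globalThr <- otsuOrNA(as.vector(enhanced))
  mask <- matrix(FALSE, nrow(enhanced), ncol(enhanced))
  if (perObject) {
    for (k in seq_len(np)) {
      inK <- parents == k
      vals <- enhanced[inK]
      thr <- if (sum(inK) < 64 || diff(range(vals)) == 0) globalThr
             else otsuOrNA(vals)
      thr <- if (is.na(thr)) {
        if (minThreshold > 0) minThreshold else NA_real_
      } else max(thr, minThreshold)
      if (!is.na(thr)) mask[inK] <- enhanced[inK] > thr
    }
  } else {
    if (!is.na(globalThr)) mask <- enhanced > max(globalThr, minThreshold)
  }
  lab <- labelComponents(mask, 4L)
  n <- nObjects(lab)
  if (n > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    drop <- which(areas < minArea | areas > maxArea)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabelConsecutive(lab)
  }
  list(labels = lab, parentMap = assignParents(lab, parents))
}

#' Assign child objects to parent objects by maximal overlap
#'
#' Each child maps to the parent covering the largest share of its pixels;
#' ties go to the lower parent label, and a child overlapping only
#' background maps to 0.
#'
#' @param children,parents label rasters of equal dimensions
#' @return integer vector of length n_children: child label -> parent label
#' @export
assignParents <- function(children, parents) {
  children <- checkLabelRaster(children, "children")
  parents <- checkLabelRaster(parents, "parents")
  if (!identical(dim(children), dim(parents)))
    stop("children and parents dimensions differ")
  n <- nObjects(children)
  if (n == 0) return(integer(0))
  pm <- integer(n)
  sel <- children > 0L
  ch <- children[sel]; pa <- parents[sel]
  for (k in seq_len(n)) {
    pk <- pa[ch == k]
    pk <- pk[pk > 0L]
    if (!length(pk)) { pm[k] <- 0L; next }
    cnt <- tabulate(pk)
    pm[k] <- which.max(cnt)  # which.max takes the first (lowest) on ties
  }
  pm
}
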