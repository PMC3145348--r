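## Per-object measurement library. Every function returns a data.frame with
## one row per object label (1..n), all-finite values or NA for objects
## where the measurement is undefined.

shiftPad <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Internal boundary: object pixels with an 8-neighbour of a different
## label; out-of-image counts as background.
boundaryMask <- function(labels) {
  b <- matrix(FALSE, nrow(labels), ncol(labels))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    b <- b | (labels != shiftPad(labels, dr, dc, fill = 0L))
  }
  b & labels > 0L
}

sampleSD <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Per-object intensity statistics
#'
#' For every object: Integrated (sum), Mean, Median, Std (sample SD, 0 for
#' single-pixel objects), Max, Min, MAD (raw median absolute deviation),
#' and the same statistics restricted to the object's internal boundary
#' (pixels with an 8-neighbour outside the object): IntegratedEdge,
#' MeanEdge, StdEdge, MaxEdge, MinEdge.
#'
#' @param objects label raster
#' @param raster intensity raster of equal dimensions
#' @return data.frame with one row per object (column \code{label} first)
#' @export
measureIntensity <- function(objects, raster) {
  objects <- checkLabelRaster(objects)
  checkIntensityRaster(raster)
  if (!identical(dim(objects), dim(raster)))
    stop("objects and raster dimensions differ")
  n <- nObjects(objects)
  cols <- c("Integrated", "Mean", "Median", "Std", "Max", "Min", "MAD",
            "IntegratedEdge", "MeanEdge", "StdEdge", "MaxEdge", "MinEdge")
  out <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(out) <- cols
  if (n == 0) return(cbind(label = integer(0), out))
  sel <- objects > 0L
  vals <- split(raster[sel], objects[sel])
  edge <- boundaryMask(objects)
  evals <- split(raster[edge], objects[edge])
  for (k in seq_len(n)) {
    v <- vals[[as.character(k)]]
    if (is.null(v) || !length(v)) next
    e <- evals[[as.character(k)]]
    out$Integrated[k] <- sum(v)
    out$Mean[k] <- mean(v)
    out$Median[k] <- stats::median(v)
    out$Std[k] <- sampleSD(v)
    out$Max[k] <- max(v)
    out$Min[k] <- min(v)
    out$MAD[k] <- stats::median(abs(v - stats::median(v)))
    if (length(e)) {
      out$IntegratedEdge[k] <- sum(e)
      out$MeanEdge[k] <- mean(e)
      out$StdEdge[k] <- sampleSD(e)
      out$MaxEdge[k] <- max(e)
      out$MinEdge[k] <- min(e)
    }
  }
  cbind(label = seq_len(n), out)
}

## Chain-code weighted perimeter (Benkrid-Crookes): border pixels (object
## minus its 4-erosion) are weighted by their local border configuration —
## straight runs count 1, diagonal steps sqrt(2), corners (1+sqrt(2))/2.
## Gives ~0.92 form factor for a rendered disk, against 2*pi*r exactly 1.
benkridPerimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  er <- mask
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    er <- er & shiftPad(mask, s[1], s[2], fill = FALSE)
  border <- mask & !er
  if (!any(border)) return(0)
  n4 <- matrix(0L, nr, nc); nd <- matrix(0L, nr, nc)
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    n4 <- n4 + shiftPad(border, s[1], s[2], fill = FALSE)
  for (s in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
    nd <- nd + shiftPad(border, s[1], s[2], fill = FALSE)
  code <- 1L + 2L * n4 + 10L * nd
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27)] <- 1
  w[c(21, 33)] <- sqrt(2)
  w[c(13, 23)] <- (1 + sqrt(2)) / 2
  sum(w[code[border]])
}

## Convex-hull area as a pixel count (the rasterized hull of the pixel
## centers), the regionprops convention, so a convex object has solidity 1
## up to digitization.
convexHullArea <- function(r, c) {
  if (length(r) < 3) return(length(r))
  h <- grDevices::chull(c, r)
  hx <- c[h]; hy <- r[h]
  if (length(unique(paste(hx, hy))) < 3) return(length(r))
  ## orient clockwise (negative shoelace sum) so the edge test below holds
  if (sum(hx * (c(hy[-1], hy[1]) - c(hy[length(hy)], hy[-length(hy)]))) > 0) {
    hx <- rev(hx); hy <- rev(hy)
  }
  gx <- rep(min(c):max(c), each = max(r) - min(r) + 1)
  gy <- rep(min(r):max(r), max(c) - min(c) + 1)
  inside <- rep(TRUE, length(gx))
  nh <- length(hx)
  for (e in seq_len(nh)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[if (e == nh) 1 else e + 1]; y2 <- hy[if (e == nh) 1 else e + 1]
    ## chull returns vertices clockwise in (x, y); keep points on the
    ## inner side of every edge, boundary included
    inside <- inside &
      ((x2 - x1) * (gy - y1) - (y2 - y1) * (gx - x1)) <= 1e-9
  }
  max(sum(inside), length(r))
}

#' Per-object size and shape statistics
#'
#' Area (pixel count), Perimeter (chain-code weighted boundary estimate),
#' FormFactor = 4*pi*Area/Perimeter^2, Eccentricity (from second central
#' moments), Solidity (Area / convex-hull area, hull taken over pixel
#' corners), Extent (Area / bounding-box area) and EquivalentDiameter.
#'
#' @param objects label raster
#' @return data.frame with one row per object
#' @export
measureShape <- function(objects) {
  objects <- checkLabelRaster(objects)
  n <- nObjects(objects)
  cols <- c("Area", "Perimeter", "FormFactor", "Eccentricity", "Solidity",
            "Extent", "EquivalentDiameter")
  out <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(out) <- cols
  if (n == 0) return(cbind(label = integer(0), out))
  idx <- which(objects > 0L)
  rr <- (idx - 1L) %% nrow(objects) + 1L
  cc <- (idx - 1L) %/% nrow(objects) + 1L
  lab <- objects[idx]
  for (k in seq_len(n)) {
    ik <- lab == k
    if (!any(ik)) next
    r <- rr[ik]; c <- cc[ik]
    A <- length(r)
    out$Area[k] <- A
    r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
    sub <- matrix(FALSE, r1 - r0 + 3, c1 - c0 + 3)
    sub[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
    P <- benkridPerimeter(sub)
    out$Perimeter[k] <- P
    out$FormFactor[k] <- if (P > 0) 4 * pi * A / P^2 else NA_real_
    mu20 <- mean((r - mean(r))^2); mu02 <- mean((c - mean(c))^2)
    mu11 <- mean((r - mean(r)) * (c - mean(c)))
    tr <- mu20 + mu02
    dd <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
    l1 <- (tr + dd) / 2; l2 <- (tr - dd) / 2
    out$Eccentricity[k] <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
    ha <- convexHullArea(r, c)
    out$Solidity[k] <- if (ha > 0) min(1, A / ha) else 1
    out$Extent[k] <- A / ((r1 - r0 + 1) * (c1 - c0 + 1))
    out$EquivalentDiameter[k] <- sqrt(4 * A / pi)
  }
  cbind(label = seq_len(n), out)
}

haralickNames <- c("ASM", "Contrast", "Correlation", "Variance",
                   "InverseDifferenceMoment", "SumAverage", "SumVariance",
                   "SumEntropy", "Entropy", "DifferenceVariance",
                   "DifferenceEntropy", "InfoMeas1", "InfoMeas2")

## The 13 Haralick statistics of a symmetric, normalized GLCM P (natural
## logarithms; Variance is the marginal gray-level variance, SumVariance is
## centred on SumAverage).
haralickFromGLCM <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  mux <- sum(seq_len(L) * px)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  corr <- if (sx > 0) (sum(i * j * P) - mux^2) / sx^2 else NA_real_
  variance <- sum((seq_len(L) - mux)^2 * px)
  idm <- sum(P / (1 + (i - j)^2))
  sidx <- as.vector(i + j)
  pxy <- vapply(2:(2 * L), function(k) sum(P[sidx == k]), numeric(1))
  ks <- 2:(2 * L)
  sumavg <- sum(ks * pxy)
  sumvar <- sum((ks - sumavg)^2 * pxy)
  sument <- -sum(pxy[pxy > 0] * log(pxy[pxy > 0]))
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  didx <- as.vector(abs(i - j))
  pd <- vapply(0:(L - 1), function(k) sum(P[didx == k]), numeric(1))
  kd <- 0:(L - 1)
  davg <- sum(kd * pd)
  dvar <- sum((kd - davg)^2 * pd)
  dent <- -sum(pd[pd > 0] * log(pd[pd > 0]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  pp <- outer(px, px)
  sel <- P > 0 & pp > 0
  hxy1 <- -sum(P[sel] * log(pp[sel]))
  hxy2 <- -sum(pp[pp > 0] * log(pp[pp > 0]))
  im1 <- if (hx > 0) (entropy - hxy1) / hx else NA_real_
  im2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  stats::setNames(c(asm, contrast, corr, variance, idm, sumavg, sumvar,
                    sument, entropy, dvar, dent, im1, im2), haralickNames)
}

glcmPairCounts <- function(q, offset, levels) {
  counts <- matrix(0, levels, levels)
  offs <- rbind(c(0, offset), c(offset, 0), c(offset, offset),
                c(offset, -offset))
  nr <- nrow(q); nc <- ncol(q)
  for (t in seq_len(nrow(offs))) {
    dr <- offs[t, 1]; dc <- offs[t, 2]
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next
    a <- q[r0:r1, c0:c1, drop = FALSE]
    b <- q[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate((a[ok] - 1L) * levels + b[ok], nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
  }
  counts
}

#' Per-object Haralick texture statistics
#'
#' Pixels of each object are quantized to \code{levels} gray levels by
#' equal-width bins over the object's own min-max range (which makes the
#' statistics robust to residual illumination differences), a symmetric
#' normalized gray-level co-occurrence matrix is pooled over the four
#' direction offsets at distance \code{offset} — (0,d), (d,0), (d,d),
#' (d,-d) — restricted to pixel pairs both inside the object, and the 13
#' classical Haralick statistics are computed. Objects with zero intensity
#' range or fewer than 4 co-occurring pairs yield missing values.
#'
#' @param objects label raster
#' @param raster intensity raster
#' @param offset pair distance in pixels, >= 1
#' @param levels number of gray levels, >= 2
#' @return data.frame with one row per object, columns the 13 Haralick
#'   statistics
#' @export
measureTexture <- function(objects, raster, offset = 1L, levels = 8L) {
  objects <- checkLabelRaster(objects)
  checkIntensityRaster(raster)
  if (!identical(dim(objects), dim(raster)))
    stop("objects and raster dimensions differ")
  stopifnot(offset >= 1, levels >= 2)
  offset <- as.integer(offset); levels <- as.integer(levels)
  n <- nObjects(objects)
  out <- as.data.frame(matrix(NA_real_, n, length(haralickNames)))
  names(out) <- haralickNames
  if (n == 0) return(cbind(label = integer(0), out))
  idx <- which(objects > 0L)
  rr <- (idx - 1L) %% nrow(objects) + 1L
  cc <- (idx - 1L) %/% nrow(objects) + 1L
  lab <- objects[idx]
  vv <- raster[idx]
  for (k in seq_len(n)) {
    ik <- lab == k
    if (!any(ik)) next
    v <- vv[ik]
    mn <- min(v); mx <- max(v)
    if (mx <= mn) next
    r <- rr[ik]; c <- cc[ik]
    q <- matrix(NA_integer_, max(r) - min(r) + 1L, max(c) - min(c) + 1L)
    q[cbind(r - min(r) + 1L, c - min(c) + 1L)] <-
      pmin(levels, floor((v - mn) / (mx - mn) * levels) + 1L)
    counts <- glcmPairCounts(q, offset, levels)
    tot <- sum(counts)
    if (tot < 4) next
    P <- (counts + t(counts)) / (2 * tot)
    out[k, ] <- haralickFromGLCM(P)
  }
  cbind(label = seq_len(n), out)
}

#' Per-object two-channel correlation statistics
#'
#' Pearson correlation of channels A and B over each object's pixels, the
#' least-squares slope of B on A, and their covariance; plus the same three
#' statistics over the whole image. Objects where either channel is
#' constant give missing values.
#'
#' @param objects label raster
#' @param rasterA,rasterB intensity rasters of equal dimensions
#' @return list with \code{perObject} (data.frame: label, Correlation,
#'   Slope, Covariance) and \code{image} (named numeric vector of the same
#'   statistics over all pixels)
#' @export
measureCorrelation <- function(objects, rasterA, rasterB) {
  objects <- checkLabelRaster(objects)
  checkIntensityRaster(rasterA, "rasterA")
  checkIntensityRaster(rasterB, "rasterB")
  if (!identical(dim(objects), dim(rasterA)) ||
      !identical(dim(rasterA), dim(rasterB)))
    stop("dimension mismatch")
  corStats <- function(a, b) {
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(c(Correlation = NA_real_, Slope = NA_real_,
               Covariance = NA_real_))
    c(Correlation = stats::cor(a, b),
      Slope = stats::cov(a, b) / stats::var(a),
      Covariance = stats::cov(a, b))
  }
  n <- nObjects(objects)
  out <- data.frame(label = seq_len(n),
                    Correlation = rep(NA_real_, n),
                    Slope = rep(NA_real_, n),
                    Covariance = rep(NA_real_, n))
  sel <- objects > 0L
  av <- split(rasterA[sel], objects[sel])
  bv <- split(rasterB[sel], objects[sel])
  for (k in seq_len(n)) {
    a <- av[[as.character(k)]]
    if (is.null(a)) next
    out[k, -1] <- corStats(a, bv[[as.character(k)]])
  }
  list(perObject = out,
       image = corStats(as.vector(rasterA), as.vector(rasterB)))
}

#' Per-object radial intensity distribution
#'
#' Measures how intensity is distributed from each object's centroid out to
#' its boundary. Each pixel gets a normalized radial coordinate: its
#' distance from the centroid divided by the largest such distance among
#' object pixels in the same angular sector (of \code{nWedges} sectors),
#' clamped to [0,1]. Per radial bin b: \code{FracAtD_b} = fraction of total
#' object intensity in the bin; \code{MeanFrac_b} = FracAtD_b divided by
#' the fraction of pixels in the bin (1 everywhere for a radially uniform
#' object); \code{RadialCV_b} = coefficient of variation (sample SD over
#' mean) of the per-wedge mean intensities within the bin, over wedges
#' that contain pixels — means rather than sums, so the statistic is 0 for
#' angularly uniform intensity irrespective of how the pixel grid
#' distributes pixel counts over wedges. Zero-intensity objects and empty
#' bins give missing values.
#'
#' @param objects label raster
#' @param raster intensity raster
#' @param nBins number of radial bins, >= 1
#' @param nWedges number of angular sectors, >= 2
#' @return data.frame with one row per object
#' @export
measureRadial <- function(objects, raster, nBins = 4L, nWedges = 8L) {
  objects <- checkLabelRaster(objects)
  checkIntensityRaster(raster)
  if (!identical(dim(objects), dim(raster)))
    stop("objects and raster dimensions differ")
  stopifnot(nBins >= 1, nWedges >= 2)
  nBins <- as.integer(nBins); nWedges <- as.integer(nWedges)
  n <- nObjects(objects)
  cols <- c(paste0("FracAtD_", seq_len(nBins)),
            paste0("MeanFrac_", seq_len(nBins)),
            paste0("RadialCV_", seq_len(nBins)))
  out <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(out) <- cols
  if (n == 0) return(cbind(label = integer(0), out))
  idx <- which(objects > 0L)
  rr <- (idx - 1L) %% nrow(objects) + 1L
  cc <- (idx - 1L) %/% nrow(objects) + 1L
  lab <- objects[idx]
  vv <- raster[idx]
  for (k in seq_len(n)) {
    ik <- lab == k
    if (!any(ik)) next
    r <- rr[ik]; c <- cc[ik]; v <- vv[ik]
    tot <- sum(v)
    if (tot <= 0) next
    dy <- r - mean(r); dx <- c - mean(c)
    rad <- sqrt(dy^2 + dx^2)
    wedge <- pmin(nWedges,
                  floor((atan2(dy, dx) + pi) / (2 * pi) * nWedges) + 1L)
    wmax <- tapply(rad, wedge, max)
    norm <- rad / pmax(wmax[as.character(wedge)], .Machine$double.eps)
    norm <- pmin(norm, 1)
    bin <- pmax(1L, ceiling(norm * nBins))
    nPix <- length(v)
    for (b in seq_len(nBins)) {
      inb <- bin == b
      if (!any(inb)) next
      frac <- sum(v[inb]) / tot
      out[[paste0("FracAtD_", b)]][k] <- frac
      out[[paste0("MeanFrac_", b)]][k] <- frac / (sum(inb) / nPix)
      ws <- vapply(seq_len(nWedges), function(w) {
        sel <- inb & wedge == w
        if (any(sel)) mean(v[sel]) else NA_real_
      }, numeric(1))
      ws <- ws[!is.na(ws)]
      m <- mean(ws)
      out[[paste0("RadialCV_", b)]][k] <-
        if (length(ws) >= 2 && m > 0) stats::sd(ws) / m else NA_real_
    }
  }
  cbind(label = seq_len(n), out)
}

#' Count child objects per parent
#'
#' @param parentMap integer vector mapping each child label to its parent
#'   label (0 = unassigned), as returned by \code{\link{assignParents}}
#' @param parents parent label raster (fixes the number of parents)
#' @return list with \code{perParent} (data.frame: label, ChildCount, 0 for
#'   childless parents) and \code{total} (number of children in the image,
#'   unassigned children included)
#' @export
countChildren <- function(parentMap, parents) {
  parents <- checkLabelRaster(parents, "parents")
  np <- nObjects(parents)
  if (length(parentMap) && (any(is.na(parentMap)) ||
      any(parentMap < 0) || any(parentMap > np)))
    stop("parentMap refers to unknown parent labels")
  counts <- tabulate(parentMap[parentMap > 0L], nbins = np)
  list(perParent = data.frame(label = seq_len(np), ChildCount = counts),
       total = length(parentMap))
}
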