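#' Logistic dose-response curve
#'
#' effect(dose) = lo + (hi - lo) * dose^hill / (ec50^hill + dose^hill),
#' with dose 0 mapping to lo exactly. This is the dose-to-effect map the
#' synthetic generators use to place intermediate doses on a sigmoid
#' between the negative-control (lo) and maximal (hi) phenotype.
#'
#' @param dose non-negative dose(s)
#' @param ec50 dose of half-maximal effect, > 0
#' @param hill Hill coefficient, > 0
#' @param lo,hi effect at zero and saturating dose, lo <= hi
#' @return effect value(s)
#' @export
logisticResponse <- function(dose, ec50, hill, lo = 0, hi = 1) {
  stopifnot(ec50 > 0, hill > 0, lo <= hi)
  if (any(dose < 0)) stop("dose must be non-negative")
  ifelse(dose == 0, lo,
         lo + (hi - lo) * dose^hill / (ec50^hill + dose^hill))
}

#' Synthetic image-set parameters
#'
#' Defaults describe a two-channel field emulating the public benchmark
#' assays: ~30 elliptical nuclei per 360x360 image, each inside a circular
#' cell; green intensity partitioned between cytoplasm and nucleus by an
#' effect e in [0,1] (translocation), or Poisson-distributed bright spots
#' (speckles); a low-order multiplicative illumination gradient; Gaussian
#' read noise; a logistic dose-to-effect map.
#'
#' @param width,height image size in pixels
#' @param meanCells Poisson mean of cells per image
#' @param nucleusRadius range of nucleus ellipse semi-axes (pixels)
#' @param cellRadius range of cell disk radii (pixels)
#' @param dnaIntensity nuclear DNA-stain level
#' @param dnaBackground background DNA-stain level
#' @param greenCyto cytoplasmic green level c at zero effect
#' @param greenNucleus nuclear green level n at zero effect
#' @param greenBaseline residual cytoplasmic green at full effect
#' @param deltaNuc extra nuclear gain at full effect, so nuclear green
#'   reaches c + deltaNuc
#' @param doses dose grid; images at dose 0 are negative controls, at the
#'   top dose positive controls, in between samples
#' @param imagesPerDose replicate images per dose
#' @param ec50,hill,maxEffect logistic dose-to-effect parameters (effect
#'   runs from 0 toward maxEffect)
#' @param speckleLambda0,speckleLambdaMax Poisson speckle rate per cell at
#'   effect 0 and 1
#' @param speckleSigma,speckleAmplitude Gaussian spot width (pixels) and
#'   peak amplitude
#' @param greenDiffuse,greenNucDiffuse diffuse cytoplasmic / nuclear green
#'   in speckle images (equal by default: the speckle marker is diffuse
#'   across the whole cell until it aggregates)
#' @param gradientAmplitude multiplicative illumination gradient amplitude
#'   (0 = flat)
#' @param noiseSD Gaussian read-noise SD
#' @param seed integer; fixes all randomness
#' @return named parameter list
#' @export
synthParams <- function(width = 360L, height = 360L, meanCells = 30,
                        nucleusRadius = c(6, 9), cellRadius = c(14, 17),
                        dnaIntensity = 0.7, dnaBackground = 0.02,
                        greenCyto = 0.4, greenNucleus = 0.1,
                        greenBaseline = 0.05, deltaNuc = 0.1,
                        doses = c(0, 0.3, 1, 3, 100),
                        imagesPerDose = 4L,
                        ec50 = 1, hill = 2, maxEffect = 0.9,
                        speckleLambda0 = 0.3, speckleLambdaMax = 8,
                        speckleSigma = 1.5, speckleAmplitude = 0.45,
                        greenDiffuse = 0.25, greenNucDiffuse = 0.25,
                        gradientAmplitude = 0.3, noiseSD = 0.01,
                        seed = 1L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            meanCells = meanCells, nucleusRadius = nucleusRadius,
            cellRadius = cellRadius, dnaIntensity = dnaIntensity,
            dnaBackground = dnaBackground, greenCyto = greenCyto,
            greenNucleus = greenNucleus, greenBaseline = greenBaseline,
            deltaNuc = deltaNuc, doses = doses,
            imagesPerDose = as.integer(imagesPerDose), ec50 = ec50,
            hill = hill, maxEffect = maxEffect,
            speckleLambda0 = speckleLambda0,
            speckleLambdaMax = speckleLambdaMax,
            speckleSigma = speckleSigma,
            speckleAmplitude = speckleAmplitude,
            greenDiffuse = greenDiffuse,
            greenNucDiffuse = greenNucDiffuse,
            gradientAmplitude = gradientAmplitude, noiseSD = noiseSD,
            seed = as.integer(seed))
  stopifnot(all(p$nucleusRadius > 0), all(p$cellRadius > 0),
            p$noiseSD >= 0, p$meanCells > 0, length(p$doses) >= 2,
            all(p$doses >= 0), p$imagesPerDose >= 1,
            max(p$nucleusRadius) < min(p$cellRadius))
  vals <- c(p$dnaIntensity, p$dnaBackground, p$greenCyto, p$greenNucleus,
            p$greenBaseline, p$greenDiffuse, p$greenNucDiffuse)
  stopifnot(all(vals >= 0), all(vals <= 1))
  p
}

quantize16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

illuminationField <- function(p) {
  xn <- matrix(rep(seq_len(p$width) / p$width, each = p$height),
               p$height, p$width)
  yn <- matrix(rep(seq_len(p$height) / p$height, p$width),
               p$height, p$width)
  1 + p$gradientAmplitude *
    ((xn - 0.5) + (yn - 0.5) + (xn - 0.5) * (yn - 0.5))
}

## Rejection-sample non-overlapping cell centers and radii; up to 1000
## attempts per cell, error only if not even one cell can be placed.
placeCells <- function(p, nCells) {
  rows <- cols <- cellR <- numeric(0)
  for (i in seq_len(nCells)) {
    placed <- FALSE
    for (att in seq_len(1000)) {
      R <- stats::runif(1, p$cellRadius[1], p$cellRadius[2])
      r0 <- stats::runif(1, R + 2, p$height - R - 1)
      c0 <- stats::runif(1, R + 2, p$width - R - 1)
      if (!length(rows) ||
          all(sqrt((rows - r0)^2 + (cols - c0)^2) > cellR + R + 2)) {
        rows <- c(rows, r0); cols <- c(cols, c0); cellR <- c(cellR, R)
        placed <- TRUE
        break
      }
    }
    if (!placed && !length(rows))
      stop("cell placement failed: parameters leave no room for any cell")
  }
  data.frame(row = rows, col = cols, cellR = cellR)
}

ellipseMask <- function(p, r0, c0, a, b, theta) {
  rr <- matrix(rep(seq_len(p$height), p$width), p$height, p$width) - r0
  cc <- matrix(rep(seq_len(p$width), each = p$height),
               p$height, p$width) - c0
  u <- cc * cos(theta) + rr * sin(theta)
  v <- -cc * sin(theta) + rr * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

diskMask <- function(p, r0, c0, R) {
  rr <- matrix(rep(seq_len(p$height), p$width), p$height, p$width) - r0
  cc <- matrix(rep(seq_len(p$width), each = p$height),
               p$height, p$width) - c0
  rr^2 + cc^2 <= R^2
}

withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## Shared scaffolding for both generators: build the image-set metadata
## grid, render each image via renderFun(setRow, effect), write 16-bit
## TIFFs + plate.csv + truth.csv.
generateSet <- function(p, dir, renderFun, assayName) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doses <- rep(p$doses, each = p$imagesPerDose)
  repl <- rep(seq_len(p$imagesPerDose), length(p$doses))
  setId <- sprintf("%s_d%02d_r%d", assayName,
                   rep(seq_along(p$doses), each = p$imagesPerDose), repl)
  control <- ifelse(doses == 0, "negative",
             ifelse(doses == max(p$doses), "positive", "sample"))
  meta <- data.frame(set_id = setId,
                     path_dna = paste0(setId, "_dna.tiff"),
                     path_green = paste0(setId, "_green.tiff"),
                     plate = "SYNTH1",
                     well = sprintf("%s%02d",
                                    LETTERS[(seq_along(setId) - 1) %/% 12 + 1],
                                    (seq_along(setId) - 1) %% 12 + 1),
                     compound = ifelse(doses == 0, "vehicle", "cpdA"),
                     dose = doses, control = control,
                     cell_type = "synthetic",
                     stringsAsFactors = FALSE)
  truth <- vector("list", nrow(meta))
  illum <- illuminationField(p)
  for (i in seq_len(nrow(meta))) {
    effect <- logisticResponse(doses[i], p$ec50, p$hill,
                               lo = 0, hi = p$maxEffect)
    rend <- renderFun(effect)
    for (ch in c("dna", "green")) {
      img <- rend[[ch]] * illum
      if (p$noiseSD > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, p$noiseSD),
                            nrow(img), ncol(img))
      writeImageRaster(quantize16(img),
                       file.path(dir, meta[[paste0("path_", ch)]][i]))
    }
    tr <- rend$truth
    if (nrow(tr)) {
      tr$set_id <- meta$set_id[i]
      tr$dose <- doses[i]
      tr$effect <- effect
      tr$control <- control[i]
    }
    truth[[i]] <- tr
  }
  utils::write.csv(meta, file.path(dir, "plate.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  list(experiment = loadExperiment(file.path(dir, "plate.csv"),
                                   c("dna", "green")),
       truth = truth, dir = dir)
}

#' Generate a synthetic cytoplasm-to-nucleus translocation image set
#'
#' Renders two-channel fields of non-overlapping cells: elliptical nuclei
#' at the DNA-stain level, circular cells whose green channel carries
#' (1-e)*c + baseline in the cytoplasm and n + e*(c - n + deltaNuc) in the
#' nucleus, the effect e following the logistic dose-response. A
#' multiplicative illumination gradient and Gaussian read noise are
#' applied, images are written as 16-bit TIFF next to a plate-map CSV
#' (negative controls at dose 0, positives at the top dose) and a
#' ground-truth CSV. With zero gradient and noise, each cell's true
#' nucleus:cytoplasm green ratio (recorded after 16-bit quantization) is
#' exactly recoverable from the images.
#'
#' @param p parameters from \code{\link{synthParams}}
#' @param dir output directory
#' @return list with \code{experiment} (a
#'   \code{\linkS4class{ScreenExperiment}} over the written files),
#'   \code{truth} (per-cell data.frame) and \code{dir}
#' @export
generateTranslocationSet <- function(p = synthParams(), dir = tempfile("cnt")) {
  withSeed(p$seed, generateSet(p, dir, function(effect) {
    nCells <- max(1L, stats::rpois(1, p$meanCells))
    cells <- placeCells(p, nCells)
    dna <- matrix(p$dnaBackground, p$height, p$width)
    green <- matrix(0, p$height, p$width)
    cytoVal <- (1 - effect) * p$greenCyto + p$greenBaseline
    nucVal <- p$greenNucleus +
      effect * (p$greenCyto - p$greenNucleus + p$deltaNuc)
    qc <- quantize16(cytoVal); qn <- quantize16(nucVal)
    tr <- cells
    tr$nucA <- stats::runif(nrow(cells), p$nucleusRadius[1],
                            p$nucleusRadius[2])
    tr$nucB <- stats::runif(nrow(cells), p$nucleusRadius[1],
                            p$nucleusRadius[2])
    tr$theta <- stats::runif(nrow(cells), 0, pi)
    for (i in seq_len(nrow(cells))) {
      cell <- diskMask(p, cells$row[i], cells$col[i], cells$cellR[i])
      nuc <- ellipseMask(p, cells$row[i], cells$col[i],
                         tr$nucA[i], tr$nucB[i], tr$theta[i])
      nuc <- nuc & cell
      dna[nuc] <- p$dnaIntensity
      green[cell & !nuc] <- cytoVal
      green[nuc] <- nucVal
    }
    tr$ratio_nc <- qn / qc
    tr$cell <- seq_len(nrow(tr))
    list(dna = dna, green = green, truth = tr)
  }, assayName = "cnt"))
}

#' Generate a synthetic speckle-formation (Transfluor-like) image set
#'
#' As \code{\link{generateTranslocationSet}}, but the green channel is a
#' diffuse cytoplasmic level plus K ~ Poisson(lambda(e)) bright Gaussian
#' spots per cell, the rate interpolating linearly between
#' \code{speckleLambda0} and \code{speckleLambdaMax} with the effect. Spots
#' are placed uniformly inside the cell disk, non-overlapping by rejection;
#' the number actually placed is recorded as the per-cell truth.
#'
#' @inheritParams generateTranslocationSet
#' @return as \code{\link{generateTranslocationSet}}; the truth column
#'   \code{speckle_count} holds the planted spot count per cell
#' @export
generateSpeckleSet <- function(p = synthParams(), dir = tempfile("transfluor")) {
  minSep <- 4 * p$speckleSigma
  withSeed(p$seed, generateSet(p, dir, function(effect) {
    nCells <- max(1L, stats::rpois(1, p$meanCells))
    cells <- placeCells(p, nCells)
    lambda <- p$speckleLambda0 +
      effect * (p$speckleLambdaMax - p$speckleLambda0)
    dna <- matrix(p$dnaBackground, p$height, p$width)
    green <- matrix(0, p$height, p$width)
    tr <- cells
    tr$nucA <- stats::runif(nrow(cells), p$nucleusRadius[1],
                            p$nucleusRadius[2])
    tr$nucB <- stats::runif(nrow(cells), p$nucleusRadius[1],
                            p$nucleusRadius[2])
    tr$theta <- stats::runif(nrow(cells), 0, pi)
    tr$speckle_count <- 0L
    for (i in seq_len(nrow(cells))) {
      cell <- diskMask(p, cells$row[i], cells$col[i], cells$cellR[i])
      nuc <- ellipseMask(p, cells$row[i], cells$col[i],
                         tr$nucA[i], tr$nucB[i], tr$theta[i]) & cell
      dna[nuc] <- p$dnaIntensity
      green[cell] <- p$greenDiffuse
      green[nuc] <- p$greenNucDiffuse
      K <- stats::rpois(1, lambda)
      maxR <- cells$cellR[i] - 3 * p$speckleSigma - 1
      sr <- sc <- numeric(0)
      if (K > 0 && maxR > 0) {
        for (s in seq_len(K)) {
          for (att in seq_len(1000)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- sqrt(stats::runif(1)) * maxR
            y <- cells$row[i] + rad * sin(ang)
            x <- cells$col[i] + rad * cos(ang)
            if (!length(sr) ||
                all(sqrt((sr - y)^2 + (sc - x)^2) >= minSep)) {
              sr <- c(sr, y); sc <- c(sc, x)
              break
            }
          }
        }
      }
      tr$speckle_count[i] <- length(sr)
      for (s in seq_along(sr)) {
        rs <- max(1, floor(sr[s] - 3 * p$speckleSigma)):
              min(p$height, ceiling(sr[s] + 3 * p$speckleSigma))
        cs <- max(1, floor(sc[s] - 3 * p$speckleSigma)):
              min(p$width, ceiling(sc[s] + 3 * p$speckleSigma))
        d2 <- outer((rs - sr[s])^2, (cs - sc[s])^2, `+`)
        green[rs, cs] <- green[rs, cs] +
          p$speckleAmplitude * exp(-d2 / (2 * p$speckleSigma^2))
      }
    }
    tr$cell <- seq_len(nrow(tr))
    list(dna = dna, green = green, truth = tr)
  }, assayName = "spk"))
}
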