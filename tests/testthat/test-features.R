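test_that("intensity statistics match hand arithmetic and handle edges", {
  lab <- matrix(0L, 10, 10)
  lab[3:6, 3:6] <- 1L
  r <- matrix(0, 10, 10)
  r[lab == 1L] <- 0.4
  st <- measureIntensity(lab, r)
  expect_equal(st$Mean, 0.4)
  expect_equal(st$Median, 0.4)
  expect_equal(st$Max, 0.4)
  expect_equal(st$Min, 0.4)
  expect_equal(st$Std, 0)
  expect_equal(st$Integrated, 0.4 * 16)
  # 2x2 object with values 0.1..0.4
  lab2 <- matrix(0L, 5, 5)
  lab2[2:3, 2:3] <- 1L
  r2 <- matrix(0, 5, 5)
  r2[2, 2] <- 0.1; r2[3, 2] <- 0.2; r2[2, 3] <- 0.3; r2[3, 3] <- 0.4
  st2 <- measureIntensity(lab2, r2)
  expect_equal(st2$Mean, 0.25)
  expect_equal(st2$Integrated, 1.0)
  expect_equal(st2$Median, 0.25)
  # all four pixels are boundary pixels
  expect_equal(st2$IntegratedEdge, 1.0)
  # single pixel: it is its own boundary
  lab3 <- matrix(0L, 3, 3); lab3[2, 2] <- 1L
  r3 <- matrix(0.7, 3, 3)
  st3 <- measureIntensity(lab3, r3)
  expect_equal(st3$IntegratedEdge, 0.7)
  expect_equal(st3$MeanEdge, 0.7)
  expect_equal(st3$Std, 0)
  # derived compartments may have empty labels: reported missing, not error
  gap <- matrix(0L, 8, 8); gap[2:3, 2:3] <- 1L; gap[6:7, 6:7] <- 3L
  stG <- measureIntensity(gap, matrix(0.5, 8, 8))
  expect_equal(nrow(stG), 3L)
  expect_true(is.na(stG$Mean[2]))
  expect_equal(stG$Mean[3], 0.5)
})

test_that("edge statistics use only the internal boundary", {
  lab <- matrix(0L, 9, 9)
  lab[3:7, 3:7] <- 1L          # 5x5 square: 16 boundary + 9 interior
  r <- matrix(0, 9, 9)
  r[lab == 1L] <- 0.2
  r[4:6, 4:6] <- 0.9           # bright interior
  st <- measureIntensity(lab, r)
  expect_equal(st$MeanEdge, 0.2)
  expect_equal(st$IntegratedEdge, 0.2 * 16)
  expect_equal(st$Max, 0.9)
})

test_that("shape statistics are exact on canonical shapes", {
  lab <- matrix(0L, 14, 14)
  lab[3:12, 3:12] <- 1L
  st <- measureShape(lab)
  expect_equal(st$Area, 100)
  expect_equal(st$Extent, 1.0)
  expect_equal(st$Solidity, 1.0)
  expect_equal(st$EquivalentDiameter, sqrt(400 / pi))
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  st1 <- measureShape(one)
  expect_equal(st1$Area, 1)
  expect_equal(st1$Solidity, 1)
  expect_equal(st1$Eccentricity, 0)
})

test_that("disk form factor matches the frozen chain-code regression value", {
  lab <- labelFrom(renderDisk(31, 10))
  st <- measureShape(lab)
  expect_equal(st$Area, 317)
  expect_equal(st$FormFactor, 0.9161285450, tolerance = 1e-9)
  expect_gt(st$FormFactor, 0.85)
  expect_lt(st$FormFactor, 1.1)
  expect_equal(st$Solidity, 1.0)
})

test_that("elongated objects have higher eccentricity than round ones", {
  disk <- measureShape(labelFrom(renderDisk(31, 10)))
  bar <- matrix(0L, 31, 31); bar[14:17, 4:28] <- 1L
  stBar <- measureShape(bar)
  expect_lt(disk$Eccentricity, 0.2)
  expect_gt(stBar$Eccentricity, 0.9)
})

test_that("texture statistics equal the brute-force GLCM oracle", {
  set.seed(31)
  for (trial in 1:4) {
    n <- sample(6:10, 1)
    r <- matrix(runif(n * n), n, n)
    lab <- matrix(1L, n, n)
    for (off in c(1L, 2L)) {
      got <- measureTexture(lab, r, off, 8L)
      q <- matrix(oracleQuantize(as.vector(r), 8L), n, n)
      want <- oracleHaralick(oracleGLCM(q, off, 8L))
      for (nm in names(want))
        expect_equal(got[[nm]], unname(want[[nm]]), tolerance = 1e-10,
                     info = paste(nm, "offset", off, "trial", trial))
    }
  }
})

test_that("degenerate textures are missing: uniform objects, tiny objects", {
  lab <- matrix(1L, 6, 6)
  st <- measureTexture(lab, matrix(0.5, 6, 6), 1L, 8L)
  expect_true(all(is.na(st[, -1])))
  one <- matrix(0L, 4, 4); one[2, 2] <- 1L
  st1 <- measureTexture(one, matrix(runif(16), 4, 4), 1L, 8L)
  expect_true(all(is.na(st1[, -1])))
})

test_that("the two-level checkerboard texture matches oracle enumeration", {
  cb <- outer(1:4, 1:4, function(r, c) (r + c) %% 2) * 0.6 + 0.2
  lab <- matrix(1L, 4, 4)
  got <- measureTexture(lab, cb, 1L, 2L)
  q <- matrix(oracleQuantize(as.vector(cb), 2L), 4, 4)
  want <- oracleHaralick(oracleGLCM(q, 1L, 2L))
  expect_equal(got$Contrast, unname(want["Contrast"]), tolerance = 1e-12)
  expect_equal(got$ASM, unname(want["ASM"]), tolerance = 1e-12)
  # orthogonal neighbours always differ, diagonal always agree: the
  # off-diagonal GLCM mass is 24 of 42 pairs
  expect_equal(got$Contrast, 24 / 42, tolerance = 1e-12)
})

test_that("correlation statistics match hand Pearson cases", {
  lab <- matrix(0L, 4, 4)
  lab[1, 1:4] <- 1L
  a <- matrix(0, 4, 4); a[1, ] <- c(0.1, 0.2, 0.3, 0.4)
  co1 <- measureCorrelation(lab, a, a)$perObject
  expect_equal(co1$Correlation, 1)
  expect_equal(co1$Slope, 1)
  b <- 0.5 - a
  co2 <- measureCorrelation(lab, a, b)$perObject
  expect_equal(co2$Correlation, -1)
  expect_equal(co2$Slope, -1)
  b3 <- matrix(0, 4, 4); b3[1, ] <- c(0.1, 0.3, 0.2, 0.4)
  co3 <- measureCorrelation(lab, a, b3)$perObject
  expect_equal(co3$Correlation, 0.8)
  const <- matrix(0.5, 4, 4)
  expect_true(is.na(measureCorrelation(lab, a, const)$perObject$Correlation))
})

test_that("radial distribution concentrates mass where intensity sits", {
  lab <- labelFrom(renderDisk(21, 8))
  point <- matrix(0, 21, 21)
  point[11, 11] <- 0.9
  st <- measureRadial(lab, point, nBins = 4L)
  expect_equal(st$FracAtD_1, 1)
  expect_equal(st$FracAtD_4, 0)
  uniform <- matrix(0, 21, 21)
  uniform[lab == 1L] <- 0.5
  stU <- measureRadial(lab, uniform, nBins = 4L)
  for (b in 1:4) {
    expect_equal(stU[[paste0("RadialCV_", b)]], 0, tolerance = 1e-12)
    expect_equal(stU[[paste0("MeanFrac_", b)]], 1, tolerance = 0.1)
  }
  # sum rule
  fr <- unlist(stU[paste0("FracAtD_", 1:4)])
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # zero-intensity object is missing
  stZ <- measureRadial(lab, matrix(0, 21, 21), nBins = 4L)
  expect_true(all(is.na(stZ[, -1])))
})

test_that("radial fraction sums to one across random objects", {
  set.seed(37)
  for (trial in 1:5) {
    lab <- labelFrom(renderDisk(25, sample(5:10, 1),
                                cy = 12 + runif(1), cx = 12 + runif(1)))
    r <- matrix(runif(625), 25, 25)
    st <- measureRadial(lab, r, nBins = 4L)
    fr <- unlist(st[paste0("FracAtD_", 1:4)])
    expect_equal(sum(fr, na.rm = TRUE), 1, tolerance = 1e-9)
  }
})

test_that("child counts tally per parent and per image", {
  parents <- matrix(0L, 10, 10)
  parents[, 1:5] <- 1L
  parents[, 6:10] <- 2L
  cc0 <- countChildren(integer(0), parents)
  expect_equal(cc0$perParent$ChildCount, c(0L, 0L))
  expect_equal(cc0$total, 0L)
  cc <- countChildren(c(1L, 1L, 1L, 2L, 2L), parents)
  expect_equal(cc$perParent$ChildCount, c(3L, 2L))
  expect_equal(cc$total, 5L)
  ccU <- countChildren(c(1L, 0L, 1L, 1L), parents)
  expect_equal(cc$total, 5L)
  expect_equal(ccU$total, 4L)
  expect_equal(sum(ccU$perParent$ChildCount), 3L)
})

test_that("intensity scales with the raster, texture and radial do not", {
  set.seed(41)
  lab <- labelFrom(renderDisk(25, 9))
  r <- matrix(runif(625, 0.2, 1), 25, 25)
  s <- 0.5
  i1 <- measureIntensity(lab, r); i2 <- measureIntensity(lab, s * r)
  for (nm in c("Mean", "Integrated", "Max", "Min", "Std"))
    expect_equal(i2[[nm]], s * i1[[nm]], tolerance = 1e-12, info = nm)
  t1 <- measureTexture(lab, r, 1L); t2 <- measureTexture(lab, s * r, 1L)
  expect_equal(unlist(t2[, -1]), unlist(t1[, -1]), tolerance = 1e-10)
  r1 <- measureRadial(lab, r); r2 <- measureRadial(lab, s * r)
  expect_equal(unlist(r2[, -1]), unlist(r1[, -1]), tolerance = 1e-12)
  b <- matrix(runif(625), 25, 25)
  c1 <- measureCorrelation(lab, r, b)$perObject$Correlation
  c2 <- measureCorrelation(lab, s * r, b)$perObject$Correlation
  expect_equal(c2, c1, tolerance = 1e-12)
})

test_that("integrated intensity is additive over nucleus + ring", {
  set.seed(43)
  lab <- matrix(0L, 60, 60)
  lab[renderDisk(60, 7, cy = 18, cx = 18)] <- 1L
  lab[renderDisk(60, 6, cy = 42, cx = 40)] <- 2L
  r <- matrix(runif(3600), 60, 60)
  dil <- dilateObjects(lab, 6)
  ring <- subtractCompartment(dil, lab)
  iN <- measureIntensity(lab, r)$Integrated
  iR <- measureIntensity(ring, r)$Integrated
  iD <- measureIntensity(dil, r)$Integrated
  expect_equal(iN + iR, iD, tolerance = 1e-12)
})

test_that("the default configuration yields a library of 500+ features", {
  p <- synthParams(width = 200L, height = 200L, meanCells = 6,
                   doses = c(0, 100), imagesPerDose = 1L,
                   gradientAmplitude = 0, noiseSD = 0, seed = 9L)
  g <- generateTranslocationSet(p, dir = withr::local_tempdir())
  sid <- setIds(g$experiment)[1]
  rasters <- list(dna = readImageRaster(channelPaths(g$experiment, "dna", sid)),
                  green = readImageRaster(channelPaths(g$experiment, "green", sid)))
  cfg <- validateConfig(list(illumination = list(enabled = FALSE)))
  m <- measureImageSet(rasters, cfg, sid)
  featNames <- setdiff(names(m$cells), c("set_id", "label"))
  expect_gte(length(unique(featNames)), 500L)
  expect_equal(anyDuplicated(featNames), 0L)
})
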