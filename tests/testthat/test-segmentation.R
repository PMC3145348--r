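test_that("nuclei segment from a dark background, blanks give 0 objects", {
  blank <- matrix(0.1, 60, 60)
  expect_equal(max(segmentNuclei(blank)), 0)
  img <- matrix(0.05, 60, 60)
  img[renderDisk(60, 12)] <- 0.8
  lab <- segmentNuclei(img, segmentationParams(smoothingSigma = 0))
  expect_equal(max(lab), 1L)
  expect_lt(abs(sum(lab == 1L) - pi * 144) / (pi * 144), 0.1)
  img[3, 3] <- NaN
  expect_error(segmentNuclei(img), "finite")
})

test_that("declumping splits two touching equal disks at their centers", {
  img <- matrix(0.05, 80, 80)
  img[renderDisk(80, 12, cy = 40, cx = 29)] <- 0.8
  img[renderDisk(80, 12, cy = 40, cx = 52)] <- 0.8
  lab <- segmentNuclei(img, segmentationParams(declump = TRUE,
                                               smoothingSigma = 0))
  expect_equal(max(lab), 2L)
  for (truth in list(c(40, 29), c(40, 52))) {
    cent <- sapply(1:2, function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      colMeans(px)
    })
    expect_lt(min(sqrt(colSums((cent - truth)^2))), 3)
  }
})

test_that("dilation assigns contested pixels to the exact nearest object", {
  lab <- matrix(0L, 40, 40)
  lab[renderDisk(40, 4, cy = 15, cx = 12)] <- 0L
  lab[15, 10:14] <- 1L
  lab[24, 18:22] <- 2L   # 6+ px gap
  expect_identical(dilateObjects(lab, 0), lab)
  out <- dilateObjects(lab, 10)
  expect_identical(out, oracleDilate(lab, 10))
  # labels preserved, never merged
  expect_true(all(out[lab == 1L] == 1L))
  expect_true(all(out[lab == 2L] == 2L))
  expect_equal(sort(unique(as.vector(out))), 0:2)
})

test_that("dilating a disk grows its area geometrically", {
  lab <- labelFrom(renderDisk(60, 8))
  out <- dilateObjects(lab, 7)
  expect_lt(abs(sum(out == 1L) - pi * 15^2) / (pi * 15^2), 0.1)
  expect_error(dilateObjects(lab, -1), "non-negative")
})

test_that("compartment subtraction yields exact per-label rings", {
  inner <- labelFrom(renderDisk(50, 10))
  outer_ <- labelFrom(renderDisk(50, 15))
  ring <- subtractCompartment(outer_, inner)
  expect_equal(sum(ring == 1L), sum(outer_ == 1L) - sum(inner == 1L))
  expect_lt(abs(sum(ring == 1L) - pi * (225 - 100)) / (pi * 125), 0.1)
  expect_equal(sum(subtractCompartment(inner, inner)), 0)
  expect_true(all(ring[inner == 1L] == 0L))
  shifted <- labelFrom(renderDisk(50, 10, cy = 5, cx = 5))
  expect_error(subtractCompartment(inner, shifted), "containment")
})

test_that("propagation collapses to seeds above max intensity and fills
           uniform foreground from a single seed", {
  green <- matrix(0.4, 30, 30)
  seeds <- matrix(0L, 30, 30)
  seeds[14:16, 14:16] <- 1L
  expect_identical(propagateCells(seeds, green, threshold = 0.9), seeds)
  out <- propagateCells(seeds, green, threshold = 0.2)
  expect_true(all(out == 1L))
  expect_error(propagateCells(matrix(0L, 30, 30), green, 0.5), "seeds")
})

test_that("two seeds in uniform intensity split at the equidistant line", {
  green <- matrix(0.5, 41, 41)
  seeds <- matrix(0L, 41, 41)
  seeds[21, 6] <- 1L
  seeds[21, 36] <- 2L
  out <- propagateCells(seeds, green, 0, regularization = 1)
  left <- out[, 1:20]; right <- out[, 22:41]
  expect_true(all(left == 1L))
  expect_true(all(right == 2L))
})

test_that("geodesic propagation matches the relaxation oracle", {
  set.seed(11)
  for (trial in 1:3) {
    n <- c(24, 32, 48)[trial]
    img <- matrix(runif(n * n), n, n)
    img <- t(as.matrix(EBImage::gblur(EBImage::Image(t(img)), 2)))
    img <- (img - min(img)) / diff(range(img))
    seeds <- matrix(0L, n, n)
    for (k in 1:3) seeds[sample(n, 1), sample(n, 1)] <- k
    mask <- img >= stats::quantile(img, 0.2)
    out <- assayScreen:::cpp_propagate(img, seeds, mask, 0.05)
    expect_identical(out, oracleGeodesic(img, seeds, mask, 0.05))
  }
})

test_that("propagation at huge regularization reduces to nearest-seed
           assignment on the foreground", {
  set.seed(13)
  green <- matrix(runif(900), 30, 30)
  seeds <- matrix(0L, 30, 30)
  seeds[8, 8] <- 1L
  seeds[23, 21] <- 2L
  out <- propagateCells(seeds, green, threshold = 0, regularization = 1e8)
  near <- oracleDilate(seeds, 1e6)
  ## the 8-neighbour geodesic is an octagonal approximation of Euclidean
  ## distance, so demand exact agreement only off the bisector band
  d1 <- sqrt(outer((1:30 - 8)^2, (1:30 - 8)^2, `+`))
  d2 <- sqrt(outer((1:30 - 23)^2, (1:30 - 21)^2, `+`))
  off <- abs(d1 - d2) > 3
  expect_true(all(out[off] == near[off]))
  expect_lt(mean(out != near), 0.05)
})

test_that("top-hat enhancement isolates structures smaller than the element", {
  expect_equal(max(tophatEnhance(matrix(0.5, 20, 20), 3)), 0)
  one <- matrix(0, 21, 21)
  one[11, 11] <- 0.8
  enh <- tophatEnhance(one, 3)
  expect_equal(enh[11, 11], 0.8)
  expect_equal(sum(enh) - enh[11, 11], 0)
  disk <- matrix(0, 51, 51)
  disk[renderDisk(51, 10)] <- 0.6
  big <- tophatEnhance(disk, 15)   # element bigger than the disk
  small <- tophatEnhance(disk, 5)  # disk survives the opening
  expect_gt(max(big), 0.55)
  expect_lt(max(small[renderDisk(51, 7)]), 0.05)
  expect_error(tophatEnhance(disk, 0), "elementRadius")
})

test_that("top-hat equals the brute-force opening oracle", {
  set.seed(17)
  x <- matrix(runif(24 * 24), 24, 24)
  for (rad in c(1, 2, 3)) {
    brush <- EBImage::makeBrush(2L * rad + 1L, "disc")
    expected <- pmax(x - oracleOpening(x, brush), 0)
    expect_equal(tophatEnhance(x, rad), expected, tolerance = 1e-12,
                 info = paste("radius", rad))
  }
})

test_that("speckles are detected per object with exact size filtering", {
  parents <- matrix(0L, 60, 60)
  parents[renderDisk(60, 28)] <- 1L
  zero <- matrix(0, 60, 60)
  det0 <- detectSpeckles(zero, parents, 2, 50, TRUE)
  expect_equal(max(det0$labels), 0L)
  enh <- matrix(0, 60, 60)
  spots <- list(c(20, 20), c(20, 40), c(40, 20), c(40, 40), c(30, 30))
  for (s in spots) enh[s[1] + (-1:1), s[2] + (-1:1)] <- 0.6
  det <- detectSpeckles(enh, parents, 2, 50, TRUE)
  expect_equal(max(det$labels), 5L)
  expect_equal(det$parentMap, rep(1L, 5))
  # one blob larger than maxArea (inside the parent) is rejected
  enh[24:37, 42:55] <- 0.6
  det2 <- detectSpeckles(enh, parents, 2, 50, TRUE)
  expect_equal(max(det2$labels), 5L)
  expect_error(detectSpeckles(enh, matrix(0L, 60, 60), 2, 50, TRUE),
               "non-empty")
})

test_that("children map to the parent with the dominant overlap", {
  parents <- matrix(0L, 20, 30)
  parents[, 1:12] <- 1L
  parents[, 13:24] <- 2L
  child <- matrix(0L, 20, 30)
  child[10, 3:5] <- 1L                 # fully inside parent 1... label 1
  child[5, 10:19] <- 2L                # 3 px in parent 1, 7 in parent 2
  child[15, 26:29] <- 3L               # background only
  pm <- assignParents(child, parents)
  expect_equal(pm, c(1L, 2L, 0L))
  # 60/40 split goes to the majority side; exact tie to the lower label
  child2 <- matrix(0L, 20, 30)
  child2[8, 11:15] <- 1L               # 2 px parent1, 3 px parent2
  child2[12, 11:14] <- 2L              # 2 px each: tie -> parent 1
  pm2 <- assignParents(child2, parents)
  expect_equal(pm2, c(2L, 1L))
})

test_that("compartments nest: nucleus inside dilation, ring disjoint", {
  set.seed(23)
  lab <- matrix(0L, 50, 50)
  lab[renderDisk(50, 6, cy = 15, cx = 15)] <- 1L
  lab[renderDisk(50, 5, cy = 35, cx = 33)] <- 2L
  dil <- dilateObjects(lab, 8)
  ring <- subtractCompartment(dil, lab)
  for (k in 1:2) {
    expect_true(all(dil[lab == k] == k))
    expect_equal(sum(ring == k & lab == k), 0)
    expect_equal(sum(ring == k) + sum(lab == k), sum(dil == k))
  }
})
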