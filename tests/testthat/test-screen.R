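test_that("Z-prime matches hand arithmetic on the canonical cases", {
  expect_equal(zPrime(c(1, 1, 1), c(0, 0, 0)), 1.0)
  expect_equal(zPrime(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1)), 0.4,
               tolerance = 1e-12)
  expect_true(is.na(zPrime(c(0.5, 0.5), c(0.5, 0.5))))
  expect_error(zPrime(1, c(0, 0)), "at least 2")
})

test_that("Z-prime is symmetric and affine invariant", {
  set.seed(61)
  for (trial in 1:5) {
    p <- rnorm(6, 1, 0.1); n <- rnorm(6, 0, 0.2)
    expect_equal(zPrime(p, n), zPrime(n, p), tolerance = 1e-12)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1); b <- rnorm(1)
    expect_equal(zPrime(a * p + b, a * n + b), zPrime(p, n),
                 tolerance = 1e-9)
  }
})

test_that("V factor matches hand arithmetic and edge cases", {
  expect_equal(vFactor(list("0" = c(0, 0), "1" = c(1, 1))), 1.0)
  expect_equal(vFactor(list("0" = c(-0.05, 0, 0.05),
                            "1" = c(0.45, 0.5, 0.55),
                            "2" = c(0.95, 1, 1.05))), 0.7,
               tolerance = 1e-12)
  expect_true(is.na(vFactor(list("0" = c(0.2, 0.4), "1" = c(0.4, 0.2)))))
  expect_error(vFactor(list("0" = c(1, 2))), "at least 2")
  expect_error(vFactor(list("0" = c(1, 2), "1" = 3)), "at least 2")
})

test_that("V factor on two dose groups is exactly the Z-prime factor", {
  set.seed(67)
  for (trial in 1:10) {
    p <- rnorm(5, 1, 0.1); n <- rnorm(5, 0, 0.15)
    expect_equal(vFactor(list("0" = n, "10" = p)), zPrime(p, n),
                 tolerance = 1e-12)
  }
  # the worked Z-prime case carries over
  expect_equal(vFactor(list("0" = c(-0.1, 0, 0.1),
                            "1" = c(0.9, 1.0, 1.1))), 0.4,
               tolerance = 1e-12)
})

test_that("V factor is affine invariant", {
  set.seed(71)
  g <- list("0" = rnorm(4, 0, 0.1), "1" = rnorm(4, 0.5, 0.1),
            "2" = rnorm(4, 1, 0.1))
  v0 <- vFactor(g)
  g2 <- lapply(g, function(x) -2.5 * x + 3)
  expect_equal(vFactor(g2), v0, tolerance = 1e-9)
})

test_that("Gaussian controls recover the closed-form score", {
  ## pos ~ N(1, 0.05^2), neg ~ N(0, 0.05^2): E[Z'] ~ 1 - 6 * 0.05 = 0.7
  set.seed(73)
  z <- replicate(100, zPrime(rnorm(200, 1, 0.05), rnorm(200, 0, 0.05)))
  expect_gt(mean(abs(z - 0.7) <= 0.05), 0.95)
})

test_that("the dose-response-fit V variant tracks the per-dose form on
           clean sigmoid data", {
  set.seed(79)
  doses <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  g <- lapply(stats::setNames(nm = doses), function(d)
    logisticResponse(d, 1, 1.5) + rnorm(6, 0, 0.03))
  names(g) <- doses
  v1 <- vFactor(g)
  v2 <- vFactor(g, method = "fit_residual")
  expect_lt(abs(v1 - v2), 0.1)
})

test_that("screening bands, ranks and invalidates features correctly", {
  set.seed(83)
  ids <- paste0("w", 1:10)
  dose <- c(rep(0, 5), rep(1, 5))
  tab <- data.frame(set_id = ids,
                    A_Intensity_Good_g = c(rnorm(5, 0, 0.05), rnorm(5, 1, 0.05)),
                    A_Intensity_Weak_g = c(rnorm(5, 0, 0.5), rnorm(5, 1, 0.5)),
                    A_Shape_Const = rep(2, 10),
                    stringsAsFactors = FALSE)
  spec <- list(positive = ids[6:10], negative = ids[1:5],
               dose = stats::setNames(dose, ids),
               doseGroups = split(ids, dose))
  rep1 <- screenFeatures(tab, spec)
  sc <- scores(rep1)
  expect_equal(sc$feature[1], "A_Intensity_Good_g")
  expect_equal(sc$band[1], "excellent")
  expect_gt(sc$zprime[1], 0.5)
  expect_equal(sc$band[sc$feature == "A_Shape_Const"], "invalid")
  expect_equal(sc$rank[sc$feature == "A_Shape_Const"], 3L)
  expect_true(is.na(sc$zprime[sc$feature == "A_Shape_Const"]))
  # two dose groups: auto ranking falls back to Z-prime
  expect_equal(rep1@scoreType, "zprime")
  # V factor and Z-prime agree here (two dose groups)
  expect_equal(sc$vfactor[1], sc$zprime[1], tolerance = 1e-12)
  bc <- bestByCategory(rep1)
  expect_equal(bc$feature[bc$category == "Intensity"], "A_Intensity_Good_g")
})

test_that("band boundaries follow the conventional cutoffs", {
  ## three points c(-s, 0, s) have sample SD exactly s; s and the group
  ## separations are dyadic rationals so every score below is exact in
  ## floating point, including the 0.5 band boundary (not "excellent")
  ids <- paste0("w", 1:6)
  spec <- list(positive = ids[4:6], negative = ids[1:3],
               dose = stats::setNames(c(0, 0, 0, 1, 1, 1), ids),
               doseGroups = split(ids, c(0, 0, 0, 1, 1, 1)))
  cases <- list(
    list(s = 0.0625, sep = 1, z = 0.625, band = "excellent"),
    list(s = 0.25, sep = 3, z = 0.5, band = "screenable"),
    list(s = 0.125, sep = 1, z = 0.25, band = "screenable"),
    list(s = 0.5, sep = 3, z = 0, band = "not screenable"),
    list(s = 0.25, sep = 1, z = -0.5, band = "not screenable"))
  for (cs in cases) {
    neg <- c(-cs$s, 0, cs$s)
    tab <- data.frame(set_id = ids,
                      A_Intensity_F_g = c(neg, neg + cs$sep),
                      stringsAsFactors = FALSE)
    sc <- scores(screenFeatures(tab, spec))
    expect_identical(sc$zprime[1], cs$z, info = paste("z =", cs$z))
    expect_equal(sc$band[1], cs$band, info = paste("z =", cs$z))
  }
})

test_that("an informative feature among pure noise ranks first", {
  set.seed(89)
  ids <- paste0("w", 1:12)
  dose <- c(rep(0, 6), rep(1, 6))
  tab <- data.frame(set_id = ids, stringsAsFactors = FALSE)
  for (i in 1:30) tab[[paste0("N_Intensity_F", i, "_g")]] <- rnorm(12)
  tab[["Derived_Ratio_R_over_N"]] <- c(rnorm(6, 4, 0.1), rnorm(6, 0.4, 0.05))
  spec <- list(positive = ids[7:12], negative = ids[1:6],
               dose = stats::setNames(dose, ids),
               doseGroups = split(ids, dose))
  sc <- scores(screenFeatures(tab, spec))
  expect_equal(sc$feature[1], "Derived_Ratio_R_over_N")
  expect_equal(sc$category[1], "Ratio")
})

test_that("holdout validation is deterministic and detects overfitting", {
  set.seed(97)
  ids <- paste0("w", 1:16)
  dose <- c(rep(0, 8), rep(1, 8))
  spec <- list(positive = ids[9:16], negative = ids[1:8],
               dose = stats::setNames(dose, ids),
               doseGroups = split(ids, dose))
  noise <- data.frame(set_id = ids, stringsAsFactors = FALSE)
  for (i in 1:40) noise[[paste0("N_Intensity_F", i, "_g")]] <- rnorm(16)
  v1 <- splitValidate(noise, spec, 0.5, seed = 7L, topK = 3L)
  v2 <- splitValidate(noise, spec, 0.5, seed = 7L, topK = 3L)
  expect_identical(v1, v2)
  expect_error(splitValidate(noise, spec, 0.9, seed = 1L), "fewer than 2")
  ## noise-only features: the best training feature regresses toward the
  ## mean on held-out controls
  diffs <- vapply(1:100, function(s) {
    noise2 <- data.frame(set_id = ids, stringsAsFactors = FALSE)
    for (i in 1:25) noise2[[paste0("N_Intensity_F", i, "_g")]] <- rnorm(16)
    v <- splitValidate(noise2, spec, 0.5, seed = s, topK = 1L)$validation
    v$train_zprime[1] - v$test_zprime[1]
  }, numeric(1))
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})
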