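cfg <- featureConfig()
cfgTiny <- featureConfig(minClumpArea = 1L)

test_that("dark binarization follows the strict relative threshold", {
  crop <- matrix(c(0, 0, 100, 100), 2)
  expect_identical(binarizeDark(crop, 0.5),
                   matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  expect_warning(m <- binarizeDark(matrix(5, 3, 3), 0.5), "constant")
  expect_false(any(m))
  # tau near 1 excludes only the maximum pixels (strict inequality)
  crop2 <- matrix(c(1, 2, 3, 10, 10, 10), 2)
  m2 <- binarizeDark(crop2, 0.999)
  expect_identical(m2, crop2 < 1 + 0.999 * 9)
  expect_identical(sum(!m2), 3L)
})

test_that("a planted dark disk is recovered exactly at tau = 0.5", {
  crop <- diskCrop(31, radius = 5, bg = 200, depth = 60)
  mask <- binarizeDark(crop, 0.5)
  truthDisk <- crop == 140
  expect_identical(mask, truthDisk)
  clumps <- labelClumps(mask, cfg)
  expect_identical(nrow(clumps), 1L)
  expect_equal(clumps$area, sum(truthDisk))
})

test_that("clump labeling follows connectivity and area conventions", {
  m <- matrix(FALSE, 6, 9)
  m[2:4, 2:4] <- TRUE
  m[2:4, 6:8] <- TRUE
  two <- labelClumps(m, cfg)
  expect_identical(two$area, c(9, 9))
  expect_identical(two$perimeter, c(12, 12))
  # diagonal touch merges under 8-connectivity, splits under 4
  d <- matrix(FALSE, 4, 4)
  d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_identical(nrow(labelClumps(d, cfgTiny)), 1L)
  cfg4 <- featureConfig(connectivity = 4L, minClumpArea = 1L)
  expect_identical(nrow(labelClumps(d, cfg4)), 2L)
  # a single pixel is dropped by the minimum-area filter
  s <- matrix(FALSE, 3, 3); s[2, 2] <- TRUE
  expect_identical(nrow(labelClumps(s, featureConfig(minClumpArea = 2L))),
                   0L)
})

test_that("labeling equals a flood-fill oracle on random masks", {
  withr::with_seed(99, {
    for (i in 1:50) {
      m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.6), 32, 32)
      conn <- if (i %% 2) 8L else 4L
      cfgX <- featureConfig(connectivity = conn, minClumpArea = 1L)
      got <- labelClumps(m, cfgX)
      ref <- regionStatsOracle(floodFillOracle(m, conn))
      expect_identical(nrow(got), nrow(ref))
      expect_equal(sort(got$area), sort(unname(ref[, "area"])))
      o <- order(got$area, got$perimeter)
      ro <- order(ref[, "area"], ref[, "perimeter"])
      expect_equal(got$perimeter[o], unname(ref[ro, "perimeter"]))
    }
  })
})

test_that("noncircularity closed forms and elongation ordering", {
  expect_equal(noncircularity(9, 12), 1 - 36 * pi / 144)
  expect_equal(noncircularity(9, 20), 1 - 36 * pi / 400)
  expect_gt(noncircularity(9, 20), noncircularity(9, 12))
  # the ideal continuous circle: A = pi r^2, P = 2 pi r
  r <- 3.7
  expect_equal(noncircularity(pi * r^2, 2 * pi * r), 0)
  expect_error(noncircularity(0, 10), "positive")
  expect_error(noncircularity(5, 0), "positive")
})

test_that("clump summary measurements follow the stated conventions", {
  empty <- labelClumps(matrix(FALSE, 4, 4), cfg)
  m0 <- clumpMeasurements(empty, cropArea = 16)
  expect_identical(unname(m0[c("n_clumps", "mean_clump_area",
                               "mean_noncircularity")]), c(0, 0, 0))
  expect_true(all(m0 == 0))
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  m1 <- clumpMeasurements(labelClumps(sq, cfg), cropArea = 25)
  expect_equal(unname(m1["n_clumps"]), 1)
  expect_equal(unname(m1["mean_clump_area"]), 9)
  expect_equal(unname(m1["mean_noncircularity"]), 1 - 36 * pi / 144)
  two <- matrix(FALSE, 9, 16)
  two[2:4, 2:4] <- TRUE; two[2:6, 7:11] <- TRUE
  m2 <- clumpMeasurements(labelClumps(two, cfg), cropArea = 144)
  expect_equal(unname(m2["mean_clump_area"]), 17)
  expect_equal(unname(m2["total_clump_area"]), 34)
})

test_that("intensity statistics match hand values and a brute oracle", {
  s <- intensityStatistics(c(0, 0, 0, 100))
  expect_equal(unname(s["mean"]), 25)
  expect_equal(unname(s["median"]), 0)
  cst <- intensityStatistics(rep(4, 10))
  expect_identical(unname(cst[c("sd", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_identical(unname(cst["min"]), unname(cst["max"]))
  withr::with_seed(17, {
    for (i in 1:20) {
      x <- rnorm(200, 10, 4)
      s <- intensityStatistics(x)
      m <- sum(x) / length(x)
      m2 <- sum((x - m)^2) / length(x)
      expect_equal(unname(s["mean"]), m)
      expect_equal(unname(s["sd"]), sqrt(sum((x - m)^2) / (length(x) - 1)))
      expect_equal(unname(s["skewness"]), sum((x - m)^3) / length(x) / m2^1.5)
      expect_equal(unname(s["kurtosis"]), sum((x - m)^4) / length(x) / m2^2 - 3)
      expect_equal(unname(s["interdecile"]),
                   unname(diff(quantile(x, c(0.1, 0.9)))))
      expect_equal(unname(s["iqr"]),
                   unname(diff(quantile(x, c(0.25, 0.75)))))
    }
  })
})

test_that("binarized shape measures and the isoperimetric ordering", {
  expect_identical(binarizedShapeMeasures(matrix(FALSE, 3, 3)),
                   c(total_size = 0, total_perimeter = 0, thinness = 0))
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  s <- binarizedShapeMeasures(sq)
  expect_equal(unname(s), c(9, 12, 4 * pi * 9 / 144))
  disk <- ellipseMask(100, 1)
  bar <- matrix(FALSE, 41, 41); bar[20, 3:39] <- TRUE; bar[21, 3:39] <- TRUE
  expect_gt(binarizedShapeMeasures(disk)["thinness"],
            binarizedShapeMeasures(bar)["thinness"])
})

test_that("rasterized-ellipse mean noncircularity rises with the axis
          ratio", {
  ncs <- meanNcLadder(cfg)
  expect_true(all(diff(ncs) > 0))
})

test_that("the schema is fixed at 296 uniquely named entries", {
  sch <- featureSchema()
  expect_identical(nrow(sch), 296L)
  expect_identical(anyDuplicated(sch$name), 0L)
  expect_identical(anyDuplicated(sch$id), 0L)
  expect_identical(sch, featureSchema())
  expect_true(all(c("tau_mean_n_clumps", "tau_mean_mean_clump_area",
                    "tau_mean_mean_noncircularity") %in% sch$name))
  path <- withr::local_tempfile(fileext = ".json")
  writeFeatureSchema(cfg, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$name, sch$name)
  expect_error(featureConfig(tauLadder = c(0.2, 0.1)), "increasing")
  expect_error(featureConfig(tauLadder = c(0.1, 0.5)), "296")
  expect_error(featureConfig(connectivity = 6), "connectivity")
})

test_that("extraction yields a complete deterministic 296-vector", {
  fp <- generateCellImage(genotypeParams("WT"), seed = 31)
  v <- extractFeatures(bfImage(fp), cfg)
  expect_length(v, 296)
  expect_identical(names(v), cfg$schema$id)
  expect_true(all(is.finite(v)))
  expect_identical(v, extractFeatures(bfImage(fp), cfg))
  expect_warning(vc <- extractFeatures(matrix(9, 20, 20), cfg), "constant")
  countIds <- cfg$schema$id[grepl("^n_clumps|^tau_mean_n_clumps",
                                  cfg$schema$name)]
  expect_true(all(vc[countIds] == 0))
})

test_that("the fused per-threshold block equals the compositional path", {
  withr::with_seed(7, {
    for (i in 1:20) {
      img <- matrix(rnorm(28 * 35), 28, 35)
      if (i %% 5 == 0) img <- round(img)  # heavy ties
      fused <- BFProfiler:::.per_tau_block(img, cfg$tauLadder,
                                           cfg$connectivity,
                                           cfg$minClumpArea)
      for (t in seq_along(cfg$tauLadder)) {
        mask <- binarizeDark(img, cfg$tauLadder[t])
        ref <- c(clumpMeasurements(labelClumps(mask, cfg),
                                   cropArea = length(img)),
                 BFProfiler:::.binMeasures(mask))
        expect_equal(unname(fused[t, ]), unname(ref), tolerance = 1e-12)
      }
    }
  })
})

test_that("adding a planted clump never decreases the matched-tau count", {
  p0 <- genotypeParams("WT", clumpRate = 2, cloneOffsets = c(0, 0))
  cnt <- function(fp) {
    v <- extractFeatures(bfImage(fp), cfg)
    unname(v[cfg$schema$id[cfg$schema$name == "n_clumps_t50"]])
  }
  fp <- generateCellImage(p0, seed = 77)
  base <- cnt(fp)
  # plant one more clump by darkening a disk far from existing clumps
  img <- bfImage(fp)
  img[5:9, 5:9] <- img[5:9, 5:9] - p0@clumpDarkness
  fp2 <- new("FieldImagePair", bf = pmax(img, 0),
             nuclear = nuclearImage(fp), truth = truthRecords(fp),
             log = character(0))
  expect_gte(cnt(fp2), base + 1)
})

test_that("preprocessing filters have the documented fixed-kernel behavior", {
  cst <- matrix(42, 9, 9)
  for (kind in c("blur", "edge_enhance", "sharpen"))
    expect_equal(applyFilter(cst, kind), cst, tolerance = 1e-12)
  # sharpen does not reduce the contrast of a step edge
  step <- matrix(rep(c(0, 100), each = 50), 10, 10)
  shp <- applyFilter(step, "sharpen")
  edgeContrast <- function(m) max(m[, 6] - m[, 5])
  expect_gte(edgeContrast(shp), edgeContrast(step))
  blr <- applyFilter(step, "blur")
  expect_lte(edgeContrast(blr), edgeContrast(step))
  expect_error(applyFilter(step, "emboss"), "unknown filter")
  crops <- toyCropClasses(2)
  out <- applyFilter(crops$wt[[1]], "blur")
  expect_s4_class(out, "CellCrop")
  expect_identical(out@cellId, crops$wt[[1]]@cellId)
})
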