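blobImage <- function(centers, size = 128, sigma = 8, amp = 20000,
                      bg = 500) {
  img <- matrix(bg, size, size)
  for (k in seq_len(nrow(centers))) {
    cr <- centers[k, 1]; cc <- centers[k, 2]
    for (r in seq_len(size)) for (c in seq_len(size))
      img[r, c] <- img[r, c] + amp * exp(-((r - cr)^2 + (c - cc)^2) /
                                           (2 * sigma^2))
  }
  img
}

test_that("blank or constant images yield no detections", {
  expect_identical(nrow(detectNuclei(matrix(0, 16, 16))), 0L)
  expect_identical(nrow(detectNuclei(matrix(7, 16, 16))), 0L)
})

test_that("two separated blobs give two boxes containing their centers", {
  img <- blobImage(rbind(c(32, 32), c(96, 90)))
  boxes <- detectNuclei(img)
  expect_identical(nrow(boxes), 2L)
  # boxes sorted by (r0, c0); centers in 0-based coordinates
  expect_true(boxes$r0[1] <= 31 && 31 < boxes$r1[1])
  expect_true(boxes$c0[1] <= 31 && 31 < boxes$c1[1])
  expect_true(boxes$r0[2] <= 95 && 95 < boxes$r1[2])
  expect_true(boxes$c0[2] <= 89 && 89 < boxes$c1[2])
})

test_that("the component area filter excludes small blobs", {
  img <- blobImage(rbind(c(64, 64)))
  big <- detectNuclei(img, minArea = 20)
  expect_identical(nrow(big), 1L)
  expect_identical(nrow(detectNuclei(img, minArea = big$area[1] + 1)), 0L)
  expect_identical(nrow(detectNuclei(img, minArea = 20,
                                     maxArea = big$area[1] - 1)), 0L)
})

test_that("crop expansion arithmetic and border handling", {
  bf <- matrix(seq_len(100 * 100), 100, 100)
  interior <- data.frame(r0 = 40L, c0 = 50L, r1 = 50L, c1 = 58L)
  crops <- cropCells(bf, interior, expandFrac = 0.5)
  expect_length(crops, 1)
  expect_identical(dim(cropImage(crops[[1]])), c(20L, 16L))
  expect_identical(crops[[1]]@box, c(35L, 46L, 55L, 62L))
  # expandFrac = 0 reproduces the nucleus box exactly
  crops0 <- cropCells(bf, interior, expandFrac = 0)
  expect_identical(dim(cropImage(crops0[[1]])), c(10L, 8L))
  expect_identical(cropImage(crops0[[1]]), bf[41:50, 51:58])
  # a corner box whose expansion leaves the image is dropped
  corner <- data.frame(r0 = 0L, c0 = 0L, r1 = 10L, c1 = 10L)
  both <- rbind(corner, interior)
  expect_length(cropCells(bf, both, expandFrac = 0.5), 1)
  expect_error(cropCells(bf, interior, nuclearImage = matrix(0, 5, 5)),
               "dimensions differ")
})

test_that("greedy truth matching reports precision and recall", {
  truth <- list(list(cell_center = c(10, 10)),
                list(cell_center = c(50, 50)),
                list(cell_center = c(90, 30)))
  boxes <- data.frame(r0 = c(8, 48), c0 = c(8, 48), r1 = c(12, 52),
                      c1 = c(12, 52))
  m <- matchToTruth(boxes, truth, maxDist = 5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 2 / 3)
  mAll <- matchToTruth(rbind(boxes,
                             data.frame(r0 = 88, c0 = 28, r1 = 92,
                                        c1 = 32)),
                       truth, maxDist = 5)
  expect_equal(mAll$precision, 1)
  expect_equal(mAll$recall, 1)
})

test_that("greedy matching agrees with the exhaustive optimum on small,
          well-separated instances", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      nt <- sample(3:6, 1)
      tc <- cbind(runif(nt, 0, 100), runif(nt, 0, 100))
      # well-separated truth centers, detections jittered slightly
      while (nt > 1 && min(dist(tc)) < 25)
        tc <- cbind(runif(nt, 0, 100), runif(nt, 0, 100))
      keep <- sort(sample(nt, max(2, nt - 1)))
      dc <- tc[keep, , drop = FALSE] + matrix(rnorm(2 * length(keep), 0, 2),
                                              ncol = 2)
      boxes <- data.frame(r0 = dc[, 1] - 2, c0 = dc[, 2] - 2,
                          r1 = dc[, 1] + 2, c1 = dc[, 2] + 2)
      truth <- lapply(seq_len(nt), function(i)
        list(cell_center = tc[i, ]))
      g <- matchToTruth(boxes, truth, maxDist = 10)
      o <- optimalMatchOracle(dc, tc, maxDist = 10)
      expect_identical(nrow(g$assignment), o$n)
      gp <- g$assignment[order(g$assignment$detection), c(1, 2)]
      op <- o$pairs[order(o$pairs[, 1]), , drop = FALSE]
      expect_equal(unname(as.matrix(gp)), unname(op))
    }
  })
})

test_that("detection is near-perfect on a synthetic population", {
  p <- genotypeParams("WT")
  pop <- generatePopulation(p, nCells = 100, cellsPerField = 10, seed = 2,
                            fieldSize = c(512L, 512L))
  nDet <- 0; nMatch <- 0; nTruth <- 0
  for (fp in pop) {
    boxes <- detectNuclei(nuclearImage(fp))
    m <- matchToTruth(boxes, truthRecords(fp), maxDist = 20)
    nDet <- nDet + nrow(boxes)
    nMatch <- nMatch + nrow(m$assignment)
    nTruth <- nTruth + length(truthRecords(fp))
  }
  expect_gte(nMatch / nDet, 0.99)
  expect_gte(nMatch / nTruth, 0.99)
})

test_that("crops stay in bounds and carry unique ids", {
  p <- genotypeParams("WT")
  fp <- generatePopulation(p, nCells = 8, cellsPerField = 8, seed = 13,
                           fieldSize = c(512L, 512L))[[1]]
  boxes <- detectNuclei(nuclearImage(fp))
  crops <- cropCells(bfImage(fp), boxes, fieldId = "F001")
  ids <- vapply(crops, function(x) x@cellId, character(1))
  expect_false(anyDuplicated(ids) > 0)
  for (cr in crops) {
    expect_true(all(cr@box[c(1, 2)] >= 0))
    expect_true(cr@box[3] <= nrow(bfImage(fp)))
    expect_true(cr@box[4] <= ncol(bfImage(fp)))
    expect_identical(dim(cropImage(cr)),
                     c(cr@box[3] - cr@box[1], cr@box[4] - cr@box[2]))
  }
})

test_that("crop export writes a provenance manifest and PNGs", {
  crops <- toyCropClasses(2)$wt
  dir <- withr::local_tempdir()
  writeCrops(crops, dir)
  man <- read.csv(file.path(dir, "crops_manifest.csv"))
  expect_identical(nrow(man), 2L)
  expect_identical(colnames(man),
                   c("cell_id", "field", "r0", "c0", "r1", "c1"))
  expect_true(all(file.exists(file.path(dir, paste0(man$cell_id,
                                                    ".png")))))
})
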