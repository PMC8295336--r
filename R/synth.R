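#' Synthetic bright-field image generation
#'
#' The generator emulates the statistical structure the downstream analysis
#' relies on: each cell is a faint disk on a noisy 16-bit bright-field
#' background containing a Poisson number of darker elliptical "clumps"
#' (organelle-like structures) whose count, area and elongation depend on
#' genotype, plus a bright Gaussian nuclear blob in the paired
#' nuclear-stain channel that makes nucleus detection reliable. Clumps are
#' placed in the perinuclear region so that nucleus-anchored crops capture
#' them. Every planted cell and clump is recorded as ground truth.
#'
#' @name synth
NULL

# geometry defaults shared by the generator functions
.synthDefaults <- function() {
  list(cellRadius = 40, clumpFieldFrac = 0.35, nucleusSigma = 8,
       nucleusAmplitude = 20000, nuclearBackground = 500,
       nuclearNoiseSd = 50, cellContrast = 300, minClumpArea = 5)
}

# rasterize a filled ellipse; returns integer matrix with columns r, c
# (1-based pixel indices)
.rasterEllipse <- function(cr, cc, a, b, theta, nr, nc) {
  rmin <- max(1L, floor(cr - a)); rmax <- min(nr, ceiling(cr + a))
  cmin <- max(1L, floor(cc - a)); cmax <- min(nc, ceiling(cc + a))
  if (rmin > rmax || cmin > cmax) return(cbind(r = integer(0), c = integer(0)))
  rr <- rmin:rmax; ccs <- cmin:cmax
  dy <- outer(rr - cr, rep(1, length(ccs)))
  dx <- outer(rep(1, length(rr)), ccs - cc)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sel <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(r = rr[sel[, 1]], c = ccs[sel[, 2]])
}

# Plant one cell (body, clumps, nuclear blob) onto the field matrices.
# Operates on a cell-local window of the field so that large field
# matrices are never copied per cell; the caller assigns the returned
# window patches back in place. Coordinates are 1-based matrix indices;
# truth output is 0-based. Returns list(rows, cols, bfPatch, nucPatch,
# truth, log).
.addCell <- function(bf, nuc, center, params, clone, geo,
                     maxTries = 200L) {
  NR <- nrow(bf); NC <- ncol(bf)
  half <- max(geo$cellRadius, ceiling(4 * geo$nucleusSigma)) + 2L
  w0r <- max(1L, floor(center[1]) - half)
  w0c <- max(1L, floor(center[2]) - half)
  w1r <- min(NR, ceiling(center[1]) + half)
  w1c <- min(NC, ceiling(center[2]) + half)
  rows <- w0r:w1r; cols <- w0c:w1c
  bf <- bf[rows, cols, drop = FALSE]
  nuc <- nuc[rows, cols, drop = FALSE]
  nr <- nrow(bf); nc <- ncol(bf)
  cr <- center[1] - w0r + 1; cc <- center[2] - w0c + 1
  logs <- character(0)

  # faint cell body
  body <- .rasterEllipse(cr, cc, geo$cellRadius, geo$cellRadius, 0, nr, nc)
  bf[body] <- bf[body] - geo$cellContrast

  rate <- max(0, params@clumpRate + params@cloneOffsets[clone])
  k <- rpois(1L, rate)
  clumpField <- geo$clumpFieldFrac * geo$cellRadius
  occupied <- matrix(FALSE, nr, nc)
  wnr <- nr; wnc <- nc
  planted <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      area <- rlnorm(1L, params@clumpAreaMu, params@clumpAreaSigma)
      if (area < geo$minClumpArea) {
        logs <- c(logs, "clump resampled: target area below minimum")
        next
      }
      b <- sqrt(area / (pi * params@clumpAxisRatio))
      a <- params@clumpAxisRatio * b
      ang <- runif(1L, 0, pi)
      rad <- clumpField * sqrt(runif(1L))
      phi <- runif(1L, 0, 2 * pi)
      qr <- cr + rad * sin(phi); qc <- cc + rad * cos(phi)
      px <- .rasterEllipse(qr, qc, a, b, ang, nr, nc)
      if (nrow(px) < geo$minClumpArea) {
        logs <- c(logs, "clump resampled: rasterized area below minimum")
        next
      }
      if (any(sqrt((px[, 1] - cr)^2 + (px[, 2] - cc)^2) >
              geo$cellRadius - 1)) {
        logs <- c(logs, "clump resampled: outside cell region")
        next
      }
      # keep a 1-px gap so 8-connected components never merge
      lpx <- px
      clash <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          nb <- cbind(pmin(pmax(lpx[, 1] + dr, 1L), wnr),
                      pmin(pmax(lpx[, 2] + dc, 1L), wnc))
          if (any(occupied[nb])) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (clash) {
        logs <- c(logs, "clump resampled: overlaps existing clump")
        next
      }
      occupied[lpx] <- TRUE
      bf[px] <- bf[px] - params@clumpDarkness
      planted[[length(planted) + 1L]] <- list(
        center = c(qr, qc) - 1, area = nrow(px),
        axis_ratio = params@clumpAxisRatio)
      placed <- TRUE
      break
    }
    if (!placed)
      logs <- c(logs, sprintf(
        "clump dropped after %d placement attempts", maxTries))
  }

  # nuclear blob: 2-D Gaussian intensity
  w <- ceiling(4 * geo$nucleusSigma)
  rr <- max(1L, round(cr) - w):min(nr, round(cr) + w)
  ccs <- max(1L, round(cc) - w):min(nc, round(cc) + w)
  d2 <- outer((rr - cr)^2, rep(1, length(ccs))) +
    outer(rep(1, length(rr)), (ccs - cc)^2)
  nuc[rr, ccs] <- nuc[rr, ccs] +
    geo$nucleusAmplitude * exp(-d2 / (2 * geo$nucleusSigma^2))

  # truth in global 0-based field coordinates
  gcr <- center[1]; gcc <- center[2]
  h <- ceiling(2.5 * geo$nucleusSigma)
  box <- c(max(0, round(gcr) - 1 - h), max(0, round(gcc) - 1 - h),
           min(NR, round(gcr) - 1 + h), min(NC, round(gcc) - 1 + h))
  off <- c(w0r, w0c) - 1
  planted <- lapply(planted, function(pc) {
    pc$center <- pc$center + off
    pc
  })
  truth <- list(cell_center = c(gcr, gcc) - 1,
                nucleus_box = as.integer(box),
                planted_clumps = planted, genotype = params@name,
                clone = as.integer(clone))
  list(rows = rows, cols = cols, bfPatch = bf, nucPatch = nuc,
       truth = truth, log = logs)
}

.finalizeField <- function(bf, nuc, truth, logs) {
  bf <- pmin(pmax(round(bf), 0), 65535)
  nuc <- pmin(pmax(round(nuc), 0), 65535)
  new("FieldImagePair", bf = bf, nuclear = nuc, truth = truth, log = logs)
}

#' Generate a single-cell synthetic image pair
#'
#' Produces one field containing a single cell of the given genotype and
#' clone: a bright-field image whose darker elliptical clumps carry the
#' genotype signal, the paired nuclear-stain image with one bright blob at
#' the cell center, and a truth record listing every planted clump.
#'
#' @param params a [GenotypeParams-class] object.
#' @param clone clone index (1 or 2), selecting the clone offset.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   images.
#' @param fieldSize image size in pixels, `c(rows, cols)`.
#' @param geometry optional list overriding generator geometry (cellRadius,
#'   clumpFieldFrac, nucleusSigma, nucleusAmplitude, nuclearBackground,
#'   nuclearNoiseSd, cellContrast, minClumpArea).
#' @return a [FieldImagePair-class] with one truth record.
#' @export
#' @examples
#' fp <- generateCellImage(genotypeParams("WT"), seed = 1)
#' length(truthRecords(fp)[[1]]$planted_clumps)
generateCellImage <- function(params, clone = 1L, seed,
                              fieldSize = c(128L, 128L),
                              geometry = list()) {
  stopifnot(is(params, "GenotypeParams"))
  validObject(params)
  if (missing(seed)) stop("a seed is required")
  if (!clone %in% c(1L, 2L)) stop("clone must be 1 or 2")
  geo <- utils::modifyList(.synthDefaults(), geometry)
  withSeed(seed, {
    nr <- fieldSize[1]; nc <- fieldSize[2]
    bf <- matrix(rnorm(nr * nc, params@backgroundMean,
                       params@backgroundNoiseSd), nr, nc)
    nuc <- matrix(rnorm(nr * nc, geo$nuclearBackground, geo$nuclearNoiseSd),
                  nr, nc)
    res <- .addCell(bf, nuc, c((nr + 1) / 2, (nc + 1) / 2), params, clone,
                    geo)
    bf[res$rows, res$cols] <- res$bfPatch
    nuc[res$rows, res$cols] <- res$nucPatch
    .finalizeField(bf, nuc, list(res$truth), res$log)
  })
}

#' Generate a synthetic cell population over imaging fields
#'
#' Distributes `nCells` cells of one genotype over fields of
#' `cellsPerField` cells each (the last field takes the remainder), placing
#' cell centers by rejection sampling so that cells do not overlap. Clones
#' alternate cell by cell through `clones`. Each field uses a child seed
#' derived from the master seed, so any field is reproducible in isolation.
#'
#' @inheritParams generateCellImage
#' @param nCells total number of cells (>= 1); the returned truth records
#'   sum to exactly this count.
#' @param cellsPerField cells placed per field.
#' @param clones integer vector cycled over cells, usually `c(1L, 2L)`; pass
#'   a single value to emulate one clone's independent screen.
#' @return list of [FieldImagePair-class] objects.
#' @export
#' @examples
#' pop <- generatePopulation(genotypeParams("WT"), nCells = 4,
#'                           cellsPerField = 2, seed = 1,
#'                           fieldSize = c(256L, 256L))
#' length(pop)
generatePopulation <- function(params, nCells, cellsPerField = 27L, seed,
                               fieldSize = c(1024L, 1024L),
                               clones = c(1L, 2L), geometry = list()) {
  stopifnot(is(params, "GenotypeParams"), nCells >= 1)
  if (missing(seed)) stop("a seed is required")
  geo <- utils::modifyList(.synthDefaults(), geometry)
  nFields <- ceiling(nCells / cellsPerField)
  counts <- rep(cellsPerField, nFields)
  counts[nFields] <- nCells - cellsPerField * (nFields - 1)
  margin <- geo$cellRadius + 2
  minSep <- 2 * geo$cellRadius + 16
  nr <- fieldSize[1]; nc <- fieldSize[2]
  if (nr - 2 * margin <= 0 || nc - 2 * margin <= 0)
    stop(sprintf("field of %d x %d px cannot hold cells of radius %g",
                 nr, nc, geo$cellRadius))
  fields <- vector("list", nFields)
  globalIdx <- 0L
  for (f in seq_len(nFields)) {
    fields[[f]] <- withSeed(childSeed(seed, f), {
      bf <- matrix(rnorm(nr * nc, params@backgroundMean,
                         params@backgroundNoiseSd), nr, nc)
      nuc <- matrix(rnorm(nr * nc, geo$nuclearBackground,
                          geo$nuclearNoiseSd), nr, nc)
      centers <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(centers) < counts[f]) {
        tries <- tries + 1L
        if (tries > 500L * counts[f])
          stop(sprintf(
            paste0("field of %d x %d px cannot hold %d cells with ",
                   "minimum separation %g px"),
            nr, nc, counts[f], minSep))
        cand <- c(runif(1, margin, nr - margin), runif(1, margin,
                                                       nc - margin))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= minSep))
          centers <- rbind(centers, cand)
      }
      truth <- list(); logs <- character(0)
      for (i in seq_len(counts[f])) {
        clone <- clones[(globalIdx + i - 1L) %% length(clones) + 1L]
        res <- .addCell(bf, nuc, centers[i, ], params, clone, geo)
        bf[res$rows, res$cols] <- res$bfPatch
        nuc[res$rows, res$cols] <- res$nucPatch
        truth[[i]] <- res$truth
        logs <- c(logs, res$log)
      }
      .finalizeField(bf, nuc, truth, logs)
    })
    globalIdx <- globalIdx + counts[f]
  }
  fields
}

#' The default nine-genotype panel
#'
#' One wild-type reference plus eight mutants forming four paralog pairs
#' (PSMA2/PSMA7, PSMB5/PSMB6, PSME1/PSME2, UBQLN1/UBQLN2). Each pair shifts
#' the same clump parameter in the same direction relative to wild type
#' (clump count, clump area, clump elongation, and clump darkness
#' respectively), with slightly different magnitudes within a pair, so that
#' coefficient-profile clustering can recover the pairs. The wild-type
#' entry carries the reference parameters exactly.
#'
#' @return named list of nine [GenotypeParams-class] objects, wild type
#'   first.
#' @export
#' @examples
#' names(defaultGenotypePanel())
defaultGenotypePanel <- function() {
  wt <- genotypeParams("WT")
  list(
    WT = wt,
    PSMA2 = genotypeParams("PSMA2", clumpRate = 5.0),
    PSMA7 = genotypeParams("PSMA7", clumpRate = 5.5),
    PSMB5 = genotypeParams("PSMB5", clumpRate = 2.0,
                           clumpAreaMu = wt@clumpAreaMu + 0.55),
    PSMB6 = genotypeParams("PSMB6", clumpRate = 1.8,
                           clumpAreaMu = wt@clumpAreaMu + 0.60),
    PSME1 = genotypeParams("PSME1", clumpAxisRatio = 2.2),
    PSME2 = genotypeParams("PSME2", clumpAxisRatio = 2.5),
    UBQLN1 = genotypeParams("UBQLN1", clumpDarkness = 7800),
    UBQLN2 = genotypeParams("UBQLN2", clumpDarkness = 8200)
  )
}

#' Specification of a model-level synthetic effect
#'
#' Describes a feature-table shortcut past the imaging stages: wild-type
#' cells are equicorrelated standard multivariate normal over `nFeatures`
#' features; mutant cells are identical except for mean shifts `delta` (in
#' SD units) at `shiftedIndices`.
#'
#' @param nFeatures number of features (default 296, the package schema
#'   size).
#' @param shiftedIndices integer feature indices carrying the effect.
#' @param delta per-index mean shift in SD units (same length as
#'   `shiftedIndices`).
#' @param correlation common pairwise correlation rho in `[0, 1)`.
#' @return a list of class `EffectSpec`.
#' @export
#' @examples
#' effectSpec(shiftedIndices = 7L, delta = 3)
effectSpec <- function(nFeatures = 296L, shiftedIndices = integer(0),
                       delta = numeric(0), correlation = 0) {
  shiftedIndices <- as.integer(shiftedIndices)
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  if (length(delta) != length(shiftedIndices))
    stop("delta must match shiftedIndices in length")
  if (length(shiftedIndices) &&
      (any(shiftedIndices < 1L) || any(shiftedIndices > nFeatures) ||
       anyDuplicated(shiftedIndices)))
    stop("shiftedIndices must be unique indices in [1, nFeatures]")
  structure(list(nFeatures = as.integer(nFeatures),
                 shiftedIndices = shiftedIndices, delta = delta,
                 correlation = correlation),
            class = "EffectSpec")
}

#' Generate a model-level synthetic feature table
#'
#' Draws `nPerClass` wild-type and `nPerClass` mutant cells from the
#' equicorrelated normal model of [effectSpec()]. With all deltas zero the
#' two classes are exchangeable, so downstream discriminators are
#' calibrated at AUC 0.5; a single feature shifted by delta has the
#' closed-form single-feature AUC `pnorm(delta / sqrt(2))`.
#'
#' @param spec an [effectSpec()] object.
#' @param nPerClass cells per class (>= 2).
#' @param seed integer seed.
#' @return a feature table `data.frame` with columns `cell_id`, `genotype`
#'   (`"WT"`/`"MUT"`), `clone`, and `f001`..`fNNN`.
#' @export
#' @examples
#' tab <- generateFeatureTable(effectSpec(nFeatures = 10), 5, seed = 1)
#' dim(tab)
generateFeatureTable <- function(spec, nPerClass, seed) {
  stopifnot(inherits(spec, "EffectSpec"), nPerClass >= 2)
  if (missing(seed)) stop("a seed is required")
  p <- spec$nFeatures
  n <- 2L * nPerClass
  X <- withSeed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    if (spec$correlation > 0) {
      g <- rnorm(n)
      Z <- sqrt(1 - spec$correlation) * Z + sqrt(spec$correlation) * g
    }
    Z
  })
  if (length(spec$shiftedIndices))
    X[seq_len(nPerClass) + nPerClass, spec$shiftedIndices] <-
      sweep(X[seq_len(nPerClass) + nPerClass, spec$shiftedIndices,
              drop = FALSE], 2, spec$delta, "+")
  colnames(X) <- sprintf("f%03d", seq_len(p))
  data.frame(
    cell_id = c(sprintf("wt_%04d", seq_len(nPerClass)),
                sprintf("mut_%04d", seq_len(nPerClass))),
    genotype = rep(c("WT", "MUT"), each = nPerClass),
    clone = 1L, X, stringsAsFactors = FALSE)
}

#' Write a synthetic population to disk
#'
#' Writes each field as a 16-bit TIFF pair `<prefix>_F###_bf.tif` /
#' `<prefix>_F###_nuc.tif` plus one JSON truth file for the population.
#'
#' @param fields list of [FieldImagePair-class] objects.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the truth JSON path.
#' @export
writePopulation <- function(fields, dir, prefix = "pop") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(fields)) {
    tiff::writeTIFF(bfImage(fields[[f]]) / 65535,
                    file.path(dir, sprintf("%s_F%03d_bf.tif", prefix, f)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(nuclearImage(fields[[f]]) / 65535,
                    file.path(dir, sprintf("%s_F%03d_nuc.tif", prefix, f)),
                    bits.per.sample = 16L)
  }
  truth <- lapply(fields, truthRecords)
  path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field image pair from TIFF files
#'
#' @param bfPath,nucPath paths to the bright-field and nuclear 16-bit TIFFs.
#' @return a [FieldImagePair-class] (without truth records).
#' @export
readFieldPair <- function(bfPath, nucPath) {
  bf <- round(tiff::readTIFF(bfPath) * 65535)
  nuc <- round(tiff::readTIFF(nucPath) * 65535)
  new("FieldImagePair", bf = bf, nuclear = nuc, truth = list(),
      log = character(0))
}

#' Write / read a feature table CSV
#'
#' The interchange format is a CSV with header
#' `cell_id,genotype,clone,f001..f296`.
#'
#' @param table a feature table `data.frame`.
#' @param path file path.
#' @return `writeFeatureTable` invisibly returns `path`;
#'   `readFeatureTable` returns the `data.frame`.
#' @export
writeFeatureTable <- function(table, path) {
  .assertFeatureTable(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .assertFeatureTable(tab)
  tab
}
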