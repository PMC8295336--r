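#' The 296-feature texture schema
#'
#' The per-cell texture profile is a fixed, fully documented 296-entry
#' schema built from three families:
#'
#' * per-threshold clump morphology: for each of the 8 thresholds tau in
#'   the ladder, darker pixels are selected ([binarizeDark()]), connected
#'   components are identified as clumps ([labelClumps()]), and 26
#'   measurements are taken (19 clump statistics: count, density, areas,
#'   equivalent diameters, perimeters, noncircularity, extent, aspect;
#'   plus 7 measures of the binarized foreground as a whole) — 208 entries;
#' * across-threshold summaries: the sample mean and SD over the 8
#'   thresholds of each of the 26 measurements — 52 entries. The entries
#'   `tau_mean_n_clumps`, `tau_mean_mean_clump_area` and
#'   `tau_mean_mean_noncircularity` are the named "sample mean of number of
#'   clumps / average size of clump areas / average value of
#'   noncircularity" features;
#' * intensity-distribution statistics of the raw crop and of its Sobel
#'   gradient magnitude (18 each) — 36 entries.
#'
#' Thresholds are fractions of each crop's own min-max intensity range, so
#' all features are invariant to illumination offset and gain.
#'
#' @param tauLadder strictly increasing thresholds in (0, 1).
#' @return `data.frame` with columns `id` (`f001`..`f296`), `name`,
#'   `family`, `tau` (`NA` where not applicable) and `description`.
#' @export
#' @examples
#' nrow(featureSchema())  # 296
featureSchema <- function(tauLadder = seq(0.1, 0.8, by = 0.1)) {
  m <- .perTauMeasureNames()
  s <- .statNames()
  rows <- list()
  for (tau in tauLadder)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("%s_t%02d", m, round(100 * tau)),
      family = "per_tau", tau = tau,
      description = sprintf("%s at threshold tau=%.2f", m, tau))
  rows[[length(rows) + 1L]] <- data.frame(
    name = c(paste0("tau_mean_", m), paste0("tau_sd_", m)),
    family = "across_tau", tau = NA_real_,
    description = c(sprintf("sample mean over the tau ladder of %s", m),
                    sprintf("sample SD over the tau ladder of %s", m)))
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("int_", s), family = "intensity", tau = NA_real_,
    description = sprintf("pixel intensity %s", s))
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("grad_", s), family = "gradient", tau = NA_real_,
    description = sprintf("Sobel gradient magnitude %s", s))
  out <- do.call(rbind, rows)
  out <- data.frame(id = sprintf("f%03d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.perTauMeasureNames <- function() {
  c("n_clumps", "clump_density", "total_clump_area", "clump_area_fraction",
    "mean_clump_area", "sd_clump_area", "min_clump_area", "max_clump_area",
    "mean_clump_eqdiam", "max_clump_eqdiam", "mean_clump_perimeter",
    "sd_clump_perimeter", "max_clump_perimeter", "mean_noncircularity",
    "sd_noncircularity", "min_noncircularity", "max_noncircularity",
    "mean_clump_extent", "mean_clump_aspect",
    "bin_size", "bin_size_fraction", "bin_perimeter", "bin_thinness",
    "bin_bbox_fill", "bin_row_extent", "bin_col_extent")
}

.statNames <- function() {
  c("mean", "sd", "skewness", "kurtosis", "min", "max", "range", "median",
    "q10", "q20", "q30", "q40", "q60", "q70", "q80", "q90", "interdecile",
    "iqr")
}

#' Feature extraction configuration
#'
#' @param tauLadder strictly increasing thresholds in (0, 1), as fractions
#'   of each crop's intensity range; default `0.1..0.8` in steps of 0.1.
#' @param connectivity clump pixel connectivity, 4 or 8.
#' @param minClumpArea smallest component kept as a clump (pixels);
#'   suppresses single-pixel noise.
#' @return a list of class `FeatureConfig` with the frozen 296-entry
#'   schema attached.
#' @export
#' @examples
#' cfg <- featureConfig()
#' nrow(cfg$schema)
featureConfig <- function(tauLadder = seq(0.1, 0.8, by = 0.1),
                          connectivity = 8L, minClumpArea = 5L) {
  if (any(tauLadder <= 0) || any(tauLadder >= 1) ||
      any(diff(tauLadder) <= 0))
    stop("tauLadder must be strictly increasing within (0, 1)")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  schema <- featureSchema(tauLadder)
  if (nrow(schema) != 296L || anyDuplicated(schema$name))
    stop("schema must have 296 unique entries; use an 8-value tau ladder")
  structure(list(tauLadder = tauLadder,
                 connectivity = as.integer(connectivity),
                 minClumpArea = as.integer(minClumpArea), schema = schema,
                 schemaHash = .charHash(schema$name)),
            class = "FeatureConfig")
}

#' Write the feature schema as JSON
#'
#' @param config a [featureConfig()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFeatureSchema <- function(config, path) {
  jsonlite::write_json(config$schema, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select darker pixels at a relative threshold
#'
#' A pixel belongs to the mask when its value is strictly below
#' `min + tau * (max - min)` of the crop. A constant crop yields an empty
#' mask with a warning.
#'
#' @param crop numeric matrix.
#' @param tau threshold fraction in (0, 1).
#' @return logical matrix.
#' @export
#' @examples
#' binarizeDark(matrix(c(0, 0, 100, 100), 2), 0.5)
binarizeDark <- function(crop, tau) {
  stopifnot(is.matrix(crop), tau > 0, tau < 1)
  rng <- range(crop)
  if (rng[1] == rng[2]) {
    warning("constant crop: empty mask")
    return(matrix(FALSE, nrow(crop), ncol(crop)))
  }
  crop < rng[1] + tau * (rng[2] - rng[1])
}

#' Identify clumps as connected components of a dark mask
#'
#' Components of the given connectivity with area below `minClumpArea` are
#' discarded. Perimeter is the exposed-edge count: the number of
#' pixel edges bordering background or the image boundary.
#'
#' @param mask logical matrix.
#' @param config a [featureConfig()] object (connectivity and minimum
#'   area).
#' @return `data.frame` with one row per clump: `area`, `perimeter`,
#'   centroid (`centroid_r`, `centroid_c`, 0-based) and 0-based half-open
#'   bounding box (`r0`, `c0`, `r1`, `c1`).
#' @export
labelClumps <- function(mask, config = featureConfig()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- .cc_label(mask, config$connectivity)
  n <- attr(lab, "n")
  if (n == 0L)
    return(data.frame(area = numeric(0), perimeter = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      r0 = integer(0), c0 = integer(0), r1 = integer(0),
                      c1 = integer(0)))
  props <- .region_props(lab, n)
  props <- props[props$area >= config$minClumpArea, , drop = FALSE]
  rownames(props) <- NULL
  props[, c("area", "perimeter", "centroid_r", "centroid_c",
            "r0", "c0", "r1", "c1")]
}

#' Noncircularity of a shape
#'
#' `NC = 1 - 4 * pi * area / perimeter^2`, clamped below at 0; the
#' continuous ideal circle gives 0 and elongated or irregular shapes give
#' larger values. With the package's exposed-edge perimeter convention a
#' 3x3 pixel square gives `1 - 36 * pi / 144`.
#'
#' @param area shape area (> 0), vectorized.
#' @param perimeter exposed-edge perimeter (> 0), vectorized.
#' @return noncircularity value(s) in `[0, 1]`.
#' @export
#' @examples
#' noncircularity(9, 12)   # 3x3 square
#' noncircularity(9, 20)   # 1x9 bar, more elongated
noncircularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  pmax(0, 1 - 4 * pi * area / perimeter^2)
}

#' Summary measurements of a clump set
#'
#' Returns the 19 clump statistics of the feature schema, including the
#' spec triple `n_clumps`, `mean_clump_area` and `mean_noncircularity`.
#' An empty clump set yields all zeros by convention so feature vectors
#' are always complete.
#'
#' @param clumps `data.frame` from [labelClumps()].
#' @param cropArea crop area in pixels (for the density and fraction
#'   entries); `NA` leaves those entries `NA`.
#' @return named numeric vector of length 19.
#' @export
clumpMeasurements <- function(clumps, cropArea = NA_real_) {
  nm <- .perTauMeasureNames()[1:19]
  if (nrow(clumps) == 0L) {
    out <- setNames(numeric(19), nm)
    if (is.na(cropArea))
      out[c("clump_density", "clump_area_fraction")] <- NA_real_
    return(out)
  }
  a <- clumps$area; p <- clumps$perimeter
  nc <- noncircularity(a, p)
  eqd <- 2 * sqrt(a / pi)
  bh <- clumps$r1 - clumps$r0
  bw <- clumps$c1 - clumps$c0
  extent <- a / (bh * bw)
  aspect <- pmax(bh, bw) / pmin(bh, bw)
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  setNames(c(
    nrow(clumps), 1000 * nrow(clumps) / cropArea, sum(a),
    sum(a) / cropArea, mean(a), sd0(a), min(a), max(a), mean(eqd),
    max(eqd), mean(p), sd0(p), max(p), mean(nc), sd0(nc), min(nc),
    max(nc), mean(extent), mean(aspect)), nm)
}

#' Intensity-distribution statistics
#'
#' Mean, SD (denominator n-1), moment skewness, excess kurtosis, min, max,
#' range, median, the deciles 10..40 and 60..90 percent, the interdecile
#' range (q90 - q10) and the interquartile range. A constant sample has SD
#' 0 and skewness/kurtosis defined as 0 by convention.
#'
#' @param values numeric vector or matrix of pixel values.
#' @return named numeric vector of length 18.
#' @export
#' @examples
#' intensityStatistics(c(0, 0, 0, 100))["mean"]  # 25
intensityStatistics <- function(values) {
  x <- as.numeric(values)
  stopifnot(length(x) > 0)
  n <- length(x)
  mu <- mean(x)
  s <- if (n > 1L) sd(x) else 0
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  q <- quantile(x, c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.25,
                     0.75), names = FALSE)
  setNames(c(mu, s, skew, kurt, min(x), max(x), max(x) - min(x), q[5],
             q[1], q[2], q[3], q[4], q[6], q[7], q[8], q[9], q[9] - q[1],
             q[11] - q[10]),
           .statNames())
}

#' Shape measures of a binarized foreground
#'
#' Area, exposed-edge perimeter and thinness ratio
#' (`4 * pi * area / perimeter^2`, the complement of noncircularity) of
#' the union of all foreground pixels. An empty mask yields `(0, 0, 0)`.
#'
#' @param mask logical matrix.
#' @return named numeric vector `total_size`, `total_perimeter`,
#'   `thinness`.
#' @export
binarizedShapeMeasures <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  a <- sum(mask)
  if (a == 0L)
    return(c(total_size = 0, total_perimeter = 0, thinness = 0))
  p <- .mask_perimeter(mask)
  c(total_size = a, total_perimeter = p, thinness = 4 * pi * a / p^2)
}

# the 7 whole-foreground measures used inside the per-tau block
.binMeasures <- function(mask) {
  a <- sum(mask)
  n <- length(mask)
  if (a == 0L)
    return(c(bin_size = 0, bin_size_fraction = 0, bin_perimeter = 0,
             bin_thinness = 0, bin_bbox_fill = 0, bin_row_extent = 0,
             bin_col_extent = 0))
  p <- .mask_perimeter(mask)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  bh <- rows[2] - rows[1] + 1L
  bw <- cols[2] - cols[1] + 1L
  c(bin_size = a, bin_size_fraction = a / n, bin_perimeter = p,
    bin_thinness = 4 * pi * a / p^2, bin_bbox_fill = a / (bh * bw),
    bin_row_extent = bh / nrow(mask), bin_col_extent = bw / ncol(mask))
}

#' Extract the 296-feature texture profile of a cell crop
#'
#' Assembles, in the fixed order of [featureSchema()]: the 26 per-threshold
#' clump and binarized-shape measurements for each threshold of the
#' ladder, their across-threshold sample means and SDs, and the
#' intensity-distribution statistics of the raw crop and of its Sobel
#' gradient magnitude. On a constant crop the clump and shape families are
#' all zero and the intensity family follows its degenerate conventions.
#'
#' @param crop a [CellCrop-class] or numeric matrix.
#' @param config a [featureConfig()] object.
#' @return named numeric vector of length 296 (names `f001`..`f296`); all
#'   values finite.
#' @export
#' @examples
#' fp <- generateCellImage(genotypeParams("WT"), seed = 1)
#' v <- extractFeatures(bfImage(fp), featureConfig())
#' length(v)
extractFeatures <- function(crop, config = featureConfig()) {
  img <- if (is(crop, "CellCrop")) cropImage(crop) else crop
  stopifnot(is.matrix(img), inherits(config, "FeatureConfig"))
  taus <- config$tauLadder
  constant <- (max(img) == min(img))
  if (constant)
    warning("constant crop: clump and shape features are all zero")
  # fused compiled path; agrees exactly with the compositional
  # binarizeDark / labelClumps / clumpMeasurements route (tested)
  perTau <- .per_tau_block(img, taus, config$connectivity,
                           config$minClumpArea)
  colnames(perTau) <- .perTauMeasureNames()
  acrossMean <- colMeans(perTau)
  acrossSd <- apply(perTau, 2, sd)
  gx <- .conv2_reflect(img, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
  gy <- .conv2_reflect(img, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))
  grad <- sqrt(gx^2 + gy^2)
  vals <- c(as.vector(t(perTau)), acrossMean, acrossSd,
            intensityStatistics(img), intensityStatistics(grad))
  stopifnot(length(vals) == nrow(config$schema))
  vals[!is.finite(vals)] <- 0
  setNames(as.numeric(vals), config$schema$id)
}

#' Extract a feature table from a list of crops
#'
#' @param crops list of [CellCrop-class] objects.
#' @param config a [featureConfig()] object.
#' @param genotype,clone labels attached to every row; `clone` may be a
#'   vector with one entry per crop.
#' @return feature table `data.frame` (`cell_id`, `genotype`, `clone`,
#'   `f001`..`f296`).
#' @export
extractFeatureTable <- function(crops, config = featureConfig(),
                                genotype = NA_character_, clone = 1L) {
  stopifnot(length(crops) > 0)
  clone <- rep_len(as.integer(clone), length(crops))
  X <- t(vapply(crops, extractFeatures, numeric(nrow(config$schema)),
                config = config))
  ids <- vapply(crops, function(cr) cr@cellId, character(1))
  if (anyDuplicated(ids)) stop("cell ids must be unique in a population")
  data.frame(cell_id = ids, genotype = genotype, clone = clone, X,
             stringsAsFactors = FALSE)
}

# fixed kernels of the classical image-library preprocessing filters:
# 'blur' is the 5x5 ring mean (sum 16), 'edge_enhance' and 'sharpen' are
# the usual 3x3 center-heavy kernels; all sum to 1 so constant regions are
# unchanged
.filterKernels <- function() {
  list(
    blur = matrix(c(1, 1, 1, 1, 1,
                    1, 0, 0, 0, 1,
                    1, 0, 0, 0, 1,
                    1, 0, 0, 0, 1,
                    1, 1, 1, 1, 1), 5, 5, byrow = TRUE) / 16,
    edge_enhance = matrix(c(-1, -1, -1,
                            -1, 10, -1,
                            -1, -1, -1), 3, 3, byrow = TRUE) / 2,
    sharpen = matrix(c(-2, -2, -2,
                       -2, 32, -2,
                       -2, -2, -2), 3, 3, byrow = TRUE) / 16
  )
}

#' Apply a fixed preprocessing filter to a crop
#'
#' 2-D convolution with one of the fixed kernels `blur`, `edge_enhance` or
#' `sharpen` (classical image-library constants; all kernels sum to 1),
#' with reflected borders.
#'
#' @param crop a [CellCrop-class] or numeric matrix.
#' @param kind one of `"blur"`, `"edge_enhance"`, `"sharpen"`.
#' @return the filtered crop, same class as the input.
#' @export
#' @examples
#' applyFilter(matrix(1, 5, 5), "blur")
applyFilter <- function(crop, kind) {
  kernels <- .filterKernels()
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% names(kernels))
    stop("unknown filter kind; use one of: ",
         paste(names(kernels), collapse = ", "))
  if (is(crop, "CellCrop")) {
    out <- crop
    out@image <- .conv2_reflect(crop@image, kernels[[kind]])
    return(out)
  }
  stopifnot(is.matrix(crop))
  .conv2_reflect(crop, kernels[[kind]])
}
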