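#' Otsu threshold of a grayscale image
#'
#' Classical histogram threshold maximizing between-class variance over a
#' 256-bin histogram of the image's intensity range. Used by the nucleus
#' detector; returns `NA` for a constant image.
#'
#' @param img numeric matrix.
#' @param nbins histogram bins.
#' @return threshold value on the image's intensity scale, or `NA`.
#' @export
otsuThreshold <- function(img, nbins = 256L) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(img, br, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[nbins]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  br[which.max(sigma2) + 1L]
}

#' Detect nuclei in a nuclear-stain image
#'
#' Classical stand-in for a learned detector: global Otsu threshold,
#' 8-connected components, area filter, tight bounding boxes. Intended for
#' images where nuclei are bright, well-separated blobs (as the synthetic
#' generator produces). A constant image yields an empty result, not an
#' error.
#'
#' @param nuclearImage numeric matrix (nuclear-stain channel).
#' @param minArea,maxArea component area filter in pixels.
#' @return `data.frame` with 0-based half-open boxes (`r0`, `c0`, `r1`,
#'   `c1`), component `area` and centroid columns, sorted by (`r0`, `c0`).
#' @export
#' @examples
#' detectNuclei(matrix(0, 8, 8))  # empty
detectNuclei <- function(nuclearImage, minArea = 20, maxArea = Inf) {
  stopifnot(is.matrix(nuclearImage))
  empty <- data.frame(r0 = integer(0), c0 = integer(0), r1 = integer(0),
                      c1 = integer(0), area = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0))
  thr <- otsuThreshold(nuclearImage)
  if (is.na(thr)) return(empty)
  mask <- nuclearImage > thr
  lab <- .cc_label(mask, 8L)
  n <- attr(lab, "n")
  if (n == 0L) return(empty)
  props <- .region_props(lab, n)
  props <- props[props$area >= minArea & props$area <= maxArea, ,
                 drop = FALSE]
  if (nrow(props) == 0L) return(empty)
  out <- data.frame(r0 = props$r0, c0 = props$c0, r1 = props$r1,
                    c1 = props$c1, area = props$area,
                    centroid_r = props$centroid_r,
                    centroid_c = props$centroid_c)
  out <- out[order(out$r0, out$c0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop cellular regions from a bright-field image
#'
#' Each nucleus box is expanded by `expandFrac` times its height (width) on
#' every side; boxes whose expanded region would extend past the image
#' border are dropped, so no crop contains truncated morphology. Crops
#' carry provenance (source field, box, cell id).
#'
#' @param bfImage bright-field numeric matrix.
#' @param boxes `data.frame` of nucleus boxes from [detectNuclei()]
#'   (0-based half-open `r0`, `c0`, `r1`, `c1`).
#' @param expandFrac expansion fraction per side (0 keeps the nucleus box).
#' @param fieldId source-field label used in cell ids.
#' @param nuclearImage optional paired nuclear image; if supplied its
#'   dimensions must match `bfImage`.
#' @return list of [CellCrop-class] objects.
#' @export
cropCells <- function(bfImage, boxes, expandFrac = 0.5, fieldId = "field",
                      nuclearImage = NULL) {
  stopifnot(is.matrix(bfImage), expandFrac >= 0)
  if (!is.null(nuclearImage) &&
      !identical(dim(bfImage), dim(nuclearImage)))
    stop("bright-field and nuclear image dimensions differ")
  H <- nrow(bfImage); W <- ncol(bfImage)
  crops <- list()
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    er <- round(expandFrac * (b$r1 - b$r0))
    ec <- round(expandFrac * (b$c1 - b$c0))
    r0 <- b$r0 - er; r1 <- b$r1 + er
    c0 <- b$c0 - ec; c1 <- b$c1 + ec
    if (r0 < 0 || c0 < 0 || r1 > H || c1 > W) next  # touches border
    img <- bfImage[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
    crops[[length(crops) + 1L]] <- new(
      "CellCrop", image = img, sourceField = fieldId,
      box = as.integer(c(r0, c0, r1, c1)),
      cellId = sprintf("%s_%04d", fieldId, i))
  }
  crops
}

#' Match detected nuclei to ground truth
#'
#' Greedy one-to-one matching of detected box centers to truth cell
#' centers: the globally closest unmatched pair under `maxDist` is matched
#' repeatedly. Reports detection precision and recall.
#'
#' @param boxes `data.frame` from [detectNuclei()].
#' @param truth list of truth records (from the synthetic generator).
#' @param maxDist maximum center distance in pixels for a match.
#' @return list with `assignment` (`data.frame` of matched detection/truth
#'   indices and distances), `precision`, and `recall`.
#' @export
matchToTruth <- function(boxes, truth, maxDist = 20) {
  nd <- nrow(boxes); nt <- length(truth)
  if (nd == 0L || nt == 0L)
    return(list(assignment = data.frame(detection = integer(0),
                                        truth = integer(0),
                                        dist = numeric(0)),
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_))
  dc <- cbind((boxes$r0 + boxes$r1) / 2, (boxes$c0 + boxes$c1) / 2)
  tc <- t(vapply(truth, function(t) t$cell_center, numeric(2)))
  D <- outer(dc[, 1], tc[, 1], "-")^2 + outer(dc[, 2], tc[, 2], "-")^2
  D <- sqrt(D)
  D[D > maxDist] <- Inf
  det <- integer(0); tru <- integer(0); dist <- numeric(0)
  while (any(is.finite(D))) {
    idx <- arrayInd(which.min(D), dim(D))
    det <- c(det, idx[1]); tru <- c(tru, idx[2])
    dist <- c(dist, D[idx])
    D[idx[1], ] <- Inf
    D[, idx[2]] <- Inf
  }
  list(assignment = data.frame(detection = det, truth = tru, dist = dist),
       precision = length(det) / nd, recall = length(det) / nt)
}

#' Write crops as PNG files plus a manifest CSV
#'
#' The manifest records provenance (`cell_id,field,r0,c0,r1,c1`); images
#' are written as 16-bit grayscale PNGs scaled by 65535.
#'
#' @param crops list of [CellCrop-class] objects.
#' @param dir output directory (created if needed).
#' @param writeImages also write the PNGs (manifest is always written).
#' @return invisibly, the manifest path.
#' @export
writeCrops <- function(crops, dir, writeImages = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(crops, function(cr)
    data.frame(cell_id = cr@cellId, field = cr@sourceField,
               r0 = cr@box[1], c0 = cr@box[2], r1 = cr@box[3],
               c1 = cr@box[4], stringsAsFactors = FALSE)))
  path <- file.path(dir, "crops_manifest.csv")
  write.csv(man, path, row.names = FALSE)
  if (writeImages)
    for (cr in crops)
      png::writePNG(cropImage(cr) / 65535,
                    file.path(dir, paste0(cr@cellId, ".png")))
  invisible(path)
}
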