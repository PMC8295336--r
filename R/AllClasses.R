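#' Genotype parameters for the synthetic image generator
#'
#' Describes one genotype's dark-clump phenotype: the expected number of
#' clumps per cell (Poisson mean), the log-normal distribution of clump
#' pixel areas, the ellipse axis ratio that drives noncircularity, the
#' intensity offset of clump pixels below the image background, the
#' background model, and the pair of small additive clump-rate offsets
#' distinguishing the two independently isolated clones of the genotype.
#'
#' @slot name genotype label, e.g. `"WT"` or `"PSMB5"`.
#' @slot clumpRate expected clumps per cell (Poisson mean, >= 0).
#' @slot clumpAreaMu,clumpAreaSigma log-scale mean and SD of the log-normal
#'   clump pixel area.
#' @slot clumpAxisRatio major/minor axis ratio of the elliptical clumps
#'   (>= 1; 1 = circular).
#' @slot clumpDarkness intensity offset of clump pixels below background,
#'   in gray levels.
#' @slot backgroundMean,backgroundNoiseSd bright-field background gray level
#'   and Gaussian noise SD.
#' @slot cloneOffsets additive shifts on `clumpRate` for the two clones.
#'
#' @seealso [genotypeParams()], [defaultGenotypePanel()]
#' @export
setClass("GenotypeParams",
  representation(
    name = "character",
    clumpRate = "numeric",
    clumpAreaMu = "numeric",
    clumpAreaSigma = "numeric",
    clumpAxisRatio = "numeric",
    clumpDarkness = "numeric",
    backgroundMean = "numeric",
    backgroundNoiseSd = "numeric",
    cloneOffsets = "numeric"
  )
)

setValidity("GenotypeParams", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (object@clumpRate < 0) msg <- c(msg, "clumpRate must be >= 0")
  if (object@clumpAxisRatio < 1) msg <- c(msg, "clumpAxisRatio must be >= 1")
  if (object@clumpAreaSigma < 0) msg <- c(msg, "clumpAreaSigma must be >= 0")
  if (object@backgroundMean - object@clumpDarkness < 0)
    msg <- c(msg, "backgroundMean - clumpDarkness must be >= 0")
  if (object@backgroundNoiseSd < 0)
    msg <- c(msg, "backgroundNoiseSd must be >= 0")
  if (length(object@cloneOffsets) != 2L)
    msg <- c(msg, "exactly 2 clone offsets are required")
  if (length(object@cloneOffsets) == 2L &&
      any(object@clumpRate + object@cloneOffsets < 0))
    msg <- c(msg, "clumpRate + cloneOffsets must be >= 0 for both clones")
  if (length(msg)) msg else TRUE
})

#' Construct genotype parameters
#'
#' Defaults describe the wild-type reference phenotype used throughout the
#' package: about three perinuclear dark clumps per cell of median area
#' 30 px, nearly circular, 6000 gray levels darker than a 16-bit background
#' of 30000 with noise SD 200, and clone offsets of +/- 0.15 clumps.
#'
#' @param name genotype label.
#' @param clumpRate,clumpAreaMu,clumpAreaSigma,clumpAxisRatio,clumpDarkness
#'   clump phenotype parameters; see [GenotypeParams-class].
#' @param backgroundMean,backgroundNoiseSd background model in gray levels.
#' @param cloneOffsets length-2 additive shifts on `clumpRate` per clone.
#' @return a [GenotypeParams-class] object.
#' @export
#' @examples
#' genotypeParams("WT")
#' genotypeParams("PSMB5", clumpAreaMu = log(30) + 0.3)
genotypeParams <- function(name, clumpRate = 3, clumpAreaMu = log(30),
                           clumpAreaSigma = 0.45, clumpAxisRatio = 1.2,
                           clumpDarkness = 6000, backgroundMean = 30000,
                           backgroundNoiseSd = 200,
                           cloneOffsets = c(0.15, -0.15)) {
  new("GenotypeParams", name = name, clumpRate = clumpRate,
      clumpAreaMu = clumpAreaMu, clumpAreaSigma = clumpAreaSigma,
      clumpAxisRatio = clumpAxisRatio, clumpDarkness = clumpDarkness,
      backgroundMean = backgroundMean, backgroundNoiseSd = backgroundNoiseSd,
      cloneOffsets = cloneOffsets)
}

#' @describeIn GenotypeParams-class compact display
#' @param object a `GenotypeParams` object.
#' @export
setMethod("show", "GenotypeParams", function(object) {
  cat("GenotypeParams '", object@name, "': rate=", object@clumpRate,
      " areaMu=", round(object@clumpAreaMu, 3),
      " axisRatio=", object@clumpAxisRatio,
      " darkness=", object@clumpDarkness, "\n", sep = "")
})

#' Paired bright-field / nuclear-stain field image with ground truth
#'
#' One imaging field: the bright-field channel, the nuclear-stain channel
#' (same shape), and for synthetic fields the list of truth records (one per
#' planted cell, each a list with `cell_center`, `nucleus_box`,
#' `planted_clumps`, `genotype`, `clone`). Boxes are 0-based half-open
#' `c(r0, c0, r1, c1)`.
#'
#' @slot bf,nuclear numeric matrices of identical dimension, gray levels in
#'   `[0, 65535]`.
#' @slot truth list of truth records.
#' @slot log character vector of generator notes (e.g. resampled clumps).
#' @export
setClass("FieldImagePair",
  representation(bf = "matrix", nuclear = "matrix", truth = "list",
                 log = "character")
)

setValidity("FieldImagePair", function(object) {
  msg <- character()
  if (!identical(dim(object@bf), dim(object@nuclear)))
    msg <- c(msg, "bf and nuclear images must have identical dimensions")
  rng <- range(object@bf, object@nuclear)
  if (rng[1] < 0 || rng[2] >= 65536)
    msg <- c(msg, "pixel values must lie in [0, 65536)")
  if (length(msg)) msg else TRUE
})

#' @describeIn FieldImagePair-class compact display
#' @param object a `FieldImagePair` object.
#' @export
setMethod("show", "FieldImagePair", function(object) {
  cat("FieldImagePair ", nrow(object@bf), "x", ncol(object@bf), ", ",
      length(object@truth), " cell(s)\n", sep = "")
})

#' @describeIn FieldImagePair-class bright-field channel
#' @export
bfImage <- function(object) object@bf

#' @describeIn FieldImagePair-class nuclear-stain channel
#' @export
nuclearImage <- function(object) object@nuclear

#' @describeIn FieldImagePair-class ground-truth records
#' @export
truthRecords <- function(object) object@truth

#' Single-cell bright-field crop
#'
#' The unit of feature extraction: a bright-field sub-image cut around one
#' detected nucleus, with provenance (source field, bounding box, cell id).
#'
#' @slot image numeric matrix (gray levels).
#' @slot sourceField field identifier.
#' @slot box integer `c(r0, c0, r1, c1)`, 0-based half-open, in source-field
#'   coordinates.
#' @slot cellId unique cell label within a population.
#' @export
setClass("CellCrop",
  representation(image = "matrix", sourceField = "character",
                 box = "integer", cellId = "character")
)

setValidity("CellCrop", function(object) {
  msg <- character()
  b <- object@box
  if (length(b) != 4L) msg <- c(msg, "box must be c(r0, c0, r1, c1)")
  if (length(b) == 4L) {
    if (b[3] <= b[1] || b[4] <= b[2])
      msg <- c(msg, "box must satisfy r1 > r0 and c1 > c0")
    if (!identical(dim(object@image),
                   as.integer(c(b[3] - b[1], b[4] - b[2]))))
      msg <- c(msg, "image dimensions must equal box dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CellCrop-class compact display
#' @param object a `CellCrop` object.
#' @export
setMethod("show", "CellCrop", function(object) {
  cat("CellCrop '", object@cellId, "' ", nrow(object@image), "x",
      ncol(object@image), " from ", object@sourceField, "\n", sep = "")
})

#' @describeIn CellCrop-class the pixel matrix of the crop
#' @export
cropImage <- function(object) object@image

#' L1-regularized logistic discriminative model
#'
#' A fitted lasso-logistic discriminator of mutant versus wild-type cells:
#' intercept `alpha`, coefficient vector `beta` (zeros mark unselected
#' features), penalty `lambda`, and fit metadata (convergence, objective
#' trace, feature-schema hash, seed). The linear predictor of a cell with
#' feature vector `x` is `beta' x + alpha` and the posterior probability of
#' being a mutant is the logistic transform of it; see [linearPredictor()].
#'
#' @slot alpha intercept.
#' @slot beta named numeric coefficient vector.
#' @slot lambda L1 penalty weight (>= 0).
#' @slot fitMeta list of fit metadata.
#' @export
setClass("DiscriminativeModel",
  representation(alpha = "numeric", beta = "numeric", lambda = "numeric",
                 fitMeta = "list")
)

setValidity("DiscriminativeModel", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || !is.finite(object@alpha))
    msg <- c(msg, "alpha must be a single finite number")
  if (length(object@lambda) != 1L || object@lambda < 0)
    msg <- c(msg, "lambda must be a single number >= 0")
  if (any(!is.finite(object@beta)))
    msg <- c(msg, "beta must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn DiscriminativeModel-class compact display
#' @param object a `DiscriminativeModel` object.
#' @export
setMethod("show", "DiscriminativeModel", function(object) {
  cat("DiscriminativeModel: ", length(object@beta), " features, ",
      sum(object@beta != 0), " selected, lambda=",
      signif(object@lambda, 4), ", alpha=", signif(object@alpha, 4), "\n",
      sep = "")
})

#' @describeIn DiscriminativeModel-class coefficient vector (named; zeros =
#'   unselected features)
#' @param object a `DiscriminativeModel` object.
#' @export
setGeneric("modelCoefficients",
           function(object) standardGeneric("modelCoefficients"))

#' @rdname DiscriminativeModel-class
#' @export
setMethod("modelCoefficients", "DiscriminativeModel",
          function(object) object@beta)

#' @describeIn DiscriminativeModel-class model intercept
#' @export
setGeneric("modelIntercept",
           function(object) standardGeneric("modelIntercept"))

#' @rdname DiscriminativeModel-class
#' @export
setMethod("modelIntercept", "DiscriminativeModel",
          function(object) object@alpha)

#' @describeIn DiscriminativeModel-class names of features with nonzero
#'   coefficients
#' @export
setGeneric("selectedFeatures",
           function(object) standardGeneric("selectedFeatures"))

#' @rdname DiscriminativeModel-class
#' @export
setMethod("selectedFeatures", "DiscriminativeModel", function(object) {
  names(object@beta)[object@beta != 0]
})

#' Labeled, preprocessed design matrix for discrimination
#'
#' Cells-by-features standardized matrix `X` with binary labels `y`
#' (1 = mutant, 0 = wild type) and per-cell clone ids. Built by
#' [buildDataset()] after wild-type standardization and outlier removal.
#'
#' @slot X numeric matrix, cells x features, all finite.
#' @slot y integer labels in \{0, 1\}.
#' @slot clone integer clone id per row.
#' @slot removalLog data.frame of outlier removals that produced this set.
#' @export
setClass("CellDataset",
  representation(X = "matrix", y = "integer", clone = "integer",
                 removalLog = "data.frame")
)

setValidity("CellDataset", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "nrow(X) must equal length(y)")
  if (length(object@clone) && length(object@clone) != length(object@y))
    msg <- c(msg, "clone must match length(y)")
  if (any(!is.finite(object@X))) msg <- c(msg, "X must be all finite")
  if (!all(object@y %in% c(0L, 1L))) msg <- c(msg, "y must be 0/1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CellDataset-class compact display
#' @param object a `CellDataset` object.
#' @export
setMethod("show", "CellDataset", function(object) {
  cat("CellDataset: ", nrow(object@X), " cells x ", ncol(object@X),
      " features (", sum(object@y == 1L), " mutant / ",
      sum(object@y == 0L), " wild type)\n", sep = "")
})

#' Construct a CellDataset
#'
#' @param X numeric cells-by-features matrix.
#' @param y binary labels (1 = mutant, 0 = wild type).
#' @param clone optional integer clone ids per row.
#' @param removalLog optional data.frame of outlier removals.
#' @return a [CellDataset-class] object.
#' @export
cellDataset <- function(X, y, clone = integer(0),
                        removalLog = data.frame()) {
  new("CellDataset", X = as.matrix(X), y = as.integer(y),
      clone = as.integer(clone), removalLog = removalLog)
}

#' @describeIn CellDataset-class design matrix
#' @export
designMatrix <- function(object) object@X

#' @describeIn CellDataset-class binary labels
#' @export
labels01 <- function(object) object@y
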