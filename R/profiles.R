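#' Assemble the genotypes-by-features coefficient profile matrix
#'
#' One row per genotype, containing the regression coefficients of that
#' genotype's full-data refit; exact zeros mark features not selected by
#' the L1 penalty. All models must share the same feature schema.
#'
#' @param modelsByGenotype named list of [DiscriminativeModel-class]
#'   objects.
#' @return numeric matrix (genotypes x features) with attribute
#'   `nSelected` (per-genotype selected-feature counts).
#' @export
coefficientProfiles <- function(modelsByGenotype) {
  stopifnot(length(modelsByGenotype) >= 1,
            !is.null(names(modelsByGenotype)))
  hashes <- vapply(modelsByGenotype, function(m) {
    h <- m@fitMeta$schemaHash
    if (is.null(h)) .charHash(names(m@beta)) else h
  }, character(1))
  if (length(unique(hashes)) != 1L)
    stop("models do not share one feature schema")
  mat <- do.call(rbind, lapply(modelsByGenotype, modelCoefficients))
  rownames(mat) <- names(modelsByGenotype)
  attr(mat, "nSelected") <- rowSums(mat != 0)
  mat
}

#' Pearson similarity between coefficient profiles
#'
#' Symmetric matrix of Pearson correlations between the rows of a profile
#' matrix; unit diagonal. The corresponding clustering distance is
#' `1 - r`. A constant (e.g. all-zero) profile row has no defined
#' correlation and raises an error naming the genotype.
#'
#' @param matrix profile matrix from [coefficientProfiles()].
#' @return correlation matrix with unit diagonal.
#' @export
profileSimilarity <- function(matrix) {
  stopifnot(nrow(matrix) >= 2L)
  sds <- apply(matrix, 1, sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant coefficient profile for genotype(s): ",
         paste(rownames(matrix)[sds == 0 | !is.finite(sds)],
               collapse = ", "))
  r <- cor(t(matrix))
  diag(r) <- 1
  r
}

#' Complete-linkage clustering of coefficient profiles
#'
#' Agglomerative complete-linkage clustering of a distance matrix
#' (typically `1 - profileSimilarity(mat)`). Merge heights are
#' non-decreasing (complete linkage is ultrametric), which is asserted.
#'
#' @param distMatrix symmetric distance matrix with zero diagonal.
#' @return list of class `ProfileDendrogram` with `hclust` (the
#'   [stats::hclust()] tree) and `newick` (Newick string with branch
#'   heights).
#' @export
#' @examples
#' d <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' clusterProfiles(d)$hclust$height
clusterProfiles <- function(distMatrix) {
  distMatrix <- as.matrix(distMatrix)
  if (max(abs(distMatrix - t(distMatrix))) > 1e-8)
    stop("distance matrix must be symmetric")
  hc <- hclust(as.dist(distMatrix), method = "complete")
  if (is.unsorted(hc$height, strictly = FALSE))
    stop("internal error: complete-linkage heights decreased")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = nwk),
            class = "ProfileDendrogram")
}

#' @export
print.ProfileDendrogram <- function(x, ...) {
  cat("ProfileDendrogram with", length(x$hclust$labels), "leaves;",
      "heights:", paste(signif(x$hclust$height, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Are given leaf pairs monophyletic in a dendrogram?
#'
#' A pair is monophyletic when the two leaves are merged together before
#' either joins any other leaf, i.e. some merge joins exactly the two
#' singletons.
#'
#' @param dendro a `ProfileDendrogram` or `hclust` object.
#' @param pairs list of length-2 character vectors of leaf labels.
#' @return named logical vector, one entry per pair.
#' @export
pairsMonophyletic <- function(dendro, pairs) {
  hc <- if (inherits(dendro, "ProfileDendrogram")) dendro$hclust
        else dendro
  vapply(pairs, function(p) {
    i <- match(p, hc$labels)
    if (any(is.na(i))) stop("pair labels not in dendrogram")
    any(hc$merge[, 1] == -i[1] & hc$merge[, 2] == -i[2] |
          hc$merge[, 1] == -i[2] & hc$merge[, 2] == -i[1])
  }, logical(1), USE.NAMES = TRUE)
}

#' Features specific to a paralog pair
#'
#' Features with positive regression coefficients in both members of the
#' pair but zero or negative coefficients in every other genotype; the
#' symmetric variant (negative in both pair members, zero or positive
#' elsewhere) is reported as well.
#'
#' @param matrix profile matrix from [coefficientProfiles()].
#' @param pair character vector of the two pair row names.
#' @param others character vector of the remaining rows of interest;
#'   must not overlap `pair`.
#' @return list with `positive` and `negative` feature-name vectors.
#' @export
paralogSpecificFeatures <- function(matrix, pair, others) {
  stopifnot(length(pair) == 2L)
  if (length(intersect(pair, others)))
    stop("pair and others must not overlap")
  if (!all(c(pair, others) %in% rownames(matrix)))
    stop("unknown genotype row names")
  P <- matrix[pair, , drop = FALSE]
  O <- matrix[others, , drop = FALSE]
  pos <- colSums(P > 0) == 2L & colSums(O <= 0) == length(others)
  neg <- colSums(P < 0) == 2L & colSums(O >= 0) == length(others)
  list(positive = colnames(matrix)[pos],
       negative = colnames(matrix)[neg])
}
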