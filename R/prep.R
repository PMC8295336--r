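#' Wild-type reference statistics
#'
#' Per-feature sample mean and SD (denominator n-1) computed from the
#' wild-type cell population. Every downstream population is standardized
#' against these statistics so that feature values are expressed as
#' deviations from the wild type. Features that are constant in the wild
#' type (SD 0) are flagged; standardization maps them to 0.
#'
#' @param wtTable wild-type feature table (>= 2 cells).
#' @return list of class `ReferenceStats` with `mean`, `sd`, `zeroSd`
#'   (logical flags) and `features` (column names).
#' @export
#' @examples
#' tab <- generateFeatureTable(effectSpec(nFeatures = 5), 10, seed = 1)
#' ref <- wtReferenceStats(tab[tab$genotype == "WT", ])
wtReferenceStats <- function(wtTable) {
  fc <- .assertFeatureTable(wtTable)
  if (nrow(wtTable) < 2L) stop("need at least 2 wild-type cells")
  X <- as.matrix(wtTable[, fc])
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  zero <- !is.finite(s) | s == 0
  if (any(zero))
    warning(sum(zero), " feature(s) constant in the wild type; ",
            "they standardize to 0")
  structure(list(mean = m, sd = s, zeroSd = zero, features = fc),
            class = "ReferenceStats")
}

#' Standardize a feature table against the wild-type reference
#'
#' Each feature value becomes `z = (value - ref.mean) / ref.sd`. Zero-SD
#' reference features map to 0.
#'
#' @param table a feature table.
#' @param ref a [wtReferenceStats()] object.
#' @return the standardized table.
#' @export
standardizeFeatures <- function(table, ref) {
  stopifnot(inherits(ref, "ReferenceStats"))
  fc <- .assertFeatureTable(table)
  if (!identical(fc, ref$features))
    stop("feature schema mismatch between table and reference")
  X <- as.matrix(table[, fc])
  s <- ref$sd
  s[ref$zeroSd] <- 1
  Z <- sweep(sweep(X, 2, ref$mean), 2, s, "/")
  Z[, ref$zeroSd] <- 0
  table[fc] <- as.data.frame(Z)
  table
}

#' Remove (or clip) outlier cells at a z-score cutoff
#'
#' On a standardized table, the default policy `"drop_cell"` removes every
#' cell with `|z| > cutoff` in at least one feature; the alternative
#' `"clip"` truncates offending values to `+/- cutoff` and keeps all
#' cells. Either way, the removal log records each offending
#' (cell, feature, z) triple. Dropping whole cells at 296 features removes
#' a substantial fraction of even well-behaved populations, which is why
#' the clip policy is offered.
#'
#' @param ztable standardized feature table.
#' @param cutoff z-score cutoff (> 0), default 3.
#' @param policy `"drop_cell"` or `"clip"`.
#' @return list with `table` (filtered or clipped) and `log`
#'   (`data.frame` with `cell_id`, `feature`, `z`).
#' @export
removeOutliers <- function(ztable, cutoff = 3,
                           policy = c("drop_cell", "clip")) {
  if (cutoff <= 0) stop("cutoff must be positive")
  policy <- match.arg(policy)
  fc <- .assertFeatureTable(ztable)
  Z <- as.matrix(ztable[, fc])
  bad <- abs(Z) > cutoff
  idx <- which(bad, arr.ind = TRUE)
  log <- data.frame(cell_id = ztable$cell_id[idx[, 1]],
                    feature = fc[idx[, 2]], z = Z[idx],
                    stringsAsFactors = FALSE)
  if (policy == "drop_cell") {
    keep <- rowSums(bad) == 0L
    out <- ztable[keep, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    Z[bad] <- sign(Z[bad]) * cutoff
    out <- ztable
    out[fc] <- as.data.frame(Z)
  }
  list(table = out, log = log)
}

#' Pool the feature tables of two clones of one genotype
#'
#' Row-concatenation preserving per-cell clone labels; both tables must
#' share the feature schema and the genotype and be non-empty.
#'
#' @param tableClone1,tableClone2 feature tables of the two clones.
#' @return the pooled feature table.
#' @export
poolClones <- function(tableClone1, tableClone2) {
  fc1 <- .assertFeatureTable(tableClone1)
  fc2 <- .assertFeatureTable(tableClone2)
  if (nrow(tableClone1) == 0L || nrow(tableClone2) == 0L)
    stop("cannot pool an empty clone table")
  if (!identical(fc1, fc2)) stop("feature schema mismatch between clones")
  g1 <- unique(tableClone1$genotype)
  g2 <- unique(tableClone2$genotype)
  if (length(g1) != 1L || !identical(g1, g2))
    stop("genotype mismatch between clone tables: ",
         paste(g1, collapse = ","), " vs ", paste(g2, collapse = ","))
  out <- rbind(tableClone1, tableClone2)
  rownames(out) <- NULL
  out
}

#' Build a labeled dataset from standardized wild-type and mutant tables
#'
#' @param wtTable,mutTable standardized (and outlier-handled) feature
#'   tables; wild type is labeled 0, mutant 1.
#' @param removalLog optional combined removal log to carry along.
#' @return a [CellDataset-class].
#' @export
buildDataset <- function(wtTable, mutTable, removalLog = data.frame()) {
  fc <- .assertFeatureTable(wtTable)
  if (!identical(fc, .assertFeatureTable(mutTable)))
    stop("feature schema mismatch between tables")
  X <- rbind(as.matrix(wtTable[, fc]), as.matrix(mutTable[, fc]))
  rownames(X) <- c(wtTable$cell_id, mutTable$cell_id)
  y <- c(rep(0L, nrow(wtTable)), rep(1L, nrow(mutTable)))
  clone <- as.integer(c(wtTable$clone, mutTable$clone))
  cellDataset(X, y, clone, removalLog)
}
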