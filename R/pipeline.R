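#' Default experiment configuration
#'
#' Assembles the configuration for [runExperiment()]. All randomness flows
#' from the single master seed. The default problem size (cells per clone,
#' field size) is chosen so that a full nine-genotype run is a
#' desk-scale computation; the genotype panel itself defaults to
#' [defaultGenotypePanel()].
#'
#' @param seed master seed (mandatory).
#' @param outDir output directory (mandatory).
#' @param panel named list of [GenotypeParams-class]; the first entry is
#'   the wild-type reference.
#' @param nCellsPerClone cells generated per clone of each genotype.
#' @param cellsPerField cells per imaging field.
#' @param fieldSize field size in pixels `c(rows, cols)`.
#' @param expandFrac crop expansion, see [cropCells()].
#' @param cutoff,policy outlier handling, see [removeOutliers()]; the
#'   pipeline defaults to `"clip"` because cell-wise dropping at a 3-SD
#'   cutoff over 296 heavy-tailed image features removes nearly every
#'   cell.
#' @param cv list of [nestedCV()] settings: `K`, `innerK`, `nLambda`,
#'   `decades`.
#' @param featureCfg a [featureConfig()].
#' @param geometry generator geometry overrides, see
#'   [generateCellImage()].
#' @return a list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(seed, outDir, panel = defaultGenotypePanel(),
                             nCellsPerClone = 75L, cellsPerField = 10L,
                             fieldSize = c(512L, 512L), expandFrac = 0.5,
                             cutoff = 3, policy = "clip",
                             cv = list(K = 10L, innerK = 10L,
                                       nLambda = 100L, decades = 4),
                             featureCfg = featureConfig(),
                             geometry = list()) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  if (missing(outDir) || is.null(outDir)) stop("outDir is mandatory")
  cv <- utils::modifyList(list(K = 10L, innerK = 10L, nLambda = 100L,
                               decades = 4), cv)
  structure(list(seed = as.integer(seed), outDir = outDir, panel = panel,
                 nCellsPerClone = as.integer(nCellsPerClone),
                 cellsPerField = as.integer(cellsPerField),
                 fieldSize = as.integer(fieldSize),
                 expandFrac = expandFrac, cutoff = cutoff,
                 policy = policy, cv = cv, featureCfg = featureCfg,
                 geometry = geometry),
            class = "ExperimentConfig")
}

#' Read an experiment configuration from a YAML file
#'
#' Scalar fields of [experimentConfig()] may be given in YAML; the
#' genotype panel and feature configuration use the package defaults.
#'
#' @param path YAML file path.
#' @return an `ExperimentConfig`.
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("a master seed is mandatory")
  if (is.null(raw$outDir)) stop("outDir is mandatory")
  args <- raw[intersect(names(raw),
                        c("seed", "outDir", "nCellsPerClone",
                          "cellsPerField", "fieldSize", "expandFrac",
                          "cutoff", "policy", "cv"))]
  do.call(experimentConfig, args)
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# segment one population and extract its feature table, labeling each
# crop by the clone of its nearest truth record
.fieldsToTable <- function(fields, genotype, cfg) {
  crops <- list(); clones <- integer(0)
  geo <- utils::modifyList(.synthDefaults(), cfg$geometry)
  for (f in seq_along(fields)) {
    fp <- fields[[f]]
    boxes <- detectNuclei(nuclearImage(fp))
    cr <- cropCells(bfImage(fp), boxes, expandFrac = cfg$expandFrac,
                    fieldId = sprintf("%s_F%03d", genotype, f))
    if (length(cr) == 0L) next
    kept <- do.call(rbind, lapply(cr, function(x)
      data.frame(r0 = x@box[1], c0 = x@box[2], r1 = x@box[3],
                 c1 = x@box[4])))
    m <- matchToTruth(kept, truthRecords(fp), maxDist = geo$cellRadius / 2)
    keep <- m$assignment$detection
    crops <- c(crops, cr[keep])
    clones <- c(clones, vapply(truthRecords(fp)[m$assignment$truth],
                               function(t) t$clone, integer(1)))
  }
  if (length(crops) == 0L)
    stop("no cells segmented for genotype ", genotype)
  extractFeatureTable(crops, cfg$featureCfg, genotype = genotype,
                      clone = clones)
}

#' Run the full synthetic discrimination experiment
#'
#' Orchestrates all stages from one configuration and master seed:
#' synthetic image generation per genotype and clone, nucleus detection
#' and cropping, 296-feature quantification, wild-type standardization
#' with outlier removal and clone pooling, per-genotype nested-CV
#' evaluation plus a full-data cross-validated refit, and
#' coefficient-profile clustering. Writes per-genotype model JSONs, a
#' summary CSV, the profile and correlation CSVs, a Newick dendrogram and
#' a machine-readable run manifest into `config$outDir`. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config an [experimentConfig()] (or a YAML path understood by
#'   [readExperimentConfig()]).
#' @return invisibly, the results bundle: tables, datasets, CV results,
#'   models, profile matrix, similarity matrix, dendrogram, summary and
#'   output paths.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- readExperimentConfig(config)
  if (!inherits(config, "ExperimentConfig"))
    stop("config must be an ExperimentConfig or a YAML path")
  if (is.null(config$seed)) stop("a master seed is mandatory")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$outDir, "models"), showWarnings = FALSE)
  panel <- config$panel
  wtName <- names(panel)[1]
  mutants <- names(panel)[-1]

  rawTables <- .stage("synthesize+segment+features", {
    out <- list()
    for (g in seq_along(panel)) {
      gname <- names(panel)[g]
      perClone <- lapply(1:2, function(cl) {
        fields <- generatePopulation(
          panel[[g]], nCells = config$nCellsPerClone,
          cellsPerField = config$cellsPerField, clones = cl,
          seed = childSeed(config$seed, 100L * g + cl),
          fieldSize = config$fieldSize, geometry = config$geometry)
        tab <- .fieldsToTable(fields, gname, config)
        tab$clone <- cl
        tab
      })
      out[[gname]] <- perClone
    }
    out
  })

  prep <- .stage("preprocess", {
    wtRaw <- do.call(rbind, rawTables[[wtName]])
    ref <- suppressWarnings(wtReferenceStats(wtRaw))
    pooled <- list()
    logs <- list()
    for (gname in names(rawTables)) {
      z <- lapply(rawTables[[gname]], function(tab) {
        removeOutliers(standardizeFeatures(tab, ref),
                       cutoff = config$cutoff, policy = config$policy)
      })
      pooled[[gname]] <- poolClones(z[[1]]$table, z[[2]]$table)
      logs[[gname]] <- rbind(z[[1]]$log, z[[2]]$log)
    }
    list(ref = ref, tables = pooled, logs = logs)
  })

  discrim <- .stage("discriminate", {
    cvResults <- list(); models <- list(); rows <- list()
    for (gname in mutants) {
      ds <- buildDataset(prep$tables[[wtName]], prep$tables[[gname]],
                         removalLog = prep$logs[[gname]])
      gi <- match(gname, names(panel))
      cvResults[[gname]] <- nestedCV(
        ds, K = config$cv$K, innerK = config$cv$innerK,
        nLambda = config$cv$nLambda, decades = config$cv$decades,
        seed = childSeed(config$seed, 1000L + gi), cvTol = 1e-4)
      models[[gname]] <- fitModelCV(
        ds, K = config$cv$innerK, nLambda = config$cv$nLambda,
        decades = config$cv$decades,
        seed = childSeed(config$seed, 2000L + gi), cvTol = 1e-4)
      writeModelJSON(models[[gname]],
                     file.path(config$outDir, "models",
                               paste0(gname, ".json")),
                     genotype = gname)
      rows[[gname]] <- data.frame(
        genotype = gname, mean_auc = cvResults[[gname]]$meanAuc,
        sd_auc = cvResults[[gname]]$sdAuc,
        n_selected = length(selectedFeatures(models[[gname]])),
        n_cells = nrow(ds@X))
    }
    list(cvResults = cvResults, models = models,
         summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
  })

  prof <- .stage("profiles", {
    if (length(discrim$models) >= 2L) {
      mat <- coefficientProfiles(discrim$models)
      sim <- profileSimilarity(mat)
      dendro <- clusterProfiles(1 - sim)
      list(matrix = mat, similarity = sim, dendro = dendro)
    } else {
      message("fewer than two mutant models; profile clustering skipped")
      NULL
    }
  })

  bundle <- list(config = config, ref = prep$ref, tables = prep$tables,
                 logs = prep$logs, cvResults = discrim$cvResults,
                 models = discrim$models, summary = discrim$summary,
                 profiles = prof)
  .stage("write-outputs", .writeBundleTables(bundle, config$outDir))
  invisible(bundle)
}

# deterministic CSV/Newick/manifest outputs shared by runExperiment and
# writeReport
.writeBundleTables <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(outDir, "summary.csv"))
  write.csv(bundle$summary, paths["summary"], row.names = FALSE)
  if (!is.null(bundle$profiles)) {
    paths["profile"] <- file.path(outDir, "profile.csv")
    write.csv(data.frame(genotype = rownames(bundle$profiles$matrix),
                         bundle$profiles$matrix, check.names = FALSE),
              paths["profile"], row.names = FALSE)
    paths["correlation"] <- file.path(outDir, "correlation.csv")
    write.csv(data.frame(genotype = rownames(bundle$profiles$similarity),
                         bundle$profiles$similarity, check.names = FALSE),
              paths["correlation"], row.names = FALSE)
    paths["dendrogram"] <- file.path(outDir, "dendrogram.nwk")
    writeLines(bundle$profiles$dendro$newick, paths["dendrogram"])
  }
  manifest <- list(
    package = "BFProfiler",
    version = as.character(packageVersion("BFProfiler")),
    seed = bundle$config$seed,
    n_cells_per_clone = bundle$config$nCellsPerClone,
    field_size = bundle$config$fieldSize,
    cv = bundle$config$cv,
    schema_hash = bundle$config$featureCfg$schemaHash,
    file_md5 = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write figures and tables from a results bundle
#'
#' Produces, per genotype, the fold ROC curves with the mean AUC, the
#' linear-predictor histograms with the posterior sigmoid, and the
#' distributions of the three named clump features (threshold-ladder means
#' of clump count, average clump area and average noncircularity)
#' annotated with the one-sided U-test p-value and the model coefficient;
#' plus the profile heatmap with the complete-linkage dendrogram. The
#' deterministic CSV outputs are regenerated byte-identically.
#'
#' @param bundle result of [runExperiment()].
#' @param outDir output directory.
#' @return invisibly, the vector of files written.
#' @export
writeReport <- function(bundle, outDir) {
  if (is.null(bundle$cvResults) || length(bundle$cvResults) == 0L)
    stop("empty bundle: run the experiment first")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wtName <- names(bundle$config$panel)[1]
  schema <- bundle$config$featureCfg$schema
  named <- c("tau_mean_n_clumps", "tau_mean_mean_clump_area",
             "tau_mean_mean_noncircularity")
  namedIds <- schema$id[match(named, schema$name)]

  for (gname in names(bundle$cvResults)) {
    cv <- bundle$cvResults[[gname]]
    f <- file.path(outDir, paste0("roc_", gname, ".png"))
    grDevices::png(f, 600, 600)
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                   ylab = "TPR",
                   main = sprintf("%s vs %s", gname, wtName))
    for (cur in cv$foldCurves)
      graphics::lines(cur$fpr, cur$tpr, col = "#7f9fcf")
    graphics::abline(0, 1, lty = 2, col = "gray")
    graphics::text(0.65, 0.1, sprintf("mean AUC = %.3f", cv$meanAuc))
    grDevices::dev.off()
    files <- c(files, f)

    rocTab <- do.call(rbind, lapply(seq_along(cv$foldCurves), function(k)
      data.frame(fold = k, fpr = cv$foldCurves[[k]]$fpr,
                 tpr = cv$foldCurves[[k]]$tpr)))
    f <- file.path(outDir, paste0("roc_", gname, ".csv"))
    write.csv(rocTab, f, row.names = FALSE)
    files <- c(files, f)

    model <- bundle$models[[gname]]
    ds <- buildDataset(bundle$tables[[wtName]], bundle$tables[[gname]])
    eta <- linearPredictor(model, ds@X)$eta
    f <- file.path(outDir, paste0("linpred_", gname, ".png"))
    grDevices::png(f, 600, 800)
    graphics::par(mfrow = c(3, 1))
    graphics::hist(eta[ds@y == 0], breaks = 30, col = "#cf7f7f",
                   main = paste(wtName, "linear predictors"), xlab = "")
    graphics::hist(eta[ds@y == 1], breaks = 30, col = "#7f9fcf",
                   main = paste(gname, "linear predictors"), xlab = "")
    tt <- seq(min(eta), max(eta), length.out = 200)
    graphics::plot(tt, sigmoid(tt), type = "l",
                   xlab = "linear predictor",
                   ylab = "posterior probability")
    grDevices::dev.off()
    files <- c(files, f)

    f <- file.path(outDir, paste0("features_", gname, ".png"))
    grDevices::png(f, 900, 300 * length(namedIds))
    graphics::par(mfrow = c(length(namedIds), 1))
    for (i in seq_along(namedIds)) {
      id <- namedIds[i]
      wtv <- bundle$tables[[wtName]][[id]]
      mv <- bundle$tables[[gname]][[id]]
      ut <- featureUTest(mv, wtv, "greater")
      br <- pretty(c(wtv, mv), 40)
      graphics::hist(wtv, breaks = br, col = "#cf7f7f88", border = NA,
                     main = sprintf("%s  (U-test p = %.3g, RC = %.3g)",
                                    named[i], ut$p,
                                    modelCoefficients(model)[[id]]),
                     xlab = "standardized value")
      graphics::hist(mv, breaks = br, col = "#7f9fcf88", border = NA,
                     add = TRUE)
    }
    grDevices::dev.off()
    files <- c(files, f)
  }

  if (!is.null(bundle$profiles)) {
    mat <- bundle$profiles$matrix
    keep <- colSums(mat != 0) > 0
    f <- file.path(outDir, "heatmap.png")
    dcol <- 1 - suppressWarnings(cor(mat[, keep, drop = FALSE]))
    dcol[!is.finite(dcol)] <- 1
    colHc <- hclust(as.dist(dcol), method = "complete")
    pheatmap::pheatmap(
      mat[, keep, drop = FALSE],
      cluster_rows = bundle$profiles$dendro$hclust, cluster_cols = colHc,
      show_colnames = FALSE, filename = f, width = 10, height = 4)
    files <- c(files, f)
  }
  files <- c(files, .writeBundleTables(bundle, outDir))
  invisible(files)
}
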