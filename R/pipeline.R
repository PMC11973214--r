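#' Pipeline configuration
#'
#' Collects the paths and settings for an end-to-end run over a cohort
#' directory laid out as by \code{\link{makeCohort}}: templates and
#' segmentations for the reference (young) and old ages, a pair SVF (or the
#' option to register the pair), one subject SVF per scan under
#' \code{svf/}, and a \code{demographics.csv} with columns \code{scan_id},
#' \code{age}, \code{group}.
#'
#' @param cohortDir Input cohort directory.
#' @param outDir Output directory for scores, statistics and the resolved
#'   configuration.
#' @param referenceAge,ageOld Template ages (years), defaults 60 and 90.
#' @param pairSVFSource \code{"file"} to read \code{pair_svf.nii.gz} from the
#'   cohort directory, or \code{"register"} to estimate it by registering the
#'   young template to the old one.
#' @param steps Squaring steps for SVF integration.
#' @param regions Region names to analyse.
#' @param quantile \code{"auto"} to choose the rejection quantile per region
#'   by maximizing the CN AS-age R-squared over \code{quantileGrid}, or a
#'   fixed numeric quantile.
#' @param quantileGrid Candidate quantiles for automatic selection.
#' @param eps Magnitude guard for \eqn{\|v_0\|}.
#' @param equalVar Pooled-variance t-tests instead of Welch.
#' @param minGroupSize Smallest group entered into pairwise testing.
#' @param seed Seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return A list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(cohortDir, outDir,
                           referenceAge = 60, ageOld = 90,
                           pairSVFSource = c("file", "register"),
                           steps = 7L,
                           regions = c("whole-brain", "ventricles",
                                       "hippocampi-amygdala",
                                       "ventricle-edge"),
                           quantile = "auto",
                           quantileGrid = seq(0, 0.9, by = 0.1),
                           eps = 1e-8, equalVar = FALSE, minGroupSize = 5L,
                           seed = 1L) {
  structure(list(cohortDir = cohortDir, outDir = outDir,
                 referenceAge = referenceAge, ageOld = ageOld,
                 pairSVFSource = match.arg(pairSVFSource), steps = steps,
                 regions = regions, quantile = quantile,
                 quantileGrid = quantileGrid, eps = eps,
                 equalVar = equalVar, minGroupSize = minGroupSize,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full scoring and statistics pipeline
#'
#' Stages: (1) load templates, segmentations and the pair SVF (or register
#' the template pair); (2) build the one-year normal-aging field by dividing
#' the pair SVF by the age gap; (3) decompose every scan's SVF voxel-wise and
#' aggregate per region, selecting the outlier-rejection quantile on the CN
#' group if requested; (4) age-adjust the regional scores by ANCOVA with
#' CN-mean centering and run pairwise Bonferroni-corrected t-tests per region
#' and score. Writes \code{scores.csv}, \code{stats.csv},
#' \code{quantiles.csv}, a resolved \code{config.json} and a structured
#' \code{log.json} (per-stage timings and input checksums) into
#' \code{outDir}. Rerunning with the same config and inputs is bit-identical.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with \code{scores}, \code{stats},
#'   \code{quantiles} data.frames and the output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  t0 <- Sys.time()
  log <- list(stages = list())
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log$stages[[name]] <<- list(seconds = as.numeric(Sys.time() - ts,
                                                     units = "secs"))
    res
  }
  cd <- config$cohortDir
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  inputs <- stage("load-inputs", {
    demoPath <- file.path(cd, "demographics.csv")
    if (!file.exists(demoPath))
      stop(sprintf("no demographics.csv in cohort directory '%s'", cd))
    demo <- read.csv(demoPath, stringsAsFactors = FALSE)
    need <- c("scan_id", "age", "group")
    if (!all(need %in% names(demo)))
      stop(sprintf("demographics.csv needs columns %s",
                   paste(need, collapse = ", ")))
    list(demo = demo,
         template = readScalarVolume(file.path(cd, "template.nii.gz")),
         seg = readLabelVolume(file.path(cd, "seg.nii.gz")),
         segOld = readLabelVolume(file.path(cd, "seg_old.nii.gz")))
  })
  log$inputChecksums <- list(
    demographics = unname(tools::md5sum(file.path(cd, "demographics.csv"))))

  pairSVF <- stage("pair-svf", {
    if (config$pairSVFSource == "file") {
      loadExternalSVF(file.path(cd, "pair_svf.nii.gz"),
                      grid = gridDim(inputs$template))
    } else {
      old <- readScalarVolume(file.path(cd, "template_old.nii.gz"))
      registerSVF(fixed = old, moving = inputs$template,
                  mask = inputs$seg, steps = config$steps)@svf
    }
  })

  aging <- stage("build-aging-field", {
    buildAgingField(pairSVF, ageYoung = config$referenceAge,
                    ageOld = config$ageOld,
                    referenceAge = config$referenceAge)
  })

  scored <- stage("score", {
    demo <- inputs$demo
    masks <- lapply(config$regions, function(rn)
      regionMask(rn, segRef = inputs$seg, segOld = inputs$segOld))
    names(masks) <- config$regions
    v0 <- aging@v0
    perScan <- vector("list", nrow(demo))
    for (i in seq_len(nrow(demo))) {
      id <- demo$scan_id[i]
      svf <- loadExternalSVF(file.path(cd, "svf", paste0(id, ".nii.gz")),
                             grid = gridDim(inputs$template))
      sm <- decomposeVoxelwise(svf, v0, eps = config$eps)
      rows <- list()
      for (rn in config$regions) {
        qs <- if (identical(config$quantile, "auto")) config$quantileGrid
              else as.numeric(config$quantile)
        for (q in qs) {
          agg <- aggregateRegion(rejectOutliers(sm, v0, masks[[rn]],
                                                quantile = q))
          rows[[length(rows) + 1L]] <- data.frame(
            scan_id = id, region = rn, quantile = q,
            AS = agg$AS, ADS = agg$ADS, nVoxels = agg$nVoxels,
            stringsAsFactors = FALSE)
        }
      }
      perScan[[i]] <- do.call(rbind, rows)
    }
    merge(do.call(rbind, perScan), demo[, c("scan_id", "age", "group")],
          by = "scan_id", sort = FALSE)
  })

  selection <- stage("select-quantile", {
    if (identical(config$quantile, "auto")) {
      cn <- scored[scored$group == "CN", , drop = FALSE]
      sel <- lapply(config$regions, function(rn) {
        qs <- selectQuantile(cn[cn$region == rn, , drop = FALSE],
                             grid = config$quantileGrid)
        data.frame(region = rn, chosenQuantile = qs@chosenQuantile,
                   r2 = max(qs@r2PerQuantile), stringsAsFactors = FALSE)
      })
      do.call(rbind, sel)
    } else {
      data.frame(region = config$regions,
                 chosenQuantile = as.numeric(config$quantile),
                 r2 = NA_real_, stringsAsFactors = FALSE)
    }
  })

  scores <- stage("final-scores", {
    keep <- mapply(function(rn, q)
      scored$region == rn & abs(scored$quantile - q) < 1e-9,
      selection$region, selection$chosenQuantile)
    scored[rowSums(as.matrix(keep)) > 0, , drop = FALSE]
  })

  statsTab <- stage("stats", {
    out <- list()
    for (rn in config$regions) {
      sub <- scores[scores$region == rn, , drop = FALSE]
      for (sc in c("AS", "ADS")) {
        adjusted <- ancovaAdjust(sub, sc)
        pt <- suppressMessages(
          pairwiseTests(adjusted, paste0(sc, ".adj"),
                        equalVar = config$equalVar,
                        minGroupSize = config$minGroupSize))
        pt$region <- rn
        pt$score <- sc
        out[[length(out) + 1L]] <- pt
      }
    }
    do.call(rbind, out)
  })

  paths <- list(scores = file.path(config$outDir, "scores.csv"),
                stats = file.path(config$outDir, "stats.csv"),
                quantiles = file.path(config$outDir, "quantiles.csv"),
                config = file.path(config$outDir, "config.json"),
                log = file.path(config$outDir, "log.json"))
  write.csv(scores, paths$scores, row.names = FALSE)
  write.csv(statsTab, paths$stats, row.names = FALSE)
  write.csv(selection, paths$quantiles, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  log$totalSeconds <- as.numeric(Sys.time() - t0, units = "secs")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = 6)
  invisible(list(scores = scores, stats = statsTab, quantiles = selection,
                 allScores = scored, paths = paths))
}
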