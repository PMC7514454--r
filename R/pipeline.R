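## End-to-end orchestration: simulate -> extract -> reduce -> select ->
## evaluate -> report, driven by one configuration, with every stage seed
## recorded and the configuration serialized into the output directory.

#' Assemble a pipeline run configuration
#'
#' @param cohort a \linkS4class{CohortConfig} (synthetic run) or the path
#'   to an existing manifest CSV
#' @param sets feature sets to process
#' @param glcmDistance,glcmLevels co-occurrence parameters
#' @param selectionRounds,alpha permutation-significance parameters
#' @param evalRounds,evalFolds,kernel CV evaluation parameters
#' @param maxPcs PC-sweep depth
#' @param sweepRounds CV rounds of the PC sweep (lighter than the final
#'   evaluation by default)
#' @param seed master seed; stage seeds derive from it deterministically
#' @return a list of class \code{"RunConfig"}
#' @export
runConfig <- function(cohort = cohortConfig(), sets = .FEATURE_SETS,
                      glcmDistance = 1L, glcmLevels = 16L,
                      selectionRounds = 100L, alpha = 0.05,
                      evalRounds = 100L, evalFolds = 10L,
                      kernel = "linear", maxPcs = 10L, sweepRounds = 10L,
                      seed = 1L) {
    structure(list(cohort = cohort,
                   sets = match.arg(sets, .FEATURE_SETS, several.ok = TRUE),
                   glcmDistance = as.integer(glcmDistance),
                   glcmLevels = as.integer(glcmLevels),
                   selectionRounds = as.integer(selectionRounds),
                   alpha = alpha, evalRounds = as.integer(evalRounds),
                   evalFolds = as.integer(evalFolds), kernel = kernel,
                   maxPcs = as.integer(maxPcs),
                   sweepRounds = as.integer(sweepRounds),
                   seed = as.integer(seed)),
              class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the \code{\link{runConfig}} arguments; a
#' \code{cohort:} mapping holds \code{\link{cohortConfig}} arguments
#' (alternatively \code{manifest: path} points at an existing cohort).
#'
#' @param path YAML file
#' @return a \code{"RunConfig"}
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    cohort <- if (!is.null(y$manifest)) y$manifest
              else do.call(cohortConfig, as.list(y$cohort %||% list()))
    args <- y[setdiff(names(y), c("cohort", "manifest"))]
    do.call(runConfig, c(list(cohort = cohort), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise feature-correlation screen
#'
#' Pearson correlation of every feature pair with two-sided p-values from
#' the t-distribution.  A pair involving a constant feature gets r = 0 and
#' p = 1 by convention (logged with a message).
#'
#' @param table a \linkS4class{FeatureTable} with >= 3 lesions
#' @return list with matrices \code{r} and \code{p}
#' @export
correlationScreen <- function(table) {
    x <- featureValues(table)
    n <- nrow(x)
    if (n < 3L) stop("correlation screen needs at least 3 lesions")
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
        message(sum(sds == 0), " constant feature(s): correlations set to 0")
    r <- suppressWarnings(stats::cor(x))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[!is.finite(p)] <- 1
    const <- sds == 0
    r[const, ] <- 0; r[, const] <- 0
    p[const, ] <- 1; p[, const] <- 1
    diag(r) <- 1; diag(p)[!const] <- 0
    list(r = r, p = p)
}

.writeMatrixCsv <- function(m, path)
    utils::write.csv(format(m, digits = 15, trim = TRUE), path, quote = FALSE)

#' Run the full radiomic study replica
#'
#' From one configuration: generate (or load) the cohort, extract the
#' requested feature sets, screen feature correlations, sweep SVM
#' performance over leading principal components, run wrapper and embedded
#' feature importance with the permutation/Fisher significance test, and
#' evaluate SVM performance of the full set, of each method's significant
#' sub-set, and of their union, under repeated stratified cross-validation.
#' All artifacts (CSV tables, JSON reports, the serialized configuration
#' and a log) are written under \code{outDir}; a stage failure aborts with
#' the stage name while completed stages persist.
#'
#' @param config a \code{"RunConfig"} from \code{\link{runConfig}} or
#'   \code{\link{readRunConfig}}
#' @param outDir output directory
#' @return invisibly, a list with the per-set feature tables, selection
#'   results and performance tables
#' @export
runAll <- function(config, outDir) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(outDir, "run.log")
    logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                   file = logFile, append = TRUE)
    stage <- function(name, expr) {
        logf("[stage %s] start", name)
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    saveConfig <- config
    saveConfig$cohort <- if (is(config$cohort, "CohortConfig")) {
        cc <- config$cohort
        c(list(nLesions = cc@nLesions, nBenign = cc@nBenign,
               nMalignant = cc@nMalignant,
               roiSizeRange = cc@roiSizeRange, bpeLevels = cc@bpeLevels,
               benignParams = as.list(cc@benignParams),
               malignantParams = as.list(cc@malignantParams),
               backgroundSd = cc@backgroundSd, baseline = cc@baseline,
               leFactor = cc@leFactor, noiseSd = cc@noiseSd,
               seed = cc@seed))
    } else config$cohort
    yaml::write_yaml(unclass(saveConfig), file.path(outDir, "config.yaml"))

    manifestPath <- stage("simulate", {
        if (is(config$cohort, "CohortConfig")) {
            generateCohort(config$cohort, file.path(outDir, "cohort"))
            file.path(outDir, "cohort", "manifest.csv")
        } else config$cohort
    })

    pairs <- stage("load", loadCohort(manifestPath))
    tables <- stage("extract", {
        tb <- extractFeatures(pairs, sets = config$sets,
                              glcmDistance = config$glcmDistance,
                              glcmLevels = config$glcmLevels)
        for (s in names(tb))
            writeFeatureTable(tb[[s]],
                              file.path(outDir, sprintf("features_%s.csv", s)))
        tb
    })

    selections <- list(); perfRows <- list(); sweeps <- list()
    for (s in names(tables)) {
        ft <- tables[[s]]
        stage(paste0("correlate:", s), {
            cs <- correlationScreen(ft)
            .writeMatrixCsv(cs$r, file.path(outDir,
                                            sprintf("correlation_%s.csv", s)))
            .writeMatrixCsv(cs$p,
                            file.path(outDir,
                                      sprintf("correlation_p_%s.csv", s)))
        })
        sweeps[[s]] <- stage(paste0("reduce:", s), {
            sw <- pcSweep(ft, maxPcs = config$maxPcs,
                          rounds = config$sweepRounds,
                          folds = config$evalFolds,
                          seed = config$seed, kernel = config$kernel)
            utils::write.csv(
                data.frame(k = seq_along(attr(sw, "accuracy")),
                           mean_accuracy = as.numeric(attr(sw, "accuracy"))),
                file.path(outDir, sprintf("pc_sweep_%s.csv", s)),
                row.names = FALSE)
            sw
        })
        sel <- stage(paste0("select:", s), {
            res <- lapply(c(wrapper = "wrapper", embedded = "embedded"),
                          function(m) permutationSignificance(
                              ft, method = m,
                              nRounds = config$selectionRounds,
                              alpha = config$alpha, seed = config$seed))
            for (m in names(res)) {
                tb <- as.data.frame(selectionTable(res[[m]]))
                jsonlite::write_json(
                    cbind(feature = rownames(tb), tb),
                    file.path(outDir, sprintf("selection_%s_%s.json", s, m)),
                    auto_unbox = TRUE, digits = NA)
            }
            res
        })
        selections[[s]] <- sel
        subsets <- list(
            all = featureNames(ft),
            wrapper = selectedFeatures(sel$wrapper),
            embedded = selectedFeatures(sel$embedded),
            union = union(selectedFeatures(sel$wrapper),
                          selectedFeatures(sel$embedded)))
        for (m in names(subsets)) {
            if (length(subsets[[m]]) == 0L) {
                logf("[stage evaluate:%s] %s subset empty, skipped", s, m)
                next
            }
            rep <- stage(paste0("evaluate:", s, ":", m),
                         cvEvaluate(ft, subsets[[m]],
                                    rounds = config$evalRounds,
                                    folds = config$evalFolds,
                                    seed = config$seed,
                                    kernel = config$kernel))
            writePerformanceReport(
                rep, file.path(outDir,
                               sprintf("performance_%s_%s.json", s, m)))
            mt <- rep@metrics
            perfRows[[paste(s, m)]] <- data.frame(
                set = s, subset = m, n_features = length(subsets[[m]]),
                accuracy = mt["accuracy", "mean"],
                accuracy_lo = mt["accuracy", "ci_lower"],
                accuracy_hi = mt["accuracy", "ci_upper"],
                sensitivity = mt["sensitivity", "mean"],
                specificity = mt["specificity", "mean"],
                stringsAsFactors = FALSE)
        }
    }
    perf <- do.call(rbind, c(perfRows, list(make.row.names = FALSE)))
    utils::write.csv(perf, file.path(outDir, "performance_table.csv"),
                     row.names = FALSE)
    logf("run complete: %d set(s)", length(tables))
    invisible(list(tables = tables, selections = selections,
                   sweeps = sweeps, performance = perf))
}
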