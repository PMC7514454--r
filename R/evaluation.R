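## PCA-based global assessment and cross-validated SVM benchmarking.
## Standardization and PCA are always fitted inside the training fold only;
## malignant is the positive class.

#' Principal component model of a feature table
#'
#' Z-score standardization followed by an eigendecomposition of the
#' correlation structure (\code{prcomp} on the standardized matrix).
#' Constant features are dropped (with a message) before standardization.
#' Loadings carry a deterministic sign convention: the largest-magnitude
#' entry of each component is positive.
#'
#' @param table a \linkS4class{FeatureTable} (or plain lesions x features
#'   matrix) with >= 2 lesions
#' @return a \linkS4class{PcaModel}
#' @export
fitPca <- function(table) {
    x <- if (is(table, "FeatureTable")) featureValues(table)
         else as.matrix(table)
    if (nrow(x) < 2L) stop("PCA needs at least 2 lesions")
    sds <- apply(x, 2, stats::sd)
    dropped <- colnames(x)[sds == 0]
    if (length(dropped))
        message("dropping ", length(dropped),
                " constant feature(s) before standardization: ",
                paste(utils::head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else "")
    x <- x[, sds > 0, drop = FALSE]
    pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    L <- pc$rotation
    flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
    L <- sweep(L, 2, flip, `*`)
    ev <- pc$sdev^2
    new("PcaModel", center = pc$center, scale = pc$scale, loadings = L,
        varianceExplained = ev / sum(ev), dropped = dropped)
}

#' Project lesions onto a fitted PCA model
#'
#' @param model a \linkS4class{PcaModel}
#' @param x lesions x features matrix (same feature columns the model was
#'   fitted on, dropped constants excluded)
#' @param k number of leading components (default: all)
#' @return lesions x k score matrix
#' @export
pcaScores <- function(model, x, k = ncol(model@loadings)) {
    x <- as.matrix(x)
    if (!is.null(names(model@center)))
        x <- x[, names(model@center), drop = FALSE]
    z <- sweep(sweep(x, 2, model@center), 2, model@scale, `/`)
    z %*% model@loadings[, seq_len(k), drop = FALSE]
}

## ---- shared CV machinery ------------------------------------------------

.svmFit <- function(x, y, kernel = "linear", cost = 1) {
    e1071::svm(x, y, kernel = kernel, cost = cost, scale = FALSE)
}

## one CV round; preprocess(trainX, testX) -> list(train, test) is fitted
## on the training fold only (standardization, PCA, ...)
.cvRound <- function(x, y, nFolds, seed, preprocess, kernel) {
    fold <- .stratifiedFolds(y, nFolds, seed)
    conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (f in seq_len(nFolds)) {
        tr <- fold != f
        pp <- preprocess(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
        fit <- .svmFit(pp$train, y[tr], kernel)
        pred <- stats::predict(fit, pp$test)
        truth <- y[!tr]
        conf["TP"] <- conf["TP"] + sum(pred == "malignant" &
                                       truth == "malignant")
        conf["TN"] <- conf["TN"] + sum(pred == "benign" & truth == "benign")
        conf["FP"] <- conf["FP"] + sum(pred == "malignant" &
                                       truth == "benign")
        conf["FN"] <- conf["FN"] + sum(pred == "benign" &
                                       truth == "malignant")
    }
    conf
}

.standardizePreprocess <- function(trainX, testX) {
    mu <- colMeans(trainX)
    s <- apply(trainX, 2, stats::sd)
    s[s == 0] <- 1
    list(train = sweep(sweep(trainX, 2, mu), 2, s, `/`),
         test = sweep(sweep(testX, 2, mu), 2, s, `/`))
}

.performanceReport <- function(confPerRound, nFolds, classifier, features) {
    metric <- function(conf) c(
        accuracy = (conf["TP"] + conf["TN"]) / sum(conf),
        sensitivity = if (conf["TP"] + conf["FN"] > 0)
            conf["TP"] / (conf["TP"] + conf["FN"]) else NA_real_,
        specificity = if (conf["TN"] + conf["FP"] > 0)
            conf["TN"] / (conf["TN"] + conf["FP"]) else NA_real_)
    m <- 100 * t(vapply(confPerRound, metric, numeric(3)))
    colnames(m) <- c("accuracy", "sensitivity", "specificity")
    nR <- length(confPerRound)
    mu <- colMeans(m)
    half <- 1.96 * apply(m, 2, stats::sd) / sqrt(nR)
    half[is.na(half)] <- 0                    # single round
    metrics <- data.frame(mean = mu,
                          ci_lower = pmax(mu - half, 0),
                          ci_upper = pmin(mu + half, 100),
                          row.names = colnames(m))
    new("PerformanceReport", metrics = metrics,
        confusion = colMeans(do.call(rbind, confPerRound)),
        nRounds = as.integer(nR), nFolds = as.integer(nFolds),
        classifier = classifier, features = features, roundMetrics = m)
}

#' Repeated stratified cross-validated SVM evaluation
#'
#' Evaluates benign-vs-malignant discrimination of a feature subset with a
#' linear-kernel SVM under stratified k-fold cross-validation repeated over
#' several rounds with round-specific shuffles.  Per-fold standardization
#' is fitted on the training data only.  Reported per metric: mean percent
#' over rounds and the 95\% confidence interval
#' mean +/- 1.96 sd / sqrt(rounds).
#'
#' @param table a \linkS4class{FeatureTable}
#' @param features optional feature-name subset (default: all)
#' @param rounds,folds CV geometry (defaults 100 and 10; each class must
#'   hold at least \code{folds} lesions)
#' @param seed master seed
#' @param kernel SVM kernel, \code{"linear"} (default) or \code{"radial"}
#' @return a \linkS4class{PerformanceReport}
#' @export
cvEvaluate <- function(table, features = featureNames(table),
                       rounds = 100L, folds = 10L, seed = 1L,
                       kernel = "linear") {
    if (length(features) == 0L) stop("feature subset must not be empty")
    tb <- subsetFeatures(table, features)
    d <- .tableXY(tb)
    if (min(table(d$y)) < folds)
        stop("each class needs at least `folds` lesions for stratified CV")
    conf <- lapply(seq_len(rounds), function(r)
        .cvRound(d$x, d$y, folds, (seed + 7717L * r) %% 2147483647L,
                 .standardizePreprocess, kernel))
    .performanceReport(conf, folds, paste0("SVM (", kernel, ")"),
                       sprintf("%s [%d features]", setId(tb),
                               length(features)))
}

#' SVM performance for an increasing number of principal components
#'
#' For k = 1..maxPcs, evaluates a linear SVM trained on the first k
#' principal components of the standardized feature set under repeated
#' stratified cross-validation.  Standardization and PCA are refitted
#' inside each training fold (no leakage into the test fold).
#'
#' @param table a \linkS4class{FeatureTable}
#' @param maxPcs largest number of components (capped at the training-fold
#'   rank)
#' @param rounds,folds,seed,kernel as in \code{\link{cvEvaluate}}
#' @return named list of \linkS4class{PerformanceReport}, one per k; the
#'   per-k mean accuracies are attached as attribute \code{"accuracy"}
#' @export
pcSweep <- function(table, maxPcs = 10L, rounds = 10L, folds = 10L,
                    seed = 1L, kernel = "linear") {
    d <- .tableXY(table)
    if (min(table(d$y)) < folds)
        stop("each class needs at least `folds` lesions for stratified CV")
    maxPcs <- min(maxPcs, nrow(d$x) - ceiling(nrow(d$x) / folds) - 1L,
                  ncol(d$x))
    reports <- lapply(seq_len(maxPcs), function(k) {
        pre <- function(trainX, testX) {
            model <- fitPca(trainX)
            kk <- min(k, ncol(model@loadings))
            list(train = pcaScores(model, trainX, kk),
                 test = pcaScores(model, testX, kk))
        }
        conf <- lapply(seq_len(rounds), function(r)
            .cvRound(d$x, d$y, folds, (seed + 7717L * r) %% 2147483647L,
                     pre, kernel))
        .performanceReport(conf, folds, paste0("SVM (", kernel, ")"),
                           sprintf("%s [first %d PCs]", setId(table), k))
    })
    names(reports) <- sprintf("k%02d", seq_len(maxPcs))
    acc <- vapply(reports, function(r) r@metrics["accuracy", "mean"],
                  numeric(1))
    structure(reports, accuracy = acc)
}

#' Serialize a PerformanceReport to JSON (and back)
#'
#' @param report a \linkS4class{PerformanceReport}
#' @param path JSON file path
#' @return \code{writePerformanceReport}: invisibly the path;
#'   \code{readPerformanceReport}: the restored report (round-level metrics
#'   included)
#' @export
writePerformanceReport <- function(report, path) {
    obj <- list(metrics = cbind(metric = rownames(report@metrics),
                                report@metrics),
                confusion = as.list(report@confusion),
                n_rounds = report@nRounds, n_folds = report@nFolds,
                classifier = report@classifier, features = report@features,
                round_metrics = report@roundMetrics)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePerformanceReport
#' @export
readPerformanceReport <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    metrics <- obj$metrics
    rownames(metrics) <- metrics$metric
    metrics$metric <- NULL
    rm <- as.matrix(obj$round_metrics)
    colnames(rm) <- c("accuracy", "sensitivity", "specificity")
    new("PerformanceReport", metrics = metrics,
        confusion = unlist(obj$confusion),
        nRounds = as.integer(obj$n_rounds), nFolds = as.integer(obj$n_folds),
        classifier = obj$classifier, features = obj$features,
        roundMetrics = rm)
}
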