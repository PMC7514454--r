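## Feature importance: wrapper (WMW filter + sequential backward selection
## with Gaussian naive Bayes), embedded (random-forest OOB permutation
## importance, above-average rule), and the permutation/Fisher significance
## test of selection frequency against label-permuted baselines.

.tableXY <- function(table) {
    list(x = featureValues(table),
         y = droplevels(factor(lesionLabels(table), levels = .CLASS_LEVELS)))
}

.wmwPvalues <- function(x, y) {
    g1 <- x[y == levels(y)[1], , drop = FALSE]
    g2 <- x[y == levels(y)[2], , drop = FALSE]
    vapply(seq_len(ncol(x)), function(j) {
        if (length(unique(x[, j])) == 1L) return(1)   # all tied
        stats::wilcox.test(g1[, j], g2[, j], exact = FALSE,
                           correct = TRUE)$p.value
    }, numeric(1))
}

#' Wilcoxon-Mann-Whitney feature filter
#'
#' Two-sided rank-sum test of each feature between benign and malignant
#' lesions (normal approximation with tie correction); features with
#' p < alpha are kept.  No multiplicity correction is applied.  A constant
#' feature is never selected (p = 1 by the all-ties convention).
#'
#' @param table a \linkS4class{FeatureTable} with both classes present
#'   (>= 2 lesions each)
#' @param alpha significance level (default 0.05)
#' @return character vector of retained feature names, with the per-feature
#'   p-values attached as attribute \code{"p"} (named, all features)
#' @export
wmwFilter <- function(table, alpha = 0.05) {
    d <- .tableXY(table)
    if (nlevels(d$y) < 2L || min(table(d$y)) < 2L)
        stop("both classes must be present with at least 2 lesions each")
    p <- .wmwPvalues(d$x, d$y)
    names(p) <- colnames(d$x)
    structure(colnames(d$x)[p < alpha], p = p)
}

## --- Gaussian naive Bayes with per-feature log-density caching ----------
## Class-conditional normals per feature; the log posterior is additive
## over features, so the misclassification cost of dropping one feature is
## obtained by subtracting its cached log-density slice.  Variances are
## floored to avoid degenerate densities on (near-)constant folds.

.nbLogDensities <- function(xTrain, yTrain, xTest) {
    eps <- 1e-9
    lev <- levels(yTrain)
    out <- array(0, c(nrow(xTest), ncol(xTest), length(lev)))
    for (k in seq_along(lev)) {
        xi <- xTrain[yTrain == lev[k], , drop = FALSE]
        mu <- colMeans(xi)
        s2 <- pmax(colMeans(xi^2) - mu^2, eps) * nrow(xi) / max(1, nrow(xi) - 1)
        out[, , k] <- -0.5 * (sweep(xTest, 2, mu)^2 %*% diag(1 / s2,
                                                            ncol(xTest))) -
            matrix(0.5 * log(2 * pi * s2), nrow(xTest), ncol(xTest),
                   byrow = TRUE)
    }
    list(ll = out, logPrior = log(as.numeric(table(yTrain)) /
                                  length(yTrain)))
}

.nbPredictFromCache <- function(cache, subsetIdx) {
    ll <- cache$ll[, subsetIdx, , drop = FALSE]
    score <- apply(ll, c(1, 3), sum)
    score <- sweep(score, 2, cache$logPrior, `+`)
    max.col(score, ties.method = "first")
}

.stratifiedFolds <- function(y, nFolds, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    fold <- integer(length(y))
    for (lev in levels(y)) {
        idx <- which(y == lev)
        fold[idx] <- sample(rep(seq_len(nFolds), length.out = length(idx)))
    }
    fold
}

.nbCvError <- function(x, y, nFolds = 5L, seed = 1L) {
    ## returns a function(subsetIdx) -> CV misclassification error, with the
    ## per-fold log-density caches computed once for all features
    fold <- .stratifiedFolds(y, nFolds, seed)
    caches <- lapply(seq_len(nFolds), function(f) {
        tr <- fold != f
        list(cache = .nbLogDensities(x[tr, , drop = FALSE], y[tr],
                                     x[!tr, , drop = FALSE]),
             truth = as.integer(y[!tr]))
    })
    function(subsetIdx) {
        wrong <- 0L
        for (cf in caches)
            wrong <- wrong + sum(.nbPredictFromCache(cf$cache, subsetIdx) !=
                                 cf$truth)
        wrong / length(y)
    }
}

#' Sequential backward selection with a Gaussian naive Bayes classifier
#'
#' Starting from all candidate features, repeatedly removes the single
#' feature whose removal most decreases the stratified 5-fold
#' cross-validated naive Bayes misclassification error, and stops at the
#' first local minimum (no removal strictly decreases the error).  Ties are
#' broken by removing the feature with the larger Wilcoxon-Mann-Whitney
#' p-value, then by name order.
#'
#' @param table a \linkS4class{FeatureTable}, typically already restricted
#'   to the WMW-filtered subset
#' @param innerFolds folds of the inner CV (default 5)
#' @param innerSeed fixed seed of the inner fold assignment
#' @param wmwP optional named p-values used for tie-breaking (recomputed
#'   from \code{table} when missing)
#' @return character vector of retained feature names, with the error
#'   trajectory attached as attribute \code{"errors"}
#' @export
sbsNaiveBayes <- function(table, innerFolds = 5L, innerSeed = 1L,
                          wmwP = NULL) {
    d <- .tableXY(table)
    if (min(table(d$y)) < innerFolds)
        stop("need at least innerFolds lesions per class for stratified CV")
    nm <- colnames(d$x)
    if (length(nm) < 2L)
        return(structure(nm, errors = NA_real_))
    if (is.null(wmwP)) {
        wmwP <- .wmwPvalues(d$x, d$y)
        names(wmwP) <- nm
    }
    errorOf <- .nbCvError(d$x, d$y, innerFolds, innerSeed)
    current <- seq_along(nm)
    errTrace <- errorOf(current)
    repeat {
        if (length(current) == 1L) break
        cand <- vapply(seq_along(current), function(i)
            errorOf(current[-i]), numeric(1))
        best <- min(cand)
        if (best >= errTrace[length(errTrace)]) break   # local minimum
        ties <- which(cand == best)
        if (length(ties) > 1L) {
            tp <- wmwP[nm[current[ties]]]
            ties <- ties[order(-tp, nm[current[ties]])]
        }
        current <- current[-ties[1]]
        errTrace <- c(errTrace, best)
    }
    structure(nm[current], errors = errTrace)
}

#' Wrapper feature selection (WMW filter + backward selection)
#'
#' The two-step wrapper: keep features with Wilcoxon-Mann-Whitney p < alpha,
#' then run sequential backward selection with a Gaussian naive Bayes
#' classifier on the retained set.  Returns an empty selection when the
#' filter leaves nothing.
#'
#' @inheritParams sbsNaiveBayes
#' @param alpha filter significance level
#' @return character vector of selected feature names
#' @export
wrapperSelect <- function(table, alpha = 0.05, innerFolds = 5L,
                          innerSeed = 1L) {
    kept <- wmwFilter(table, alpha)
    if (length(kept) == 0L) return(character(0))
    if (length(kept) == 1L) return(kept)
    sbsNaiveBayes(subsetFeatures(table, kept), innerFolds, innerSeed,
                  wmwP = attr(kept, "p")[kept])
}

#' Embedded feature selection by random-forest permutation importance
#'
#' Fits a random forest and scores each feature by the mean decrease in
#' out-of-bag accuracy when its out-of-bag values are permuted (unscaled);
#' features with importance strictly above the average over all candidates
#' are selected.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param nTrees number of trees (default 500)
#' @param seed RNG seed for the forest
#' @return character vector of selected feature names, with the importance
#'   vector attached as attribute \code{"importance"}
#' @export
rfEmbeddedSelect <- function(table, nTrees = 500L, seed = 1L) {
    d <- .tableXY(table)
    if (ncol(d$x) < 2L) stop("need at least 2 candidate features")
    if (nlevels(d$y) < 2L) stop("both classes must be present")
    set.seed(seed)
    rf <- randomForest::randomForest(d$x, d$y, ntree = nTrees,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    structure(names(imp)[imp > mean(imp)], importance = imp)
}

## one-sided Fisher's exact test (enrichment of selection under true
## labels) on [[selTrue, n - selTrue], [selPerm, n - selPerm]]
.fisherEnrichment <- function(selTrue, selPerm, nRounds,
                              alternative = "greater") {
    vapply(seq_along(selTrue), function(i) {
        m <- matrix(c(selTrue[i], nRounds - selTrue[i],
                      selPerm[i], nRounds - selPerm[i]), 2, byrow = TRUE)
        stats::fisher.test(m, alternative = alternative)$p.value
    }, numeric(1))
}

#' Selection-frequency significance against label-permuted baselines
#'
#' Runs a selector \code{nRounds} times on stratified bootstrap resamples
#' of the cohort with true labels, and \code{nRounds} times with labels
#' freshly permuted within each resample; per feature, the 2x2 table of
#' selection counts is tested with a one-sided Fisher's exact test for
#' enrichment under the true labels.  Features with p < alpha have a
#' selection frequency different from chance.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param method \code{"wrapper"} or \code{"embedded"}
#' @param nRounds resampling rounds per arm (>= 20, default 100)
#' @param alpha significance level (default 0.05)
#' @param seed master seed; every round derives from it
#' @param alternative \code{"greater"} (enrichment, default) or
#'   \code{"two.sided"}
#' @param ... passed to the selector (\code{\link{wrapperSelect}} or
#'   \code{\link{rfEmbeddedSelect}})
#' @return a \linkS4class{SelectionResult}
#' @export
permutationSignificance <- function(table, method = c("wrapper", "embedded"),
                                    nRounds = 100L, alpha = 0.05, seed = 1L,
                                    alternative = c("greater", "two.sided"),
                                    ...) {
    method <- match.arg(method)
    alternative <- match.arg(alternative)
    nRounds <- as.integer(nRounds)
    if (nRounds < 20L) stop("nRounds must be at least 20")
    d <- .tableXY(table)
    nm <- colnames(d$x)
    selector <- switch(method, wrapper = wrapperSelect,
                       embedded = rfEmbeddedSelect)

    runArm <- function(permute, armOffset) {
        counts <- setNames(integer(length(nm)), nm)
        ok <- 0L; failed <- 0L
        for (r in seq_len(nRounds)) {
            set.seed((seed + armOffset + 131L * r) %% 2147483647L)
            idx <- unlist(lapply(levels(d$y), function(lev) {
                i <- which(d$y == lev)
                sample(i, length(i), replace = TRUE)
            }))
            y <- d$y[idx]
            if (permute) y <- sample(y)
            boot <- FeatureTable(d$x[idx, , drop = FALSE], as.character(y),
                                 setId(table))
            sel <- tryCatch(
                selector(boot, innerSeed = seed + r, ...),
                error = function(e) {
                    warning("selection round failed (", method, "): ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                })
            if (is.null(sel)) { failed <- failed + 1L; next }
            ok <- ok + 1L
            counts[sel] <- counts[sel] + 1L
        }
        if (ok < ceiling(0.9 * nRounds))
            stop(sprintf(
                "only %d/%d selection rounds succeeded (>= 90%% required)",
                ok, nRounds))
        list(counts = counts, ok = ok)
    }
    ## rfEmbeddedSelect has no innerSeed argument; adapt
    if (method == "embedded") {
        selector <- function(boot, innerSeed, ...)
            rfEmbeddedSelect(boot, seed = innerSeed, ...)
    }
    true <- runArm(FALSE, 0L)
    perm <- runArm(TRUE, 900000L)
    n <- min(true$ok, perm$ok)
    ## scale counts to the common number of successful rounds
    ct <- round(true$counts * n / true$ok)
    cp <- round(perm$counts * n / perm$ok)
    p <- .fisherEnrichment(ct, cp, n, alternative)
    tb <- DataFrame(count_true = as.integer(ct), count_perm = as.integer(cp),
                    fisher_p = p, significant = p < alpha, row.names = nm)
    new("SelectionResult", method = method, table = tb,
        nRounds = as.integer(n), alpha = alpha)
}
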