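## Cohort and feature-table I/O.  Images: PNG or TIFF, 8- or 16-bit
## grayscale, returned in native gray-level units (0 .. 2^bits - 1).
## Feature tables round-trip through CSV at full double precision.

.readGrayImage <- function(path) {
    if (!file.exists(path)) stop("image file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        img <- png::readPNG(path, info = TRUE)
        bits <- attr(img, "info")$bit.depth
        if (is.null(bits)) bits <- 8L
    } else if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, info = TRUE)
        bits <- attr(img, "bits.per.sample")
        if (is.null(bits)) bits <- 8L
    } else {
        stop("unsupported image format '", ext, "' (PNG or TIFF expected): ",
             path)
    }
    if (length(dim(img)) == 3L) img <- img[, , 1L]   # first plane if multi
    m <- matrix(as.numeric(img) * (2^bits - 1), nrow(img), ncol(img))
    attr(m, "bits") <- as.integer(bits)
    m
}

#' Load a cohort of LE/RC ROI pairs from a manifest
#'
#' Reads the manifest CSV (columns \code{lesion_id}, \code{patient_id},
#' \code{view}, \code{label}, \code{bpe_level}, \code{le_path},
#' \code{rc_path}; relative paths are resolved against the manifest's
#' directory) and loads each image pair.  PNG and TIFF, 8- or 16-bit
#' grayscale, may be mixed within one cohort; the bit depth is recorded per
#' lesion.  Pairs whose LE and RC dimensions disagree are rejected with an
#' error naming the lesion and both shapes.
#'
#' @param manifestPath path to the manifest CSV
#' @return list of \linkS4class{RoiPair}
#' @export
loadCohort <- function(manifestPath) {
    if (!file.exists(manifestPath))
        stop("manifest not found: ", manifestPath)
    manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
    need <- c("lesion_id", "patient_id", "view", "label", "bpe_level",
              "le_path", "rc_path")
    missing <- setdiff(need, colnames(manifest))
    if (length(missing))
        stop("manifest lacks columns: ", paste(missing, collapse = ", "))
    base <- dirname(manifestPath)
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    lapply(seq_len(nrow(manifest)), function(i) {
        rec <- manifest[i, , drop = FALSE]
        le <- tryCatch(.readGrayImage(resolve(rec$le_path)),
                       error = function(e) stop(
                           "lesion ", rec$lesion_id, " (LE): ",
                           conditionMessage(e), call. = FALSE))
        rc <- tryCatch(.readGrayImage(resolve(rec$rc_path)),
                       error = function(e) stop(
                           "lesion ", rec$lesion_id, " (RC): ",
                           conditionMessage(e), call. = FALSE))
        if (!identical(dim(le), dim(rc)))
            stop(sprintf(
                "lesion %s: LE shape %s does not match RC shape %s",
                rec$lesion_id, paste(dim(le), collapse = "x"),
                paste(dim(rc), collapse = "x")), call. = FALSE)
        rec$bits_le <- attr(le, "bits")
        rec$bits_rc <- attr(rc, "bits")
        rec$roi_size <- nrow(le)
        new("RoiPair", le = `attr<-`(le, "bits", NULL),
            rc = `attr<-`(rc, "bits", NULL), record = rec)
    })
}

.SET_EXTRACTORS <- function() list(
    STAT = statSet, GRAD = gradSet, HAAR = haarSet, GLCM = glcmSet)

#' Extract feature sets from a cohort
#'
#' Runs the requested extractors over every lesion pair and assembles one
#' \linkS4class{FeatureTable} per set, with the fixed arities 22 (STAT),
#' 24 (GRAD), 96 (HAAR) and 312 (GLCM).
#'
#' @param pairs list of \linkS4class{RoiPair} (from \code{\link{loadCohort}})
#' @param sets subset of \code{c("STAT", "GRAD", "HAAR", "GLCM")}
#' @param glcmDistance,glcmLevels co-occurrence parameters for the GLCM set
#' @return named list of \linkS4class{FeatureTable}
#' @export
extractFeatures <- function(pairs, sets = .FEATURE_SETS,
                            glcmDistance = 1L, glcmLevels = 16L) {
    sets <- match.arg(sets, .FEATURE_SETS, several.ok = TRUE)
    labels <- vapply(pairs, function(p) p@record$label, character(1))
    ids <- vapply(pairs, function(p) p@record$lesion_id, character(1))
    out <- lapply(sets, function(s) {
        fun <- .SET_EXTRACTORS()[[s]]
        rows <- if (s == "GLCM")
            lapply(pairs, fun, distance = glcmDistance, nLevels = glcmLevels)
        else lapply(pairs, fun)
        values <- do.call(rbind, rows)
        rownames(values) <- ids
        stopifnot(ncol(values) == .SET_ARITY[[s]],
                  all(is.finite(values)))
        params <- if (s == "GLCM")
            list(distance = glcmDistance, nLevels = glcmLevels) else list()
        FeatureTable(values, labels, s, lesionIds = ids, params = params)
    })
    names(out) <- sets
    out
}

#' Write / read a FeatureTable as CSV
#'
#' The CSV holds one lesion per row: \code{lesion_id}, \code{label}, then
#' the feature columns.  Values are written with 17 significant digits so a
#' round trip preserves doubles exactly; the set id is kept in a
#' \code{#setId} comment line.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path CSV file path
#' @return \code{writeFeatureTable}: invisibly, the path;
#'   \code{readFeatureTable}: the restored \linkS4class{FeatureTable}
#' @export
writeFeatureTable <- function(table, path) {
    stopifnot(is(table, "FeatureTable"))
    validObject(table)
    v <- featureValues(table)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#setId=%s", setId(table)), con)
    writeLines(paste(c("lesion_id", "label", colnames(v)), collapse = ","),
               con)
    if (nrow(v))
        writeLines(paste(rownames(v), as.character(lesionLabels(table)),
                         apply(v, 1, function(r) paste(
                             formatC(r, digits = 17, format = "g"),
                             collapse = ",")), sep = ","), con)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1], "#setId="))
        stop("malformed feature-table CSV (line 1): missing #setId header")
    sid <- sub("^#setId=", "", lines[1])
    header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
    if (length(header) < 2L || header[1] != "lesion_id" ||
        header[2] != "label")
        stop("malformed feature-table CSV (line 2): expected lesion_id,label,...")
    fnames <- header[-(1:2)]
    body <- lines[-(1:2)]
    if (!length(body)) {
        values <- matrix(numeric(0), 0, length(fnames),
                         dimnames = list(NULL, fnames))
        return(FeatureTable(values, character(0), sid,
                            lesionIds = character(0)))
    }
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != length(header))
    if (length(bad))
        stop(sprintf("malformed feature-table CSV (line %d): %d fields, expected %d",
                     bad[1] + 2L, lengths(parts)[bad[1]], length(header)))
    values <- do.call(rbind, lapply(parts, function(p)
        as.numeric(p[-(1:2)])))
    if (anyNA(values))
        stop("malformed feature-table CSV: non-numeric feature value")
    colnames(values) <- fnames
    FeatureTable(values, vapply(parts, `[`, character(1), 2L), sid,
                 lesionIds = vapply(parts, `[`, character(1), 1L))
}
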