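#' Read a count table
#'
#' TSV/CSV tables are expected with samples as rows, the sample identifier
#' in the first column and taxon identifiers in the header (the format
#' written by [writeCounts()]); set `taxaAsRows = TRUE` for the transposed
#' layout. BIOM tables (JSON) follow the taxa-as-rows convention and are
#' transposed on read (requires the `biomformat` package).
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"biom"`; default guessed from the
#'   file extension.
#' @param taxaAsRows logical, for tsv/csv only.
#' @return a [CountMatrix-class].
#' @export
readCounts <- function(path, format = c("auto", "tsv", "csv", "biom"),
                       taxaAsRows = FALSE) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", biom = "biom", "tsv")
    }
    if (format == "biom") {
        if (!requireNamespace("biomformat", quietly = TRUE))
            stop("reading BIOM files requires the 'biomformat' package")
        b <- biomformat::read_biom(path)
        m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
        return(.checkCounts(t(m), path))
    }
    df <- if (format == "csv")
        utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    else
        utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed count table: ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate identifiers in first column of ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- ids
    if (taxaAsRows) m <- t(m)
    .checkCounts(m, path)
}

.checkCounts <- function(m, path) {
    if (any(!is.finite(m))) stop("non-finite counts in ", path)
    if (any(m < 0)) stop("negative counts in ", path)
    if (max(abs(m - round(m))) > 1e-8) stop("non-integer counts in ", path)
    CountMatrix(m, samplesAsRows = TRUE)
}

#' Write a count table as TSV
#'
#' Samples as rows, first column `sample_id`, header of taxon identifiers.
#'
#' @param Y a [CountMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(Y, path) {
    m <- .smat(Y)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write the generative truth of a simulated draw as TSV
#'
#' Long format with columns `role` (`sample`/`taxon`), `id`, and the
#' per-entity values: samples carry the treatment `x` and sample effect
#' `a`, taxa carry the treatment effect `b`.
#'
#' @param draw a [SimDraw-class].
#' @param path output file path.
#' @param sampleIDs,taxonIDs identifier vectors (defaults generated).
#' @return `path`, invisibly.
#' @export
writeSimTruth <- function(draw, path, sampleIDs = NULL, taxonIDs = NULL) {
    stopifnot(methods::is(draw, "SimDraw"))
    I <- length(draw@a); J <- length(draw@t)
    if (is.null(sampleIDs)) sampleIDs <- paste0("sample_", seq_len(I))
    if (is.null(taxonIDs)) taxonIDs <- paste0("taxon_", seq_len(J))
    df <- rbind(
        data.frame(role = "sample", id = sampleIDs, x = draw@x, a = draw@a,
                   b = NA_real_, stringsAsFactors = FALSE),
        data.frame(role = "taxon", id = taxonIDs, x = NA_real_,
                   a = NA_real_, b = draw@bVec, stringsAsFactors = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a count table together with sample metadata
#'
#' Aligns the metadata rows to the count table's sample identifiers
#' (matching on a `sample_id` column, or on the first column) and returns
#' both plus a provenance record.
#'
#' @param countPath count table path (see [readCounts()]).
#' @param metadataPath TSV/CSV of per-sample metadata.
#' @param treatmentCol name of the treatment column (default
#'   `"treatment"`).
#' @param ... passed to [readCounts()].
#' @return list with `counts` (a [CountMatrix-class] whose `colData` holds
#'   the metadata), `metadata` (data.frame), `treatment` (the extracted
#'   column) and `provenance` (source paths and applied filters).
#' @export
readDataset <- function(countPath, metadataPath,
                        treatmentCol = "treatment", ...) {
    Y <- readCounts(countPath, ...)
    md <- if (tolower(tools::file_ext(metadataPath)) == "csv")
        utils::read.csv(metadataPath, check.names = FALSE,
                        stringsAsFactors = FALSE)
    else utils::read.delim(metadataPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
    idCol <- if ("sample_id" %in% names(md)) "sample_id" else names(md)[1]
    ids <- as.character(md[[idCol]])
    if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
    samples <- colnames(counts(Y))
    if (!setequal(ids, samples))
        stop("metadata sample ids do not match the count table 1:1")
    md <- md[match(samples, ids), , drop = FALSE]
    rownames(md) <- samples
    if (!treatmentCol %in% names(md))
        stop("treatment column '", treatmentCol, "' not found in metadata")
    SummarizedExperiment::colData(Y) <- S4Vectors::DataFrame(md)
    list(counts = Y, metadata = md, treatment = md[[treatmentCol]],
         provenance = list(countPath = countPath,
                           metadataPath = metadataPath,
                           filters = character(0)))
}

#' Write an ordination's scores and loadings as TSV
#'
#' Axes as columns, identifiers as the first column.
#'
#' @param ord an [OrdinationResult-class].
#' @param scoresPath,loadingsPath output paths.
#' @return invisibly, the two paths.
#' @export
writeOrdination <- function(ord, scoresPath, loadingsPath) {
    sc <- data.frame(id = rownames(ord@U) %||%
                         paste0("sample_", seq_len(nrow(ord@U))),
                     ord@U, check.names = FALSE)
    ld <- data.frame(id = rownames(ord@V) %||%
                         paste0("taxon_", seq_len(nrow(ord@V))),
                     ord@V, check.names = FALSE)
    utils::write.table(sc, scoresPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ld, loadingsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(scoresPath, loadingsPath))
}

#' Write a permutation test result as a one-row TSV
#'
#' @param res an [RdaTestResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTestResult <- function(res, path) {
    df <- data.frame(statistic = res@statistic, n_perm = res@nPerm,
                     p_value = res@pValue, method = res@method)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
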