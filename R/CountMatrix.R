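#' Construct a CountMatrix
#'
#' @param counts numeric matrix of nonnegative integer counts. By default
#'   samples are rows and taxa are columns (the orientation used by the
#'   ordination machinery); set `samplesAsRows = FALSE` for a taxa-by-samples
#'   matrix.
#' @param samplesAsRows logical, orientation of `counts`.
#' @param sampleIDs,taxonIDs optional identifier vectors; taken from the
#'   dimnames of `counts` when present, otherwise generated.
#' @return a [CountMatrix-class] object.
#' @examples
#' Y <- CountMatrix(matrix(c(0, 1, 2, 0, 3, 5), nrow = 2))
#' librarySizes(Y)
#' zeroFraction(Y)
#' @export
CountMatrix <- function(counts, samplesAsRows = TRUE,
                        sampleIDs = NULL, taxonIDs = NULL) {
    counts <- as.matrix(counts)
    if (samplesAsRows) counts <- t(counts)
    ## now taxa x samples
    if (is.null(rownames(counts)))
        rownames(counts) <- if (!is.null(taxonIDs)) taxonIDs else
            paste0("taxon_", seq_len(nrow(counts)))
    else if (!is.null(taxonIDs)) rownames(counts) <- taxonIDs
    if (is.null(colnames(counts)))
        colnames(counts) <- if (!is.null(sampleIDs)) sampleIDs else
            paste0("sample_", seq_len(ncol(counts)))
    else if (!is.null(sampleIDs)) colnames(counts) <- sampleIDs
    if (anyDuplicated(rownames(counts)))
        stop("duplicate taxon identifiers")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample identifiers")
    storage.mode(counts) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts))
    methods::new("CountMatrix", se)
}

## samples x taxa matrix from a CountMatrix or plain matrix
.smat <- function(x) {
    if (methods::is(x, "CountMatrix"))
        t(SummarizedExperiment::assay(x, "counts"))
    else as.matrix(x)
}

#' @rdname CountMatrix
#' @aliases counts,CountMatrix-method
#' @param object a `CountMatrix`.
#' @export
setMethod("counts", "CountMatrix", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn CountMatrix counts as a samples-by-taxa matrix.
#' @export
setMethod("countMatrix", "CountMatrix", function(x) .smat(x))

#' @describeIn CountMatrix per-sample total counts (row sums of the
#'   samples-by-taxa table).
#' @export
setMethod("librarySizes", "CountMatrix", function(x) colSums(counts(x)))

#' @describeIn CountMatrix number of samples in which each taxon has a
#'   nonzero count.
#' @export
setMethod("taxonPrevalence", "CountMatrix", function(x)
    rowSums(counts(x) > 0))

setMethod("show", "CountMatrix", function(object) {
    m <- counts(object)
    cat("CountMatrix:", ncol(m), "samples x", nrow(m), "taxa\n")
    cat(sprintf("  zero cells: %.1f%%; library sizes: %s\n",
        100 * mean(m == 0),
        paste(range(colSums(m)), collapse = " - ")))
    flt <- metadata(object)$filters
    if (!is.null(flt))
        cat("  filters applied:", paste(flt, collapse = "; "), "\n")
})

#' Fraction of zero cells in a count table
#'
#' @param x a [CountMatrix-class] or numeric matrix.
#' @return scalar in `[0, 1]`.
#' @examples
#' zeroFraction(CountMatrix(rbind(c(0, 1), c(2, 0))))  # 0.5
#' @export
setMethod("zeroFraction", "CountMatrix", function(x) {
    m <- counts(x)
    if (length(m) == 0) stop("empty count table")
    mean(m == 0)
})

#' @rdname zeroFraction
#' @export
setMethod("zeroFraction", "matrix", function(x) {
    if (length(x) == 0) stop("empty count table")
    mean(x == 0)
})

#' Remove low-prevalence (and optionally low-abundance) taxa
#'
#' Retains the taxa with nonzero counts in at least `minPrevalence` samples,
#' matching the convention that taxa present in fewer than `minPrevalence`
#' samples are removed before analysis. Optionally also requires a mean
#' count of at least `minMeanAbundance` (a stricter filter that reduces the
#' influence of rare taxa on clr-based analyses). The sample set is
#' unchanged; library sizes are recomputed implicitly as the filtered row
#' sums.
#'
#' @param x a [CountMatrix-class].
#' @param minPrevalence integer >= 0; `0` retains all taxa.
#' @param minMeanAbundance numeric >= 0, minimum mean count per taxon.
#' @return the filtered `CountMatrix`; the filter is recorded in
#'   `metadata(x)$filters`.
#' @examples
#' Y <- CountMatrix(matrix(c(1, 2, 3, 0, 0, 1), nrow = 3))
#' prevalenceFilter(Y, 2)
#' @export
setMethod("prevalenceFilter", "CountMatrix",
    function(x, minPrevalence = 5L, minMeanAbundance = 0) {
        if (minPrevalence < 0) stop("minPrevalence must be >= 0")
        keep <- taxonPrevalence(x) >= minPrevalence &
            rowMeans(counts(x)) >= minMeanAbundance
        if (!any(keep))
            stop("all taxa removed by the prevalence filter")
        out <- x[keep, ]
        metadata(out)$filters <- c(metadata(x)$filters,
            sprintf("prevalence >= %d, mean >= %g (%d of %d taxa retained)",
                    as.integer(minPrevalence), minMeanAbundance,
                    sum(keep), length(keep)))
        out
    })
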