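#' @rdname AsvExperiment-accessors
#' @export
setGeneric("asvCounts", function(x, ...) standardGeneric("asvCounts"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("seasons", function(x) standardGeneric("seasons"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("sampleYears", function(x) standardGeneric("sampleYears"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname ParasiteCalls-accessors
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @rdname ParasiteCalls-accessors
#' @export
setGeneric("parasiteStatus", function(x) standardGeneric("parasiteStatus"))

#' @rdname ParasiteCalls-accessors
#' @export
setGeneric("parasiteAsvs", function(x) standardGeneric("parasiteAsvs"))

#' @rdname tallyProvenance
#' @export
setGeneric("tallyProvenance", function(x) standardGeneric("tallyProvenance"))

#' @rdname BetaPartition-accessors
#' @export
setGeneric("betaSor", function(x) standardGeneric("betaSor"))

#' @rdname BetaPartition-accessors
#' @export
setGeneric("betaSim", function(x) standardGeneric("betaSim"))

#' @rdname BetaPartition-accessors
#' @export
setGeneric("betaNes", function(x) standardGeneric("betaNes"))

#' Accessors for AsvExperiment
#'
#' \code{asvCounts} returns the count matrix (ASVs x samples by default;
#' \code{samplesAsRows = TRUE} gives the interchange orientation).
#' \code{seasons}, \code{sampleYears} and \code{isControl} return the
#' per-sample factors derived from the sampling dates;
#' \code{taxonomyTable} returns the ranked taxonomy as a data.frame.
#'
#' @param x an \code{AsvExperiment}
#' @param samplesAsRows return samples as rows (the TSV orientation)?
#' @param ... unused
#' @name AsvExperiment-accessors
NULL

#' @rdname AsvExperiment-accessors
#' @export
setMethod("asvCounts", "AsvExperiment", function(x, samplesAsRows = FALSE) {
    m <- SummarizedExperiment::assay(x, "counts")
    if (samplesAsRows) t(m) else m
})

#' @rdname AsvExperiment-accessors
#' @export
setMethod("seasons", "AsvExperiment", function(x)
    SummarizedExperiment::colData(x)$season)

#' @rdname AsvExperiment-accessors
#' @export
setMethod("sampleYears", "AsvExperiment", function(x)
    SummarizedExperiment::colData(x)$year)

#' @rdname AsvExperiment-accessors
#' @export
setMethod("isControl", "AsvExperiment", function(x)
    SummarizedExperiment::colData(x)$is_control)

#' @rdname AsvExperiment-accessors
#' @export
setMethod("taxonomyTable", "AsvExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)[, PR2_RANKS, drop = FALSE]
    df <- as.data.frame(rd)
    df <- cbind(asv_id = rownames(x), df)
    rownames(df) <- NULL
    df
})

setMethod("show", "AsvExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    n_ctrl <- sum(cd$is_control)
    cat(sprintf("AsvExperiment: %d ASVs x %d samples (%d controls)\n",
                nrow(object), ncol(object), n_ctrl))
    if (ncol(object) > 0L) {
        rng <- range(cd$date)
        cat(sprintf("  dates %s .. %s; years %s\n", rng[1], rng[2],
                    paste(sort(unique(cd$year)), collapse = ", ")))
    }
    cat(sprintf("  total reads: %s\n",
                format(sum(asvCounts(object)), big.mark = ",")))
})

#' Accessors for ParasiteCalls
#'
#' \code{annotationTable} returns the per-ASV annotations as a
#' data.frame; \code{parasiteStatus} the named status vector;
#' \code{parasiteAsvs} the identifiers of ASVs classified parasitic.
#'
#' @param x a \code{ParasiteCalls} object
#' @name ParasiteCalls-accessors
NULL

#' @rdname ParasiteCalls-accessors
#' @export
setMethod("annotationTable", "ParasiteCalls", function(x) {
    df <- as.data.frame(x@annotations)
    rownames(df) <- NULL
    df
})

#' @rdname ParasiteCalls-accessors
#' @export
setMethod("parasiteStatus", "ParasiteCalls", function(x) {
    stats::setNames(x@annotations$status, x@annotations$asv_id)
})

#' @rdname ParasiteCalls-accessors
#' @export
setMethod("parasiteAsvs", "ParasiteCalls", function(x) {
    an <- x@annotations
    an$asv_id[an$status == "parasitic"]
})

setMethod("show", "ParasiteCalls", function(object) {
    tl <- tallyProvenance(object)
    cat(sprintf("ParasiteCalls over %d ASVs\n", tl$n_asvs))
    cat(sprintf("  parasitic: %d (%.1f%%) [literature %d | ncbi %d | both %d]\n",
                tl$parasitic, tl$percent, tl$literature, tl$ncbi, tl$both))
    cat(sprintf("  non-parasitic: %d; excluded by preselection: %d\n",
                tl$non_parasitic, tl$excluded))
})

#' Accessors for BetaPartition
#'
#' @param x a \code{BetaPartition}
#' @name BetaPartition-accessors
NULL

#' @rdname BetaPartition-accessors
#' @export
setMethod("betaSor", "BetaPartition", function(x) x@beta_sor)

#' @rdname BetaPartition-accessors
#' @export
setMethod("betaSim", "BetaPartition", function(x) x@beta_sim)

#' @rdname BetaPartition-accessors
#' @export
setMethod("betaNes", "BetaPartition", function(x) x@beta_nes)

setMethod("show", "BetaPartition", function(object) {
    cat(sprintf("BetaPartition (%s): beta_sor = %.4f = %.4f (turnover) + %.4f (nestedness)\n",
                object@scope, object@beta_sor, object@beta_sim,
                object@beta_nes))
})
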