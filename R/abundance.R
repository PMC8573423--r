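#' Remove singleton ASVs
#'
#' Drops every ASV present (count >= 1) in fewer than two samples,
#' i.e. singletons and all-zero columns. Presence is counted over all
#' samples of the object, controls included. Idempotent.
#'
#' @param x an \code{AsvExperiment}
#' @return the filtered \code{AsvExperiment}
#' @export
dropSingletons <- function(x) {
    stopifnot(is(x, "AsvExperiment"))
    presence <- rowSums(asvCounts(x) >= 1L)
    keep <- presence >= 2L
    if (!any(keep))
        stop("all ASVs are singletons; nothing left after filtering")
    x[keep, ]
}

#' Convert counts to relative abundances
#'
#' Divides each count by its sample's total over all ASVs (parasitic
#' and non-parasitic alike) and stores the result as the
#' \code{"relabund"} assay. Samples with zero total reads get an
#' all-zero row and a warning.
#'
#' @param x an \code{AsvExperiment}
#' @return \code{x} with a \code{"relabund"} assay added
#' @export
relativeAbundance <- function(x) {
    stopifnot(is(x, "AsvExperiment"))
    cnt <- asvCounts(x)
    tot <- colSums(cnt)
    zero <- tot == 0
    if (any(zero)) {
        warning("samples with zero total reads: ",
                paste(colnames(x)[zero], collapse = ", "))
        tot[zero] <- 1
    }
    rel <- sweep(cnt, 2L, tot, "/")
    SummarizedExperiment::assay(x, "relabund") <- rel
    x
}

.relMatrix <- function(x) {
    if (!"relabund" %in% SummarizedExperiment::assayNames(x))
        x <- relativeAbundance(x)
    SummarizedExperiment::assay(x, "relabund")
}

#' Per-sample parasite abundance and richness
#'
#' For every non-control sample: the summed relative read abundance of
#' parasitic ASVs (denominator = all reads of the sample) and parasite
#' richness (number of parasitic ASVs with at least one read). With
#' \code{by_group = TRUE} the same two metrics are additionally
#' reported per parasite taxon group (the taxonomy rank given by
#' \code{group_rank}, e.g. Chytridiomycota), for the groups in
#' \code{groups} (default: every group observed among parasitic ASVs).
#'
#' @param x an \code{AsvExperiment} (singleton-filtered)
#' @param calls a \code{ParasiteCalls} for the same ASVs
#' @param by_group also compute per-taxon-group metrics?
#' @param group_rank taxonomy rank defining the groups
#' @param groups restrict per-group output to these group names
#' @return tidy data.frame with columns \code{sample_id},
#'   \code{season}, \code{year}, \code{group} (\code{"all"} for the
#'   totals), \code{rel_abundance}, \code{richness}
#' @export
sampleSummaries <- function(x, calls, by_group = FALSE,
                            group_rank = "division", groups = NULL) {
    stopifnot(is(x, "AsvExperiment"), is(calls, "ParasiteCalls"))
    an <- annotationTable(calls)
    miss <- setdiff(rownames(x), an$asv_id)
    if (length(miss))
        stop("annotations missing for ASVs: ", paste(miss, collapse = ", "))
    keep <- !isControl(x)
    rel <- .relMatrix(x)[, keep, drop = FALSE]
    cnt <- asvCounts(x)[, keep, drop = FALSE]
    cd <- SummarizedExperiment::colData(x)[keep, , drop = FALSE]
    para_ids <- intersect(rownames(x), parasiteAsvs(calls))
    blocks <- list(all = para_ids)
    if (by_group) {
        tax <- taxonomyTable(x)
        grp <- stats::setNames(tax[[group_rank]], tax$asv_id)[para_ids]
        gl <- if (is.null(groups)) sort(unique(grp[!is.na(grp)])) else groups
        for (g in gl) blocks[[g]] <- para_ids[!is.na(grp) & grp == g]
    }
    out <- lapply(names(blocks), function(g) {
        ids <- blocks[[g]]
        ra <- if (length(ids))
            colSums(rel[ids, , drop = FALSE]) else numeric(ncol(rel))
        ri <- if (length(ids))
            colSums(cnt[ids, , drop = FALSE] >= 1L) else integer(ncol(cnt))
        data.frame(sample_id = rownames(cd),
                   season = cd$season, year = cd$year, group = g,
                   rel_abundance = unname(ra),
                   richness = as.integer(unname(ri)),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Negative-control screen
#'
#' Reports what the negative-control samples contain: total reads,
#' number of ASVs present, a per-taxon-group breakdown of those ASVs,
#' and the list (expected to be empty) of control ASVs that were
#' classified parasitic. Controls are reported, never subtracted.
#'
#' @param x an \code{AsvExperiment} whose \code{colData} flags controls
#' @param calls a \code{ParasiteCalls}; optional
#' @param group_rank taxonomy rank for the breakdown
#' @return list with \code{n_reads}, \code{n_asvs}, \code{by_group}
#'   (named integer vector), \code{parasitic_asvs} (character)
#' @export
controlScreen <- function(x, calls = NULL, group_rank = "division") {
    stopifnot(is(x, "AsvExperiment"))
    ctrl <- isControl(x)
    if (!any(ctrl))
        return(list(n_reads = 0L, n_asvs = 0L,
                    by_group = integer(0), parasitic_asvs = character(0)))
    cnt <- asvCounts(x)[, ctrl, drop = FALSE]
    present <- rowSums(cnt) > 0
    ids <- rownames(x)[present]
    tax <- taxonomyTable(x)
    grp <- stats::setNames(tax[[group_rank]], tax$asv_id)[ids]
    grp[is.na(grp)] <- "unassigned"
    viol <- character(0)
    if (!is.null(calls))
        viol <- intersect(ids, parasiteAsvs(calls))
    list(n_reads = sum(cnt),
         n_asvs = length(ids),
         by_group = table(grp) |> c(),
         parasitic_asvs = viol)
}
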