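#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

#' The PR2-style taxonomy ranks used throughout the package
#'
#' Eight ranked levels, kingdom through species, matching the layout of the
#' PR2 reference database used for 18S rRNA amplicon classification.
#'
#' @export
PR2_RANKS <- c("kingdom", "supergroup", "division", "class",
               "order", "family", "genus", "species")

#' AsvExperiment: container for an ASV count time series
#'
#' An \code{AsvExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are amplicon sequence
#' variants (ASVs), columns are samples. The \code{"counts"} assay holds
#' non-negative integer read counts. \code{rowData} carries the ranked
#' taxonomy (columns \code{kingdom} ... \code{species}, \code{NA} =
#' unassigned). \code{colData} carries \code{date}, the derived factors
#' \code{season} and \code{year}, and the logical \code{is_control} flag
#' for negative-control samples.
#'
#' @seealso \code{\link{AsvExperiment}} (constructor),
#'   \code{\link{readAsvExperiment}}
#' @import SummarizedExperiment
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

.validAsvExperiment <- function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cnt)))
            msg <- c(msg, "counts contain non-finite values")
        else {
            if (any(cnt < 0))
                msg <- c(msg, "counts contain negative values")
            if (any(cnt != round(cnt)))
                msg <- c(msg, "counts contain non-integer values")
        }
    }
    if (nrow(object) < 1L || ncol(object) < 1L)
        msg <- c(msg, "need at least one ASV and one sample")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicate ASV identifier: %s",
                              rownames(object)[duplicated(rownames(object))][1L]))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, sprintf("duplicate sample identifier: %s",
                              colnames(object)[duplicated(colnames(object))][1L]))
    if (length(msg)) msg else TRUE
}
setValidity("AsvExperiment", .validAsvExperiment)

#' Construct an AsvExperiment
#'
#' @param counts samples-by-ASVs matrix of non-negative integer read
#'   counts, in the row orientation of the interchange TSV (it is
#'   transposed into the ASVs-by-samples orientation internally). Row
#'   names are sample identifiers, column names ASV identifiers.
#' @param taxonomy data.frame with column \code{asv_id} and the eight
#'   \code{PR2_RANKS} columns, one row per ASV (\code{NA} or empty string
#'   means unassigned). Optional; ranks default to all-unassigned.
#' @param dates Date vector (or ISO-8601 strings), one per sample.
#' @param is_control logical vector, one per sample; defaults to all
#'   \code{FALSE}.
#' @return a validated \code{AsvExperiment}; \code{season} and
#'   \code{year} are derived from \code{dates}.
#' @examples
#' cnt <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'               dimnames = list(c("S1", "S2"), c("ASV1", "ASV2")))
#' ae <- AsvExperiment(cnt, dates = c("2015-06-15", "2015-12-07"))
#' seasons(ae)
#' @export
AsvExperiment <- function(counts, taxonomy = NULL, dates = NULL,
                          is_control = NULL) {
    if (is.data.frame(counts)) counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have sample row names and ASV column names")
    m <- t(counts)
    storage.mode(m) <- "integer"
    n_samp <- ncol(m)
    if (is.null(dates))
        stop("sample dates are required")
    dates <- parseIsoDate(dates)
    if (length(dates) != n_samp)
        stop("need exactly one date per sample")
    if (is.null(is_control)) is_control <- rep(FALSE, n_samp)
    cd <- S4Vectors::DataFrame(
        date = dates,
        season = assignSeason(dates),
        year = as.integer(format(dates, "%Y")),
        is_control = as.logical(is_control),
        row.names = colnames(m))
    rd <- .taxonomyRowData(taxonomy, rownames(m))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m), rowData = rd, colData = cd)
    new("AsvExperiment", se)
}

.taxonomyRowData <- function(taxonomy, asv_ids) {
    if (is.null(taxonomy)) {
        rd <- S4Vectors::DataFrame(row.names = asv_ids)
        for (r in PR2_RANKS) rd[[r]] <- rep(NA_character_, length(asv_ids))
        return(rd)
    }
    taxonomy <- validateTaxonomy(taxonomy)
    miss <- setdiff(asv_ids, taxonomy$asv_id)
    if (length(miss))
        stop("taxonomy missing for ASVs: ", paste(miss, collapse = ", "))
    taxonomy <- taxonomy[match(asv_ids, taxonomy$asv_id), , drop = FALSE]
    rd <- S4Vectors::DataFrame(taxonomy[PR2_RANKS], row.names = asv_ids)
    rd
}

#' ParasiteCalls: per-ASV parasite classification results
#'
#' Holds one annotation per ASV: \code{status} (\code{parasitic},
#' \code{non_parasitic} or \code{excluded_by_preselection}),
#' \code{provenance} of the host evidence (\code{literature},
#' \code{ncbi}, \code{both}, \code{none}), the recorded host names,
#' the host-taxon group, and for metadata-derived evidence the rank and
#' accession of the hit that supplied it.
#'
#' @slot annotations a \code{DataFrame} with columns \code{asv_id},
#'   \code{status}, \code{provenance}, \code{hosts} (semicolon-joined),
#'   \code{host_group}, \code{evidence_rank}, \code{evidence_accession}.
#' @slot params list of classifier parameters (max_rank, min_identity,
#'   preselection groups and rank).
#' @export
setClass("ParasiteCalls",
         representation(annotations = "DataFrame", params = "list"))

.validParasiteCalls <- function(object) {
    an <- object@annotations
    msg <- character()
    need <- c("asv_id", "status", "provenance", "hosts", "host_group",
              "evidence_rank", "evidence_accession")
    if (!all(need %in% colnames(an)))
        return(paste("missing annotation columns:",
                     paste(setdiff(need, colnames(an)), collapse = ", ")))
    ok_status <- c("parasitic", "non_parasitic", "excluded_by_preselection")
    if (!all(an$status %in% ok_status))
        msg <- c(msg, "invalid status value")
    if (!all(an$provenance %in% c("literature", "ncbi", "both", "none")))
        msg <- c(msg, "invalid provenance value")
    para <- an$status == "parasitic"
    if (any(para != (an$provenance != "none")))
        msg <- c(msg, "status 'parasitic' must coincide with provenance != 'none'")
    if (any(!para & nzchar(an$hosts)))
        msg <- c(msg, "non-parasitic annotations must carry no hosts")
    has_rank <- !is.na(an$evidence_rank)
    if (any(has_rank != (an$provenance %in% c("ncbi", "both"))))
        msg <- c(msg, "evidence_rank present iff provenance is 'ncbi' or 'both'")
    if (length(msg)) msg else TRUE
}
setValidity("ParasiteCalls", .validParasiteCalls)

#' BetaPartition: Sorensen dissimilarity split into turnover and nestedness
#'
#' The Baselga decomposition of (multi-site or pairwise) Sorensen
#' dissimilarity \eqn{\beta_{SOR}} into a turnover component
#' \eqn{\beta_{SIM}} (Simpson dissimilarity; species replacement) and a
#' nestedness-resultant component
#' \eqn{\beta_{NES} = \beta_{SOR} - \beta_{SIM}}.
#'
#' @slot beta_sor,beta_sim,beta_nes numeric scalars in [0, 1].
#' @slot scope \code{"pairwise"} or \code{"multi"}.
#' @slot components named numeric vector: for pairwise scope the
#'   incidence components \code{a} (shared), \code{b}, \code{c} (unique
#'   to each side); for multi-site scope the summation terms
#'   \code{sum_min}, \code{sum_max} and \code{K} (= sum of site
#'   richnesses minus pooled richness).
#' @export
setClass("BetaPartition",
         representation(beta_sor = "numeric", beta_sim = "numeric",
                        beta_nes = "numeric", scope = "character",
                        components = "numeric"))

.validBetaPartition <- function(object) {
    v <- c(object@beta_sor, object@beta_sim, object@beta_nes)
    msg <- character()
    if (any(v < -1e-12 | v > 1 + 1e-12))
        msg <- c(msg, "beta components must lie in [0, 1]")
    if (abs(object@beta_sor - object@beta_sim - object@beta_nes) > 1e-9)
        msg <- c(msg, "beta_nes must equal beta_sor - beta_sim")
    if (!object@scope %in% c("pairwise", "multi"))
        msg <- c(msg, "scope must be 'pairwise' or 'multi'")
    if (length(msg)) msg else TRUE
}
setValidity("BetaPartition", .validBetaPartition)
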