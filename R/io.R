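#' Read an ASV count table
#'
#' Interchange format: delimited text, header row of ASV identifiers,
#' first column of sample identifiers, one sample per row. Counts must
#' be non-negative integers.
#'
#' @param path file path
#' @param sep field delimiter; \code{"\t"} (default) or \code{","}
#' @return samples-by-ASVs integer matrix with dimnames
#' @seealso \code{\link{writeAsvTable}}, \code{\link{readAsvExperiment}}
#' @export
readAsvTable <- function(path, sep = "\t") {
    raw <- readTsv(path, sep = sep)
    if (ncol(raw) < 2L)
        stop("ASV table needs a sample-id column plus at least one ASV column")
    sample_ids <- raw[[1L]]
    asv_ids <- colnames(raw)[-1L]
    if (anyDuplicated(sample_ids))
        stop("duplicate sample identifier: ",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
    if (anyDuplicated(asv_ids))
        stop("duplicate ASV identifier: ",
             paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
    m <- matrix(NA_integer_, nrow(raw), length(asv_ids),
                dimnames = list(sample_ids, asv_ids))
    for (j in seq_along(asv_ids)) {
        v <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) | num < 0 | num != round(num))
        if (length(bad))
            stop(sprintf(
                "invalid count '%s' at sample '%s', ASV '%s' (must be a non-negative integer)",
                v[bad[1L]], sample_ids[bad[1L]], asv_ids[j]))
        m[, j] <- as.integer(num)
    }
    m
}

#' Write an ASV count table
#'
#' @param counts samples-by-ASVs matrix (the orientation returned by
#'   \code{readAsvTable} / \code{asvCounts(x, samplesAsRows = TRUE)})
#' @param path output path
#' @return the path, invisibly
#' @export
writeAsvTable <- function(counts, path) {
    df <- data.frame(sample_id = rownames(counts),
                     as.data.frame(counts, check.names = FALSE),
                     check.names = FALSE)
    writeTsv(df, path)
}

#' Validate a ranked taxonomy table
#'
#' Normalizes empty strings to \code{NA} (unassigned) and enforces the
#' prefix rule: once a rank is unassigned all deeper ranks must be
#' unassigned too.
#'
#' @param taxonomy data.frame with \code{asv_id} and the
#'   \code{PR2_RANKS} columns
#' @return normalized data.frame
#' @export
validateTaxonomy <- function(taxonomy) {
    need <- c("asv_id", PR2_RANKS)
    miss <- setdiff(need, colnames(taxonomy))
    if (length(miss))
        stop("taxonomy lacks columns: ", paste(miss, collapse = ", "))
    taxonomy <- as.data.frame(taxonomy)[need]
    if (anyDuplicated(taxonomy$asv_id))
        stop("duplicate ASV identifier in taxonomy: ",
             taxonomy$asv_id[duplicated(taxonomy$asv_id)][1L])
    for (r in PR2_RANKS) {
        v <- as.character(taxonomy[[r]])
        v[!is.na(v) & (v == "" | tolower(v) == "unassigned")] <- NA_character_
        taxonomy[[r]] <- v
    }
    rk <- as.matrix(taxonomy[PR2_RANKS])
    gap <- is.na(rk[, -ncol(rk), drop = FALSE]) &
        !is.na(rk[, -1L, drop = FALSE])
    if (any(gap)) {
        i <- which(rowSums(gap) > 0)[1L]
        stop("taxonomy for ", taxonomy$asv_id[i],
             " has an assigned rank below an unassigned one")
    }
    taxonomy
}

#' Deepest assigned rank of each taxonomy row
#'
#' @param taxonomy validated taxonomy data.frame
#' @return character vector of rank names (\code{NA} if fully
#'   unassigned)
#' @export
assignedLevel <- function(taxonomy) {
    rk <- as.matrix(taxonomy[PR2_RANKS])
    idx <- apply(!is.na(rk), 1L, function(z) {
        w <- which(z)
        if (length(w)) max(w) else NA_integer_
    })
    PR2_RANKS[idx]
}

#' Read a taxonomy table
#'
#' TSV with columns \code{asv_id}, \code{kingdom} ... \code{species};
#' empty cells mean unassigned.
#'
#' @param path file path
#' @return validated taxonomy data.frame
#' @export
readTaxonomy <- function(path) validateTaxonomy(readTsv(path))

#' @rdname readTaxonomy
#' @param taxonomy validated taxonomy data.frame
#' @export
writeTaxonomy <- function(taxonomy, path) writeTsv(taxonomy, path)

#' Read sample metadata and derive temporal factors
#'
#' TSV with columns \code{sample_id}, \code{date} (ISO-8601) and an
#' optional logical \code{is_control}. \code{buildSampleRecords} checks
#' coverage of a set of sample identifiers and attaches \code{season}
#' and calendar \code{year}.
#'
#' @param path file path
#' @return data.frame sample_id, date, is_control
#' @export
readSampleMetadata <- function(path) {
    md <- readTsv(path)
    need <- c("sample_id", "date")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(md$sample_id))
        stop("duplicate sample identifier in metadata: ",
             md$sample_id[duplicated(md$sample_id)][1L])
    md$date <- parseIsoDate(md$date)
    md$is_control <- if ("is_control" %in% colnames(md))
        as.logical(md$is_control) else FALSE
    md[c("sample_id", "date", "is_control")]
}

#' @rdname readSampleMetadata
#' @param metadata data.frame from \code{readSampleMetadata} (or a path)
#' @param sample_ids identifiers that must all be covered
#' @return data.frame sample_id, date, season, year, is_control in the
#'   order of \code{sample_ids}
#' @export
buildSampleRecords <- function(metadata, sample_ids) {
    if (is.character(metadata) && length(metadata) == 1L)
        metadata <- readSampleMetadata(metadata)
    miss <- setdiff(sample_ids, metadata$sample_id)
    if (length(miss))
        stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    metadata$date <- parseIsoDate(metadata$date)
    if (is.null(metadata$is_control)) metadata$is_control <- FALSE
    metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
    metadata$season <- assignSeason(metadata$date)
    metadata$year <- as.integer(format(metadata$date, "%Y"))
    rownames(metadata) <- NULL
    metadata[c("sample_id", "date", "season", "year", "is_control")]
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(metadata, path)
    writeTsv(metadata[c("sample_id", "date", "is_control")], path)

HIT_STORE_COLUMNS <- c("qseqid", "saccver", "pident", "evalue", "bitscore",
                       "host", "isolation_source", "title", "note", "organism")

#' Read an offline hit store
#'
#' BLAST outfmt-6-like tabular file extended with free-text metadata
#' columns, one row per hit: \code{qseqid}, \code{saccver},
#' \code{pident}, \code{evalue}, \code{bitscore}, \code{host},
#' \code{isolation_source}, \code{title}, \code{note}, \code{organism}.
#' This stands in for live BLAST + record retrieval; build one from real
#' output by joining \code{blastn -outfmt 6} to the source-record
#' qualifiers of each subject accession.
#'
#' @param path file path
#' @return data.frame with the columns above, numerics parsed
#' @export
readHitStore <- function(path) {
    h <- readTsv(path)
    miss <- setdiff(HIT_STORE_COLUMNS, colnames(h))
    if (length(miss))
        stop("hit store lacks columns: ", paste(miss, collapse = ", "))
    h <- h[HIT_STORE_COLUMNS]
    for (col in c("pident", "evalue", "bitscore"))
        h[[col]] <- as.numeric(h[[col]])
    if (any(is.na(h$pident) | h$pident < 0 | h$pident > 100))
        stop("pident must lie in [0, 100]")
    if (any(is.na(h$bitscore) | h$bitscore < 0))
        stop("bitscore must be >= 0")
    if (any(is.na(h$evalue) | h$evalue < 0))
        stop("evalue must be >= 0")
    h
}

#' @rdname readHitStore
#' @param hits hit-store data.frame
#' @export
writeHitStore <- function(hits, path) writeTsv(hits[HIT_STORE_COLUMNS], path)

#' Read a literature host registry
#'
#' TSV with columns \code{species} (binomial), \code{hosts}
#' (semicolon-joined names), \code{host_group}, \code{is_parasite}
#' (TRUE/FALSE) and \code{citation}. It records, per species, the
#' outcome of a literature search for parasitism and host identity.
#'
#' @param path file path
#' @return data.frame
#' @export
readLiteratureRegistry <- function(path) {
    reg <- readTsv(path)
    need <- c("species", "hosts", "host_group", "is_parasite", "citation")
    miss <- setdiff(need, colnames(reg))
    if (length(miss))
        stop("registry lacks columns: ", paste(miss, collapse = ", "))
    reg$is_parasite <- as.logical(reg$is_parasite)
    if (any(!nzchar(reg$species)))
        stop("registry species binomial must be non-empty")
    bad <- reg$is_parasite & !nzchar(reg$hosts) & reg$host_group != "Various"
    if (any(bad))
        stop("parasitic registry entry without hosts (and not 'Various'): ",
             reg$species[bad][1L])
    reg
}

#' @rdname readLiteratureRegistry
#' @param registry registry data.frame
#' @export
writeLiteratureRegistry <- function(registry, path)
    writeTsv(registry[c("species", "hosts", "host_group",
                        "is_parasite", "citation")], path)

#' Assemble an AsvExperiment from interchange files
#'
#' @param counts_path ASV count table (see \code{readAsvTable})
#' @param taxonomy_path taxonomy TSV
#' @param metadata_path sample metadata TSV
#' @param sep count-table delimiter
#' @return an \code{AsvExperiment}
#' @export
readAsvExperiment <- function(counts_path, taxonomy_path, metadata_path,
                              sep = "\t") {
    counts <- readAsvTable(counts_path, sep = sep)
    tax <- readTaxonomy(taxonomy_path)
    rec <- buildSampleRecords(metadata_path, rownames(counts))
    AsvExperiment(counts, taxonomy = tax, dates = rec$date,
                  is_control = rec$is_control)
}
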