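#' Default preselection of parasite-containing higher taxa
#'
#' Parasite classification only examines ASVs whose taxonomy, at a
#' chosen rank, falls in a configurable set of higher taxa with known
#' parasitic members; everything else is excluded up front. The default
#' list names 18 phyla/clades with well-documented parasitic species in
#' freshwater plankton (chytrids, oomycetes, dinoflagellates,
#' Perkinsozoa and other parasite-rich protist and fungal lineages).
#'
#' @param groups character vector of higher-taxon names
#' @param rank taxonomy rank the set is matched against
#' @return list with elements \code{groups} and \code{rank}
#' @export
preselectionList <- function(groups, rank = "division") {
    if (!length(groups)) stop("preselection list must be non-empty")
    if (!rank %in% PR2_RANKS) stop("unknown taxonomy rank: ", rank)
    list(groups = unique(as.character(groups)), rank = rank)
}

#' @rdname preselectionList
#' @export
defaultPreselection <- function() {
    preselectionList(c(
        "Chytridiomycota", "Dinoflagellata", "Oomycota", "Perkinsozoa",
        "Basidiomycota", "Ascomycota", "Cryptomycota", "Aphelida",
        "Blastocladiomycota", "Microsporidia", "Apicomplexa",
        "Ciliophora", "Cercozoa", "Ichthyosporea", "Labyrinthulomycetes",
        "Syndiniales", "Platyhelminthes", "Nematoda"),
        rank = "division")
}

#' Preselection gate
#'
#' @param taxonomy validated taxonomy data.frame (one or more rows)
#' @param preselection a \code{preselectionList}
#' @return logical vector: does the taxon at the matching rank belong to
#'   a preselected group? Unassigned at that rank is \code{FALSE}.
#' @export
preselect <- function(taxonomy, preselection = defaultPreselection()) {
    v <- taxonomy[[preselection$rank]]
    !is.na(v) & tolower(v) %in% tolower(preselection$groups)
}

#' Host-information extraction rules
#'
#' What counts as "host information" in free-text record metadata is a
#' package convention, kept in configuration: a non-empty \code{host}
#' qualifier always qualifies; failing that, \code{isolation_source}
#' and then \code{title}/\code{note} are matched against regular
#' expressions whose first capture group is taken as the host name.
#' \code{loadHostRules} reads the same structure from a YAML file (see
#' \code{system.file("extdata", "host_rules.yaml", package =
#' "paraplank")}).
#'
#' @return list with \code{isolation_patterns} and \code{title_patterns}
#' @export
defaultHostRules <- function() {
    list(
        isolation_patterns = c(
            "gut content[s]? of (?:the )?([A-Za-z][A-Za-z ]*)",
            "isolated from (?:the )?([A-Za-z][A-Za-z ]*)",
            "swab(?: sample)?s? (?:of|from) (?:the )?([A-Za-z][A-Za-z ]*)",
            "tissue[s]? (?:of|from) (?:the )?([A-Za-z][A-Za-z ]*)",
            "infect(?:ed|ing) ([A-Za-z][A-Za-z ]*)"),
        title_patterns = c(
            "parasite of (?:the )?(?:[a-z ]+, )?([A-Z][A-Za-z]*(?: [a-z.]+)?)",
            "parasitizing (?:the )?([A-Z][A-Za-z]*(?: [a-z.]+)?)",
            "infecting (?:the )?([A-Z][A-Za-z]*(?: [a-z.]+)?)",
            "isolated from (?:the )?([A-Z][A-Za-z]*(?: [a-z.]+)?)",
            "associated with (?:the )?(?:[a-z]+, )?([A-Z][A-Za-z]*(?: [a-z.]+)?)"))
}

#' @rdname defaultHostRules
#' @param path YAML file with keys \code{isolation_patterns},
#'   \code{title_patterns}
#' @export
loadHostRules <- function(path) {
    r <- yaml::read_yaml(path)
    need <- c("isolation_patterns", "title_patterns")
    miss <- setdiff(need, names(r))
    if (length(miss))
        stop("host rules lack keys: ", paste(miss, collapse = ", "))
    lapply(r[need], as.character)
}

.captureAll <- function(text, patterns) {
    out <- character(0)
    for (p in patterns) {
        m <- regmatches(text, regexec(p, text, ignore.case = TRUE))[[1L]]
        if (length(m) >= 2L) out <- c(out, trimws(m[2L]))
    }
    unique(out[nzchar(out)])
}

#' Extract host names from the metadata of one hit
#'
#' Field priority: a non-empty \code{host} qualifier (semicolon-split)
#' wins outright; otherwise \code{isolation_source} is matched against
#' the isolation patterns; otherwise \code{title} then \code{note}
#' against the title patterns. All distinct names from the first field
#' that yields any are returned; a record whose free text never matches
#' (e.g. a phylogenetic-placement title) yields no host.
#'
#' @param metadata named list or one-row data.frame with fields
#'   \code{host}, \code{isolation_source}, \code{title}, \code{note}
#' @param rules see \code{\link{defaultHostRules}}
#' @return character vector of host names (length 0 = no host
#'   information)
#' @examples
#' extractHost(list(host = "Daphnia galeata"))
#' extractHost(list(isolation_source = "gut content of fish"))
#' extractHost(list(title = "phylogenetic placement of uncultured clone"))
#' @export
extractHost <- function(metadata, rules = defaultHostRules()) {
    g <- function(f) {
        v <- metadata[[f]]
        if (is.null(v) || is.na(v)) "" else trimws(as.character(v))
    }
    host <- g("host")
    if (nzchar(host)) {
        hosts <- trimws(strsplit(host, ";", fixed = TRUE)[[1L]])
        return(unique(hosts[nzchar(hosts)]))
    }
    iso <- g("isolation_source")
    if (nzchar(iso)) {
        hosts <- .captureAll(iso, rules$isolation_patterns)
        if (length(hosts)) return(hosts)
    }
    for (f in c("title", "note")) {
        v <- g(f)
        if (nzchar(v)) {
            hosts <- .captureAll(v, rules$title_patterns)
            if (length(hosts)) return(hosts)
        }
    }
    character(0)
}

#' Scan the ranked hits of one query for host information
#'
#' Hits are first filtered to \code{pident >= min_identity}, then
#' ranked by descending bit score (ties: ascending E-value, then
#' accession), truncated to the top \code{max_rank}, and scanned in
#' order. The first hit whose metadata yields host information decides;
#' later hits are never consulted. If none of the retained hits carries
#' host information the result is "no host".
#'
#' @param hits hit-store rows for a single query ASV
#' @param max_rank number of top hits examined (default 10)
#' @param min_identity percent-identity admission threshold (default 90)
#' @param rules host-extraction rules
#' @return list with \code{hosts} (character, possibly empty),
#'   \code{rank} and \code{accession} (\code{NA} when no host found)
#' @export
iterateHits <- function(hits, max_rank = 10L, min_identity = 90,
                        rules = defaultHostRules()) {
    nohost <- list(hosts = character(0), rank = NA_integer_,
                   accession = NA_character_)
    if (is.null(hits) || nrow(hits) == 0L) return(nohost)
    if (length(unique(hits$qseqid)) > 1L)
        stop("iterateHits expects hits of a single query")
    h <- hits[hits$pident >= min_identity, , drop = FALSE]
    if (!nrow(h)) return(nohost)
    h <- h[order(-h$bitscore, h$evalue, h$saccver), , drop = FALSE]
    h <- utils::head(h, max_rank)
    for (i in seq_len(nrow(h))) {
        hosts <- extractHost(h[i, ], rules)
        if (length(hosts))
            return(list(hosts = hosts, rank = i, accession = h$saccver[i]))
    }
    nohost
}

#' Host-name to host-taxon-group mapping
#'
#' An ordered pattern table (first match wins, case-insensitive) that
#' buckets free-text host names into host taxon groups; unmatched names
#' fall through to \code{"other"}. The default covers the groups most
#' often reported for freshwater plankton parasites: phytoplankton,
#' zooplankton, amphibians, fish, fungi, plants, sponges, nematodes,
#' shellfish, plus the literal \code{"Various"} used when the
#' literature reports a broad host range.
#'
#' @return data.frame with columns \code{pattern}, \code{group}
#' @export
defaultHostGrouping <- function() {
    data.frame(
        pattern = c(
            "^various$",
            "diatom|alga(?:e)?|Aulacoseira|Synedra|Asterionella|Fragilaria|Yamagishiella|Melosira|phytoplankton|dinoflagellate|cryptophyte|cyanobacteri",
            "Daphnia|cladocer|copepod|rotifer|euphausiid|zooplankton|Meganyctiphanes|Eudiaptomus|crab|Cancer\\b",
            "amphibian|frog|toad|\\bRana\\b|Thoropa",
            "fish|Ctenochaetus|Perca\\b|Cyprinus|trout",
            "fungus|fungal|Entomophaga",
            "sponge|Baikalospongia|Spongilla",
            "nematode",
            "shellfish|oyster|mussel|clam",
            "plant|macrophyte|moss"),
        group = c("Various", "phytoplankton", "zooplankton", "amphibians",
                  "fish", "fungi", "sponges", "nematodes", "shellfish",
                  "plants"),
        stringsAsFactors = FALSE)
}

.groupOneHostSet <- function(hosts, grouping) {
    if (!length(hosts)) return("")
    for (i in seq_len(nrow(grouping))) {
        if (any(grepl(grouping$pattern[i], hosts, ignore.case = TRUE,
                      perl = TRUE)))
            return(grouping$group[i])
    }
    "other"
}

#' Fill host-taxon groups on a set of parasite calls
#'
#' Rows that already carry a non-empty \code{host_group} (e.g. from a
#' registry entry) are left alone; for the rest the recorded host names
#' are matched against the grouping patterns, first match wins,
#' no match = \code{"other"}.
#'
#' @param calls a \code{ParasiteCalls} object
#' @param grouping pattern table, see \code{\link{defaultHostGrouping}}
#' @return the updated \code{ParasiteCalls}
#' @export
groupHosts <- function(calls, grouping = defaultHostGrouping()) {
    an <- calls@annotations
    for (i in seq_len(nrow(an))) {
        if (nzchar(an$host_group[i]) || !nzchar(an$hosts[i])) next
        hosts <- strsplit(an$hosts[i], ";", fixed = TRUE)[[1L]]
        an$host_group[i] <- .groupOneHostSet(trimws(hosts), grouping)
    }
    initialize(calls, annotations = an)
}

.isBinomial <- function(species) {
    !is.na(species) &
        lengths(strsplit(trimws(species), "[ _]+")) >= 2L
}

.lookupRegistry <- function(species, registry) {
    if (is.null(registry) || !nrow(registry)) return(NULL)
    i <- which(tolower(registry$species) == tolower(trimws(species)) &
                   registry$is_parasite)
    if (!length(i)) NULL else registry[i[1L], , drop = FALSE]
}

#' Classify one species-level ASV
#'
#' The species route combines two independent evidence sources: a
#' literature registry entry for the binomial marking the species as
#' parasitic, and host information recovered from the metadata of the
#' ASV's own ranked hits (\code{\link{iterateHits}}). Provenance is
#' \code{both} when both sources yield evidence, \code{literature} or
#' \code{ncbi} when only one does, and the ASV is non-parasitic when
#' neither does.
#'
#' @param asv_id identifier
#' @param species species binomial from the taxonomy
#' @param registry literature registry data.frame
#' @param hits hit-store rows for this ASV
#' @param max_rank,min_identity,rules see \code{\link{iterateHits}}
#' @return one-row annotation data.frame
#' @export
classifySpeciesLevel <- function(asv_id, species, registry, hits,
                                 max_rank = 10L, min_identity = 90,
                                 rules = defaultHostRules()) {
    lit <- .lookupRegistry(species, registry)
    ncbi <- iterateHits(hits, max_rank = max_rank,
                        min_identity = min_identity, rules = rules)
    has_lit <- !is.null(lit)
    has_ncbi <- length(ncbi$hosts) > 0L
    prov <- if (has_lit && has_ncbi) "both"
            else if (has_lit) "literature"
            else if (has_ncbi) "ncbi"
            else "none"
    hosts <- character(0)
    group <- ""
    if (has_lit) {
        hosts <- trimws(strsplit(lit$hosts, ";", fixed = TRUE)[[1L]])
        hosts <- hosts[nzchar(hosts)]
        group <- lit$host_group
    }
    hosts <- unique(c(hosts, ncbi$hosts))
    data.frame(
        asv_id = asv_id,
        status = if (prov == "none") "non_parasitic" else "parasitic",
        provenance = prov,
        hosts = paste(hosts, collapse = ";"),
        host_group = if (prov == "none") "" else group,
        evidence_rank = if (has_ncbi) ncbi$rank else NA_integer_,
        evidence_accession = if (has_ncbi) ncbi$accession else NA_character_,
        stringsAsFactors = FALSE)
}

#' Classify every ASV as parasitic or not
#'
#' Implements the two-route protocol. ASVs outside the preselected
#' higher taxa are excluded outright and never sent to the hit store.
#' Preselected ASVs assigned to species level take the species route
#' (\code{\link{classifySpeciesLevel}}: literature registry plus own-hit
#' metadata); ASVs assigned to genus or higher take the metadata route
#' only (\code{\link{iterateHits}} over the top hits). An ASV with no
#' registry match and no hits is non-parasitic (absence of evidence).
#' The result is deterministic: hit-store row order never matters
#' because ranking is a total order.
#'
#' @param x an \code{AsvExperiment} or a validated taxonomy data.frame
#' @param registry literature registry (data.frame or path); may be
#'   \code{NULL}
#' @param hits hit store (data.frame or path); may be \code{NULL}
#' @param preselection see \code{\link{preselectionList}}
#' @param rules host-extraction rules
#' @param grouping host-group pattern table
#' @param max_rank top hits examined per ASV (default 10)
#' @param min_identity percent-identity threshold (default 90)
#' @return a \code{\linkS4class{ParasiteCalls}} object
#' @export
classifyParasites <- function(x, registry = NULL, hits = NULL,
                              preselection = defaultPreselection(),
                              rules = defaultHostRules(),
                              grouping = defaultHostGrouping(),
                              max_rank = 10L, min_identity = 90) {
    taxonomy <- if (is(x, "AsvExperiment")) taxonomyTable(x)
                else validateTaxonomy(x)
    if (is.character(registry)) registry <- readLiteratureRegistry(registry)
    if (is.character(hits)) hits <- readHitStore(hits)
    hit_split <- if (!is.null(hits) && nrow(hits))
        split(hits, hits$qseqid) else list()
    pre <- preselect(taxonomy, preselection)
    rows <- vector("list", nrow(taxonomy))
    for (i in seq_len(nrow(taxonomy))) {
        id <- taxonomy$asv_id[i]
        if (!pre[i]) {
            rows[[i]] <- data.frame(
                asv_id = id, status = "excluded_by_preselection",
                provenance = "none", hosts = "", host_group = "",
                evidence_rank = NA_integer_,
                evidence_accession = NA_character_,
                stringsAsFactors = FALSE)
            next
        }
        sp <- taxonomy$species[i]
        species_route <- !is.na(sp) && nzchar(trimws(sp))
        if (species_route && !.isBinomial(sp)) {
            warning("malformed binomial '", sp, "' for ", id,
                    "; using the genus-level route", call. = FALSE)
            species_route <- FALSE
        }
        asv_hits <- hit_split[[id]]
        if (species_route) {
            rows[[i]] <- classifySpeciesLevel(
                id, sp, registry, asv_hits,
                max_rank = max_rank, min_identity = min_identity,
                rules = rules)
        } else {
            res <- iterateHits(asv_hits, max_rank = max_rank,
                               min_identity = min_identity, rules = rules)
            found <- length(res$hosts) > 0L
            rows[[i]] <- data.frame(
                asv_id = id,
                status = if (found) "parasitic" else "non_parasitic",
                provenance = if (found) "ncbi" else "none",
                hosts = paste(res$hosts, collapse = ";"),
                host_group = "",
                evidence_rank = if (found) res$rank else NA_integer_,
                evidence_accession = if (found) res$accession
                                     else NA_character_,
                stringsAsFactors = FALSE)
        }
    }
    an <- do.call(rbind, rows)
    calls <- new("ParasiteCalls",
                 annotations = S4Vectors::DataFrame(an),
                 params = list(max_rank = max_rank,
                               min_identity = min_identity,
                               preselection = preselection))
    groupHosts(calls, grouping)
}

#' Tally parasite-call provenance
#'
#' Counts parasite calls by evidence provenance. The categories
#' literature / ncbi / both partition the parasitic set, so their sum is
#' the total number of parasitic ASVs; the percentage is parasitic ASVs
#' over all ASVs, reported to one decimal.
#'
#' @param x a \code{ParasiteCalls} object or an annotation data.frame
#'   with columns \code{status} and \code{provenance}
#' @return list with counts \code{literature}, \code{ncbi}, \code{both},
#'   \code{parasitic}, \code{non_parasitic}, \code{excluded},
#'   \code{n_asvs} and \code{percent}
#' @name tallyProvenance
NULL

.tallyAnnotations <- function(an) {
    prov <- an$provenance[an$status == "parasitic"]
    lit <- sum(prov == "literature")
    ncbi <- sum(prov == "ncbi")
    both <- sum(prov == "both")
    n <- nrow(an)
    list(literature = lit, ncbi = ncbi, both = both,
         parasitic = lit + ncbi + both,
         non_parasitic = sum(an$status == "non_parasitic"),
         excluded = sum(an$status == "excluded_by_preselection"),
         n_asvs = n,
         percent = if (n) round(100 * (lit + ncbi + both) / n, 1) else NA_real_)
}

#' @rdname tallyProvenance
#' @export
setMethod("tallyProvenance", "ParasiteCalls", function(x)
    .tallyAnnotations(as.data.frame(x@annotations)))

#' @rdname tallyProvenance
#' @export
setMethod("tallyProvenance", "data.frame", function(x)
    .tallyAnnotations(x))

#' Write parasite annotations to TSV
#'
#' @param calls a \code{ParasiteCalls}
#' @param path output path
#' @export
writeAnnotations <- function(calls, path)
    writeTsv(annotationTable(calls), path)
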