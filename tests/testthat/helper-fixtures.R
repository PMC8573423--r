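## Shared fixtures and independent oracles for the test suite.

toyExperiment <- function(counts = NULL, dates = NULL, taxonomy = NULL,
                          is_control = NULL) {
    if (is.null(counts)) {
        counts <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
                         dimnames = list(c("S1", "S2"), c("ASV1", "ASV2")))
    }
    if (is.null(dates))
        dates <- rep("2015-06-15", nrow(counts))
    AsvExperiment(counts, taxonomy = taxonomy, dates = dates,
                  is_control = is_control)
}

toyTaxonomy <- function(asv_ids, division = "Chytridiomycota",
                        species = NA_character_) {
    n <- length(asv_ids)
    data.frame(asv_id = asv_ids, kingdom = "Eukaryota",
               supergroup = "Opisthokonta",
               division = rep_len(division, n),
               class = "cl", order = "or", family = "fa",
               genus = paste0("G", seq_len(n)),
               species = rep_len(species, n),
               stringsAsFactors = FALSE)
}

makeHit <- function(qseqid, saccver, bitscore, pident = 95,
                    evalue = 1e-80, host = "", isolation_source = "",
                    title = "", note = "", organism = "") {
    data.frame(qseqid = qseqid, saccver = saccver, pident = pident,
               evalue = evalue, bitscore = bitscore, host = host,
               isolation_source = isolation_source, title = title,
               note = note, organism = organism,
               stringsAsFactors = FALSE)
}

## independent evaluation of the multi-site partition sums, written as
## a direct transcription of the summation formulas
naiveBaselgaMulti <- function(sets) {
    n <- length(sets)
    smin <- 0; smax <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j) {
            bij <- sum(!(sets[[i]] %in% sets[[j]]))
            bji <- sum(!(sets[[j]] %in% sets[[i]]))
            smin <- smin + min(bij, bji)
            smax <- smax + max(bij, bji)
        }
    }
    St <- length(unique(unlist(sets)))
    K <- sum(sapply(sets, length)) - St
    sim <- if (K + smin == 0) 0 else smin / (K + smin)
    sor <- if (2 * K + smin + smax == 0) 0 else
        (smin + smax) / (2 * K + smin + smax)
    c(sor = sor, sim = sim, nes = sor - sim)
}

## one-way pseudo-F via the direct within/total group-sum formula
## (independent of the Gower-projection implementation)
oneWayPseudoF <- function(d, g) {
    n <- nrow(d)
    sst <- sum(d[lower.tri(d)]^2) / n
    ssw <- 0
    for (lv in unique(g)) {
        i <- which(g == lv)
        sub <- d[i, i, drop = FALSE]
        ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(i)
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

allPermutationsList <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (s in allPermutationsList(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], s)
    out
}

## does `lev` carry a compact letter shared with no other level?
hasDistinctLetter <- function(letters_vec, lev) {
    own <- strsplit(letters_vec[[lev]], "")[[1]]
    others <- paste(letters_vec[setdiff(names(letters_vec), lev)],
                    collapse = "")
    length(own) > 0 && !any(vapply(own, grepl, logical(1), x = others))
}

## classification performance against generator truth
classifierScores <- function(sim, calls) {
    tr <- sim$truth
    an <- annotationTable(calls)
    an <- an[match(tr$asv_id, an$asv_id), ]
    pred <- an$status == "parasitic"
    list(recall = mean(pred[tr$is_parasite]),
         precision = if (any(pred)) mean(tr$is_parasite[pred]) else NA,
         route_match = mean(an$provenance[tr$is_parasite] ==
                                tr$route[tr$is_parasite]))
}
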