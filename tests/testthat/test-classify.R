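test_that("host extraction respects field priority and keyword rules", {
    expect_equal(extractHost(list(host = "Daphnia galeata")),
                 "Daphnia galeata")
    expect_equal(extractHost(list(isolation_source = "gut content of fish")),
                 "fish")
    expect_length(
        extractHost(list(title = "phylogenetic placement of uncultured clone")),
        0)
    ## host qualifier wins over isolation_source
    expect_equal(
        extractHost(list(host = "Synedra acus",
                         isolation_source = "gut content of fish")),
        "Synedra acus")
    ## several hosts in one qualifier
    expect_setequal(
        extractHost(list(host = "Daphnia galeata; Daphnia pulex")),
        c("Daphnia galeata", "Daphnia pulex"))
    expect_equal(
        extractHost(list(title = "Parasite of Aulacoseira granulata strain X")),
        "Aulacoseira granulata")
})

test_that("hit iteration scans ranked hits and stops at the first host", {
    hits <- do.call(rbind, lapply(1:10, function(i)
        makeHit("Q", sprintf("ACC%02d", i), bitscore = 500 - 5 * i,
                host = if (i %in% c(3, 7)) "Daphnia galeata" else "")))
    res <- iterateHits(hits)
    expect_equal(res$rank, 3L)
    expect_equal(res$accession, "ACC03")
    expect_equal(res$hosts, "Daphnia galeata")

    ## no host anywhere: no-host result, not an error
    blank <- do.call(rbind, lapply(1:10, function(i)
        makeHit("Q", sprintf("ACC%02d", i), bitscore = 500 - 5 * i)))
    expect_length(iterateHits(blank)$hosts, 0)
    expect_length(iterateHits(blank[0, ])$hosts, 0)
})

test_that("hits beyond the top 10 are never consulted", {
    hits <- do.call(rbind, lapply(1:12, function(i)
        makeHit("Q", sprintf("ACC%02d", i), bitscore = 500 - 5 * i,
                host = if (i == 11) "Daphnia galeata" else "")))
    expect_length(iterateHits(hits)$hosts, 0)
    ## the same host inside the window is found
    expect_equal(iterateHits(hits, max_rank = 11L)$rank, 11L)
})

test_that("identity threshold is applied before ranking", {
    ## a high-scoring sub-threshold hit with a host must be ignored
    hits <- rbind(
        makeHit("Q", "LOWID", bitscore = 900, pident = 85,
                host = "Daphnia galeata"),
        makeHit("Q", "GOOD1", bitscore = 500, pident = 97),
        makeHit("Q", "GOOD2", bitscore = 495, pident = 96,
                host = "Synedra acus"))
    res <- iterateHits(hits)
    expect_equal(res$hosts, "Synedra acus")
    expect_equal(res$rank, 2L)
    ## raising the threshold can only lose the host
    expect_length(iterateHits(hits, min_identity = 98)$hosts, 0)
})

test_that("hit-store row order never changes the outcome", {
    set.seed(71)
    hits <- do.call(rbind, lapply(1:10, function(i)
        makeHit("Q", sprintf("ACC%02d", i), bitscore = 500 - 5 * i,
                pident = runif(1, 90, 99),
                host = if (i %in% c(4, 9)) "Daphnia galeata" else "")))
    ref <- iterateHits(hits)
    for (r in 1:20) {
        perm <- hits[sample.int(nrow(hits)), ]
        expect_identical(iterateHits(perm), ref)
    }
    ## bit-score ties broken by E-value then accession
    tied <- rbind(makeHit("Q", "BBB", bitscore = 500, evalue = 1e-70),
                  makeHit("Q", "AAA", bitscore = 500, evalue = 1e-70,
                          host = "Daphnia galeata"),
                  makeHit("Q", "CCC", bitscore = 500, evalue = 1e-90))
    expect_equal(iterateHits(tied)$rank, 2L)  # CCC (better E), then AAA
})

test_that("species route combines literature and metadata provenance", {
    reg <- data.frame(species = "Zygophlyctis planktonica",
                      hosts = "Synedra acus", host_group = "phytoplankton",
                      is_parasite = TRUE, citation = "x",
                      stringsAsFactors = FALSE)
    hostHit <- makeHit("Q", "ACC01", bitscore = 500,
                       host = "Synedra acus")
    blank <- makeHit("Q", "ACC02", bitscore = 490)

    lit <- classifySpeciesLevel("Q", "Zygophlyctis planktonica", reg, blank)
    expect_equal(lit$status, "parasitic")
    expect_equal(lit$provenance, "literature")
    expect_true(is.na(lit$evidence_rank))

    ncbi <- classifySpeciesLevel("Q", "Unknown species", reg, hostHit)
    expect_equal(ncbi$provenance, "ncbi")
    expect_equal(ncbi$evidence_rank, 1L)

    both <- classifySpeciesLevel("Q", "Zygophlyctis planktonica", reg,
                                 rbind(hostHit, blank))
    expect_equal(both$provenance, "both")

    none <- classifySpeciesLevel("Q", "Unknown species", reg, blank)
    expect_equal(none$status, "non_parasitic")
    expect_equal(none$hosts, "")
})

test_that("classification recovers planted truth end to end", {
    sim <- simulateParasiteDataset(simulationConfig(seed = 17))
    calls <- classifyParasites(sim$experiment, registry = sim$registry,
                               hits = sim$hits)
    sc <- classifierScores(sim, calls)
    expect_equal(sc$recall, 1.0)
    expect_equal(sc$precision, 1.0)
    expect_equal(sc$route_match, 1.0)

    ## annotation categories partition the ASV set
    tl <- tallyProvenance(calls)
    expect_equal(tl$parasitic + tl$non_parasitic + tl$excluded, tl$n_asvs)
    expect_equal(tl$literature + tl$ncbi + tl$both, tl$parasitic)

    ## ASVs outside the preselection are excluded and never classified
    an <- annotationTable(calls)
    tax <- taxonomyTable(sim$experiment)
    outside <- !preselect(tax)
    expect_true(all(an$status[match(tax$asv_id[outside], an$asv_id)] ==
                        "excluded_by_preselection"))
})

test_that("all ASVs outside the preselection list are excluded", {
    tax <- toyTaxonomy(c("A1", "A2"), division = "Bacillariophyta")
    calls <- classifyParasites(tax, registry = NULL, hits = NULL)
    expect_true(all(annotationTable(calls)$status ==
                        "excluded_by_preselection"))
})

test_that("classifier is monotone in max_rank and min_identity", {
    sim <- simulateParasiteDataset(simulationConfig(seed = 23))
    nParasitic <- function(max_rank = 10L, min_identity = 90) {
        calls <- classifyParasites(sim$experiment, sim$registry, sim$hits,
                                   max_rank = max_rank,
                                   min_identity = min_identity)
        tallyProvenance(calls)
    }
    base <- nParasitic()
    for (mr in c(5L, 2L, 1L)) {
        tl <- nParasitic(max_rank = mr)
        expect_lte(tl$ncbi + tl$both, base$ncbi + base$both)
        ## literature calls are untouched by the hit window
        expect_equal(tl$literature + tl$both, base$literature + base$both)
    }
    prev <- base$ncbi
    for (mi in c(94, 97, 99.9)) {
        tl <- nParasitic(min_identity = mi)
        expect_lte(tl$ncbi, prev)
        prev <- tl$ncbi
    }
})

test_that("metadata-route recall is non-increasing in completeness", {
    recalls <- vapply(c(1, 0.7, 0.4, 0), function(cm) {
        sim <- simulateParasiteDataset(
            simulationConfig(seed = 29, completeness = cm))
        calls <- classifyParasites(sim$experiment, sim$registry, sim$hits)
        tr <- sim$truth
        an <- annotationTable(calls)
        an <- an[match(tr$asv_id, an$asv_id), ]
        idx <- tr$is_parasite & tr$route == "ncbi"
        mean(an$status[idx] == "parasitic")
    }, numeric(1))
    expect_true(all(diff(recalls) <= 0))
    expect_equal(recalls[1], 1.0)
    expect_equal(recalls[4], 0.0)
})

test_that("provenance tally reproduces the arithmetic identities", {
    an <- data.frame(
        status = c(rep("parasitic", 6), "non_parasitic",
                   "excluded_by_preselection"),
        provenance = c(rep("literature", 2), rep("ncbi", 3), "both",
                       "none", "none"))
    tl <- tallyProvenance(an)
    expect_equal(tl$parasitic, 6L)
    expect_equal(tl$percent, 75.0)

    empty <- data.frame(status = character(0), provenance = character(0))
    tl0 <- tallyProvenance(empty)
    expect_equal(unlist(tl0[c("literature", "ncbi", "both", "parasitic")]),
                 c(literature = 0L, ncbi = 0L, both = 0L, parasitic = 0L))
})

test_that("host names map to host taxon groups, first match wins", {
    g <- defaultHostGrouping()
    expect_equal(paraplank:::.groupOneHostSet("Aulacoseira granulata", g),
                 "phytoplankton")
    expect_equal(paraplank:::.groupOneHostSet("Daphnia galeata", g), "zooplankton")
    expect_equal(paraplank:::.groupOneHostSet("Various", g), "Various")
    expect_equal(paraplank:::.groupOneHostSet("cryptid beast", g), "other")
})
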