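test_that("singleton removal keeps ASVs present in >= 2 samples", {
    cnt <- matrix(c(5L, 0L, 0L, 0L,   # present in 1 sample -> dropped
                    1L, 2L, 0L, 0L,   # present in 2 -> kept
                    0L, 0L, 0L, 0L,   # absent -> dropped
                    1L, 1L, 1L, 4L,   # kept
                    0L, 7L, 0L, 0L),  # singleton -> dropped
                  nrow = 4, ncol = 5,
                  dimnames = list(paste0("S", 1:4), paste0("A", 1:5)))
    x <- toyExperiment(cnt, dates = rep("2015-06-15", 4))
    filt <- dropSingletons(x)
    expect_setequal(rownames(filt), c("A2", "A4"))
    ## idempotent
    expect_identical(asvCounts(dropSingletons(filt)), asvCounts(filt))
})

test_that("relative abundance normalizes by the whole-sample total", {
    cnt <- matrix(c(50L, 3L, 0L, 1L), 2, 2,
                  dimnames = list(c("S1", "S2"), c("A1", "A2")))
    x <- relativeAbundance(toyExperiment(cnt, dates = rep("2015-06-15", 2)))
    rel <- SummarizedExperiment::assay(x, "relabund")
    expect_equal(rel[, "S1"], c(A1 = 1.0, A2 = 0.0))
    expect_equal(rel[, "S2"], c(A1 = 0.75, A2 = 0.25))
    expect_equal(unname(colSums(rel)), c(1, 1))

    zero <- matrix(c(1L, 0L, 2L, 0L), 2, 2,
                   dimnames = list(c("S1", "S2"), c("A1", "A2")))
    expect_warning(relativeAbundance(
        toyExperiment(zero, dates = rep("2015-06-15", 2))),
        "zero total")
})

test_that("sample summaries add parasite proportions and richness", {
    cnt <- matrix(c(10L, 25L, 60L, 5L), 1, 4,
                  dimnames = list("S1", paste0("A", 1:4)))
    tax <- toyTaxonomy(paste0("A", 1:4))
    x <- toyExperiment(cnt, dates = "2015-06-15", taxonomy = tax)
    an <- data.frame(
        asv_id = paste0("A", 1:4),
        status = c("parasitic", "parasitic", "non_parasitic",
                   "non_parasitic"),
        provenance = c("ncbi", "literature", "none", "none"),
        hosts = c("Daphnia galeata", "Synedra acus", "", ""),
        host_group = c("zooplankton", "phytoplankton", "", ""),
        evidence_rank = c(1L, NA, NA, NA),
        evidence_accession = c("X", NA, NA, NA))
    calls <- new("ParasiteCalls", annotations = S4Vectors::DataFrame(an),
                 params = list())
    sm <- sampleSummaries(x, calls)
    expect_equal(sm$rel_abundance, 0.35)   # 0.10 + 0.25
    expect_equal(sm$richness, 2L)

    ## no parasites at all
    an$status <- "non_parasitic"; an$provenance <- "none"
    an$hosts <- ""; an$evidence_rank <- NA_integer_
    an$evidence_accession <- NA_character_
    calls0 <- new("ParasiteCalls", annotations = S4Vectors::DataFrame(an),
                  params = list())
    sm0 <- sampleSummaries(x, calls0)
    expect_equal(sm0$rel_abundance, 0)
    expect_equal(sm0$richness, 0L)
})

test_that("per-group metrics partition the totals", {
    sim <- simulateParasiteDataset(simulationConfig(seed = 31))
    calls <- classifyParasites(sim$experiment, sim$registry, sim$hits)
    x <- relativeAbundance(dropSingletons(sim$experiment))
    sm <- sampleSummaries(x, calls, by_group = TRUE)
    tot <- sm[sm$group == "all", ]
    per <- sm[sm$group != "all", ]
    agg_rich <- tapply(per$richness, per$sample_id, sum)
    agg_ra <- tapply(per$rel_abundance, per$sample_id, sum)
    ## every parasitic ASV belongs to exactly one division
    expect_equal(as.vector(agg_rich[tot$sample_id]), tot$richness)
    expect_equal(as.vector(agg_ra[tot$sample_id]), tot$rel_abundance,
                 tolerance = 1e-12)
})

test_that("control screen reports contents and parasitic violations", {
    sim <- simulateParasiteDataset(simulationConfig(seed = 37))
    calls <- classifyParasites(sim$experiment, sim$registry, sim$hits)
    cs <- controlScreen(sim$experiment, calls)
    ctrl_cnt <- asvCounts(sim$experiment)[, isControl(sim$experiment)]
    expect_equal(cs$n_reads, sum(ctrl_cnt))
    expect_equal(cs$n_asvs, sum(rowSums(ctrl_cnt) > 0))
    ## generator controls carry only non-parasitic ASVs
    expect_length(cs$parasitic_asvs, 0)

    ## plant one parasitic ASV into a control: it must be flagged
    cnt <- asvCounts(sim$experiment, samplesAsRows = TRUE)
    para1 <- sim$truth$asv_id[sim$truth$is_parasite][1]
    ctrl_row <- which(isControl(sim$experiment))[1]
    cnt[ctrl_row, para1] <- 9L
    x2 <- AsvExperiment(cnt, taxonomy = taxonomyTable(sim$experiment),
                        dates = SummarizedExperiment::colData(sim$experiment)$date,
                        is_control = isControl(sim$experiment))
    cs2 <- controlScreen(x2, calls)
    expect_true(para1 %in% cs2$parasitic_asvs)

    ## empty controls
    x3 <- sim$experiment[, !isControl(sim$experiment)]
    cs3 <- controlScreen(x3, calls)
    expect_equal(cs3$n_reads, 0L)
    expect_equal(cs3$n_asvs, 0L)
})
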