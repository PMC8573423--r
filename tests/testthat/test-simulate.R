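test_that("generation is byte-identical under a fixed seed", {
    cfg <- simulationConfig(seed = 81, n_parasite_asvs = 10,
                            n_nonparasite_asvs = 20)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    p1 <- writeSyntheticData(simulateParasiteDataset(cfg), d1)
    p2 <- writeSyntheticData(simulateParasiteDataset(cfg), d2)
    for (k in names(p1))
        expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                         label = k)
})

test_that("emitted files pass every reader/validator round trip", {
    sim <- simulateParasiteDataset(simulationConfig(
        seed = 82, n_parasite_asvs = 8, n_nonparasite_asvs = 15))
    dir <- withr::local_tempdir()
    p <- writeSyntheticData(sim, dir)
    x <- readAsvExperiment(p[["counts"]], p[["taxonomy"]],
                           p[["metadata"]])
    expect_s4_class(x, "AsvExperiment")
    expect_identical(asvCounts(x), asvCounts(sim$experiment))
    expect_identical(as.character(seasons(x)),
                     as.character(seasons(sim$experiment)))
    hits <- readHitStore(p[["hits"]])
    expect_true(all(hits$pident >= 0 & hits$pident <= 100))
    reg <- readLiteratureRegistry(p[["registry"]])
    expect_true(all(nzchar(reg$species)))
})

test_that("sampling calendar spans the years weekly", {
    sim <- simulateParasiteDataset(simulationConfig(seed = 83))
    cd <- SummarizedExperiment::colData(sim$experiment)
    real <- cd[!cd$is_control, ]
    expect_setequal(unique(real$year), c(2015L, 2016L))
    expect_equal(nlevels(droplevels(real$season)), 4L)
    ## weekly spacing
    gaps <- diff(sort(unique(real$date)))
    expect_true(all(as.integer(gaps) == 7L))
    ## roughly 52 samples a year
    expect_true(all(table(real$year) >= 52))
})

test_that("negative-binomial means respect the seasonal multipliers", {
    ## many years of draws pool enough samples for a mean check
    sim <- simulateParasiteDataset(simulationConfig(
        seed = 84, n_years = 10, n_parasite_asvs = 10,
        n_nonparasite_asvs = 10, n_controls = 0))
    tr <- sim$truth
    cnt <- asvCounts(sim$experiment)
    sea <- as.character(seasons(sim$experiment))
    dino <- tr$asv_id[tr$group == "Dinoflagellata" & tr$is_parasite]
    skip_if(length(dino) == 0)
    for (id in dino[1:min(3, length(dino))]) {
        mu0 <- tr$base_mean[tr$asv_id == id]
        wint <- cnt[id, sea == "winter"]
        summ <- cnt[id, sea == "summer"]
        ## t-test against the configured means
        expect_gt(stats::t.test(wint, mu = mu0)$p.value, 1e-4)
        expect_gt(stats::t.test(summ, mu = 5 * mu0)$p.value, 1e-4)
    }
})

test_that("planting beyond rank 10 defeats the metadata route", {
    cfg <- simulationConfig(seed = 85,
                            rank_law = c(rep(0, 10), 1))  # rank 11 only
    sim <- simulateParasiteDataset(cfg)
    calls <- classifyParasites(sim$experiment, sim$registry, sim$hits)
    tr <- sim$truth
    an <- annotationTable(calls)
    an <- an[match(tr$asv_id, an$asv_id), ]
    idx <- tr$is_parasite & tr$route == "ncbi"
    expect_equal(mean(an$status[idx] == "parasitic"), 0)
    ## literature-route ASVs are unaffected by hit-rank planting
    lit <- tr$is_parasite & tr$route == "literature"
    expect_equal(mean(an$status[lit] == "parasitic"), 1)
})

test_that("partial completeness yields binomial-rate recall", {
    cfg <- simulationConfig(seed = 86, n_parasite_asvs = 120,
                            n_nonparasite_asvs = 60, completeness = 0.5,
                            route_probs = c(literature = 0, ncbi = 1,
                                            both = 0))
    sim <- simulateParasiteDataset(cfg)
    calls <- classifyParasites(sim$experiment, sim$registry, sim$hits)
    tr <- sim$truth
    an <- annotationTable(calls)
    an <- an[match(tr$asv_id, an$asv_id), ]
    idx <- tr$is_parasite & tr$route == "ncbi"
    rec <- mean(an$status[idx] == "parasitic")
    ## binomial(n, 0.5): stay within 4 standard errors
    n <- sum(idx)
    expect_lt(abs(rec - 0.5), 4 * sqrt(0.25 / n))
})

test_that("turnover and nestedness scenarios shape the beta partition", {
    simT <- simulateParasiteDataset(simulationConfig(
        seed = 87, scenario = "turnover"))
    cntT <- asvCounts(simT$experiment)[
        simT$truth$asv_id[simT$truth$is_parasite],
        !isControl(simT$experiment)]
    setsT <- lapply(seq_len(ncol(cntT)), function(j) which(cntT[, j] >= 1))
    bpT <- baselgaMulti(setsT[seq(1, 100, by = 4)])
    expect_gt(betaSim(bpT) / betaSor(bpT), 0.9)  # replacement dominates
    expect_lt(betaNes(bpT), 0.1)

    simN <- simulateParasiteDataset(simulationConfig(
        seed = 87, scenario = "nestedness"))
    cntN <- asvCounts(simN$experiment)[
        simN$truth$asv_id[simN$truth$is_parasite],
        !isControl(simN$experiment)]
    setsN <- lapply(seq_len(ncol(cntN)), function(j) which(cntN[, j] >= 1))
    bpN <- baselgaMulti(setsN[seq(1, 100, by = 4)])
    expect_equal(betaSim(bpN), 0)               # pure nestedness
    expect_gt(betaNes(bpN), 0.3)
})
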