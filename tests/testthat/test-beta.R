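test_that("Bray-Curtis evaluates its formula and bounds", {
    expect_equal(brayCurtis(c(2, 2), c(1, 3)), 0.25)
    expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(brayCurtis(c(1, 0), c(0, 4)), 1)
    expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
    ## cross-check against vegan on random compositions
    skip_if_not_installed("vegan")
    set.seed(21)
    m <- matrix(abs(rnorm(8 * 6)), 8, 6,
                dimnames = list(paste0("s", 1:8), paste0("a", 1:6)))
    expect_equal(max(abs(brayCurtisMatrix(m) -
                             as.matrix(vegan::vegdist(m)))), 0,
                 tolerance = 1e-12)
})

test_that("pairwise partition matches hand-computed components", {
    bp <- baselgaPair(c(1, 2, 3), c(2, 3, 4))
    expect_equal(bp@components, c(a = 2, b = 1, c = 1))
    expect_equal(betaSim(bp), 1 / 3)
    expect_equal(betaSor(bp), 1 / 3)
    expect_equal(betaNes(bp), 0)

    nested <- baselgaPair(c(1, 2, 3), c(1, 2))
    expect_equal(betaSim(nested), 0)
    expect_equal(betaSor(nested), 0.2)
    expect_equal(betaNes(nested), 0.2)

    same <- baselgaPair(c("x", "y"), c("y", "x"))
    expect_equal(c(betaSor(same), betaSim(same), betaNes(same)),
                 c(0, 0, 0))
    expect_error(baselgaPair(integer(0), integer(0)), "empty")
})

test_that("multi-site partition matches a direct-summation oracle", {
    set.seed(33)
    for (r in 1:30) {
        sets <- lapply(1:sample(3:6, 1), function(i)
            sample(1:20, sample(2:10, 1)))
        bp <- baselgaMulti(sets)
        oracle <- naiveBaselgaMulti(sets)
        expect_equal(betaSor(bp), unname(oracle["sor"]), tolerance = 1e-12)
        expect_equal(betaSim(bp), unname(oracle["sim"]), tolerance = 1e-12)
        expect_equal(betaNes(bp), unname(oracle["nes"]), tolerance = 1e-12)
    }
})

test_that("two-set multi-site partition reduces to the pairwise one", {
    set.seed(34)
    for (r in 1:20) {
        p <- sample(1:15, sample(1:8, 1))
        q <- sample(1:15, sample(1:8, 1))
        multi <- baselgaMulti(list(p, q))
        pair <- baselgaPair(p, q)
        expect_equal(betaSor(multi), betaSor(pair), tolerance = 1e-12)
        expect_equal(betaSim(multi), betaSim(pair), tolerance = 1e-12)
    }
    ## identical replicated sets give zero dissimilarity for any k
    for (k in c(2, 3, 5, 8)) {
        bp <- baselgaMulti(rep(list(c(1, 4, 9)), k))
        expect_equal(betaSor(bp), 0)
    }
})

test_that("beta identities hold over random incidence data", {
    set.seed(35)
    for (r in 1:200) {
        p <- sample(1:25, sample(1:12, 1))
        q <- sample(1:25, sample(1:12, 1))
        bp <- baselgaPair(p, q)
        v <- c(betaSor(bp), betaSim(bp), betaNes(bp))
        expect_true(all(v >= 0 & v <= 1))
        expect_equal(v[3], v[1] - v[2], tolerance = 1e-12)
        expect_gte(v[1], v[2])
    }
})

test_that("per-year resampling is seeded and degenerates correctly", {
    sim <- simulateParasiteDataset(simulationConfig(seed = 41))
    x <- sim$experiment[sim$truth$asv_id[sim$truth$is_parasite], ]
    r1 <- resampledBeta(x, k = 10, reps = 5, seed = 99)
    r2 <- resampledBeta(x, k = 10, reps = 5, seed = 99)
    expect_identical(r1$draws, r2$draws)

    ## k = full year size leaves no sampling freedom
    one_year <- x[, !isControl(x) & sampleYears(x) == 2015]
    rf <- resampledBeta(one_year, k = ncol(one_year), reps = 4, seed = 1)
    expect_equal(unname(rf$summary$sd_sor), rep(0, nrow(rf$summary)))

    expect_error(resampledBeta(x, k = 10000, reps = 2, seed = 1),
                 "fewer than k")
})
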