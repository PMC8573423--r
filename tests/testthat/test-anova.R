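test_that("sequential SS match the nested-regression oracle on random toys", {
    set.seed(101)
    for (r in 1:50) {
        n <- sample(10:30, 1)
        se <- factor(sample(c("sp", "su", "au", "wi"), n, TRUE))
        yr <- factor(sample(c("y1", "y2", "y3"), n, TRUE))
        if (nlevels(droplevels(se)) < 2 || nlevels(droplevels(yr)) < 2) next
        if (any(table(se, yr) == 0)) next
        y <- rnorm(n)
        fit <- twoWayAnova(y, se, yr)
        ## oracle: R's own sequential decomposition via aov
        oracle <- summary(aov(y ~ se * yr))[[1]][["Sum Sq"]]
        expect_equal(fit$table$sumsq, oracle, tolerance = 1e-8)
    }
})

test_that("exact additivity gives zero interaction SS", {
    d <- expand.grid(season = c("sp", "su"), year = c("y1", "y2"),
                     rep = 1:3)
    y <- 2 * (d$season == "su") + 3 * (d$year == "y2")
    ## add a within-cell perturbation that preserves cell means
    y <- y + rep(c(-1, 0, 1), each = 4) * 0.5
    fit <- twoWayAnova(y, d$season, d$year)
    expect_equal(fit$table$sumsq[fit$table$term == "season:year"], 0,
                 tolerance = 1e-12)
})

test_that("term and residual SS sum to the total SS", {
    set.seed(7)
    n <- 24
    se <- factor(rep(c("sp", "su", "au", "wi"), each = 6))
    yr <- factor(rep(c("y1", "y2"), 12))
    y <- rnorm(n)
    fit <- twoWayAnova(y, se, yr)
    expect_equal(sum(fit$table$sumsq), sum((y - mean(y))^2),
                 tolerance = 1e-10)
    ## row order of the data is irrelevant
    p <- sample(n)
    fit2 <- twoWayAnova(y[p], se[p], yr[p])
    expect_equal(fit$table$sumsq, fit2$table$sumsq, tolerance = 1e-10)
})

test_that("balanced designs make sequential SS order-invariant", {
    set.seed(8)
    se <- factor(rep(c("sp", "su"), each = 8))
    yr <- factor(rep(c("y1", "y2"), 8))
    y <- rnorm(16)
    a <- twoWayAnova(y, se, yr)$table
    b <- twoWayAnova(y, yr, se)$table   # swapped roles
    expect_equal(a$sumsq[a$term == "season"],
                 b$sumsq[b$term == "year"], tolerance = 1e-10)
    expect_equal(a$sumsq[a$term == "year"],
                 b$sumsq[b$term == "season"], tolerance = 1e-10)
})

test_that("degenerate inputs are rejected or downgraded", {
    expect_error(twoWayAnova(rep(1, 12),
                             rep(c("a", "b"), 6), rep(c("x", "y"), 6)),
                 "constant")
    ## an empty cell drops the interaction with a warning
    se <- c("a", "a", "a", "b", "b", "b", "a", "b")
    yr <- c("x", "x", "y", "y", "y", "y", "x", "y")  # cell (b, x) empty
    expect_warning(twoWayAnova(rnorm(8), se, yr), "interaction")
})

test_that("Tukey-Kramer p-values equal the stats::TukeyHSD oracle", {
    set.seed(11)
    ## unbalanced one-way layout
    g <- factor(sample(c("sp", "su", "au", "wi"), 37, TRUE))
    y <- rnorm(37) + 2 * (g == "su")
    mine <- tukeyHsd(y, g)
    oracle <- TukeyHSD(aov(y ~ g))$g
    key <- paste(mine$comparisons$level2, mine$comparisons$level1,
                 sep = "-")
    key2 <- paste(mine$comparisons$level1, mine$comparisons$level2,
                  sep = "-")
    idx <- ifelse(key %in% rownames(oracle), key, key2)
    expect_equal(mine$comparisons$p_adj, unname(oracle[idx, "p adj"]),
                 tolerance = 1e-10)
})

test_that("letters join identical groups and separate distant ones", {
    ## two groups with identical values: zero difference, p = 1
    y1 <- rep(c(1, 2, 3, 4, 5), 2)
    g1 <- factor(rep(c("a", "b"), each = 5))
    t1 <- tukeyHsd(y1, g1)
    expect_equal(t1$comparisons$diff, 0)
    expect_equal(t1$comparisons$p_adj, 1)
    expect_equal(unname(t1$letters["a"]), unname(t1$letters["b"]))

    ## separation of 10 sigma with n = 20 per group
    y2 <- c(rnorm(20, 0), rnorm(20, 10))
    g2 <- factor(rep(c("lo", "hi"), each = 20))
    t2 <- tukeyHsd(y2, g2)
    expect_lt(t2$comparisons$p_adj, 0.05)
    expect_false(t2$letters["lo"] == t2$letters["hi"])
})

test_that("a summer-elevated season earns its own letter", {
    set.seed(13)
    g <- factor(rep(c("spring", "summer", "autumn", "winter"), each = 15),
                levels = c("spring", "summer", "autumn", "winter"))
    y <- rnorm(60) + 6 * (g == "summer")
    tk <- tukeyHsd(y, g)
    expect_true(hasDistinctLetter(tk$letters, "summer"))
    ## the three background seasons share a letter
    bg <- tk$letters[c("spring", "autumn", "winter")]
    shared <- Reduce(intersect, strsplit(unname(bg), ""))
    expect_gt(length(shared), 0)
})

test_that("season-term type-I error is calibrated under the null", {
    set.seed(1009)
    rej <- 0L
    n_rep <- 400L
    d <- expand.grid(se = c("sp", "su", "au", "wi"),
                     yr = c("y1", "y2"), rep = 1:5)
    for (r in seq_len(n_rep)) {
        y <- rnorm(nrow(d))
        fit <- twoWayAnova(y, d$se, d$yr)
        rej <- rej + (fit$table$p.value[1] < 0.05)
    }
    expect_gt(rej / n_rep, 0.025)
    expect_lt(rej / n_rep, 0.075)
})
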