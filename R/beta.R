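#' Bray-Curtis dissimilarity
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' [0, 1] for non-negative vectors; undefined (error) when both vectors
#' are all-zero.
#'
#' @param x,y non-negative abundance vectors of equal length
#' @return dissimilarity in [0, 1]
#' @examples
#' brayCurtis(c(2, 2), c(1, 3))  # 0.25
#' @export
brayCurtis <- function(x, y) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
    denom <- sum(x + y)
    if (denom == 0) stop("Bray-Curtis undefined for two all-zero vectors")
    sum(abs(x - y)) / denom
}

#' Bray-Curtis distance matrix over samples
#'
#' @param mat samples-by-ASVs abundance matrix (rows are compared)
#' @return \code{dist}-like symmetric matrix with sample dimnames
#' @export
brayCurtisMatrix <- function(mat) {
    n <- nrow(mat)
    d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(n - 1L)) {
        xi <- mat[i, ]
        for (j in (i + 1L):n) {
            d[i, j] <- d[j, i] <- brayCurtis(xi, mat[j, ])
        }
    }
    d
}

.newBetaPartition <- function(sor, sim, scope, components) {
    new("BetaPartition", beta_sor = unname(sor), beta_sim = unname(sim),
        beta_nes = unname(sor - sim), scope = scope,
        components = components)
}

#' Pairwise Baselga partition of Sorensen dissimilarity
#'
#' With incidence components a (shared), b and c (unique to either
#' side): \eqn{\beta_{sim} = \min(b,c) / (a + \min(b,c))},
#' \eqn{\beta_{sor} = (b+c) / (2a+b+c)}, and the nestedness-resultant
#' component is their difference. When one set is empty
#' (\eqn{a + \min(b,c) = 0}) turnover is defined as 0 and the whole
#' dissimilarity is nestedness.
#'
#' @param p,q presence sets: character/integer vectors of taxon ids, or
#'   logical/numeric incidence vectors of equal length (>= 1 means
#'   present)
#' @return a \code{\linkS4class{BetaPartition}} with pairwise scope
#' @examples
#' betaSim(baselgaPair(c(1, 2, 3), c(2, 3, 4)))  # 1/3
#' @export
baselgaPair <- function(p, q) {
    sets <- .asPresenceSets(list(p, q))
    p <- sets[[1L]]; q <- sets[[2L]]
    if (!length(p) && !length(q))
        stop("Baselga partition undefined for two empty sets")
    a <- length(intersect(p, q))
    b <- length(setdiff(p, q))
    c_ <- length(setdiff(q, p))
    m <- min(b, c_)
    sim <- if (a + m == 0) 0 else m / (a + m)
    sor <- (b + c_) / (2 * a + b + c_)
    .newBetaPartition(sor, sim, "pairwise", c(a = a, b = b, c = c_))
}

## normalize inputs to lists of id sets
.asPresenceSets <- function(xs) {
    lapply(xs, function(x) {
        if (is.logical(x)) which(x)
        else if (is.numeric(x) && !is.null(names(x))) names(x)[x >= 1]
        else unique(x)
    })
}

#' Multi-site Baselga partition
#'
#' The multiple-site generalization: with \eqn{b_{ij}} the number of
#' taxa present at site i but not j, \eqn{K = \sum_i S_i - S_T} (sum of
#' site richnesses minus pooled richness),
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij}, b_{ji})}{K + \sum\min},\qquad
#'   \beta_{SOR} = \frac{\sum\min + \sum\max}{2K + \sum\min + \sum\max},}
#' and \eqn{\beta_{NES} = \beta_{SOR} - \beta_{SIM}}. With exactly two
#' sites this reduces to \code{\link{baselgaPair}}.
#'
#' @param sets list of presence sets (see \code{\link{baselgaPair}} for
#'   accepted forms); at least two, not all empty
#' @return a \code{\linkS4class{BetaPartition}} with multi scope
#' @export
baselgaMulti <- function(sets) {
    if (length(sets) < 2L) stop("need at least two sets")
    sets <- .asPresenceSets(sets)
    if (all(lengths(sets) == 0L))
        stop("Baselga partition undefined when all sets are empty")
    n <- length(sets)
    sum_min <- 0; sum_max <- 0
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            bij <- length(setdiff(sets[[i]], sets[[j]]))
            bji <- length(setdiff(sets[[j]], sets[[i]]))
            sum_min <- sum_min + min(bij, bji)
            sum_max <- sum_max + max(bij, bji)
        }
    }
    K <- sum(lengths(sets)) - length(unique(unlist(sets)))
    sim <- if (K + sum_min == 0) 0 else sum_min / (K + sum_min)
    sor <- if (2 * K + sum_min + sum_max == 0) 0 else
        (sum_min + sum_max) / (2 * K + sum_min + sum_max)
    .newBetaPartition(sor, sim, "multi",
                      c(sum_min = sum_min, sum_max = sum_max, K = K))
}

#' Resampled per-year multi-site beta diversity
#'
#' For each year, draws \code{k} samples at random without replacement,
#' computes the multi-site Baselga partition on their presence sets
#' (presence = count >= 1), and repeats \code{reps} times. This evens
#' out unequal yearly sample numbers before comparing years. Fully
#' reproducible from \code{seed}.
#'
#' @param x an \code{AsvExperiment} (controls are excluded)
#' @param k subsample size per year (default 30)
#' @param reps number of resampling repetitions (default 100)
#' @param seed integer seed
#' @return list with \code{draws} (data.frame year, rep, beta_sor,
#'   beta_sim, beta_nes) and \code{summary} (per-year mean and sd of
#'   each component)
#' @export
resampledBeta <- function(x, k = 30L, reps = 100L, seed = NULL) {
    stopifnot(is(x, "AsvExperiment"))
    x <- x[, !isControl(x)]
    cnt <- asvCounts(x)
    yr <- sampleYears(x)
    years <- sort(unique(yr))
    small <- years[tabulate(factor(yr, levels = years)) < k]
    if (length(small))
        stop("years with fewer than k = ", k, " samples: ",
             paste(small, collapse = ", "))
    draws <- withSeed(seed, {
        out <- list()
        for (y in years) {
            idx <- which(yr == y)
            for (r in seq_len(reps)) {
                take <- sample(idx, k)
                sets <- lapply(take, function(s) which(cnt[, s] >= 1L))
                bp <- baselgaMulti(sets)
                out[[length(out) + 1L]] <- data.frame(
                    year = y, rep = r,
                    beta_sor = betaSor(bp), beta_sim = betaSim(bp),
                    beta_nes = betaNes(bp))
            }
        }
        do.call(rbind, out)
    })
    agg <- do.call(rbind, lapply(split(draws, draws$year), function(d)
        data.frame(year = d$year[1L],
                   mean_sor = mean(d$beta_sor), sd_sor = stats::sd(d$beta_sor),
                   mean_sim = mean(d$beta_sim), sd_sim = stats::sd(d$beta_sim),
                   mean_nes = mean(d$beta_nes), sd_nes = stats::sd(d$beta_nes))))
    rownames(agg) <- NULL
    list(draws = draws, summary = agg, k = k, reps = reps, seed = seed)
}
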