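## Gower-centred inner-product matrix of a dissimilarity matrix:
## G = (I - 11'/n) (-d^2/2) (I - 11'/n). tr(H G) gives the SS
## explained by the subspace projected on by H (McArdle-Anderson).
.gowerCentre <- function(d) {
    a <- -0.5 * d^2
    n <- nrow(a)
    rm_ <- rowMeans(a); cm <- colMeans(a); gm <- mean(a)
    sweep(sweep(a, 1L, rm_), 2L, cm) + gm
}

.asDistMatrix <- function(d) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("d must be a square dissimilarity matrix or 'dist'")
    if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix not symmetric")
    d
}

## hat matrices of the cumulative model sequence implied by `terms`
.cumulativeHats <- function(data, terms) {
    hats <- list(matrix(1 / nrow(data), nrow(data), nrow(data)))
    ranks <- 1L
    fstr <- "~ 1"
    for (t in terms) {
        fstr <- paste(fstr, "+", t)
        X <- stats::model.matrix(stats::as.formula(fstr), data)
        qrx <- qr(X)
        Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
        hats <- c(hats, list(tcrossprod(Q)))
        ranks <- c(ranks, qrx$rank)
    }
    list(hats = hats, ranks = ranks)
}

## all permutations of 1..n (n small), as a list
.allPermutations <- function(n) {
    if (n == 1L) return(list(1L))
    sub <- .allPermutations(n - 1L)
    out <- vector("list", n * length(sub))
    k <- 0L
    for (i in seq_len(n)) {
        for (s in sub) {
            k <- k + 1L
            rest <- seq_len(n)[-i]
            out[[k]] <- c(i, rest[s])
        }
    }
    out
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the variation of a dissimilarity matrix among factors via
#' distance-based sums of squares (Gower-centred inner-product matrix,
#' sequential model sequence in the order of \code{terms}) and tests
#' each term's pseudo-F against free permutations of the sample labels:
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. With
#' \code{exact = TRUE} all \eqn{n!} permutations are enumerated instead
#' (feasible for n <= 8) and \eqn{p = \#\{F^* \ge F\}/n!} with the
#' identity included.
#'
#' @param d square dissimilarity matrix (or \code{dist}) over samples
#' @param data data.frame of factors, rows aligned with \code{d}
#' @param terms model terms in sequential order, e.g.
#'   \code{c("season", "year", "season:year")}
#' @param n_perm number of random permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @param exact enumerate all permutations instead of sampling?
#' @return list of class \code{"paraplankPermanova"}: \code{table}
#'   (term, df, sumsq, statistic = pseudo-F, r.squared, p.value),
#'   \code{n_perm}, \code{seed}, \code{degenerate}
#' @export
permanovaTest <- function(d, data, terms = colnames(data), n_perm = 999L,
                          seed = NULL, exact = FALSE) {
    d <- .asDistMatrix(d)
    n <- nrow(d)
    if (nrow(data) != n) stop("data rows must match the matrix dimension")
    data <- as.data.frame(lapply(as.data.frame(data),
                                 function(c) droplevels(as.factor(c))))
    for (v in colnames(data)) {
        if (any(table(data[[v]]) == 1L))
            warning("factor '", v, "' has a level with a single sample")
    }
    G <- .gowerCentre(d)
    ss_total <- sum(diag(G))
    cm <- .cumulativeHats(data, terms)
    nt <- length(terms)
    df <- diff(cm$ranks)
    df_resid <- n - cm$ranks[nt + 1L]
    if (ss_total <= 1e-12) {
        tab <- data.frame(term = c(terms, "Residuals"),
                          df = c(df, df_resid), sumsq = 0,
                          statistic = NA_real_, r.squared = NA_real_,
                          p.value = NA_real_, stringsAsFactors = FALSE)
        return(structure(list(table = tab, n_perm = 0L, seed = seed,
                              degenerate = TRUE),
                         class = "paraplankPermanova"))
    }
    termSS <- function(Gm) {
        ss <- numeric(nt)
        for (k in seq_len(nt))
            ss[k] <- sum(cm$hats[[k + 1L]] * Gm) - sum(cm$hats[[k]] * Gm)
        ss
    }
    ss_obs <- termSS(G)
    ss_res <- ss_total - sum(ss_obs)  # tr(H_intercept G) = 0 after centring
    f_of <- function(ss, ssr) (ss / df) / (ssr / df_resid)
    f_obs <- f_of(ss_obs, ss_res)
    eps <- 1e-12
    if (exact) {
        perms <- .allPermutations(n)
        count <- integer(nt)
        for (p in perms) {
            Gp <- G[p, p]
            ssp <- termSS(Gp)
            fp <- f_of(ssp, sum(diag(Gp)) - sum(ssp))
            count <- count + (fp >= f_obs - eps)
        }
        pval <- count / length(perms)
        n_used <- length(perms)
    } else {
        count <- withSeed(seed, {
            cnt <- integer(nt)
            for (r in seq_len(n_perm)) {
                p <- sample.int(n)
                Gp <- G[p, p]
                ssp <- termSS(Gp)
                fp <- f_of(ssp, sum(diag(Gp)) - sum(ssp))
                cnt <- cnt + (fp >= f_obs - eps)
            }
            cnt
        })
        pval <- (1 + count) / (1 + n_perm)
        n_used <- n_perm
    }
    tab <- data.frame(
        term = c(terms, "Residuals"),
        df = c(df, df_resid),
        sumsq = c(ss_obs, ss_res),
        statistic = c(f_obs, NA_real_),
        r.squared = c(ss_obs, ss_res) / ss_total,
        p.value = c(pval, NA_real_),
        stringsAsFactors = FALSE)
    structure(list(table = tab, n_perm = n_used, seed = seed,
                   degenerate = FALSE),
              class = "paraplankPermanova")
}

#' @export
print.paraplankPermanova <- function(x, ...) {
    cat(sprintf("PERMANOVA (%s permutations)\n",
                format(x$n_perm, big.mark = ",")))
    if (x$degenerate) cat("  degenerate: zero total sum of squares\n")
    tab <- x$table
    tab$signif <- signifCodes(tab$p.value)
    print(format(tab, digits = 4), row.names = FALSE)
    invisible(x)
}

#' Pairwise PERMANOVA between factor levels
#'
#' Runs one single-factor PERMANOVA per level pair on the corresponding
#' sub-matrix and adjusts the permutation p-values for multiple
#' comparisons (Bonferroni by default).
#'
#' @param d square dissimilarity matrix (or \code{dist})
#' @param group factor over the samples of \code{d}
#' @param n_perm permutations per pair
#' @param adjust p-adjustment method (see \code{\link[stats]{p.adjust}})
#' @param seed integer seed; each pair uses a derived sub-seed
#' @return data.frame: level1, level2, df, statistic (pseudo-F),
#'   r.squared, p.value, p.adjusted
#' @export
pairwisePermanova <- function(d, group, n_perm = 999L,
                              adjust = "bonferroni", seed = NULL) {
    d <- .asDistMatrix(d)
    group <- droplevels(as.factor(group))
    lv <- levels(group)
    if (length(lv) < 2L) stop("need at least two levels")
    pairs <- utils::combn(lv, 2L)
    out <- vector("list", ncol(pairs))
    for (i in seq_len(ncol(pairs))) {
        g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
        sel <- group %in% c(g1, g2)
        sub_seed <- if (is.null(seed)) NULL
                    else deriveSeed(seed, paste0("pair:", g1, ":", g2))
        fit <- permanovaTest(d[sel, sel, drop = FALSE],
                             data.frame(group = droplevels(group[sel])),
                             terms = "group", n_perm = n_perm,
                             seed = sub_seed)
        row <- fit$table[fit$table$term == "group", ]
        out[[i]] <- data.frame(level1 = g1, level2 = g2, df = row$df,
                               statistic = row$statistic,
                               r.squared = row$r.squared,
                               p.value = row$p.value,
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res$p.adjusted <- stats::p.adjust(res$p.value, method = adjust)
    res
}
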