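#' Two-way ANOVA with sequential sums of squares
#'
#' Fits the season x year two-way layout to a per-sample metric by
#' successive least-squares projections (intercept, + season, + year,
#' + interaction) and reports sequential (Type I) sums of squares in
#' that order. The design is unbalanced in a multi-year weekly series
#' (year lengths differ), so the SS type matters and is fixed here. F
#' for each term is its mean square over the residual mean square; p
#' comes from the F distribution.
#'
#' @param values numeric response, one per sample
#' @param season factor (or coercible) of season levels
#' @param year factor of calendar years
#' @return object of class \code{"paraplankAnova"}: a list with
#'   \code{table} (term, df, sumsq, meansq, statistic, p.value),
#'   \code{df_resid}, \code{ms_resid} and the model frame \code{data}
#' @examples
#' set.seed(1)
#' d <- expand.grid(season = c("sp", "su"), year = 2015:2016, rep = 1:5)
#' y <- rnorm(nrow(d)) + 2 * (d$season == "su")
#' twoWayAnova(y, d$season, d$year)$table
#' @export
twoWayAnova <- function(values, season, year) {
    values <- as.numeric(values)
    season <- droplevels(as.factor(season))
    year <- droplevels(as.factor(year))
    n <- length(values)
    if (length(season) != n || length(year) != n)
        stop("values, season and year must have equal length")
    if (anyNA(values)) stop("values contain NA")
    if (nlevels(season) < 2L || nlevels(year) < 2L)
        stop("each factor needs at least two observed levels")
    if (stats::var(values) == 0)
        stop("constant response: ANOVA undefined")
    has_interaction <- TRUE
    if (any(table(season, year) == 0L)) {
        warning("empty season x year cells; interaction term dropped")
        has_interaction <- FALSE
    }
    if (n <= nlevels(season) * nlevels(year) && has_interaction)
        warning("fewer observations than cells; interaction unreliable")

    mf <- data.frame(y = values, season = season, year = year)
    designs <- list(
        stats::model.matrix(~ 1, mf),
        stats::model.matrix(~ season, mf),
        stats::model.matrix(~ season + year, mf))
    terms <- c("season", "year")
    if (has_interaction) {
        designs <- c(designs,
                     list(stats::model.matrix(~ season * year, mf)))
        terms <- c(terms, "season:year")
    }
    rss <- numeric(length(designs))
    rnk <- integer(length(designs))
    for (k in seq_along(designs)) {
        fit <- stats::lm.fit(designs[[k]], values)
        rss[k] <- sum(fit$residuals^2)
        rnk[k] <- fit$rank
    }
    ss <- rss[-length(rss)] - rss[-1L]
    df <- rnk[-1L] - rnk[-length(rnk)]
    df_resid <- n - rnk[length(rnk)]
    ss_resid <- rss[length(rss)]
    if (df_resid <= 0L) stop("no residual degrees of freedom")
    ms_resid <- ss_resid / df_resid
    ms <- ss / df
    fstat <- ms / ms_resid
    pval <- stats::pf(fstat, df, df_resid, lower.tail = FALSE)
    tab <- data.frame(
        term = c(terms, "Residuals"),
        df = c(df, df_resid),
        sumsq = c(ss, ss_resid),
        meansq = c(ms, ms_resid),
        statistic = c(fstat, NA_real_),
        p.value = c(pval, NA_real_),
        stringsAsFactors = FALSE)
    structure(list(table = tab, df_resid = df_resid, ms_resid = ms_resid,
                   data = mf),
              class = "paraplankAnova")
}

#' @export
print.paraplankAnova <- function(x, ...) {
    cat("Two-way ANOVA (sequential SS: season, year, season:year)\n")
    tab <- x$table
    tab$signif <- signifCodes(tab$p.value)
    print(format(tab, digits = 4), row.names = FALSE)
    invisible(x)
}

#' Significance codes for p-values
#'
#' @param p numeric vector of p-values
#' @return character vector: \code{***} p<0.001, \code{**} p<0.01,
#'   \code{*} p<0.05, empty otherwise
#' @export
signifCodes <- function(p) {
    out <- rep("", length(p))
    out[!is.na(p) & p < 0.05] <- "*"
    out[!is.na(p) & p < 0.01] <- "**"
    out[!is.na(p) & p < 0.001] <- "***"
    out
}

#' Tukey HSD with compact letter display
#'
#' All-pairs comparisons of group means using the studentized-range
#' distribution with Tukey-Kramer standard errors for unequal group
#' sizes: for groups i, j, \eqn{SE = \sqrt{(MS_{res}/2)(1/n_i + 1/n_j)}},
#' \eqn{q = |\bar y_i - \bar y_j| / SE}, and the adjusted p-value is the
#' upper tail of the studentized range with the residual df. By default
#' the residual mean square of the one-way fit on \code{group} is used;
#' pass \code{df_resid}/\code{ms_resid} from a richer model (e.g. a
#' \code{\link{twoWayAnova}} fit) to test within it. Letters come from
#' the insert-and-absorb compact-letter algorithm: two levels share a
#' letter iff their adjusted p is >= alpha.
#'
#' @param values numeric response
#' @param group factor of group levels
#' @param alpha family-wise significance level for the letters
#' @param df_resid,ms_resid residual df and mean square to test against
#'   (default: from the one-way fit)
#' @return list with \code{comparisons} (level1, level2, diff, se, q,
#'   p_adj), \code{letters} (named character), \code{means},
#'   \code{alpha}, \code{flagged} (levels with < 2 observations,
#'   excluded from the letters)
#' @export
tukeyHsd <- function(values, group, alpha = 0.05,
                     df_resid = NULL, ms_resid = NULL) {
    values <- as.numeric(values)
    group <- droplevels(as.factor(group))
    if (nlevels(group) < 2L) stop("need at least two group levels")
    ni <- tapply(values, group, length)
    mi <- tapply(values, group, mean)
    k <- nlevels(group)
    if (is.null(df_resid) || is.null(ms_resid)) {
        fit <- stats::lm.fit(stats::model.matrix(~ group), values)
        df_resid <- length(values) - fit$rank
        ms_resid <- sum(fit$residuals^2) / df_resid
    }
    flagged <- names(ni)[ni < 2L]
    lv <- levels(group)
    pairs <- utils::combn(lv, 2L)
    comp <- data.frame(level1 = pairs[1L, ], level2 = pairs[2L, ],
                       stringsAsFactors = FALSE)
    comp$diff <- as.numeric(mi[comp$level1] - mi[comp$level2])
    comp$se <- as.numeric(sqrt(ms_resid / 2 *
                                   (1 / ni[comp$level1] + 1 / ni[comp$level2])))
    comp$q <- abs(comp$diff) / comp$se
    comp$p_adj <- stats::ptukey(comp$q, nmeans = k, df = df_resid,
                                lower.tail = FALSE)
    comp$p_adj[comp$se == 0] <- 1
    rownames(comp) <- NULL
    keep <- setdiff(lv, flagged)
    sig <- comp[comp$p_adj < alpha &
                    comp$level1 %in% keep & comp$level2 %in% keep, ,
                drop = FALSE]
    letters <- compactLetters(keep, sig[c("level1", "level2")])
    list(comparisons = comp, letters = letters,
         means = mi, alpha = alpha, flagged = flagged)
}

#' Insert-and-absorb compact letter display
#'
#' Builds the letter display from a list of significantly different
#' level pairs: start with one letter covering all levels; for each
#' significant pair, split every letter group containing both; absorb
#' groups that became subsets of others. The result satisfies: two
#' levels share a letter iff their pair is not significant.
#'
#' @param levels character vector of level names
#' @param sig_pairs data.frame (or 2-column matrix) of significantly
#'   different pairs
#' @return named character vector of letter strings per level
#' @export
compactLetters <- function(levels, sig_pairs) {
    cols <- list(levels)
    sig_pairs <- as.data.frame(sig_pairs)
    for (r in seq_len(nrow(sig_pairs))) {
        a <- sig_pairs[[1L]][r]; b <- sig_pairs[[2L]][r]
        new_cols <- list()
        for (col in cols) {
            if (a %in% col && b %in% col) {
                new_cols <- c(new_cols, list(setdiff(col, a)),
                              list(setdiff(col, b)))
            } else new_cols <- c(new_cols, list(col))
        }
        ## absorb: drop any column whose membership is a subset of another
        keep <- rep(TRUE, length(new_cols))
        for (i in seq_along(new_cols)) {
            for (j in seq_along(new_cols)) {
                if (i != j && keep[j] &&
                    all(new_cols[[i]] %in% new_cols[[j]]) &&
                    (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
                    keep[i] <- FALSE
                    break
                }
            }
        }
        cols <- new_cols[keep]
        cols <- cols[lengths(cols) > 0L]
    }
    lab <- stats::setNames(rep("", length(levels)), levels)
    for (ci in seq_along(cols)) {
        for (lv in cols[[ci]])
            lab[lv] <- paste0(lab[lv], letters[ci])
    }
    lab
}
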