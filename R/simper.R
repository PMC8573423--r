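#' SIMPER: per-ASV contributions to between-group dissimilarity
#'
#' For every between-group sample pair (j, k) the contribution of ASV i
#' to their Bray-Curtis dissimilarity is
#' \eqn{|x_{ij} - x_{ik}| / \sum_m (x_{mj} + x_{mk})}; the per-pair
#' contributions sum to the pair's Bray-Curtis value exactly.
#' Averaging over all between-group pairs decomposes the average
#' between-group dissimilarity into per-ASV shares, reported in
#' descending order with percentages and cumulative percentages.
#'
#' @param rel samples-by-ASVs relative-abundance matrix
#' @param groups factor over the samples (rows of \code{rel})
#' @param pairs list of 2-vectors of level names to compare; default
#'   all level pairs
#' @return named list (one element per pair, \code{"g1_vs_g2"}) of
#'   data.frames with columns \code{asv_id}, \code{average}, \code{sd},
#'   \code{contribution_pct}, \code{cumulative_pct}; each carries
#'   attribute \code{average_dissimilarity}
#' @export
simperAnalysis <- function(rel, groups, pairs = NULL) {
    groups <- droplevels(as.factor(groups))
    if (nrow(rel) != length(groups))
        stop("groups must have one entry per sample row")
    lv <- levels(groups)
    if (is.null(pairs)) {
        cmb <- utils::combn(lv, 2L)
        pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    }
    out <- list()
    for (pr in pairs) {
        g1 <- pr[1L]; g2 <- pr[2L]
        i1 <- which(groups == g1); i2 <- which(groups == g2)
        if (!length(i1) || !length(i2))
            stop("empty group in pair ", g1, " vs ", g2)
        contrib <- matrix(0, ncol(rel), length(i1) * length(i2))
        used <- logical(ncol(contrib))
        p <- 0L
        for (j in i1) {
            xj <- rel[j, ]
            for (k in i2) {
                p <- p + 1L
                denom <- sum(xj + rel[k, ])
                if (denom == 0) {
                    warning("degenerate pair with zero total reads skipped")
                    next
                }
                contrib[, p] <- abs(xj - rel[k, ]) / denom
                used[p] <- TRUE
            }
        }
        contrib <- contrib[, used, drop = FALSE]
        avg <- rowMeans(contrib)
        sdv <- apply(contrib, 1L, stats::sd)
        total <- sum(avg)
        df <- data.frame(asv_id = colnames(rel), average = avg, sd = sdv,
                         stringsAsFactors = FALSE)
        df <- df[order(-df$average), ]
        df$contribution_pct <- 100 * df$average / total
        df$cumulative_pct <- cumsum(df$contribution_pct)
        rownames(df) <- NULL
        attr(df, "average_dissimilarity") <- total
        out[[paste0(g1, "_vs_", g2)]] <- df
    }
    out
}
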