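#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in \code{k} dimensions so that configuration
#' distances monotonically match the input dissimilarities. The fit
#' alternates isotonic (monotone) regression of configuration distances
#' on the dissimilarity ranks (primary tie treatment: ties may reorder
#' to reduce stress) with a Guttman-transform configuration update
#' (iterative majorization), minimizing
#' \deqn{\mathrm{stress}_1 = \sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}.}
#' The reported run is the best of one metric-scaling
#' (\code{cmdscale}) start plus \code{restarts} random starts; within a
#' run the stress sequence is non-increasing (the iteration stops if an
#' update fails to improve). The final configuration is centred and
#' rotated to its principal axes.
#'
#' @param d square dissimilarity matrix (or \code{dist})
#' @param k embedding dimension (default 2)
#' @param restarts number of random starts in addition to the metric
#'   start
#' @param max_iter maximum majorization iterations per start
#' @param tol stop when the stress improvement falls below this
#' @param seed integer seed for the random starts
#' @return list: \code{points} (n x k), \code{stress}, \code{converged},
#'   \code{stress_trace} (per-iteration stress of the winning start),
#'   \code{start_stress} (final stress of every start; element
#'   \code{"metric"} is the metric-scaling start)
#' @export
nmdsOrdination <- function(d, k = 2L, restarts = 10L, max_iter = 300L,
                           tol = 1e-7, seed = NULL) {
    d <- .asDistMatrix(d)
    n <- nrow(d)
    if (n < 3L) stop("need at least three samples")
    delta <- d[lower.tri(d)]
    if (all(delta == 0)) {
        pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
        return(list(points = pts, stress = 0, converged = TRUE,
                    stress_trace = 0, start_stress = c(metric = 0)))
    }
    metric0 <- stats::cmdscale(d, k = k)
    if (ncol(metric0) < k)
        metric0 <- cbind(metric0, matrix(0, n, k - ncol(metric0)))
    starts <- list(metric = metric0)
    starts <- c(starts, withSeed(seed, {
        lapply(seq_len(restarts), function(i)
            matrix(stats::rnorm(n * k), n, k))
    }))
    runs <- lapply(starts, function(X0)
        .nmdsRun(X0, delta, n, k, max_iter, tol))
    fin <- vapply(runs, function(r) r$stress, numeric(1L))
    best <- runs[[which.min(fin)]]
    X <- scale(best$points, center = TRUE, scale = FALSE)
    sv <- svd(X)
    X <- X %*% sv$v
    dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    list(points = X, stress = best$stress, converged = best$converged,
         stress_trace = best$trace, start_stress = fin)
}

.nmdsRun <- function(X, delta, n, k, max_iter, tol) {
    lowtri <- lower.tri(matrix(0, n, n))
    confDist <- function(X) as.matrix(stats::dist(X))[lowtri]
    dv <- confDist(X)
    trace <- numeric(0)
    prev_stress <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
        ## disparities: monotone regression of dv against delta order,
        ## ties ordered by dv (primary treatment)
        ord <- order(delta, dv)
        dhat <- numeric(length(dv))
        dhat[ord] <- stats::isoreg(dv[ord])$yf
        ss_d <- sum(dv^2)
        stress <- sqrt(sum((dv - dhat)^2) / ss_d)
        if (stress > prev_stress + 1e-15) {
            X <- X_prev; dv <- confDist(X)
            break
        }
        trace <- c(trace, stress)
        if (prev_stress - stress < tol && it > 1L) {
            converged <- TRUE
            prev_stress <- stress
            break
        }
        prev_stress <- stress
        if (stress < 1e-12) { converged <- TRUE; break }
        ## Guttman transform
        B <- matrix(0, n, n)
        ratio <- ifelse(dv > 0, dhat / dv, 0)
        B[lowtri] <- -ratio
        B <- B + t(B)
        diag(B) <- -rowSums(B)
        X_prev <- X
        X <- B %*% X / n
        dv <- confDist(X)
    }
    list(points = X, stress = prev_stress, converged = converged,
         trace = trace)
}
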