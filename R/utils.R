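#' Season of a sampling date
#'
#' Meteorological seasons: spring = March-May, summer = June-August,
#' autumn = September-November, winter = December-February. Total on
#' valid dates; December is assigned to the winter of its own calendar
#' year (the \code{year} factor elsewhere is always the calendar year).
#'
#' @param dates Date vector or ISO-8601 (YYYY-MM-DD) strings
#' @return factor with levels spring, summer, autumn, winter
#' @examples
#' assignSeason(as.Date(c("2015-06-15", "2016-12-31")))
#' @export
assignSeason <- function(dates) {
    dates <- parseIsoDate(dates)
    m <- as.integer(format(dates, "%m"))
    lab <- c("winter", "winter", "spring", "spring", "spring",
             "summer", "summer", "summer", "autumn", "autumn",
             "autumn", "winter")[m]
    factor(lab, levels = SEASON_LEVELS)
}

#' @rdname assignSeason
#' @export
SEASON_LEVELS <- c("spring", "summer", "autumn", "winter")

#' Parse strict ISO-8601 dates
#'
#' Accepts Date vectors as-is; character input must match
#' \code{YYYY-MM-DD} exactly. Anything else is an error naming the
#' offending value.
#'
#' @param x Date or character vector
#' @return Date vector
#' @export
parseIsoDate <- function(x) {
    if (inherits(x, "Date")) return(x)
    x <- as.character(x)
    bad <- !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    if (any(bad))
        stop("unparseable date (expected YYYY-MM-DD): ",
             paste(unique(x[bad]), collapse = ", "))
    d <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(d))
        stop("invalid calendar date: ",
             paste(unique(x[is.na(d)]), collapse = ", "))
    d
}

## Evaluate expr under a temporary RNG state seeded from `seed`,
## restoring the caller's state afterwards. seed = NULL leaves the
## stream untouched.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic 31-bit sub-seed for a named stage of a seeded pipeline.
deriveSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483399) + 1L
}

## Deterministic TSV writer: UTF-8, LF endings, no quoting surprises.
writeTsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
    if (nrow(df)) {
        cells <- vapply(df, function(col) {
            if (inherits(col, "Date")) format(col, "%Y-%m-%d")
            else as.character(col)
        }, character(nrow(df)))
        if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
        cells[is.na(cells)] <- ""
        writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
    }
    invisible(path)
}

readTsv <- function(path, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character")
}
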