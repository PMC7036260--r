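# Copy-number categorization and 2x2 cohort contingency statistics.

#' Categorize an absolute copy number
#'
#' Half-open intervals: loss (cn <= 1), balanced (1 < cn <= 3),
#' gain (3 < cn <= 6), amplification (cn > 6).
#'
#' @param cn numeric vector of absolute copy numbers (>= 0).
#' @return character vector of categories.
#' @export
#' @examples
#' cnCategory(c(2, 3, 6, 6.01))
cnCategory <- function(cn) {
    if (any(is.na(cn)) || any(cn < 0)) stop("cn must be >= 0")
    out <- character(length(cn))
    out[cn <= 1] <- "loss"
    out[cn > 1 & cn <= 3] <- "balanced"
    out[cn > 3 & cn <= 6] <- "gain"
    out[cn > 6] <- "amplification"
    out
}

#' Pearson chi-square test of a 2x2 table
#'
#' Without continuity correction by default. The closed form
#' \code{n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with df = 1 and a
#' two-sided p.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param correction apply the Yates continuity correction.
#' @return list of class \code{ContingencyResult}: \code{table},
#'   \code{chi2}, \code{p}, \code{correction}.
#' @export
#' @examples
#' chiSquare2x2(matrix(c(13, 137, 28, 591), 2, byrow = TRUE))$p  # 0.0427
chiSquare2x2 <- function(table, correction = FALSE) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
    if (any(table < 0)) stop("counts must be non-negative")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("zero marginal: the chi-square test is undefined; ",
             "consider a Fisher exact test")
    ct <- suppressWarnings(stats::chisq.test(table, correct = correction))
    structure(list(table = table, chi2 = unname(ct$statistic),
                   p = ct$p.value, correction = correction),
              class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
    cat("2x2 chi-square", if (x$correction) "(Yates-corrected)" else
        "(no continuity correction)", "\n")
    print(x$table)
    cat(sprintf("chi2 = %.4g, df = 1, p = %.4g\n", x$chi2, x$p))
    if (!is.null(x$frequencies))
        cat(sprintf("frequencies: %.1f%% vs %.1f%%\n",
                    x$frequencies[1], x$frequencies[2]))
    invisible(x)
}

# Half-up rounding to `digits` decimals (to match printed percentages).
roundHalfUp <- function(x, digits = 1) {
    floor(x * 10^digits + 0.5) / 10^digits
}

#' Compare two carrier frequencies by chi-square
#'
#' Builds the 2x2 table [[countA, nA - countA], [countB, nB - countB]] and
#' delegates to [chiSquare2x2()]; frequencies are reported as percentages
#' rounded half-up to one decimal.
#'
#' @param countA,nA carriers and cohort size of group A.
#' @param countB,nB carriers and cohort size of group B.
#' @param correction apply the Yates continuity correction.
#' @return a \code{ContingencyResult} with an extra \code{frequencies}
#'   element (percent).
#' @export
#' @examples
#' compareFrequencies(13, 150, 28, 619)  # 8.7% vs 4.5%, p = 0.043
compareFrequencies <- function(countA, nA, countB, nB,
                               correction = FALSE) {
    if (countA > nA || countB > nB) stop("counts must not exceed n")
    res <- chiSquare2x2(matrix(c(countA, nA - countA, countB, nB - countB),
                               2, byrow = TRUE), correction = correction)
    res$frequencies <- c(roundHalfUp(100 * countA / nA),
                         roundHalfUp(100 * countB / nB))
    res
}
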