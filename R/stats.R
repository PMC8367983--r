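## Nonparametric group statistics, implemented from first principles:
## tie-corrected Kruskal-Wallis, ranked epsilon squared, two-sided Dunn
## pairwise tests and Holm step-down adjustment.

.checkGroups <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need >= 2 groups")
    n <- vapply(groups, length, integer(1))
    if (any(n == 0L)) stop("group with zero observations")
    if (sum(n) < 3L) stop("need >= 3 observations in total")
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    groups
}

## mid-ranks of the pooled sample and the tie-size spectrum
.pooledRanks <- function(groups) {
    x <- unlist(groups, use.names = FALSE)
    r <- rank(x, ties.method = "average")
    g <- rep(names(groups), lengths(groups))
    ties <- table(x)
    list(r = r, g = g, N = length(x),
         tieTerm = sum(ties^3 - ties))  # sum over tie groups of t^3 - t
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' H = [12/(N(N+1)) * sum n_i Rbar_i^2] - 3(N+1), divided by the tie
#' correction 1 - sum(t^3 - t)/(N^3 - N); p-value from the chi-square
#' distribution with k-1 degrees of freedom (the approximation is used at
#' every sample size). When all values are identical H = 0 and p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each nonempty, total n >= 3.
#' @return List with \code{H}, \code{p_value}, \code{df}, \code{n_total},
#'   \code{group_sizes}.
#' @examples
#' kruskalWallis(list(a = 1:3, b = 4:6, c = 7:9))  # H = 8 (= N - 1)
#' @export
kruskalWallis <- function(groups) {
    groups <- .checkGroups(groups)
    pr <- .pooledRanks(groups)
    rbar <- tapply(pr$r, pr$g, mean)
    ni <- tapply(pr$r, pr$g, length)
    N <- pr$N
    H <- 12 / (N * (N + 1)) * sum(ni * rbar^2) - 3 * (N + 1)
    corr <- 1 - pr$tieTerm / (N^3 - N)
    H <- if (corr > 0) H / corr else 0  # all values tied
    H <- max(H, 0)
    df <- length(groups) - 1L
    list(H = H, p_value = pchisq(H, df, lower.tail = FALSE), df = df,
         n_total = N, group_sizes = as.integer(ni)[match(names(groups),
                                                         names(ni))])
}

#' Ranked epsilon squared effect size
#'
#' epsilon^2 = H * (n + 1) / (n^2 - 1), in [0, 1]; 1 corresponds to perfect
#' group separation (H = n - 1 without ties).
#'
#' @param H Kruskal-Wallis statistic.
#' @param nTotal total number of observations (>= 2).
#' @return Effect size in [0, 1].
#' @examples
#' rankEpsilonSquared(4, 9)  # 0.5
#' @export
rankEpsilonSquared <- function(H, nTotal) {
    if (nTotal < 2) stop("nTotal must be >= 2")
    H * (nTotal + 1) / (nTotal^2 - 1)
}

#' Two-sided Dunn pairwise comparisons
#'
#' For each pair of groups, z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 -
#' TIE/(12(N-1))) * (1/n_i + 1/n_j)) with TIE = sum(t^3 - t) over tie
#' groups, using the mid-ranks of the pooled sample; two-sided p from the
#' standard normal. Holm-adjusted p-values over the whole family are
#' appended ([holmAdjust()]).
#'
#' @param groups as in [kruskalWallis()].
#' @return Data frame with one row per unordered pair: \code{group_a},
#'   \code{group_b}, \code{z}, \code{p_raw}, \code{p_holm}.
#' @export
dunnPairwise <- function(groups) {
    groups <- .checkGroups(groups)
    pr <- .pooledRanks(groups)
    N <- pr$N
    rbar <- tapply(pr$r, pr$g, mean)
    ni <- tapply(pr$r, pr$g, length)
    sigma2 <- N * (N + 1) / 12 - pr$tieTerm / (12 * (N - 1))
    if (sigma2 <= 0)
        stop("degenerate variance: all values tied across groups")
    nm <- names(groups)
    pairs <- utils::combn(nm, 2)
    z <- apply(pairs, 2, function(p)
        (rbar[[p[1]]] - rbar[[p[2]]]) /
            sqrt(sigma2 * (1 / ni[[p[1]]] + 1 / ni[[p[2]]])))
    p_raw <- 2 * pnorm(abs(z), lower.tail = FALSE)
    data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
               p_raw = p_raw, p_holm = holmAdjust(p_raw),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the p-values ascending and sets adjusted p_(i) = min(1, max over
#' j <= i of (m - j + 1) * p_(j)); results are returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' holmAdjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holmAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
    m <- length(p)
    if (m <= 1L) return(p)
    o <- order(p)
    adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
    out <- numeric(m)
    out[o] <- adj
    out
}

#' Full group-comparison battery
#'
#' Runs [kruskalWallis()], [rankEpsilonSquared()] and [dunnPairwise()] on
#' one family of groups. Pairs with Holm-adjusted p <= `alphaReport` are
#' marked significant, the convention used when annotating plots.
#'
#' @param groups as in [kruskalWallis()].
#' @param alphaReport significance mark threshold on Holm-adjusted p
#'   (default 0.001).
#' @return List with elements \code{H}, \code{p_value}, \code{epsilon_sq},
#'   \code{n_total}, \code{group_sizes} and a \code{pairwise} data frame
#'   with a \code{significant} column.
#' @export
compareGroups <- function(groups, alphaReport = 0.001) {
    kw <- kruskalWallis(groups)
    pw <- dunnPairwise(groups)
    pw$significant <- pw$p_holm <= alphaReport
    list(H = kw$H, p_value = kw$p_value,
         epsilon_sq = rankEpsilonSquared(kw$H, kw$n_total),
         n_total = kw$n_total, group_sizes = kw$group_sizes,
         pairwise = pw)
}

#' Pearson correlation on the shared detected set
#'
#' Correlates a quantity between two libraries using only transcripts
#' present, and not placeholder-masked, in both tables.
#'
#' @param xTable,yTable summary tables with \code{transcript_id}, the value
#'   column and (optionally) \code{placeholder_flag}.
#' @param value column to correlate (default \code{"mean_tail"}).
#' @return List with \code{r} and \code{n_used}.
#' @export
pearsonOnIntersection <- function(xTable, yTable, value = "mean_tail") {
    keep <- function(s) if (is.null(s$placeholder_flag)) s else
        s[!s$placeholder_flag, , drop = FALSE]
    xT <- keep(xTable); yT <- keep(yTable)
    shared <- intersect(xT$transcript_id, yT$transcript_id)
    if (length(shared) < 3L) stop("fewer than 3 shared detected transcripts")
    x <- xT[[value]][match(shared, xT$transcript_id)]
    y <- yT[[value]][match(shared, yT$transcript_id)]
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance on the intersection")
    list(r = cor(x, y), n_used = length(shared))
}
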