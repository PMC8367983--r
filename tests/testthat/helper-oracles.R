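# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and rank()/p.adjust()) so agreement is informative.

# mid-ranks by counting: rank of x_i = #(x < x_i) + (#(x == x_i) + 1)/2
bruteRanks <- function(x) {
    vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2,
           numeric(1))
}

bruteKruskalWallis <- function(groups) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(seq_along(groups), lengths(groups))
    r <- bruteRanks(x)
    N <- length(x)
    H <- 0
    for (i in seq_along(groups))
        H <- H + length(groups[[i]]) * mean(r[g == i])^2
    H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
    tie <- 0
    for (v in unique(x)) {
        t <- sum(x == v)
        tie <- tie + t^3 - t
    }
    corr <- 1 - tie / (N^3 - N)
    H <- if (corr > 0) H / corr else 0
    list(H = H, p = 1 - pchisq(H, length(groups) - 1))
}

bruteDunn <- function(groups) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(seq_along(groups), lengths(groups))
    r <- bruteRanks(x)
    N <- length(x)
    tie <- 0
    for (v in unique(x)) {
        t <- sum(x == v)
        tie <- tie + t^3 - t
    }
    s2 <- N * (N + 1) / 12 - tie / (12 * (N - 1))
    out <- NULL
    k <- length(groups)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        z <- (mean(r[g == i]) - mean(r[g == j])) /
            sqrt(s2 * (1 / sum(g == i) + 1 / sum(g == j)))
        out <- rbind(out, data.frame(i = i, j = j, z = z,
                                     p = 2 * (1 - pnorm(abs(z)))))
    }
    out
}

# literal step-down definition: adjusted_(i) = min(1, max_{j<=i} (m-j+1) p_(j))
bruteHolm <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
        best <- 0
        for (j in seq_len(i)) best <- max(best, (m - j + 1) * p[o][j])
        adj[i] <- min(1, best)
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

brutePearson <- function(x, y) {
    n <- length(x)
    sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# truncated normal on [lo, hi]: mean and quantile by numerical integration
# over a fine grid (independent of the simulator's inverse-CDF sampling)
truncNormGrid <- function(mean, sd, lo, hi, n = 200001) {
    x <- seq(lo, hi, length.out = n)
    d <- dnorm(x, mean, sd)
    d <- d / sum(d * diff(x)[1])
    list(x = x, d = d, cdf = cumsum(d) * diff(x)[1])
}

truncNormMeanNum <- function(mean, sd, lo, hi) {
    g <- truncNormGrid(mean, sd, lo, hi)
    sum(g$x * g$d) * diff(g$x)[1]
}

truncNormQuantileNum <- function(q, mean, sd, lo, hi) {
    g <- truncNormGrid(mean, sd, lo, hi)
    g$x[which.min(abs(g$cdf - q))]
}
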