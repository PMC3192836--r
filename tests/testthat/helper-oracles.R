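# Independent oracles used across tests. These enumerate the exact null
# distributions directly and never call the package functions they check.

# Two-sided Fisher p for the 2x2 table [[c1, N1-c1], [c2, N2-c2]] by
# hypergeometric enumeration over all tables with the observed margins.
fisherOracle2s <- function(c1, N1, c2, N2) {
    m <- c1 + c2
    k <- max(0, m - N2):min(m, N1)
    pr <- dhyper(k, N1, N2, m)
    pObs <- dhyper(c1, N1, N2, m)
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

# One-sided (excess in library 1) Fisher p by the same enumeration.
fisherOracle1s <- function(c1, N1, c2, N2) {
    m <- c1 + c2
    k <- max(0, m - N2):min(m, N1)
    pr <- dhyper(k, N1, N2, m)
    sum(pr[k >= c1])
}

# Exact two-sided rank-sum p by exhaustive enumeration of all group
# assignments (tie-free data only). Uses the Mann-Whitney U statistic and
# the doubled smaller tail, capped at 1, the convention of exact
# wilcox.test.
rankSumOracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pooled <- c(x, y)
    stopifnot(!anyDuplicated(pooled))
    obsU <- sum(outer(x, y, ">"))
    idx <- utils::combn(nx + ny, nx)
    us <- apply(idx, 2L, function(i)
        sum(outer(pooled[i], pooled[-i], ">")))
    pl <- mean(us <= obsU)
    pu <- mean(us >= obsU)
    min(1, 2 * min(pl, pu))
}

# Brute-force 5'-anchored quantification over an enumerated record table:
# retain |offset| <= window, reference = max copies (lexicographic
# tie-break), count = copies at the reference's 5' position.
quantifyOracle <- function(records, mature5, window = 3L) {
    keep <- abs(records$pos0 - mature5) <= window
    r <- records[keep, , drop = FALSE]
    if (!nrow(r)) return(list(count = 0L, reference = ""))
    agg <- aggregate(copies ~ sequence + pos0, r, sum)
    agg <- agg[order(-agg$copies, agg$sequence), ]
    ref <- agg[1L, ]
    list(count = sum(agg$copies[agg$pos0 == ref$pos0]),
         reference = ref$sequence)
}
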