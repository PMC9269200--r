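# small cohorts built in code

SECTORS6 <- c("TS", "T", "TI", "NS", "N", "NI")

# cohort from explicit per-patient sector vectors (lists of named 6-vectors)
makeCohort <- function(right, left, label) {
    r <- do.call(cbind, lapply(right, function(v) v[SECTORS6]))
    l <- do.call(cbind, lapply(left, function(v) v[SECTORS6]))
    rownames(r) <- rownames(l) <- SECTORS6
    RNFLCohort(r, l, label = label)
}

flat6 <- function(x) stats::setNames(rep(x, 6), SECTORS6)

# two-patient cohort with a known asymmetric glaucoma patient
toyCohort <- function() {
    makeCohort(
        right = list(flat6(100), flat6(120)),
        left = list(flat6(100), flat6(80)),
        label = c("healthy", "glaucoma"))
}

# exhaustive-enumeration oracle over binary trees with <= maxSplits split
# nodes (midpoint thresholds), minimizing weighted misclassification;
# independent of the greedy grower
oracleLeafLoss <- function(y, w) min(sum(w[y == "healthy"]), sum(w[y == "glaucoma"]))

oracleStumps <- function(x) {
    out <- list()
    for (j in seq_len(ncol(x))) {
        v <- sort(unique(x[, j]))
        if (length(v) > 1)
            for (i in seq_len(length(v) - 1))
                out[[length(out) + 1]] <- c(j, (v[i] + v[i + 1]) / 2)
    }
    out
}

oracleBestStumpLoss <- function(x, y, w) {
    best <- oracleLeafLoss(y, w)
    for (s in oracleStumps(x)) {
        L <- x[, s[1]] < s[2]
        best <- min(best, oracleLeafLoss(y[L], w[L]) + oracleLeafLoss(y[!L], w[!L]))
    }
    best
}

oracleBestLoss <- function(x, y, w, maxSplits) {
    best <- oracleLeafLoss(y, w)
    if (maxSplits >= 1) best <- min(best, oracleBestStumpLoss(x, y, w))
    if (maxSplits >= 2) {
        for (s in oracleStumps(x)) {
            L <- x[, s[1]] < s[2]
            best <- min(best,
                oracleBestStumpLoss(x[L, , drop = FALSE], y[L], w[L]) +
                    oracleLeafLoss(y[!L], w[!L]),
                oracleLeafLoss(y[L], w[L]) +
                    oracleBestStumpLoss(x[!L, , drop = FALSE], y[!L], w[!L]))
        }
    }
    best
}

# one random tiny classification instance for the oracle comparisons
randomTinyInstance <- function() {
    n <- sample(4:8, 1)
    x <- matrix(stats::runif(2 * n), n, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- factor(sample(c("healthy", "glaucoma"), n, replace = TRUE),
                levels = c("healthy", "glaucoma"))
    if (length(unique(y)) < 2) y[1:2] <- c("healthy", "glaucoma")
    list(x = x, y = y, maxSplits = sample(1:2, 1))
}
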