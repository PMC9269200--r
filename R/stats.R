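#' Half-normal mean
#'
#' If `X ~ Normal(0, sigma^2)`, then `|X|` follows a half-normal distribution
#' with mean `sigma * sqrt(2/pi)`. This is why the absolute asymmetry metrics
#' turn the group difference in *variance* of the signed, zero-centered
#' metrics into a difference in *mean*, which a threshold classifier can use.
#'
#' @param sigma Standard deviation of the underlying normal, >= 0.
#' @return `sigma * sqrt(2/pi)`.
#' @examples
#' halfNormalMean(1) # 0.7979
#' @export
halfNormalMean <- function(sigma) {
    if (any(sigma < 0)) stop("'sigma' must be >= 0")
    sigma * sqrt(2 / pi)
}

#' Two-group comparison p-value
#'
#' Two-sided p-value comparing healthy and glaucoma samples of one asymmetry
#' feature. The default is the Wilcoxon rank-sum test: for combined sample
#' sizes up to 20 the permutation null of the rank-sum statistic is
#' enumerated exactly (midranks handle ties; two-sided p is twice the smaller
#' tail, capped at 1); for larger samples the normal approximation with
#' tie-corrected variance is used (`stats::wilcox.test`). `welch_t` gives
#' Welch's unequal-variance t-test for comparison. Rank-based p-values are
#' invariant under any positive rescaling of the values, so `Delta`,
#' `Delta_bar` and `Delta_dbar` columns that differ only by positive factors
#' share identical p-values.
#'
#' @param healthy,glaucoma Numeric vectors, both non-empty.
#' @param method `"rank_sum"` (default) or `"welch_t"`.
#' @return Two-sided p-value in (0, 1]. All values tied across both groups
#'   gives p = 1 with a warning.
#' @export
compareGroups <- function(healthy, glaucoma,
                          method = c("rank_sum", "welch_t")) {
    method <- match.arg(method)
    if (!length(healthy) || !length(glaucoma))
        stop("both samples must be non-empty")
    pooled <- c(healthy, glaucoma)
    if (length(unique(pooled)) == 1L) {
        warning("all values tied; p-value set to 1")
        return(1)
    }
    if (method == "welch_t")
        return(stats::t.test(healthy, glaucoma)$p.value)
    n <- length(pooled)
    if (n <= 20) {
        rk <- rank(pooled)
        ng <- length(glaucoma)
        idx <- utils::combn(n, ng)
        sums <- colSums(matrix(rk[idx], nrow = ng))
        obs <- sum(rk[length(healthy) + seq_len(ng)])
        p <- 2 * min(mean(sums <= obs), mean(sums >= obs))
        return(min(p, 1))
    }
    stats::wilcox.test(healthy, glaucoma, exact = FALSE)$p.value
}

#' Group summary of an asymmetry feature matrix
#'
#' The statistical characterization table: per feature (TS..NI, G) and per
#' diagnosis group, the mean and sample standard deviation (n - 1
#' denominator) of the metric, plus a two-sided p-value for the
#' healthy-vs-glaucoma comparison from [compareGroups()].
#'
#' @param x An [AsymmetryFeatures-class]; both diagnosis groups must have at
#'   least two patients.
#' @param method Passed to [compareGroups()].
#' @return A data.frame with columns `feature`, `mean_h`, `sd_h`, `n_h`,
#'   `mean_g`, `sd_g`, `n_g`, `p_value`, one row per feature in reporting
#'   order.
#' @examples
#' cohort <- generateCohort(seed = 1)
#' summarizeGroups(asymmetryFeatures(cohort, "abs_Delta"))
#' @export
summarizeGroups <- function(x, method = c("rank_sum", "welch_t")) {
    stopifnot(is(x, "AsymmetryFeatures"))
    method <- match.arg(method)
    lab <- diagnosis(x)
    v <- SummarizedExperiment::assay(x)  # 7 x n
    nh <- sum(lab == "healthy"); ng <- sum(lab == "glaucoma")
    if (nh < 2 || ng < 2)
        stop("each group needs >= 2 patients (sd undefined otherwise)")
    h <- v[, lab == "healthy", drop = FALSE]
    g <- v[, lab == "glaucoma", drop = FALSE]
    data.frame(
        feature = .FEATURES,
        mean_h = rowMeans(h), sd_h = apply(h, 1, stats::sd), n_h = nh,
        mean_g = rowMeans(g), sd_g = apply(g, 1, stats::sd), n_g = ng,
        p_value = vapply(.FEATURES, function(f)
            compareGroups(h[f, ], g[f, ], method = method), numeric(1)),
        row.names = .FEATURES, stringsAsFactors = FALSE)
}

#' Notched box-plot summary
#'
#' The quantities behind a notched box plot: quartiles by linear
#' interpolation of order statistics (R quantile type 7), whiskers at the
#' most extreme observations within 1.5 interquartile ranges of the box
#' edges, observations beyond the whiskers flagged as outliers, and notches
#' at `median +/- 1.57 * IQR / sqrt(n)` (boxes whose notches do not overlap
#' have medians that differ at roughly the 5% level).
#'
#' @param values Numeric vector with at least 5 observations.
#' @return A list with elements `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `notch_low`, `notch_high`, `outliers`, `n`.
#' @examples
#' boxSummary(c(1:10, 100))$outliers # 100
#' @export
boxSummary <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 5) stop("need at least 5 values")
    if (anyNA(values)) stop("missing values not allowed")
    q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    inside <- values >= lo & values <= hi
    n <- length(values)
    notch <- 1.57 * iqr / sqrt(n)
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_low = min(values[inside]), whisker_high = max(values[inside]),
         notch_low = q[2] - notch, notch_high = q[2] + notch,
         outliers = sort(values[!inside]), n = n)
}

#' Write a group summary table to CSV
#'
#' One row per feature with the group means, SDs and p-value, values rounded
#' half away from zero to 4 decimals, plus a leading `# metric=<id>` comment
#' line identifying the metric.
#'
#' @param summary A data.frame from [summarizeGroups()].
#' @param metric The metric id the summary describes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSummaryCsv <- function(summary, metric, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# metric=%s", metric), con)
    out <- summary
    for (col in c("mean_h", "sd_h", "mean_g", "sd_g"))
        out[[col]] <- roundHalfUp(out[[col]], 4)
    out$p_value <- signif(out$p_value, 5)
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}
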