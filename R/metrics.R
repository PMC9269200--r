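#' Asymmetry metric identifiers
#'
#' The nine inter-eye asymmetry metrics. With `d = w_r - w_l` the inter-eye
#' difference of sector mean thickness:
#' \describe{
#'   \item{`delta`}{`d`, in micrometres.}
#'   \item{`abs_delta`}{`|d|`, micrometres.}
#'   \item{`Delta`}{`d / (w_r + w_l)`, the difference normalized by the
#'     patient's own sector thickness sum; dimensionless in \[-1, 1\].}
#'   \item{`abs_Delta`}{`|d| / (w_r + w_l)`, in \[0, 1\].}
#'   \item{`Delta_bar`}{`d / (wbar_r + wbar_l)`, normalized by the sum of the
#'     cohort mean thicknesses of that sector (one denominator per sector,
#'     shared by all patients).}
#'   \item{`abs_Delta_bar`}{absolute counterpart of `Delta_bar`.}
#'   \item{`Delta_dbar`}{`d / (wG_r + wG_l)`, normalized by the patient's own
#'     global thickness sum; coincides with `Delta` for the G feature.}
#'   \item{`abs_Delta_dbar`}{absolute counterpart of `Delta_dbar`.}
#'   \item{`sqrt_abs_Delta`}{`sqrt(abs_Delta)`: a square-root (gamma)
#'     compression that spreads the small values of `abs_Delta` apart.}
#' }
#'
#' @return Character vector of the nine metric ids.
#' @examples
#' asymmetryMetrics()
#' @export
asymmetryMetrics <- function() {
    c("delta", "abs_delta", "Delta", "abs_Delta", "Delta_bar",
      "abs_Delta_bar", "Delta_dbar", "abs_Delta_dbar", "sqrt_abs_Delta")
}

.SIGNED_METRICS <- c("delta", "Delta", "Delta_bar", "Delta_dbar")

#' Cohort sector means
#'
#' Arithmetic means over all patients of the per-eye sector thicknesses
#' (including G): the shared denominators of the `Delta_bar` metrics. Means
#' pool all patients regardless of diagnosis.
#'
#' @param x An [RNFLCohort-class].
#' @return A 2 x 7 matrix (rows `right`/`left`, columns TS..NI, G) in
#'   micrometres, with attribute `n` = patient count.
#' @export
cohortSectorMeans <- function(x) {
    stopifnot(is(x, "RNFLCohort"))
    if (ncol(x) == 0) stop("empty cohort")
    m <- rbind(right = rowMeans(rightEye(x)), left = rowMeans(leftEye(x)))
    attr(m, "n") <- ncol(x)
    m
}

#' Compute one asymmetry value
#'
#' Scalar/vector kernel for a single sector: the chosen metric applied to a
#' right/left thickness pair. `refSum` (sum of cohort mean thicknesses for
#' the sector) is required for the `Delta_bar` metrics; `globalSum`
#' (patient's `wG_r + wG_l`) for the `Delta_dbar` metrics.
#'
#' @param wr,wl Right/left sector mean thickness, micrometres (> 0).
#' @param metric One of [asymmetryMetrics()].
#' @param refSum,globalSum Denominators, micrometres; see Details.
#' @return The asymmetry value (micrometres for `delta`/`abs_delta`,
#'   dimensionless otherwise).
#' @examples
#' asymmetryValue(150, 50, "Delta")          # 0.5
#' asymmetryValue(150, 50, "sqrt_abs_Delta") # sqrt(0.5)
#' @export
asymmetryValue <- function(wr, wl, metric = asymmetryMetrics(),
                           refSum = NULL, globalSum = NULL) {
    metric <- match.arg(metric)
    if (any(wr <= 0) || any(wl <= 0))
        stop("thicknesses must be > 0")
    d <- wr - wl
    den <- switch(metric,
        delta = , abs_delta = 1,
        Delta = , abs_Delta = , sqrt_abs_Delta = wr + wl,
        Delta_bar = , abs_Delta_bar = {
            if (is.null(refSum)) stop("'refSum' required for Delta_bar metrics")
            refSum
        },
        Delta_dbar = , abs_Delta_dbar = {
            if (is.null(globalSum)) stop("'globalSum' required for Delta_dbar metrics")
            globalSum
        })
    if (any(den <= 0)) stop("non-positive denominator")
    v <- d / den
    if (metric %in% .SIGNED_METRICS) v
    else if (metric == "sqrt_abs_Delta") sqrt(abs(v))
    else abs(v)
}

#' AsymmetryFeatures: per-patient asymmetry feature matrix
#'
#' One asymmetry metric evaluated for every patient and every feature
#' (TS, T, TI, NS, N, NI, G), stored as a
#' \link[SummarizedExperiment]{SummarizedExperiment} with a single 7 x n
#' assay `asymmetry` and the cohort's diagnosis labels in `colData`. The
#' metric id is kept in `metadata(x)$metric`.
#'
#' @seealso [asymmetryFeatures()], [summarizeGroups()], [growTree()]
#' @aliases AsymmetryFeatures
#' @export
setClass("AsymmetryFeatures", contains = "SummarizedExperiment")

setValidity("AsymmetryFeatures", function(object) {
    msg <- character()
    if (!identical(names(SummarizedExperiment::assays(object)), "asymmetry"))
        return("assay must be 'asymmetry'")
    metric <- S4Vectors::metadata(object)$metric
    if (is.null(metric) || !metric %in% asymmetryMetrics())
        msg <- c(msg, "metadata()$metric must be a known metric id")
    if (!identical(rownames(object), .FEATURES))
        msg <- c(msg, "rows must be TS, T, TI, NS, N, NI, G")
    v <- SummarizedExperiment::assay(object)
    if (length(v) && !is.null(metric) && metric %in% asymmetryMetrics()) {
        rng <- range(v)
        if (metric %in% c("Delta", "Delta_bar", "Delta_dbar") &&
            (rng[1] < -1 || rng[2] > 1))
            msg <- c(msg, "normalized signed values must lie in [-1, 1]")
        if (metric %in% c("abs_Delta", "abs_Delta_bar", "abs_Delta_dbar",
                          "sqrt_abs_Delta") && (rng[1] < 0 || rng[2] > 1))
            msg <- c(msg, "normalized absolute values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Compute an asymmetry feature matrix
#'
#' Applies one metric to every patient and feature of a cohort. For the
#' `Delta_bar` metrics the per-sector denominators default to the cohort's
#' own pooled means ([cohortSectorMeans()]); external reference means may be
#' supplied instead.
#'
#' @param x An [RNFLCohort-class].
#' @param metric One of [asymmetryMetrics()].
#' @param refMeans Optional 2 x 7 matrix as returned by
#'   [cohortSectorMeans()] or [referenceSectorMeans()].
#' @return An [AsymmetryFeatures-class] (7 x n).
#' @examples
#' cohort <- generateCohort(seed = 1)
#' af <- asymmetryFeatures(cohort, "abs_Delta")
#' featureMatrix(af)[1:3, 1:4]
#' @export
asymmetryFeatures <- function(x, metric = asymmetryMetrics(), refMeans = NULL) {
    stopifnot(is(x, "RNFLCohort"))
    metric <- match.arg(metric)
    r <- rightEye(x); l <- leftEye(x)
    d <- r - l
    v <- switch(metric,
        delta = d,
        abs_delta = abs(d),
        Delta = d / (r + l),
        abs_Delta = abs(d) / (r + l),
        sqrt_abs_Delta = sqrt(abs(d) / (r + l)),
        Delta_bar = , abs_Delta_bar = {
            if (is.null(refMeans)) refMeans <- cohortSectorMeans(x)
            sums <- refMeans["right", .FEATURES] + refMeans["left", .FEATURES]
            out <- d / sums  # recycle per-row denominators down columns
            if (metric == "abs_Delta_bar") abs(out) else out
        },
        Delta_dbar = , abs_Delta_dbar = {
            gsum <- r["G", ] + l["G", ]
            out <- sweep(d, 2, gsum, "/")
            if (metric == "abs_Delta_dbar") abs(out) else out
        })
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(asymmetry = v),
        colData = SummarizedExperiment::colData(x),
        metadata = list(metric = metric))
    new("AsymmetryFeatures", se)
}

#' @describeIn AsymmetryFeatures-class the n x 7 feature matrix (patients in
#'   rows, features TS..G in columns) used by statistics and the classifier
#' @param x An `AsymmetryFeatures`.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "asymmetry"))

#' @describeIn AsymmetryFeatures-class the metric id
#' @export
metricId <- function(x) S4Vectors::metadata(x)$metric

setMethod("show", "AsymmetryFeatures", function(object) {
    cat(sprintf("AsymmetryFeatures: metric '%s', %d patients x %d features\n",
                metricId(object), ncol(object), nrow(object)))
})

#' Rescale a delta-scale summary to the Delta_bar scale
#'
#' The `Delta_bar` metric divides every patient's inter-eye difference in a
#' sector by the fixed sum of the cohort mean thicknesses of that sector, so
#' any group mean or standard deviation on the `Delta_bar` scale equals the
#' corresponding `delta`-scale statistic divided by that sum. This helper is
#' the reporting path for converting published micrometre-scale difference
#' statistics into the dimensionless normalized scale.
#'
#' @param value `delta`-scale statistic(s) in micrometres (a mean or SD).
#' @param meanRight,meanLeft Cohort mean thickness of the sector for the
#'   right and left eye, micrometres.
#' @return `value / (meanRight + meanLeft)`.
#' @examples
#' deltaBarLink(2.7563, 128.1691, 126.3527)
#' @export
deltaBarLink <- function(value, meanRight, meanLeft) {
    if (any(meanRight <= 0) || any(meanLeft <= 0))
        stop("mean thicknesses must be > 0")
    value / (meanRight + meanLeft)
}
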