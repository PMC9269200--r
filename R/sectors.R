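#' Peripapillary TSNIT sector geometry
#'
#' The circumpapillary OCT B-scan is divided into six angular sectors:
#' temporal-superior (TS), temporal (T), temporal-inferior (TI),
#' nasal-superior (NS), nasal (N) and nasal-inferior (NI). The temporal and
#' nasal sectors span 90 degrees each, the remaining four 45 degrees, so the
#' six extents cover the full 360 degree contour. `G` denotes the global mean
#' thickness over the whole contour.
#'
#' @return A data.frame with columns `sector` and `degrees`, one row per
#'   sector, in the fixed reporting order TS, T, TI, NS, N, NI.
#' @examples
#' rnflSectors()
#' sum(rnflSectors()$degrees) # 360
#' @export
rnflSectors <- function() {
    data.frame(sector = names(.SECTOR_DEGREES),
               degrees = unname(.SECTOR_DEGREES),
               stringsAsFactors = FALSE)
}

# fixed reporting order for all matrices and outputs
.SECTOR_DEGREES <- c(TS = 45, T = 90, TI = 45, NS = 45, N = 90, NI = 45)
.SECTORS <- names(.SECTOR_DEGREES)
.FEATURES <- c(.SECTORS, "G")

.DIAGNOSIS_LEVELS <- c("healthy", "glaucoma")

#' Angle-weighted global RNFL thickness
#'
#' Computes the global circumpapillary mean thickness `G` as the
#' angle-weighted average of the six sector means: each sector contributes in
#' proportion to its angular extent (90 degrees for T and N, 45 degrees for
#' the rest), i.e. `sum(extent_S * w_S) / 360`.
#'
#' @param thickness Named numeric vector (or a matrix with one row per
#'   sector) of sector mean thicknesses in micrometres. Names must cover all
#'   of TS, T, TI, NS, N, NI; all values must be finite and positive.
#' @return The global mean thickness in micrometres (a numeric vector when a
#'   matrix of per-patient columns is supplied).
#' @examples
#' angleWeightedGlobal(c(TS = 100, T = 100, TI = 100, NS = 100, N = 100, NI = 100))
#' @export
angleWeightedGlobal <- function(thickness) {
    if (is.matrix(thickness)) {
        missing <- setdiff(.SECTORS, rownames(thickness))
        if (length(missing))
            stop("missing sector(s): ", paste(missing, collapse = ", "))
        w <- thickness[.SECTORS, , drop = FALSE]
        if (any(!is.finite(w)) || any(w <= 0))
            stop("all sector thicknesses must be finite and > 0")
        return(as.numeric(.SECTOR_DEGREES %*% w) / 360)
    }
    missing <- setdiff(.SECTORS, names(thickness))
    if (length(missing))
        stop("missing sector(s): ", paste(missing, collapse = ", "))
    w <- thickness[.SECTORS]
    if (any(!is.finite(w)) || any(w <= 0))
        stop("all sector thicknesses must be finite and > 0")
    sum(.SECTOR_DEGREES * w) / 360
}

#' Published cohort calibration statistics
#'
#' Reference statistics of the clinical cohort (160 healthy and 47 glaucoma
#' patients) that the synthetic-cohort generator is calibrated to: per-sector,
#' per-eye dataset mean thicknesses, and per-group means and standard
#' deviations of the inter-eye difference `delta = w_r - w_l` and of its
#' absolute value, for the six sectors and the global contour G.
#'
#' `referenceSectorMeans()` returns a 2 x 7 matrix (rows `right`, `left`;
#' columns TS, T, TI, NS, N, NI, G) of dataset mean thicknesses in
#' micrometres. `referenceDeltaStats()` returns a data.frame with one row per
#' feature and columns for the healthy/glaucoma mean and SD of `delta` and of
#' `|delta|` (micrometres).
#'
#' @return See Details.
#' @examples
#' referenceSectorMeans()["right", "TS"]
#' @name referenceStats
NULL

#' @rdname referenceStats
#' @export
referenceSectorMeans <- function() {
    m <- rbind(
        right = c(128.1691, 68.7826, 130.0773, 101.2029, 74.1932, 106.1353, 93.9469),
        left  = c(126.3527, 68.0531, 132.8454, 109.5266, 70.9469, 106.6957, 93.9710))
    colnames(m) <- .FEATURES
    m
}

#' @rdname referenceStats
#' @export
referenceDeltaStats <- function() {
    data.frame(
        feature = .FEATURES,
        delta_mean_h = c(2.7563, 2.1500, -2.3375, -7.5938, 4.2875, -1.0625, 0.6563),
        delta_sd_h   = c(16.8122, 9.6793, 14.9220, 16.6878, 12.5123, 16.5372, 6.5895),
        delta_mean_g = c(-1.3830, -4.1064, -4.2340, -10.8085, -0.2979, 1.1489, -2.3404),
        delta_sd_g   = c(45.3539, 20.1022, 51.8594, 34.9370, 26.0576, 34.5989, 25.8728),
        abs_delta_mean_h = c(12.7438, 7.0125, 11.7500, 14.3938, 10.0000, 12.8125, 4.2188),
        abs_delta_sd_h   = c(11.2637, 6.9896, 9.4463, 11.3149, 8.6271, 10.4606, 5.0937),
        abs_delta_mean_g = c(34.1489, 15.2979, 40.0213, 27.8298, 17.3617, 26.7660, 20.6383),
        abs_delta_sd_g   = c(29.4522, 13.4987, 32.7291, 23.4227, 19.2641, 21.5973, 15.4855),
        row.names = .FEATURES,
        stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Report-rounding convention used throughout: exact halves move away from
#' zero (unlike [round()], which rounds halves to even).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 4, the reporting precision).
#' @return Rounded numeric.
#' @examples
#' roundHalfUp(0.93125) # 0.9313
#' @export
roundHalfUp <- function(x, digits = 4) {
    sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
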