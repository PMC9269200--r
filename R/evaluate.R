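#' Confusion counts for glaucoma screening
#'
#' Counts the four screening outcomes with glaucoma as the positive class:
#' TP (glaucoma predicted glaucoma), FP (healthy predicted glaucoma),
#' TN (healthy predicted healthy), FN (glaucoma predicted healthy).
#'
#' @param truth,predicted Equal-length vectors/factors of
#'   `healthy`/`glaucoma` labels.
#' @return Named integer vector `c(TP, FP, TN, FN)` of class
#'   `ConfusionCounts`.
#' @examples
#' confusionCounts(c("glaucoma", "glaucoma", "healthy"),
#'                 c("glaucoma", "healthy", "healthy"))
#' @export
confusionCounts <- function(truth, predicted) {
    truth <- as.character(truth); predicted <- as.character(predicted)
    if (length(truth) != length(predicted))
        stop("label vectors differ in length")
    known <- c(truth, predicted) %in% .DIAGNOSIS_LEVELS
    if (!all(known)) stop("unknown label(s): ",
                          paste(unique(c(truth, predicted)[!known]), collapse = ", "))
    out <- c(TP = sum(truth == "glaucoma" & predicted == "glaucoma"),
             FP = sum(truth == "healthy" & predicted == "glaucoma"),
             TN = sum(truth == "healthy" & predicted == "healthy"),
             FN = sum(truth == "glaucoma" & predicted == "healthy"))
    structure(as.integer(out), names = names(out), class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
    print(stats::setNames(as.integer(x), names(x)))
    invisible(x)
}

#' Screening metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity (true positive rate)
#' `TP/(TP+FN)`, specificity (true negative rate) `TN/(TN+FP)` and precision
#' (positive predictive value) `TP/(TP+FP)`. A metric whose denominator is
#' zero is undefined and returned as `NA` with a warning. Values are exact
#' ratios; rounding (half away from zero, 4 decimals) happens only in
#' reports.
#'
#' @param cm A [confusionCounts()] result, or any named vector/list with
#'   `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity,
#'   precision)`.
#' @examples
#' screeningMetrics(c(TP = 33, FP = 11, TN = 149, FN = 14))
#' @export
screeningMetrics <- function(cm) {
    cm <- unlist(cm)[c("TP", "FP", "TN", "FN")]
    if (anyNA(cm) || any(cm < 0)) stop("counts must be non-negative TP/FP/TN/FN")
    ratio <- function(num, den, what) {
        if (den == 0) { warning(what, " undefined (zero denominator)"); return(NA_real_) }
        num / den
    }
    c(accuracy = ratio(cm[["TP"]] + cm[["TN"]], sum(cm), "accuracy"),
      sensitivity = ratio(cm[["TP"]], cm[["TP"]] + cm[["FN"]], "sensitivity"),
      specificity = ratio(cm[["TN"]], cm[["TN"]] + cm[["FP"]], "specificity"),
      precision = ratio(cm[["TP"]], cm[["TP"]] + cm[["FP"]], "precision"))
}

#' Reconstruct integer confusion counts from reported rates
#'
#' Published screening tables report sensitivity and specificity as rounded
#' rates; with the group sizes known, the underlying integer confusion matrix
#' is recovered by rounding `TPR * nGlaucoma` and `TNR * nHealthy` (half away
#' from zero) and taking complements. This bridges printed rate tables back
#' to exact counts so accuracy and precision can be recomputed.
#'
#' @param tpr,tnr Sensitivity and specificity in \[0, 1\].
#' @param nGlaucoma,nHealthy Positive group sizes.
#' @return A `ConfusionCounts` vector.
#' @examples
#' reconstructConfusion(0.7021, 0.9312, 47, 160)
#' @export
reconstructConfusion <- function(tpr, tnr, nGlaucoma, nHealthy) {
    stopifnot(tpr >= 0, tpr <= 1, tnr >= 0, tnr <= 1,
              nGlaucoma > 0, nHealthy > 0)
    tp <- as.integer(roundHalfUp(tpr * nGlaucoma, 0))
    tn <- as.integer(roundHalfUp(tnr * nHealthy, 0))
    if (tp > nGlaucoma || tn > nHealthy)
        stop("rounded counts exceed group sizes")
    structure(c(TP = tp, FP = nHealthy - tn, TN = tn, FN = nGlaucoma - tp),
              class = "ConfusionCounts")
}

#' Evaluation report row
#'
#' Machine-readable twin of a screening performance table: model identifier,
#' split budget, glaucoma weight, the four counts and the four metrics
#' rounded half away from zero to 4 decimals.
#'
#' @param modelId Character tag (e.g. the metric id).
#' @param maxSplits,weightGlaucoma Training configuration.
#' @param cm A `ConfusionCounts`.
#' @return One-row data.frame.
#' @export
evaluationReport <- function(modelId, maxSplits, weightGlaucoma, cm) {
    m <- screeningMetrics(cm)
    data.frame(model = modelId, max_splits = maxSplits, w_g = weightGlaucoma,
               TP = cm[["TP"]], FP = cm[["FP"]], TN = cm[["TN"]], FN = cm[["FN"]],
               ACC = roundHalfUp(m[["accuracy"]], 4),
               TPR = roundHalfUp(m[["sensitivity"]], 4),
               TNR = roundHalfUp(m[["specificity"]], 4),
               PPV = roundHalfUp(m[["precision"]], 4),
               stringsAsFactors = FALSE)
}
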