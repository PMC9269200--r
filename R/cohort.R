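#' RNFLCohort: paired-eye sector thickness data
#'
#' An `RNFLCohort` holds one cohort of patients with both eyes measured by
#' peripapillary OCT. It extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with two assays, `right`
#' and `left`, each a 7 x n matrix of mean RNFL thicknesses in micrometres
#' (rows TS, T, TI, NS, N, NI, G; one column per patient). Column data carry
#' the per-patient diagnosis (`label`, a factor with levels `healthy` and
#' `glaucoma`) and optional `age` and `gender`.
#'
#' Validity requires: exactly the seven canonical feature rows; identical
#' dimnames on both assays; unique patient identifiers (colnames); all
#' thicknesses finite and positive; a `label` column with only the two
#' diagnosis levels. One diagnosis applies to both eyes of a patient; cohorts
#' never mix diagnoses within a patient.
#'
#' @slot gSupplied logical; `TRUE` when the global thickness G was supplied
#'   by the device rather than computed as the angle-weighted sector mean.
#'
#' @seealso [readCohortCsv()], [generateCohort()], [asymmetryFeatures()]
#' @aliases RNFLCohort
#' @export
setClass("RNFLCohort",
    contains = "SummarizedExperiment",
    representation(gSupplied = "logical"),
    prototype(gSupplied = FALSE))

setValidity("RNFLCohort", function(object) {
    msg <- character()
    if (!identical(sort(names(SummarizedExperiment::assays(object))),
                   sort(c("right", "left"))))
        return("assays must be exactly 'right' and 'left'")
    r <- SummarizedExperiment::assay(object, "right")
    l <- SummarizedExperiment::assay(object, "left")
    if (!identical(rownames(object), .FEATURES))
        msg <- c(msg, sprintf("rows must be exactly %s",
                              paste(.FEATURES, collapse = ", ")))
    if (ncol(object) > 0) {
        if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
            msg <- c(msg, "patient ids (colnames) must be present and unique")
        if (any(!is.finite(r)) || any(r <= 0) || any(!is.finite(l)) || any(l <= 0))
            msg <- c(msg, "all thicknesses must be finite and > 0")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"label" %in% names(cd))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(as.character(cd$label) %in% .DIAGNOSIS_LEVELS))
        msg <- c(msg, "labels must be 'healthy' or 'glaucoma'")
    if (length(msg)) msg else TRUE
})

#' Construct an RNFLCohort
#'
#' @param right,left 7 x n (or 6 x n, without G) numeric matrices of sector
#'   mean thicknesses in micrometres; rownames must name the sectors. When
#'   the G row is absent it is computed with [angleWeightedGlobal()].
#' @param label Character or factor vector of per-patient diagnoses
#'   (`healthy`/`glaucoma`).
#' @param patientId Optional character vector of unique patient identifiers;
#'   defaults to the matrix colnames, or `P1..Pn`.
#' @param age,gender Optional per-patient covariates (carried, never used as
#'   features).
#' @return An [RNFLCohort-class] object.
#' @examples
#' w <- matrix(100, 6, 2, dimnames = list(c("TS","T","TI","NS","N","NI"), NULL))
#' RNFLCohort(right = w, left = w, label = c("healthy", "glaucoma"))
#' @export
RNFLCohort <- function(right, left, label, patientId = NULL,
                       age = NULL, gender = NULL) {
    right <- .completeThickness(as.matrix(right))
    left <- .completeThickness(as.matrix(left))
    gSupplied <- attr(right, "gSupplied") && attr(left, "gSupplied")
    attr(right, "gSupplied") <- NULL
    attr(left, "gSupplied") <- NULL
    n <- ncol(right)
    if (ncol(left) != n)
        stop("'right' and 'left' must have the same number of patients")
    if (is.null(patientId))
        patientId <- if (!is.null(colnames(right))) colnames(right)
                     else paste0("P", seq_len(n))
    label <- factor(as.character(label), levels = .DIAGNOSIS_LEVELS)
    if (length(label) != n || anyNA(label))
        stop("'label' must give 'healthy' or 'glaucoma' for every patient")
    colnames(right) <- colnames(left) <- patientId
    cd <- S4Vectors::DataFrame(label = label, row.names = patientId)
    if (!is.null(age)) cd$age <- as.numeric(age)
    if (!is.null(gender)) cd$gender <- as.character(gender)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(right = right, left = left), colData = cd)
    new("RNFLCohort", se, gSupplied = gSupplied)
}

# order rows canonically; compute G when missing
.completeThickness <- function(m) {
    if (is.null(rownames(m)))
        stop("thickness matrices must have sector rownames")
    missing <- setdiff(.SECTORS, rownames(m))
    if (length(missing))
        stop("missing sector(s): ", paste(missing, collapse = ", "))
    if ("G" %in% rownames(m)) {
        out <- m[.FEATURES, , drop = FALSE]
        attr(out, "gSupplied") <- TRUE
    } else {
        out <- rbind(m[.SECTORS, , drop = FALSE],
                     G = angleWeightedGlobal(m))
        attr(out, "gSupplied") <- FALSE
    }
    out
}

#' @describeIn RNFLCohort-class right-eye thickness matrix (7 x n, micrometres)
#' @param x,object An `RNFLCohort`.
#' @export
rightEye <- function(x) SummarizedExperiment::assay(x, "right")

#' @describeIn RNFLCohort-class left-eye thickness matrix (7 x n, micrometres)
#' @export
leftEye <- function(x) SummarizedExperiment::assay(x, "left")

#' @describeIn RNFLCohort-class per-patient diagnosis factor
#' @export
diagnosis <- function(x) SummarizedExperiment::colData(x)$label

#' @describeIn RNFLCohort-class number of patients
#' @export
nPatients <- function(x) ncol(x)

#' @describeIn RNFLCohort-class patient counts per diagnosis
#' @export
diagnosisCounts <- function(x) table(diagnosis(x))

setMethod("show", "RNFLCohort", function(object) {
    cts <- diagnosisCounts(object)
    cat(sprintf("RNFLCohort: %d patients (%d healthy, %d glaucoma)\n",
                ncol(object), cts[["healthy"]], cts[["glaucoma"]]))
    cat(sprintf("  sectors: %s; G %s\n", paste(.SECTORS, collapse = " "),
                if (object@gSupplied) "supplied" else "angle-weighted"))
})

#' Read a paired-eye cohort from CSV
#'
#' The file is long format, one row per eye, with header exactly
#' `patient_id,eye,label,TS,T,TI,NS,N,NI,G` (`eye` in `right`/`left`,
#' `label` in `healthy`/`glaucoma`, thicknesses in micrometres). The `G`
#' column may be empty or absent, in which case the global mean is computed
#' as the angle-weighted sector mean. Optional `age`/`gender` columns are
#' carried through. Rows are merged into patients; a patient must contribute
#' exactly one right and one left eye with a single diagnosis.
#'
#' @param path Path to a CSV file.
#' @return An [RNFLCohort-class].
#' @export
readCohortCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "eye", "label", .SECTORS)
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    if (nrow(df) == 0) stop("empty cohort file: ", path)
    if (!all(df$eye %in% c("right", "left")))
        stop("'eye' must be 'right' or 'left' (lowercase)")
    bad <- !df$label %in% .DIAGNOSIS_LEVELS
    if (any(bad))
        stop("unknown label in row(s): ", paste(which(bad), collapse = ", "))
    key <- paste(df$patient_id, df$eye)
    if (anyDuplicated(key))
        stop("duplicate (patient, eye) row(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    split_eyes <- split(seq_len(nrow(df)), df$patient_id)
    one_eyed <- names(split_eyes)[vapply(split_eyes, length, 1L) != 2L]
    if (length(one_eyed))
        stop("patient(s) without both eyes: ", paste(one_eyed, collapse = ", "))
    mixed <- names(split_eyes)[vapply(split_eyes, function(i)
        length(unique(df$label[i])) != 1L, logical(1))]
    if (length(mixed))
        stop("mixed diagnosis within patient(s): ", paste(mixed, collapse = ", "))
    ids <- unique(df$patient_id)  # preserve file order
    ri <- match(paste(ids, "right"), key)
    li <- match(paste(ids, "left"), key)
    hasG <- "G" %in% names(df) && !all(is.na(df$G))
    feat <- if (hasG) .FEATURES else .SECTORS
    right <- t(as.matrix(df[ri, feat, drop = FALSE]))
    left <- t(as.matrix(df[li, feat, drop = FALSE]))
    rownames(right) <- rownames(left) <- feat
    RNFLCohort(right, left, label = df$label[ri], patientId = ids,
               age = if ("age" %in% names(df)) df$age[ri],
               gender = if ("gender" %in% names(df)) df$gender[ri])
}

#' Write a cohort to CSV
#'
#' Inverse of [readCohortCsv()]: writes one row per eye with the canonical
#' header, thicknesses printed with six decimals. Reading the file back
#' reproduces the cohort to that precision.
#'
#' @param x An [RNFLCohort-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(x, path) {
    stopifnot(is(x, "RNFLCohort"))
    ids <- colnames(x)
    cd <- SummarizedExperiment::colData(x)
    n <- length(ids)
    mk <- function(eye, m) {
        df <- data.frame(patient_id = ids, eye = eye,
                         label = as.character(cd$label),
                         stringsAsFactors = FALSE)
        for (f in .FEATURES) df[[f]] <- sprintf("%.6f", m[f, ])
        if (!is.null(cd$age)) df$age <- cd$age
        if (!is.null(cd$gender)) df$gender <- cd$gender
        df
    }
    out <- rbind(mk("right", rightEye(x)), mk("left", leftEye(x)))
    out <- out[order(match(out$patient_id, ids)), , drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
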