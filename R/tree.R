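#' Weighted Gini impurity
#'
#' Gini impurity of a node from the summed observation weights of each class:
#' `1 - p_h^2 - p_g^2` with `p_c = W_c / (W_h + W_g)`. With per-class
#' observation weights this is the class-weighted impurity the tree grower
#' minimizes.
#'
#' @param wh,wg Non-negative summed weights of the healthy and glaucoma
#'   observations in the node; not both zero.
#' @return Impurity in \[0, 0.5\].
#' @examples
#' weightedGini(1, 1)   # 0.5
#' weightedGini(1, 1.5) # 0.48
#' @export
weightedGini <- function(wh, wg) {
    if (any(wh < 0) || any(wg < 0)) stop("weights must be >= 0")
    tot <- wh + wg
    if (any(tot == 0)) stop("node has zero total weight")
    1 - (wh / tot)^2 - (wg / tot)^2
}

#' Best single split of a node
#'
#' Exhaustively scans every feature; candidate thresholds are the midpoints
#' between consecutive distinct sorted values. Returns the split maximizing
#' the node-relative weighted-Gini decrease
#' `I(node) - (W_L/W) I(left) - (W_R/W) I(right)`, with `value < threshold`
#' routed left. Ties are broken by lowest feature index, then smallest
#' threshold.
#'
#' @param x Numeric matrix, observations in rows, features in columns.
#' @param y Factor of labels (`healthy`/`glaucoma`).
#' @param weights Positive per-observation weights.
#' @return A list `(feature, threshold, decrease)` or `NULL` when the node is
#'   pure or no feature varies.
#' @export
bestSplit <- function(x, y, weights = rep(1, nrow(x))) {
    x <- as.matrix(x)
    y <- factor(as.character(y), levels = .DIAGNOSIS_LEVELS)
    isg <- y == "glaucoma"
    W <- sum(weights)
    wg_tot <- sum(weights[isg]); wh_tot <- W - wg_tot
    if (wh_tot == 0 || wg_tot == 0) return(NULL)  # pure node
    parent <- weightedGini(wh_tot, wg_tot)
    best <- NULL
    for (j in seq_len(ncol(x))) {
        v <- x[, j]
        ord <- order(v)
        vs <- v[ord]
        wh <- ifelse(isg[ord], 0, weights[ord])
        wg <- ifelse(isg[ord], weights[ord], 0)
        cwh <- cumsum(wh); cwg <- cumsum(wg)
        cut <- which(diff(vs) > 0)  # split after position i
        for (i in cut) {
            WL <- cwh[i] + cwg[i]; WR <- W - WL
            iL <- weightedGini(cwh[i], cwg[i])
            iR <- weightedGini(max(0, wh_tot - cwh[i]), max(0, wg_tot - cwg[i]))
            dec <- parent - (WL / W) * iL - (WR / W) * iR
            thr <- unname((vs[i] + vs[i + 1]) / 2)
            if (is.null(best) || dec > best$decrease + 1e-12)
                best <- list(feature = j, threshold = thr, decrease = dec)
        }
    }
    if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
    best
}

#' AsymmetryTree: a budgeted binary classification tree
#'
#' A CART-style binary classification tree over the seven asymmetry features,
#' grown best-first under a maximum-number-of-splits budget with per-class
#' observation weights. Internal nodes route `value < threshold` left; leaves
#' predict the class with the larger weighted proportion.
#'
#' @slot root Recursive list representation of the tree (split nodes carry
#'   `feature`, `threshold`, `left`, `right`; leaves carry `label`,
#'   `proportions`, `n_train`).
#' @slot featureNames Column names the tree was trained on.
#' @slot config Training configuration (`maxSplits`, `classWeights`,
#'   `metric` when known).
#' @slot nSplits Number of split nodes actually placed (<= `maxSplits`).
#' @seealso [growTree()], [treeRules()], [cvLoss()]
#' @aliases AsymmetryTree
#' @export
setClass("AsymmetryTree",
    representation(root = "list", featureNames = "character",
                   config = "list", nSplits = "integer"))

# leaf from weighted class masses; ties predict healthy
.makeLeaf <- function(wh, wg, n) {
    tot <- wh + wg
    list(leaf = TRUE,
         label = if (wg > wh) "glaucoma" else "healthy",
         proportions = c(healthy = wh / tot, glaucoma = wg / tot),
         n_train = n)
}

#' Grow a classification tree
#'
#' Best-first growth: at every step the candidate best split ([bestSplit()])
#' of each current leaf is evaluated and the leaf whose split yields the
#' largest mass-weighted impurity decrease (`W_leaf` times the node-relative
#' decrease) is split, until `maxSplits` splits are placed or no leaf
#' improves. Each observation carries its class weight, normalized so all
#' training weights sum to 1; `classWeights = c(healthy = 1, glaucoma = 1.5)`
#' makes glaucoma misclassifications costlier and shifts leaves toward the
#' glaucoma label.
#'
#' @param x An [AsymmetryFeatures-class], or a numeric matrix (observations
#'   in rows) with `labels` supplied.
#' @param labels Factor/character of `healthy`/`glaucoma` labels (ignored
#'   when `x` is an `AsymmetryFeatures`).
#' @param maxSplits Split budget, >= 1.
#' @param classWeights Named positive weights for `healthy` and `glaucoma`.
#' @return An [AsymmetryTree-class].
#' @examples
#' cohort <- generateCohort(seed = 1)
#' af <- asymmetryFeatures(cohort, "sqrt_abs_Delta")
#' tr <- growTree(af, maxSplits = 3, classWeights = c(healthy = 1, glaucoma = 1.5))
#' tr
#' @export
growTree <- function(x, labels = NULL, maxSplits = 3,
                     classWeights = c(healthy = 1, glaucoma = 1)) {
    if (is(x, "AsymmetryFeatures")) {
        labels <- diagnosis(x)
        metric <- metricId(x)
        x <- featureMatrix(x)
    } else metric <- NA_character_
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        colnames(x) <- paste0("f", seq_len(ncol(x)))
    y <- factor(as.character(labels), levels = .DIAGNOSIS_LEVELS)
    if (anyNA(y) || length(y) != nrow(x))
        stop("'labels' must give healthy/glaucoma for every row")
    maxSplits <- as.integer(maxSplits)
    if (maxSplits < 1) stop("'maxSplits' must be >= 1")
    if (any(classWeights <= 0) ||
        !all(c("healthy", "glaucoma") %in% names(classWeights)))
        stop("'classWeights' must be positive and named healthy/glaucoma")
    w <- unname(classWeights[as.character(y)])
    w <- w / sum(w)

    # growing front: each entry one leaf with its cached candidate split
    mkNode <- function(idx) {
        wh <- sum(w[idx][y[idx] == "healthy"])
        wg <- sum(w[idx][y[idx] == "glaucoma"])
        cand <- if (length(idx) >= 2) bestSplit(x[idx, , drop = FALSE], y[idx], w[idx])
                else NULL
        list(idx = idx, wh = wh, wg = wg,
             cand = cand,
             gain = if (is.null(cand)) -Inf else (wh + wg) * cand$decrease)
    }
    front <- list(mkNode(seq_len(nrow(x))))
    # tree as a flat list of nodes; children referenced by index
    nodes <- list(NULL)
    front_at <- 1L  # front[[k]] will become nodes[[which]]
    front_pos <- c(1L)
    nsplit <- 0L
    while (nsplit < maxSplits) {
        gains <- vapply(front, `[[`, numeric(1), "gain")
        k <- which.max(gains)  # earliest leaf wins ties (deterministic)
        if (!length(gains) || gains[k] <= 1e-15) break
        nd <- front[[k]]
        sp <- nd$cand
        goL <- x[nd$idx, sp$feature] < sp$threshold
        li <- nd$idx[goL]; ri <- nd$idx[!goL]
        posL <- length(nodes) + 1L; posR <- length(nodes) + 2L
        nodes[[posL]] <- NA; nodes[[posR]] <- NA  # reserve
        nodes[[front_pos[k]]] <- list(leaf = FALSE, feature = sp$feature,
                                      threshold = sp$threshold,
                                      left = posL, right = posR)
        front <- c(front[-k], list(mkNode(li), mkNode(ri)))
        front_pos <- c(front_pos[-k], posL, posR)
        nsplit <- nsplit + 1L
    }
    for (k in seq_along(front)) {
        nd <- front[[k]]
        nodes[[front_pos[k]]] <- .makeLeaf(nd$wh, nd$wg, length(nd$idx))
    }
    # materialize the recursive structure from node 1
    build <- function(i) {
        nd <- nodes[[i]]
        if (isTRUE(nd$leaf)) return(nd)
        list(leaf = FALSE, feature = colnames(x)[nd$feature],
             threshold = nd$threshold,
             left = build(nd$left), right = build(nd$right))
    }
    new("AsymmetryTree", root = build(1L), featureNames = colnames(x),
        config = list(maxSplits = maxSplits,
                      classWeights = classWeights, metric = metric),
        nSplits = nsplit)
}

#' @describeIn AsymmetryTree-class number of split nodes in the fitted tree
#' @param x,object An `AsymmetryTree`.
#' @export
nSplits <- function(x) x@nSplits

.predictRow <- function(node, row) {
    while (!isTRUE(node$leaf))
        node <- if (row[[node$feature]] < node$threshold) node$left else node$right
    node$label
}

#' Predict diagnoses with a fitted tree
#'
#' Root-to-leaf descent per observation; `value < threshold` goes left,
#' values exactly equal to a threshold go right.
#'
#' @param object An [AsymmetryTree-class].
#' @param newdata An [AsymmetryFeatures-class] or a matrix/data.frame with
#'   the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels (`healthy`/`glaucoma`).
#' @export
setMethod("predict", "AsymmetryTree", function(object, newdata, ...) {
    if (is(newdata, "AsymmetryFeatures")) newdata <- featureMatrix(newdata)
    newdata <- as.matrix(newdata)
    missing <- setdiff(object@featureNames, colnames(newdata))
    if (length(missing))
        stop("missing feature(s): ", paste(missing, collapse = ", "))
    out <- vapply(seq_len(nrow(newdata)), function(i)
        .predictRow(object@root, as.list(newdata[i, ])), character(1))
    factor(out, levels = .DIAGNOSIS_LEVELS)
})

#' Cross-validated classification loss
#'
#' Stratified k-fold cross-validation of [growTree()]: folds are drawn per
#' class from a seeded shuffle, each fold is predicted by a tree trained on
#' the remaining folds, and the loss is the sum of the normalized weights of
#' the misclassified held-out observations (weights normalized over the full
#' dataset, so the loss lies in \[0, 1\]). With `lossWeighted = FALSE` the
#' class weights still shape training but the reported loss is the plain
#' misclassification proportion.
#'
#' @inheritParams growTree
#' @param nFolds Number of folds (default 5); every class must have at least
#'   `nFolds` members.
#' @param seed Integer seed for the fold shuffle.
#' @param lossWeighted Use class-weighted loss (default) or raw error rate.
#' @return The cross-validated loss, a number in \[0, 1\].
#' @export
cvLoss <- function(x, labels = NULL, maxSplits = 3,
                   classWeights = c(healthy = 1, glaucoma = 1),
                   nFolds = 5, seed = 1, lossWeighted = TRUE) {
    if (is(x, "AsymmetryFeatures")) {
        labels <- diagnosis(x)
        x <- featureMatrix(x)
    }
    x <- as.matrix(x)
    y <- factor(as.character(labels), levels = .DIAGNOSIS_LEVELS)
    n <- nrow(x)
    if (any(table(y) < nFolds))
        stop("every class needs at least 'nFolds' members for stratification")
    w <- unname(classWeights[as.character(y)])
    if (!lossWeighted) w <- rep(1, n)
    w <- w / sum(w)
    fold <- integer(n)
    set.seed(seed)
    for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    loss <- 0
    for (k in seq_len(nFolds)) {
        train <- fold != k
        tr <- growTree(x[train, , drop = FALSE], y[train],
                       maxSplits = maxSplits, classWeights = classWeights)
        pred <- predict(tr, x[!train, , drop = FALSE])
        loss <- loss + sum(w[!train][pred != y[!train]])
    }
    loss
}

#' In-sample weighted training loss of a tree
#'
#' Sum of normalized class weights of the misclassified training
#' observations — the quantity the split budget trades off against.
#'
#' @inheritParams growTree
#' @param tree An [AsymmetryTree-class].
#' @return Loss in \[0, 1\].
#' @export
trainingLoss <- function(tree, x, labels = NULL,
                         classWeights = tree@config$classWeights) {
    if (is(x, "AsymmetryFeatures")) {
        labels <- diagnosis(x)
        x <- featureMatrix(x)
    }
    y <- factor(as.character(labels), levels = .DIAGNOSIS_LEVELS)
    w <- unname(classWeights[as.character(y)])
    w <- w / sum(w)
    sum(w[predict(tree, x) != y])
}

#' Clinician-readable if-then rules
#'
#' @param tree An [AsymmetryTree-class].
#' @return Character vector, one indented line per node.
#' @export
treeRules <- function(tree) {
    rec <- function(node, depth) {
        pad <- strrep("  ", depth)
        if (isTRUE(node$leaf))
            return(sprintf("%spredict %s (healthy %.3f, glaucoma %.3f, n=%d)",
                           pad, node$label, node$proportions[["healthy"]],
                           node$proportions[["glaucoma"]], node$n_train))
        c(sprintf("%sif %s < %.6g then", pad, node$feature, node$threshold),
          rec(node$left, depth + 1),
          sprintf("%selse (%s >= %.6g)", pad, node$feature, node$threshold),
          rec(node$right, depth + 1))
    }
    rec(tree@root, 0)
}

setMethod("show", "AsymmetryTree", function(object) {
    cat(sprintf("AsymmetryTree: %d split(s) (budget %d), weights h=%g g=%g%s\n",
                object@nSplits, object@config$maxSplits,
                object@config$classWeights[["healthy"]],
                object@config$classWeights[["glaucoma"]],
                if (is.na(object@config$metric)) ""
                else sprintf(", metric '%s'", object@config$metric)))
    cat(treeRules(object), sep = "\n")
})

#' Serialize a tree to / from JSON
#'
#' Plain JSON mirror of the node structure so trained screening rules can be
#' stored, exchanged and printed without R.
#'
#' @param tree An [AsymmetryTree-class].
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `treeToJson`: the path (invisibly) or a JSON string;
#'   `treeFromJson`: an [AsymmetryTree-class].
#' @export
treeToJson <- function(tree, path = NULL) {
    # jsonlite drops names on atomic vectors; keep them as JSON objects
    listify <- function(node) {
        if (isTRUE(node$leaf)) { node$proportions <- as.list(node$proportions); node }
        else { node$left <- listify(node$left); node$right <- listify(node$right); node }
    }
    config <- tree@config
    config$classWeights <- as.list(config$classWeights)
    payload <- list(root = listify(tree@root), featureNames = tree@featureNames,
                    config = config, nSplits = tree@nSplits)
    js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
    if (is.null(path)) return(as.character(js))
    writeLines(js, path)
    invisible(path)
}

#' @rdname treeToJson
#' @param json A path to a JSON file written by [treeToJson()], or the JSON
#'   string itself.
#' @export
treeFromJson <- function(json) {
    payload <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
    fix <- function(node) {
        if (isTRUE(node$leaf)) {
            node$proportions <- unlist(node$proportions)
            node$n_train <- as.integer(node$n_train)
            return(node)
        }
        node$left <- fix(node$left); node$right <- fix(node$right)
        node
    }
    cw <- unlist(payload$config$classWeights)
    new("AsymmetryTree", root = fix(payload$root),
        featureNames = as.character(payload$featureNames),
        config = list(maxSplits = as.integer(payload$config$maxSplits),
                      classWeights = cw,
                      metric = if (is.null(payload$config$metric)) NA_character_
                               else payload$config$metric),
        nSplits = as.integer(payload$nSplits))
}
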