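#' ROC curve and AUC from class scores
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order (tied scores form a single step), yielding an ROC polyline from
#' (0,0) to (1,1); the AUC is its trapezoidal area, which equals the
#' Mann-Whitney concordance probability (ties counted half).
#'
#' @param scores numeric class scores (larger = more positive).
#' @param labels class labels, same length.
#' @param positiveClass label treated as positive.
#' @return list with `points` (two-column fpr/tpr matrix) and `auc`.
#' @export
rocCurve <- function(scores, labels, positiveClass) {
    labels <- as.character(labels)
    pos <- labels == positiveClass
    P <- sum(pos); N <- sum(!pos)
    if (P == 0L || N == 0L)
        stop("undefined ROC: both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- pos[ord]
    lastOfTie <- c(s[-1L] != s[-length(s)], TRUE)
    tp <- cumsum(p)[lastOfTie]
    fp <- cumsum(!p)[lastOfTie]
    pts <- cbind(fpr = c(0, fp / N), tpr = c(0, tp / P))
    auc <- sum(diff(pts[, 1L]) * (pts[-1L, 2L] + pts[-nrow(pts), 2L]) / 2)
    list(points = pts, auc = auc)
}

#' Confusion-matrix metrics for the positive class
#'
#' Precision, recall, F1 and accuracy of hard predictions against the
#' truth; degenerate denominators fall back to 0 with a warning.
#'
#' @param truth,predicted class labels.
#' @param positiveClass label treated as positive.
#' @return named numeric: `precision`, `recall`, `f1`, `accuracy`.
#' @examples
#' confusionMetrics(rep(c("A","B"), c(9, 12)),
#'                  rep(c("A","B","B"), c(10, 1, 10)), "A")
#' @export
confusionMetrics <- function(truth, predicted, positiveClass) {
    truth <- as.character(truth); predicted <- as.character(predicted)
    tp <- sum(predicted == positiveClass & truth == positiveClass)
    fp <- sum(predicted == positiveClass & truth != positiveClass)
    fn <- sum(predicted != positiveClass & truth == positiveClass)
    precision <- if (tp + fp > 0) tp / (tp + fp) else {
        warning("no positive predictions; precision set to 0"); 0 }
    recall <- if (tp + fn > 0) tp / (tp + fn) else {
        warning("no positive truths; recall set to 0"); 0 }
    f1 <- if (precision + recall > 0)
        2 * precision * recall / (precision + recall) else 0
    c(precision = precision, recall = recall, f1 = f1,
      accuracy = mean(predicted == truth))
}

#' Score a fitted model into a ModelReport
#'
#' Computes the comparison metrics for one fitted strategy: accuracy on
#' the train and test partitions, precision/recall/F1 for the positive
#' class on the test set, AUC by trapezoidal integration of the ROC of
#' the test-set class scores, and out-of-bag accuracy for random
#' forests. The positive class defaults to the alphabetically first
#' group label.
#'
#' @param model a `FusionModel` from [trainClassifier()].
#' @param fused design matrix covering at least train and test rows.
#' @param labels named labels (names = sample ids).
#' @param partition a [partitionModelSet()] result.
#' @param modelName name recorded in the report.
#' @param positiveClass positive label (default: first alphabetically).
#' @param seed seed recorded in the report.
#' @param digest config digest recorded in the report.
#' @return a [ModelReport-class].
#' @export
scoreModel <- function(model, fused, labels, partition, modelName = "model",
                       positiveClass = NULL, seed = 1L, digest = "") {
    if (length(partition$test) == 0L) stop("empty test set")
    if (is.null(positiveClass))
        positiveClass <- sort(unique(as.character(
            labels[c(partition$train, partition$test)])))[1L]
    trX <- fused[partition$train, , drop = FALSE]
    teX <- fused[partition$test, , drop = FALSE]
    trY <- labels[partition$train]; teY <- labels[partition$test]
    accTrain <- mean(predictClassOf(model, trX) == as.character(trY))
    predTest <- predictClassOf(model, teX)
    bm <- confusionMetrics(teY, predTest, positiveClass)
    sc <- predictScoresOf(model, teX, positiveClass)
    if (length(unique(sc)) <= 2L && all(sc %in% c(0, 1)))
        warning("model lacks continuous scores; AUC computed from 0/1 predictions")
    roc <- rocCurve(sc, teY, positiveClass)
    new("ModelReport", modelName = modelName,
        oob = oobAccuracy(model, trY),
        accuracyTrain = accTrain, accuracyTest = unname(bm["accuracy"]),
        precision = unname(bm["precision"]), recall = unname(bm["recall"]),
        f1 = unname(bm["f1"]), auc = roc$auc, rocPoints = roc$points,
        positiveClass = positiveClass, seed = as.integer(seed),
        configDigest = digest)
}

#' Compare fusion strategies
#'
#' Collects reports into one comparison table sorted by (AUC, test
#' accuracy) descending and names the best model.
#'
#' @param reports list of [ModelReport-class].
#' @return list with `table` (one row per strategy, the seven metric
#'   columns) and `best` (name of the top-ranked model).
#' @export
compareStrategies <- function(reports) {
    stopifnot(length(reports) >= 1L)
    tab <- do.call(rbind, lapply(reports, function(r)
        data.frame(model = r@modelName, t(metrics(r)),
                   stringsAsFactors = FALSE)))
    tab <- tab[order(-tab$auc, -tab$accuracy_test), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab, best = tab$model[1L])
}

#' Serialize / restore a ModelReport
#'
#' Lossless JSON round trip of the report (metrics, ROC points,
#' provenance).
#'
#' @param report a [ModelReport-class].
#' @param path file path.
#' @return `readModelReport` returns the restored [ModelReport-class].
#' @export
writeModelReport <- function(report, path) {
    obj <- list(model_name = report@modelName, oob = report@oob,
                accuracy_train = report@accuracyTrain,
                accuracy_test = report@accuracyTest,
                precision = report@precision, recall = report@recall,
                f1 = report@f1, auc = report@auc,
                roc_fpr = report@rocPoints[, 1L],
                roc_tpr = report@rocPoints[, 2L],
                positive_class = report@positiveClass,
                seed = report@seed, config_digest = report@configDigest)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModelReport
#' @export
readModelReport <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("ModelReport", modelName = o$model_name,
        oob = as.numeric(o$oob), accuracyTrain = o$accuracy_train,
        accuracyTest = o$accuracy_test, precision = o$precision,
        recall = o$recall, f1 = o$f1, auc = o$auc,
        rocPoints = cbind(fpr = o$roc_fpr, tpr = o$roc_tpr),
        positiveClass = o$positive_class, seed = as.integer(o$seed),
        configDigest = o$config_digest)
}
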