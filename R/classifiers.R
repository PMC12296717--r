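#' Train one of the workflow's classifiers
#'
#' Fits a single classifier on a (standardized or feature-extracted)
#' design matrix under the workflow's reference settings: SVM with
#' radial-basis kernel, k-nearest-neighbour with k = 3 and Euclidean
#' distance, a 500/200/10 feed-forward neural network, a Gini decision
#' tree, a 100-tree random forest, or the projection models PCA and
#' PLS-DA with 2 components (PCA classifies by nearest group centroid in
#' score space; PLS-DA by its maximum predicted indicator).
#'
#' @param x numeric matrix, samples x features (train set only).
#' @param labels factor or character of class labels (two classes).
#' @param classifier one of `"SVM"`, `"kNN"`, `"NN"`, `"DT"`, `"RF"`,
#'   `"PCA"`, `"PLSDA"`.
#' @param seed integer seed (forest bootstraps, network init).
#' @param nnMaxIter gradient steps for the neural network.
#' @return a `FusionModel` object; use [predictClassOf()] /
#'   [predictScoresOf()] on new data.
#' @export
trainClassifier <- function(x, labels,
                            classifier = c("SVM", "kNN", "NN", "DT", "RF",
                                           "PCA", "PLSDA"),
                            seed = 1L, nnMaxIter = 150L) {
    classifier <- match.arg(classifier)
    if (!is.matrix(x)) x <- as.matrix(x)
    if (any(!is.finite(x))) stop("invalid input: non-finite values in design matrix")
    y <- factor(labels)
    if (nrow(x) != length(y)) stop("invalid input: labels do not match rows")
    if (classifier != "PCA" && nlevels(y) < 2L)
        stop("invalid labels: need two classes in the training labels")
    if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
    vmap <- stats::setNames(colnames(x), sprintf("V%d", seq_len(ncol(x))))
    set.seed(seed)
    fit <- switch(classifier,
        SVM = e1071::svm(x = x, y = y, kernel = "radial", scale = FALSE),
        kNN = list(train = x, cl = y),
        NN  = mlpFit(x, y, maxIter = nnMaxIter, seed = seed),
        DT  = {
            df <- as.data.frame(x); names(df) <- names(vmap)
            df$.y <- y
            rpart::rpart(.y ~ ., data = df, method = "class",
                         parms = list(split = "gini"))
        },
        RF  = randomForest::randomForest(x = x, y = y, ntree = 100L),
        PCA = {
            pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
            k <- min(2L, ncol(pc$x))
            sc <- pc$x[, seq_len(k), drop = FALSE]
            cen <- do.call(rbind, lapply(levels(y), function(g)
                colMeans(sc[y == g, , drop = FALSE])))
            rownames(cen) <- levels(y)
            list(pca = pc, k = k, centroids = cen)
        },
        PLSDA = mixOmics::plsda(X = x, Y = y,
                                ncomp = min(2L, ncol(x), nrow(x) - 1L)))
    structure(list(classifier = classifier, fit = fit, levels = levels(y),
                   vmap = vmap, seed = seed),
              class = "FusionModel")
}

#' Predicted class labels
#' @param model a `FusionModel` from [trainClassifier()].
#' @param newdata numeric matrix with the training columns.
#' @return character vector of predicted labels.
#' @export
predictClassOf <- function(model, newdata) {
    stopifnot(inherits(model, "FusionModel"))
    if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
    cls <- model$classifier
    out <- switch(cls,
        SVM = as.character(stats::predict(model$fit, newdata)),
        kNN = as.character(class::knn(model$fit$train, newdata,
                                      model$fit$cl, k = 3L)),
        NN  = model$levels[max.col(mlpProb(model$fit, newdata))],
        DT  = {
            df <- as.data.frame(newdata); names(df) <- names(model$vmap)
            as.character(stats::predict(model$fit, df, type = "class"))
        },
        RF  = as.character(stats::predict(model$fit, newdata)),
        PCA = {
            f <- model$fit
            sc <- scale(newdata, center = f$pca$center, scale = FALSE) %*%
                f$pca$rotation[, seq_len(f$k), drop = FALSE]
            d <- vapply(rownames(f$centroids), function(g)
                rowSums(sweep(sc, 2L, f$centroids[g, ])^2), numeric(nrow(sc)))
            rownames(f$centroids)[max.col(-matrix(d, nrow(sc)))]
        },
        PLSDA = {
            pr <- stats::predict(model$fit, newdata, dist = "max.dist")
            nc <- dim(pr$predict)[3L]
            as.character(pr$class$max.dist[, nc])
        })
    out
}

#' Continuous positive-class scores
#'
#' Returns a monotone class score for the requested positive class:
#' SVM decision values, kNN vote fractions, network/forest/tree class
#' probabilities, the PLS-DA predicted indicator, or (for PCA) the
#' centroid-distance margin.
#'
#' @inheritParams predictClassOf
#' @param positiveClass label treated as positive.
#' @return numeric vector, larger = more positive-class-like.
#' @export
predictScoresOf <- function(model, newdata, positiveClass) {
    stopifnot(inherits(model, "FusionModel"))
    if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
    if (!positiveClass %in% model$levels)
        stop("positiveClass not among the model's classes")
    cls <- model$classifier
    switch(cls,
        SVM = {
            dv <- attr(stats::predict(model$fit, newdata,
                                      decision.values = TRUE),
                       "decision.values")
            pair <- strsplit(colnames(dv)[1L], "/")[[1L]]
            if (pair[1L] == positiveClass) dv[, 1L] else -dv[, 1L]
        },
        kNN = {
            pr <- class::knn(model$fit$train, newdata, model$fit$cl,
                             k = 3L, prob = TRUE)
            p <- attr(pr, "prob")
            ifelse(as.character(pr) == positiveClass, p, 1 - p)
        },
        NN  = mlpProb(model$fit, newdata)[, positiveClass],
        DT  = {
            df <- as.data.frame(newdata); names(df) <- names(model$vmap)
            stats::predict(model$fit, df, type = "prob")[, positiveClass]
        },
        RF  = stats::predict(model$fit, newdata,
                             type = "prob")[, positiveClass],
        PCA = {
            f <- model$fit
            sc <- scale(newdata, center = f$pca$center, scale = FALSE) %*%
                f$pca$rotation[, seq_len(f$k), drop = FALSE]
            neg <- setdiff(rownames(f$centroids), positiveClass)[1L]
            rowSums(sweep(sc, 2L, f$centroids[neg, ])^2) -
                rowSums(sweep(sc, 2L, f$centroids[positiveClass, ])^2)
        },
        PLSDA = {
            pr <- stats::predict(model$fit, newdata, dist = "max.dist")
            nc <- dim(pr$predict)[3L]
            pr$predict[, positiveClass, nc]
        })
}

# out-of-bag accuracy, defined for random forests only
oobAccuracy <- function(model, trainLabels) {
    if (!inherits(model, "FusionModel") || model$classifier != "RF")
        return(NA_real_)
    mean(as.character(model$fit$predicted) == as.character(trainLabels))
}
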