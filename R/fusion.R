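#' Stratified train/test split of the model set
#'
#' Splits the model samples (role `"model"`) into a training and a test
#' set, stratified by group. The total training size is
#' `round(n * trainFraction)`; per-group counts are apportioned by
#' largest remainder (ties to earlier groups), so a 70-sample model set
#' at 0.7 yields 49 train and 21 test samples.
#'
#' @param manifest the study manifest.
#' @param trainFraction train share, strictly inside (0, 1).
#' @param seed integer seed; fixed seed gives identical membership.
#' @return list with `train` and `test` character vectors of sample ids.
#' @export
partitionModelSet <- function(manifest, trainFraction = 0.7, seed = 1L) {
    if (!(trainFraction > 0 && trainFraction < 1))
        stop("invalid parameter: trainFraction must lie strictly in (0, 1)")
    m <- manifest[manifest$role == "model", , drop = FALSE]
    if (nrow(m) < 10L) stop("need at least 10 model samples")
    grp <- unique(m$group)
    if (length(grp) < 2L)
        stop("stratification error: both classes must be present")
    n <- nrow(m)
    nTrain <- round(n * trainFraction)
    sizes <- vapply(grp, function(g) sum(m$group == g), integer(1L))
    raw <- sizes * trainFraction
    base <- floor(raw)
    rem <- nTrain - sum(base)
    if (rem > 0) {
        ord <- order(-(raw - base), seq_along(grp))  # ties: earlier group
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    }
    set.seed(seed)
    train <- character()
    for (i in seq_along(grp)) {
        ids <- m$sample_id[m$group == grp[i]]
        train <- c(train, sample(ids, base[i]))
    }
    test <- setdiff(m$sample_id, train)
    for (g in grp)
        if (!any(m$group[m$sample_id %in% train] == g) ||
            !any(m$group[m$sample_id %in% test] == g))
            stop("stratification error: a class is absent from one side")
    list(train = m$sample_id[m$sample_id %in% train],
         test = m$sample_id[m$sample_id %in% test])
}

#' Low-level fusion: direct concatenation
#'
#' Column-binds the blocks (which must share sample order) into one wide
#' [FeatureBlock-class]; feature ids are prefixed with the block name so
#' every fused column stays traceable.
#'
#' @param blks named list of [FeatureBlock-class] with identical sample
#'   ordering.
#' @return a `FeatureBlock` (platform `"LLDF"`) whose
#'   `metadata()$featureOrigin` maps fused columns to (block, feature).
#' @export
lldfConcatenate <- function(blks) {
    stopifnot(length(blks) >= 1L)
    ids <- rownames(blockMatrix(blks[[1L]]))
    for (b in blks)
        if (!identical(rownames(blockMatrix(b)), ids))
            stop("alignment error: blocks must share sample ordering")
    if (is.null(names(blks)))
        names(blks) <- vapply(blks, platformOf, character(1L))
    mats <- lapply(names(blks), function(nm) {
        m <- blockMatrix(blks[[nm]])
        colnames(m) <- paste(nm, colnames(m), sep = ".")
        m
    })
    origin <- data.frame(
        block = rep(names(blks), vapply(mats, ncol, integer(1L))),
        feature = unlist(lapply(blks, function(b)
            colnames(blockMatrix(b))), use.names = FALSE),
        stringsAsFactors = FALSE)
    featureBlock(do.call(cbind, mats), "LLDF",
                 metadata = list(featureOrigin = origin))
}

# rank of a centered matrix via its singular spectrum
matrixRank <- function(sdev, tol = 1e-9) sum(sdev > tol * max(sdev, 1))

#' Per-block PCA feature extraction
#'
#' Fits PCA on the training samples of one block and keeps the smallest
#' number of components whose cumulative explained variance reaches the
#' target (capped at the matrix rank, with a warning when the cap
#' binds); all samples (train, test, external) are projected onto those
#' components.
#'
#' @param block a standardized [FeatureBlock-class] (or matrix).
#' @param trainIds sample ids the PCA is fitted on.
#' @param varianceTarget cumulative explained-variance target.
#' @return list with `scores` (all samples x k), `k`, `explained`
#'   (per-component variance fractions of the fit).
#' @export
selectPcaFeatures <- function(block, trainIds, varianceTarget = 0.95) {
    mat <- if (is(block, "FeatureBlock")) blockMatrix(block) else block
    fit <- stats::prcomp(mat[trainIds, , drop = FALSE], center = TRUE,
                         scale. = FALSE)
    ev <- fit$sdev^2 / sum(fit$sdev^2)
    rk <- matrixRank(fit$sdev)
    k <- which(cumsum(ev) >= varianceTarget - 1e-12)[1L]
    if (is.na(k) || k > rk) {
        if (!is.na(k) && k > rk)
            warning("component count capped at matrix rank")
        k <- rk
    }
    k <- max(1L, k)
    sc <- scale(mat, center = fit$center, scale = FALSE) %*%
        fit$rotation[, seq_len(k), drop = FALSE]
    list(scores = sc, k = k, explained = ev[seq_len(k)])
}

#' Per-block PLS-DA feature extraction
#'
#' Fits PLS-DA on the training samples against the class labels and
#' keeps the smallest number of latent variables whose cumulative
#' explained X-variance reaches the target (at least one); scores for
#' held-out samples come from projecting them through the fitted
#' loadings.
#'
#' @inheritParams selectPcaFeatures
#' @param labels named class labels (names = sample ids) covering at
#'   least the training samples; two classes required on the train set.
#' @param maxComp upper bound on the number of latent variables.
#' @return list with `scores` (all samples x k), `k`, `explained`.
#' @export
selectPlsdaFeatures <- function(block, labels, trainIds,
                                varianceTarget = 0.95, maxComp = 30L) {
    mat <- if (is(block, "FeatureBlock")) blockMatrix(block) else block
    ytr <- factor(labels[trainIds])
    if (nlevels(ytr) < 2L)
        stop("invalid labels: PLS-DA needs two classes on the train set")
    nc <- min(maxComp, length(trainIds) - 1L, ncol(mat))
    fit <- mixOmics::plsda(X = mat[trainIds, , drop = FALSE], Y = ytr,
                           ncomp = nc)
    evx <- as.numeric(fit$prop_expl_var$X)
    k <- which(cumsum(evx) >= varianceTarget - 1e-12)[1L]
    if (is.na(k)) k <- nc
    k <- max(1L, k)
    sc <- stats::predict(fit, newdata = mat, dist = "max.dist")$variates
    list(scores = sc[, seq_len(k), drop = FALSE], k = k,
         explained = evx[seq_len(k)])
}

# normalized impurity importance over every column of x
impurityImportance <- function(x, y, method = c("RF", "DT"), seed = 1L) {
    method <- match.arg(method)
    set.seed(seed)
    if (method == "RF") {
        fit <- randomForest::randomForest(x = x, y = y, ntree = 100L)
        imp <- fit$importance[, "MeanDecreaseGini"]
    } else {
        df <- as.data.frame(x)
        vnames <- sprintf("V%d", seq_len(ncol(x)))
        names(df) <- vnames
        df$.y <- y
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            parms = list(split = "gini"))
        imp <- stats::setNames(numeric(ncol(x)), vnames)
        vi <- fit$variable.importance
        imp[names(vi)] <- vi
        names(imp) <- colnames(x)
    }
    tot <- sum(imp)
    if (tot > 0) imp / tot else imp
}

#' Impurity-importance feature selection (DT / RF)
#'
#' Fits a Gini decision tree or a 100-tree random forest on the training
#' samples of one block, normalizes the impurity importances to sum to
#' one, and returns the top-`budget` features ranked by importance
#' (ties broken by lower original column index).
#'
#' @inheritParams selectPlsdaFeatures
#' @param method `"RF"` or `"DT"`.
#' @param budget number of features to keep (capped at the block width,
#'   with a warning).
#' @param seed integer seed.
#' @return a ranked-feature data.frame: `block`, `feature`, `index`,
#'   `raw_importance`, `fused_importance` (`NA` here), `rank`.
#' @export
selectImportanceFeatures <- function(block, labels, trainIds,
                                     method = c("RF", "DT"), budget = 40L,
                                     seed = 1L) {
    method <- match.arg(method)
    mat <- if (is(block, "FeatureBlock")) blockMatrix(block) else block
    blockName <- if (is(block, "FeatureBlock")) platformOf(block) else "block"
    y <- factor(labels[trainIds])
    if (budget > ncol(mat)) {
        warning("budget exceeds block width; capped")
        budget <- ncol(mat)
    }
    imp <- impurityImportance(mat[trainIds, , drop = FALSE], y,
                              method = method, seed = seed)
    ord <- order(-imp, seq_along(imp))
    top <- ord[seq_len(budget)]
    data.frame(block = blockName, feature = colnames(mat)[top],
               index = top, raw_importance = unname(imp[top]),
               fused_importance = NA_real_, rank = seq_len(budget),
               stringsAsFactors = FALSE)
}

#' Mid-level data fusion
#'
#' Extracts features from every block independently — PCA or PLS-DA
#' scores at the cumulative-variance target, or the top-`midBudget`
#' original variables by DT/RF impurity importance — fitted on the
#' training samples only, concatenates the per-block extracts, and
#' trains the second-stage classifier on the fused design. The model
#' name records both stages, e.g. `"RF-RF"`.
#'
#' For DT/RF selectors the fused columns remain original variables, so
#' when the second-stage classifier is also impurity-based the fitted
#' model yields a traceable ranked-feature table (used for
#' characteristic-variable screening).
#'
#' @param blks named list of standardized [FeatureBlock-class].
#' @param manifest study manifest.
#' @param partition a [partitionModelSet()] result.
#' @param selector `"PCA"`, `"PLSDA"`, `"DT"` or `"RF"`.
#' @param classifier second-stage classifier, see [trainClassifier()].
#' @param config a [fusionConfig()].
#' @return list: `name`, `model`, `fused` (all samples x fused width),
#'   `origin` (fused-column provenance), `ranked` (ranked-feature table
#'   or `NULL`), `selector`, `classifier`.
#' @export
mldfFuse <- function(blks, manifest, partition,
                     selector = c("PCA", "PLSDA", "DT", "RF"),
                     classifier = "RF", config = fusionConfig()) {
    selector <- match.arg(selector)
    stopifnot(length(blks) >= 2L)
    labels <- stats::setNames(manifest$group, manifest$sample_id)
    parts <- vector("list", length(blks))
    for (i in seq_along(blks)) {
        nm <- names(blks)[i]
        sd_i <- childSeed(config@seed, i)
        if (selector %in% c("PCA", "PLSDA")) {
            ext <- if (selector == "PCA")
                selectPcaFeatures(blks[[i]], partition$train,
                                  config@varianceTarget)
            else
                selectPlsdaFeatures(blks[[i]], labels, partition$train,
                                    config@varianceTarget)
            sc <- ext$scores
            colnames(sc) <- sprintf("%s.%s%d", nm,
                                    ifelse(selector == "PCA", "PC", "LV"),
                                    seq_len(ncol(sc)))
            parts[[i]] <- list(mat = sc,
                               origin = data.frame(block = nm,
                                                   feature = colnames(sc),
                                                   type = "score"))
        } else {
            rk <- selectImportanceFeatures(blks[[i]], labels,
                                           partition$train, method = selector,
                                           budget = config@midBudget,
                                           seed = sd_i)
            m <- blockMatrix(blks[[i]])[, rk$feature, drop = FALSE]
            colnames(m) <- paste(nm, rk$feature, sep = ".")
            parts[[i]] <- list(mat = m,
                               origin = data.frame(block = nm,
                                                   feature = rk$feature,
                                                   type = "variable"))
        }
    }
    fused <- do.call(cbind, lapply(parts, `[[`, "mat"))
    origin <- do.call(rbind, lapply(parts, `[[`, "origin"))
    model <- trainClassifier(fused[partition$train, , drop = FALSE],
                             labels[partition$train], classifier,
                             seed = config@seed,
                             nnMaxIter = config@nnMaxIter)
    ranked <- NULL
    if (selector %in% c("DT", "RF") && classifier %in% c("DT", "RF")) {
        imp <- impurityImportance(fused[partition$train, , drop = FALSE],
                                  factor(labels[partition$train]),
                                  method = classifier, seed = config@seed)
        ord <- order(-imp, seq_along(imp))
        ranked <- data.frame(block = origin$block[ord],
                             feature = origin$feature[ord],
                             index = ord,
                             raw_importance = unname(imp[ord]),
                             fused_importance = unname(imp[ord]),
                             rank = seq_along(ord), stringsAsFactors = FALSE)
    }
    list(name = paste(selector, classifier, sep = "-"), model = model,
         fused = fused, origin = origin, ranked = ranked,
         selector = selector, classifier = classifier)
}

#' High-level fusion by weighted Gini importances
#'
#' Per block, a 100-tree random forest ranks all features and the top
#' `hldfBudgets[1]` (120) survive; a second forest refit on the
#' survivors ranks them again and the top `hldfBudgets[2]` (40) are kept
#' with the refit importances (set `hldfRefit = FALSE` in the config to
#' reuse the stage-1 importances instead). Each block's importances are
#' multiplied by the block weight (1/n_blocks, i.e. 0.25 for four
#' blocks), the weighted lists are merged (4 x 40 = 160 candidates),
#' sorted by fused importance (ties: block order, then column index),
#' and the top `hldfFinalBudget` (40) variables train the final
#' 100-tree forest.
#'
#' @inheritParams mldfFuse
#' @return list: `name` (`"RF-RF-RF"`), `ranked` (the full merged pool
#'   with fused importances and ranks), `panel` (the final-budget
#'   subset), `model` (final forest), `fused` (all samples x panel),
#'   `origin`.
#' @export
hldfGiniFusion <- function(blks, manifest, partition,
                           config = fusionConfig()) {
    stopifnot(length(blks) >= 2L)
    labels <- stats::setNames(manifest$group, manifest$sample_id)
    ytr <- factor(labels[partition$train])
    w <- if (is.na(config@hldfWeight)) 1 / length(blks) else config@hldfWeight
    perBlock <- vector("list", length(blks))
    for (i in seq_along(blks)) {
        nm <- names(blks)[i]
        mat <- blockMatrix(blks[[i]])
        sd_i <- childSeed(config@seed, i)
        b1 <- config@hldfBudgets[1L]
        if (b1 > ncol(mat)) {
            warning(sprintf("block %s narrower than stage-1 budget; capped",
                            nm))
            b1 <- ncol(mat)
        }
        imp1 <- impurityImportance(mat[partition$train, , drop = FALSE],
                                   ytr, "RF", seed = sd_i)
        ord1 <- order(-imp1, seq_along(imp1))
        keep1 <- ord1[seq_len(b1)]
        b2 <- min(config@hldfBudgets[2L], b1)
        if (config@hldfRefit) {
            sub <- mat[partition$train, keep1, drop = FALSE]
            imp2 <- impurityImportance(sub, ytr, "RF",
                                       seed = childSeed(sd_i, 1L))
            ord2 <- order(-imp2, seq_along(imp2))
            keep2 <- keep1[ord2[seq_len(b2)]]
            raw <- unname(imp2[ord2[seq_len(b2)]])
        } else {
            keep2 <- keep1[seq_len(b2)]
            raw <- unname(imp1[keep2])
        }
        perBlock[[i]] <- data.frame(
            block = nm, blockOrder = i, feature = colnames(mat)[keep2],
            index = keep2, raw_importance = raw,
            fused_importance = w * raw, stringsAsFactors = FALSE)
    }
    merged <- do.call(rbind, perBlock)
    merged <- merged[order(-merged$fused_importance, merged$blockOrder,
                           merged$index), , drop = FALSE]
    merged$rank <- seq_len(nrow(merged))
    rownames(merged) <- NULL
    nFinal <- min(config@hldfFinalBudget, nrow(merged))
    panel <- merged[seq_len(nFinal), , drop = FALSE]
    cols <- lapply(seq_len(nrow(panel)), function(j)
        blockMatrix(blks[[panel$block[j]]])[, panel$feature[j]])
    fused <- do.call(cbind, cols)
    colnames(fused) <- paste(panel$block, panel$feature, sep = ".")
    rownames(fused) <- rownames(blockMatrix(blks[[1L]]))
    model <- trainClassifier(fused[partition$train, , drop = FALSE],
                             labels[partition$train], "RF",
                             seed = config@seed)
    list(name = "RF-RF-RF",
         ranked = merged[, c("block", "feature", "index", "raw_importance",
                             "fused_importance", "rank")],
         panel = panel, model = model, fused = fused,
         origin = panel[, c("block", "feature")])
}
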