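test_that("stratified partition respects the rounding and seed contracts", {
    man <- sampleManifest(c(YN = 35L, GX = 35L))
    p <- partitionModelSet(man, 0.7, 1L)
    expect_equal(length(p$train), 49L)
    expect_equal(length(p$test), 21L)
    grpTrain <- table(man$group[match(p$train, man$sample_id)])
    expect_true(all(sort(as.integer(grpTrain)) == c(24L, 25L)))
    expect_identical(p, partitionModelSet(man, 0.7, 1L))
    expect_false(identical(p, partitionModelSet(man, 0.7, 2L)))
    expect_error(partitionModelSet(man, 1.0), "invalid parameter")
    one <- sampleManifest(c(YN = 12L))
    expect_error(partitionModelSet(one, 0.7, 1L), "stratification")
})

test_that("low-level concatenation is additive, prefixed and alignment-checked", {
    man <- sampleManifest(c(A = 4L, B = 4L))
    widths <- c(LCMS = 5L, GCMS = 7L, NMR = 11L, MIR = 13L)
    blks <- lapply(names(widths), function(p)
        generateFeatureBlock(blockSpec(p, nFeatures = widths[[p]]), man, 1L))
    names(blks) <- names(widths)
    fused <- lldfConcatenate(blks)
    expect_equal(ncol(blockMatrix(fused)), 36L)
    expect_true(all(startsWith(colnames(blockMatrix(fused))[1:5], "LCMS.")))
    one <- lldfConcatenate(blks[1L])
    expect_equal(unname(blockMatrix(one)), unname(blockMatrix(blks[[1L]])))
    bad <- blks
    bm <- blockMatrix(bad$MIR)[c(2:8, 1L), ]
    bad$MIR <- featureBlock(bm, "MIR")
    expect_error(lldfConcatenate(bad), "alignment")
})

test_that("block order does not change a permutation-invariant fused model", {
    pr <- preparedStudy(tinyStudySpec(4L))
    f1 <- blockMatrix(lldfConcatenate(pr$blocks))
    f2 <- blockMatrix(lldfConcatenate(rev(pr$blocks)))
    m1 <- trainClassifier(f1[pr$partition$train, ],
                          pr$labels[pr$partition$train], "SVM", seed = 4L)
    m2 <- trainClassifier(f2[pr$partition$train, ],
                          pr$labels[pr$partition$train], "SVM", seed = 4L)
    expect_identical(predictClassOf(m1, f1[pr$partition$test, ]),
                     predictClassOf(m2, f2[pr$partition$test, ]))
})

test_that("PCA component count tracks rank and the variance target", {
    ids <- sprintf("S%02d", 1:40)
    set.seed(3)
    basis <- matrix(rnorm(2 * 12), 2, 12)
    planar <- matrix(rnorm(40 * 2), 40, 2) %*% basis
    dimnames(planar) <- list(ids, paste0("F", 1:12))
    expect_equal(selectPcaFeatures(planar, ids, 0.95)$k, 2L)
    expect_equal(selectPcaFeatures(planar, ids, 1.0)$k, 2L)  # k = rank
    iso <- matrix(rnorm(300 * 10), 300, 10,
                  dimnames = list(sprintf("S%03d", 1:300), paste0("F", 1:10)))
    expect_equal(selectPcaFeatures(iso, rownames(iso), 0.95)$k, 10L)
})

test_that("PLS-DA extraction needs two classes and finds aligned signal", {
    ids <- sprintf("S%02d", 1:40)
    y <- stats::setNames(rep(c("A", "B"), each = 20L), ids)
    set.seed(5)
    X <- matrix(rnorm(40 * 25), 40, 25,
                dimnames = list(ids, paste0("F", 1:25)))
    X[, 1L] <- X[, 1L] + ifelse(y == "A", 0, 3)  # informative direction
    out <- selectPlsdaFeatures(X, y, ids, varianceTarget = 1e-6)
    expect_equal(out$k, 1L)
    # a perfect score at standardized shift d has point-biserial
    # correlation (d/2)/sqrt(d^2/4 + 1) = 0.832 at d = 3; require the
    # LV to sit close to that ceiling
    expect_gt(abs(stats::cor(out$scores[, 1L], as.integer(y == "A"))), 0.75)
    expect_error(selectPlsdaFeatures(X, stats::setNames(rep("A", 40), ids),
                                     ids),
                 "invalid labels")
})

test_that("impurity selection ranks a perfect separator first and sums to one", {
    ids <- sprintf("S%02d", 1:30)
    y <- stats::setNames(rep(c("A", "B"), each = 15L), ids)
    hits <- vapply(1:8, function(s) {
        set.seed(s + 100)
        X <- matrix(rnorm(30 * 25), 30, 25,
                    dimnames = list(ids, paste0("F", 1:25)))
        X[, 7L] <- ifelse(y == "A", -4, 4) + rnorm(30, 0, 0.1)
        rk <- selectImportanceFeatures(X, y, ids, "RF", budget = 25L,
                                       seed = s)
        rk$feature[1L] == "F7"
    }, logical(1L))
    expect_gte(mean(hits), 0.9)
    set.seed(9)
    X <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(ids, paste0("F", 1:12)))
    X[, 2L] <- X[, 2L] + ifelse(y == "A", 0, 2)
    full <- selectImportanceFeatures(X, y, ids, "RF", budget = 12L, seed = 1L)
    expect_setequal(full$feature, colnames(X))     # budget = width
    expect_equal(sum(full$raw_importance), 1, tolerance = 1e-9)
    expect_warning(selectImportanceFeatures(X, y, ids, "DT", budget = 40L,
                                            seed = 1L),
                   "capped")
})

test_that("mid-level fusion concatenates per-block extracts as specified", {
    pr <- preparedStudy(wideTabularSpec(6L))
    cfg <- fusionConfig(seed = 6L)
    fit <- mldfFuse(pr$blocks, pr$manifest, pr$partition, "RF", "RF", cfg)
    expect_equal(ncol(fit$fused), 160L)           # 4 x 40
    expect_equal(fit$name, "RF-RF")
    expect_equal(nrow(fit$ranked), 160L)
    expect_false(is.null(fit$ranked))
    pca <- mldfFuse(pr$blocks, pr$manifest, pr$partition, "PCA", "SVM", cfg)
    ks <- vapply(pr$blocks, function(b)
        selectPcaFeatures(b, pr$partition$train, cfg@varianceTarget)$k,
        integer(1L))
    expect_equal(ncol(pca$fused), sum(ks))        # additivity of k_i
    expect_null(pca$ranked)                        # score features untraceable
})

test_that("high-level Gini fusion obeys its budgets, weights and ordering", {
    pr <- preparedStudy(wideTabularSpec(7L))
    cfg <- fusionConfig(seed = 7L)
    h <- hldfGiniFusion(pr$blocks, pr$manifest, pr$partition, cfg)
    expect_equal(nrow(h$ranked), 160L)            # merged pool
    expect_equal(nrow(h$panel), 40L)              # final budget
    expect_equal(ncol(h$fused), 40L)
    expect_true(all(h$ranked$fused_importance <= 0.25 + 1e-12))
    expect_lte(sum(h$ranked$fused_importance), 1 + 1e-9)
    expect_true(all(diff(h$ranked$fused_importance) <= 1e-12))
    # within one block the fused ordering equals the refit ordering
    for (b in unique(h$ranked$block)) {
        sub <- h$ranked[h$ranked$block == b, ]
        expect_true(all(diff(sub$raw_importance) <= 1e-12))
    }
    # narrow blocks trigger the stage-1 cap warning
    prN <- preparedStudy(tinyStudySpec(7L))
    expect_warning(hldfGiniFusion(prN$blocks[c("LCMS", "GCMS")],
                                  prN$manifest, prN$partition, cfg),
                   "capped")
})

test_that("high-level fusion equals a brute-force reimplementation on a toy", {
    pr <- preparedStudy(wideTabularSpec(8L))
    blks <- pr$blocks[c("LCMS", "GCMS")]
    cfg <- fusionConfig(seed = 8L, hldfBudgets = c(20L, 6L),
                        hldfFinalBudget = 6L)
    h <- hldfGiniFusion(blks, pr$manifest, pr$partition, cfg)
    # independent oracle: explicit fit / sort / refit / weight / merge
    ytr <- factor(pr$labels[pr$partition$train])
    oracle <- do.call(rbind, lapply(seq_along(blks), function(i) {
        mat <- blockMatrix(blks[[i]])[pr$partition$train, ]
        sd_i <- as.integer((8 + 7919 * i) %% 2147483647)
        set.seed(sd_i)
        rf1 <- randomForest::randomForest(x = mat, y = ytr, ntree = 100L)
        imp1 <- rf1$importance[, "MeanDecreaseGini"]
        imp1 <- imp1 / sum(imp1)
        keep1 <- order(-imp1, seq_along(imp1))[1:20]
        set.seed(as.integer((sd_i + 7919) %% 2147483647))
        rf2 <- randomForest::randomForest(x = mat[, keep1], y = ytr,
                                          ntree = 100L)
        imp2 <- rf2$importance[, "MeanDecreaseGini"]
        imp2 <- imp2 / sum(imp2)
        o2 <- order(-imp2, seq_along(imp2))[1:6]
        data.frame(block = names(blks)[i], blockOrder = i,
                   feature = colnames(mat)[keep1][o2],
                   fused = 0.5 * unname(imp2[o2]))
    }))
    oracle <- oracle[order(-oracle$fused, oracle$blockOrder), ]
    expect_equal(h$ranked$feature, oracle$feature)
    expect_equal(h$ranked$fused_importance, oracle$fused, tolerance = 1e-12)
})

test_that("every classifier solves a separable toy and kNN follows its votes", {
    set.seed(2)
    n <- 15L
    X <- rbind(matrix(rnorm(n * 2, -3, 0.4), n, 2),
               matrix(rnorm(n * 2, 3, 0.4), n, 2))
    colnames(X) <- c("F1", "F2")
    y <- rep(c("A", "B"), each = n)
    for (cl in c("SVM", "kNN", "NN", "DT", "RF", "PCA", "PLSDA")) {
        fit <- trainClassifier(X, y, cl, seed = 2L, nnMaxIter = 200L)
        expect_equal(mean(predictClassOf(fit, X) == y), 1.0,
                     info = cl)
    }
    # 3-NN unanimity
    train <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 5, 5), 4, 2, byrow = TRUE,
                    dimnames = list(NULL, c("F1", "F2")))
    fit <- trainClassifier(train, c("A", "A", "A", "B"), "kNN", seed = 1L)
    expect_equal(predictClassOf(fit, matrix(c(0.02, 0.02), 1, 2,
                                            dimnames = list(NULL,
                                                            c("F1", "F2")))),
                 "A")
    expect_error(trainClassifier(cbind(F1 = c(1, NA)), c("A", "B"), "RF"),
                 "non-finite")
})

test_that("selection and ranking never read test-sample values (leakage guard)", {
    pr <- preparedStudy(wideTabularSpec(9L))
    cfg <- fusionConfig(seed = 9L)
    rk1 <- selectImportanceFeatures(pr$blocks$LCMS, pr$labels,
                                    pr$partition$train, "RF", 40L, seed = 9L)
    h1 <- hldfGiniFusion(pr$blocks, pr$manifest, pr$partition, cfg)
    # corrupt every non-training row of every block
    blks2 <- lapply(pr$blocks, function(b) {
        m <- blockMatrix(b)
        out <- !(rownames(m) %in% pr$partition$train)
        m[out, ] <- m[out, ] * 100 + 7
        featureBlock(m, platformOf(b))
    })
    rk2 <- selectImportanceFeatures(blks2$LCMS, pr$labels,
                                    pr$partition$train, "RF", 40L, seed = 9L)
    h2 <- hldfGiniFusion(blks2, pr$manifest, pr$partition, cfg)
    expect_identical(rk1$feature, rk2$feature)
    expect_identical(rk1$raw_importance, rk2$raw_importance)
    expect_identical(h1$ranked, h2$ranked)
})

test_that("a fixed config and seed reproduce rankings and predictions exactly", {
    pr <- preparedStudy(tinyStudySpec(10L))
    cfg <- fusionConfig(seed = 10L, midBudget = 20L)
    f1 <- mldfFuse(pr$blocks, pr$manifest, pr$partition, "RF", "RF", cfg)
    f2 <- mldfFuse(pr$blocks, pr$manifest, pr$partition, "RF", "RF", cfg)
    expect_identical(f1$ranked, f2$ranked)
    expect_identical(predictClassOf(f1$model, f1$fused),
                     predictClassOf(f2$model, f2$fused))
})
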