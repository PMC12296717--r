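test_that("generation is deterministic and block-stable under the master seed", {
    man <- sampleManifest(c(YN = 5L, GX = 5L))
    bs <- blockSpec("LCMS", nFeatures = 20L, nInformative = 3L)
    b1 <- generateFeatureBlock(bs, man, 42L)
    b2 <- generateFeatureBlock(bs, man, 42L)
    expect_identical(blockMatrix(b1), blockMatrix(b2))

    spec3 <- tinyStudySpec(11L)
    spec2 <- spec3; spec2$blocks <- spec2$blocks[1:2]
    st3 <- generateStudy(spec3); st2 <- generateStudy(spec2)
    # adding later blocks never perturbs earlier ones (child-seed fanout)
    expect_identical(blockMatrix(blocks(st2)$LCMS),
                     blockMatrix(blocks(st3)$LCMS))
    expect_identical(blockMatrix(blocks(st2)$GCMS),
                     blockMatrix(blocks(st3)$GCMS))
    st3b <- generateStudy(tinyStudySpec(11L))
    expect_identical(blockMatrix(blocks(st3)$LCMS),
                     blockMatrix(blocks(st3b)$LCMS))
    expect_identical(spectrumIntensity(spectra(blocks(st3)$NMR)[[1L]]),
                     spectrumIntensity(spectra(blocks(st3b)$NMR)[[1L]]))
})

test_that("null tabular blocks carry no group signal (t-test size near alpha)", {
    rates <- vapply(1:4, function(s) {
        man <- sampleManifest(c(A = 30L, B = 30L))
        b <- generateFeatureBlock(blockSpec("LCMS", nFeatures = 200L,
                                            nInformative = 0L,
                                            effectSize = 0),
                                  man, s)
        m <- blockMatrix(b)
        mean(apply(m, 2L, function(x)
            stats::t.test(x[man$group == "A"],
                          x[man$group == "B"])$p.value) < 0.01)
    }, numeric(1L))
    # intensities are lognormal, so allow a band around the nominal 1%
    expect_gt(mean(rates), 0.001)
    expect_lt(mean(rates), 0.03)
})

test_that("informative features hit the closed-form two-group AUC", {
    # unit-variance log-intensities shifted by 2 => AUC = Phi(2/sqrt(2)),
    # checked by brute-force rank comparison on the raw intensities
    target <- stats::pnorm(2 / sqrt(2))
    aucs <- unlist(lapply(1:4, function(s) {
        man <- sampleManifest(c(A = 30L, B = 30L))
        b <- generateFeatureBlock(blockSpec("LCMS", nFeatures = 60L,
                                            nInformative = 20L,
                                            effectSize = 2, noiseSd = 1),
                                  man, s)
        m <- blockMatrix(b)
        info <- S4Vectors::metadata(b)$informative$feature
        vapply(info, function(f) {
            a <- pairCountAUC(m[, f], man$group, "A")
            max(a, 1 - a)
        }, numeric(1L))
    }))
    expect_lt(abs(mean(aucs) - target), 0.02)
})

test_that("noise-free spectra equal the analytic Gaussian peak", {
    man <- sampleManifest(c(A = 2L, B = 2L))
    bs <- blockSpec("MIR", axis = c(1000, 1100, 1), nInformative = 0L,
                    effectSize = 0, noiseSd = 0, baselineAmplitude = 0,
                    peakWidth = 5, ampSigma = 0,
                    peakPositions = 1050, peakAmplitudes = 7)
    ss <- generateSpectrumBlock(bs, man, 3L)
    sp <- spectra(ss)[[1L]]
    ax <- spectrumAxis(sp)
    expect_equal(spectrumIntensity(sp),
                 7 * exp(-(ax - 1050)^2 / (2 * 5^2)), tolerance = 1e-12)
})

test_that("planted NMR peaks map onto the buckets containing their apexes", {
    st <- generateStudy(tinyStudySpec(5L))
    tr <- plantedTruth(st)$blocks$NMR
    fb <- nmrPreprocess(blocks(st)$NMR)
    centers <- as.data.frame(SummarizedExperiment::rowData(fb))$coordinate
    scheme <- bucketingScheme()
    for (p in tr$positions) {
        apexBucket <- scheme$range[1L] +
            (floor((p - scheme$range[1L]) / scheme$width) + 0.5) * scheme$width
        expect_true(min(abs(centers - apexBucket)) < 1e-9)
    }
})

test_that("study bookkeeping matches the declared group structure", {
    spec <- syntheticSpec(1L, c(YN = 35L, GX = 35L),
                          externalGroups = c(GD = 4L, FJ = 4L,
                                             MD = 3L, LQS = 3L),
                          blocks = list(blockSpec("LCMS", nFeatures = 25L,
                                                  nInformative = 4L),
                                        blockSpec("GCMS", nFeatures = 20L,
                                                  nInformative = 3L)))
    st <- generateStudy(spec)
    man <- manifest(st)
    expect_equal(nrow(man), 84L)
    expect_equal(sum(man$role == "model"), 70L)
    expect_equal(sum(man$role == "external"), 14L)
    tr <- plantedTruth(st)
    expect_equal(tr$nPlanted, 7L)
    expect_equal(sum(vapply(tr$blocks, function(b)
        length(b$features), integer(1L))), 7L)

    noExt <- syntheticSpec(1L, c(YN = 6L, GX = 6L),
                           blocks = list(blockSpec("LCMS", nFeatures = 10L)))
    expect_equal(sum(manifest(generateStudy(noExt))$role == "external"), 0L)
})

test_that("invalid block and study specs are rejected", {
    expect_error(blockSpec("NMR", axis = c(0, 10, 0), peakWidth = 1),
                 "invalid spec")
    expect_error(blockSpec("LCMS", nFeatures = 5L, nInformative = 9L),
                 "invalid spec")
    expect_error(blockSpec("LCMS", nFeatures = 5L, effectSize = -1),
                 "invalid spec")
    expect_error(syntheticSpec(1L, c(A = 1L, B = 5L),
                               blocks = list(blockSpec("LCMS",
                                                       nFeatures = 5L))),
                 "invalid spec")
    man <- sampleManifest(c(A = 3L, B = 3L))
    expect_error(generateFeatureBlock(
        blockSpec("NMR", axis = c(0, 1, 0.1), peakWidth = 0.01), man, 1L),
        "tabular")
    expect_error(generateSpectrumBlock(
        blockSpec("LCMS", nFeatures = 5L), man, 1L), "spectral")
})

test_that("single-block accuracy is monotone in effect size", {
    grid <- c(0, 1, 2.5)
    acc <- sapply(1:6, function(s) {
        vapply(grid, function(es) {
            man <- sampleManifest(c(A = 20L, B = 20L))
            b <- generateFeatureBlock(blockSpec("LCMS", nFeatures = 60L,
                                                nInformative = 6L,
                                                effectSize = es), man, s)
            m <- blockMatrix(b)
            part <- partitionModelSet(man, 0.7, s)
            fit <- trainClassifier(m[part$train, ], man$group[
                match(part$train, man$sample_id)], "RF", seed = s)
            mean(predictClassOf(fit, m[part$test, ]) ==
                     man$group[match(part$test, man$sample_id)])
        }, numeric(1L))
    })
    med <- apply(acc, 1L, stats::median)
    expect_true(all(diff(med) >= 0))
})
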