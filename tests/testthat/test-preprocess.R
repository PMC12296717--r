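test_that("chemical-shift referencing pins the lock peak at zero", {
    ax <- seq(-0.1, 1, by = 0.001)
    peak <- function(center, amp = 1, w = 0.005)
        amp * exp(-(ax - center)^2 / (2 * w^2))
    # already referenced: identity
    sp <- spectrum(ax, peak(0) + peak(0.8))
    expect_equal(spectrumAxis(referenceAlign(sp)), ax)
    # uniform +0.01 offset: all shifts reduced by 0.01
    spOff <- spectrum(ax, peak(0.01) + peak(0.8))
    expect_equal(spectrumAxis(referenceAlign(spOff)), ax - 0.01)
    # two candidate maxima in the window: the taller wins (argmax oracle)
    y2 <- peak(-0.03, amp = 1) + peak(0.02, amp = 2)
    win <- abs(ax) <= 0.05
    apexOracle <- ax[win][which.max(y2[win])]
    sp2 <- spectrum(ax, y2)
    expect_equal(spectrumAxis(referenceAlign(sp2)), ax - apexOracle)
    # no peak in the window
    flat <- spectrum(ax, peak(0.8))
    expect_error(referenceAlign(flat), "reference not found")
})

test_that("bucketing retains 5700 buckets and conserves in-range intensity", {
    # grid offset by a half step so no point sits on a bucket edge
    ax <- seq(-0.2005, 12.2005, by = 0.001)
    set.seed(1)
    y <- abs(stats::rnorm(length(ax)))
    b <- bucketSpectrum(spectrum(ax, y))
    expect_equal(length(b$values), 5700L)
    # conservation: retained sums + dropped-bucket mass = all in-range mass
    inRange <- ax >= 0.4 & ax < 12.0
    scheme <- bucketingScheme()
    inKept <- rep(FALSE, length(ax))
    for (j in seq_along(b$lo))
        inKept <- inKept | (ax >= b$lo[j] - 1e-12 & ax < b$hi[j] - 1e-12)
    expect_equal(sum(b$values) + sum(y[inRange & !inKept]),
                 sum(y[inRange]), tolerance = 1e-9)
    # mass concentrated in the water window leaves every retained bucket
    yw <- exp(-(ax - 4.9)^2 / (2 * 0.01^2))
    bw <- bucketSpectrum(spectrum(ax, yw))
    expect_lt(max(bw$values), 1e-6)
    expect_error(bucketSpectrum(spectrum(numeric(), numeric())))
})

test_that("Savitzky-Golay reproduces low-degree polynomials and its derived weights", {
    ax <- seq_len(101)
    expect_equal(spectrumIntensity(savitzkyGolay(spectrum(ax, rep(3, 101)),
                                                 11L, 3L)),
                 rep(3, 101))
    yq <- 2 + 0.5 * ax - 0.01 * ax^2
    sm <- spectrumIntensity(savitzkyGolay(spectrum(ax, yq), 11L, 3L))
    expect_equal(sm[6:96], yq[6:96], tolerance = 1e-9)
    # window-5 / order-2 center weights from the local least-squares
    # system, solved directly as the oracle
    z <- -2:2
    A <- outer(z, 0:2, `^`)
    wOracle <- drop(solve(crossprod(A)) %*% t(A))[1L, ]
    expect_equal(wOracle, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
    # impulse response of the filter at an interior point equals them
    imp <- numeric(21); imp[11] <- 1
    resp <- spectrumIntensity(savitzkyGolay(spectrum(seq_len(21), imp),
                                            5L, 2L))[9:13]
    expect_equal(resp, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-9)
    expect_error(savitzkyGolay(spectrum(1:10, 1:10), 4L, 2L),
                 "invalid parameter")
})

test_that("vector normalization yields unit norm and is scale-invariant", {
    sp <- spectrum(1:2, c(3, 4))
    expect_equal(spectrumIntensity(vectorNormalize(sp)), c(0.6, 0.8))
    expect_equal(spectrumIntensity(vectorNormalize(vectorNormalize(sp))),
                 c(0.6, 0.8))
    sp2 <- spectrum(1:2, 17.3 * c(3, 4))
    expect_equal(spectrumIntensity(vectorNormalize(sp2)), c(0.6, 0.8))
    expect_error(vectorNormalize(spectrum(1:2, c(0, 0))),
                 "degenerate")
})

test_that("region removal drops closed intervals, boundaries included", {
    ax <- seq(400, 4000, by = 4)
    y <- seq_along(ax)
    out <- removeRegions(spectrum(ax, y))
    expect_false(3500 %in% out$axis)
    expect_false(2200 %in% out$axis)
    expect_true(3496 %in% out$axis)
    # enumeration oracle for the default scheme on this grid
    keepOracle <- !((ax >= 3500 & ax <= 4000) |
                    (ax >= 2200 & ax <= 2400) |
                    (ax >= 400 & ax <= 500))
    expect_equal(length(out$values), sum(keepOracle))
    expect_equal(sum(keepOracle), 698L)
    # no regions: identity
    cfg0 <- mirPipelineConfig(removedRegions = list())
    expect_equal(removeRegions(spectrum(ax, y), cfg0)$values,
                 stats::setNames(y, sprintf("wn_%g", ax)))
    cfgAll <- mirPipelineConfig(removedRegions = list(c(400, 4000)))
    expect_error(removeRegions(spectrum(ax, y), cfgAll), "empty output")
})

test_that("MIR pipeline order matters: normalize before, not after, masking", {
    st <- generateStudy(tinyStudySpec(3L))
    ss <- blocks(st)$MIR
    cfg <- mirPipelineConfig()
    sp <- spectra(ss)[[1L]]
    viaPipeline <- removeRegions(vectorNormalize(
        savitzkyGolay(sp, cfg$sgWindow, cfg$sgPolyorder)), cfg)$values
    swapped <- local({
        sm <- savitzkyGolay(sp, cfg$sgWindow, cfg$sgPolyorder)
        kept <- removeRegions(sm, cfg)
        v <- kept$values / sqrt(sum(kept$values^2))
        v
    })
    expect_equal(unname(blockMatrix(mirPreprocess(ss, cfg))[1L, ]),
                 unname(viaPipeline))
    expect_gt(max(abs(viaPipeline - swapped)), 1e-6)
})

test_that("model-set Z-scoring standardizes exactly and never leaks", {
    expect_equal((c(1, 2, 3) - 2) / sqrt(2 / 3),
                 c(-1.224745, 0, 1.224745), tolerance = 1e-6)
    st <- generateStudy(tinyStudySpec(2L))
    fb <- blocks(st)$LCMS
    man <- manifest(st)
    z <- zscoreBlock(fb, man)
    zm <- blockMatrix(z)[man$sample_id[man$role == "model"], ]
    expect_lt(max(abs(colMeans(zm))), 1e-10)
    expect_lt(max(abs(sqrt(colMeans(sweep(zm, 2, colMeans(zm))^2)) - 1)),
              1e-10)
    # round trip through the stored statistics recovers the input
    std <- S4Vectors::metadata(z)$standardization
    back <- sweep(sweep(blockMatrix(z), 2L, std$scale, `*`), 2L,
                  std$center, `+`)
    expect_equal(back, blockMatrix(fb), tolerance = 1e-9)
    # external rows use the model-fitted transform, not their own
    ext <- man$sample_id[man$role == "external"][1L]
    expect_equal(unname(blockMatrix(z)[ext, 1L]),
                 unname((blockMatrix(fb)[ext, 1L] - std$center[1L]) /
                            std$scale[1L]))
    # constant column is dropped with a warning, not NaN
    m <- blockMatrix(fb); m[, 3L] <- 5
    fb2 <- featureBlock(m, "LCMS")
    expect_warning(z2 <- zscoreBlock(fb2, man), "zero-variance")
    expect_equal(ncol(blockMatrix(z2)), ncol(m) - 1L)
    expect_false(anyNA(blockMatrix(z2)))
    mAll <- matrix(1, nrow(m), 3L,
                   dimnames = list(rownames(m), paste0("F", 1:3)))
    expect_error(suppressWarnings(zscoreBlock(featureBlock(mAll, "LCMS"),
                                              man)),
                 "degenerate block")
})
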