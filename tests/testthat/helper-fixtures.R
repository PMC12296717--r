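# Small study specs used across test files; sized for speed, not for
# the benchmark regime (that one is defaultStudySpec()).

tinyStudySpec <- function(seed = 1L, effect = 2, externalGroups = c(GD = 3L, FJ = 3L)) {
    syntheticSpec(
        seed = seed,
        groups = c(YN = 12L, GX = 12L),
        externalGroups = externalGroups,
        blocks = list(
            blockSpec("LCMS", nFeatures = 40L, nInformative = 5L,
                      effectSize = effect),
            blockSpec("GCMS", nFeatures = 30L, nInformative = 4L,
                      effectSize = effect),
            blockSpec("NMR", axis = c(-0.2, 12.2, 0.002), nPeaks = 12L,
                      nInformative = 3L, effectSize = effect,
                      noiseSd = 0.05, peakWidth = 0.004,
                      baselineAmplitude = 0.5,
                      peakRegions = list(c(0.5, 4.6), c(5.2, 11.8))),
            blockSpec("MIR", axis = c(400, 4000, 8), nPeaks = 10L,
                      nInformative = 2L, effectSize = effect,
                      noiseSd = 0.05, peakWidth = 3,
                      baselineAmplitude = 1,
                      peakRegions = list(c(520, 2180), c(2420, 3480)))))
}

# four wide tabular blocks (every width >= the stage-1 budget of 120)
wideTabularSpec <- function(seed = 1L, effect = 2) {
    syntheticSpec(
        seed = seed,
        groups = c(YN = 12L, GX = 12L),
        blocks = list(
            blockSpec("LCMS", nFeatures = 150L, nInformative = 5L,
                      effectSize = effect),
            blockSpec("GCMS", nFeatures = 130L, nInformative = 5L,
                      effectSize = effect),
            blockSpec("NMR", nFeatures = 125L, nInformative = 5L,
                      effectSize = effect),
            blockSpec("MIR", nFeatures = 140L, nInformative = 5L,
                      effectSize = effect)))
}

# standardized blocks + manifest + partition for a generated study
preparedStudy <- function(spec, seed = spec$seed) {
    st <- generateStudy(spec)
    blks <- preprocessStudy(st)
    man <- manifest(st)
    list(study = st, blocks = blks, manifest = man,
         labels = stats::setNames(man$group, man$sample_id),
         partition = partitionModelSet(man, 0.7, seed))
}

# exhaustive Mann-Whitney concordance (ties counted half): the
# independent AUC oracle used against rocCurve()
pairCountAUC <- function(scores, labels, positiveClass) {
    pos <- scores[labels == positiveClass]
    neg <- scores[labels != positiveClass]
    cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
    mean(cmp)
}
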