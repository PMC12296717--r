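#' Specify one synthetic data block
#'
#' Describes one platform block of a synthetic multi-platform study:
#' either a tabular feature block (LC-MS / GC-MS style, `nFeatures`
#' columns) or a spectral block (NMR / MIR style, a regular `axis` grid
#' carrying Gaussian peaks over a smooth baseline). `nInformative`
#' features (tabular columns, or peak amplitudes) are planted with
#' group-dependent means; everything else is noise.
#'
#' Group effects are multiplicative: tabular log-intensities receive a
#' mean shift of `effectSize * noiseSd` between the two model groups
#' (so `effectSize` is the standardized shift), and informative peak
#' amplitudes are multiplied by `exp(effect)` on the same standardized
#' scale relative to the lognormal amplitude variation `ampSigma`.
#'
#' @param platform `"LCMS"`, `"GCMS"` (tabular) or `"NMR"`, `"MIR"`
#'   (spectral).
#' @param nFeatures number of columns (tabular blocks only).
#' @param axis numeric `c(start, stop, step)` grid definition, in ppm
#'   (NMR) or cm^-1 (MIR); spectral blocks only; `step` must be > 0.
#' @param nInformative number of planted group-discriminative features
#'   (columns or peaks).
#' @param effectSize standardized mean shift between the two model
#'   groups; must be >= 0.
#' @param noiseSd noise standard deviation (log-intensity scale for
#'   tabular blocks, additive white noise for spectra); must be > 0
#'   (spectral blocks accept 0 for noise-free analytic checks).
#' @param baselineAmplitude spectral only: amplitude of the smooth
#'   baseline component.
#' @param peakWidth spectral only: Gaussian peak standard deviation in
#'   axis units.
#' @param nPeaks spectral only: number of simulated analyte peaks.
#' @param ampSigma spectral only: lognormal sd of per-sample peak
#'   amplitude variation.
#' @param peakRegions spectral only: list of `c(lo, hi)` axis windows
#'   inside which analyte peaks are placed (default: central 90% of the
#'   axis); lets informative peaks avoid masked/excluded regions.
#' @param peakPositions,peakAmplitudes optional fixed peak layout
#'   (overrides random placement; lengths must agree).
#' @return a `BlockSpec` (validated list).
#' @examples
#' blockSpec("LCMS", nFeatures = 171, nInformative = 12)
#' blockSpec("NMR", axis = c(-0.2, 12.2, 0.002), nPeaks = 30,
#'           nInformative = 6, peakWidth = 0.03)
#' @export
blockSpec <- function(platform, nFeatures = NULL, axis = NULL,
                      nInformative = 0L, effectSize = 2, noiseSd = 1,
                      baselineAmplitude = 0, peakWidth = NULL,
                      nPeaks = NULL, ampSigma = 0.25,
                      peakRegions = NULL, peakPositions = NULL,
                      peakAmplitudes = NULL) {
    platform <- match.arg(platform, c("LCMS", "GCMS", "NMR", "MIR"))
    spectral <- !is.null(axis)
    if (effectSize < 0) stop("invalid spec: effectSize must be >= 0")
    if (spectral) {
        if (length(axis) != 3L || axis[3L] <= 0)
            stop("invalid spec: axis must be c(start, stop, step) with step > 0")
        if (axis[1L] >= axis[2L])
            stop("invalid spec: axis start must precede stop")
        if (noiseSd < 0) stop("invalid spec: noiseSd must be >= 0")
        if (!is.null(peakPositions)) {
            nPeaks <- length(peakPositions)
            if (is.null(peakAmplitudes) ||
                length(peakAmplitudes) != nPeaks)
                stop("invalid spec: peakAmplitudes must match peakPositions")
        }
        if (is.null(nPeaks)) nPeaks <- 30L
        if (is.null(peakWidth) || peakWidth <= 0)
            stop("invalid spec: spectral blocks need peakWidth > 0")
        if (nInformative > nPeaks)
            stop("invalid spec: nInformative exceeds number of peaks")
        if (is.null(peakRegions)) {
            span <- axis[2L] - axis[1L]
            peakRegions <- list(c(axis[1L] + 0.05 * span,
                                  axis[2L] - 0.05 * span))
        }
    } else {
        if (is.null(nFeatures) || nFeatures < 1L)
            stop("invalid spec: tabular blocks need nFeatures >= 1")
        if (noiseSd <= 0) stop("invalid spec: noiseSd must be > 0")
        if (nInformative > nFeatures)
            stop("invalid spec: nInformative exceeds nFeatures")
    }
    structure(list(platform = platform, spectral = spectral,
                   nFeatures = nFeatures, axis = axis,
                   nInformative = as.integer(nInformative),
                   effectSize = effectSize, noiseSd = noiseSd,
                   baselineAmplitude = baselineAmplitude,
                   peakWidth = peakWidth,
                   nPeaks = if (spectral) as.integer(nPeaks) else NULL,
                   ampSigma = ampSigma, peakRegions = peakRegions,
                   peakPositions = peakPositions,
                   peakAmplitudes = peakAmplitudes),
              class = "BlockSpec")
}

#' Specify a synthetic multi-block study
#'
#' @param seed integer master seed; per-block child seeds are derived by
#'   fixed offsets so adding a block never perturbs earlier blocks.
#' @param groups named integer vector of model-set group sizes, e.g.
#'   `c(YN = 35, GX = 35)`; every size must be >= 2 and names unique.
#' @param blocks list of [blockSpec()] objects (platforms must be unique).
#' @param externalGroups named integer vector of external-validation
#'   group sizes (may be empty), e.g. `c(GD = 4, FJ = 4, MD = 3, LQS = 3)`.
#' @return a `SyntheticSpec` (validated list).
#' @seealso [generateStudy()], [defaultStudySpec()]
#' @export
syntheticSpec <- function(seed, groups, blocks, externalGroups = integer()) {
    labels <- c(names(groups), names(externalGroups))
    if (is.null(names(groups)) || anyDuplicated(labels))
        stop("invalid spec: group labels must be unique and named")
    if (any(c(groups, externalGroups) < 2L))
        stop("invalid spec: all group sizes must be >= 2")
    if (!all(vapply(blocks, inherits, logical(1L), "BlockSpec")))
        stop("invalid spec: blocks must be BlockSpec objects")
    plats <- vapply(blocks, `[[`, character(1L), "platform")
    if (anyDuplicated(plats)) stop("invalid spec: duplicate platforms")
    names(blocks) <- plats
    structure(list(seed = as.integer(seed), groups = groups,
                   blocks = blocks, externalGroups = externalGroups),
              class = "SyntheticSpec")
}

#' Build the sample manifest of a synthetic study
#'
#' @inheritParams syntheticSpec
#' @return data.frame with `sample_id`, `group`, `role` ("model" or
#'   "external"), samples numbered consecutively model-first.
#' @export
sampleManifest <- function(groups, externalGroups = integer()) {
    grp <- c(rep(names(groups), groups),
             rep(names(externalGroups), externalGroups))
    role <- c(rep("model", sum(groups)),
              rep("external", sum(as.integer(externalGroups))))
    data.frame(sample_id = sprintf("S%03d", seq_along(grp)),
               group = grp, role = role, stringsAsFactors = FALSE)
}

# Per-group coefficients on the planted features. The two model groups
# sit at 0 and 1, so their separation is exactly effectSize * noiseSd.
# External groups get distinct coefficients interleaved on both sides of
# the model groups at comparable magnitude, so the same planted
# variables also separate them without being trivially visible.
groupCoefficients <- function(manifest) {
    mg <- unique(manifest$group[manifest$role == "model"])
    eg <- unique(manifest$group[manifest$role == "external"])
    cm <- seq_along(mg) - 1
    ce <- numeric(length(eg))
    for (i in seq_along(eg)) {
        j <- (i - 1L) %/% 4L
        ce[i] <- switch(((i - 1L) %% 4L) + 1L,
                        1.5 + 2 * j, 2.5 + 2 * j, -0.5 - 2 * j, -1.5 - 2 * j)
    }
    stats::setNames(c(cm, ce), c(mg, eg))
}

childSeed <- function(seed, index)
    as.integer((as.numeric(seed) + 7919 * index) %% 2147483647)

#' Generate a tabular synthetic feature block
#'
#' Log-intensities are Gaussian around per-feature baselines; the planted
#' (informative) columns receive group-dependent mean shifts of
#' `sign_j * c_g * effectSize * noiseSd` (alternating signs, per-group
#' coefficients `c_g` with the two model groups at 0 and 1), and the
#' stored intensities are the exponentials, i.e. effects are
#' multiplicative on the intensity scale. The planted column identities
#' are recorded in `metadata()$informative`.
#'
#' @param spec a tabular [blockSpec()].
#' @param manifest a manifest from [sampleManifest()].
#' @param seed integer seed for this block.
#' @return a [FeatureBlock-class].
#' @export
generateFeatureBlock <- function(spec, manifest, seed) {
    stopifnot(inherits(spec, "BlockSpec"))
    if (spec$spectral)
        stop("invalid spec: generateFeatureBlock needs a tabular BlockSpec")
    if (!is.data.frame(manifest) || nrow(manifest) == 0L)
        stop("invalid spec: manifest must be a non-empty data.frame")
    n <- nrow(manifest); p <- spec$nFeatures
    set.seed(seed)
    base <- stats::runif(p, 4, 8)
    idx <- if (spec$nInformative > 0L) sort(sample.int(p, spec$nInformative))
           else integer()
    sgn <- rep_len(c(1, -1), length(idx))
    coef <- groupCoefficients(manifest)
    shift <- matrix(0, n, p)
    if (length(idx))
        shift[, idx] <- outer(coef[manifest$group],
                              sgn * spec$effectSize * spec$noiseSd)
    logI <- matrix(base, n, p, byrow = TRUE) + shift +
        matrix(stats::rnorm(n * p, 0, spec$noiseSd), n, p)
    mat <- exp(logI)
    dimnames(mat) <- list(manifest$sample_id,
                          sprintf("%s_F%03d", spec$platform, seq_len(p)))
    featureBlock(mat, spec$platform,
                 metadata = list(informative = data.frame(
                     feature = colnames(mat)[idx], index = idx, sign = sgn,
                     stringsAsFactors = FALSE)))
}

#' Generate a spectral synthetic block
#'
#' Each per-sample spectrum is a smooth baseline plus Gaussian peaks at
#' positions fixed across the study plus white noise. Peak amplitudes
#' vary lognormally between samples (`ampSigma`); the planted informative
#' peaks additionally carry group-dependent amplitude multipliers
#' `exp(sign * c_g * effectSize * ampSigma)`. NMR blocks always carry a
#' TSP reference peak at 0.00 ppm and a nuisance water band at 4.9 ppm
#' whose amplitude varies wildly between samples.
#'
#' @param spec a spectral [blockSpec()].
#' @inheritParams generateFeatureBlock
#' @return a [SpectrumSet-class]; peak provenance (positions, informative
#'   indices, signs) in its `peakInfo`.
#' @export
generateSpectrumBlock <- function(spec, manifest, seed) {
    stopifnot(inherits(spec, "BlockSpec"))
    if (!spec$spectral)
        stop("invalid spec: generateSpectrumBlock needs a spectral BlockSpec")
    if (!is.data.frame(manifest) || nrow(manifest) == 0L)
        stop("invalid spec: manifest must be a non-empty data.frame")
    ax <- seq(spec$axis[1L], spec$axis[2L], by = spec$axis[3L])
    set.seed(seed)
    if (!is.null(spec$peakPositions)) {
        pos <- spec$peakPositions
        amp <- spec$peakAmplitudes
    } else {
        widths <- vapply(spec$peakRegions, function(r) r[2L] - r[1L],
                         numeric(1L))
        reg <- sample.int(length(spec$peakRegions), spec$nPeaks,
                          replace = TRUE, prob = widths)
        pos <- vapply(seq_len(spec$nPeaks), function(i)
            stats::runif(1L, spec$peakRegions[[reg[i]]][1L],
                         spec$peakRegions[[reg[i]]][2L]), numeric(1L))
        amp <- stats::runif(spec$nPeaks, 2, 10)
    }
    nP <- length(pos)
    idx <- if (spec$nInformative > 0L) sort(sample.int(nP, spec$nInformative))
           else integer()
    sgn <- rep_len(c(1, -1), length(idx))
    coef <- groupCoefficients(manifest)
    # baseline shape fixed for the block; samples rescale it slightly
    blShape <- 0.6 + 0.4 * sin(2 * pi * (ax - ax[1L]) /
                               (ax[length(ax)] - ax[1L]) + stats::runif(1L, 0, 2 * pi))
    gauss <- function(center, width) exp(-(ax - center)^2 / (2 * width^2))
    peakMat <- vapply(pos, gauss, numeric(length(ax)), width = spec$peakWidth)
    groupMult <- rep(1, nP)
    specs <- vector("list", nrow(manifest))
    for (s in seq_len(nrow(manifest))) {
        g <- manifest$group[s]
        mult <- rep(1, nP)
        if (length(idx))
            mult[idx] <- exp(sgn * coef[[g]] * spec$effectSize * spec$ampSigma)
        sampAmp <- amp * mult * exp(stats::rnorm(nP, 0, spec$ampSigma))
        y <- as.numeric(peakMat %*% sampAmp) +
            spec$baselineAmplitude * blShape * exp(stats::rnorm(1L, 0, 0.1))
        if (spec$platform == "NMR") {
            y <- y + 8 * gauss(0, spec$peakWidth) +
                abs(stats::rnorm(1L, 20, 15)) * gauss(4.9, 0.05)
        }
        if (spec$noiseSd > 0)
            y <- y + stats::rnorm(length(ax), 0, spec$noiseSd)
        specs[[s]] <- spectrum(ax, y)
    }
    names(specs) <- manifest$sample_id
    spectrumSet(specs, spec$platform,
                peakInfo = list(positions = pos, amplitudes = amp,
                                informative = idx, sign = sgn,
                                peakWidth = spec$peakWidth))
}

#' Generate a full synthetic multi-block study
#'
#' Draws every block of `spec` with per-block child seeds derived from
#' the master seed by fixed offsets, assembles the manifest (model
#' samples first, then external) and the planted-feature ground truth.
#'
#' @param spec a [syntheticSpec()].
#' @return a [FusionStudy-class]; `plantedTruth()` lists, per block, the
#'   planted tabular feature ids or spectral peak positions together with
#'   their effect signs.
#' @examples
#' st <- generateStudy(syntheticSpec(1, c(A = 5, B = 5),
#'     list(blockSpec("LCMS", nFeatures = 20, nInformative = 3))))
#' manifest(st)
#' @export
generateStudy <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    man <- sampleManifest(spec$groups, spec$externalGroups)
    blks <- vector("list", length(spec$blocks))
    truth <- vector("list", length(spec$blocks))
    for (i in seq_along(spec$blocks)) {
        bs <- spec$blocks[[i]]
        sd_i <- childSeed(spec$seed, i)
        if (bs$spectral) {
            blk <- generateSpectrumBlock(bs, man, sd_i)
            truth[[i]] <- list(platform = bs$platform, type = "spectral",
                               positions = blk@peakInfo$positions[blk@peakInfo$informative],
                               sign = blk@peakInfo$sign,
                               peakWidth = bs$peakWidth)
        } else {
            blk <- generateFeatureBlock(bs, man, sd_i)
            info <- S4Vectors::metadata(blk)$informative
            truth[[i]] <- list(platform = bs$platform, type = "tabular",
                               features = info$feature, sign = info$sign)
        }
        blks[[i]] <- blk
    }
    names(blks) <- names(truth) <- names(spec$blocks)
    new("FusionStudy", manifest = man, blocks = blks,
        truth = list(seed = spec$seed, blocks = truth,
                     nPlanted = sum(vapply(spec$blocks, `[[`, integer(1L),
                                           "nInformative"))))
}

#' Reference synthetic study conditions
#'
#' The default multi-block study the package's benchmarks run on: two
#' model groups of 35 (YN, GX) and four external groups (GD 4, FJ 4,
#' MD 3, LQS 3), with an LC-MS block of 171 features (12 planted), a
#' GC-MS block of 78 features (8 planted), an NMR block on a
#' -0.2 to 12.2 ppm grid (30 peaks, 6 planted) and an MIR block on a
#' 400 to 4000 cm^-1 grid (20 peaks, 4 planted) — 30 planted features in
#' total. The tabular feature counts mirror typical LC-MS/GC-MS panel
#' sizes for this crop; effect size defaults to a standardized shift of
#' 2 between the model groups.
#'
#' @param seed integer master seed.
#' @param effectSize standardized between-model-group shift applied to
#'   every block (0 gives a pure-noise null study).
#' @return a `SyntheticSpec`.
#' @export
defaultStudySpec <- function(seed = 1L, effectSize = 2) {
    syntheticSpec(
        seed = seed,
        groups = c(YN = 35L, GX = 35L),
        externalGroups = c(GD = 4L, FJ = 4L, MD = 3L, LQS = 3L),
        blocks = list(
            blockSpec("LCMS", nFeatures = 171L, nInformative = 12L,
                      effectSize = effectSize, noiseSd = 1),
            blockSpec("GCMS", nFeatures = 78L, nInformative = 8L,
                      effectSize = effectSize, noiseSd = 1),
            blockSpec("NMR", axis = c(-0.2, 12.2, 2.5e-4), nPeaks = 30L,
                      nInformative = 6L, effectSize = effectSize,
                      noiseSd = 0.05, peakWidth = 8e-4,
                      baselineAmplitude = 0.5, ampSigma = 0.25,
                      peakRegions = list(c(0.5, 4.6), c(5.2, 11.8))),
            blockSpec("MIR", axis = c(400, 4000, 8), nPeaks = 20L,
                      nInformative = 4L, effectSize = effectSize,
                      noiseSd = 0.05, peakWidth = 3,
                      baselineAmplitude = 1, ampSigma = 0.25,
                      peakRegions = list(c(520, 2180), c(2420, 3480)))))
}
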