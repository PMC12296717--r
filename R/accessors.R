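#' Construct a FeatureBlock
#'
#' @param mat numeric matrix, samples in rows and features in columns
#'   (the orientation user code works in; storage is transposed to the
#'   features-by-samples convention of SummarizedExperiment).
#' @param platform platform tag, one of `"LCMS"`, `"GCMS"`, `"NMR"`,
#'   `"MIR"` (other tags are allowed for user data).
#' @param featureData optional data.frame of per-feature metadata
#'   (e.g. a `coordinate` column holding ppm or wavenumber values).
#' @param metadata optional list stored in `metadata()`.
#' @return a [FeatureBlock-class].
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("S", 1:4), paste0("F", 1:5)))
#' fb <- featureBlock(m, "LCMS")
#' dim(blockMatrix(fb))
#' @export
featureBlock <- function(mat, platform, featureData = NULL, metadata = list()) {
    if (!is.matrix(mat) || !is.numeric(mat))
        stop("'mat' must be a numeric matrix (samples x features)")
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("S%03d", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("F%04d", seq_len(ncol(mat)))
    rd <- if (is.null(featureData)) S4Vectors::DataFrame(row.names = colnames(mat))
          else S4Vectors::DataFrame(featureData, row.names = colnames(mat))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = t(mat)), rowData = rd)
    new("FeatureBlock", se, platform = as.character(platform),
        metadata = metadata)
}

#' @rdname FeatureBlock-class
#' @export
setMethod("platformOf", "FeatureBlock", function(x) x@platform)

#' @rdname FeatureBlock-class
#' @export
setMethod("platformOf", "SpectrumSet", function(x) x@platform)

#' @describeIn FeatureBlock-class the samples-by-features intensity
#'   matrix (base matrix, sample ids as rownames).
#' @export
setMethod("blockMatrix", "FeatureBlock",
    function(x) t(SummarizedExperiment::assay(x, "intensity")))

setMethod("show", "FeatureBlock", function(object) {
    cat(sprintf("FeatureBlock [%s]: %d samples x %d features\n",
                object@platform, ncol(object), nrow(object)))
    std <- S4Vectors::metadata(object)$standardization
    if (!is.null(std)) cat("  standardized (model-set Z-score)\n")
})

#' Construct a Spectrum
#'
#' @param axis numeric strictly monotone axis (ppm or cm^-1).
#' @param intensity numeric intensity, same length.
#' @return a [Spectrum-class].
#' @export
spectrum <- function(axis, intensity)
    new("Spectrum", axis = as.numeric(axis), intensity = as.numeric(intensity))

#' @rdname Spectrum-class
#' @param x,object a `Spectrum`.
#' @export
spectrumAxis <- function(x) x@axis

#' @rdname Spectrum-class
#' @export
spectrumIntensity <- function(x) x@intensity

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum: %d points, axis [%g, %g]\n",
                length(object@axis), min(object@axis), max(object@axis)))
})

#' Construct a SpectrumSet
#'
#' @param spectra named list of [Spectrum-class] (names = sample ids).
#' @param platform platform tag (`"NMR"` or `"MIR"`).
#' @param peakInfo optional peak provenance list.
#' @return a [SpectrumSet-class].
#' @export
spectrumSet <- function(spectra, platform, peakInfo = list())
    new("SpectrumSet", spectra = spectra, platform = as.character(platform),
        peakInfo = peakInfo)

#' @rdname SpectrumSet-class
#' @param x,object a `SpectrumSet`.
#' @export
spectra <- function(x) x@spectra

setMethod("show", "SpectrumSet", function(object) {
    cat(sprintf("SpectrumSet [%s]: %d spectra\n",
                object@platform, length(object@spectra)))
})

#' @describeIn FusionStudy-class sample manifest (sample_id, group, role).
#' @export
setMethod("manifest", "FusionStudy", function(x) x@manifest)

#' @describeIn FusionStudy-class named list of per-platform blocks.
#' @export
setMethod("blocks", "FusionStudy", function(x) x@blocks)

#' @describeIn FusionStudy-class planted-feature ground truth (synthetic
#'   studies; empty list for real data).
#' @export
setMethod("plantedTruth", "FusionStudy", function(x) x@truth)

setMethod("show", "FusionStudy", function(object) {
    m <- object@manifest
    cat(sprintf("FusionStudy: %d samples (%d model, %d external), %d blocks\n",
                nrow(m), sum(m$role == "model"), sum(m$role == "external"),
                length(object@blocks)))
    for (nm in names(object@blocks)) {
        b <- object@blocks[[nm]]
        cat(sprintf("  %-6s %s\n", nm,
                    if (is(b, "FeatureBlock"))
                        sprintf("feature table (%d features)", nrow(b))
                    else sprintf("spectra (%d points)",
                                 length(b@spectra[[1L]]@axis))))
    }
})

#' Construct a FusionConfig
#'
#' All arguments default to the workflow's reference settings; see
#' [FusionConfig-class] for their meaning.
#'
#' @param midBudget per-block variable budget for DT/RF mid-level selectors.
#' @param hldfBudgets two successive per-block RF budgets (high-level).
#' @param hldfWeight per-block Gini weight; `NA` means 1/n_blocks.
#' @param hldfFinalBudget size of the final merged high-level panel.
#' @param hldfRefit logical; refit the second-stage forest on the stage-1
#'   survivors (the default) or reuse stage-1 importances.
#' @param varianceTarget cumulative-variance target for PCA/PLS-DA.
#' @param trainFraction train share of the model set.
#' @param screenK characteristic-variable count.
#' @param nnMaxIter gradient steps for the neural-network classifier.
#' @param seed integer seed.
#' @return a [FusionConfig-class].
#' @export
fusionConfig <- function(midBudget = 40L, hldfBudgets = c(120L, 40L),
                         hldfWeight = NA_real_, hldfFinalBudget = 40L,
                         hldfRefit = TRUE, varianceTarget = 0.95,
                         trainFraction = 0.7, screenK = 38L,
                         nnMaxIter = 150L, seed = 1L) {
    new("FusionConfig", midBudget = as.integer(midBudget),
        hldfBudgets = as.integer(hldfBudgets),
        hldfWeight = as.numeric(hldfWeight),
        hldfFinalBudget = as.integer(hldfFinalBudget),
        hldfRefit = hldfRefit, varianceTarget = varianceTarget,
        trainFraction = trainFraction, screenK = as.integer(screenK),
        nnMaxIter = as.integer(nnMaxIter), seed = as.integer(seed))
}

#' Short digest of a FusionConfig
#'
#' Deterministic fingerprint used to tie reports and screened panels to
#' the configuration that produced them.
#' @param config a [FusionConfig-class].
#' @return character scalar.
#' @export
configDigest <- function(config) {
    stopifnot(is(config, "FusionConfig"))
    fields <- c(config@midBudget, config@hldfBudgets, config@hldfWeight,
                config@hldfFinalBudget, as.integer(config@hldfRefit),
                config@varianceTarget, config@trainFraction, config@screenK,
                config@nnMaxIter, config@seed)
    paste0("cfg-", format(sum(cumsum(as.numeric(
        utf8ToInt(paste(fields, collapse = "|")))) %% 999983), scientific = FALSE))
}

setMethod("show", "FusionConfig", function(object) {
    cat(sprintf(paste0(
        "FusionConfig: mid budget %d | HLDF budgets %d->%d, weight %s, ",
        "final %d | variance target %.2f | train fraction %.2f | k = %d | ",
        "seed %d\n"),
        object@midBudget, object@hldfBudgets[1L], object@hldfBudgets[2L],
        ifelse(is.na(object@hldfWeight), "1/n_blocks",
               format(object@hldfWeight)),
        object@hldfFinalBudget, object@varianceTarget, object@trainFraction,
        object@screenK, object@seed))
})

#' @describeIn ModelReport-class named numeric vector of the seven
#'   comparison metrics.
#' @export
setMethod("metrics", "ModelReport", function(x)
    c(oob = x@oob, accuracy_train = x@accuracyTrain,
      accuracy_test = x@accuracyTest, precision = x@precision,
      f1 = x@f1, recall = x@recall, auc = x@auc))

setMethod("show", "ModelReport", function(object) {
    m <- metrics(object)
    cat(sprintf("ModelReport [%s]\n", object@modelName))
    for (nm in names(m))
        cat(sprintf("  %-14s %s\n", nm,
                    ifelse(is.na(m[[nm]]), "-", sprintf("%.4f", m[[nm]]))))
})

#' @describeIn CharacteristicVariableSet-class the ranked variable table.
#' @export
setMethod("variables", "CharacteristicVariableSet", function(x) x@variables)

setMethod("show", "CharacteristicVariableSet", function(object) {
    cat(sprintf("CharacteristicVariableSet: top %d from %s\n",
                nrow(object@variables), object@sourceModel))
    print(utils::head(object@variables, 5L), row.names = FALSE)
    if (nrow(object@variables) > 5L)
        cat(sprintf("  ... %d more\n", nrow(object@variables) - 5L))
})

#' @describeIn ProjectionReport-class the scalar separation index.
#' @export
setMethod("separationIndexOf", "ProjectionReport",
    function(x) x@separationIndex)

setMethod("show", "ProjectionReport", function(object) {
    cat(sprintf(
        "ProjectionReport: %d samples, %d groups, PC1+PC2 = %.1f%% var, separation index %.3f\n",
        nrow(object@scores), length(unique(object@groups)),
        100 * sum(object@explainedVariance), object@separationIndex))
})
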