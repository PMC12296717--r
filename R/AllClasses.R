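#' @import methods
#' @importFrom S4Vectors SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' FeatureBlock: one platform's feature table
#'
#' A `FeatureBlock` holds a single analytical platform's samples-by-features
#' intensity table as a [SummarizedExperiment::SummarizedExperiment]
#' (features as rows, samples as columns, one assay named `"intensity"`),
#' tagged with the platform it came from (`"LCMS"`, `"GCMS"`, `"NMR"` or
#' `"MIR"`). Feature coordinates (chemical shift in ppm, wavenumber in
#' cm^-1) live in `rowData`; provenance such as planted-feature ground
#' truth or fitted standardization statistics lives in `metadata()`.
#'
#' @slot platform single character scalar naming the platform.
#' @seealso [featureBlock()], [blockMatrix()], [platformOf()]
#' @export
setClass("FeatureBlock",
    contains = "SummarizedExperiment",
    representation(platform = "character"))

setValidity("FeatureBlock", function(object) {
    if (length(object@platform) != 1L || is.na(object@platform))
        return("'platform' must be a single non-NA character scalar")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'intensity' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("features must have unique names")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("samples must have unique names")
    TRUE
})

#' Spectrum: a single 1-D spectrum
#'
#' An axis/intensity pair: chemical shift (ppm, NMR) or wavenumber
#' (cm^-1, MIR) against intensity. The axis must be strictly monotone,
#' the two vectors equal-length and finite.
#'
#' @slot axis numeric, strictly monotone.
#' @slot intensity numeric, same length as `axis`.
#' @export
setClass("Spectrum",
    representation(axis = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
    a <- object@axis; y <- object@intensity
    if (length(a) != length(y))
        return("axis and intensity must have equal length")
    if (length(a) < 2L)
        return("a spectrum needs at least two grid points")
    if (anyNA(a) || anyNA(y) || any(!is.finite(a)) || any(!is.finite(y)))
        return("axis and intensity must be finite and free of NA")
    d <- diff(a)
    if (!(all(d > 0) || all(d < 0)))
        return("axis must be strictly monotone")
    TRUE
})

#' SpectrumSet: per-sample raw spectra from one platform
#'
#' A named list of [Spectrum-class] objects (names are sample ids), all
#' from the same platform. Axes may differ between samples (e.g. after
#' chemical-shift referencing), which is why spectra are not forced onto
#' a shared grid until bucketing/region removal produces a
#' [FeatureBlock-class].
#'
#' @slot spectra named list of `Spectrum`.
#' @slot platform single character scalar.
#' @slot peakInfo list of per-study peak provenance (may be empty).
#' @export
setClass("SpectrumSet",
    representation(spectra = "list", platform = "character",
                   peakInfo = "list"))

setValidity("SpectrumSet", function(object) {
    if (length(object@platform) != 1L)
        return("'platform' must be a single character scalar")
    if (length(object@spectra) == 0L)
        return("at least one spectrum is required")
    if (is.null(names(object@spectra)) || anyDuplicated(names(object@spectra)))
        return("spectra must be uniquely named by sample id")
    ok <- vapply(object@spectra, is, logical(1L), class2 = "Spectrum")
    if (!all(ok)) return("all elements must be Spectrum objects")
    TRUE
})

#' FusionStudy: a co-registered multi-block study
#'
#' The manifest (sample id, group label, model/external role) together
#' with the per-platform blocks ([FeatureBlock-class] for tabular
#' platforms, [SpectrumSet-class] for spectral ones) and, for synthetic
#' studies, the planted-feature ground truth.
#'
#' @slot manifest data.frame with columns `sample_id`, `group`, `role`.
#' @slot blocks named list of `FeatureBlock` / `SpectrumSet`.
#' @slot truth list: planted-feature provenance (empty for real data).
#' @export
setClass("FusionStudy",
    representation(manifest = "data.frame", blocks = "list", truth = "list"))

setValidity("FusionStudy", function(object) {
    m <- object@manifest
    need <- c("sample_id", "group", "role")
    if (!all(need %in% names(m)))
        return("manifest needs columns sample_id, group, role")
    if (anyDuplicated(m$sample_id)) return("duplicate sample ids in manifest")
    if (!all(m$role %in% c("model", "external")))
        return("roles must be 'model' or 'external'")
    if (length(object@blocks) &&
        (is.null(names(object@blocks)) || anyDuplicated(names(object@blocks))))
        return("blocks must be uniquely named")
    TRUE
})

#' FusionConfig: hyper-parameters of the fusion pipeline
#'
#' Collects every tunable of the fusion workflow in one validated object:
#' the mid-level selection budget (40 variables for DT/RF selectors), the
#' two-stage high-level budgets (120 then 40 per block), the high-level
#' block weight (1/4 for four blocks), the merged-pool final budget (40),
#' the cumulative-variance target for PCA/PLS-DA component counts (0.95),
#' the train fraction of the model set (0.7), the screening size k (38),
#' classifier settings (RBF SVM, 3-NN, a 500/200/10 feed-forward network,
#' Gini decision tree, 100-tree random forest) and the seed.
#'
#' @slot midBudget integer, per-block variable budget for DT/RF selectors.
#' @slot hldfBudgets integer(2), successive per-block RF budgets.
#' @slot hldfWeight numeric, per-block Gini weight (`NA` = 1/n_blocks).
#' @slot hldfFinalBudget integer, size of the final merged panel.
#' @slot hldfRefit logical, refit the stage-2 forest on the survivors.
#' @slot varianceTarget numeric in (0, 1].
#' @slot trainFraction numeric in (0, 1).
#' @slot screenK integer, characteristic-variable count.
#' @slot nnMaxIter integer, gradient steps for the neural network.
#' @slot seed integer.
#' @export
setClass("FusionConfig",
    representation(midBudget = "integer", hldfBudgets = "integer",
                   hldfWeight = "numeric", hldfFinalBudget = "integer",
                   hldfRefit = "logical", varianceTarget = "numeric",
                   trainFraction = "numeric", screenK = "integer",
                   nnMaxIter = "integer", seed = "integer"),
    prototype(midBudget = 40L, hldfBudgets = c(120L, 40L),
              hldfWeight = NA_real_, hldfFinalBudget = 40L,
              hldfRefit = TRUE, varianceTarget = 0.95,
              trainFraction = 0.7, screenK = 38L,
              nnMaxIter = 150L, seed = 1L))

setValidity("FusionConfig", function(object) {
    if (length(object@hldfBudgets) != 2L || any(object@hldfBudgets <= 0L))
        return("hldfBudgets must be two positive integers")
    if (diff(object@hldfBudgets) > 0L)
        return("hldfBudgets must be non-increasing")
    if (object@midBudget <= 0L || object@hldfFinalBudget <= 0L ||
        object@screenK <= 0L)
        return("budgets must be positive")
    if (!(object@trainFraction > 0 && object@trainFraction < 1))
        return("trainFraction must lie strictly inside (0, 1)")
    if (!(object@varianceTarget > 0 && object@varianceTarget <= 1))
        return("varianceTarget must lie in (0, 1]")
    TRUE
})

#' ModelReport: the performance surface of one fitted model
#'
#' Holds the seven comparison metrics (out-of-bag accuracy where defined,
#' train/test accuracy, precision, recall, F1, AUC) and the ROC polyline
#' for one fusion strategy, plus the seed and a config digest for
#' provenance.
#'
#' @slot modelName character, e.g. `"RF-RF"`.
#' @slot oob numeric, out-of-bag accuracy (`NA` for non-forest models).
#' @slot accuracyTrain,accuracyTest,precision,recall,f1,auc numerics in
#'   `[0, 1]`.
#' @slot rocPoints two-column matrix of (fpr, tpr), from (0,0) to (1,1).
#' @slot positiveClass character.
#' @slot seed integer.
#' @slot configDigest character.
#' @export
setClass("ModelReport",
    representation(modelName = "character", oob = "numeric",
                   accuracyTrain = "numeric", accuracyTest = "numeric",
                   precision = "numeric", recall = "numeric", f1 = "numeric",
                   auc = "numeric", rocPoints = "matrix",
                   positiveClass = "character", seed = "integer",
                   configDigest = "character"))

setValidity("ModelReport", function(object) {
    vals <- c(object@accuracyTrain, object@accuracyTest, object@precision,
              object@recall, object@f1, object@auc)
    if (any(!is.na(vals) & (vals < -1e-9 | vals > 1 + 1e-9)))
        return("metrics must lie in [0, 1]")
    rp <- object@rocPoints
    if (ncol(rp) != 2L) return("rocPoints must have two columns (fpr, tpr)")
    if (nrow(rp) >= 2L) {
        if (any(abs(rp[1L, ] - 0) > 1e-9) || any(abs(rp[nrow(rp), ] - 1) > 1e-9))
            return("ROC must start at (0,0) and end at (1,1)")
        if (any(diff(rp[, 1L]) < -1e-12) || any(diff(rp[, 2L]) < -1e-12))
            return("ROC coordinates must be non-decreasing")
    }
    TRUE
})

#' CharacteristicVariableSet: screened top-k variables
#'
#' The ordered characteristic variables exported from the best fusion
#' model (by default the top 38 by fused Gini importance), each traceable
#' to its platform block and original feature id.
#'
#' @slot sourceModel character, name of the model screened from.
#' @slot k integer, requested panel size.
#' @slot variables data.frame: `rank`, `block`, `feature`,
#'   `raw_importance`, `fused_importance`.
#' @slot provenance list (seed, config digest).
#' @export
setClass("CharacteristicVariableSet",
    representation(sourceModel = "character", k = "integer",
                   variables = "data.frame", provenance = "list"))

setValidity("CharacteristicVariableSet", function(object) {
    v <- object@variables
    need <- c("rank", "block", "feature", "raw_importance", "fused_importance")
    if (!all(need %in% names(v)))
        return("variables needs rank, block, feature, raw_importance, fused_importance")
    if (nrow(v) > 1L && any(diff(v$fused_importance) > 1e-12))
        return("fused importances must be non-increasing")
    TRUE
})

#' ProjectionReport: unsupervised 2-D projection of a sample set
#'
#' PCA scores of (typically) the external validation samples restricted
#' to a screened variable panel, with group labels and a separation
#' index: the ratio of mean between-group to mean within-group pairwise
#' distance in the 2-D score space.
#'
#' @slot scores numeric matrix, samples x 2.
#' @slot explainedVariance numeric(2), variance fractions of the two PCs.
#' @slot groups character, group label per sample.
#' @slot separationIndex numeric scalar, > 0.
#' @export
setClass("ProjectionReport",
    representation(scores = "matrix", explainedVariance = "numeric",
                   groups = "character", separationIndex = "numeric"))

setValidity("ProjectionReport", function(object) {
    if (ncol(object@scores) != 2L) return("scores must have two columns")
    if (nrow(object@scores) != length(object@groups))
        return("one group label per projected sample is required")
    if (length(object@separationIndex) != 1L || object@separationIndex <= 0)
        return("separationIndex must be a positive scalar")
    if (any(abs(colMeans(object@scores)) > 1e-6))
        return("scores must be column-centered")
    TRUE
})
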