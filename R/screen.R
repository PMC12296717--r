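#' Screen the top-k characteristic variables
#'
#' Takes the first `k` entries (default 38) of a fused ranked-feature
#' table — a pure function of the ranking, so re-screening without a
#' refit is idempotent — and packages them with their provenance.
#'
#' @param ranked ranked-feature data.frame (`block`, `feature`,
#'   `raw_importance`, `fused_importance`, `rank`), e.g. from
#'   [mldfFuse()] or [hldfGiniFusion()].
#' @param k panel size; if larger than the pool the whole pool is
#'   returned with a warning.
#' @param sourceModel name of the model the ranking came from.
#' @param provenance list (seed, config digest) recorded alongside.
#' @return a [CharacteristicVariableSet-class].
#' @export
screenTopK <- function(ranked, k = 38L, sourceModel = "RF-RF",
                       provenance = list()) {
    if (is.null(ranked) || nrow(ranked) == 0L)
        stop("invalid input: empty ranking")
    if (k <= 0L) stop("invalid parameter: k must be positive")
    if (k > nrow(ranked)) {
        warning("k exceeds the ranked pool; returning the whole pool")
        k <- nrow(ranked)
    }
    v <- ranked[order(ranked$rank), , drop = FALSE][seq_len(k), , drop = FALSE]
    rownames(v) <- NULL
    new("CharacteristicVariableSet", sourceModel = sourceModel,
        k = as.integer(k),
        variables = v[, c("rank", "block", "feature", "raw_importance",
                          "fused_importance")],
        provenance = provenance)
}

#' Write a characteristic-variable table
#'
#' CSV in the conventional screening layout: rank, Gini importance,
#' block, feature id.
#'
#' @param vs a [CharacteristicVariableSet-class].
#' @param path output CSV path.
#' @export
writeVariableSet <- function(vs, path) {
    v <- vs@variables
    utils::write.csv(data.frame(rank = v$rank,
                                importance = v$fused_importance,
                                block = v$block, feature = v$feature),
                     path, row.names = FALSE)
    invisible(path)
}

#' Group-separation index of a 2-D projection
#'
#' Ratio of the mean between-group to the mean within-group pairwise
#' Euclidean distance (an epsilon guard handles degenerate zero
#' within-group spread). Invariant under rotation and translation of
#' the scores.
#'
#' @param scores numeric matrix, samples x d.
#' @param groups group label per sample.
#' @param eps denominator guard.
#' @return positive scalar; larger = better separated groups.
#' @export
separationIndex <- function(scores, groups, eps = 1e-8) {
    groups <- as.character(groups)
    d <- as.matrix(stats::dist(scores))
    same <- outer(groups, groups, `==`)
    upper <- upper.tri(d)
    within <- d[upper & same]
    between <- d[upper & !same]
    if (length(between) == 0L)
        stop("separation index needs at least two groups")
    w <- if (length(within)) mean(within) else 0
    max(mean(between) / (w + eps), eps)
}

#' Project the external set onto screened variables
#'
#' Restricts the external-validation samples to the screened
#' characteristic variables (original variables only — score-type
#' mid-level features are untraceable and are rejected), keeps the
#' model-set standardization already carried by the blocks, fits PCA on
#' the external samples themselves (the default; set
#' `fitOn = "model"` to project through model-set loadings instead) and
#' summarizes the 2-D scores with the group [separationIndex()].
#'
#' With `variableSet = NULL` the projection uses every column of every
#' block (the full-concatenation baseline the screened panel is
#' compared against).
#'
#' @param blks named list of standardized [FeatureBlock-class] covering
#'   model and external samples.
#' @param manifest study manifest (role `"external"` marks the samples
#'   projected).
#' @param variableSet a [CharacteristicVariableSet-class], or `NULL`
#'   for the all-variables baseline.
#' @param fitOn `"external"` (default) or `"model"`: which samples the
#'   PCA loadings are estimated from.
#' @return a [ProjectionReport-class].
#' @export
projectExternal <- function(blks, manifest, variableSet = NULL,
                            fitOn = c("external", "model")) {
    fitOn <- match.arg(fitOn)
    extIds <- manifest$sample_id[manifest$role == "external"]
    if (length(extIds) < 3L)
        stop("need at least 3 external samples to project")
    if (is.null(variableSet)) {
        fusedAll <- blockMatrix(lldfConcatenate(blks))
        X <- fusedAll
    } else {
        v <- variableSet@variables
        cols <- vector("list", nrow(v))
        for (j in seq_len(nrow(v))) {
            if (!v$block[j] %in% names(blks))
                stop(sprintf("schema error: block '%s' absent", v$block[j]))
            m <- blockMatrix(blks[[v$block[j]]])
            if (!v$feature[j] %in% colnames(m))
                stop(sprintf(
                    "schema error: screened variable '%s' missing from block '%s' (score-type features cannot be screened)",
                    v$feature[j], v$block[j]))
            cols[[j]] <- m[, v$feature[j]]
        }
        X <- do.call(cbind, cols)
        colnames(X) <- paste(v$block, v$feature, sep = ".")
        rownames(X) <- rownames(blockMatrix(blks[[1L]]))
    }
    Xext <- X[extIds, , drop = FALSE]
    if (fitOn == "external") {
        pc <- stats::prcomp(Xext, center = TRUE, scale. = FALSE)
        sc <- pc$x[, 1:2, drop = FALSE]
        ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
    } else {
        modIds <- manifest$sample_id[manifest$role == "model"]
        pc <- stats::prcomp(X[modIds, , drop = FALSE], center = TRUE,
                            scale. = FALSE)
        sc <- scale(Xext, center = pc$center, scale = FALSE) %*%
            pc$rotation[, 1:2, drop = FALSE]
        sc <- scale(sc, center = TRUE, scale = FALSE)[, , drop = FALSE]
        ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
    }
    grp <- manifest$group[match(extIds, manifest$sample_id)]
    new("ProjectionReport", scores = unname(sc[, 1:2, drop = FALSE]),
        explainedVariance = as.numeric(ev), groups = as.character(grp),
        separationIndex = separationIndex(sc[, 1:2, drop = FALSE], grp))
}

#' Recovery of planted features by a screened panel
#'
#' Fraction of a synthetic study's planted features matched by a
#' screened variable set: tabular planted features match by exact
#' feature id; spectral planted peaks match when a screened variable
#' from the same platform lies within `tolFactor` peak widths of the
#' peak apex (screened bucket/wavenumber positions are parsed from the
#' `ppm_*` / `wn_*` feature names).
#'
#' @param study a synthetic [FusionStudy-class] (needs `plantedTruth`).
#' @param variableSet a [CharacteristicVariableSet-class].
#' @param tolFactor spectral matching tolerance in peak widths.
#' @return recall in `[0, 1]`.
#' @export
plantedRecovery <- function(study, variableSet, tolFactor = 2) {
    truth <- plantedTruth(study)
    if (length(truth) == 0L) stop("study carries no planted truth")
    v <- variableSet@variables
    hits <- 0L; total <- 0L
    for (tb in truth$blocks) {
        vb <- v[v$block == tb$platform, , drop = FALSE]
        if (tb$type == "tabular") {
            total <- total + length(tb$features)
            hits <- hits + sum(tb$features %in% vb$feature)
        } else {
            total <- total + length(tb$positions)
            if (nrow(vb) == 0L) next
            coords <- suppressWarnings(as.numeric(sub("^(ppm|wn)_", "",
                                                      vb$feature)))
            coords <- coords[is.finite(coords)]
            tol <- tolFactor * tb$peakWidth
            hits <- hits + sum(vapply(tb$positions, function(p)
                any(abs(coords - p) <= tol), logical(1L)))
        }
    }
    if (total == 0L) stop("no planted features recorded")
    hits / total
}
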