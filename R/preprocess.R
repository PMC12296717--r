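#' NMR bucketing scheme
#'
#' Defaults follow the standard high-resolution workflow for 1H spectra:
#' 0.002 ppm buckets tiling 0.4-12.0 ppm as half-open intervals, the
#' residual-water window 4.8-5.0 ppm excluded (any bucket overlapping it
#' is dropped whole), chemical shift referenced to TSP at 0.00 ppm.
#'
#' @param width bucket width in ppm.
#' @param range `c(lo, hi)` bucketed chemical-shift range.
#' @param exclusions list of `c(lo, hi)` excluded windows inside `range`.
#' @param referenceShift chemical shift of the reference signal (ppm).
#' @param referenceWindow half-width of the search window around
#'   `referenceShift` when locating the reference peak.
#' @return a `BucketingScheme` list.
#' @export
bucketingScheme <- function(width = 0.002, range = c(0.4, 12.0),
                            exclusions = list(c(4.8, 5.0)),
                            referenceShift = 0.0, referenceWindow = 0.05) {
    if (width <= 0) stop("invalid scheme: width must be > 0")
    if (range[1L] >= range[2L]) stop("invalid scheme: empty range")
    for (e in exclusions)
        if (e[1L] >= e[2L] || e[1L] < range[1L] || e[2L] > range[2L])
            stop("invalid scheme: exclusions must be lo < hi inside range")
    structure(list(width = width, range = range, exclusions = exclusions,
                   referenceShift = referenceShift,
                   referenceWindow = referenceWindow),
              class = "BucketingScheme")
}

#' MIR preprocessing configuration
#'
#' Savitzky-Golay smoothing followed by vector normalization followed by
#' removal of uninformative wavenumber regions (defaults: 3500-4000,
#' 2200-2400 and 400-500 cm^-1, as closed intervals — boundary points are
#' removed).
#'
#' The default window (5 points, i.e. 40 cm^-1 at the typical 8 cm^-1
#' FTIR sampling interval) is matched to the width of the narrowest
#' analyte bands: a substantially wider window smears each band across
#' many neighbouring grid points, distorting sharp features and
#' inflating the number of redundant discriminative variables.
#'
#' @param sgWindow odd window length (points) of the SG filter.
#' @param sgPolyorder polynomial order, < `sgWindow`.
#' @param removedRegions list of `c(lo, hi)` closed removed regions.
#' @param fullRange instrument range, cm^-1.
#' @return a `MirPipelineConfig` list.
#' @export
mirPipelineConfig <- function(sgWindow = 5L, sgPolyorder = 3L,
                              removedRegions = list(c(3500, 4000),
                                                    c(2200, 2400),
                                                    c(400, 500)),
                              fullRange = c(400, 4000)) {
    if (sgWindow %% 2L == 0L || sgPolyorder >= sgWindow)
        stop("invalid config: need odd sgWindow and sgPolyorder < sgWindow")
    for (r in removedRegions)
        if (r[1L] >= r[2L] || r[1L] < fullRange[1L] || r[2L] > fullRange[2L])
            stop("invalid config: regions must be lo < hi inside fullRange")
    structure(list(sgWindow = as.integer(sgWindow),
                   sgPolyorder = as.integer(sgPolyorder),
                   removedRegions = removedRegions, fullRange = fullRange),
              class = "MirPipelineConfig")
}

#' Reference a spectrum to its lock signal
#'
#' Locates the reference peak (tallest local maximum within
#' `referenceWindow` of `referenceShift`, TSP at 0.00 ppm by default) and
#' translates the axis so the apex sits exactly at the reference shift.
#'
#' @param x a [Spectrum-class].
#' @param scheme a [bucketingScheme()].
#' @return the referenced `Spectrum`.
#' @export
referenceAlign <- function(x, scheme = bucketingScheme()) {
    stopifnot(is(x, "Spectrum"))
    ax <- x@axis; y <- x@intensity
    win <- which(abs(ax - scheme$referenceShift) <= scheme$referenceWindow)
    if (length(win) == 0L)
        stop("reference not found: no grid points in the reference window")
    # local maxima within the window (interior of the full grid)
    isMax <- vapply(win, function(i) {
        i > 1L && i < length(y) && y[i] >= y[i - 1L] && y[i] >= y[i + 1L] &&
            (y[i] > y[i - 1L] || y[i] > y[i + 1L])
    }, logical(1L))
    cand <- win[isMax]
    if (length(cand) == 0L)
        stop("reference not found: no peak inside the reference window")
    apex <- cand[which.max(y[cand])]
    spectrum(ax - (ax[apex] - scheme$referenceShift), y)
}

# bucket edges and retained-bucket mask for a scheme
bucketEdges <- function(scheme) {
    n <- max(1L, round((scheme$range[2L] - scheme$range[1L]) / scheme$width))
    lo <- scheme$range[1L] + (seq_len(n) - 1L) * scheme$width
    hi <- lo + scheme$width
    keep <- rep(TRUE, n)
    # a half-open bucket [lo, hi) overlaps an exclusion (a, b) iff
    # lo < b and hi > a; boundary-touching buckets are retained
    for (e in scheme$exclusions)
        keep <- keep & !(lo < e[2L] - 1e-12 & hi > e[1L] + 1e-12)
    list(lo = lo, hi = hi, keep = keep,
         center = lo + scheme$width / 2)
}

#' Bucket a referenced NMR spectrum
#'
#' Tiles the scheme range with half-open `[b, b + width)` buckets, drops
#' every bucket overlapping an exclusion window whole, and sums the
#' intensities of the grid points falling in each retained bucket
#' (the sum preserves integral proportionality on a uniform grid).
#'
#' @param x a referenced [Spectrum-class].
#' @param scheme a [bucketingScheme()].
#' @return list with `values` (named numeric, names `"ppm_<center>"`),
#'   `centers`, `lo`, `hi` for the retained buckets.
#' @export
bucketSpectrum <- function(x, scheme = bucketingScheme()) {
    stopifnot(is(x, "Spectrum"))
    if (length(x@axis) == 0L) stop("invalid input: empty spectrum")
    ed <- bucketEdges(scheme)
    edges <- c(ed$lo, ed$hi[length(ed$hi)])
    idx <- findInterval(x@axis, edges, left.open = FALSE,
                        rightmost.closed = FALSE)
    inside <- idx >= 1L & x@axis < edges[length(edges)] - 1e-12 &
        idx <= length(ed$lo)
    sums <- numeric(length(ed$lo))
    if (any(inside)) {
        agg <- rowsum(x@intensity[inside], idx[inside])
        sums[as.integer(rownames(agg))] <- agg[, 1L]
    }
    keep <- ed$keep
    values <- sums[keep]
    names(values) <- sprintf("ppm_%.4f", ed$center[keep])
    list(values = values, centers = ed$center[keep],
         lo = ed$lo[keep], hi = ed$hi[keep])
}

#' Savitzky-Golay smoothing
#'
#' Degree-`polyorder` local least-squares smoothing over an odd
#' `window`; each interior point is replaced by the window-center value
#' of the local fit, edge points by the terminal windows' polynomial
#' fits evaluated in place. Polynomials of degree <= `polyorder` are
#' exact fixed points.
#'
#' @param x a [Spectrum-class].
#' @param window odd integer window length (points).
#' @param polyorder polynomial order, < `window`.
#' @return the smoothed `Spectrum`.
#' @export
savitzkyGolay <- function(x, window = 11L, polyorder = 3L) {
    stopifnot(is(x, "Spectrum"))
    if (window %% 2L == 0L || polyorder >= window ||
        length(x@intensity) < window)
        stop("invalid parameter: need odd window, polyorder < window, length >= window")
    spectrum(x@axis,
             as.numeric(signal::sgolayfilt(x@intensity, p = polyorder,
                                           n = window)))
}

#' Vector normalization
#'
#' Scales the intensity vector to unit Euclidean norm (scale-invariant;
#' idempotent on unit vectors).
#'
#' @param x a [Spectrum-class].
#' @return the normalized `Spectrum`.
#' @export
vectorNormalize <- function(x) {
    stopifnot(is(x, "Spectrum"))
    nrm <- sqrt(sum(x@intensity^2))
    if (nrm == 0) stop("degenerate spectrum: zero intensity vector")
    spectrum(x@axis, x@intensity / nrm)
}

#' Remove uninformative spectral regions
#'
#' Drops every grid point whose axis value lies inside any removed
#' region (closed intervals: boundary points are removed); the remaining
#' points in axis order become the feature vector.
#'
#' @param x a [Spectrum-class].
#' @param config a [mirPipelineConfig()].
#' @return list with `values` (named numeric, names `"wn_<axis>"`) and
#'   `axis` (retained axis values).
#' @export
removeRegions <- function(x, config = mirPipelineConfig()) {
    stopifnot(is(x, "Spectrum"))
    drop <- rep(FALSE, length(x@axis))
    for (r in config$removedRegions)
        drop <- drop | (x@axis >= r[1L] - 1e-9 & x@axis <= r[2L] + 1e-9)
    if (all(drop)) stop("empty output: all grid points removed")
    values <- x@intensity[!drop]
    names(values) <- sprintf("wn_%g", x@axis[!drop])
    list(values = values, axis = x@axis[!drop])
}

#' Bucket an NMR SpectrumSet into a FeatureBlock
#'
#' Applies [referenceAlign()] then [bucketSpectrum()] to every spectrum
#' and stacks the bucket vectors into a samples-by-buckets
#' [FeatureBlock-class] (bucket centers in `rowData()$coordinate`).
#'
#' @param x a [SpectrumSet-class] (NMR).
#' @param scheme a [bucketingScheme()].
#' @param align logical, run chemical-shift referencing first.
#' @return a [FeatureBlock-class].
#' @export
nmrPreprocess <- function(x, scheme = bucketingScheme(), align = TRUE) {
    stopifnot(is(x, "SpectrumSet"))
    rows <- lapply(x@spectra, function(sp) {
        if (align) sp <- referenceAlign(sp, scheme)
        bucketSpectrum(sp, scheme)
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "values"))
    rownames(mat) <- names(x@spectra)
    featureBlock(mat, x@platform,
                 featureData = data.frame(coordinate = rows[[1L]]$centers))
}

#' MIR preprocessing pipeline
#'
#' Savitzky-Golay smoothing, then vector normalization, then removal of
#' the uninformative regions, per spectrum; results are stacked into a
#' samples-by-wavenumbers [FeatureBlock-class]. The order matters:
#' normalizing before region removal scales each spectrum by the norm of
#' the full (smoothed) spectrum, not of the retained segment.
#'
#' @param x a [SpectrumSet-class] (MIR).
#' @param config a [mirPipelineConfig()].
#' @return a [FeatureBlock-class].
#' @export
mirPreprocess <- function(x, config = mirPipelineConfig()) {
    stopifnot(is(x, "SpectrumSet"))
    rows <- lapply(x@spectra, function(sp) {
        sp <- savitzkyGolay(sp, config$sgWindow, config$sgPolyorder)
        sp <- vectorNormalize(sp)
        removeRegions(sp, config)
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "values"))
    rownames(mat) <- names(x@spectra)
    featureBlock(mat, x@platform,
                 featureData = data.frame(coordinate = rows[[1L]]$axis))
}

#' Z-score standardization fitted on the model set
#'
#' Standardizes every feature with mean and population standard
#' deviation (denominator n) estimated from the model samples only; the
#' fitted transform is applied unchanged to external samples, so the
#' external set never leaks into the statistics. Zero-variance features
#' are dropped with a warning. The fitted `(center, scale)` per feature
#' is stored in `metadata()$standardization`.
#'
#' @param block a [FeatureBlock-class].
#' @param manifest the study manifest (`role` column decides which
#'   samples the statistics are fitted on).
#' @param tol features with model-set sd below `tol` are dropped.
#' @return the standardized `FeatureBlock`.
#' @export
zscoreBlock <- function(block, manifest, tol = 1e-12) {
    stopifnot(is(block, "FeatureBlock"))
    mat <- blockMatrix(block)
    model <- manifest$sample_id[manifest$role == "model"]
    model <- intersect(model, rownames(mat))
    if (length(model) < 2L)
        stop("degenerate block: need >= 2 model samples to fit statistics")
    mm <- mat[model, , drop = FALSE]
    ctr <- colMeans(mm)
    scl <- sqrt(colMeans(sweep(mm, 2L, ctr)^2))  # population denominator
    keep <- scl > tol
    if (!any(keep))
        stop("degenerate block: all features have zero model-set variance")
    if (!all(keep))
        warning(sprintf("dropping %d zero-variance feature(s)", sum(!keep)))
    z <- sweep(sweep(mat[, keep, drop = FALSE], 2L, ctr[keep]), 2L,
               scl[keep], `/`)
    fd <- as.data.frame(rowData(block))[keep, , drop = FALSE]
    featureBlock(z, block@platform,
                 featureData = if (ncol(fd)) fd else NULL,
                 metadata = c(S4Vectors::metadata(block),
                              list(standardization = list(
                                  center = ctr[keep], scale = scl[keep]))))
}
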