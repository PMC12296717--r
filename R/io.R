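#' Write a study to plain-text files
#'
#' Tabular blocks become one CSV each (rows = samples, header = feature
#' ids), spectra one two-column text file per sample
#' (`<PLATFORM>_<sample>.txt`: axis, intensity), plus `manifest.csv`
#' (sample_id, group, role) and, for synthetic studies, `truth.json`
#' with the planted-feature ground truth.
#'
#' @param study a [FusionStudy-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(manifest(study), file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    for (nm in names(blocks(study))) {
        b <- blocks(study)[[nm]]
        if (is(b, "FeatureBlock")) {
            utils::write.csv(as.data.frame(blockMatrix(b)),
                             file.path(dir, paste0(nm, ".csv")))
        } else {
            for (sid in names(b@spectra)) {
                sp <- b@spectra[[sid]]
                utils::write.table(
                    data.frame(axis = sp@axis, intensity = sp@intensity),
                    file.path(dir, sprintf("%s_%s.txt", nm, sid)),
                    row.names = FALSE, col.names = FALSE)
            }
        }
    }
    if (length(plantedTruth(study)))
        jsonlite::write_json(plantedTruth(study),
                             file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a study written by [writeStudy()]
#'
#' @param dir directory holding `manifest.csv`, per-block CSVs and/or
#'   per-sample spectrum text files (and optionally `truth.json`).
#' @return a [FusionStudy-class].
#' @export
readStudy <- function(dir) {
    man <- utils::read.csv(file.path(dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    files <- list.files(dir)
    csvs <- setdiff(grep("\\.csv$", files, value = TRUE), "manifest.csv")
    blks <- list()
    for (f in csvs) {
        nm <- sub("\\.csv$", "", f)
        df <- utils::read.csv(file.path(dir, f), row.names = 1L,
                              check.names = FALSE)
        blks[[nm]] <- featureBlock(as.matrix(df), nm)
    }
    txts <- grep("_S[0-9]+\\.txt$", files, value = TRUE)
    if (length(txts)) {
        plats <- unique(sub("_S[0-9]+\\.txt$", "", txts))
        for (p in plats) {
            fs <- sort(grep(paste0("^", p, "_"), txts, value = TRUE))
            sp <- lapply(fs, function(f) {
                d <- utils::read.table(file.path(dir, f))
                spectrum(d[[1L]], d[[2L]])
            })
            names(sp) <- sub("\\.txt$", "", sub(paste0("^", p, "_"), "", fs))
            blks[[p]] <- spectrumSet(sp, p)
        }
    }
    truth <- if (file.exists(file.path(dir, "truth.json")))
        jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
    else list()
    new("FusionStudy", manifest = man,
        blocks = blks[intersect(c("LCMS", "GCMS", "NMR", "MIR",
                                  setdiff(names(blks), c("LCMS", "GCMS",
                                                         "NMR", "MIR"))),
                                names(blks))],
        truth = if (is.null(truth)) list() else truth)
}

#' Read a FusionConfig from YAML
#'
#' Keys mirror the arguments of [fusionConfig()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a [FusionConfig-class].
#' @export
readFusionConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[intersect(names(y), names(formals(fusionConfig)))]
    do.call(fusionConfig, args)
}
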