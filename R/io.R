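#' Read and write frame-level sequence CSVs
#'
#' The sequence schema has one row per frame with columns `animal_id`,
#' `session_id`, `trial_index`, `frame_index` (0-based, contiguous per
#' animal/session/trial) and `syllable` (integer, -1 allowed). Unknown
#' columns are tolerated with a warning. Round-trips are lossless.
#'
#' @param path CSV file path.
#' @param fps Frames per second to record on the objects (default 30; not
#'   part of the schema).
#' @return `readSequences`: list of [FrameLabels-class] objects.
#' @export
readSequences <- function(path, fps = 30) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("animal_id", "session_id", "trial_index", "frame_index",
              "syllable")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("sequence CSV missing column(s): ", paste(miss, collapse = ", "))
    extra <- setdiff(names(df), need)
    if (length(extra))
        warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    key <- paste(df$animal_id, df$session_id, df$trial_index, sep = "\r")
    groups <- split(seq_len(nrow(df)), key)
    seqs <- lapply(groups, function(idx) {
        idx <- idx[order(df$frame_index[idx])]
        fi <- df$frame_index[idx]
        expect <- seq_along(fi) - 1L
        bad <- which(fi != expect)
        if (length(bad))
            stop("frame_index not contiguous for animal '",
                 df$animal_id[idx[1L]], "' (row ", idx[bad[1L]],
                 ": found ", fi[bad[1L]], ", expected ", expect[bad[1L]], ")")
        FrameLabels(df$animal_id[idx[1L]], df$syllable[idx],
                    sessionId = df$session_id[idx[1L]],
                    trialIndex = df$trial_index[idx[1L]], fps = fps)
    })
    names(seqs) <- NULL
    # stable order: by animal, session, trial of first appearance
    first <- vapply(groups, `[`, integer(1), 1L)
    seqs[order(first)]
}

#' @rdname readSequences
#' @param seqs List of [FrameLabels-class] objects.
#' @export
writeSequences <- function(seqs, path) {
    rows <- lapply(seqs, function(s) {
        data.frame(animal_id = s@animalId, session_id = s@sessionId,
                   trial_index = s@trialIndex,
                   frame_index = seq_along(s@labels) - 1L,
                   syllable = s@labels)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Read and write cohort metadata CSVs
#'
#' Schema: one row per animal with at least `animal_id`, `genotype` and
#' `dose_mg_per_ml`.
#'
#' @param path CSV file path.
#' @return `readCohortMeta`: data.frame.
#' @export
readCohortMeta <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("animal_id", "genotype", "dose_mg_per_ml")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("metadata CSV missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$animal_id))
        stop("duplicate animal_id in metadata")
    df
}

#' @rdname readCohortMeta
#' @param meta data.frame of cohort metadata.
#' @export
writeCohortMeta <- function(meta, path) {
    utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Export run-length-encoded sequences
#'
#' @param runs List of [RunSeq-class] objects.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeRuns <- function(runs, path) {
    rows <- lapply(runs, function(r) {
        data.frame(animal_id = r@animalId,
                   run_index = seq_along(r@syllable) - 1L,
                   syllable = r@syllable, duration_frames = r@duration)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Select animals by a "genotype:dose" group expression
#'
#' @param meta Cohort metadata data.frame.
#' @param expr Expression like `"del:0.5"` or `"wt:0"`.
#' @return Character vector of matching animal IDs.
#' @export
parseGroupExpr <- function(meta, expr) {
    parts <- strsplit(expr, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
        stop("invalid group expression '", expr, "'; expected genotype:dose")
    dose <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(dose)) stop("invalid dose in group expression '", expr, "'")
    hit <- meta$genotype == parts[1L] & meta$dose_mg_per_ml == dose
    if (!any(hit)) stop("no animals match group expression '", expr, "'")
    meta$animal_id[hit]
}

#' Write a tidy results table as TSV
#'
#' @param df data.frame of results.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeResultsTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Build and write a run manifest
#'
#' The manifest records everything needed to regenerate a pipeline run
#' bit-exactly: the configuration snapshot, every stage seed and
#' resampling parameter, input file digests, the package version, and a
#' timestamp (the only non-reproducible field).
#'
#' @param stage Stage name (e.g. "usage-test").
#' @param params Named list of stage parameters (seeds, n_boot, alphas...).
#' @param inputs Character vector of input file paths (digested with
#'   md5sum).
#' @param config Optional configuration list to snapshot.
#' @return Manifest list (class `RunManifest`).
#' @export
runManifest <- function(stage, params, inputs = character(0),
                        config = NULL) {
    digests <- if (length(inputs))
        as.list(tools::md5sum(inputs)) else list()
    m <- list(stage = stage,
              package = "SyllableSeq",
              version = as.character(utils::packageVersion("SyllableSeq")),
              params = params,
              input_digests = digests,
              config = config,
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"))
    class(m) <- "RunManifest"
    m
}

#' @rdname runManifest
#' @param manifest A manifest from `runManifest()`.
#' @param path Output JSON path.
#' @export
writeRunManifest <- function(manifest, path) {
    jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    invisible(path)
}
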