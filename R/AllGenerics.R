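#' Accessors for SyllableSeq classes
#'
#' @param x An object of the corresponding class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setMethod("animalId", "FrameLabels", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "RunSeq", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "UsageVector", function(x) x@animalId)

#' @rdname accessors
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))
#' @rdname accessors
#' @export
setMethod("frameLabels", "FrameLabels", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("runLabels", function(x) standardGeneric("runLabels"))
#' @rdname accessors
#' @export
setMethod("runLabels", "RunSeq", function(x) x@syllable)

#' @rdname accessors
#' @export
setGeneric("runDurations", function(x) standardGeneric("runDurations"))
#' @rdname accessors
#' @export
setMethod("runDurations", "RunSeq", function(x) x@duration)

#' @rdname accessors
#' @export
setGeneric("usage", function(x) standardGeneric("usage"))
#' @rdname accessors
#' @export
setMethod("usage", "UsageVector", function(x) x@usage)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameLabels", function(x) length(x@labels))
#' @rdname accessors
#' @export
setMethod("nFrames", "UsageVector", function(x) x@nFrames)
#' @rdname accessors
#' @export
setMethod("nFrames", "RunSeq", function(x) sum(x@duration))

#' @rdname accessors
#' @export
setGeneric("includedSyllables", function(x) standardGeneric("includedSyllables"))
#' @rdname accessors
#' @export
setMethod("includedSyllables", "SyllableSet", function(x) x@included)

#' @rdname accessors
#' @export
setGeneric("excludedSyllables", function(x) standardGeneric("excludedSyllables"))
#' @rdname accessors
#' @export
setMethod("excludedSyllables", "SyllableSet", function(x) {
    stats::setNames(x@exclusionReason, x@excluded)
})

#' @rdname accessors
#' @export
setGeneric("syllableMap", function(x) standardGeneric("syllableMap"))
#' @rdname accessors
#' @export
setMethod("syllableMap", "SyllableSet", function(x) x@newId)

#' @rdname accessors
#' @export
setGeneric("ngramCounts", function(x) standardGeneric("ngramCounts"))
#' @rdname accessors
#' @export
setMethod("ngramCounts", "NgramTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("ngramProbs", function(x) standardGeneric("ngramProbs"))
#' @rdname accessors
#' @export
setMethod("ngramProbs", "NgramTable", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("totalTransitions", function(x) standardGeneric("totalTransitions"))
#' @rdname accessors
#' @export
setMethod("totalTransitions", "NgramTable", function(x) x@totalTransitions)

#' @rdname accessors
#' @export
setGeneric("bootReplicates", function(x) standardGeneric("bootReplicates"))
#' @rdname accessors
#' @export
setMethod("bootReplicates", "BootstrapEstimate", function(x) x@replicates)

#' @rdname accessors
#' @export
setGeneric("scaledDifference", function(x) standardGeneric("scaledDifference"))
#' @rdname accessors
#' @export
setMethod("scaledDifference", "RescueResult", function(x) x@scaled)

#' @rdname accessors
#' @export
setGeneric("summedDifferences", function(x) standardGeneric("summedDifferences"))
#' @rdname accessors
#' @export
setMethod("summedDifferences", "RescueResult", function(x) x@summed)

setMethod("show", "FrameLabels", function(object) {
    lab <- object@labels
    cat("FrameLabels '", object@animalId, "' session ", object@sessionId,
        " trial ", object@trialIndex, ": ", length(lab), " frames @ ",
        object@fps, " fps, ", length(unique(lab[lab >= 0L])),
        " syllables, ", sum(lab == -1L), " unassigned\n", sep = "")
})

setMethod("show", "RunSeq", function(object) {
    cat("RunSeq '", object@animalId, "': ", length(object@syllable),
        " runs over ", sum(object@duration), " frames (mean dwell ",
        round(mean(object@duration), 2), " frames)\n", sep = "")
})

setMethod("show", "SyllableSet", function(object) {
    cat("SyllableSet: ", length(object@included), " included (usage > ",
        object@threshold * 100, "%), ", length(object@excluded),
        " excluded\n", sep = "")
    if (length(object@included)) {
        k <- utils::head(object@included, 8L)
        cat("  rank order: ", paste(k, collapse = ", "),
            if (length(object@included) > 8L) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "NgramTable", function(object) {
    cat("NgramTable (n=", object@n, "): ", length(object@counts),
        " distinct n-grams over ", object@totalTransitions,
        " transitions\n", sep = "")
    if (length(object@probs)) {
        top <- sort(object@probs, decreasing = TRUE)
        top <- utils::head(top, 5L)
        cat("  top: ", paste(sprintf("%s (%.4f)", names(top), top),
                             collapse = ", "), "\n", sep = "")
    }
})

setMethod("show", "BootstrapEstimate", function(object) {
    cat("BootstrapEstimate (", object@nBoot, " replicates, seed ",
        object@seed, ")\n", sep = "")
    df <- data.frame(point = object@point, ci95.low = object@ciLow,
                     ci95.high = object@ciHigh)
    print(utils::head(df, 10L))
    if (nrow(df) > 10L) cat("  ... ", nrow(df) - 10L, " more\n", sep = "")
})

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams: ", object@nSyllables, " syllables, ",
        object@framesPerSession, " frames/session, ",
        length(object@genotypeEffect), " genotype effect(s), seed ",
        object@seed, "\n  dose -> lambda: ",
        paste(names(object@rescueLambda), object@rescueLambda,
              sep = ":", collapse = ", "), "\n", sep = "")
})

setMethod("show", "RescueResult", function(object) {
    cat("RescueResult (n=", object@n, ", |set|=", length(object@over),
        ", reference '", object@reference, "', ", object@nBoot,
        " bootstraps)\n", sep = "")
    print(data.frame(summed = object@summed, scaled = object@scaled,
                     ci95.low = object@ciLow, ci95.high = object@ciHigh,
                     p = object@pSummed, p.bonf = object@pBonferroni))
})
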