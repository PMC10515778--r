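#' @import methods
NULL

#' FrameLabels: one animal-session's frame-level syllable labels
#'
#' The raw substrate of syllable analysis: one integer syllable label per
#' video frame, typically recorded at 30 frames per second for a 15-minute
#' open-field session. The label -1 marks unassigned/noise frames.
#'
#' @slot animalId Character scalar, opaque animal identifier.
#' @slot sessionId Character scalar, opaque session identifier.
#' @slot trialIndex Integer >= 1; downstream analyses use the first trial
#'   of each session by default.
#' @slot fps Frames per second (default 30).
#' @slot labels Integer vector, one syllable ID per frame; -1 allowed.
#' @export
setClass("FrameLabels",
    representation(
        animalId = "character",
        sessionId = "character",
        trialIndex = "integer",
        fps = "numeric",
        labels = "integer"
    ),
    prototype(sessionId = "s1", trialIndex = 1L, fps = 30)
)

setValidity("FrameLabels", function(object) {
    msg <- character(0)
    if (length(object@animalId) != 1L || is.na(object@animalId) ||
        !nzchar(object@animalId))
        msg <- c(msg, "animalId must be a non-empty string")
    if (length(object@trialIndex) != 1L || is.na(object@trialIndex) ||
        object@trialIndex < 1L)
        msg <- c(msg, "trialIndex must be an integer >= 1")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
        msg <- c(msg, "fps must be > 0")
    if (length(object@labels) < 1L)
        msg <- c(msg, "labels must contain at least one frame")
    if (anyNA(object@labels) || any(object@labels < -1L))
        msg <- c(msg, "labels must be integers >= -1")
    if (length(msg)) msg else TRUE
})

#' Construct a FrameLabels object
#'
#' @param animalId,sessionId Identifiers.
#' @param labels Integer syllable label per frame (-1 = unassigned).
#' @param trialIndex Trial number within session (1-based).
#' @param fps Frames per second.
#' @return A [FrameLabels-class] object.
#' @examples
#' FrameLabels("m1", c(0L, 0L, 1L, 1L, 1L, 0L))
#' @export
FrameLabels <- function(animalId, labels, sessionId = "s1",
                        trialIndex = 1L, fps = 30) {
    new("FrameLabels", animalId = as.character(animalId),
        sessionId = as.character(sessionId),
        trialIndex = as.integer(trialIndex), fps = fps,
        labels = as.integer(labels))
}

#' RunSeq: run-length-encoded syllable sequence
#'
#' Consecutive identical frame labels collapsed into (syllable, duration)
#' runs. Transitions between syllables are defined between runs, so
#' self-transitions are impossible by construction.
#'
#' @slot animalId Character scalar.
#' @slot syllable Integer vector of run labels; no two consecutive equal.
#' @slot duration Integer vector of run lengths in frames, each >= 1.
#' @export
setClass("RunSeq",
    representation(
        animalId = "character",
        syllable = "integer",
        duration = "integer"
    )
)

setValidity("RunSeq", function(object) {
    msg <- character(0)
    if (length(object@syllable) != length(object@duration))
        msg <- c(msg, "syllable and duration lengths differ")
    if (length(object@syllable) == 0L)
        msg <- c(msg, "empty run sequence")
    if (any(object@duration < 1L))
        msg <- c(msg, "durations must be >= 1")
    n <- length(object@syllable)
    if (n > 1L && any(object@syllable[-1L] == object@syllable[-n]))
        msg <- c(msg, "consecutive runs share a syllable ID")
    if (length(msg)) msg else TRUE
})

#' Construct a RunSeq object
#'
#' @param animalId Identifier.
#' @param syllable Integer run labels (no two consecutive equal).
#' @param duration Integer run durations in frames.
#' @return A [RunSeq-class] object.
#' @export
RunSeq <- function(animalId, syllable, duration) {
    new("RunSeq", animalId = as.character(animalId),
        syllable = as.integer(syllable), duration = as.integer(duration))
}

#' UsageVector: per-animal syllable usage fractions
#'
#' Usage of a syllable is the fraction of the session's frames it accounts
#' for; the denominator includes unassigned/noise frames, so the values over
#' all observed labels sum to 1.
#'
#' @slot animalId Character scalar.
#' @slot usage Named numeric vector, names = syllable IDs (may include "-1").
#' @slot nFrames Total frame count of the source sequence.
#' @export
setClass("UsageVector",
    representation(
        animalId = "character",
        usage = "numeric",
        nFrames = "integer"
    )
)

setValidity("UsageVector", function(object) {
    msg <- character(0)
    if (is.null(names(object@usage)))
        msg <- c(msg, "usage must be named by syllable ID")
    if (any(object@usage < 0) || any(object@usage > 1))
        msg <- c(msg, "usage values must lie in [0, 1]")
    if (abs(sum(object@usage) - 1) > 1e-12)
        msg <- c(msg, "usage values must sum to 1")
    if (length(msg)) msg else TRUE
})

#' SyllableSet: included syllables ranked by pooled usage
#'
#' The inclusion rule of the analysis: syllables whose pooled usage exceeds
#' a threshold (default 1% of all frames), minus explicitly flagged noise
#' syllables, renumbered 0..k-1 in descending pooled-usage order (ties
#' broken by ascending original ID).
#'
#' @slot included Integer vector of original IDs, in rank order.
#' @slot newId Named integer vector mapping original ID -> new rank ID.
#' @slot excluded Integer vector of excluded original IDs.
#' @slot exclusionReason Character vector parallel to `excluded`
#'   ("low-usage" or "noise").
#' @slot threshold Usage threshold fraction.
#' @slot pooledUsage Named numeric vector of pooled usages for all IDs seen.
#' @export
setClass("SyllableSet",
    representation(
        included = "integer",
        newId = "integer",
        excluded = "integer",
        exclusionReason = "character",
        threshold = "numeric",
        pooledUsage = "numeric"
    )
)

setValidity("SyllableSet", function(object) {
    msg <- character(0)
    if (length(intersect(object@included, object@excluded)))
        msg <- c(msg, "included and excluded sets overlap")
    if (length(object@excluded) != length(object@exclusionReason))
        msg <- c(msg, "exclusionReason length mismatch")
    if (length(object@included) &&
        is.unsorted(-object@pooledUsage[as.character(object@included)]) &&
        {
            u <- object@pooledUsage[as.character(object@included)]
            any(diff(u) > 1e-15)
        })
        msg <- c(msg, "included IDs not in descending pooled-usage order")
    if (length(msg)) msg else TRUE
})

#' NgramTable: group-pooled n-gram counts and probabilities
#'
#' Counts of overlapping windows of n consecutive run-level syllables,
#' pooled across the animals of one experimental group, with probabilities
#' count / total windows. The bigram probability between syllables i and j
#' is the number of i-to-j transitions divided by the total number of
#' transitions in the group.
#'
#' @slot n N-gram order (2 or 3).
#' @slot counts Named integer vector keyed as "i-j" / "i-j-k" (original IDs).
#' @slot probs Named numeric vector, `counts / totalTransitions`.
#' @slot totalTransitions Total number of windows pooled.
#' @export
setClass("NgramTable",
    representation(
        n = "integer",
        counts = "integer",
        probs = "numeric",
        totalTransitions = "integer"
    )
)

setValidity("NgramTable", function(object) {
    msg <- character(0)
    if (!object@n %in% c(2L, 3L))
        msg <- c(msg, "n must be 2 or 3")
    if (length(object@counts) != length(object@probs))
        msg <- c(msg, "counts/probs length mismatch")
    if (object@totalTransitions > 0L &&
        abs(sum(object@probs) - 1) > 1e-12)
        msg <- c(msg, "probabilities must sum to 1")
    if (length(object@counts)) {
        m <- parseNgramKey(names(object@counts))
        if (ncol(m) != object@n)
            msg <- c(msg, "key order does not match n")
        else if (ncol(m) > 1L &&
                 any(m[, -1L, drop = FALSE] == m[, -ncol(m), drop = FALSE]))
            msg <- c(msg, "tuple contains equal adjacent IDs")
    }
    if (length(msg)) msg else TRUE
})

#' BootstrapEstimate: point estimate with percentile confidence interval
#'
#' @slot point Point estimate(s) computed on the full group.
#' @slot ciLow,ciHigh 95% percentile bootstrap interval bounds.
#' @slot nBoot Number of bootstrap replicates.
#' @slot seed RNG seed used.
#' @slot replicates Numeric matrix of replicate values
#'   (statistics x replicates), retained for paired p-value computation.
#' @export
setClass("BootstrapEstimate",
    representation(
        point = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        nBoot = "integer",
        seed = "integer",
        replicates = "matrix"
    )
)

setValidity("BootstrapEstimate", function(object) {
    if (any(object@ciLow > object@ciHigh + 1e-15))
        "ciLow exceeds ciHigh" else TRUE
})

#' SimulationParams: generative parameters for a synthetic syllable cohort
#'
#' Defines a semi-Markov generator: a row-stochastic transition matrix with
#' zero diagonal over syllables, per-syllable geometric dwell-time means,
#' multiplicative genotype effects, a dose-to-rescue-fraction map, and
#' per-animal Dirichlet jitter of transition rows.
#'
#' @slot nSyllables Number of syllables.
#' @slot usageProfile Target usage weights (power-law-like by default).
#' @slot baseTransition Row-stochastic matrix, zero diagonal.
#' @slot dwellMeanFrames Per-syllable mean run length in frames.
#' @slot genotypeEffect List of effects, each `list(target=, odds=)` where
#'   target is a single syllable ID or an integer n-gram vector.
#' @slot rescueLambda Named numeric map dose -> lambda in [0, 1].
#' @slot animalJitterConcentration Dirichlet concentration for per-animal
#'   transition rows (larger = less heterogeneity).
#' @slot nPerGroup Default animals per group.
#' @slot framesPerSession Frames per session.
#' @slot seed Master seed.
#' @export
setClass("SimulationParams",
    representation(
        nSyllables = "integer",
        usageProfile = "numeric",
        baseTransition = "matrix",
        dwellMeanFrames = "numeric",
        genotypeEffect = "list",
        rescueLambda = "numeric",
        animalJitterConcentration = "numeric",
        nPerGroup = "integer",
        framesPerSession = "integer",
        seed = "integer"
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character(0)
    K <- object@nSyllables
    tm <- object@baseTransition
    if (!all(dim(tm) == c(K, K)))
        msg <- c(msg, "baseTransition must be nSyllables x nSyllables")
    else {
        if (any(abs(diag(tm)) > 0))
            msg <- c(msg, "baseTransition diagonal must be zero")
        if (any(abs(rowSums(tm) - 1) > 1e-8))
            msg <- c(msg, "baseTransition rows must sum to 1")
    }
    if (length(object@dwellMeanFrames) != K || any(object@dwellMeanFrames < 1))
        msg <- c(msg, "dwellMeanFrames must have length nSyllables, all >= 1")
    if (any(object@rescueLambda < 0) || any(object@rescueLambda > 1))
        msg <- c(msg, "rescue lambdas must lie in [0, 1]")
    if (object@framesPerSession < 1L)
        msg <- c(msg, "framesPerSession must be >= 1")
    if (length(msg)) msg else TRUE
})

#' RescueResult: scaled summed-difference comparison across conditions
#'
#' Holds, per condition, the summed absolute difference in n-gram
#' probabilities between two groups over a fixed differential n-gram set,
#' scaled so the reference comparison equals 1, with bootstrap CIs, paired
#' bootstrap p-values and Bonferroni correction, plus the per-n-gram group
#' estimates and CI-overlap significance calls.
#'
#' @slot n N-gram order.
#' @slot over Character vector of n-gram keys the sum runs over.
#' @slot reference Name of the reference condition (scaled value 1).
#' @slot summed Named numeric, raw summed difference per condition.
#' @slot scaled Named numeric, summed difference / reference value.
#' @slot ciLow,ciHigh Named numeric, 95% CIs of the scaled values.
#' @slot pSummed Named numeric, paired bootstrap p vs the reference (NA for
#'   the reference itself).
#' @slot pBonferroni Named numeric, Bonferroni-corrected p.
#' @slot perNgram data.frame of per-n-gram, per-condition group estimates,
#'   CIs and CI-overlap significance flags.
#' @slot nBoot,seed Resampling parameters.
#' @export
setClass("RescueResult",
    representation(
        n = "integer",
        over = "character",
        reference = "character",
        summed = "numeric",
        scaled = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        pSummed = "numeric",
        pBonferroni = "numeric",
        perNgram = "data.frame",
        nBoot = "integer",
        seed = "integer"
    )
)

setValidity("RescueResult", function(object) {
    msg <- character(0)
    if (!object@reference %in% names(object@summed))
        msg <- c(msg, "reference must be one of the conditions")
    else if (abs(object@scaled[[object@reference]] - 1) > 1e-12)
        msg <- c(msg, "scaled value at the reference must equal 1")
    p <- object@pSummed[!is.na(object@pSummed)]
    if (any(p <= 0) || any(p > 1))
        msg <- c(msg, "pSummed must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})
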