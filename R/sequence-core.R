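#' Run-length encode a frame-level syllable sequence
#'
#' Collapses consecutive identical frame labels into (syllable, duration)
#' runs. Behavioral syllables are contiguous multi-frame bouts, so
#' transitions are defined between runs; frame-level "transitions" would be
#' dominated by self-transitions and are never used here.
#'
#' @param seq A [FrameLabels-class] object.
#' @return A [RunSeq-class] object whose runs reproduce the frame stream
#'   exactly when decoded.
#' @seealso [runLengthDecode()]
#' @examples
#' runLengthEncode(FrameLabels("m1", c(1L, 1L, 2L, 2L, 2L, 1L)))
#' @export
runLengthEncode <- function(seq) {
    stopifnot(is(seq, "FrameLabels"))
    if (length(seq@labels) == 0L)
        stop("sequence has no frames")
    r <- rle(seq@labels)
    RunSeq(seq@animalId, r$values, r$lengths)
}

#' Decode a run sequence back to frame labels
#'
#' @param runs A [RunSeq-class] object.
#' @param ... Passed to [FrameLabels()] (sessionId, trialIndex, fps).
#' @return A [FrameLabels-class] object.
#' @export
runLengthDecode <- function(runs, ...) {
    stopifnot(is(runs, "RunSeq"))
    FrameLabels(runs@animalId, rep(runs@syllable, runs@duration), ...)
}

#' Compute per-animal syllable usage
#'
#' Usage of syllable s is the fraction of the session's frames labeled s.
#' The denominator is the total frame count including unassigned (-1)
#' frames, so usages over all observed labels sum to 1.
#'
#' @param seq A [FrameLabels-class] object.
#' @return A [UsageVector-class] object.
#' @examples
#' usage(computeUsage(FrameLabels("m1", c(1L, 1L, 2L, 2L, 2L, 1L))))
#' @export
computeUsage <- function(seq) {
    stopifnot(is(seq, "FrameLabels"))
    lab <- seq@labels
    if (length(lab) == 0L) stop("sequence has no frames")
    tab <- table(lab)
    u <- as.numeric(tab) / length(lab)
    new("UsageVector", animalId = seq@animalId,
        usage = stats::setNames(u, names(tab)),
        nFrames = length(lab))
}

#' Pool usage vectors across animals
#'
#' The pooled usage of a group is the frame-weighted mean of per-animal
#' usages, i.e. total frames of each syllable over total frames of the
#' group — equivalent to concatenating all sessions.
#'
#' @param usages List of [UsageVector-class] objects.
#' @param ids Optional integer vector of syllable IDs to report (missing
#'   syllables get usage 0). Default: union of observed IDs, sorted.
#' @return Named numeric vector of pooled usage fractions.
#' @export
pooledUsage <- function(usages, ids = NULL) {
    stopifnot(length(usages) >= 1L)
    if (is.null(ids)) {
        ids <- sort(unique(as.integer(unlist(lapply(usages,
            function(u) names(u@usage))))))
    }
    key <- as.character(ids)
    frames <- vapply(usages, function(u) as.numeric(u@nFrames), numeric(1))
    acc <- stats::setNames(numeric(length(key)), key)
    for (i in seq_along(usages)) {
        u <- usages[[i]]@usage
        hit <- intersect(names(u), key)
        acc[hit] <- acc[hit] + u[hit] * frames[i]
    }
    acc / sum(frames)
}

#' Select analysis syllables by pooled usage
#'
#' Applies the inclusion rule used for syllable analyses: keep syllables
#' whose pooled usage across all supplied animals is strictly greater than
#' `threshold` (default 1% of total frames), drop explicitly flagged noise
#' syllables, and renumber the survivors 0..k-1 by descending pooled usage
#' (ties broken by ascending original ID). The unassigned label -1 is never
#' included.
#'
#' @param usages List of [UsageVector-class] objects (pool across all
#'   experimental groups).
#' @param threshold Usage fraction; inclusion requires pooled usage
#'   strictly above it.
#' @param noiseIds Integer vector of syllable IDs to exclude as noise
#'   regardless of usage.
#' @return A [SyllableSet-class] object.
#' @export
selectSyllables <- function(usages, threshold = 0.01, noiseIds = integer(0)) {
    stopifnot(length(usages) >= 1L, threshold >= 0, threshold < 1)
    pooled <- pooledUsage(usages)
    ids <- as.integer(names(pooled))
    keepId <- ids[ids >= 0L]
    pu <- pooled[as.character(keepId)]
    noiseIds <- as.integer(noiseIds)

    lowUsage <- keepId[pu <= threshold]
    noise <- intersect(keepId, noiseIds)
    included <- setdiff(keepId[pu > threshold], noiseIds)
    if (length(included) == 0L)
        stop("no syllables survive usage threshold and noise exclusion")

    # rank: descending pooled usage, ties by ascending original ID
    ord <- order(-pu[as.character(included)], included)
    included <- included[ord]
    excluded <- c(setdiff(lowUsage, noise), noise)
    reason <- c(rep("low-usage", length(setdiff(lowUsage, noise))),
                rep("noise", length(noise)))
    new("SyllableSet",
        included = included,
        newId = stats::setNames(seq_along(included) - 1L,
                                as.character(included)),
        excluded = as.integer(excluded),
        exclusionReason = reason,
        threshold = threshold,
        pooledUsage = pooled)
}

# Drop runs with excluded syllable IDs and merge flanking runs of equal ID;
# returns the bare label vector used for n-gram windowing. Excluded runs are
# treated as unobserved so tuples never contain excluded IDs and never
# contain equal adjacent IDs.
analysisLabels <- function(runs, included) {
    lab <- runs@syllable[runs@syllable %in% included]
    if (length(lab) == 0L) return(integer(0))
    lab[c(TRUE, lab[-1L] != lab[-length(lab)])]
}

# Count n-gram windows of a coded label vector (values 1..K) into a dense
# K^n bin vector; bin index is row-major: ((a-1)K + (b-1))K + c for n = 3.
countCodedNgrams <- function(code, n, K, bins) {
    len <- length(code)
    if (len < n) return(bins)
    if (n == 2L) {
        idx <- (code[-len] - 1L) * K + code[-1L]
    } else {
        a <- code[seq_len(len - 2L)]
        b <- code[seq_len(len - 2L) + 1L]
        c <- code[seq_len(len - 2L) + 2L]
        idx <- ((a - 1L) * K + (b - 1L)) * K + c
    }
    bins + tabulate(idx, nbins = K^n)
}

# Keys for every bin of the dense K^n layout, in original syllable IDs.
codedBinKeys <- function(included, n) {
    K <- length(included)
    if (n == 2L) {
        a <- rep(included, each = K)
        b <- rep(included, K)
        paste(a, b, sep = "-")
    } else {
        a <- rep(included, each = K * K)
        b <- rep(rep(included, each = K), K)
        c <- rep(included, K * K)
        paste(a, b, c, sep = "-")
    }
}

#' Build a group-pooled n-gram probability table
#'
#' Counts overlapping (stride-1) windows of `n` consecutive run-level
#' syllable labels, pooled across all animals of one experimental group,
#' after deleting runs of excluded syllables and merging flanking runs of
#' equal ID. Windows never cross animal boundaries. Probabilities are
#' counts divided by the pooled total number of windows, matching the
#' definition of the bigram probability P(i,j) as the number of i-to-j
#' transitions over the total number of transitions.
#'
#' @param runs List of [RunSeq-class] objects (one experimental group).
#' @param n N-gram order, 2 (bigrams) or 3 (trigrams).
#' @param syllables A [SyllableSet-class] object, or an integer vector of
#'   included syllable IDs.
#' @return An [NgramTable-class] object; only n-grams with nonzero count
#'   are stored.
#' @examples
#' r <- RunSeq("m1", c(1L, 2L, 1L), c(2L, 3L, 1L))
#' ngramProbs(ngramTable(list(r), 2L, c(1L, 2L)))
#' @export
ngramTable <- function(runs, n, syllables) {
    stopifnot(is.list(runs), length(runs) >= 1L)
    n <- as.integer(n)
    if (!n %in% c(2L, 3L)) stop("n must be 2 or 3")
    included <- if (is(syllables, "SyllableSet"))
        syllables@included else as.integer(syllables)
    K <- length(included)
    bins <- numeric(K^n)
    total <- 0L
    for (r in runs) {
        lab <- analysisLabels(r, included)
        if (length(lab) >= n) {
            code <- match(lab, included)
            bins <- countCodedNgrams(code, n, K, bins)
            total <- total + length(lab) - n + 1L
        }
    }
    if (total == 0L)
        stop("no animal contributes at least ", n, " runs after exclusion")
    nz <- which(bins > 0)
    keys <- codedBinKeys(included, n)[nz]
    counts <- as.integer(bins[nz])
    new("NgramTable", n = n,
        counts = stats::setNames(counts, keys),
        probs = stats::setNames(counts / total, keys),
        totalTransitions = as.integer(total))
}
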