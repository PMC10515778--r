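#' Bootstrap a pooled group statistic over animals
#'
#' Resamples *animals* with replacement — animals are the independent
#' units of a behavioral cohort — and recomputes the pooled statistic on
#' each replicate. Returns the point estimate on the full group together
#' with the 95% percentile interval and the replicate values.
#'
#' @param group List of per-animal objects (e.g. [RunSeq-class] or
#'   [UsageVector-class]).
#' @param stat Function taking a list of per-animal objects and returning
#'   a numeric scalar or named vector (the pooled statistic).
#' @param nBoot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @return A [BootstrapEstimate-class] object.
#' @export
bootstrapStatistic <- function(group, stat, nBoot = 1000L, seed = 1L) {
    stopifnot(is.list(group))
    if (length(group) < 2L)
        stop("need at least 2 animals to bootstrap")
    nBoot <- as.integer(nBoot)
    point <- stat(group)
    reps <- withSeed(seed, {
        vapply(seq_len(nBoot), function(b) {
            idx <- sample.int(length(group), replace = TRUE)
            as.numeric(stat(group[idx]))
        }, numeric(length(point)))
    })
    reps <- matrix(reps, nrow = length(point), ncol = nBoot,
                   dimnames = list(names(point), NULL))
    ci <- apply(reps, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    new("BootstrapEstimate", point = point,
        ciLow = stats::setNames(ci[1L, ], names(point)),
        ciHigh = stats::setNames(ci[2L, ], names(point)),
        nBoot = nBoot, seed = as.integer(seed), replicates = reps)
}

#' Compare per-syllable usage between two groups by bootstrap z-test
#'
#' For each included syllable, tests the difference in pooled group usage
#' with a z statistic whose variance is estimated by bootstrap (resampling
#' animals): z = (uA - uB) / sqrt(vA + vB), two-sided normal p, corrected
#' across syllables by Benjamini-Hochberg FDR; syllables with corrected
#' q below `alpha` are flagged significant.
#'
#' If both bootstrap variances are zero, z is 0 when the group means are
#' equal; with unequal means the syllable is reported with an infinite z
#' (p = 0) and flagged in the `degenerate` column.
#'
#' @param groupA,groupB Lists of [UsageVector-class] objects (>= 2 animals
#'   each).
#' @param syllables A [SyllableSet-class] object or integer vector of
#'   syllable IDs over which to test (the BH family).
#' @param nBoot Bootstrap replicates for the variance estimate
#'   (default 1000).
#' @param alpha Significance level on the corrected q (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with one row per syllable: `syllable`, `meanA`,
#'   `meanB`, `z`, `p`, `q`, `significant`, `degenerate`; bootstrap
#'   parameters in attributes.
#' @export
usageZTest <- function(groupA, groupB, syllables, nBoot = 1000L,
                       alpha = 0.05, seed = 1L) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("both groups need at least 2 animals")
    ids <- if (is(syllables, "SyllableSet"))
        syllables@included else as.integer(syllables)
    statFor <- function(g) pooledUsage(g, ids)
    bA <- bootstrapStatistic(groupA, statFor, nBoot, childSeed(seed, 1L))
    bB <- bootstrapStatistic(groupB, statFor, nBoot, childSeed(seed, 2L))
    vA <- apply(bA@replicates, 1L, stats::var)
    vB <- apply(bB@replicates, 1L, stats::var)
    meanA <- bA@point
    meanB <- bB@point
    denom <- sqrt(vA + vB)
    z <- ifelse(denom > 0, (meanA - meanB) / denom,
                ifelse(meanA == meanB, 0, Inf * sign(meanA - meanB)))
    degenerate <- denom == 0 & meanA != meanB
    if (any(degenerate))
        warning("zero bootstrap variance with unequal means for ",
                sum(degenerate), " syllable(s); reporting p = 0")
    p <- ifelse(is.infinite(z), 0, 2 * stats::pnorm(-abs(z)))
    q <- benjaminiHochberg(p)
    out <- data.frame(
        syllable = ids, meanA = as.numeric(meanA), meanB = as.numeric(meanB),
        z = as.numeric(z), p = as.numeric(p), q = as.numeric(q),
        significant = as.numeric(q) < alpha,
        degenerate = as.logical(degenerate))
    attr(out, "alpha") <- alpha
    attr(out, "nBoot") <- as.integer(nBoot)
    attr(out, "seed") <- as.integer(seed)
    out
}

#' Significance by 95% confidence-interval non-overlap
#'
#' Two group estimates differ significantly if and only if their 95%
#' bootstrap confidence intervals are disjoint; touching intervals overlap
#' and are not significant. Symmetric in its arguments.
#'
#' @param a,b [BootstrapEstimate-class] objects (scalar statistics), or
#'   numeric length-2 vectors `c(low, high)`.
#' @return Logical: `TRUE` when the intervals are disjoint.
#' @export
ciOverlapTest <- function(a, b) {
    asCi <- function(x) {
        if (is(x, "BootstrapEstimate")) c(x@ciLow[1L], x@ciHigh[1L])
        else { stopifnot(is.numeric(x), length(x) == 2L); x }
    }
    ca <- asCi(a); cb <- asCi(b)
    unname(ca[2L] < cb[1L] || cb[2L] < ca[1L])
}

#' Ordered union of per-group n-gram sets
#'
#' @param sets List of character vectors of n-gram keys (one per group).
#' @return Character vector: the union, in deterministic lexicographic
#'   order of the numeric syllable IDs.
#' @export
ngramUnion <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 1L)
    orderNgramKeys(unique(unlist(sets, use.names = FALSE)))
}

#' Summed absolute difference of n-gram probabilities
#'
#' Sum over a fixed n-gram set of |P_A(g) - P_B(g)|; n-grams absent from a
#' table contribute probability 0.
#'
#' @param tableA,tableB [NgramTable-class] objects of equal order.
#' @param over Character vector of n-gram keys to sum over.
#' @return Numeric scalar.
#' @export
summedDifference <- function(tableA, tableB, over) {
    stopifnot(is(tableA, "NgramTable"), is(tableB, "NgramTable"))
    if (tableA@n != tableB@n) stop("tables have different n-gram order")
    pA <- tableA@probs[over]; pA[is.na(pA)] <- 0
    pB <- tableB@probs[over]; pB[is.na(pB)] <- 0
    sum(abs(pA - pB))
}

#' Paired bootstrap p-value
#'
#' Computes the one-sided p-value comparing two bootstrap replicate series,
#' paired by replicate index, exactly as
#' p = (number of bootstraps where the value for group A is less than that
#' for group B + 1) / (number of bootstraps). Ties are not "less than".
#'
#' @param bootA,bootB Numeric replicate vectors of equal length.
#' @return Numeric p-value in (0, 1]; the replicate count is attached as
#'   attribute `nBoot`.
#' @export
bootstrapPValue <- function(bootA, bootB) {
    if (length(bootA) != length(bootB))
        stop("replicate vectors must have equal length")
    if (length(bootA) == 0L) stop("no replicates")
    p <- (sum(bootA < bootB) + 1) / length(bootA)
    attr(p, "nBoot") <- length(bootA)
    p
}
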