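#' Monte Carlo null specification for above-chance n-gram detection
#'
#' Defaults follow the analysis' convention: 50000 randomizations at
#' one-sided p < 5e-5 for bigrams, 100000 at p < 2e-5 for trigrams. The
#' threshold must be attainable: alpha >= 1 / (nRand + 1).
#'
#' @param n N-gram order (2 or 3); sets the defaults.
#' @param nRand Number of randomizations.
#' @param alpha One-sided detection threshold.
#' @param seed RNG seed.
#' @return List with elements `nRand`, `alpha`, `seed`.
#' @export
mcNullSpec <- function(n = 2L, nRand = NULL, alpha = NULL, seed = 1L) {
    n <- as.integer(n)
    if (!n %in% c(2L, 3L)) stop("n must be 2 or 3")
    if (is.null(nRand)) nRand <- if (n == 2L) 50000L else 100000L
    if (is.null(alpha)) alpha <- if (n == 2L) 5e-5 else 2e-5
    nRand <- as.integer(nRand)
    if (nRand < 1L) stop("nRand must be >= 1")
    if (alpha < 1 / (nRand + 1))
        stop("alpha below the attainable p-value floor 1/(nRand + 1)")
    list(nRand = nRand, alpha = alpha, seed = as.integer(seed))
}

#' Detect n-grams expressed above chance by Monte Carlo randomization
#'
#' The null hypothesis is that syllable order carries no information beyond
#' per-animal usage: each randomization independently permutes every
#' animal's run-label order and re-merges adjacent duplicate labels (run
#' sequences cannot contain self-transitions), then rebuilds the pooled
#' n-gram table. For each observed n-gram g the one-sided p-value is
#' p(g) = (# randomizations with P_null(g) >= P_obs(g) + 1) / (nRand + 1),
#' and g is reported when p(g) < alpha. N-grams never observed can never be
#' detected.
#'
#' @param group List of [RunSeq-class] objects (one condition).
#' @param n N-gram order (2 or 3).
#' @param spec A [mcNullSpec()] list; defaults to the order's convention.
#' @param syllables [SyllableSet-class] or integer vector of included IDs.
#' @return Character vector of detected n-gram keys, in lexicographic
#'   order; attribute `pvalues` holds the per-observed-n-gram p-values.
#' @export
mcAboveChance <- function(group, n, spec = mcNullSpec(n), syllables) {
    stopifnot(is.list(group), length(group) >= 1L)
    n <- as.integer(n)
    included <- if (is(syllables, "SyllableSet"))
        syllables@included else as.integer(syllables)
    K <- length(included)

    codes <- lapply(group, function(r) {
        lab <- analysisLabels(r, included)
        match(lab, included)
    })
    codes <- codes[lengths(codes) > 0L]
    if (length(codes) == 0L) stop("no usable runs in group")

    obsBins <- numeric(K^n)
    obsTotal <- 0L
    for (cd in codes) {
        if (length(cd) >= n) {
            obsBins <- countCodedNgrams(cd, n, K, obsBins)
            obsTotal <- obsTotal + length(cd) - n + 1L
        }
    }
    if (obsTotal == 0L) stop("fewer than n runs in every animal")
    cand <- which(obsBins > 0)
    obsP <- obsBins[cand] / obsTotal

    exceed <- numeric(length(cand))
    withSeed(spec$seed, {
        for (b in seq_len(spec$nRand)) {
            nullBins <- numeric(K^n)
            nullTotal <- 0L
            for (cd in codes) {
                perm <- cd[sample.int(length(cd))]
                perm <- perm[c(TRUE, perm[-1L] != perm[-length(perm)])]
                if (length(perm) >= n) {
                    nullBins <- countCodedNgrams(perm, n, K, nullBins)
                    nullTotal <- nullTotal + length(perm) - n + 1L
                }
            }
            if (nullTotal > 0L)
                exceed <- exceed + (nullBins[cand] / nullTotal >= obsP)
        }
    })
    pvals <- (exceed + 1) / (spec$nRand + 1)
    keys <- codedBinKeys(included, n)[cand]
    hit <- orderNgramKeys(keys[pvals < spec$alpha])
    attr(hit, "pvalues") <- stats::setNames(pvals, keys)
    hit
}
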