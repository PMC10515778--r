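# Per-animal window counts restricted to a fixed n-gram set, plus the
# animal's total window count; the unit of bootstrap resampling.
animalNgramCounts <- function(runs, n, included, overMat) {
    lab <- analysisLabels(runs, included)
    cnt <- numeric(nrow(overMat))
    total <- 0L
    if (length(lab) >= n) {
        total <- length(lab) - n + 1L
        for (g in seq_len(nrow(overMat))) {
            tup <- overMat[g, ]
            hit <- lab[seq_len(total)] == tup[1L]
            for (k in 2L:n)
                hit <- hit & lab[seq_len(total) + (k - 1L)] == tup[k]
            cnt[g] <- sum(hit)
        }
    }
    list(counts = cnt, total = total)
}

#' Scaled summed-difference rescue statistic across treatment conditions
#'
#' Quantifies how far a mutant group's n-gram transition structure sits
#' from wildtype under each treatment condition, on a common scale. For
#' each condition (a pair of groups, e.g. wildtype vs mutant at one dose)
#' the statistic is the summed absolute difference of group-pooled n-gram
#' probabilities over a fixed set of differential n-grams, computed from
#' animal-level joint bootstrap replicates. All values are scaled to the
#' reference comparison (conventionally mutant vs wildtype under vehicle),
#' whose scaled point estimate is exactly 1; values near 0 indicate rescue.
#'
#' Bootstrap replicates are paired by index across conditions (each
#' condition's groups resampled independently within a replicate); the
#' paired one-sided p-value of each condition against the reference uses
#' [bootstrapPValue()] and is Bonferroni-corrected over the non-reference
#' conditions.
#'
#' @param conditions Named list; each element is `list(groupA=, groupB=)`
#'   of [RunSeq-class] lists.
#' @param reference Name of the reference condition.
#' @param over Character vector of n-gram keys (the differential set,
#'   typically from [mcAboveChance()] unions on the reference comparison).
#' @param syllables [SyllableSet-class] or integer vector of included IDs.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return A [RescueResult-class] object.
#' @export
scaledRescueStatistic <- function(conditions, reference, over, syllables,
                                  nBoot = 1000L, seed = 1L) {
    stopifnot(is.list(conditions), length(conditions) >= 1L)
    if (!reference %in% names(conditions))
        stop("reference condition '", reference, "' not among conditions")
    if (length(over) == 0L) stop("empty n-gram set")
    overMat <- parseNgramKey(over)
    n <- ncol(overMat)
    included <- if (is(syllables, "SyllableSet"))
        syllables@included else as.integer(syllables)
    nBoot <- as.integer(nBoot)
    nCond <- length(conditions)
    condNames <- names(conditions)

    # Precompute per-animal counts; pooled probability of the set is then a
    # cheap column sum per bootstrap replicate.
    pre <- lapply(conditions, function(cond) {
        lapply(cond[c("groupA", "groupB")], function(grp) {
            if (length(grp) < 2L)
                stop("each group needs at least 2 animals")
            per <- lapply(grp, animalNgramCounts, n = n,
                          included = included, overMat = overMat)
            list(counts = matrix(vapply(per, `[[`,
                                        numeric(nrow(overMat)), "counts"),
                                 nrow = nrow(overMat)),
                 totals = vapply(per, function(x) as.numeric(x$total),
                                 numeric(1)))
        })
    })
    poolP <- function(side, idx) {
        cnt <- side$counts[, idx, drop = FALSE]
        tot <- sum(side$totals[idx])
        if (tot == 0) rep(0, nrow(overMat)) else rowSums(cnt) / tot
    }

    pointD <- vapply(pre, function(cd) {
        nA <- length(cd$groupA$totals); nB <- length(cd$groupB$totals)
        sum(abs(poolP(cd$groupA, seq_len(nA)) - poolP(cd$groupB, seq_len(nB))))
    }, numeric(1))
    if (pointD[[reference]] == 0)
        stop("reference summed difference is 0; scaling undefined")

    nG <- length(over)
    repD <- matrix(NA_real_, nCond, nBoot, dimnames = list(condNames, NULL))
    repPA <- array(NA_real_, c(nG, nBoot, nCond))
    repPB <- array(NA_real_, c(nG, nBoot, nCond))
    withSeed(seed, {
        for (b in seq_len(nBoot)) {
            for (ci in seq_len(nCond)) {
                cd <- pre[[ci]]
                idxA <- sample.int(length(cd$groupA$totals), replace = TRUE)
                idxB <- sample.int(length(cd$groupB$totals), replace = TRUE)
                pA <- poolP(cd$groupA, idxA)
                pB <- poolP(cd$groupB, idxB)
                repPA[, b, ci] <- pA
                repPB[, b, ci] <- pB
                repD[ci, b] <- sum(abs(pA - pB))
            }
        }
    })

    refReps <- repD[reference, ]
    scaledReps <- sweep(repD, 2L, refReps, "/")
    scaled <- pointD / pointD[[reference]]
    ciLow <- apply(scaledReps, 1L, stats::quantile, probs = 0.025,
                   na.rm = TRUE, names = FALSE)
    ciHigh <- apply(scaledReps, 1L, stats::quantile, probs = 0.975,
                    na.rm = TRUE, names = FALSE)

    pSummed <- rep(NA_real_, nCond); names(pSummed) <- condNames
    for (cn in setdiff(condNames, reference))
        pSummed[cn] <- min(1, as.numeric(bootstrapPValue(refReps,
                                                         repD[cn, ])))
    m <- sum(!is.na(pSummed))
    pBonf <- ifelse(is.na(pSummed), NA_real_, pmin(1, m * pSummed))

    # per-n-gram group estimates and CI-overlap significance per condition
    rows <- vector("list", nCond)
    for (ci in seq_len(nCond)) {
        cd <- pre[[ci]]
        pA <- poolP(cd$groupA, seq_along(cd$groupA$totals))
        pB <- poolP(cd$groupB, seq_along(cd$groupB$totals))
        qA <- apply(repPA[, , ci, drop = FALSE], 1L, stats::quantile,
                    probs = c(0.025, 0.975), names = FALSE)
        qB <- apply(repPB[, , ci, drop = FALSE], 1L, stats::quantile,
                    probs = c(0.025, 0.975), names = FALSE)
        rows[[ci]] <- data.frame(
            condition = condNames[ci], ngram = over,
            probA = pA, probB = pB,
            ciLowA = qA[1L, ], ciHighA = qA[2L, ],
            ciLowB = qB[1L, ], ciHighB = qB[2L, ],
            significant = qA[2L, ] < qB[1L, ] | qB[2L, ] < qA[1L, ],
            row.names = NULL)
    }

    new("RescueResult", n = as.integer(n), over = over,
        reference = reference,
        summed = pointD, scaled = scaled,
        ciLow = stats::setNames(ciLow, condNames),
        ciHigh = stats::setNames(ciHigh, condNames),
        pSummed = pSummed,
        pBonferroni = stats::setNames(as.numeric(pBonf), condNames),
        perNgram = do.call(rbind, rows),
        nBoot = nBoot, seed = as.integer(seed))
}
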