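#' Novel-object discrimination index
#'
#' DI = 100 * tB / (tA + tB): the percentage of object-exploration time
#' directed at the novel (or relocated) object; 50 is chance.
#'
#' @param tA,tB Seconds exploring the familiar and novel object
#'   (vectorized).
#' @return Numeric percentage(s).
#' @examples
#' discriminationIndex(6, 18)  # 75
#' @export
discriminationIndex <- function(tA, tB) {
    stopifnot(length(tA) == length(tB))
    if (any(tA < 0 | tB < 0)) stop("exploration times must be >= 0")
    tot <- tA + tB
    if (any(tot == 0))
        stop("discrimination index undefined for zero total exploration ",
             "(trial should have been excluded)")
    100 * tB / tot
}

#' Exclude animals with low total object exploration
#'
#' An animal is excluded when its total exploration time (both objects) is
#' strictly below `minTotal` seconds in either the training or the testing
#' phase; exactly `minTotal` seconds is kept.
#'
#' @param trials data.frame with columns `animal_id`, `phase`
#'   ("training"/"testing"), `tA_s`, `tB_s`; every animal must have both
#'   phases.
#' @param minTotal Threshold in seconds (default 3).
#' @return List with `kept` and `excluded` subsets of `trials` (a
#'   partition) and `reasons`: data.frame (animal_id, phase, total_s) of
#'   the failing phases.
#' @export
excludeLowExploration <- function(trials, minTotal = 3) {
    need <- c("animal_id", "phase", "tA_s", "tB_s")
    stopifnot(all(need %in% names(trials)))
    tot <- trials$tA_s + trials$tB_s
    bad <- vapply(split(seq_len(nrow(trials)), trials$animal_id),
        function(idx) {
            ph <- trials$phase[idx]
            if (!all(c("training", "testing") %in% ph))
                stop("animal '", trials$animal_id[idx[1L]],
                     "' is missing a phase")
            any(tot[idx] < minTotal)
        }, logical(1))
    badIds <- names(bad)[bad]
    isExcluded <- trials$animal_id %in% badIds
    failing <- isExcluded & tot < minTotal
    list(kept = trials[!isExcluded, , drop = FALSE],
         excluded = trials[isExcluded, , drop = FALSE],
         reasons = data.frame(animal_id = trials$animal_id[failing],
                              phase = trials$phase[failing],
                              total_s = tot[failing], row.names = NULL))
}

#' Exclude values beyond k standard deviations of their group mean
#'
#' Single pass: mean and SD (sample, n-1 denominator) are computed on the
#' full group including candidate outliers; a value is excluded when
#' |x - mean| is strictly greater than k * SD. With zero SD nothing is
#' excluded.
#'
#' @param values Numeric vector (one group).
#' @param k SD multiplier (default 2).
#' @return List with `kept`, `excluded` (values), and `keep`: logical mask
#'   aligned with the input.
#' @export
excludeSdOutliers <- function(values, k = 2) {
    stopifnot(length(values) >= 3L)
    m <- mean(values)
    s <- stats::sd(values)
    keep <- if (s == 0) rep(TRUE, length(values)) else
        abs(values - m) <= k * s
    list(kept = values[keep], excluded = values[!keep], keep = keep)
}

#' Percentage of 2-s epochs scored as freezing
#'
#' @param scores Binary vector (0/1), one value per 2-second epoch.
#' @return Numeric percentage.
#' @export
freezingPercent <- function(scores) {
    if (length(scores) == 0L) stop("no epochs scored")
    if (!all(scores %in% c(0, 1))) stop("scores must be 0/1")
    100 * sum(scores) / length(scores)
}

#' Percent time spent in the arena center
#'
#' 100 * (time in center / total time), vectorized over bins.
#'
#' @param centerS Seconds in center.
#' @param totalS Total seconds (must be > 0).
#' @return Numeric percentage(s).
#' @export
centerTimePercent <- function(centerS, totalS) {
    if (any(totalS <= 0)) stop("total time must be > 0")
    if (any(centerS < 0 | centerS > totalS))
        stop("center time must lie in [0, total]")
    100 * centerS / totalS
}

#' Bin activity events into fixed time windows
#'
#' Counts events whose timestamps fall in half-open windows
#' [i * bin, (i + 1) * bin); an event exactly on a boundary belongs to the
#' later bin.
#'
#' @param times Event timestamps in seconds.
#' @param sessionSeconds Session length in seconds.
#' @param binMinutes Bin width in minutes (default 5).
#' @return Integer vector of per-bin counts (named by bin index, 0-based).
#' @export
binActivity <- function(times, sessionSeconds, binMinutes = 5) {
    binS <- binMinutes * 60
    nBins <- ceiling(sessionSeconds / binS)
    if (length(times) && any(times < 0 | times >= sessionSeconds))
        stop("event timestamps beyond session bounds")
    idx <- floor(times / binS)
    stats::setNames(tabulate(idx + 1L, nbins = nBins), seq_len(nBins) - 1L)
}

#' Two-way between-subjects ANOVA (type III, sum-to-zero coding)
#'
#' Fixed-effects genotype x treatment linear model with interaction,
#' tested with type III sums of squares under sum-to-zero contrasts — the
#' convention of the commercial packages used for such endpoint analyses,
#' which matters once exclusions unbalance the cells.
#'
#' @param values Numeric response.
#' @param genotype,treatment Factors (coerced).
#' @return data.frame with rows genotype, treatment, genotype:treatment and
#'   residuals: columns `term`, `F`, `df`, `df_residual`, `p`.
#' @export
anovaTwoWay <- function(values, genotype, treatment) {
    genotype <- factor(genotype)
    treatment <- factor(treatment)
    stopifnot(length(values) == length(genotype),
              length(values) == length(treatment))
    if (nlevels(genotype) < 2L || nlevels(treatment) < 2L)
        stop("each factor needs at least 2 levels")
    cellN <- table(genotype, treatment)
    if (any(cellN < 2L)) {
        bad <- which(cellN < 2L, arr.ind = TRUE)[1L, ]
        stop("cell ", rownames(cellN)[bad[1L]], " x ",
             colnames(cellN)[bad[2L]], " has fewer than 2 observations")
    }
    dat <- data.frame(y = values, genotype = genotype, treatment = treatment)
    fit <- stats::lm(y ~ genotype * treatment, data = dat,
        contrasts = list(genotype = "contr.sum", treatment = "contr.sum"))
    aov3 <- car::Anova(fit, type = 3)
    keep <- c("genotype", "treatment", "genotype:treatment")
    dfRes <- aov3[["Df"]][rownames(aov3) == "Residuals"]
    out <- data.frame(
        term = keep,
        F = aov3[keep, "F value"],
        df = aov3[keep, "Df"],
        df_residual = dfRes,
        p = aov3[keep, "Pr(>F)"],
        row.names = NULL)
    out
}

#' Welch post-hoc t-tests with Holm-Šidák adjustment
#'
#' Runs Welch's (unequal-variance) t-test for each requested pairwise
#' comparison and adjusts the p-values with [holmSidak()] over exactly that
#' comparison family.
#'
#' @param values Numeric response.
#' @param group Group labels (coerced to character).
#' @param comparisons List of character pairs `c(groupA, groupB)`.
#' @return data.frame: `groupA`, `groupB`, `t`, `df`, `p`, `p_adjusted`.
#' @export
posthocWelchHolmSidak <- function(values, group, comparisons) {
    group <- as.character(group)
    stopifnot(length(values) == length(group), length(comparisons) >= 1L)
    rows <- lapply(comparisons, function(cmp) {
        a <- values[group == cmp[1L]]
        b <- values[group == cmp[2L]]
        if (length(a) < 2L || length(b) < 2L)
            stop("comparison ", cmp[1L], " vs ", cmp[2L],
                 ": need >= 2 observations per group")
        if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
            data.frame(groupA = cmp[1L], groupB = cmp[2L], t = 0,
                       df = length(a) + length(b) - 2, p = 1)
        } else {
            tt <- stats::t.test(a, b, var.equal = FALSE)
            data.frame(groupA = cmp[1L], groupB = cmp[2L],
                       t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value)
        }
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- holmSidak(out$p)
    out
}
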