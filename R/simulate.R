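# Default usage weights: power-law-like so the most-used syllables
# dominate, as in real ethograms where the top ~35 syllables cover most
# frames.
defaultUsageProfile <- function(K) {
    w <- seq_len(K)^-0.85
    w / sum(w)
}

# Default embedded transition matrix: attraction proportional to target
# usage, with a mild circulant band so the chain carries genuine sequential
# structure; zero diagonal, rows renormalized.
defaultBaseTransition <- function(K, usageProfile) {
    d <- abs(outer(seq_len(K), seq_len(K), "-"))
    d <- pmin(d, K - d)
    tm <- outer(rep(1, K), usageProfile) * (1 + 1.5 * exp(-d / 3))
    diag(tm) <- 0
    tm / rowSums(tm)
}

#' Construct simulation parameters for a synthetic syllable cohort
#'
#' Defines the semi-Markov generative model used to validate the analysis
#' pipeline: syllable runs are drawn from an embedded Markov chain with
#' zero self-transition probability and geometric dwell times, per-animal
#' transition rows are jittered with a Dirichlet distribution, genotype
#' effects multiply transition odds, and treatment interpolates the mutant
#' dynamics back toward wildtype by a dose-dependent fraction lambda.
#'
#' @param nSyllables Number of syllables (default 35).
#' @param usageProfile Usage weights (default power-law-like).
#' @param baseTransition Row-stochastic matrix with zero diagonal; default
#'   derived from the usage profile with mild banded structure.
#' @param dwellMeanFrames Per-syllable geometric dwell means in frames
#'   (default spread over 3-15 frames, i.e. 0.1-0.5 s at 30 fps).
#' @param genotypeEffect List of `list(target=, odds=)` effects applied to
#'   the mutant dynamics: a scalar target multiplies the odds of all
#'   transitions into that syllable; an n-gram target multiplies each of
#'   its consecutive transition entries.
#' @param rescueLambda Named map dose -> lambda in [0, 1]; lambda = 0
#'   leaves the mutant dynamics untouched, lambda = 1 restores wildtype.
#' @param animalJitterConcentration Dirichlet concentration for per-animal
#'   transition rows (default 200, mild heterogeneity).
#' @param nPerGroup Default animals per group (default 15).
#' @param framesPerSession Frames per session (default 27000: 15 min at
#'   30 fps).
#' @param seed Master seed.
#' @return A [SimulationParams-class] object.
#' @export
simulationParams <- function(nSyllables = 35L,
                             usageProfile = NULL,
                             baseTransition = NULL,
                             dwellMeanFrames = NULL,
                             genotypeEffect = list(),
                             rescueLambda = c("0" = 0, "0.25" = 0.3,
                                              "0.5" = 0.7, "1" = 1),
                             animalJitterConcentration = 200,
                             nPerGroup = 15L,
                             framesPerSession = 27000L,
                             seed = 1L) {
    K <- as.integer(nSyllables)
    if (is.null(usageProfile)) usageProfile <- defaultUsageProfile(K)
    if (is.null(baseTransition))
        baseTransition <- defaultBaseTransition(K, usageProfile)
    if (is.null(dwellMeanFrames)) {
        # common syllables slightly shorter, rare ones longer; 3-15 frames
        dwellMeanFrames <- seq(3, 15, length.out = K)
    }
    new("SimulationParams", nSyllables = K,
        usageProfile = usageProfile,
        baseTransition = baseTransition,
        dwellMeanFrames = dwellMeanFrames,
        genotypeEffect = genotypeEffect,
        rescueLambda = rescueLambda,
        animalJitterConcentration = animalJitterConcentration,
        nPerGroup = as.integer(nPerGroup),
        framesPerSession = as.integer(framesPerSession),
        seed = as.integer(seed))
}

renormalizeRows <- function(tm) {
    rs <- rowSums(tm)
    if (any(rs <= 0))
        stop("transition row ", which(rs <= 0)[1L],
             " is all zero after effect application")
    tm / rs
}

#' Group-level generative dynamics for a genotype and dose
#'
#' The mutant ("del") transition matrix applies each genotype effect as a
#' multiplicative odds factor and renormalizes rows; a treated mutant is
#' the elementwise convex combination (1 - lambda) * del + lambda * wt,
#' renormalized. Wildtype dynamics are unaffected by dose.
#'
#' @param params A [SimulationParams-class] object.
#' @param genotype `"wt"` or `"del"`.
#' @param dose Dose whose rescue lambda applies (matched against
#'   `names(params@rescueLambda)`); ignored for wildtype.
#' @return List with `transition` (row-stochastic, zero diagonal) and
#'   `dwellMeanFrames`.
#' @export
makeGroupDynamics <- function(params, genotype = c("wt", "del"), dose = 0) {
    genotype <- match.arg(genotype)
    wt <- params@baseTransition
    dwell <- params@dwellMeanFrames
    if (genotype == "wt")
        return(list(transition = wt, dwellMeanFrames = dwell))
    del <- wt
    # n-gram effects: multiply the named consecutive transition entries
    for (ef in params@genotypeEffect) {
        tgt <- as.integer(ef$target)
        if (length(tgt) > 1L)
            for (k in seq_len(length(tgt) - 1L))
                del[tgt[k], tgt[k + 1L]] <- del[tgt[k], tgt[k + 1L]] * ef$odds
    }
    del <- renormalizeRows(del)
    # syllable effects: shift the syllable's stationary *usage odds* by the
    # factor, realized by scaling its incoming transition column; the column
    # multipliers are found by fixed-point iteration because renormalization
    # couples the syllables.
    sylEff <- Filter(function(ef) length(ef$target) == 1L,
                     params@genotypeEffect)
    if (length(sylEff)) {
        tgt <- vapply(sylEff, function(ef) as.integer(ef$target), integer(1))
        odds <- vapply(sylEff, function(ef) as.numeric(ef$odds), numeric(1))
        u0 <- stationaryUsage(list(transition = del,
                                   dwellMeanFrames = dwell))[tgt]
        goal <- odds * u0 / (1 - u0)
        goal <- goal / (1 + goal)
        mult <- odds
        base <- del
        for (it in seq_len(40L)) {
            del <- base
            for (k in seq_along(tgt)) del[, tgt[k]] <- del[, tgt[k]] * mult[k]
            diag(del) <- 0
            del <- renormalizeRows(del)
            cur <- stationaryUsage(list(transition = del,
                                        dwellMeanFrames = dwell))[tgt]
            ratio <- (goal / (1 - goal)) / (cur / (1 - cur))
            if (all(abs(ratio - 1) < 1e-8)) break
            mult <- mult * ratio
        }
    }
    lam <- params@rescueLambda[as.character(as.numeric(dose))]
    if (is.na(lam)) lam <- 0
    tm <- renormalizeRows((1 - lam) * del + lam * wt)
    list(transition = tm, dwellMeanFrames = dwell)
}

#' Stationary usage of a semi-Markov chain
#'
#' The long-run fraction of frames in syllable i is proportional to the
#' embedded chain's stationary probability times the mean dwell of i.
#'
#' @param dynamics A list as returned by [makeGroupDynamics()].
#' @return Numeric vector of stationary usage fractions (sums to 1).
#' @export
stationaryUsage <- function(dynamics) {
    tm <- dynamics$transition
    K <- nrow(tm)
    pi <- rep(1 / K, K)
    for (i in seq_len(500L)) pi <- as.numeric(pi %*% tm)
    pi <- pi / sum(pi)
    u <- pi * dynamics$dwellMeanFrames
    u / sum(u)
}

#' Simulate one animal's frame-label sequence
#'
#' Semi-Markov generation: the animal's transition rows are Dirichlet
#' jittered around the group dynamics (concentration
#' `jitterConcentration`; `Inf` disables jitter), syllable runs follow the
#' embedded chain, dwell times are geometric with the configured
#' per-syllable means, and the stream is truncated at `framesPerSession`.
#' Deterministic given the seed.
#'
#' @param dynamics List from [makeGroupDynamics()].
#' @param framesPerSession Number of frames to generate.
#' @param seed RNG seed for this animal.
#' @param animalId Identifier for the output object.
#' @param jitterConcentration Dirichlet concentration (default `Inf`).
#' @param fps Frames per second recorded in the output.
#' @return A [FrameLabels-class] object.
#' @export
simulateAnimal <- function(dynamics, framesPerSession, seed,
                           animalId = "sim", jitterConcentration = Inf,
                           fps = 30) {
    stopifnot(framesPerSession >= 1L)
    tm <- dynamics$transition
    K <- nrow(tm)
    dwell <- dynamics$dwellMeanFrames
    withSeed(seed, {
        if (is.finite(jitterConcentration)) {
            for (i in seq_len(K)) {
                shp <- jitterConcentration * tm[i, ]
                g <- stats::rgamma(K, shape = shp)
                g[shp == 0] <- 0
                if (sum(g) == 0) g <- tm[i, ]
                tm[i, ] <- g / sum(g)
            }
        }
        cum <- t(apply(tm, 1L, cumsum))
        start <- sample.int(K, 1L, prob = stationaryUsage(
            list(transition = tm, dwellMeanFrames = dwell)))
        states <- integer(0)
        durs <- integer(0)
        total <- 0L
        s <- start
        while (total < framesPerSession) {
            # draw a block of runs, then extend if still short
            blk <- max(16L, ceiling((framesPerSession - total) /
                                    mean(dwell) * 1.3))
            bs <- integer(blk)
            for (b in seq_len(blk)) {
                bs[b] <- s
                s <- findInterval(stats::runif(1L), cum[s, ]) + 1L
            }
            bd <- stats::rgeom(blk, prob = 1 / dwell[bs]) + 1L
            states <- c(states, bs)
            durs <- c(durs, bd)
            total <- total + sum(bd)
        }
        cs <- cumsum(durs)
        cut <- which(cs >= framesPerSession)[1L]
        durs <- durs[seq_len(cut)]
        durs[cut] <- durs[cut] - (cs[cut] - framesPerSession)
        states <- states[seq_len(cut)]
        # syllable IDs are 0-based in frame labels
        FrameLabels(animalId, rep(states - 1L, durs), fps = fps)
    })
}

#' Build a cohort design table
#'
#' Default group sizes follow the study design of the syllable cohort:
#' wt/vehicle 15, del/vehicle 12, wt/0.5 27, del/0.5 14, wt/1.0 18,
#' del/1.0 11.
#'
#' @param groups data.frame with columns `genotype`, `dose`, `n`.
#' @return data.frame with one row per animal: `animal_id`, `genotype`,
#'   `dose_mg_per_ml`, `sex`, `cage`, `lab`.
#' @export
makeCohortDesign <- function(groups = data.frame(
        genotype = rep(c("wt", "del"), 3L),
        dose = rep(c(0, 0.5, 1.0), each = 2L),
        n = c(15L, 12L, 27L, 14L, 18L, 11L))) {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
        g <- groups[i, ]
        idx <- seq_len(g$n)
        data.frame(
            animal_id = sprintf("%s_%s_%02d", g$genotype,
                                gsub("[.]", "p", as.character(g$dose)), idx),
            genotype = g$genotype,
            dose_mg_per_ml = g$dose,
            sex = rep_len(c("F", "M"), g$n),
            cage = sprintf("c%02d", (idx - 1L) %/% 4L + 1L),
            lab = "simlab")
    })
    do.call(rbind, rows)
}

#' Simulate a full cohort of syllable sequences
#'
#' One [FrameLabels-class] sequence per design row, each generated with a
#' per-animal seed derived deterministically from the master seed, using
#' the group dynamics of the animal's genotype and dose.
#'
#' @param params A [SimulationParams-class] object.
#' @param design data.frame from [makeCohortDesign()] (or with the same
#'   columns).
#' @return List with `sequences` (list of [FrameLabels-class]) and `meta`
#'   (the design data.frame).
#' @export
simulateCohort <- function(params, design = makeCohortDesign()) {
    stopifnot(nrow(design) >= 1L)
    dynCache <- list()
    seqs <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
        key <- paste(design$genotype[i], design$dose_mg_per_ml[i])
        if (is.null(dynCache[[key]]))
            dynCache[[key]] <- makeGroupDynamics(params, design$genotype[i],
                                                 design$dose_mg_per_ml[i])
        seqs[[i]] <- simulateAnimal(
            dynCache[[key]], params@framesPerSession,
            seed = childSeed(params@seed, i),
            animalId = design$animal_id[i],
            jitterConcentration = params@animalJitterConcentration)
    }
    list(sequences = seqs, meta = design)
}

#' Default effect specification for synthetic classical endpoints
#'
#' Group means emulate the expected endpoint structure: wildtype mice
#' prefer the novel object (preference 0.7), vehicle-treated mutants sit at
#' chance (0.5), and treatment moves the mutant preference toward wildtype
#' in proportion to the rescue lambda. Freezing and activity rates are
#' genotype-independent by default.
#'
#' @param preferenceWt Wildtype novel-object preference (fraction of
#'   exploration on the novel object).
#' @param preferenceDel Vehicle mutant preference.
#' @param rescueLambda Dose -> lambda map used to interpolate mutant
#'   preference toward wildtype.
#' @param explorationMeanS,explorationShape Gamma mean/shape of total
#'   exploration seconds per phase.
#' @param preferenceKappa Beta concentration of per-animal preference.
#' @param freezeFamiliar,freezeNovel Per-2-s-epoch freezing probabilities.
#' @param nEpochs Number of 2-s epochs scored per context (default 240,
#'   i.e. 8 min).
#' @param horizontalMean,verticalMean Mean activity counts per 5-min bin.
#' @param centerFraction Mean fraction of bin time spent in the center.
#' @param nBins Number of 5-min open-field bins.
#' @return A list of effect parameters for [simulateEndpoints()].
#' @export
endpointEffects <- function(preferenceWt = 0.7, preferenceDel = 0.5,
                            rescueLambda = c("0" = 0, "0.25" = 0.3,
                                             "0.5" = 0.7, "1" = 1),
                            explorationMeanS = 20, explorationShape = 4,
                            preferenceKappa = 30,
                            freezeFamiliar = 0.35, freezeNovel = 0.15,
                            nEpochs = 240L,
                            horizontalMean = 300, verticalMean = 40,
                            centerFraction = 0.15, nBins = 3L) {
    list(preferenceWt = preferenceWt, preferenceDel = preferenceDel,
         rescueLambda = rescueLambda,
         explorationMeanS = explorationMeanS,
         explorationShape = explorationShape,
         preferenceKappa = preferenceKappa,
         freezeFamiliar = freezeFamiliar, freezeNovel = freezeNovel,
         nEpochs = as.integer(nEpochs),
         horizontalMean = horizontalMean, verticalMean = verticalMean,
         centerFraction = centerFraction, nBins = as.integer(nBins))
}

#' Simulate classical endpoint tables for a cohort design
#'
#' Generates per-animal object-exploration times (gamma-distributed totals
#' with group-specific novel-object preference), binary 2-s freezing
#' series in familiar and novel contexts, and 5-min-binned open-field
#' activity, matching the CSV schemas the endpoint analyses read.
#'
#' @param design Cohort design data.frame ([makeCohortDesign()]).
#' @param effects Effect parameters from [endpointEffects()].
#' @param seed RNG seed.
#' @return List of data.frames: `nor` (animal_id, phase, tA_s, tB_s),
#'   `freezing` (animal_id, context, epoch_index, freezing), `openfield`
#'   (animal_id, bin_index, horizontal, vertical, center_s, total_s).
#' @export
simulateEndpoints <- function(design, effects = endpointEffects(),
                              seed = 1L) {
    prefFor <- function(genotype, dose) {
        if (genotype == "wt") return(effects$preferenceWt)
        lam <- effects$rescueLambda[as.character(as.numeric(dose))]
        if (is.na(lam)) lam <- 0
        effects$preferenceDel +
            lam * (effects$preferenceWt - effects$preferenceDel)
    }
    nor <- freezing <- openfield <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
        aid <- design$animal_id[i]
        theta <- prefFor(design$genotype[i], design$dose_mg_per_ml[i])
        withSeed(childSeed(seed, i), {
            totals <- stats::rgamma(2L, shape = effects$explorationShape,
                scale = effects$explorationMeanS / effects$explorationShape)
            k <- effects$preferenceKappa
            bTrain <- stats::rbeta(1L, k * 0.5, k * 0.5)
            bTest <- stats::rbeta(1L, k * theta, k * (1 - theta))
            nor[[i]] <- data.frame(
                animal_id = aid,
                phase = c("training", "testing"),
                tA_s = round(totals * c(1 - bTrain, 1 - bTest), 3L),
                tB_s = round(totals * c(bTrain, bTest), 3L))
            ne <- effects$nEpochs
            freezing[[i]] <- data.frame(
                animal_id = aid,
                context = rep(c("familiar", "novel"), each = ne),
                epoch_index = rep(seq_len(ne) - 1L, 2L),
                freezing = c(stats::rbinom(ne, 1L, effects$freezeFamiliar),
                             stats::rbinom(ne, 1L, effects$freezeNovel)))
            nb <- effects$nBins
            binS <- 300
            cf <- effects$centerFraction
            openfield[[i]] <- data.frame(
                animal_id = aid,
                bin_index = seq_len(nb) - 1L,
                horizontal = stats::rpois(nb, effects$horizontalMean),
                vertical = stats::rpois(nb, effects$verticalMean),
                center_s = round(binS * stats::rbeta(nb, 20 * cf,
                                                     20 * (1 - cf)), 2L),
                total_s = binS)
        })
    }
    list(nor = do.call(rbind, nor),
         freezing = do.call(rbind, freezing),
         openfield = do.call(rbind, openfield))
}
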