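test_that("group dynamics: null effects give identical matrices and
           lambda interpolates back to wildtype", {
    p <- simulationParams(nSyllables = 6L, seed = 1L,
                          rescueLambda = c("0" = 0, "0.5" = 0.5, "1" = 1))
    wt <- makeGroupDynamics(p, "wt")
    del <- makeGroupDynamics(p, "del", 0)
    expect_equal(del$transition, wt$transition)

    eff <- list(list(target = c(2L, 4L), odds = 3))
    pe <- simulationParams(nSyllables = 6L, seed = 1L,
                           genotypeEffect = eff,
                           rescueLambda = c("0" = 0, "0.5" = 0.5, "1" = 1))
    wtE <- makeGroupDynamics(pe, "wt")
    delE <- makeGroupDynamics(pe, "del", 0)
    expect_gt(delE$transition[2L, 4L], wtE$transition[2L, 4L])
    full <- makeGroupDynamics(pe, "del", 1)
    expect_equal(full$transition, wtE$transition, tolerance = 1e-12)

    # lambda = 0.5 on an n-gram effect: both inputs are row-stochastic, so
    # the convex combination is exact and renormalization is a no-op
    half <- makeGroupDynamics(pe, "del", 0.5)
    expect_equal(half$transition,
                 0.5 * delE$transition + 0.5 * wtE$transition,
                 tolerance = 1e-12)
    expect_equal(half$transition[2L, 4L],
                 (delE$transition[2L, 4L] + wtE$transition[2L, 4L]) / 2)
})

test_that("syllable-level effects shift stationary usage odds by the
           configured factor", {
    eff <- list(list(target = 3L, odds = 1.5))
    p <- simulationParams(nSyllables = 10L, genotypeEffect = eff)
    uw <- stationaryUsage(makeGroupDynamics(p, "wt"))
    ud <- stationaryUsage(makeGroupDynamics(p, "del", 0))
    oddsRatio <- (ud[3L] / (1 - ud[3L])) / (uw[3L] / (1 - uw[3L]))
    expect_equal(unname(oddsRatio), 1.5, tolerance = 1e-6)
})

test_that("renormalizing an all-zero row is an error", {
    p <- simulationParams(nSyllables = 3L,
                          genotypeEffect = list(list(target = c(1L, 2L),
                                                     odds = 0),
                                                list(target = c(1L, 3L),
                                                     odds = 0)))
    expect_error(makeGroupDynamics(p, "del", 0), "all zero")
})

test_that("a deterministic alternation chain generates strict
           alternation and seeds reproduce sequences exactly", {
    dyn <- list(transition = matrix(c(0, 1, 1, 0), 2L, 2L),
                dwellMeanFrames = c(1, 1))
    s <- simulateAnimal(dyn, 40L, seed = 8L)
    lab <- frameLabels(s)
    expect_true(all(abs(diff(lab)) == 1L))
    expect_length(lab, 40L)

    s2 <- simulateAnimal(dyn, 40L, seed = 8L)
    expect_identical(frameLabels(s), frameLabels(s2))
})

test_that("long simulations reach the semi-Markov stationary usage", {
    p <- simulationParams(nSyllables = 8L, seed = 3L)
    dyn <- makeGroupDynamics(p, "wt")
    s <- simulateAnimal(dyn, 120000L, seed = 12L)
    emp <- usage(computeUsage(s))
    stat <- stationaryUsage(dyn)
    for (k in seq_len(8L)) {
        e <- emp[as.character(k - 1L)]
        if (is.na(e)) e <- 0
        expect_lt(abs(e - stat[k]), 0.02)
    }
})

test_that("cohorts are schema-valid, reproducible, and round-trip
           through the sequence CSV", {
    p <- simulationParams(nSyllables = 5L, framesPerSession = 100L,
                          seed = 6L)
    d <- makeCohortDesign(data.frame(genotype = c("wt", "del"),
                                     dose = 0, n = 2L))
    co <- simulateCohort(p, d)
    expect_length(co$sequences, 4L)
    expect_true(all(vapply(co$sequences, nFrames, integer(1)) == 100L))
    expect_equal(vapply(co$sequences, animalId, character(1)),
                 d$animal_id)

    co2 <- simulateCohort(p, d)
    expect_identical(lapply(co$sequences, frameLabels),
                     lapply(co2$sequences, frameLabels))

    f <- withr::local_tempfile(fileext = ".csv")
    writeSequences(co$sequences, f)
    back <- readSequences(f)
    expect_identical(lapply(back, frameLabels),
                     lapply(co$sequences, frameLabels))
})

test_that("generative rescue is monotone for the perturbed transitions", {
    eff <- list(list(target = c(2L, 4L), odds = 5))
    p <- simulationParams(nSyllables = 6L, genotypeEffect = eff,
                          rescueLambda = c("0" = 0, "0.5" = 0.5, "1" = 1))
    wt <- makeGroupDynamics(p, "wt")$transition[2L, 4L]
    gaps <- vapply(c(0, 0.5, 1), function(dose)
        abs(makeGroupDynamics(p, "del", dose)$transition[2L, 4L] - wt),
        numeric(1))
    expect_true(all(diff(gaps) <= 1e-12))
    expect_equal(gaps[3L], 0)
})

test_that("synthetic endpoints honor group preference means and produce
           excludable low-exploration animals", {
    d <- makeCohortDesign(data.frame(genotype = "wt", dose = 0, n = 200L))
    epChance <- simulateEndpoints(d, endpointEffects(preferenceWt = 0.5),
                                  seed = 2L)
    test <- epChance$nor[epChance$nor$phase == "testing", ]
    di <- discriminationIndex(test$tA_s, test$tB_s)
    expect_equal(mean(di), 50, tolerance = 3)

    epPref <- simulateEndpoints(d, endpointEffects(preferenceWt = 0.7),
                                seed = 3L)
    test <- epPref$nor[epPref$nor$phase == "testing", ]
    expect_equal(mean(discriminationIndex(test$tA_s, test$tB_s)), 70,
                 tolerance = 3)

    # short-exploration animals appear and are excluded downstream
    epLow <- simulateEndpoints(d, endpointEffects(explorationMeanS = 3,
                                                  preferenceWt = 0.6),
                               seed = 4L)
    part <- excludeLowExploration(epLow$nor)
    expect_gt(nrow(part$excluded), 0L)
    tot <- part$excluded$tA_s + part$excluded$tB_s
    expect_true(all(tapply(tot < 3, part$excluded$animal_id, any)))

    # dose moves mutant preference toward wildtype
    dd <- makeCohortDesign(data.frame(genotype = "del", dose = c(0, 1),
                                      n = 200L))
    ep <- simulateEndpoints(dd, seed = 5L)
    test <- merge(ep$nor[ep$nor$phase == "testing", ], dd, by = "animal_id")
    di <- discriminationIndex(test$tA_s, test$tB_s)
    expect_equal(mean(di[test$dose_mg_per_ml == 0]), 50, tolerance = 3)
    expect_equal(mean(di[test$dose_mg_per_ml == 1]), 70, tolerance = 3)
})

test_that("with no effects, wildtype and mutant generative laws agree
           in large-sample usage", {
    p <- simulationParams(nSyllables = 6L, framesPerSession = 60000L,
                          seed = 9L, animalJitterConcentration = Inf)
    wt <- simulateAnimal(makeGroupDynamics(p, "wt"), 60000L, seed = 21L)
    del <- simulateAnimal(makeGroupDynamics(p, "del", 0), 60000L,
                          seed = 22L)
    uw <- usage(computeUsage(wt))
    ud <- usage(computeUsage(del))
    for (id in union(names(uw), names(ud))) {
        a <- uw[id]; if (is.na(a)) a <- 0
        b <- ud[id]; if (is.na(b)) b <- 0
        expect_lt(abs(a - b), 0.02)
    }
})
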