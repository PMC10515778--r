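test_that("run-length encoding groups frames and decoding inverts it", {
    r <- runLengthEncode(FrameLabels("m1", c(1L, 1L, 2L, 2L, 2L, 1L)))
    expect_equal(runLabels(r), c(1L, 2L, 1L))
    expect_equal(runDurations(r), c(2L, 3L, 1L))

    single <- runLengthEncode(FrameLabels("m1", 5L))
    expect_equal(runLabels(single), 5L)
    expect_equal(runDurations(single), 1L)

    # round trip on random 1000-frame sequences, including noise frames
    set.seed(101)
    for (i in 1:10) {
        s <- randomFrameSeq("m", 1000L, K = 8L)
        expect_identical(frameLabels(runLengthDecode(runLengthEncode(s))),
                         frameLabels(s))
    }
})

test_that("constructors reject malformed sequences", {
    expect_error(FrameLabels("m1", integer(0)), "at least one frame")
    expect_error(FrameLabels("m1", c(1L, -2L)), ">= -1")
    expect_error(RunSeq("m1", c(1L, 1L, 2L), c(1L, 1L, 1L)), "consecutive")
    expect_error(RunSeq("m1", c(1L, 2L), c(1L, 0L)), "durations")
})

test_that("usage is the fraction of frames per syllable and sums to 1", {
    u <- computeUsage(FrameLabels("m1", c(1L, 1L, 2L, 2L, 2L, 1L)))
    expect_equal(usage(u), c("1" = 0.5, "2" = 0.5))

    u7 <- computeUsage(FrameLabels("m1", rep(7L, 12L)))
    expect_equal(usage(u7), c("7" = 1))

    # brute-force tally oracle on random frames; noise bucket included
    set.seed(7)
    for (i in 1:5) {
        s <- randomFrameSeq("m", 100L, K = 5L, pNoise = 0.1)
        u <- usage(computeUsage(s))
        for (id in names(u))
            expect_equal(u[[id]],
                         sum(frameLabels(s) == as.integer(id)) / 100)
        expect_equal(sum(u), 1, tolerance = 1e-12)
    }
})

test_that("pooled usage is the frame-weighted mean of per-animal usage", {
    a <- computeUsage(FrameLabels("a", c(0L, 0L, 1L, 1L)))        # 4 frames
    b <- computeUsage(FrameLabels("b", rep(0L, 12L)))             # 12 frames
    p <- pooledUsage(list(a, b))
    expect_equal(p[["0"]], (2 + 12) / 16)
    expect_equal(p[["1"]], 2 / 16)
})

test_that("syllable selection applies the >threshold rule, noise
           exclusion, and usage-rank renumbering with ID tie-break", {
    mkU <- function(id, us, n = 1000L) {
        new("UsageVector", animalId = id, usage = us, nFrames = n)
    }
    u <- mkU("a", c("10" = 0.40, "20" = 0.35, "30" = 0.005, "40" = 0.245))
    ss <- selectSyllables(list(u), threshold = 0.01)
    expect_equal(includedSyllables(ss), c(10L, 20L, 40L))
    expect_equal(unname(excludedSyllables(ss)), "low-usage")
    expect_equal(names(excludedSyllables(ss)), "30")
    expect_equal(syllableMap(ss), c("10" = 0L, "20" = 1L, "40" = 2L))

    ssNoise <- selectSyllables(list(u), threshold = 0.01, noiseIds = 20L)
    expect_equal(includedSyllables(ssNoise), c(10L, 40L))
    expect_true("noise" %in% excludedSyllables(ssNoise))

    # tie at 0.25 between IDs 9 and 3: rank order (3, 9)
    ut <- mkU("a", c("9" = 0.25, "3" = 0.25, "5" = 0.5))
    st <- selectSyllables(list(ut), threshold = 0.01)
    expect_equal(includedSyllables(st), c(5L, 3L, 9L))

    # unassigned frames count in the denominator but are never included
    un <- computeUsage(FrameLabels("a", c(-1L, -1L, 0L, 0L)))
    sn <- selectSyllables(list(un), threshold = 0.01)
    expect_equal(includedSyllables(sn), 0L)
    expect_error(selectSyllables(list(un), threshold = 0.01, noiseIds = 0L),
                 "no syllables")
})

test_that("n-gram tables match brute-force sliding-window counts", {
    r <- RunSeq("m1", c(1L, 2L, 1L), c(1L, 1L, 1L))
    bi <- ngramTable(list(r), 2L, c(1L, 2L))
    expect_equal(ngramProbs(bi), c("1-2" = 0.5, "2-1" = 0.5))
    tri <- ngramTable(list(r), 3L, c(1L, 2L))
    expect_equal(ngramProbs(tri), c("1-2-1" = 1))

    set.seed(11)
    for (i in 1:10) {
        runs <- lapply(1:4, function(j)
            randomRunSeq(paste0("m", j), 50L, K = 6L))
        included <- 1:5   # ID 6 excluded: exercises delete-and-merge
        for (n in 2:3) {
            tb <- ngramTable(runs, n, included)
            oracle <- oracleNgramCounts(lapply(runs, runLabels), n, included)
            expect_equal(totalTransitions(tb), oracle$total)
            oc <- oracle$counts
            expect_equal(ngramCounts(tb)[sort(names(ngramCounts(tb)))],
                         oc[sort(names(oc))])
            expect_equal(ngramProbs(tb),
                         ngramCounts(tb) / totalTransitions(tb))
            expect_equal(sum(ngramProbs(tb)), 1, tolerance = 1e-12)
        }
    }
})

test_that("n-gram tables are exact rational count ratios on small cases", {
    runs <- list(RunSeq("a", c(1L, 2L, 3L, 1L, 2L), rep(1L, 5)),
                 RunSeq("b", c(2L, 1L, 2L), rep(1L, 3)))
    tb <- ngramTable(runs, 2L, 1:3)
    expect_identical(ngramProbs(tb),
                     ngramCounts(tb) / totalTransitions(tb))
    expect_equal(totalTransitions(tb), 4L + 2L)
})

test_that("n-gram tables are invariant to animal order and support
           only the two possible bigrams with two syllables", {
    set.seed(3)
    runs <- lapply(1:5, function(j) randomRunSeq(paste0("m", j), 40L, 4L))
    t1 <- ngramTable(runs, 2L, 1:4)
    t2 <- ngramTable(rev(runs), 2L, 1:4)
    expect_equal(ngramCounts(t1)[sort(names(ngramCounts(t1)))],
                 ngramCounts(t2)[sort(names(ngramCounts(t2)))])
    expect_equal(totalTransitions(t1), totalTransitions(t2))

    two <- lapply(1:3, function(j) randomRunSeq(paste0("m", j), 30L, 2L))
    tb <- ngramTable(two, 2L, 1:2)
    expect_true(all(names(ngramCounts(tb)) %in% c("1-2", "2-1")))
})

test_that("excluded-syllable runs are deleted with flanking merge", {
    # 1,9,1,2 with 9 excluded: the two 1-runs merge, windows = (1,2) only
    r <- RunSeq("m", c(1L, 9L, 1L, 2L), rep(1L, 4))
    tb <- ngramTable(list(r), 2L, c(1L, 2L))
    expect_equal(ngramProbs(tb), c("1-2" = 1))
})

test_that("an empty n-gram table is an error", {
    r <- RunSeq("m", 1L, 5L)
    expect_error(ngramTable(list(r), 2L, c(1L, 2L)), "at least 2 runs")
})
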