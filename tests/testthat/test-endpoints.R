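test_that("discrimination index reproduces the printed formula", {
    expect_equal(discriminationIndex(30, 30), 50)
    expect_equal(discriminationIndex(0, 12), 100)
    expect_equal(discriminationIndex(6, 18), 75)
    expect_error(discriminationIndex(0, 0), "excluded")
    # complement identity: DI(a, b) + DI(b, a) = 100
    set.seed(4)
    a <- stats::runif(20, 1, 30); b <- stats::runif(20, 1, 30)
    expect_equal(discriminationIndex(a, b) + discriminationIndex(b, a),
                 rep(100, 20))
})

test_that("low-exploration exclusion is strict, per-phase, and
           partitions the trials", {
    tr <- data.frame(
        animal_id = rep(c("m1", "m2", "m3"), each = 2L),
        phase = rep(c("training", "testing"), 3L),
        tA_s = c(1.4, 20, 1.5, 1.5, 5, 5),
        tB_s = c(1.5, 20, 1.5, 1.5, 5, 5))
    out <- excludeLowExploration(tr)
    # m1: training total 2.9 < 3 -> excluded despite testing 40
    expect_true("m1" %in% out$excluded$animal_id)
    # m2: exactly 3.0 in both phases -> kept (strict <)
    expect_true("m2" %in% out$kept$animal_id)
    expect_true("m3" %in% out$kept$animal_id)
    expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(tr))
    expect_equal(out$reasons$animal_id, "m1")

    expect_error(excludeLowExploration(tr[-1L, ]), "missing a phase")
})

test_that("SD-outlier exclusion is single-pass with full-sample moments
           and strict boundary", {
    expect_length(excludeSdOutliers(c(50, 50, 50, 50))$excluded, 0L)

    v <- c(10, 11, 12, 13, 40)
    out <- excludeSdOutliers(v)
    expected <- abs(40 - mean(v)) > 2 * stats::sd(v)
    expect_equal(40 %in% out$excluded, expected)

    # +/-2 with seven zeros: sd = 1, extremes sit exactly at 2 SD -> kept
    x <- c(-2, rep(0, 7), 2)
    expect_equal(stats::sd(x), 1)
    expect_true(all(excludeSdOutliers(x)$keep))

    # idempotent on the kept set when nothing more crosses the bound
    out2 <- excludeSdOutliers(out$kept)
    expect_equal(sort(out2$kept), sort(out$kept))
})

test_that("freezing percent is an epoch tally and scale-invariant", {
    expect_equal(freezingPercent(c(rep(1, 30), rep(0, 90))), 25)
    expect_equal(freezingPercent(rep(0, 50)), 0)
    set.seed(8)
    s <- stats::rbinom(200, 1, 0.3)
    expect_equal(freezingPercent(s), 100 * sum(s) / 200)
    expect_equal(freezingPercent(rep(s, 3L)), freezingPercent(s))
    expect_error(freezingPercent(integer(0)), "no epochs")
})

test_that("center-time percent and activity binning follow the printed
           definitions", {
    expect_equal(centerTimePercent(300, 1800), 100 / 6)
    expect_equal(centerTimePercent(c(30, 60), c(300, 300)), c(10, 20))
    expect_error(centerTimePercent(10, 0), "> 0")

    # event exactly at t = 300 s with 5-min bins falls in bin 1
    b <- binActivity(c(0, 299.9, 300, 550), sessionSeconds = 900)
    expect_equal(unname(b), c(2L, 2L, 0L))
    expect_error(binActivity(c(10, 901), 900), "beyond session")

    set.seed(14)
    ev <- stats::runif(500, 0, 900)
    b <- binActivity(ev, 900)
    brute <- vapply(0:2, function(i)
        sum(ev >= i * 300 & ev < (i + 1) * 300), numeric(1))
    expect_equal(unname(b), as.integer(brute))
})

test_that("balanced two-way type III ANOVA matches the classical
           textbook decomposition", {
    set.seed(33)
    g <- rep(c("wt", "del"), each = 12L)
    t <- rep(rep(c("veh", "drug"), each = 6L), 2L)
    y <- stats::rnorm(24) + 2 * (g == "del")
    res <- anovaTwoWay(y, g, t)
    # classical aov on a balanced design gives the same F values
    fit <- stats::aov(y ~ gf * tf,
                      data = data.frame(y = y, gf = factor(g),
                                        tf = factor(t)))
    sm <- summary(fit)[[1L]]
    expect_equal(res$F, sm[["F value"]][1:3], tolerance = 1e-10)
    expect_equal(res$p, sm[["Pr(>F)"]][1:3], tolerance = 1e-10)
    expect_true(all(res$df == 1L))
})

test_that("two-way ANOVA detects a pure genotype main effect and
           rejects empty cells", {
    set.seed(44)
    g <- rep(c("wt", "del"), each = 20L)
    t <- rep(rep(c("veh", "drug"), each = 10L), 2L)
    y <- stats::rnorm(40, sd = 0.5) + 3 * (g == "del")
    res <- anovaTwoWay(y, g, t)
    expect_lt(res$p[res$term == "genotype"], 1e-6)
    expect_gt(res$p[res$term == "genotype:treatment"], 0.01)

    expect_error(anovaTwoWay(y[1:30], g[1:30], t[1:30]), "fewer than 2")
})

test_that("under the null the two-way ANOVA p-values are roughly
           uniform", {
    set.seed(55)
    ps <- replicate(60, {
        g <- rep(c("wt", "del"), each = 8L)
        t <- rep(rep(c("a", "b"), each = 4L), 2L)
        anovaTwoWay(stats::rnorm(16), g, t)$p[1L]
    })
    expect_gt(mean(ps < 0.05), 0)      # sanity: not degenerate at 1
    expect_lt(mean(ps < 0.05), 0.2)    # ... and near the nominal rate
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Welch post-hoc tests with Holm-Sidak adjustment", {
    set.seed(66)
    vals <- c(stats::rnorm(10), stats::rnorm(10, 3), stats::rnorm(10))
    grp <- rep(c("a", "b", "c"), each = 10L)
    res <- posthocWelchHolmSidak(vals, grp,
                                 list(c("a", "b"), c("a", "c")))
    expect_equal(res$p_adjusted, holmSidak(res$p))
    expect_lt(res$p_adjusted[1L], 0.001)

    # one group against itself: t = 0, p = 1
    same <- posthocWelchHolmSidak(c(1, 1, 1, 2, 2, 2),
                                  rep(c("a", "b"), c(3, 3)),
                                  list(c("a", "a")))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
})
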