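test_that("proportional counts give a null result", {
    len <- c(3e8, 2e8, 1e8)
    res <- testUniformAmongChromosomes(c(300, 200, 100), len)
    expect_equal(res$pearson$statistic, 0)
    expect_equal(res$g$statistic, 0)
    expect_false(any(res$components$significant))
})

test_that("a three-class toy gives the exact Pearson value", {
    res <- testUniformAmongChromosomes(c(a = 10, b = 10, c = 80), c(1, 1, 1))
    expect_equal(res$pearson$statistic, 98, tolerance = 1e-12)
    expect_equal(res$pearson$df, 2)
})

test_that("chromosome 1 and 4 deviations emerge from the printed counts", {
    t2 <- chromCountsFixture()
    res <- testUniformAmongChromosomes(setNames(t2$P + t2$M, t2$chrom),
                                       t2$lengthMbp * 1e6)
    expect_lt(res$g$p, 1e-10)
    comp <- res$components
    flagged <- comp$class[comp$significant]
    expect_setequal(flagged, c("1", "4"))
    expect_equal(comp$direction[comp$class == "1"], "over")
    expect_equal(comp$direction[comp$class == "4"], "under")
})

test_that("G components sum exactly to the overall statistic", {
    t2 <- chromCountsFixture()
    res <- testUniformAmongChromosomes(t2$P + t2$M, t2$lengthMbp)
    expect_equal(sum(res$components$g), res$g$statistic, tolerance = 1e-12)
    ## k = 2 collapses to the overall test
    res2 <- testUniformAmongChromosomes(c(30, 70), c(1, 1))
    expect_equal(nrow(res2$components), 1)
    expect_equal(res2$components$g, res2$g$statistic, tolerance = 1e-12)
})

test_that("a four-class toy matches longhand sequential pooling", {
    comp <- decomposeOrthogonal(c(40, 10, 10, 40), rep(1, 4))
    expect_equal(comp$g, gComponentsOracle(c(40, 10, 10, 40), rep(1, 4)),
                 tolerance = 1e-12)
    expect_equal(comp$g, c(10.823074, 8.451412, 19.274475),
                 tolerance = 1e-5)
})

test_that("degenerate uniformity inputs are rejected", {
    expect_error(testUniformAmongChromosomes(c(1, 2), c(1, -1)), "positive")
    expect_error(testUniformAmongChromosomes(c(0, 0), c(1, 1)), "zero total")
    expect_error(testUniformAmongChromosomes(c(5), c(1)), "at least two")
})

test_that("PM independence reproduces the printed per-chromosome pattern", {
    t2 <- chromCountsFixture()
    res <- testPmIndependence(setNames(t2$P, t2$chrom),
                              setNames(t2$M, t2$chrom))
    expect_lt(res$overall$p, 1e-12)
    expect_equal(res$overall$df, 9)
    per <- res$perChromosome
    expect_setequal(per$chrom[per$significant],
                    c("1", "2", "3", "4", "5", "7", "8", "9"))
    expect_setequal(per$chrom[per$significant & per$direction == "+"],
                    c("3", "4", "7", "9"))
    expect_setequal(per$chrom[per$significant & per$direction == "-"],
                    c("1", "2", "5", "8"))
})

test_that("PM independence edge cases behave", {
    ## identical proportions: statistic 0
    res <- testPmIndependence(c(30, 60), c(70, 140))
    expect_equal(res$overall$statistic, 0, tolerance = 1e-12)
    expect_false(any(res$perChromosome$significant))
    ## 2x2 toy with the hand-computed Pearson value 20
    res2 <- testPmIndependence(c(30, 10), c(10, 30))
    expect_equal(res2$overall$statistic, 20, tolerance = 1e-12)
    expect_equal(res2$perChromosome$statistic, c(20, 20), tolerance = 1e-12)
    expect_error(testPmIndependence(c(0, 0), c(5, 5)), "margin")
})

test_that("bin scan is null on uniform positions", {
    set.seed(55)
    pos <- list("1" = sort(ceiling(runif(2000) * 2e8)))
    sc <- scanBins(pos, c("1" = 2e8))
    expect_equal(nrow(sc$bins), 20)
    expect_true(all(sc$bins$class == "ns"))
    ## expected counts conserve the included total
    expect_equal(sum(sc$bins$expected), sum(sc$bins$observed))
})

test_that("a seeded bin is the only one flagged, matching manual BH", {
    ## 20-bin chromosome, 100 SNPs/bin baseline, bin 7 at 5x
    obs <- rep(100, 20); obs[7] <- 500
    pos <- unlist(lapply(1:20, function(b)
        seq((b - 1) * 1e7 + 1, b * 1e7 - 1, length.out = obs[b])))
    sc <- scanBins(list("1" = pos), c("1" = 2e8), test = "binomial")
    expect_equal(sc$bins$class[7], "high")
    expect_true(all(sc$bins$class[-7] == "ns"))
    ## manual BH step-up on independently computed binomial p-values
    nIn <- sum(obs)
    praw <- vapply(1:20, function(b)
        binom.test(obs[b], nIn, 1 / 20)$p.value, numeric(1))
    expect_identical(sc$bins$class != "ns", bhBruteForce(praw, 0.05))
})

test_that("terminal incomplete bins are excluded from the scan", {
    ## 205 Mbp chromosome: 20 complete bins, SNPs beyond 200 Mbp omitted
    pos <- c(seq(5e5, 2e8, by = 1e6), 2.01e8, 2.04e8)
    sc <- scanBins(list("1" = pos), c("1" = 2.05e8))
    expect_equal(nrow(sc$bins), 20)
    expect_equal(unname(sc$excluded["1"]), 2)
    expect_equal(sum(sc$bins$observed), length(pos) - 2)
    expect_error(scanBins(list("1" = pos), c("1" = 2e8), binSizeBp = 0),
                 "bin size")
})

test_that("telomeric and centromeric sets summarize the scan", {
    ## engineer a scan: high bins only in the first five bins
    obs <- rep(100, 20); obs[2:3] <- 250; obs[10] <- 2
    pos <- unlist(lapply(1:20, function(b)
        seq((b - 1) * 1e7 + 1, b * 1e7 - 2, length.out = obs[b])))
    sc <- scanBins(list("1" = pos), c("1" = 2e8))
    cen <- data.frame(chrom = "1", cenStartBp = 9.5e7, cenEndBp = 9.8e7)
    en <- summarizeTeloCentro(sc, cen)
    expect_equal(unname(en$telomeric["high", "proportion"]), 1.0)
    expect_true(en$centromereBinLow[["1"]])
    expect_equal(unname(en$centromeric["low", "inSet"]), 1)
    ## a null scan yields zero proportions
    set.seed(66)
    sc0 <- scanBins(list("1" = sort(ceiling(runif(2000) * 2e8))),
                    c("1" = 2e8))
    en0 <- summarizeTeloCentro(sc0, cen)
    expect_equal(unname(en0$telomeric[, "proportion"]), c(0, 0))
    expect_error(summarizeTeloCentro(sc, cen[0, ]), "missing centromere")
})

test_that("gap statistics match hand-derived and sorted oracles", {
    eq <- gapStatistics(list("1" = seq(1e5, 1e6, by = 1e5)))
    expect_equal(unname(eq$overall[c("mean", "median", "p95")]),
                 c(1e5, 1e5, 1e5))
    gs <- gapStatistics(list("1" = c(1, 10001, 60001, 260001)))
    expect_equal(unname(gs$overall["median"]), 50000)
    expect_equal(unname(gs$overall["p95"]), 200000)
    expect_equal(unname(gs$overall["max"]), 200000)
    ## random positions vs full-sort oracle, across two chromosomes
    set.seed(77)
    pos <- list("1" = sort(sample.int(1e8, 500)),
                "2" = sort(sample.int(1e8, 300)))
    gr <- gapStatistics(pos)
    allGaps <- sort(c(diff(pos[["1"]]), diff(pos[["2"]])))
    expect_equal(unname(gr$overall["n"]), 798)
    expect_equal(unname(gr$overall["median"]), median(allGaps))
    expect_equal(unname(gr$overall["p95"]),
                 allGaps[ceiling(0.95 * length(allGaps))])
    expect_equal(unname(gr$overall["max"]), max(allGaps))
    expect_equal(unname(gr$overall["over1Mbp"]), sum(allGaps > 1e6))
    ## invariants: per-chromosome gap count and ordering of quantiles
    expect_equal(gr$perChromosome$n, c(499, 299))
    expect_true(all(gr$overall["max"] >= gr$overall["p95"]))
    expect_true(all(gr$overall["p95"] >= gr$overall["median"]))
})
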