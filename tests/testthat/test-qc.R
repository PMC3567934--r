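test_that("self-comparison is fully identical", {
    v <- c("A/A", "G/G", "A/G", "T/T", "-/-")
    x <- makeCalls(list(s1 = v, s2 = v))
    cmp <- compareSamples(x, "s1", "s2")
    expect_equal(cmp$compared, 4)        # the failed call is not compared
    expect_equal(cmp$identicalFraction, 1)
    expect_equal(cmp$discordant, 0)
})

test_that("seed-stock comparison reproduces the discordance bookkeeping", {
    ## engineered counts: 47,937 compared of which 142 het-in-one,
    ## 239 discordant-homozygous, 14 identical-heterozygous
    n <- 47937
    a <- rep("A/A", n); b <- rep("A/A", n)
    a[1:121] <- "A/G"                    # het in A only
    b[122:142] <- "A/G"                  # het in B only
    a[143:381] <- "G/G"                  # discordant homozygous
    a[382:395] <- b[382:395] <- "A/G"    # het in both, identical
    x <- makeCalls(list(s1 = a, s2 = b))
    cmp <- compareSamples(x, "s1", "s2")
    expect_equal(cmp$compared, 47937)
    expect_equal(cmp$discordant, 381)
    expect_equal(sum(cmp$counts[c("het-in-A-only", "het-in-B-only")]), 142)
    expect_equal(unname(cmp$counts["discordant-homozygous"]), 239)
    expect_equal(unname(cmp$counts["identical-heterozygous"]), 14)
    expect_equal(roundHalfAway(100 * cmp$identicalFraction, 1), 99.2)
    expect_equal(roundHalfAway(100 * cmp$discordant / cmp$compared, 2), 0.79)
})

test_that("random allele flips land inside the binomial interval", {
    set.seed(91)
    n <- 10000
    a <- sample(c("A/A", "G/G"), n, replace = TRUE)
    b <- a
    flip <- runif(n) < 0.01
    b[flip] <- ifelse(a[flip] == "A/A", "G/G", "A/A")
    cmp <- compareSamples(makeCalls(list(s1 = a, s2 = b)), "s1", "s2")
    ci99 <- 2.576 * sqrt(0.01 * 0.99 / n)
    expect_lt(abs(cmp$discordant / cmp$compared - 0.01), ci99)
})

test_that("replicate merging imputes single failures and warns on conflict", {
    x <- makeCalls(list(r1 = c("A/A", "-/-", "G/G", "A/A"),
                        r2 = c("A/A", "G/G", "-/-", "A/A"),
                        other = rep("T/T", 4)))
    m <- mergeReplicates(x, "r1", "r2", "B73")
    expect_setequal(sampleNames(m), c("other", "B73"))
    expect_identical(unname(calls(m)[, "B73"]),
                     c("A/A", "G/G", "G/G", "A/A"))
    y <- makeCalls(list(r1 = c("A/A", "G/G"), r2 = c("A/A", "T/T")))
    expect_warning(mergeReplicates(y, "r1", "r2"), "discordant")
})

test_that("discordant clusters are maximal runs with bp spans", {
    ## an uninterrupted discordant run spanning 202.7-208.6 Mbp
    pos <- c(seq(1e6, 200e6, by = 10e6),
             seq(202.7e6, 208.6e6, length.out = 12),
             seq(215e6, 230e6, by = 5e6))
    n <- length(pos)
    a <- rep("A/A", n); b <- a
    b[21:32] <- "G/G"
    x <- makeCalls(list(s1 = a, s2 = b), chrom = rep("2", n), pos = pos)
    cl <- findDiscordantClusters(compareSamples(x, "s1", "s2"), minRun = 5)
    expect_equal(nrow(cl), 1)
    expect_equal(cl$nSnps, 12)
    expect_equal(cl$spanMbp, 5.9, tolerance = 1e-6)
    expect_equal(cl$startBp, 202.7e6)
    ## no discordant SNPs: empty result
    none <- findDiscordantClusters(compareSamples(x, "s1", "s1"), minRun = 1)
    expect_equal(nrow(none), 0)
    ## alternating pattern never reaches a 5-SNP run
    b2 <- a
    b2[seq(1, n, by = 2)] <- "G/G"
    alt <- findDiscordantClusters(
        compareSamples(makeCalls(list(s1 = a, s2 = b2),
                                 chrom = rep("2", n), pos = pos),
                       "s1", "s2"), minRun = 5)
    expect_equal(nrow(alt), 0)
})

test_that("a clean dataset passes all six filters untouched", {
    x <- makeCalls(list(parentA = rep("A/A", 10), parentB = rep("G/G", 10),
                        F1 = rep("A/G", 10), NIL1 = rep("A/A", 10)))
    r <- applyQualityFilters(x, basicRoles())
    expect_equal(sum(r$report$excluded), 0)
    expect_equal(attr(r$report, "final"), 10)
})

test_that("a SNP violating two steps is attributed to the first", {
    pA <- rep("A/A", 20); pB <- rep("G/G", 20); f1 <- rep("A/G", 20)
    nil <- rep("A/A", 20)
    chrom <- rep("1", 20); pos <- 1:20 * 100
    ## SNP 5 violates step 2 (F1 failed) and step 3 (unmapped)
    f1[5] <- "-/-"; chrom[5] <- "UNKNOWN"; pos[5] <- NA
    x <- makeCalls(list(parentA = pA, parentB = pB, F1 = f1, NIL1 = nil),
                   chrom = chrom, pos = pos)
    r <- applyQualityFilters(x, basicRoles())
    expect_equal(r$report$excluded, c(0, 1, 0, 0, 0, 0))
    expect_equal(attr(r$report, "initial") - sum(r$report$excluded),
                 attr(r$report, "final"))
})

test_that("the six-step filter reproduces the engineered full-scale counts", {
    fx <- fullScaleQcFixture()
    r <- applyQualityFilters(fx$calls, fx$roles)
    expect_equal(r$report$excluded, fx$expectedExcluded)
    expect_equal(attr(r$report, "final"), fx$expectedRetained)
    expect_equal(attr(r$report, "initial"), 57838)
    expect_equal(fx$expectedRetained, 42771)
    expect_equal(roundHalfAway(100 * 42771 / 57838, 1), 73.9)
    ## filtering is idempotent
    r2 <- applyQualityFilters(r$calls, fx$roles)
    expect_equal(sum(r2$report$excluded), 0)
})

test_that("missing mandatory roles raise an error", {
    x <- makeCalls(list(parentA = rep("A/A", 3), parentB = rep("G/G", 3)))
    roles <- data.frame(sample = c("parentA", "parentB"),
                        role = c("parentA", "parentB"),
                        stringsAsFactors = FALSE)
    expect_error(applyQualityFilters(x, roles), "exactly one 'F1'")
})

test_that("polymorphism classification follows the parental contrast", {
    x <- makeCalls(list(parentA = c("A/A", "A/A", "G/G"),
                        parentB = c("T/T", "A/A", "C/C"),
                        F1 = c("A/T", "A/A", "C/G"),
                        NIL1 = c("A/A", "A/A", "G/G")))
    st <- classifyPolymorphism(x, basicRoles())
    expect_identical(unname(st), c("polymorphic", "monomorphic",
                                   "polymorphic"))
    bad <- makeCalls(list(parentA = c("A/G"), parentB = c("T/T"),
                          F1 = c("A/T"), NIL1 = c("A/A")))
    expect_error(classifyPolymorphism(bad, basicRoles()),
                 "non-homozygous parental call")
})

test_that("simulated polymorphic fraction is recovered by classification", {
    gm <- testGenome()
    tr <- runBreedingScheme(introgressionScheme(qtl305(), seed = 41), gm)
    cc <- emulateChip(tr, noiselessChip(), seed = 3)
    roles <- truthRoles(tr)
    r <- applyQualityFilters(cc, roles)
    st <- classifyPolymorphism(r$calls, roles)
    expect_equal(mean(st == "polymorphic"), 0.35, tolerance = 0.02)
    ## and it agrees SNP-by-SNP with the simulator truth
    truthPoly <- isPolymorphicTruth(gm)[match(names(st), snpIds(panel(gm)))]
    expect_identical(unname(st == "polymorphic"), unname(truthPoly))
})
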