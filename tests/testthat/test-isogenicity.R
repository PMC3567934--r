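test_that("pair comparison classifies status and contrast", {
    a <- c("BB", "BB", "BB", "FAIL", "BH", "BB")
    b <- c("BB", "HH", "BH", "HH", "HH", "FAIL")
    st <- statusFrom(a, b)
    expect_identical(st$status, c("isogenic", "non-isogenic", "non-isogenic",
                                  "unknown", "non-isogenic", "unknown"))
    expect_identical(st$contrast[2:3], c("BB/HH", "BB/BH"))
    ident <- statusFrom(a, a)
    expect_true(all(ident$status[a != "FAIL"] == "isogenic"))
    expect_error(comparePair(makeEncoded(list(A = a)), "A", "missing"),
                 "not found")
})

test_that("block segmentation follows run-length enumeration", {
    ## 10 SNPs at 1-Mbp spacing, non-isogenic at 1-2, 4-6, 9-10
    a <- rep("BB", 10)
    b <- c("HH", "HH", "BB", "HH", "HH", "HH", "BB", "BB", "HH", "HH")
    st <- statusFrom(a, b)
    b0 <- segmentBlocks(st, gapTolerance = 0)
    expect_equal(nrow(b0$blocks), 3)
    expect_equal(b0$blocks$nSnps, c(2, 3, 2))
    b1 <- segmentBlocks(st, gapTolerance = 1)
    expect_equal(nrow(b1$blocks), 2)
    expect_equal(b1$blocks$nSnps, c(5, 2))   # first two merged
    ## all-isogenic vector: no blocks
    none <- segmentBlocks(statusFrom(a, a))
    expect_equal(nrow(none$blocks), 0)
})

test_that("unknown SNPs are transparent to runs", {
    a <- c("BB", "BB", "FAIL", "BB", "BB")
    b <- c("HH", "HH", "HH", "HH", "BB")
    bl <- segmentBlocks(statusFrom(a, b))
    expect_equal(nrow(bl$blocks), 1)
    expect_equal(bl$blocks$nSnps, 3)         # the failed SNP is not counted
    expect_equal(bl$blocks$startBp, 1e6)
    expect_equal(bl$blocks$endBp, 4e6)
})

test_that("contrast changes inside a block become sub-blocks", {
    ## 20-SNP block: BB/HH, then BH/HH (het in one line), then BB/HH
    a <- c(rep("BB", 8), rep("BH", 4), rep("BB", 8))
    b <- rep("HH", 20)
    bl <- segmentBlocks(statusFrom(a, b))
    expect_equal(nrow(bl$blocks), 1)
    expect_equal(bl$blocks$contrast, "mixed")
    sub <- bl$subBlocks
    expect_equal(nrow(sub), 3)
    expect_identical(sub$contrast, c("BB/HH", "BH/HH", "BB/HH"))
    expect_equal(sub$nSnps, c(8, 4, 8))
    ## a block heterozygous in one line throughout is flagged
    hb <- segmentBlocks(statusFrom(rep("BH", 4), rep("HH", 4)))
    expect_true(hb$blocks$hetOnly)
})

test_that("segmentation is symmetric in the pair orientation", {
    set.seed(14)
    a <- sample(c("BB", "HH", "BH", "FAIL"), 300, replace = TRUE)
    b <- sample(c("BB", "HH", "BH", "FAIL"), 300, replace = TRUE)
    f <- segmentBlocks(statusFrom(a, b), gapTolerance = 1)
    r <- segmentBlocks(statusFrom(b, a), gapTolerance = 1)
    expect_equal(f$blocks$startBp, r$blocks$startBp)
    expect_equal(f$blocks$endBp, r$blocks$endBp)
    expect_equal(f$blocks$nSnps, r$blocks$nSnps)
    expect_equal(f$blocks$spanMbp, r$blocks$spanMbp)
    ## contrasts mirror
    mirror <- vapply(strsplit(f$blocks$contrast, "/"), function(x)
        if (length(x) == 2) paste(rev(x), collapse = "/") else "mixed",
        character(1))
    expect_identical(mirror, r$blocks$contrast)
})

test_that("with zero tolerance blocks conserve the non-isogenic SNP set", {
    set.seed(15)
    a <- sample(c("BB", "HH", "FAIL"), 500, replace = TRUE)
    b <- sample(c("BB", "HH", "FAIL"), 500, replace = TRUE)
    st <- statusFrom(a, b)
    bl <- segmentBlocks(st, gapTolerance = 0)
    expect_equal(sum(bl$blocks$nSnps), sum(st$status == "non-isogenic"))
})

test_that("pair statistics reproduce the published total layout", {
    rep8 <- assemblePairReport(pairRowsFixture("3.05_R8"),
                               setNames(chromCountsFixture()$lengthMbp * 1e6,
                                        chromCountsFixture()$chrom),
                               qtlChrom = "3", pairId = "3.05_R8")
    expect_equal(unname(rep8$totals["excludingQtlChrom", "NB"]), 10)
    expect_equal(unname(rep8$totals["includingQtlChrom", "NB"]), 15)
    expect_equal(unname(rep8$totals["excludingQtlChrom", "NS"]), 637)
    expect_equal(unname(rep8$totals["includingQtlChrom", "NS"]), 1399)
    ## TS from rounded per-chromosome rows lands on the printed totals
    expect_equal(unname(rep8$totals["excludingQtlChrom", "TSMbp"]), 137.0,
                 tolerance = 0.002)
    expect_equal(unname(rep8$totals["includingQtlChrom", "TSMbp"]), 245.0,
                 tolerance = 0.002)
    expect_equal(rep8$formatted$CF_GF[rep8$formatted$chrom == "Total"],
                 "7.5% (12.0%)")
    expect_equal(rep8$formatted$NB[rep8$formatted$chrom == "Total"],
                 "10 (15)")
    expect_equal(rep8$formatted$NS[rep8$formatted$chrom == "Total"],
                 "637 (1399)")
    r63 <- assemblePairReport(pairRowsFixture("10.03_R63"),
                              setNames(chromCountsFixture()$lengthMbp * 1e6,
                                       chromCountsFixture()$chrom),
                              qtlChrom = "10", pairId = "10.03_R63")
    expect_equal(unname(r63$totals["excludingQtlChrom", "NB"]), 13)
    expect_equal(unname(r63$totals["includingQtlChrom", "NB"]), 14)
    expect_equal(r63$formatted$CF_GF[r63$formatted$chrom == "Total"],
                 "2.4% (2.7%)")
})

test_that("QTL-chromosome blocks are trimmed to outside the region", {
    q <- qtl305()
    pos <- c(seq(140e6, 146e6, by = 1e6),             # upstream drag
             seq(148e6, 166e6, by = 1e6),             # inside region
             seq(168e6, 172e6, by = 1e6),             # downstream drag
             seq(200e6, 204e6, by = 1e6))             # isogenic tail
    n <- length(pos)
    a <- rep("BB", n); b <- rep("HH", n)
    b[pos >= 200e6] <- "BB"                            # isogenic tail
    st <- statusFrom(a, b, pos = pos, chrom = rep("3", n))
    bl <- segmentBlocks(st)
    expect_equal(nrow(bl$blocks), 1)                   # one long block
    stats <- pairBlockStatistics(bl, chromLengths(testGenome()), qtl = q)
    per3 <- stats$perChromosome[stats$perChromosome$chrom == "3", ]
    expect_equal(per3$NB, 2)                           # split at the region
    expect_equal(per3$NS, 7 + 5)                       # in-region SNPs gone
    expect_equal(stats$totals["excludingQtlChrom", "NB"], 0)
    ## without a QTL the full block is kept
    raw <- pairBlockStatistics(bl, chromLengths(testGenome()))
    expect_equal(raw$perChromosome$NB[raw$perChromosome$chrom == "3"], 1)
    ## empty input gives an all-zero table
    zero <- pairBlockStatistics(segmentBlocks(statusFrom(a, a, pos = pos,
                                                         chrom = rep("3", n))),
                                chromLengths(testGenome()), qtl = q)
    expect_true(all(zero$perChromosome$NB == 0))
    expect_equal(unname(zero$totals[, "GFpct"]), c(0, 0))
})

test_that("QTL introgression verification detects violations and gaps", {
    q <- qtl305()
    pos <- seq(q@leftBp, q@rightBp, length.out = 122)
    n <- length(pos)
    good <- makeEncoded(list(NIL_BB = rep("BB", n), NIL_HH = rep("HH", n)),
                        pos = pos, chrom = rep("3", n))
    expect_true(verifyQtlIntrogression(good, "NIL_BB", "NIL_HH", q)$pass)
    ## 19 adjacent shared-HH SNPs between 152.0 and 154.4 Mbp
    hh <- rep("HH", n)
    bb <- rep("BB", n)
    shared <- pos >= 152.0e6 & pos <= 154.9e6
    bb[shared] <- "HH"
    bad <- makeEncoded(list(NIL_BB = bb, NIL_HH = hh),
                       pos = pos, chrom = rep("3", n))
    chk <- verifyQtlIntrogression(bad, "NIL_BB", "NIL_HH", q)
    expect_false(chk$pass)
    expect_equal(nrow(chk$isogenicSegments), 1)
    expect_equal(chk$isogenicSegments$sharedGenotype, "HH")
    expect_equal(chk$isogenicSegments$nSnps, sum(shared))
    ## a single stray SNP is listed as a violation
    bb2 <- rep("BB", n); bb2[60] <- "HH"
    one <- verifyQtlIntrogression(
        makeEncoded(list(NIL_BB = bb2, NIL_HH = hh),
                    pos = pos, chrom = rep("3", n)), "NIL_BB", "NIL_HH", q)
    expect_false(one$pass)
    expect_equal(nrow(one$violations), 1)
    ## region without polymorphic SNPs is unscoreable
    off <- makeEncoded(list(NIL_BB = "BB", NIL_HH = "HH"),
                       pos = 1e6, chrom = "3")
    expect_error(verifyQtlIntrogression(off, "NIL_BB", "NIL_HH", q),
                 "no polymorphic SNP")
})

test_that("linkage drag measures contiguous and joined extensions", {
    q <- qtl305()
    ## upstream concordant to 13.4 Mbp below the left flank, downstream
    ## concordant to 3.9 Mbp above the right flank
    upPos <- seq(q@leftBp - 13.4e6, q@leftBp - 0.1e6, by = 0.5e6)
    inPos <- seq(q@leftBp, q@rightBp, length.out = 50)
    downPos <- seq(q@rightBp + 0.1e6, q@rightBp + 3.9e6, by = 0.38e6)
    stopPos <- c(q@leftBp - 14e6, q@rightBp + 4.5e6)   # isogenic stops
    farPos <- seq(q@leftBp - 40e6, q@leftBp - 35e6, by = 1e6)  # joinable
    pos <- sort(c(upPos, inPos, downPos, stopPos, farPos))
    a <- rep("BB", length(pos))
    b <- ifelse(pos %in% stopPos, "BB", "HH")
    st <- statusFrom(a, b, pos = pos, chrom = rep("3", length(pos)))
    dr <- measureLinkageDrag(st, q)
    expect_equal(dr$upstreamMbp, 13.4)
    expect_equal(dr$downstreamMbp, 3.9)
    expect_equal(dr$totalMbp, 17.3)
    ## the far block is within the 25-Mbp join gap: reported separately
    expect_equal(nrow(dr$joins), 1)
    expect_equal(dr$joins$side, "upstream")
    expect_equal(dr$joinedUpstreamMbp, 40, tolerance = 1e-6)
    expect_equal(dr$joinedDownstreamMbp, dr$downstreamMbp)
    ## no concordant SNPs outside the flanks: all zeros
    b0 <- ifelse(pos >= q@leftBp & pos <= q@rightBp, "HH", "BB")
    dr0 <- measureLinkageDrag(
        statusFrom(a, b0, pos = pos, chrom = rep("3", length(pos))), q)
    expect_equal(dr0$totalMbp, 0)
})
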