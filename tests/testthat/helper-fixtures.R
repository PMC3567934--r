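## Fixture builders and independent oracles shared by the suite.
## Everything is generated in code; nothing is read from disk.

## ---- printed reference tables (used as inputs) ----------------------

## per-chromosome lengths (Mbp) and good-quality SNP counts split into
## polymorphic / monomorphic, as printed in the distribution table
chromCountsFixture <- function() {
    data.frame(
        chrom = as.character(1:10),
        lengthMbp = c(300.2, 234.8, 230.6, 247.1, 216.9,
                      169.3, 171.0, 174.5, 152.4, 149.7),
        P = c(2272, 1625, 1730, 1752, 1444, 1238, 1361, 1212, 1192, 1111),
        M = c(4540, 3285, 2967, 3018, 3196, 2230, 2178, 2500, 1959, 1961),
        stringsAsFactors = FALSE)
}

## per-chromosome NB / NS / TS rows of the pair-report table for the
## 3.05_R8 and 10.03_R63 pairs (dashes are zeros)
pairRowsFixture <- function(pair = c("3.05_R8", "10.03_R63")) {
    pair <- match.arg(pair)
    if (pair == "3.05_R8")
        data.frame(chrom = as.character(1:10),
                   NB = c(1, 0, 5, 0, 4, 1, 1, 2, 0, 1),
                   NS = c(15, 0, 762, 0, 490, 25, 3, 94, 0, 10),
                   TSMbp = c(2.5, 0, 108.0, 0, 117.8, 1.4, 0.15, 13.4, 0, 1.6),
                   stringsAsFactors = FALSE)
    else
        data.frame(chrom = as.character(1:10),
                   NB = c(3, 3, 2, 1, 0, 0, 1, 1, 2, 1),
                   NS = c(148, 155, 46, 2, 0, 0, 25, 16, 14, 69),
                   TSMbp = c(17.1, 17.6, 6.3, 0.00049, 0, 0, 2.3, 1.2, 1.9, 9.0),
                   stringsAsFactors = FALSE)
}

qtl305 <- function() qtlRegion("3.05", "3", "bnlg1505", 147812359,
                               "dupssr23", 166846373)

## ---- small hand-built objects ---------------------------------------

## an EncodedMatrix from per-sample code vectors on one chromosome
makeEncoded <- function(codesBySample, pos = NULL, chrom = NULL) {
    n <- length(codesBySample[[1]])
    if (is.null(pos)) pos <- seq_len(n) * 1e6
    if (is.null(chrom)) chrom <- rep("1", n)
    ids <- sprintf("s%04d", seq_len(n))
    pan <- SnpPanel(ids, chrom, pos)
    cm <- do.call(cbind, codesBySample)
    rownames(cm) <- ids
    new("EncodedMatrix", codes = cm[match(snpIds(pan), ids), , drop = FALSE],
        panel = pan, alleleA = rep("A", n), alleleB = rep("T", n))
}

## an IsoStatusVector from two code vectors
statusFrom <- function(a, b, pos = NULL, chrom = NULL) {
    comparePair(makeEncoded(list(A = a, B = b), pos = pos, chrom = chrom),
                "A", "B")
}

## a GenotypeCalls + roles manifest from per-sample call vectors
makeCalls <- function(callsBySample, chrom = NULL, pos = NULL) {
    n <- length(callsBySample[[1]])
    if (is.null(pos)) pos <- seq_len(n) * 1000
    if (is.null(chrom)) chrom <- rep("1", n)
    ids <- sprintf("s%04d", seq_len(n))
    cm <- do.call(cbind, callsBySample)
    rownames(cm) <- ids
    GenotypeCalls(cm, SnpPanel(ids, chrom, pos))
}

basicRoles <- function(nil = "NIL1") {
    data.frame(sample = c("parentA", "parentB", "F1", nil),
               role = c("parentA", "parentB", "F1",
                        rep("NIL", length(nil))),
               pair = c(NA, NA, NA, rep("p1", length(nil))),
               side = c(NA, NA, NA, rep("BB", length(nil))),
               stringsAsFactors = FALSE)
}

## full-chip-scale synthetic QC fixture engineered so that the six
## ordered filters exclude 8319/5386/618/114/625/5 of 57838 SNPs
fullScaleQcFixture <- function(seed = 42) {
    set.seed(seed)
    nPer <- c(8319, 5386, 618, 114, 625, 5)
    nKeep <- 57838 - sum(nPer)
    cat <- rep(c(1:6, 0), c(nPer, nKeep))
    cat <- sample(cat)          # shuffle SNP order
    n <- length(cat)
    pA <- rep("A/A", n); pB <- rep("G/G", n)
    f1 <- rep("A/G", n); nil <- rep("A/A", n)
    pA[cat == 1] <- pB[cat == 1] <- f1[cat == 1] <- nil[cat == 1] <- "-/-"
    f1[cat == 2] <- "-/-"
    pA[cat == 4] <- "A/G"
    f1[cat == 5] <- "A/A"
    pB[cat == 6] <- "A/A"; f1[cat == 6] <- "A/A"; nil[cat == 6] <- "G/G"
    chrom <- rep("1", n); chrom[cat == 3] <- "UNKNOWN"
    pos <- seq_len(n) * 100; pos[cat == 3] <- NA
    x <- makeCalls(list(parentA = pA, parentB = pB, F1 = f1, NIL1 = nil),
                   chrom = chrom, pos = pos)
    list(calls = x, roles = basicRoles(), expectedExcluded = nPer,
         expectedRetained = nKeep)
}

## a random messy fixture for filter conservation / order-invariance
randomCallsFixture <- function(n = 200) {
    tok <- c("A/A", "A/G", "G/G", "T/T", "-/-")
    draw <- function() sample(tok, n, replace = TRUE,
                              prob = c(0.4, 0.15, 0.25, 0.1, 0.1))
    chrom <- sample(c("1", "2", "UNKNOWN"), n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    pos <- seq_len(n) * 500
    pos[chrom == "UNKNOWN"] <- NA
    list(calls = makeCalls(list(parentA = draw(), parentB = draw(),
                                F1 = draw(), NIL1 = draw()),
                           chrom = chrom, pos = pos),
         roles = basicRoles())
}

## ---- independent oracles --------------------------------------------

## Benjamini-Hochberg step-up, straight from the definition
bhBruteForce <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    reject <- logical(m)
    if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
    reject
}

## run-length segmentation by explicit per-SNP walk; `status` is a
## character vector over {"isogenic","non-isogenic","unknown"}; returns
## a list of index vectors (the non-isogenic members of each block)
segmentBruteForce <- function(status, gapTolerance = 0) {
    blocks <- list()
    cur <- integer(0)
    isoRun <- 0L
    for (i in seq_along(status)) {
        s <- status[i]
        if (s == "unknown") next
        if (s == "non-isogenic") {
            if (length(cur) && isoRun > gapTolerance) {
                blocks[[length(blocks) + 1L]] <- cur
                cur <- integer(0)
            }
            cur <- c(cur, i)
            isoRun <- 0L
        } else {
            isoRun <- isoRun + 1L
        }
    }
    if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
    blocks
}

## the six filter predicates, re-derived independently of the package
filterOracle <- function(x, roles) {
    cm <- calls(x)
    pan <- panel(x)
    fail <- function(v) v == "-/-"
    het <- function(v) !fail(v) & substr(v, 1, 1) != substr(v, 3, 3)
    hom <- function(v) !fail(v) & substr(v, 1, 1) == substr(v, 3, 3)
    a <- cm[, "parentA"]; b <- cm[, "parentB"]; f <- cm[, "F1"]
    nils <- roles$sample[roles$role == "NIL"]
    mono <- hom(a) & hom(b) & a == b
    poly <- hom(a) & hom(b) & a != b
    hetTok <- function(x1, x2) paste(pmin(x1, x2), pmax(x1, x2), sep = "/")
    nilBad <- rep(FALSE, nrow(cm))
    for (s in nils)
        nilBad <- nilBad | (mono & !fail(cm[, s]) & cm[, s] != a)
    list(s1 = rowSums(!fail(cm)) == 0,
         s2 = fail(a) | fail(b) | fail(f),
         s3 = !isMapped(pan),
         s4 = het(a) | het(b),
         s5 = poly & !fail(f) &
             f != hetTok(substr(a, 1, 1), substr(b, 1, 1)),
         s6 = nilBad)
}

## sequential-pooling G components, written out longhand
gComponentsOracle <- function(counts, weights) {
    k <- length(counts)
    g <- numeric(k - 1)
    for (i in seq_len(k - 1)) {
        oi <- counts[i]
        rest <- sum(counts[(i + 1):k])
        ei <- (oi + rest) * weights[i] / sum(weights[i:k])
        er <- (oi + rest) - ei
        t1 <- if (oi > 0) oi * log(oi / ei) else 0
        t2 <- if (rest > 0) rest * log(rest / er) else 0
        g[i] <- 2 * (t1 + t2)
    }
    g
}

## small default genome reused across simulator tests (2k SNPs is
## plenty for marker-level checks and keeps the suite fast)
testGenome <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- buildGenomeModel(nSnps = 2000, seed = 20260926)
        cache
    }
})
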