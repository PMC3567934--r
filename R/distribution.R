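#' @include qc.R
NULL

#' Goodness-of-fit of SNP counts to chromosome lengths
#'
#' Tests whether per-chromosome SNP counts are proportional to physical
#' chromosome lengths.  Reports the Pearson chi-square and the
#' likelihood-ratio G statistic on k-1 degrees of freedom, plus k-1
#' orthogonal 1-df components obtained by sequential pooling in
#' ascending chromosome order: component i tests chromosome i against
#' the pooled chromosomes i+1..k with expectations renormalized to the
#' pooled total.  The G components sum exactly to the overall G.
#'
#' @param counts named vector of per-chromosome SNP counts.
#' @param lengthsBp per-chromosome physical lengths (same order).
#' @param alpha significance level for the flags (default 0.05).
#' @return a list of class `"ChromUniformityResult"` with `pearson`,
#'   `g` (each: statistic, df, p), and `components` (data.frame with
#'   per-component G and Pearson statistics, p-values, direction and
#'   significance flag).
#' @examples
#' testUniformAmongChromosomes(c(a = 10, b = 10, c = 80), c(1, 1, 1))$pearson
#' @export
testUniformAmongChromosomes <- function(counts, lengthsBp, alpha = 0.05) {
    k <- length(counts)
    if (k < 2) stop("need at least two chromosomes")
    if (any(lengthsBp <= 0)) stop("lengths must be positive")
    if (any(counts < 0)) stop("counts must be non-negative")
    N <- sum(counts)
    if (N == 0) stop("zero total count")
    expected <- N * lengthsBp / sum(lengthsBp)
    x2 <- sum((counts - expected)^2 / expected)
    nz <- counts > 0
    g <- 2 * sum(counts[nz] * log(counts[nz] / expected[nz]))
    comp <- decomposeOrthogonal(counts, lengthsBp, alpha = alpha)
    structure(list(
        counts = counts, lengthsBp = lengthsBp, expected = expected,
        pearson = list(statistic = x2, df = k - 1,
                       p = stats::pchisq(x2, k - 1, lower.tail = FALSE)),
        g = list(statistic = g, df = k - 1,
                 p = stats::pchisq(g, k - 1, lower.tail = FALSE)),
        components = comp, alpha = alpha),
        class = "ChromUniformityResult")
}

#' Orthogonal 1-df decomposition by sequential pooling
#'
#' Splits a k-class goodness-of-fit test into k-1 orthogonal 1-df
#' tests: class 1 vs classes 2..k pooled, then class 2 vs 3..k within
#' the pooled remainder, and so on.  Expectations are renormalized to
#' each pooled total, which makes the G components exactly additive.
#'
#' @param counts per-class observed counts.
#' @param weights expected-proportion weights (e.g. chromosome
#'   lengths).
#' @param alpha significance level for the flags.
#' @return data.frame: `class`, `observed`, `expected`, `g`, `pearson`,
#'   `p` (from G), `direction` (`"over"`/`"under"`), `significant`.
#' @export
decomposeOrthogonal <- function(counts, weights, alpha = 0.05) {
    k <- length(counts)
    nm <- names(counts)
    if (is.null(nm)) nm <- as.character(seq_len(k))
    out <- vector("list", k - 1L)
    for (i in seq_len(k - 1L)) {
        oi <- counts[i]
        or <- sum(counts[(i + 1L):k])
        pi <- weights[i] / sum(weights[i:k])
        n <- oi + or
        ei <- n * pi
        er <- n - ei
        terms <- c(oi, or) * log(c(oi, or) / c(ei, er))
        g <- 2 * sum(terms[c(oi, or) > 0])
        x2 <- (oi - ei)^2 / ei + (or - er)^2 / er
        out[[i]] <- data.frame(
            class = nm[i], observed = oi, expected = ei, g = g, pearson = x2,
            p = stats::pchisq(g, 1, lower.tail = FALSE),
            direction = if (oi >= ei) "over" else "under",
            stringsAsFactors = FALSE)
    }
    x <- do.call(rbind, out)
    x$significant <- x$p < alpha
    rownames(x) <- NULL
    x
}

#' Independence of polymorphic vs monomorphic counts from chromosome
#'
#' Overall 2 x k Pearson chi-square of (P, M) by chromosome, plus one
#' 2 x 2 test per chromosome (that chromosome against the pooled rest)
#' with the direction of its PM-ratio deviation.
#'
#' @param P,M per-chromosome polymorphic and monomorphic counts.
#' @param alpha significance level for the flags (default 0.05).
#' @return a list of class `"PmIndependenceResult"`: `overall`
#'   (statistic, df, p) and `perChromosome` (data.frame with
#'   `statistic`, `p`, `direction` in `"+"`/`"-"`, `significant`).
#' @export
testPmIndependence <- function(P, M, alpha = 0.05) {
    k <- length(P)
    if (k < 2 || length(M) != k) stop("need P and M for >= 2 chromosomes")
    if (any(P + M == 0) || sum(P) == 0 || sum(M) == 0)
        stop("zero margin: every chromosome needs SNPs and both classes must occur")
    nm <- names(P)
    if (is.null(nm)) nm <- as.character(seq_len(k))
    tab <- rbind(P, M)
    ov <- stats::chisq.test(tab, correct = FALSE)
    per <- do.call(rbind, lapply(seq_len(k), function(i) {
        t2 <- cbind(c(P[i], M[i]), c(sum(P) - P[i], sum(M) - M[i]))
        ct <- stats::chisq.test(t2, correct = FALSE)
        data.frame(chrom = nm[i],
                   statistic = unname(ct$statistic),
                   p = ct$p.value,
                   direction = if (P[i] >= ct$expected[1, 1]) "+" else "-",
                   stringsAsFactors = FALSE)
    }))
    per$significant <- per$p < alpha
    rownames(per) <- NULL
    structure(list(overall = list(statistic = unname(ov$statistic),
                                  df = unname(ov$parameter),
                                  p = ov$p.value),
                   perChromosome = per, alpha = alpha),
              class = "PmIndependenceResult")
}

#' Scan fixed-width bins for SNP over/under-representation
#'
#' Chromosomes are divided into complete `binSizeBp` bins (SNPs in the
#' incomplete terminal bin are omitted); each complete bin is tested
#' against the remainder of its chromosome (1-df Pearson by default, or
#' an exact binomial test), with expectations uniform across the
#' chromosome's complete bins; Benjamini-Hochberg FDR control is
#' applied across all complete bins genome-wide.
#'
#' @param positions named list (per chromosome) of sorted SNP bp
#'   positions, or a data.frame with `chrom` and `pos`.
#' @param lengthsBp named vector of chromosome lengths.
#' @param binSizeBp bin width (default 1e7, i.e. 10 Mbp).
#' @param q FDR level (default 0.05).
#' @param family `"genome"` (default; one BH family across all bins) or
#'   `"chromosome"` (BH per chromosome).
#' @param test `"pearson"` (default) or `"binomial"`.
#' @return a list of class `"BinScan"`: `bins` (data.frame with
#'   `chrom`, `bin`, `startBp`, `endBp`, `observed`, `expected`,
#'   `statistic`, `p`, `padj`, `class` in low/high/ns) and `excluded`
#'   (terminal-bin SNP counts per chromosome).
#' @export
scanBins <- function(positions, lengthsBp, binSizeBp = 1e7, q = 0.05,
                     family = c("genome", "chromosome"),
                     test = c("pearson", "binomial")) {
    family <- match.arg(family)
    test <- match.arg(test)
    if (binSizeBp <= 0) stop("bin size must be positive")
    if (is.data.frame(positions))
        positions <- split(positions$pos, positions$chrom)
    rows <- list()
    excl <- stats::setNames(integer(length(positions)), names(positions))
    for (ch in names(positions)) {
        L <- lengthsBp[[ch]]
        nb <- floor(L / binSizeBp)
        if (nb < 1L) { excl[ch] <- length(positions[[ch]]); next }
        p <- positions[[ch]]
        bin <- ceiling(p / binSizeBp)
        excl[ch] <- sum(bin > nb)
        obs <- tabulate(bin[bin <= nb], nbins = nb)
        nIn <- sum(obs)
        e <- nIn / nb
        stat <- p.raw <- numeric(nb)
        for (j in seq_len(nb)) {
            if (test == "pearson") {
                eRest <- nIn - e
                stat[j] <- (obs[j] - e)^2 / e + ((nIn - obs[j]) - eRest)^2 / eRest
                p.raw[j] <- stats::pchisq(stat[j], 1, lower.tail = FALSE)
            } else {
                bt <- stats::binom.test(obs[j], nIn, 1 / nb)
                stat[j] <- unname(bt$statistic)
                p.raw[j] <- bt$p.value
            }
        }
        rows[[ch]] <- data.frame(
            chrom = ch, bin = seq_len(nb),
            startBp = (seq_len(nb) - 1) * binSizeBp + 1,
            endBp = seq_len(nb) * binSizeBp,
            observed = obs, expected = e, statistic = stat, p = p.raw,
            stringsAsFactors = FALSE)
    }
    bins <- do.call(rbind, rows)
    rownames(bins) <- NULL
    if (family == "genome") {
        bins$padj <- stats::p.adjust(bins$p, method = "BH")
    } else {
        bins$padj <- NA_real_
        for (ch in unique(bins$chrom)) {
            i <- bins$chrom == ch
            bins$padj[i] <- stats::p.adjust(bins$p[i], method = "BH")
        }
    }
    bins$class <- ifelse(bins$padj <= q,
                         ifelse(bins$observed >= bins$expected, "high", "low"),
                         "ns")
    structure(list(bins = bins, excluded = excl, binSizeBp = binSizeBp,
                   q = q, family = family, test = test),
              class = "BinScan")
}

#' Telomeric and centromeric enrichment of significant bins
#'
#' The telomeric set is the first and last five complete bins of each
#' chromosome; the centromeric set is the five bins centered on the bin
#' containing the centromere midpoint (clipped at chromosome ends).
#' Reports the proportion of low- and high-classified bins falling in
#' each set, and whether each centromere-containing bin is classified
#' low.
#'
#' @param scan a `"BinScan"`.
#' @param centromeres data.frame with `chrom`, `cenStartBp`, `cenEndBp`
#'   covering every scanned chromosome.
#' @return a list of class `"EnrichmentSummary"`.
#' @export
summarizeTeloCentro <- function(scan, centromeres) {
    stopifnot(inherits(scan, "BinScan"))
    bins <- scan$bins
    miss <- setdiff(unique(bins$chrom), centromeres$chrom)
    if (length(miss))
        stop("missing centromere for chromosome(s): ",
             paste(miss, collapse = ", "))
    bins$telo <- FALSE
    bins$centro <- FALSE
    cenLow <- list()
    for (ch in unique(bins$chrom)) {
        i <- which(bins$chrom == ch)
        nb <- length(i)
        t5 <- c(head(seq_len(nb), 5), tail(seq_len(nb), 5))
        bins$telo[i[unique(t5)]] <- TRUE
        cen <- centromeres[centromeres$chrom == ch, ]
        mid <- (cen$cenStartBp + cen$cenEndBp) / 2
        cenBin <- min(max(ceiling(mid / scan$binSizeBp), 1L), nb)
        c5 <- intersect(seq(cenBin - 2L, cenBin + 2L), seq_len(nb))
        bins$centro[i[c5]] <- TRUE
        cenLow[[ch]] <- bins$class[i[cenBin]] == "low"
    }
    prop <- function(set, cls) {
        n <- sum(bins$class == cls)
        if (n == 0) return(c(n = 0, inSet = 0, proportion = 0))
        k <- sum(bins$class == cls & set)
        c(n = n, inSet = k, proportion = k / n)
    }
    structure(list(
        telomeric = rbind(high = prop(bins$telo, "high"),
                          low = prop(bins$telo, "low")),
        centromeric = rbind(high = prop(bins$centro, "high"),
                            low = prop(bins$centro, "low")),
        centromereBinLow = unlist(cenLow),
        bins = bins),
        class = "EnrichmentSummary")
}

#' Distances between adjacent polymorphic SNPs
#'
#' Per-chromosome and genome-wide statistics of adjacent inter-SNP
#' gaps: count, mean, median, 95th percentile (nearest-rank), maximum,
#' and the number of gaps exceeding 1 Mbp.  Gaps never cross
#' chromosome boundaries.
#'
#' @param positions named list (per chromosome) of SNP bp positions, or
#'   a data.frame with `chrom` and `pos`.
#' @return a list of class `"GapStats"`: `perChromosome` (data.frame)
#'   and `overall` (named vector), all distances in bp.
#' @export
gapStatistics <- function(positions) {
    if (is.data.frame(positions))
        positions <- split(positions$pos, positions$chrom)
    p95 <- function(x) sort(x)[ceiling(0.95 * length(x))]
    summarise <- function(g)
        c(n = length(g), mean = mean(g), median = stats::median(g),
          p95 = p95(g), max = max(g), over1Mbp = sum(g > 1e6))
    gaps <- lapply(positions, function(p) diff(sort(p)))
    gaps <- gaps[lengths(gaps) > 0]
    per <- do.call(rbind, lapply(names(gaps), function(ch)
        data.frame(chrom = ch, t(summarise(gaps[[ch]])),
                   stringsAsFactors = FALSE)))
    structure(list(perChromosome = per,
                   overall = summarise(unlist(gaps, use.names = FALSE))),
              class = "GapStats")
}
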