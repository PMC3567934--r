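#' @include meiosis.R
NULL

#' Configure the introgression breeding scheme
#'
#' Parameters of the residual-heterozygous-line (RHL) introgression
#' program simulated by [runBreedingScheme()]: an F1 of two fully
#' homozygous founders is selfed to an RHL (kept heterozygous at both
#' QTL flanking markers by marker-assisted selection) and, on a longer
#' track, to a highly homozygous recurrent RIL; the RHL is then
#' (pseudo-)backcrossed to the RIL with MAS at the flanks, selfed with
#' MAS, and finally fixed as two sibling lines carrying contrasting
#' homozygous genotypes across the whole QTL region (NIL-BB and
#' NIL-HH).
#'
#' @param qtl the target [QtlRegion-class]; both flanks must lie on a
#'   genome chromosome.
#' @param selfingsToRhl selfing generations from the F1 to the RHL
#'   (default 3, i.e. an F4:5 individual).
#' @param selfingsToRil selfing generations from the F1 to the
#'   recurrent RIL (default 10, i.e. F11:13 scale).
#' @param nBackcrosses number of (pseudo-)backcrosses to the RIL
#'   (default 2).
#' @param postBcSelfings selfing generations after the last backcross;
#'   the last one fixes the contrasting homozygotes (default 2).
#' @param broodSize offspring generated per selection attempt
#'   (default 20).
#' @param retryBroods brood retry budget before a selection step fails
#'   (default 50).
#' @param seed master integer seed; per-stage streams are derived from
#'   it deterministically.
#' @return a list of class `"IntrogressionScheme"`.
#' @export
introgressionScheme <- function(qtl,
                                selfingsToRhl = 3,
                                selfingsToRil = 10,
                                nBackcrosses = 2,
                                postBcSelfings = 2,
                                broodSize = 20,
                                retryBroods = 50,
                                seed = 1) {
    stopifnot(is(qtl, "QtlRegion"),
              selfingsToRhl >= 0, selfingsToRil >= 0,
              nBackcrosses >= 0, postBcSelfings >= 1,
              broodSize >= 1, retryBroods >= 1)
    structure(list(qtl = qtl, selfingsToRhl = selfingsToRhl,
                   selfingsToRil = selfingsToRil,
                   nBackcrosses = nBackcrosses,
                   postBcSelfings = postBcSelfings,
                   broodSize = broodSize, retryBroods = retryBroods,
                   seed = seed),
              class = "IntrogressionScheme")
}

## first offspring satisfying `ok` among up to retryBroods broods of
## broodSize; `make` draws one offspring
.selectOffspring <- function(make, ok, broodSize, retryBroods, stage) {
    for (b in seq_len(retryBroods)) {
        for (i in seq_len(broodSize)) {
            cand <- make()
            if (ok(cand)) return(cand)
        }
    }
    stop(sprintf("selection failed at stage '%s' after %d broods of %d",
                 stage, retryBroods, broodSize))
}

## genotype code (founder-B dose) at the two flanking marker positions
.flankCodes <- function(ind, qtl) {
    c(.codeAtBp(ind, qtl@chrom, qtl@leftBp),
      .codeAtBp(ind, qtl@chrom, qtl@rightBp))
}

## origin of a haplotype across the whole region when unbroken there,
## NA when the region carries a crossover
.hapUniform <- function(seg, a, b) {
    cuts <- seg$cuts[seg$cuts > a & seg$cuts < b]
    probe <- c(a, b, if (length(cuts)) (c(a, cuts) + c(cuts, b)) / 2)
    o <- .segAt(seg, probe)
    if (all(o == o[1L])) o[1L] else NA_integer_
}

## TRUE when the individual is heterozygous across the whole region
## with both introgression haplotypes intact (the genotype the scheme
## is designed to carry forward; double recombinants are discarded)
.regionIntactHet <- function(ind, qtl) {
    o1 <- .hapUniform(ind$h1[[qtl@chrom]], qtl@leftBp, qtl@rightBp)
    o2 <- .hapUniform(ind$h2[[qtl@chrom]], qtl@leftBp, qtl@rightBp)
    !is.na(o1) && !is.na(o2) && o1 + o2 == 1L
}

## TRUE when the genotype is uniformly `code` across the whole region
## (checked exactly at every segment boundary inside the region)
.regionUniform <- function(ind, qtl, code) {
    cuts <- sort(unique(c(ind$h1[[qtl@chrom]]$cuts,
                          ind$h2[[qtl@chrom]]$cuts)))
    cuts <- cuts[cuts > qtl@leftBp & cuts < qtl@rightBp]
    probe <- c(qtl@leftBp, qtl@rightBp,
               if (length(cuts)) (c(qtl@leftBp, cuts) + c(cuts, qtl@rightBp)) / 2)
    all(.codeAtBp(ind, qtl@chrom, probe) == code)
}

#' Run the introgression breeding scheme
#'
#' Forward-simulates the scheme configured by [introgressionScheme()]
#' on a [GenomeModel-class] and returns the full ground truth: the NIL
#' pair, their recorded ancestors, every crossover breakpoint of the
#' retained lineage, the exact non-isogenic intervals between the pair
#' members and the true linkage drag around the QTL flanks.  The
#' recurrent RIL is re-drawn (within the retry budget) until it is
#' homozygous and non-recombinant across the QTL region, the condition
#' under which flanking-marker MAS guarantees an intact introgression.
#'
#' @param scheme an `IntrogressionScheme`.
#' @param genome a [GenomeModel-class].
#' @return a [NilPairTruth-class].
#' @examples
#' gm <- buildGenomeModel(nSnps = 2000, seed = 7)
#' q <- qtlRegion("3.05", "3", "L", 147812359, "R", 166846373)
#' tr <- runBreedingScheme(introgressionScheme(q, seed = 7), gm)
#' trueDrag(tr)$totalMbp
#' @export
runBreedingScheme <- function(scheme, genome) {
    qtl <- scheme$qtl
    if (!qtl@chrom %in% genome@chromosomes$chrom)
        stop("QTL chromosome absent from genome")
    if (qtl@rightBp > chromLengths(genome)[qtl@chrom])
        stop("QTL region exceeds chromosome length")
    brood <- scheme$broodSize
    retry <- scheme$retryBroods
    samples <- list()
    bkLog <- list()
    keep <- function(name, ind) {
        samples[[name]] <<- ind
        bk <- attr(ind, "breakpoints")
        if (!is.null(bk) && nrow(bk))
            bkLog[[name]] <<- cbind(sample = name, bk)
        ind
    }

    founderA <- keep("founderA", founderDiplotype(genome, 0L))
    founderB <- keep("founderB", founderDiplotype(genome, 1L))
    f1 <- .withSeed(deriveSeed(scheme$seed, 1L),
                    keep("F1", crossDiplotypes(founderA, founderB, genome)))

    ## recurrent RIL: single-seed descent, no marker selection, but the
    ## line must be homozygous non-recombinant across the QTL region
    ril <- .withSeed(deriveSeed(scheme$seed, 2L), {
        makeRil <- function() {
            ind <- f1
            for (g in seq_len(scheme$selfingsToRil))
                ind <- selfDiplotype(ind, genome)
            ind
        }
        .selectOffspring(makeRil,
                         function(x) .regionUniform(x, qtl, 0L) ||
                                     .regionUniform(x, qtl, 2L),
                         1L, retry * brood, "recurrent RIL")
    })
    keep("RIL", ril)

    ## RHL: selfing chain kept heterozygous at both flanking markers
    ## with an intact introgression segment between them
    hetAtFlanks <- function(x) all(.flankCodes(x, qtl) == 1L) &&
        .regionIntactHet(x, qtl)
    rhl <- .withSeed(deriveSeed(scheme$seed, 3L), {
        ind <- f1
        for (g in seq_len(scheme$selfingsToRhl))
            ind <- .selectOffspring(function() selfDiplotype(ind, genome),
                                    hetAtFlanks, brood, retry,
                                    sprintf("RHL selfing %d", g))
        ind
    })
    keep("RHL", rhl)

    ## (pseudo-)backcrosses to the RIL with MAS at the flanks
    cur <- rhl
    for (b in seq_len(scheme$nBackcrosses)) {
        cur <- .withSeed(deriveSeed(scheme$seed, 10L + b),
            .selectOffspring(function() crossDiplotypes(cur, ril, genome),
                             hetAtFlanks, brood, retry,
                             sprintf("backcross %d", b)))
        keep(sprintf("BC%d", b), cur)
    }

    ## post-backcross selfings: MAS keeps flank heterozygotes until the
    ## final generation fixes the two contrasting homozygotes
    if (scheme$postBcSelfings > 1L) {
        for (s in seq_len(scheme$postBcSelfings - 1L)) {
            cur <- .withSeed(deriveSeed(scheme$seed, 20L + s),
                .selectOffspring(function() selfDiplotype(cur, genome),
                                 hetAtFlanks, brood, retry,
                                 sprintf("selfing S%d", s)))
            keep(sprintf("S%d", s), cur)
        }
    }
    fix <- .withSeed(deriveSeed(scheme$seed, 30L), {
        nilBB <- NULL; nilHH <- NULL
        for (b in seq_len(retry)) {
            for (i in seq_len(brood)) {
                cand <- selfDiplotype(cur, genome)
                if (is.null(nilBB) && .regionUniform(cand, qtl, 0L))
                    nilBB <- cand
                else if (is.null(nilHH) && .regionUniform(cand, qtl, 2L))
                    nilHH <- cand
                if (!is.null(nilBB) && !is.null(nilHH)) break
            }
            if (!is.null(nilBB) && !is.null(nilHH)) break
        }
        if (is.null(nilBB) || is.null(nilHH))
            stop(sprintf("selection failed at stage 'fixation S%d': %s",
                         scheme$postBcSelfings,
                         "no contrasting homozygous sibling pair found"))
        list(nilBB = nilBB, nilHH = nilHH)
    })
    keep("NIL_BB", fix$nilBB)
    keep("NIL_HH", fix$nilHH)
    nilBH <- .withSeed(deriveSeed(scheme$seed, 31L),
                       crossDiplotypes(fix$nilBB, fix$nilHH, genome))
    keep("NIL_BH", nilBH)

    geno <- vapply(samples, diplotypeCodes, character(length(genome@panel@snp)),
                   genome = genome)
    rownames(geno) <- snpIds(genome@panel)

    ti <- .trueNonIsogenicIntervals(fix$nilBB, fix$nilHH, genome)
    drag <- .trueDragFromIntervals(ti, qtl)
    bkAll <- if (length(bkLog)) do.call(rbind, bkLog) else
        data.frame(sample = character(0), gamete = integer(0),
                   chrom = character(0), bp = numeric(0))
    rownames(bkAll) <- NULL
    new("NilPairTruth", genome = genome, qtl = qtl, diplotypes = samples,
        genotypes = geno, breakpoints = bkAll, trueIntervals = ti,
        trueDrag = drag, scheme = unclass(scheme)[setdiff(names(scheme), "qtl")])
}

## exact non-isogenic intervals between two diplotypes, from segments
.trueNonIsogenicIntervals <- function(a, b, genome) {
    out <- list()
    cc <- genome@chromosomes
    lab <- c("BB", "BH", "HH")
    for (i in seq_len(nrow(cc))) {
        ch <- cc$chrom[i]; L <- cc$lengthBp[i]
        cuts <- sort(unique(c(a$h1[[ch]]$cuts, a$h2[[ch]]$cuts,
                              b$h1[[ch]]$cuts, b$h2[[ch]]$cuts)))
        bounds <- c(0, cuts, L)
        mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
        ca <- .codeAtBp(a, ch, mids)
        cb <- .codeAtBp(b, ch, mids)
        contrast <- ifelse(ca != cb, paste(lab[ca + 1L], lab[cb + 1L],
                                           sep = "/"), "iso")
        r <- rle(contrast)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        ni <- which(r$values != "iso")
        if (length(ni))
            out[[ch]] <- data.frame(chrom = ch,
                                    startBp = bounds[starts[ni]],
                                    endBp = bounds[ends[ni] + 1L],
                                    contrast = r$values[ni],
                                    stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(chrom = character(0), startBp = numeric(0),
                          endBp = numeric(0), contrast = character(0)))
    x <- do.call(rbind, out)
    rownames(x) <- NULL
    x
}

## true linkage drag: extent of the QTL-concordant (BB/HH) chain of
## touching intervals beyond each flank
.trueDragFromIntervals <- function(ti, qtl) {
    x <- ti[ti$chrom == qtl@chrom & ti$contrast == "BB/HH", , drop = FALSE]
    x <- x[order(x$startBp), , drop = FALSE]
    hit <- which(x$startBp <= qtl@leftBp & x$endBp >= qtl@rightBp)
    if (!length(hit))
        return(list(upstreamMbp = NA_real_, downstreamMbp = NA_real_,
                    totalMbp = NA_real_))
    lo <- hi <- hit[1L]
    while (lo > 1L && x$endBp[lo - 1L] >= x$startBp[lo]) lo <- lo - 1L
    while (hi < nrow(x) && x$startBp[hi + 1L] <= x$endBp[hi]) hi <- hi + 1L
    up <- max(0, qtl@leftBp - x$startBp[lo]) / 1e6
    down <- max(0, x$endBp[hi] - qtl@rightBp) / 1e6
    list(upstreamMbp = up, downstreamMbp = down, totalMbp = up + down)
}

#' @rdname accessors
#' @export
setMethod("trueIntervals", "NilPairTruth", function(x) x@trueIntervals)
#' @rdname accessors
#' @export
setMethod("trueGenotypes", "NilPairTruth", function(x) x@genotypes)
#' @rdname accessors
#' @export
setMethod("trueDrag", "NilPairTruth", function(x) x@trueDrag)
#' @rdname accessors
#' @export
setMethod("panel", "NilPairTruth", function(x) x@genome@panel)

setMethod("show", "NilPairTruth", function(object) {
    ti <- object@trueIntervals
    cat(sprintf(paste0("NilPairTruth: QTL %s, %d recorded individuals, ",
                       "%d true non-isogenic intervals (%.1f Mbp)\n"),
                object@qtl@name, length(object@diplotypes), nrow(ti),
                sum(ti$endBp - ti$startBp) / 1e6))
})
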