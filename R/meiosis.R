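#' @include genome-model.R
NULL

## Haplotypes are stored as founder-origin segments, not per-SNP
## vectors: per chromosome a list(cuts, origin) where `cuts` are the
## interior crossover cut points (bp, strictly increasing) and `origin`
## the founder origin (0 = founder A, 1 = founder B) of the
## length(cuts)+1 segments they delimit.  A diplotype is list(h1, h2)
## of whole-genome haplotypes (named lists over chromosomes).  Segment
## arithmetic keeps meiosis O(#breakpoints) and makes true non-isogenic
## intervals exact in bp.

.segNew <- function(origin) list(cuts = numeric(0), origin = as.integer(origin))

.segSimplify <- function(seg) {
    if (length(seg$cuts) == 0L) return(seg)
    keep <- seg$origin[-1L] != seg$origin[-length(seg$origin)]
    list(cuts = seg$cuts[keep], origin = seg$origin[c(TRUE, keep)])
}

## origin of a haplotype chromosome at positions `pos` (vectorized)
.segAt <- function(seg, pos) {
    seg$origin[findInterval(pos, seg$cuts) + 1L]
}

## slice of seg restricted to the open-ended window (a, b]; returns
## cuts strictly inside plus origins across the window
.segSlice <- function(seg, a, b) {
    inside <- seg$cuts > a & seg$cuts < b
    cuts <- seg$cuts[inside]
    first <- findInterval(a, seg$cuts) + 1L
    list(cuts = cuts,
         origin = seg$origin[seq(first, first + length(cuts))])
}

## recombine two chromosome haplotypes at breakpoints `bks` (sorted bp),
## starting from h1 or h2 according to `start` (1 or 2)
.segRecombine <- function(s1, s2, bks, start, L) {
    if (length(bks) == 0L)
        return(if (start == 1L) s1 else s2)
    bounds <- c(0, bks, L + 1)
    cuts <- numeric(0)
    origin <- integer(0)
    src <- start
    for (j in seq_len(length(bounds) - 1L)) {
        piece <- .segSlice(if (src == 1L) s1 else s2,
                           bounds[j], bounds[j + 1L])
        cuts <- c(cuts, piece$cuts, bounds[j + 1L])
        origin <- c(origin, piece$origin)
        src <- 3L - src
    }
    cuts <- cuts[-length(cuts)]          # last bound is the chromosome end
    .segSimplify(list(cuts = cuts, origin = origin))
}

#' Founder and offspring diplotypes
#'
#' `founderDiplotype()` builds a fully homozygous individual of the
#' given founder origin (0 = founder A, 1 = founder B).
#' `crossDiplotypes()` produces one offspring of two parents (one
#' gamete each); `selfDiplotype()` is the selfing shorthand.  Crossover
#' counts per chromosome are Poisson with mean equal to the map length
#' in Morgans and positions are uniform on the genetic map (Haldane
#' model, no interference).
#'
#' @param genome a [GenomeModel-class].
#' @param origin founder origin, 0 or 1.
#' @return a diplotype (internal segment representation) accepted by
#'   [simulateMeiosis()], [diplotypeCodes()] and the breeding scheme.
#' @export
founderDiplotype <- function(genome, origin) {
    h <- lapply(genome@chromosomes$chrom, function(ch) .segNew(origin))
    names(h) <- genome@chromosomes$chrom
    list(h1 = h, h2 = h)
}

#' Simulate one meiosis
#'
#' Draws a single gamete from a parent diplotype: per chromosome the
#' crossover count is Poisson(map length in Morgans), crossover
#' positions are uniform in genetic-map units (mapped back to bp on the
#' piecewise-linear map), and the starting chromatid is chosen at
#' random.  Uses the current R random stream; seed at the call site.
#'
#' @param parent a diplotype.
#' @param genome a [GenomeModel-class].
#' @return a haplotype (named list over chromosomes) with attribute
#'   `"breakpoints"`: a data.frame of `chrom`, `bp` crossover positions.
#' @examples
#' gm <- buildGenomeModel(nSnps = 100, seed = 1)
#' f1 <- crossDiplotypes(founderDiplotype(gm, 0), founderDiplotype(gm, 1), gm)
#' set.seed(42)
#' g <- simulateMeiosis(f1, gm)
#' @export
simulateMeiosis <- function(parent, genome) {
    chroms <- genome@chromosomes$chrom
    bkAll <- vector("list", length(chroms))
    gam <- vector("list", length(chroms))
    names(gam) <- chroms
    for (i in seq_along(chroms)) {
        ch <- chroms[i]
        Lcm <- genome@chromosomes$mapLengthCm[i]
        L <- genome@chromosomes$lengthBp[i]
        nco <- stats::rpois(1L, Lcm / 100)
        bks <- if (nco > 0)
            sort(cmToBp(genome, ch, stats::runif(nco, 0, Lcm))) else numeric(0)
        start <- sample.int(2L, 1L)
        gam[[i]] <- .segRecombine(parent$h1[[ch]], parent$h2[[ch]],
                                  bks, start, L)
        bkAll[[i]] <- bks
    }
    bp <- unlist(bkAll, use.names = FALSE)
    attr(gam, "breakpoints") <- data.frame(
        chrom = rep(chroms, lengths(bkAll)),
        bp = if (is.null(bp)) numeric(0) else bp,
        stringsAsFactors = FALSE)
    gam
}

#' @rdname founderDiplotype
#' @param mother,father parent diplotypes.
#' @export
crossDiplotypes <- function(mother, father, genome) {
    g1 <- simulateMeiosis(mother, genome)
    g2 <- simulateMeiosis(father, genome)
    out <- list(h1 = g1, h2 = g2)
    b1 <- attr(g1, "breakpoints")
    b2 <- attr(g2, "breakpoints")
    bk <- rbind(b1, b2)
    bk$gamete <- rep(c(1L, 2L), c(nrow(b1), nrow(b2)))
    attr(out, "breakpoints") <- bk
    out
}

#' @rdname founderDiplotype
#' @param individual a diplotype to self.
#' @export
selfDiplotype <- function(individual, genome) {
    crossDiplotypes(individual, individual, genome)
}

#' True genotype codes of a diplotype at panel SNPs
#'
#' @param individual a diplotype.
#' @param genome a [GenomeModel-class].
#' @param snps optional subset of SNP ids (default: the whole panel).
#'   Unmapped panel SNPs are scored from founder origin 0/1 directly
#'   (they still have founder alleles even without a map position).
#' @return character vector of `"BB"`, `"BH"`, `"HH"` codes named by
#'   SNP id.
#' @export
diplotypeCodes <- function(individual, genome, snps = NULL) {
    pan <- genome@panel
    idx <- if (is.null(snps)) seq_along(pan@snp) else match(snps, pan@snp)
    code <- integer(length(idx))
    mapped <- pan@mapped[idx]
    for (ch in unique(pan@chrom[idx][mapped])) {
        sel <- which(pan@chrom[idx] == ch & mapped)
        p <- pan@pos[idx][sel]
        code[sel] <- .segAt(individual$h1[[ch]], p) +
            .segAt(individual$h2[[ch]], p)
    }
    ## unmapped SNPs segregate with an arbitrary fixed origin of 0: the
    ## chip still assays them, but they carry no positional information
    code[!mapped] <- individual$h1[[1L]]$origin[1L] +
        individual$h2[[1L]]$origin[1L]
    stats::setNames(c("BB", "BH", "HH")[code + 1L], pan@snp[idx])
}

## genotype code (0/1/2 founder-B dose) at arbitrary bp positions
.codeAtBp <- function(individual, chrom, pos) {
    .segAt(individual$h1[[chrom]], pos) + .segAt(individual$h2[[chrom]], pos)
}

#' Genotype code of a diplotype at arbitrary positions
#'
#' Founder-B allele dose (0, 1 or 2) at given bp positions, e.g. at
#' flanking-marker positions that are not panel SNPs.
#'
#' @param individual a diplotype.
#' @param chrom chromosome name.
#' @param pos bp position(s).
#' @return integer vector of founder-B doses.
#' @export
genotypeCodeAt <- function(individual, chrom, pos) {
    .codeAtBp(individual, chrom, pos)
}

#' Heterozygous genome fraction of a diplotype
#'
#' Physical fraction of the genome (optionally restricted to some
#' chromosomes) where the two haplotypes carry different founder
#' origins.  Exact, computed from segments.
#'
#' @param individual a diplotype.
#' @param genome a [GenomeModel-class].
#' @param chroms chromosomes to include (default all).
#' @return scalar fraction in \[0, 1\].
#' @export
heterozygousFraction <- function(individual, genome, chroms = NULL) {
    cc <- genome@chromosomes
    if (!is.null(chroms)) cc <- cc[cc$chrom %in% chroms, , drop = FALSE]
    hetBp <- 0
    for (i in seq_len(nrow(cc))) {
        ch <- cc$chrom[i]
        L <- cc$lengthBp[i]
        s1 <- individual$h1[[ch]]; s2 <- individual$h2[[ch]]
        cuts <- sort(unique(c(s1$cuts, s2$cuts)))
        bounds <- c(0, cuts, L)
        mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
        het <- .segAt(s1, mids) != .segAt(s2, mids)
        hetBp <- hetBp + sum((bounds[-1L] - bounds[-length(bounds)])[het])
    }
    hetBp / sum(cc$lengthBp)
}
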