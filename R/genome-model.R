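#' @include snp-panel.R
NULL

#' Derive a per-stage seed from one master seed
#'
#' Every stage of a run (panel placement, each breeding step, chip
#' noise) draws from its own stream derived deterministically from one
#' master seed, so stages are independently reproducible.  Knuth
#' multiplicative hash folded into 31 bits.
#'
#' @param master master integer seed.
#' @param stage integer stage index.
#' @return a positive integer seed below 2^31.
#' @export
deriveSeed <- function(master, stage) {
    stopifnot(is.numeric(master), length(master) == 1L)
    h <- (as.double(master) %% 2147483647) * 2654435761 + 97 * stage
    as.integer(h %% 2147483629) + 1L
}

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Default maize chromosome table
#'
#' Physical lengths of the ten maize chromosomes (RefGen_v1 scale,
#' 2,046.5 Mbp total) with centromere intervals.  The chromosome 5
#' centromere is the annotated *cent5* interval (101.3-108.4 Mbp); the
#' other centromere intervals are synthetic representative placements
#' (approximate midpoint positions, 3.5 Mbp wide) provided so that
#' centromeric-enrichment summaries have a complete table to work from.
#'
#' @return data.frame with columns `chrom`, `lengthBp`, `cenStartBp`,
#'   `cenEndBp`.
#' @export
maizeChromosomes <- function() {
    lenMbp <- c(300.2, 234.8, 230.6, 247.1, 216.9,
                169.3, 171.0, 174.5, 152.4, 149.7)
    cenMid <- c(135, 95, 99, 107, NA, 52, 60, 51, 72, 52)
    cs <- ifelse(is.na(cenMid), 101.3, cenMid - 1.75) * 1e6
    ce <- ifelse(is.na(cenMid), 108.4, cenMid + 1.75) * 1e6
    data.frame(chrom = as.character(1:10), lengthBp = lenMbp * 1e6,
               cenStartBp = cs, cenEndBp = ce, stringsAsFactors = FALSE)
}

#' Build a genome model for simulation
#'
#' Creates chromosomes, a linear genetic map, a SNP panel and per-SNP
#' founder alleles.  Marker density profiles: `"telomere"` draws
#' positions from a U-shaped Beta(1/2, 1/2) density (markers enriched
#' towards chromosome ends, as on gene-targeted maize chips),
#' `"random"` draws them uniformly, and `"uniform"` spaces them evenly
#' and deterministically along each chromosome.
#'
#' @param chromosomes data.frame with `chrom`, `lengthBp`, `cenStartBp`,
#'   `cenEndBp` (default [maizeChromosomes()]).
#' @param nSnps total number of panel SNPs (default 50000).
#' @param polymorphicFraction fraction of SNPs polymorphic between the
#'   two founders (default 0.35).
#' @param density marker density profile, see above (default
#'   `"telomere"`).
#' @param cmPerMbp genetic map rate in cM per Mbp, a single value or one
#'   per chromosome (default 0.7, about 1,430 cM genome-wide).
#' @param unmappedSnps number of extra unmapped SNPs appended to the
#'   panel (default 0).
#' @param seed optional integer seed for panel placement and allele
#'   assignment.
#' @return a [GenomeModel-class].
#' @examples
#' gm <- buildGenomeModel(nSnps = 1000, seed = 1)
#' sum(chromLengths(gm)) / 1e6   # 2046.5
#' @export
buildGenomeModel <- function(chromosomes = maizeChromosomes(),
                             nSnps = 50000,
                             polymorphicFraction = 0.35,
                             density = c("telomere", "random", "uniform"),
                             cmPerMbp = 0.7,
                             unmappedSnps = 0,
                             seed = NULL) {
    density <- match.arg(density)
    if (nSnps <= 0 || any(chromosomes$lengthBp <= 0))
        stop("chromosome lengths and SNP count must be positive")
    if (polymorphicFraction <= 0 || polymorphicFraction > 1)
        stop("polymorphicFraction must be in (0, 1]")
    k <- nrow(chromosomes)
    cmLen <- rep_len(cmPerMbp, k) * chromosomes$lengthBp / 1e6
    chromosomes$mapLengthCm <- cmLen
    .withSeed(seed, {
        ## per-chromosome SNP counts proportional to physical length
        nPer <- round(nSnps * chromosomes$lengthBp / sum(chromosomes$lengthBp))
        nPer[1L] <- nPer[1L] + (nSnps - sum(nPer))
        chrom <- rep(chromosomes$chrom, nPer)
        pos <- unlist(lapply(seq_len(k), function(i) {
            L <- chromosomes$lengthBp[i]
            n <- nPer[i]
            p <- switch(density,
                uniform = round(seq(1, L, length.out = n)),
                random = ceiling(runif(n) * L),
                telomere = ceiling(stats::rbeta(n, 0.5, 0.5) * L))
            p <- pmin(pmax(p, 1), L)
            while (anyDuplicated(p)) {
                d <- duplicated(p)
                p[d] <- pmin(pmax(p[d] + sample(c(-1, 1), sum(d), TRUE) *
                                  sample.int(1000L, sum(d), TRUE), 1), L)
            }
            sort(p)
        }), use.names = FALSE)
        if (unmappedSnps > 0) {
            chrom <- c(chrom, rep(.UNKNOWN_CHROM, unmappedSnps))
            pos <- c(pos, rep(NA_real_, unmappedSnps))
        }
        nTot <- length(chrom)
        ids <- sprintf("SNP%06d", seq_len(nTot))
        pan <- SnpPanel(ids, chrom, pos)
        ## chip design alleles; founder B differs only at polymorphic SNPs
        bases <- c("A", "C", "G", "T")
        refIdx <- sample.int(4L, nTot, replace = TRUE)
        altIdx <- ((refIdx - 1L + sample.int(3L, nTot, replace = TRUE)) %% 4L) + 1L
        poly <- seq_len(nTot) %in% sample.int(nTot, round(nTot * polymorphicFraction))
        alleleA <- bases[refIdx]
        alleleB <- ifelse(poly, bases[altIdx], alleleA)
        o <- match(snpIds(pan), ids)
        gmap <- lapply(seq_len(k), function(i)
            data.frame(bp = c(1, chromosomes$lengthBp[i]),
                       cm = c(0, cmLen[i])))
        names(gmap) <- chromosomes$chrom
        new("GenomeModel", chromosomes = chromosomes, geneticMap = gmap,
            panel = pan, alleleA = alleleA[o], alleleB = alleleB[o])
    })
}

#' @rdname accessors
#' @export
setMethod("panel", "GenomeModel", function(x) x@panel)

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x)
    stats::setNames(x@chromosomes$lengthBp, x@chromosomes$chrom))

#' @rdname accessors
#' @export
setMethod("parentAlleles", "GenomeModel", function(x)
    data.frame(snp = x@panel@snp, alleleA = x@alleleA, alleleB = x@alleleB,
               stringsAsFactors = FALSE))

#' @describeIn buildGenomeModel logical vector: is each panel SNP truly
#'   polymorphic between the founders?
#' @param genome a [GenomeModel-class].
#' @export
isPolymorphicTruth <- function(genome) genome@alleleA != genome@alleleB

setMethod("show", "GenomeModel", function(object) {
    cat(sprintf(paste0("GenomeModel: %d chromosomes, %.1f Mbp, ",
                       "%.0f cM, %d panel SNPs (%.1f%% polymorphic)\n"),
                nrow(object@chromosomes),
                sum(object@chromosomes$lengthBp) / 1e6,
                sum(object@chromosomes$mapLengthCm),
                length(object@panel@snp),
                100 * mean(isPolymorphicTruth(object))))
})

## bp <-> cM conversion on the piecewise-linear map
bpToCm <- function(genome, chrom, bp) {
    gm <- genome@geneticMap[[chrom]]
    stats::approx(gm$bp, gm$cm, xout = bp, rule = 2)$y
}

cmToBp <- function(genome, chrom, cm) {
    gm <- genome@geneticMap[[chrom]]
    stats::approx(gm$cm, gm$bp, xout = cm, rule = 2, ties = "ordered")$y
}
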