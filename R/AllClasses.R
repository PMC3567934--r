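#' @import methods
NULL

## Call-token grammar shared by readers, validity methods and the chip
## emulator.  Calls are unordered biallelic pairs; chips are unphased.
.FAIL_TOKEN <- "-/-"
.CALL_REGEX <- "^([ACGT]/[ACGT]|-/-)$"
.UNKNOWN_CHROM <- "UNKNOWN"
.CODES <- c("BB", "HH", "BH", "FAIL")

#' SnpPanel: the ordered marker map
#'
#' Holds one row per assayed SNP: identifier, chromosome (or `"UNKNOWN"`),
#' 1-based bp position on the reference assembly, and a mapped flag.
#' Mapped SNPs are kept sorted by (chromosome, position); unmapped SNPs
#' (unknown chromosome or missing position) are retained at the end so
#' that quality filtering can count and remove them explicitly.
#'
#' @slot snp character vector of unique SNP identifiers.
#' @slot chrom character vector of chromosome names (`"UNKNOWN"` allowed).
#' @slot pos numeric vector of 1-based bp positions (`NA` for unmapped).
#' @slot mapped logical vector; `FALSE` for unknown chromosome/position.
#'
#' @exportClass SnpPanel
setClass("SnpPanel",
    representation(snp = "character", chrom = "character",
                   pos = "numeric", mapped = "logical"))

setValidity("SnpPanel", function(object) {
    msg <- character()
    n <- length(object@snp)
    if (length(object@chrom) != n || length(object@pos) != n ||
        length(object@mapped) != n)
        msg <- c(msg, "slot lengths differ")
    if (anyDuplicated(object@snp))
        msg <- c(msg, "duplicate SNP identifiers")
    if (any(object@mapped & (is.na(object@pos) | object@pos < 1)))
        msg <- c(msg, "mapped SNPs must have positions >= 1")
    if (any(object@mapped & object@chrom == .UNKNOWN_CHROM))
        msg <- c(msg, "mapped SNPs cannot sit on the unknown chromosome")
    m <- which(object@mapped)
    if (length(m) > 1L) {
        o <- order(object@chrom[m], object@pos[m])
        if (!identical(o, seq_along(m)))
            msg <- c(msg, "mapped SNPs must be sorted by (chromosome, position)")
    }
    if (length(msg)) msg else TRUE
})

#' GenotypeCalls: raw biallelic calls per sample per SNP
#'
#' A character matrix of unordered allele-pair tokens (`"A/G"`, `"C/C"`,
#' ...) or the failure token `"-/-"`, with SNPs on rows (aligned to the
#' panel) and samples on columns.
#'
#' @slot calls character matrix, `length(panel)` rows, one column per sample.
#' @slot panel the [SnpPanel-class] the rows are aligned to.
#'
#' @exportClass GenotypeCalls
setClass("GenotypeCalls",
    representation(calls = "matrix", panel = "SnpPanel"))

setValidity("GenotypeCalls", function(object) {
    msg <- character()
    if (!is.character(object@calls))
        msg <- c(msg, "calls must be a character matrix")
    if (nrow(object@calls) != length(object@panel@snp))
        msg <- c(msg, "call matrix rows must match panel size")
    if (is.null(colnames(object@calls)))
        msg <- c(msg, "call matrix must have sample names as colnames")
    else if (anyDuplicated(colnames(object@calls)))
        msg <- c(msg, "duplicate sample names")
    if (is.character(object@calls)) {
        bad <- !grepl(.CALL_REGEX, object@calls)
        if (any(bad))
            msg <- c(msg, sprintf("%d invalid call tokens (first: '%s')",
                                  sum(bad), object@calls[which(bad)[1L]]))
    }
    if (length(msg)) msg else TRUE
})

#' EncodedMatrix: parent-of-origin codes at polymorphic SNPs
#'
#' Samples x polymorphic SNPs coded `BB` (parent-A homozygote), `HH`
#' (parent-B homozygote), `BH` (heterozygote) or `FAIL`.  This is the
#' substrate of all inheritance and isogenicity analysis.
#'
#' @slot codes character matrix (SNP rows, sample columns) over
#'   `BB/HH/BH/FAIL`.
#' @slot panel the polymorphic subset of the retained [SnpPanel-class].
#' @slot alleleA,alleleB per-SNP parental alleles the codes derive from.
#'
#' @exportClass EncodedMatrix
setClass("EncodedMatrix",
    representation(codes = "matrix", panel = "SnpPanel",
                   alleleA = "character", alleleB = "character"))

setValidity("EncodedMatrix", function(object) {
    msg <- character()
    if (nrow(object@codes) != length(object@panel@snp))
        msg <- c(msg, "code matrix rows must match panel size")
    if (!all(object@codes %in% .CODES))
        msg <- c(msg, "codes must be BB/HH/BH/FAIL")
    if (length(object@alleleA) != length(object@panel@snp) ||
        length(object@alleleB) != length(object@panel@snp))
        msg <- c(msg, "allele slots must match panel size")
    if (any(object@alleleA == object@alleleB))
        msg <- c(msg, "encoded SNPs must be polymorphic (alleleA != alleleB)")
    if (length(msg)) msg else TRUE
})

#' QtlRegion: a target introgression region
#'
#' The interval on the reference assembly between the left and right
#' flanking markers used for marker-assisted introgression.
#'
#' @slot name region name (e.g. `"3.05"`).
#' @slot chrom chromosome carrying the region.
#' @slot leftMarker,rightMarker flanking marker names.
#' @slot leftBp,rightBp flanking marker 1-based bp positions.
#'
#' @exportClass QtlRegion
setClass("QtlRegion",
    representation(name = "character", chrom = "character",
                   leftMarker = "character", rightMarker = "character",
                   leftBp = "numeric", rightBp = "numeric"))

setValidity("QtlRegion", function(object) {
    msg <- character()
    if (object@leftBp >= object@rightBp)
        msg <- c(msg, "left flank must be strictly left of right flank")
    if (object@leftBp < 1)
        msg <- c(msg, "positions must be >= 1")
    if (length(msg)) msg else TRUE
})

#' GenomeModel: chromosomes, genetic map and SNP panel for simulation
#'
#' Describes the simulated genome: physical chromosome lengths with
#' centromere intervals, a per-chromosome monotone piecewise-linear
#' bp-to-centiMorgan map, the SNP panel placed on it, and the chip
#' design alleles at each SNP.  Founder A carries `alleleA`, founder B
#' `alleleB`; the two are equal at monomorphic SNPs.
#'
#' @slot chromosomes data.frame with columns `chrom`, `lengthBp`,
#'   `cenStartBp`, `cenEndBp`, `mapLengthCm`.
#' @slot geneticMap named list (per chromosome) of data.frames with
#'   columns `bp`, `cm`, non-decreasing in both.
#' @slot panel the [SnpPanel-class] generated on this genome.
#' @slot alleleA,alleleB per-SNP founder alleles (single letters).
#'
#' @exportClass GenomeModel
setClass("GenomeModel",
    representation(chromosomes = "data.frame", geneticMap = "list",
                   panel = "SnpPanel", alleleA = "character",
                   alleleB = "character"))

setValidity("GenomeModel", function(object) {
    msg <- character()
    cc <- object@chromosomes
    need <- c("chrom", "lengthBp", "cenStartBp", "cenEndBp", "mapLengthCm")
    if (!all(need %in% names(cc)))
        return("chromosomes must have chrom/lengthBp/cenStartBp/cenEndBp/mapLengthCm")
    if (any(cc$lengthBp <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (any(cc$cenStartBp < 1 | cc$cenEndBp > cc$lengthBp |
            cc$cenStartBp > cc$cenEndBp))
        msg <- c(msg, "centromere interval must lie within its chromosome")
    if (!setequal(names(object@geneticMap), cc$chrom))
        msg <- c(msg, "genetic map must cover exactly the chromosomes")
    for (ch in names(object@geneticMap)) {
        gm <- object@geneticMap[[ch]]
        if (is.unsorted(gm$bp) || is.unsorted(gm$cm))
            msg <- c(msg, sprintf("genetic map for %s must be non-decreasing", ch))
    }
    pn <- object@panel
    mapped <- which(pn@mapped)
    if (length(mapped)) {
        len <- cc$lengthBp[match(pn@chrom[mapped], cc$chrom)]
        if (anyNA(len))
            msg <- c(msg, "panel chromosomes absent from genome")
        else if (any(pn@pos[mapped] > len))
            msg <- c(msg, "panel positions exceed chromosome length")
    }
    n <- length(pn@snp)
    if (length(object@alleleA) != n || length(object@alleleB) != n)
        msg <- c(msg, "allele slots must match panel size")
    if (length(msg)) msg else TRUE
})

#' NilPairTruth: simulator output with known ground truth
#'
#' The result of forward-simulating the introgression scheme: true
#' genotypes of the NIL pair and all recorded ancestors at every panel
#' SNP, the crossover breakpoints of every meiosis, the true
#' non-isogenic intervals between the pair members (exact bp, derived
#' from the underlying founder-origin segments, not from markers), and
#' the true linkage-drag extents around the QTL flanks.
#'
#' @slot genome the [GenomeModel-class] simulated on.
#' @slot qtl the introgressed [QtlRegion-class].
#' @slot diplotypes named list of diplotypes (internal segment
#'   representation) for all recorded individuals.
#' @slot genotypes character matrix of true origin codes (`BB/BH/HH`) at
#'   every panel SNP (rows) for every recorded sample (columns).
#' @slot breakpoints data.frame of crossover positions: `sample`,
#'   `meiosis`, `chrom`, `bp`.
#' @slot trueIntervals data.frame of non-isogenic intervals between the
#'   final pair: `chrom`, `startBp`, `endBp`, `contrast`
#'   (code in NIL-BB / code in NIL-HH).
#' @slot trueDrag list with `upstreamMbp`, `downstreamMbp`, `totalMbp`.
#' @slot scheme list of the scheme parameters used.
#'
#' @exportClass NilPairTruth
setClass("NilPairTruth",
    representation(genome = "GenomeModel", qtl = "QtlRegion",
                   diplotypes = "list", genotypes = "matrix",
                   breakpoints = "data.frame", trueIntervals = "data.frame",
                   trueDrag = "list", scheme = "list"))

setValidity("NilPairTruth", function(object) {
    msg <- character()
    ti <- object@trueIntervals
    if (nrow(ti)) {
        for (ch in unique(ti$chrom)) {
            x <- ti[ti$chrom == ch, , drop = FALSE]
            x <- x[order(x$startBp), , drop = FALSE]
            if (nrow(x) > 1L && any(x$startBp[-1L] < x$endBp[-nrow(x)]))
                msg <- c(msg, sprintf("true intervals overlap on %s", ch))
        }
    }
    q <- object@qtl
    hit <- ti$chrom == q@chrom & ti$startBp <= q@leftBp &
        ti$endBp >= q@rightBp & ti$contrast == "BB/HH"
    if (!any(hit))
        msg <- c(msg, "QTL region must be contained in a BB/HH-contrast interval")
    if (length(msg)) msg else TRUE
})
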