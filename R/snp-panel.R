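#' @include AllGenerics.R
NULL

#' Construct a SnpPanel
#'
#' Rows with chromosome `"UNKNOWN"` or missing position get
#' `mapped = FALSE`.  Mapped SNPs are sorted by (chromosome, position);
#' unmapped SNPs are kept at the end in input order.
#'
#' @param snp character vector of unique SNP identifiers.
#' @param chrom chromosome names; `"UNKNOWN"` or `NA` marks unmapped.
#' @param pos 1-based bp positions; `NA` marks unmapped.
#' @return a [SnpPanel-class].
#' @examples
#' SnpPanel(c("s1", "s2"), c("1", "1"), c(100, 10))
#' @export
SnpPanel <- function(snp, chrom, pos) {
    snp <- as.character(snp)
    chrom <- as.character(chrom)
    chrom[is.na(chrom)] <- .UNKNOWN_CHROM
    pos <- suppressWarnings(as.numeric(pos))
    mapped <- !is.na(pos) & chrom != .UNKNOWN_CHROM
    pos[!mapped] <- NA_real_
    o <- c(which(mapped)[order(chrom[mapped], pos[mapped])], which(!mapped))
    new("SnpPanel", snp = snp[o], chrom = chrom[o], pos = pos[o],
        mapped = mapped[o])
}

#' @rdname accessors
#' @export
setMethod("snpIds", "SnpPanel", function(x) x@snp)
#' @rdname accessors
#' @export
setMethod("snpChrom", "SnpPanel", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("snpPos", "SnpPanel", function(x) x@pos)
#' @rdname accessors
#' @export
setMethod("isMapped", "SnpPanel", function(x) x@mapped)

#' @describeIn SnpPanel number of SNPs.
#' @param x a `SnpPanel`.
#' @export
setMethod("length", "SnpPanel", function(x) length(x@snp))

#' @describeIn SnpPanel subset by index, id or logical mask (keeps order).
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SnpPanel", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@snp)
    new("SnpPanel", snp = x@snp[i], chrom = x@chrom[i], pos = x@pos[i],
        mapped = x@mapped[i])
})

setMethod("show", "SnpPanel", function(object) {
    cat(sprintf("SnpPanel with %d SNPs (%d mapped) on %d chromosome(s)\n",
                length(object@snp), sum(object@mapped),
                length(unique(object@chrom[object@mapped]))))
})

#' Construct a GenotypeCalls object
#'
#' @param calls character matrix of call tokens (`"A/G"`, `"-/-"`, ...)
#'   with one row per panel SNP (rownames, if present, must match panel
#'   ids) and one named column per sample.
#' @param panel the [SnpPanel-class] rows align to.
#' @return a [GenotypeCalls-class].
#' @export
GenotypeCalls <- function(calls, panel) {
    calls <- as.matrix(calls)
    ## canonicalize unordered pairs ("G/A" -> "A/G") so that token
    ## equality means genotype equality throughout
    a1 <- substr(calls, 1L, 1L)
    a2 <- substr(calls, 3L, 3L)
    swap <- which(a1 > a2)
    if (length(swap))
        calls[swap] <- paste(a2[swap], a1[swap], sep = "/")
    if (!is.null(rownames(calls))) {
        if (!setequal(rownames(calls), snpIds(panel)))
            stop("call matrix rownames do not match panel SNP ids")
        calls <- calls[match(snpIds(panel), rownames(calls)), , drop = FALSE]
    } else {
        rownames(calls) <- snpIds(panel)
    }
    new("GenotypeCalls", calls = calls, panel = panel)
}

#' @rdname accessors
#' @export
setMethod("calls", "GenotypeCalls", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("panel", "GenotypeCalls", function(x) x@panel)
#' @rdname accessors
#' @export
setMethod("sampleNames", "GenotypeCalls", function(x) colnames(x@calls))

setMethod("show", "GenotypeCalls", function(object) {
    fr <- mean(object@calls == .FAIL_TOKEN)
    cat(sprintf("GenotypeCalls: %d SNPs x %d samples (%.2f%% failed calls)\n",
                nrow(object@calls), ncol(object@calls), 100 * fr))
    cat("samples:", paste(colnames(object@calls), collapse = ", "), "\n")
})

#' @describeIn GenotypeCalls subset SNPs (i) and/or samples (j).
#' @param x a `GenotypeCalls`.
#' @param i SNP index/id/mask.
#' @param j sample index/name/mask.
#' @param drop,... ignored.
#' @export
setMethod("[", "GenotypeCalls", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@calls))
    if (is.character(i)) i <- match(i, snpIds(x@panel))
    if (missing(j)) j <- seq_len(ncol(x@calls))
    new("GenotypeCalls", calls = x@calls[i, j, drop = FALSE],
        panel = x@panel[i])
})

#' @rdname accessors
#' @export
setMethod("codes", "EncodedMatrix", function(x) x@codes)
#' @rdname accessors
#' @export
setMethod("panel", "EncodedMatrix", function(x) x@panel)
#' @rdname accessors
#' @export
setMethod("sampleNames", "EncodedMatrix", function(x) colnames(x@codes))
#' @rdname accessors
#' @export
setMethod("parentAlleles", "EncodedMatrix", function(x)
    data.frame(snp = x@panel@snp, alleleA = x@alleleA, alleleB = x@alleleB,
               stringsAsFactors = FALSE))

setMethod("show", "EncodedMatrix", function(object) {
    cat(sprintf("EncodedMatrix: %d polymorphic SNPs x %d samples\n",
                nrow(object@codes), ncol(object@codes)))
    tab <- table(factor(object@codes, levels = .CODES))
    cat(sprintf("codes: BB %d, HH %d, BH %d, FAIL %d\n",
                tab["BB"], tab["HH"], tab["BH"], tab["FAIL"]))
})

#' @describeIn EncodedMatrix subset SNPs (i) and/or samples (j).
#' @param x an `EncodedMatrix`.
#' @param i SNP index/id/mask.
#' @param j sample index/name/mask.
#' @param drop,... ignored.
#' @export
setMethod("[", "EncodedMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@codes))
    if (is.character(i)) i <- match(i, snpIds(x@panel))
    if (missing(j)) j <- seq_len(ncol(x@codes))
    new("EncodedMatrix", codes = x@codes[i, j, drop = FALSE],
        panel = x@panel[i], alleleA = x@alleleA[i], alleleB = x@alleleB[i])
})

#' Construct a QtlRegion
#'
#' @param name region name (e.g. `"3.05"`).
#' @param chrom chromosome name.
#' @param leftMarker,rightMarker flanking marker names.
#' @param leftBp,rightBp flanking marker positions (1-based bp).
#' @return a [QtlRegion-class].
#' @examples
#' qtlRegion("3.05", "3", "bnlg1505", 147812359, "dupssr23", 166846373)
#' @export
qtlRegion <- function(name, chrom, leftMarker, leftBp, rightMarker, rightBp) {
    new("QtlRegion", name = as.character(name), chrom = as.character(chrom),
        leftMarker = as.character(leftMarker),
        rightMarker = as.character(rightMarker),
        leftBp = as.numeric(leftBp), rightBp = as.numeric(rightBp))
}

#' @describeIn qtlRegion interval length in bp (right - left).
#' @param region a [QtlRegion-class].
#' @export
regionLengthBp <- function(region) region@rightBp - region@leftBp

setMethod("show", "QtlRegion", function(object) {
    cat(sprintf("QtlRegion %s: chr%s %s (%s) - %s (%s), %.2f Mbp\n",
                object@name, object@chrom, object@leftMarker,
                format(object@leftBp, big.mark = ","), object@rightMarker,
                format(object@rightBp, big.mark = ","),
                regionLengthBp(object) / 1e6))
})
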