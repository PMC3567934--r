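#' @include isogenicity.R
NULL

#' Read a genotype table (TSV dialect)
#'
#' Expected layout: a header row with `snp`, `chrom`, `pos` followed by
#' one column per sample; cells are unordered allele pairs (`A/G`) or
#' the failure token `-/-`.  Rows with chromosome `UNKNOWN` or an empty
#' position are kept with the mapped flag unset.
#'
#' @param file path to a tab-separated genotype table.
#' @return a [GenotypeCalls-class] (its [SnpPanel-class] is sorted by
#'   chromosome and position, unmapped SNPs last).
#' @export
readGenotypeTable <- function(file) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    need <- c("snp", "chrom", "pos")
    if (!all(need %in% names(df)[1:3]))
        stop("genotype table must start with columns snp, chrom, pos")
    dup <- duplicated(df$snp)
    if (any(dup))
        stop(sprintf("duplicate SNP id '%s' at row %d", df$snp[dup][1L],
                     which(dup)[1L]))
    posRaw <- df$pos
    mappedLike <- !(df$chrom == .UNKNOWN_CHROM | posRaw == "" | is.na(posRaw))
    badPos <- mappedLike & !grepl("^[0-9]+$", posRaw)
    if (any(badPos))
        stop(sprintf("non-integer position '%s' at row %d",
                     posRaw[badPos][1L], which(badPos)[1L]))
    pos <- suppressWarnings(as.numeric(posRaw))
    pos[!mappedLike] <- NA_real_
    sampleCols <- setdiff(names(df), need)
    if (!length(sampleCols)) stop("genotype table has no sample columns")
    cm <- as.matrix(df[, sampleCols, drop = FALSE])
    bad <- !grepl(.CALL_REGEX, cm)
    dim(bad) <- dim(cm)
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("invalid call token '%s' at row %d (sample %s)",
                     cm[bad][1L], i[1L], sampleCols[i[2L]]))
    }
    rownames(cm) <- df$snp
    GenotypeCalls(cm, SnpPanel(df$snp, df$chrom, pos))
}

#' Write a genotype table (TSV dialect)
#'
#' @param x a [GenotypeCalls-class].
#' @param file output path.
#' @export
writeGenotypeTable <- function(x, file) {
    pan <- panel(x)
    df <- data.frame(snp = snpIds(pan), chrom = snpChrom(pan),
                     pos = ifelse(isMapped(pan),
                                  format(snpPos(pan), scientific = FALSE,
                                         trim = TRUE), ""),
                     calls(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read QTL region definitions
#'
#' TSV with columns `name`, `chrom`, `leftMarker`, `leftBp`,
#' `rightMarker`, `rightBp`.  Region length is computed from the
#' positions (right minus left).
#'
#' @param file path to the QTL table.
#' @param chromosomes optional character vector of valid chromosome
#'   names to validate against.
#' @return a list of [QtlRegion-class] objects, named by region.
#' @export
readQtlRegions <- function(file, chromosomes = NULL) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("name", "chrom", "leftMarker", "leftBp", "rightMarker",
              "rightBp")
    if (!all(need %in% names(df)))
        stop("QTL table must have columns ", paste(need, collapse = ", "))
    out <- lapply(seq_len(nrow(df)), function(i) {
        l <- as.numeric(df$leftBp[i]); r <- as.numeric(df$rightBp[i])
        if (is.na(l) || is.na(r) || l >= r)
            stop(sprintf("QTL '%s': left flank must be left of right flank",
                         df$name[i]))
        if (!is.null(chromosomes) && !df$chrom[i] %in% chromosomes)
            stop(sprintf("QTL '%s': chromosome '%s' not in panel",
                         df$name[i], df$chrom[i]))
        qtlRegion(df$name[i], df$chrom[i], df$leftMarker[i], l,
                  df$rightMarker[i], r)
    })
    stats::setNames(out, df$name)
}

#' Read a sample-role manifest
#'
#' TSV with columns `sample`, `role` and optionally `pair`, `side`.
#'
#' @param file path to the manifest.
#' @return data.frame accepted by [applyQualityFilters()].
#' @export
readSampleRoles <- function(file) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (!all(c("sample", "role") %in% names(df)))
        stop("roles manifest must have columns sample, role")
    if (!"pair" %in% names(df)) df$pair <- NA_character_
    if (!"side" %in% names(df)) df$side <- NA_character_
    df
}

#' Read a centromere table
#'
#' TSV with columns `chrom`, `cenStartBp`, `cenEndBp`.
#'
#' @param file path to the table.
#' @return data.frame.
#' @export
readCentromeres <- function(file) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (!all(c("chrom", "cenStartBp", "cenEndBp") %in% names(df)))
        stop("centromere table must have columns chrom, cenStartBp, cenEndBp")
    df$cenStartBp <- as.numeric(df$cenStartBp)
    df$cenEndBp <- as.numeric(df$cenEndBp)
    df
}

#' Convert non-isogenic blocks to GRanges
#'
#' @param blocks a `"NonIsogenicBlocks"`.
#' @param pairId pair identifier encoded in the name field.
#' @return a [GenomicRanges::GRanges] with 1-based inclusive spans and
#'   `name` = `pairId:contrast`.
#' @export
blocksToGRanges <- function(blocks, pairId = "pair") {
    b <- blocks$blocks
    gr <- GenomicRanges::GRanges(
        seqnames = if (nrow(b)) b$chrom else character(0),
        ranges = IRanges::IRanges(start = b$startBp, end = b$endBp),
        name = if (nrow(b)) paste(pairId, b$contrast, sep = ":")
               else character(0))
    GenomicRanges::sort(gr)
}

#' Export non-isogenic blocks as BED
#'
#' Internal coordinates are 1-based inclusive; the BED output is
#' 0-based half-open (start = first bp - 1, end = last bp), sorted by
#' chromosome then start, with the name field encoding pair id and
#' contrast class.  Overlapping blocks on one chromosome violate the
#' segmentation contract and raise an error.
#'
#' @param blocks a `"NonIsogenicBlocks"`.
#' @param file output path.
#' @param pairId pair identifier for the name field.
#' @return the file path, invisibly.
#' @export
exportBlocksBed <- function(blocks, file, pairId = "pair") {
    b <- blocks$blocks
    for (ch in unique(b$chrom)) {
        x <- b[b$chrom == ch, , drop = FALSE]
        x <- x[order(x$startBp), , drop = FALSE]
        if (nrow(x) > 1L && any(x$startBp[-1L] <= x$endBp[-nrow(x)]))
            stop(sprintf("overlapping blocks on chromosome %s", ch))
    }
    gr <- blocksToGRanges(blocks, pairId)
    rtracklayer::export(gr, file, format = "BED")
    invisible(file)
}

#' Re-import blocks exported with [exportBlocksBed()]
#'
#' @param file BED path.
#' @return data.frame: `chrom`, `startBp`, `endBp` (1-based inclusive),
#'   `pairId`, `contrast`.
#' @export
importBlocksBed <- function(file) {
    gr <- rtracklayer::import(file, format = "BED")
    nm <- if (length(gr)) as.character(gr$name) else character(0)
    sp <- strsplit(nm, ":", fixed = TRUE)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               startBp = GenomicRanges::start(gr),
               endBp = GenomicRanges::end(gr),
               pairId = vapply(sp, `[`, "", 1L),
               contrast = vapply(sp, `[`, "", 2L),
               stringsAsFactors = FALSE)
}

#' Export a per-sample chromosome-paint track
#'
#' Runs of identical parent-of-origin codes along each chromosome are
#' written as BED features named by the genotype class, suitable for a
#' genome browser (the graphical-genotype representation).
#'
#' @param encoded an [EncodedMatrix-class].
#' @param sample sample name.
#' @param file output BED path.
#' @return the file path, invisibly.
#' @export
exportPaintTrack <- function(encoded, sample, file) {
    pan <- panel(encoded)
    v <- codes(encoded)[, sample]
    rows <- list(); k <- 0L
    for (ch in unique(snpChrom(pan))) {
        i <- which(snpChrom(pan) == ch & v != "FAIL")
        if (!length(i)) next
        r <- rle(v[i])
        e <- cumsum(r$lengths); s <- e - r$lengths + 1L
        k <- k + 1L
        rows[[k]] <- data.frame(chrom = ch,
                                startBp = snpPos(pan)[i][s],
                                endBp = snpPos(pan)[i][e],
                                code = r$values, stringsAsFactors = FALSE)
    }
    x <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(x$startBp, x$endBp),
                                 name = paste(sample, x$code, sep = ":"))
    rtracklayer::export(GenomicRanges::sort(gr), file, format = "BED")
    invisible(file)
}
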