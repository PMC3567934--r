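#' @include encode.R
NULL

#' Per-SNP isogenicity status between paired NILs
#'
#' A polymorphic SNP is isogenic when the two lines carry identical
#' non-failed codes, unknown when either call failed, and non-isogenic
#' otherwise, with the genotype contrast recorded as
#' `code in line A / code in line B` (e.g. `"BB/HH"`, `"BB/BH"`).
#'
#' @param encoded an [EncodedMatrix-class].
#' @param lineA,lineB sample names of the pair members (A is the
#'   BB side in the usual orientation).
#' @return a data.frame of class `"IsoStatusVector"`, panel-ordered:
#'   `snp`, `chrom`, `pos`, `codeA`, `codeB`, `status`, `contrast`.
#' @export
comparePair <- function(encoded, lineA, lineB) {
    cm <- codes(encoded)
    if (!all(c(lineA, lineB) %in% colnames(cm)))
        stop("pair sample(s) not found")
    a <- cm[, lineA]; b <- cm[, lineB]
    pan <- panel(encoded)
    status <- ifelse(a == "FAIL" | b == "FAIL", "unknown",
                     ifelse(a == b, "isogenic", "non-isogenic"))
    out <- data.frame(snp = snpIds(pan), chrom = snpChrom(pan),
                      pos = snpPos(pan), codeA = a, codeB = b,
                      status = status,
                      contrast = ifelse(status == "non-isogenic",
                                        paste(a, b, sep = "/"), NA_character_),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "samples") <- c(lineA, lineB)
    class(out) <- c("IsoStatusVector", "data.frame")
    out
}

#' Segment non-isogenic SNPs into blocks
#'
#' Maximal runs of non-isogenic SNPs per chromosome.  Unknown-status
#' SNPs are transparent: they neither break a run nor count towards
#' `nSnps`.  An interleaved run of up to `gapTolerance` isogenic SNPs
#' does not break a block (default 0).  Blocks with fewer than
#' `minSnps` SNPs are kept but flagged as singletons (default 1: flag
#' nothing, drop nothing).  Changes of contrast class inside a block
#' are recorded as sub-blocks.
#'
#' @param status an `"IsoStatusVector"` from [comparePair()].
#' @param gapTolerance maximum isogenic SNPs tolerated inside a run
#'   between two non-isogenic SNPs.
#' @param minSnps blocks below this SNP count are flagged singleton.
#' @return a list of class `"NonIsogenicBlocks"`: `blocks` (data.frame
#'   `chrom`, `startBp`, `endBp`, `nSnps`, `spanMbp`, `contrast`
#'   (single class or `"mixed"`), `hetOnly`, `singleton`) and
#'   `subBlocks` (data.frame `block`, `contrast`, `startBp`, `endBp`,
#'   `nSnps`); attribute `"members"` holds each block's SNPs.
#' @export
segmentBlocks <- function(status, gapTolerance = 0, minSnps = 1) {
    stopifnot(inherits(status, "IsoStatusVector"),
              gapTolerance >= 0, minSnps >= 1)
    blocks <- list(); subs <- list(); members <- list()
    bid <- 0L
    for (ch in unique(status$chrom)) {
        s <- status[status$chrom == ch & status$status != "unknown", ,
                    drop = FALSE]
        non <- which(s$status == "non-isogenic")
        if (!length(non)) next
        newBlock <- c(TRUE, diff(non) - 1L > gapTolerance)
        grp <- cumsum(newBlock)
        for (g in unique(grp)) {
            bid <- bid + 1L
            mem <- s[non[grp == g], , drop = FALSE]
            cls <- unique(mem$contrast)
            blocks[[bid]] <- data.frame(
                block = bid, chrom = ch,
                startBp = mem$pos[1L], endBp = mem$pos[nrow(mem)],
                nSnps = nrow(mem),
                spanMbp = (mem$pos[nrow(mem)] - mem$pos[1L]) / 1e6,
                contrast = if (length(cls) == 1L) cls else "mixed",
                hetOnly = all(grepl("BH", mem$contrast)),
                singleton = nrow(mem) < minSnps,
                stringsAsFactors = FALSE)
            r <- rle(mem$contrast)
            e <- cumsum(r$lengths); b <- e - r$lengths + 1L
            subs[[bid]] <- data.frame(
                block = bid, contrast = r$values,
                startBp = mem$pos[b], endBp = mem$pos[e],
                nSnps = r$lengths, stringsAsFactors = FALSE)
            members[[bid]] <- mem
        }
    }
    emptyB <- data.frame(block = integer(0), chrom = character(0),
                         startBp = numeric(0), endBp = numeric(0),
                         nSnps = integer(0), spanMbp = numeric(0),
                         contrast = character(0), hetOnly = logical(0),
                         singleton = logical(0))
    out <- list(
        blocks = if (length(blocks)) {
            x <- do.call(rbind, blocks); rownames(x) <- NULL; x
        } else emptyB,
        subBlocks = if (length(subs)) {
            x <- do.call(rbind, subs); rownames(x) <- NULL; x
        } else emptyB[c("block", "contrast", "startBp", "endBp", "nSnps")])
    attr(out, "members") <- members
    attr(out, "samples") <- attr(status, "samples")
    class(out) <- "NonIsogenicBlocks"
    out
}

#' @export
print.NonIsogenicBlocks <- function(x, ...) {
    b <- x$blocks
    cat(sprintf("NonIsogenicBlocks: %d blocks, %d SNPs, %.1f Mbp total span\n",
                nrow(b), sum(b$nSnps), sum(b$spanMbp)))
    invisible(x)
}

#' Per-chromosome and total block statistics for a NIL pair
#'
#' Computes, per chromosome, the block count (NB), SNP count (NS),
#' total span (TS, Mbp) and chromosome fraction (CF, % of chromosome
#' length), plus totals excluding the QTL chromosome (the primary
#' convention) and including it, and the genome fraction (GF, %) in
#' both conventions.  When a QTL region is supplied, blocks on the QTL
#' chromosome are intersected with the complement of the region, so
#' the designed introgression itself is not counted as residual
#' non-isogenicity (pieces flanking the region remain).
#'
#' @param blocks a `"NonIsogenicBlocks"`.
#' @param lengthsBp named vector of chromosome physical lengths.
#' @param qtl optional [QtlRegion-class].
#' @param excludeQtlRegion intersect QTL-chromosome blocks with the
#'   complement of the region (default TRUE when `qtl` is given).
#' @return a list of class `"PairBlockStats"`: `perChromosome`
#'   (data.frame `chrom`, `NB`, `NS`, `TSMbp`, `CFpct`) and `totals`
#'   (data.frame with rows `excludingQtlChrom`, `includingQtlChrom`).
#' @export
pairBlockStatistics <- function(blocks, lengthsBp, qtl = NULL,
                                excludeQtlRegion = !is.null(qtl)) {
    stopifnot(inherits(blocks, "NonIsogenicBlocks"))
    b <- blocks$blocks
    members <- attr(blocks, "members")
    if (excludeQtlRegion && !is.null(qtl) && nrow(b)) {
        keep <- list(); k <- 0L
        for (i in seq_len(nrow(b))) {
            if (b$chrom[i] != qtl@chrom) {
                k <- k + 1L; keep[[k]] <- b[i, ]; next
            }
            mem <- members[[b$block[i]]]
            for (side in list(mem[mem$pos < qtl@leftBp, , drop = FALSE],
                              mem[mem$pos > qtl@rightBp, , drop = FALSE])) {
                if (!nrow(side)) next
                k <- k + 1L
                piece <- b[i, ]
                piece$startBp <- side$pos[1L]
                piece$endBp <- side$pos[nrow(side)]
                piece$nSnps <- nrow(side)
                piece$spanMbp <- (piece$endBp - piece$startBp) / 1e6
                cls <- unique(side$contrast)
                piece$contrast <- if (length(cls) == 1L) cls else "mixed"
                keep[[k]] <- piece
            }
        }
        b <- if (k) do.call(rbind, keep) else b[0L, ]
    }
    chroms <- names(lengthsBp)
    per <- do.call(rbind, lapply(chroms, function(ch) {
        x <- b[b$chrom == ch, , drop = FALSE]
        data.frame(chrom = ch, NB = nrow(x), NS = sum(x$nSnps),
                   TSMbp = sum(x$spanMbp),
                   CFpct = 100 * sum(x$spanMbp) * 1e6 / lengthsBp[[ch]],
                   stringsAsFactors = FALSE)
    }))
    tot <- function(sel, totalLenBp) {
        x <- per[sel, , drop = FALSE]
        data.frame(NB = sum(x$NB), NS = sum(x$NS), TSMbp = sum(x$TSMbp),
                   GFpct = 100 * sum(x$TSMbp) * 1e6 / totalLenBp)
    }
    qtlChrom <- if (!is.null(qtl)) qtl@chrom else NA_character_
    excl <- per$chrom != qtlChrom | is.na(qtlChrom)
    totals <- rbind(
        excludingQtlChrom = tot(excl, sum(lengthsBp[per$chrom[excl]])),
        includingQtlChrom = tot(rep(TRUE, nrow(per)), sum(lengthsBp)))
    structure(list(perChromosome = per, totals = totals,
                   qtlChrom = qtlChrom),
              class = "PairBlockStats")
}

#' Verify the QTL introgression in a NIL pair
#'
#' Checks every polymorphic SNP within the region: the BB line must be
#' `BB` and the HH line `HH` (failed calls are ignored but counted).
#' Runs of two or more consecutive scored SNPs with identical genotype
#' in both lines are reported as isogenic sub-segments.  The check
#' passes only with zero violations and zero sub-segments.
#'
#' @param encoded an [EncodedMatrix-class].
#' @param lineBB,lineHH pair member sample names.
#' @param qtl the [QtlRegion-class].
#' @return a list of class `"QtlCheckReport"`: `pass`, `nSnps`,
#'   `nFailed`, `violations` (data.frame), `isogenicSegments`
#'   (data.frame with `startBp`, `endBp`, `nSnps`, `sharedGenotype`,
#'   `spanMbp`).
#' @export
verifyQtlIntrogression <- function(encoded, lineBB, lineHH, qtl) {
    pan <- panel(encoded)
    inReg <- which(snpChrom(pan) == qtl@chrom & snpPos(pan) >= qtl@leftBp &
                   snpPos(pan) <= qtl@rightBp)
    if (!length(inReg))
        stop(sprintf("no polymorphic SNP within QTL region %s", qtl@name))
    cm <- codes(encoded)
    a <- cm[inReg, lineBB]; b <- cm[inReg, lineHH]
    pos <- snpPos(pan)[inReg]
    scored <- a != "FAIL" & b != "FAIL"
    viol <- scored & (a != "BB" | b != "HH")
    violations <- data.frame(snp = snpIds(pan)[inReg][viol],
                             pos = pos[viol], codeBB = a[viol],
                             codeHH = b[viol], stringsAsFactors = FALSE)
    ## isogenic sub-segments among scored SNPs
    sa <- a[scored]; sb <- b[scored]; sp <- pos[scored]
    same <- sa == sb
    r <- rle(same)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    k <- which(r$values & r$lengths >= 2L)
    segs <- data.frame(startBp = sp[s[k]], endBp = sp[e[k]],
                       nSnps = r$lengths[k], sharedGenotype = sa[s[k]],
                       spanMbp = (sp[e[k]] - sp[s[k]]) / 1e6,
                       stringsAsFactors = FALSE)
    rownames(segs) <- NULL
    structure(list(pass = nrow(violations) == 0L && nrow(segs) == 0L,
                   qtl = qtl@name, nSnps = length(inReg),
                   nFailed = sum(!scored), violations = violations,
                   isogenicSegments = segs),
              class = "QtlCheckReport")
}

#' @export
print.QtlCheckReport <- function(x, ...) {
    cat(sprintf("QTL %s introgression check: %s (%d SNPs, %d failed, %d violations, %d isogenic sub-segments)\n",
                x$qtl, if (x$pass) "PASS" else "FAIL", x$nSnps, x$nFailed,
                nrow(x$violations), nrow(x$isogenicSegments)))
    invisible(x)
}

#' Measure linkage drag around the QTL flanks
#'
#' From each flanking marker, extends outward over consecutive
#' non-isogenic SNPs whose contrast is concordant with the QTL
#' (`BB` in the BB line, `HH` in the HH line); unknown-status SNPs are
#' transparent, any other scored SNP stops the contiguous extension.
#' Further QTL-concordant blocks separated by at most `joinGapMbp` of
#' isogenic span may be joined; joined extents are reported separately
#' and never folded into the contiguous measure.
#'
#' @param status an `"IsoStatusVector"` oriented so that line A is the
#'   BB member.
#' @param qtl the [QtlRegion-class].
#' @param joinGapMbp maximum isogenic gap bridged when joining
#'   additional concordant blocks (default 25 Mbp).
#' @return a list of class `"DragMeasure"`: `upstreamMbp`,
#'   `downstreamMbp`, `totalMbp` (contiguous), `joinedUpstreamMbp`,
#'   `joinedDownstreamMbp`, `joinedTotalMbp`, and `joins` (data.frame
#'   of bridged gaps).
#' @export
measureLinkageDrag <- function(status, qtl, joinGapMbp = 25) {
    stopifnot(inherits(status, "IsoStatusVector"))
    s <- status[status$chrom == qtl@chrom & status$status != "unknown", ,
                drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    conc <- s$status == "non-isogenic" & s$contrast == "BB/HH"
    oneSide <- function(outside, flankBp, dirSign, side) {
        idx <- if (dirSign < 0) rev(which(outside)) else which(outside)
        ext <- 0; outer <- flankBp
        joins <- list(); nj <- 0L
        i <- 1L
        ## contiguous stretch
        while (i <= length(idx) && conc[idx[i]]) {
            outer <- s$pos[idx[i]]
            i <- i + 1L
        }
        ext <- abs(flankBp - outer) / 1e6
        ## candidate further blocks
        while (i <= length(idx)) {
            while (i <= length(idx) && !conc[idx[i]]) i <- i + 1L
            if (i > length(idx)) break
            near <- s$pos[idx[i]]
            gap <- abs(near - outer) / 1e6
            if (gap > joinGapMbp) break
            far <- near
            while (i <= length(idx) && conc[idx[i]]) {
                far <- s$pos[idx[i]]
                i <- i + 1L
            }
            nj <- nj + 1L
            joins[[nj]] <- data.frame(
                side = side, gapMbp = gap,
                blockStartBp = min(near, far), blockEndBp = max(near, far),
                extensionMbp = abs(far - near) / 1e6,
                stringsAsFactors = FALSE)
            outer <- far
        }
        list(contiguousMbp = ext,
             joinedMbp = abs(flankBp - outer) / 1e6,
             joins = joins)
    }
    up <- oneSide(s$pos < qtl@leftBp, qtl@leftBp, -1, "upstream")
    down <- oneSide(s$pos > qtl@rightBp, qtl@rightBp, +1, "downstream")
    joins <- c(up$joins, down$joins)
    joins <- if (length(joins)) do.call(rbind, joins) else
        data.frame(side = character(0), gapMbp = numeric(0),
                   blockStartBp = numeric(0), blockEndBp = numeric(0),
                   extensionMbp = numeric(0))
    structure(list(upstreamMbp = up$contiguousMbp,
                   downstreamMbp = down$contiguousMbp,
                   totalMbp = up$contiguousMbp + down$contiguousMbp,
                   joinedUpstreamMbp = up$joinedMbp,
                   joinedDownstreamMbp = down$joinedMbp,
                   joinedTotalMbp = up$joinedMbp + down$joinedMbp,
                   joins = joins),
              class = "DragMeasure")
}
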