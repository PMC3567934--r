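#' @include io.R
NULL

#' Round half away from zero
#'
#' Report tables round percentages with the conventional half-away
#' rule (R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
roundHalfAway <- function(x, digits = 1) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

## Table-3 style value: one decimal for values >= 1, two significant
## figures below 1 (e.g. "0.15", "0.84", "0.0002")
.fmtSmall <- function(x) {
    ifelse(x == 0, "0.0",
           ifelse(x >= 1,
                  sprintf("%.1f", roundHalfAway(x, 1)),
                  format(signif(x, 2), scientific = FALSE, trim = TRUE)))
}

#' Assemble the SNP genomic-distribution table
#'
#' Per-chromosome totals of good-quality SNPs split into polymorphic
#' and monomorphic, with length shares and percentages rounded to one
#' decimal (half away from zero), in the layout of a publication
#' distribution table.
#'
#' @param chrom chromosome names.
#' @param lengthsBp physical lengths (bp).
#' @param P,M per-chromosome polymorphic and monomorphic counts.
#' @param Tt optional per-chromosome totals; must equal `P + M`.
#' @param pmDirection optional per-chromosome direction flags
#'   (`"+"`/`"-"`/`""`), e.g. from [testPmIndependence()].
#' @return a data.frame of class `"DistributionTable"` with columns
#'   `chrom`, `lengthMbp`, `lengthPct`, `T`, `TPct`, `P`, `PPct`, `M`,
#'   `MPct`, `pmDirection`; attribute `totals`.
#' @export
assembleDistributionTable <- function(chrom, lengthsBp, P, M, Tt = P + M,
                                      pmDirection = NULL) {
    if (any(Tt != P + M))
        stop("inconsistent counts: T must equal P + M on every chromosome")
    if (is.null(pmDirection)) pmDirection <- rep("", length(chrom))
    out <- data.frame(
        chrom = chrom,
        lengthMbp = lengthsBp / 1e6,
        lengthPct = roundHalfAway(100 * lengthsBp / sum(lengthsBp), 1),
        T = Tt,
        TPct = roundHalfAway(100 * Tt / sum(Tt), 1),
        P = P,
        PPct = roundHalfAway(100 * P / Tt, 1),
        M = M,
        MPct = roundHalfAway(100 * M / Tt, 1),
        pmDirection = pmDirection,
        stringsAsFactors = FALSE)
    attr(out, "totals") <- c(T = sum(Tt), P = sum(P), M = sum(M),
                             PPct = roundHalfAway(100 * sum(P) / sum(Tt), 1),
                             MPct = roundHalfAway(100 * sum(M) / sum(Tt), 1))
    class(out) <- c("DistributionTable", "data.frame")
    out
}

#' Assemble the pair report table (NB/NS/TS/CF with GF totals)
#'
#' Publication layout for the non-isogenic summary of one NIL pair:
#' per chromosome the block count (NB), SNP count (NS), total span
#' (TS, Mbp) and chromosome fraction (CF, %), with totals excluding
#' the QTL chromosome as primary and the including-QTL totals as the
#' parenthetical convention, and the genome fraction (GF, %) in both
#' conventions (the excluding convention uses the genome length minus
#' the QTL chromosome).
#'
#' @param x a `"PairBlockStats"` from [pairBlockStatistics()], or a
#'   data.frame with columns `chrom`, `NB`, `NS`, `TSMbp`.
#' @param lengthsBp named vector of chromosome lengths (bp).
#' @param qtlChrom chromosome carrying the introgressed QTL (`NA` for
#'   none).
#' @param pairId label for the pair.
#' @return a list of class `"PairReportTable"`: `pairId`,
#'   `perChromosome` (numeric, with `CFpct`), `totals` (numeric rows
#'   `excludingQtlChrom` / `includingQtlChrom` with `NB`, `NS`,
#'   `TSMbp`, `GFpct`), `formatted` (character data.frame in table
#'   layout).
#' @export
assemblePairReport <- function(x, lengthsBp, qtlChrom = NA_character_,
                               pairId = "pair") {
    per <- if (inherits(x, "PairBlockStats")) {
        if (is.na(qtlChrom)) qtlChrom <- x$qtlChrom
        x$perChromosome[c("chrom", "NB", "NS", "TSMbp")]
    } else {
        as.data.frame(x)[c("chrom", "NB", "NS", "TSMbp")]
    }
    per <- per[match(names(lengthsBp), per$chrom), ]
    per$chrom <- names(lengthsBp)
    per[is.na(per$NB), c("NB", "NS", "TSMbp")] <- 0
    per$CFpct <- 100 * per$TSMbp * 1e6 / unname(lengthsBp)
    excl <- is.na(qtlChrom) | per$chrom != qtlChrom
    tot <- function(sel) {
        c(NB = sum(per$NB[sel]), NS = sum(per$NS[sel]),
          TSMbp = sum(per$TSMbp[sel]),
          GFpct = 100 * sum(per$TSMbp[sel]) * 1e6 / sum(lengthsBp[sel]))
    }
    totals <- rbind(excludingQtlChrom = tot(excl),
                    includingQtlChrom = tot(rep(TRUE, nrow(per))))
    paren <- function(a, b) sprintf("%s (%s)", a, b)
    formatted <- data.frame(
        chrom = c(per$chrom, "Total"),
        NB = c(as.character(per$NB),
               paren(totals["excludingQtlChrom", "NB"],
                     totals["includingQtlChrom", "NB"])),
        NS = c(as.character(per$NS),
               paren(totals["excludingQtlChrom", "NS"],
                     totals["includingQtlChrom", "NS"])),
        TS = c(.fmtSmall(per$TSMbp),
               paren(.fmtSmall(totals["excludingQtlChrom", "TSMbp"]),
                     .fmtSmall(totals["includingQtlChrom", "TSMbp"]))),
        CF_GF = c(paste0(.fmtSmall(per$CFpct), "%"),
                  paren(paste0(.fmtSmall(totals["excludingQtlChrom", "GFpct"]), "%"),
                        paste0(.fmtSmall(totals["includingQtlChrom", "GFpct"]), "%"))),
        stringsAsFactors = FALSE)
    structure(list(pairId = pairId, perChromosome = per, totals = totals,
                   qtlChrom = qtlChrom, formatted = formatted),
              class = "PairReportTable")
}

#' @export
print.PairReportTable <- function(x, ...) {
    cat(sprintf("Non-isogenic region summary for pair %s (QTL chromosome %s excluded from primary totals)\n",
                x$pairId, x$qtlChrom))
    print(x$formatted, row.names = FALSE)
    invisible(x)
}

#' Write a report table as TSV
#'
#' @param x a `"DistributionTable"` or `"PairReportTable"`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeReportTable <- function(x, file) {
    df <- if (inherits(x, "PairReportTable")) x$formatted else
        as.data.frame(x)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
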