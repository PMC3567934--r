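#' @include qc.R
NULL

#' Encode parent-of-origin genotypes at polymorphic SNPs
#'
#' For every SNP polymorphic between the two parents, calls are mapped
#' to `BB` (parent-A homozygote), `HH` (parent-B homozygote), `BH`
#' (the unordered pair of both parental alleles) or `FAIL`.  Any other
#' allele combination is a contract violation (the quality filters
#' should have removed it) and raises an error naming SNP and sample.
#'
#' @param x a retained [GenotypeCalls-class] (after
#'   [applyQualityFilters()]).
#' @param roles the sample-role manifest.
#' @param samples samples to encode (default: all chip samples).
#' @return an [EncodedMatrix-class] over the polymorphic SNPs.
#' @export
encodeParentOfOrigin <- function(x, roles, samples = sampleNames(x)) {
    status <- classifyPolymorphism(x, roles)
    poly <- which(status == "polymorphic")
    xp <- x[poly, ]
    cm <- calls(xp)[, samples, drop = FALSE]
    a <- .allele1(cm[, .getRole(roles, "parentA")])
    b <- .allele1(cm[, .getRole(roles, "parentB")])
    homA <- paste(a, a, sep = "/")
    homB <- paste(b, b, sep = "/")
    het <- .sortedPair(a, b)
    out <- matrix(NA_character_, nrow(cm), ncol(cm), dimnames = dimnames(cm))
    for (j in seq_len(ncol(cm))) {
        v <- cm[, j]
        code <- rep(NA_character_, length(v))
        code[v == homA] <- "BB"
        code[v == homB] <- "HH"
        code[v == het] <- "BH"
        code[.isFail(v)] <- "FAIL"
        if (anyNA(code)) {
            i <- which(is.na(code))[1L]
            stop(sprintf("unexpected allele combination '%s' at SNP %s in sample %s",
                         v[i], rownames(cm)[i], colnames(cm)[j]))
        }
        out[, j] <- code
    }
    new("EncodedMatrix", codes = out, panel = panel(xp),
        alleleA = a, alleleB = b)
}

#' Per-sample inheritance summary
#'
#' Failure rate over all polymorphic SNPs; heterozygosity and parent-A
#' homozygote share over the non-failed polymorphic SNPs; the same
#' broken down per chromosome.  All rates are percentages.
#'
#' @param encoded an [EncodedMatrix-class].
#' @param sample sample name.
#' @return a list of class `"SampleSummary"`: `sample`, `nPolymorphic`,
#'   `counts` (BB/HH/BH/FAIL), `failurePct`, `hetPct`, `bbPct`,
#'   `perChromosome` (data.frame).
#' @export
sampleSummary <- function(encoded, sample) {
    if (!sample %in% sampleNames(encoded)) stop("sample not found")
    v <- codes(encoded)[, sample]
    pan <- panel(encoded)
    tally <- function(x) {
        n <- length(x)
        cnt <- table(factor(x, levels = .CODES))
        ok <- n - cnt[["FAIL"]]
        c(n = n, nOk = ok, BB = cnt[["BB"]], HH = cnt[["HH"]],
          BH = cnt[["BH"]], FAIL = cnt[["FAIL"]],
          failurePct = 100 * cnt[["FAIL"]] / n,
          hetPct = if (ok) 100 * cnt[["BH"]] / ok else NA_real_,
          bbPct = if (ok) 100 * cnt[["BB"]] / ok else NA_real_)
    }
    tot <- tally(v)
    chroms <- unique(snpChrom(pan))
    per <- do.call(rbind, lapply(chroms, function(ch)
        data.frame(chrom = ch, t(tally(v[snpChrom(pan) == ch])))))
    structure(list(sample = sample, nPolymorphic = length(v),
                   counts = tot[c("BB", "HH", "BH", "FAIL")],
                   failurePct = tot[["failurePct"]],
                   hetPct = tot[["hetPct"]], bbPct = tot[["bbPct"]],
                   perChromosome = per),
              class = "SampleSummary")
}

#' @export
print.SampleSummary <- function(x, ...) {
    cat(sprintf("%s: %d polymorphic SNPs; failure %.2f%%, heterozygosity %.2f%%, parent-A share %.1f%%\n",
                x$sample, x$nPolymorphic, x$failurePct, x$hetPct, x$bbPct))
    invisible(x)
}

#' Trio consistency of a NIL cross
#'
#' Scores every polymorphic SNP called in all three samples of a trio
#' (two parental NILs and their cross) and classifies the non-matching
#' SNPs into the four situations seen in trio checks of residually
#' heterozygous lines: (1) heterozygous child with exactly one
#' heterozygous parent, (2) all three heterozygous, (3) homozygous
#' child with contrasting homozygous parents, (4) homozygous child with
#' a heterozygous parent.  A SNP is consistent when both parents are
#' homozygous and the child carries the genotype those parents force.
#' Case-3 SNPs sitting inside a long run of consistent SNPs are flagged
#' as probable child mis-calls (advisory only, never corrected).
#'
#' @param encoded an [EncodedMatrix-class].
#' @param child,parent1,parent2 sample names (`parent1` is the BB-side
#'   parent in the reported sub-splits).
#' @param flagRunLength minimum consistent surrounding run for the
#'   case-3 advisory flag (default 20 SNPs).
#' @return a list of class `"TrioReport"`.
#' @export
trioConsistency <- function(encoded, child, parent1, parent2,
                            flagRunLength = 20) {
    cm <- codes(encoded)
    ch <- cm[, child]; p1 <- cm[, parent1]; p2 <- cm[, parent2]
    pan <- panel(encoded)
    scored <- which(ch != "FAIL" & p1 != "FAIL" & p2 != "FAIL")
    ch <- ch[scored]; p1 <- p1[scored]; p2 <- p2[scored]
    hom <- function(x) x %in% c("BB", "HH")
    forced <- ifelse(p1 == p2, p1, "BH")       # meaningful when both hom
    bothHom <- hom(p1) & hom(p2)
    cls <- character(length(ch))
    cls[bothHom & ch == forced] <- "consistent"
    cls[bothHom & ch != forced & hom(ch) & p1 != p2] <- "case3"
    cls[ch == "BH" & xor(p1 == "BH", p2 == "BH")] <- "case1"
    cls[ch == "BH" & p1 == "BH" & p2 == "BH"] <- "case2"
    cls[hom(ch) & (p1 == "BH" | p2 == "BH")] <- "case4"
    cls[cls == ""] <- "other"
    n <- function(k) sum(cls == k)
    ## advisory: case-3 SNPs inside long consistent runs
    advisory <- data.frame(snp = character(0), chrom = character(0),
                           pos = numeric(0), surroundingConsistent = integer(0),
                           flagged = logical(0))
    if (n("case3") > 0) {
        idx3 <- which(cls == "case3")
        chrom <- snpChrom(pan)[scored]
        surround <- vapply(idx3, function(i) {
            cnt <- 0L
            j <- i - 1L
            while (j >= 1L && chrom[j] == chrom[i] && cls[j] == "consistent") {
                cnt <- cnt + 1L; j <- j - 1L
            }
            j <- i + 1L
            while (j <= length(cls) && chrom[j] == chrom[i] &&
                   cls[j] == "consistent") {
                cnt <- cnt + 1L; j <- j + 1L
            }
            cnt
        }, integer(1))
        advisory <- data.frame(snp = snpIds(pan)[scored][idx3],
                               chrom = chrom[idx3],
                               pos = snpPos(pan)[scored][idx3],
                               surroundingConsistent = surround,
                               flagged = surround >= flagRunLength,
                               stringsAsFactors = FALSE)
    }
    structure(list(
        samples = c(child = child, parent1 = parent1, parent2 = parent2),
        scored = length(cls),
        consistent = n("consistent"),
        nonMatching = length(cls) - n("consistent") - n("other"),
        case1 = n("case1"),
        case1ByParent = c(parent1 = sum(cls == "case1" & p1 == "BH"),
                          parent2 = sum(cls == "case1" & p2 == "BH")),
        case2 = n("case2"),
        case3 = n("case3"),
        case4 = n("case4"),
        case4ByParent = c(parent1 = sum(cls == "case4" & p1 == "BH" & p2 != "BH"),
                          parent2 = sum(cls == "case4" & p2 == "BH" & p1 != "BH"),
                          both = sum(cls == "case4" & p1 == "BH" & p2 == "BH")),
        other = n("other"),
        hetChildFromContrastingHom = sum(ch == "BH" & bothHom & p1 != p2),
        hetChildTotal = sum(ch == "BH"),
        advisory = advisory,
        class = cls),
        class = "TrioReport")
}

#' @export
print.TrioReport <- function(x, ...) {
    cat(sprintf("TrioReport %s = %s x %s\n", x$samples["child"],
                x$samples["parent1"], x$samples["parent2"]))
    cat(sprintf("  scored %d; consistent %d (%.1f%%); cases 1-4: %d/%d/%d/%d; other %d\n",
                x$scored, x$consistent, 100 * x$consistent / x$scored,
                x$case1, x$case2, x$case3, x$case4, x$other))
    invisible(x)
}
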