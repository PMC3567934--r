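#' @include chip.R
NULL

.isFail <- function(x) x == .FAIL_TOKEN
.allele1 <- function(x) substr(x, 1L, 1L)
.allele2 <- function(x) substr(x, 3L, 3L)
.isHet <- function(x) !.isFail(x) & .allele1(x) != .allele2(x)
.isHom <- function(x) !.isFail(x) & .allele1(x) == .allele2(x)

.getRole <- function(roles, role, exactlyOne = TRUE) {
    s <- roles$sample[roles$role == role]
    if (exactlyOne && length(s) != 1L)
        stop(sprintf("roles must define exactly one '%s' sample", role))
    s
}

#' Merge replicate reference samples into one logical sample
#'
#' A call failed in only one replicate is imputed from the other; two
#' discordant non-failed calls raise a warning and the first replicate
#' wins.  The replicate columns are replaced by the merged column.
#'
#' @param x a [GenotypeCalls-class].
#' @param rep1,rep2 replicate sample names.
#' @param newName name of the merged column (default `rep1`).
#' @return a [GenotypeCalls-class] with the replicates merged.
#' @export
mergeReplicates <- function(x, rep1, rep2, newName = rep1) {
    cm <- calls(x)
    a <- cm[, rep1]; b <- cm[, rep2]
    merged <- a
    merged[.isFail(a)] <- b[.isFail(a)]
    disc <- !.isFail(a) & !.isFail(b) & a != b
    if (any(disc)) {
        warning(sprintf("%d discordant replicate calls; keeping %s",
                        sum(disc), rep1))
        merged[disc] <- a[disc]
    }
    keep <- setdiff(colnames(cm), c(rep1, rep2))
    out <- cbind(cm[, keep, drop = FALSE], merged)
    colnames(out) <- c(keep, newName)
    GenotypeCalls(out, panel(x))
}

#' Compare two samples SNP by SNP
#'
#' Classifies every panel SNP into identical-homozygous,
#' identical-heterozygous, het-in-A-only, het-in-B-only,
#' discordant-homozygous, discordant-heterozygous (both heterozygous
#' with different alleles) or not-compared.  Replicate/seed-stock
#' comparisons drop unmapped SNPs and SNPs failed in either sample
#' (imputation across replicates is [mergeReplicates()]'s job).
#'
#' @param x a [GenotypeCalls-class].
#' @param sampleA,sampleB sample names to compare.
#' @param dropUnmapped exclude unmapped SNPs from the comparison
#'   (default TRUE).
#' @return a list of class `"SampleComparison"`: per-SNP `class`
#'   (aligned to the panel), `counts`, `compared`, `discordant`,
#'   `identicalFraction`.
#' @export
compareSamples <- function(x, sampleA, sampleB, dropUnmapped = TRUE) {
    cm <- calls(x)
    if (!all(c(sampleA, sampleB) %in% colnames(cm)))
        stop("samples not found")
    a <- cm[, sampleA]; b <- cm[, sampleB]
    if (length(a) != length(b)) stop("call vectors differ in length")
    cl <- rep("not-compared", length(a))
    ok <- !.isFail(a) & !.isFail(b)
    if (dropUnmapped) ok <- ok & isMapped(panel(x))
    hetA <- .isHet(a); hetB <- .isHet(b)
    cl[ok & a == b & !hetA] <- "identical-homozygous"
    cl[ok & a == b & hetA] <- "identical-heterozygous"
    cl[ok & a != b & hetA & !hetB] <- "het-in-A-only"
    cl[ok & a != b & !hetA & hetB] <- "het-in-B-only"
    cl[ok & a != b & !hetA & !hetB] <- "discordant-homozygous"
    cl[ok & a != b & hetA & hetB] <- "discordant-heterozygous"
    lev <- c("identical-homozygous", "identical-heterozygous",
             "het-in-A-only", "het-in-B-only", "discordant-homozygous",
             "discordant-heterozygous", "not-compared")
    cl <- factor(cl, levels = lev)
    counts <- table(cl)
    compared <- sum(ok)
    discordant <- sum(counts[3:6])
    structure(list(samples = c(sampleA, sampleB), class = cl,
                   counts = counts, compared = compared,
                   discordant = discordant,
                   identicalFraction = sum(counts[1:2]) / compared,
                   panel = panel(x)),
              class = "SampleComparison")
}

#' @export
print.SampleComparison <- function(x, ...) {
    cat(sprintf("SampleComparison %s vs %s: %d compared, %.2f%% identical, %d discordant\n",
                x$samples[1], x$samples[2], x$compared,
                100 * x$identicalFraction, x$discordant))
    print(x$counts)
    invisible(x)
}

#' Find clusters of consecutive discordant SNPs
#'
#' Maximal runs of discordant SNPs (no concordant compared SNP
#' interleaved; not-compared SNPs are transparent) of at least
#' `minRun` SNPs, with their bp spans.
#'
#' @param comparison a `"SampleComparison"`.
#' @param minRun minimum SNPs per cluster (default 5; the source data
#'   never define "cluster" quantitatively, so the floor is explicit).
#' @return data.frame: `chrom`, `startBp`, `endBp`, `nSnps`, `spanMbp`.
#' @export
findDiscordantClusters <- function(comparison, minRun = 5) {
    stopifnot(inherits(comparison, "SampleComparison"), minRun >= 1)
    pan <- comparison$panel
    cmp <- which(comparison$class != "not-compared" & isMapped(pan))
    disc <- comparison$class[cmp] %in%
        c("het-in-A-only", "het-in-B-only", "discordant-homozygous",
          "discordant-heterozygous")
    out <- list()
    for (ch in unique(snpChrom(pan)[cmp])) {
        sel <- snpChrom(pan)[cmp] == ch
        d <- disc[sel]
        p <- snpPos(pan)[cmp][sel]
        r <- rle(d)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- which(r$values & r$lengths >= minRun)
        if (length(keep))
            out[[ch]] <- data.frame(
                chrom = ch, startBp = p[starts[keep]], endBp = p[ends[keep]],
                nSnps = r$lengths[keep],
                spanMbp = (p[ends[keep]] - p[starts[keep]]) / 1e6,
                stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(chrom = character(0), startBp = numeric(0),
                          endBp = numeric(0), nSnps = integer(0),
                          spanMbp = numeric(0)))
    x <- do.call(rbind, out)
    rownames(x) <- NULL
    x[order(x$chrom, x$startBp), , drop = FALSE]
}

## the six ordered violation predicates, each defined independently of
## the others so that the retained set is order-invariant
.filterMasks <- function(cm, pan, roles) {
    pA <- .getRole(roles, "parentA")
    pB <- .getRole(roles, "parentB")
    f1 <- .getRole(roles, "F1")
    nil <- roles$sample[roles$role == "NIL"]
    a <- cm[, pA]; b <- cm[, pB]; f <- cm[, f1]
    bothHom <- .isHom(a) & .isHom(b)
    polym <- bothHom & a != b
    monom <- bothHom & a == b
    sharedAllele <- .allele1(a)
    nilViol <- rep(FALSE, nrow(cm))
    if (length(nil)) {
        for (s in nil) {
            v <- cm[, s]
            bad <- !.isFail(v) &
                (.allele1(v) != sharedAllele | .allele2(v) != sharedAllele)
            nilViol <- nilViol | (monom & bad)
        }
    }
    list(
        "failed in all samples" = rowSums(!.isFail(cm)) == 0L,
        "failed in parentA, parentB or F1" =
            .isFail(a) | .isFail(b) | .isFail(f),
        "unmapped or unknown chromosome" = !isMapped(pan),
        "heterozygous in either parent" = .isHet(a) | .isHet(b),
        "F1-inconsistent" = polym & !.isFail(f) &
            f != .sortedPair(.allele1(a), .allele1(b)),
        "NIL-inconsistent" = nilViol)
}

#' Apply the six ordered quality and pedigree filters
#'
#' SNPs are removed when they (1) failed in all samples, (2) failed in
#' parent A, parent B or the F1, (3) are unmapped or on the unknown
#' chromosome, (4) are heterozygous in either parent, (5) are
#' polymorphic between the parents but the F1 call is not the parental
#' heterozygote, or (6) are monomorphic between the parents but a NIL
#' sample carries the alternative allele.  Each excluded SNP is
#' attributed to the first step it violates (sequential counting); the
#' retained set itself does not depend on the order.  Step 6 is
#' reported as 0 when the roles define no NIL samples.
#'
#' @param x a [GenotypeCalls-class].
#' @param roles data.frame with columns `sample`, `role` (values
#'   `parentA`, `parentB`, `F1`, `referenceReplicate`, `NIL`), and for
#'   NILs `pair` and `side`.
#' @return list with `calls` (retained [GenotypeCalls-class]) and
#'   `report` (a `"FilterReport"` data.frame: `step`, `name`,
#'   `excluded`, `retainedAfter`; attributes `initial`, `final`).
#' @export
applyQualityFilters <- function(x, roles) {
    cm <- calls(x)
    pan <- panel(x)
    masks <- .filterMasks(cm, pan, roles)
    first <- rep(NA_integer_, nrow(cm))
    for (j in rev(seq_along(masks)))
        first[masks[[j]]] <- j
    excluded <- tabulate(first, nbins = length(masks))
    retained <- is.na(first)
    report <- data.frame(step = seq_along(masks), name = names(masks),
                         excluded = excluded,
                         retainedAfter = nrow(cm) - cumsum(excluded),
                         stringsAsFactors = FALSE)
    attr(report, "initial") <- nrow(cm)
    attr(report, "final") <- sum(retained)
    class(report) <- c("FilterReport", "data.frame")
    list(calls = x[retained, ], report = report)
}

#' Classify retained SNPs as polymorphic or monomorphic
#'
#' A retained SNP is polymorphic when the two parental homozygous calls
#' differ.  Calls that should have been removed by the filters
#' (heterozygous or failed parents) raise an error.
#'
#' @param x a retained [GenotypeCalls-class] (after
#'   [applyQualityFilters()]).
#' @param roles the sample-role manifest.
#' @return named character vector (`"polymorphic"` / `"monomorphic"`)
#'   over the retained SNPs.
#' @export
classifyPolymorphism <- function(x, roles) {
    cm <- calls(x)
    a <- cm[, .getRole(roles, "parentA")]
    b <- cm[, .getRole(roles, "parentB")]
    bad <- !(.isHom(a) & .isHom(b))
    if (any(bad))
        stop(sprintf("non-homozygous parental call at %d SNPs (first: %s); run applyQualityFilters first",
                     sum(bad), rownames(cm)[which(bad)[1L]]))
    stats::setNames(ifelse(a != b, "polymorphic", "monomorphic"),
                    rownames(cm))
}
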