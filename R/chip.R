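#' @include breeding.R
NULL

#' Chip read-out noise model
#'
#' @param failureRate probability a call fails (`"-/-"`); default
#'   0.0086, the average per-sample failure rate observed in NILs.
#' @param errorRate probability a non-failed call is mis-called as one
#'   of the other two genotypes over the SNP's two design alleles
#'   (default 0.0005).
#' @param hetMiscallSplit probability an error on a homozygous truth
#'   lands on the heterozygous call rather than the opposite homozygote
#'   (default 0.5).
#' @return a list of class `"ChipNoiseModel"`.
#' @export
chipNoiseModel <- function(failureRate = 0.0086, errorRate = 0.0005,
                           hetMiscallSplit = 0.5) {
    p <- c(failureRate, errorRate, hetMiscallSplit)
    if (any(p < 0 | p > 1)) stop("noise probabilities must be in [0, 1]")
    structure(list(failureRate = failureRate, errorRate = errorRate,
                   hetMiscallSplit = hetMiscallSplit),
              class = "ChipNoiseModel")
}

#' Zero-noise model
#' @rdname chipNoiseModel
#' @export
noiselessChip <- function() chipNoiseModel(0, 0, 0.5)

.sortedPair <- function(a, b) {
    lo <- ifelse(a <= b, a, b)
    hi <- ifelse(a <= b, b, a)
    paste(lo, hi, sep = "/")
}

#' Emulate a SNP-chip read-out of simulated individuals
#'
#' Converts true genotype codes into biallelic call tokens over each
#' SNP's two design alleles, then applies independent per-call failures
#' and mis-calls.  Two reference replicates of founder A (`refRep1`,
#' `refRep2`) are added with independent noise, mirroring the duplicate
#' reference samples of a chip experiment.  At monomorphic SNPs the chip
#' still assays a second design allele, so mis-calls there can produce
#' the alternative allele (the situation the NIL-consistency filter
#' step targets).
#'
#' @param truth a [NilPairTruth-class].
#' @param noise a [chipNoiseModel()] (default: paper-calibrated rates).
#' @param samples which recorded samples to put on the chip; defaults
#'   to parents, F1, the two reference replicates and the NIL trio.
#' @param seed optional integer seed for the noise draws.
#' @return a [GenotypeCalls-class] whose columns are chip samples.
#' @export
emulateChip <- function(truth, noise = chipNoiseModel(),
                        samples = NULL, seed = NULL) {
    stopifnot(is(truth, "NilPairTruth"), inherits(noise, "ChipNoiseModel"))
    geno <- truth@genotypes
    avail <- colnames(geno)
    if (is.null(samples)) {
        map <- c(parentA = "founderA", parentB = "founderB", F1 = "F1",
                 NIL_BB = "NIL_BB", NIL_HH = "NIL_HH", NIL_BH = "NIL_BH")
        samples <- map[map %in% avail]
    } else if (is.null(names(samples))) {
        names(samples) <- samples
    }
    if (!all(samples %in% avail)) stop("unknown truth sample requested")
    gm <- truth@genome
    a <- gm@alleleA
    b <- gm@alleleB
    ## design alternative allele: at monomorphic SNPs pick a fixed
    ## second assay allele (next base in ACGT order)
    bases <- c("A", "C", "G", "T")
    alt <- ifelse(a == b, bases[(match(a, bases) %% 4L) + 1L], b)
    homRef <- paste(a, a, sep = "/")
    homAlt <- paste(alt, alt, sep = "/")
    het <- .sortedPair(a, alt)        # design het, target of mis-calls
    trueHet <- .sortedPair(a, b)      # founder het (= homRef when monomorphic)
    callOf <- function(codeVec) {
        ## truth codes are founder-B dose; founder B carries `b`, which
        ## equals `a` at monomorphic SNPs
        out <- homRef
        out[codeVec == "BH"] <- trueHet[codeVec == "BH"]
        isHH <- codeVec == "HH"
        out[isHH] <- paste(b[isHH], b[isHH], sep = "/")
        out
    }
    .withSeed(seed, {
        n <- nrow(geno)
        cols <- c(names(samples), "refRep1", "refRep2")
        truthCols <- c(unname(samples), "founderA", "founderA")
        m <- matrix(.FAIL_TOKEN, nrow = n, ncol = length(cols),
                    dimnames = list(rownames(geno), cols))
        for (j in seq_along(cols)) {
            cl <- callOf(geno[, truthCols[j]])
            if (noise$errorRate > 0) {
                err <- which(stats::runif(n) < noise$errorRate)
                for (i in err) {
                    truthHet <- cl[i] == het[i]
                    cl[i] <- if (truthHet) {
                        if (stats::runif(1) < 0.5) homRef[i] else homAlt[i]
                    } else if (stats::runif(1) < noise$hetMiscallSplit) {
                        het[i]
                    } else if (cl[i] == homRef[i]) homAlt[i] else homRef[i]
                }
            }
            if (noise$failureRate > 0) {
                fl <- stats::runif(n) < noise$failureRate
                cl[fl] <- .FAIL_TOKEN
            }
            m[, j] <- cl
        }
        GenotypeCalls(m, gm@panel)
    })
}

#' Sample-role manifest for simulator output
#'
#' @param truth a [NilPairTruth-class] (only the QTL name is used for
#'   the pair id).
#' @param pairId pair identifier put on the NIL records.
#' @return a data.frame with columns `sample`, `role`, `pair`, `side`
#'   accepted by [applyQualityFilters()] and friends.
#' @export
truthRoles <- function(truth, pairId = NULL) {
    if (is.null(pairId)) pairId <- truth@qtl@name
    data.frame(
        sample = c("parentA", "parentB", "F1", "refRep1", "refRep2",
                   "NIL_BB", "NIL_HH", "NIL_BH"),
        role = c("parentA", "parentB", "F1", "referenceReplicate",
                 "referenceReplicate", "NIL", "NIL", "NIL"),
        pair = c(NA, NA, NA, NA, NA, pairId, pairId, pairId),
        side = c(NA, NA, NA, NA, NA, "BB", "HH", "BH"),
        stringsAsFactors = FALSE)
}
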