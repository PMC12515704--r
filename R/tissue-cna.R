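## Tissue copy-number support: aggregate purity-adjusted segments to arm
## level, express arms as log2 deviation from the expected normal copy
## number, and quantify per-sample concordance with cfDNA arm Z-scores.

#' Read a copy-number segment table
#'
#' @param path TSV with header columns `chromosome`, `start`, `end`
#'   (0-based half-open) and `copyNumber` (purity-adjusted total copy
#'   number), as produced by arm-level CN callers.
#' @return `GRanges` with metadata column `cn`.
#' @export
readSegments <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    need <- c("chromosome", "start", "end", "copyNumber")
    if (!all(need %in% names(df)))
        stop("segment table needs columns: ", paste(need, collapse = ", "))
    segmentRanges(df)
}

#' @rdname readSegments
#' @param df `data.frame` with the same columns as above.
#' @export
segmentRanges <- function(df) {
    if (any(df$end <= df$start)) stop("segments must satisfy start < end")
    if (any(df$copyNumber < 0)) stop("copy numbers must be non-negative")
    gr <- GenomicRanges::GRanges(df$chromosome,
                                 IRanges::IRanges(df$start + 1L, df$end))
    S4Vectors::mcols(gr)$cn <- df$copyNumber
    if (!GenomicRanges::isDisjoint(gr))
        stop("segments overlap within a chromosome")
    gr
}

#' Aggregate copy-number segments to chromosome arms
#'
#' Arm copy number is the length-weighted mean of segment copy numbers over
#' the intersection of the segments with the arm interval.  Arms whose
#' segment coverage falls below `minCoverage` (fraction of the arm length)
#' are flagged missing (`NA`) with a warning and should be dropped from
#' downstream concordance.
#'
#' @param segments `GRanges` with a `cn` metadata column (see
#'   [readSegments()]), or a `data.frame` accepted by [segmentRanges()].
#' @param arms arm `GRanges`.
#' @param minCoverage minimum covered fraction per arm (default 0.5).
#' @param includedOnly restrict to included arms (default `TRUE`).
#' @return Named numeric vector of arm copy numbers (`NA` = insufficient
#'   coverage).
#' @export
segmentsToArmCN <- function(segments, arms, minCoverage = 0.5,
                            includedOnly = TRUE) {
    .checkArms(arms)
    if (is.data.frame(segments)) segments <- segmentRanges(segments)
    if (includedOnly)
        arms <- arms[S4Vectors::mcols(arms)$included]
    hits <- suppressWarnings(GenomicRanges::findOverlaps(arms, segments))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    pint <- suppressWarnings(GenomicRanges::pintersect(arms[qh],
                                                       segments[sh]))
    w <- GenomicRanges::width(pint)
    cn <- S4Vectors::mcols(segments)$cn[sh]
    wsum <- tapply(w, qh, sum)
    wcn <- tapply(w * cn, qh, sum)
    out <- setNames(rep(NA_real_, length(arms)),
                    S4Vectors::mcols(arms)$armName)
    idx <- as.integer(names(wsum))
    cov <- as.numeric(wsum) / GenomicRanges::width(arms)[idx]
    val <- as.numeric(wcn) / as.numeric(wsum)
    val[cov < minCoverage] <- NA_real_
    out[idx] <- val
    low <- is.na(out)
    if (any(low))
        warning("arm(s) below coverage minimum, flagged missing: ",
                paste(names(out)[low], collapse = ", "))
    out
}

#' Expected normal copy number per arm (male)
#'
#' Two copies for autosomal arms, one for chrX arms (male cohort).
#'
#' @param arms arm `GRanges`.
#' @param includedOnly restrict to included arms (default `TRUE`).
#' @return Named numeric vector.
#' @export
expectedCnMale <- function(arms, includedOnly = TRUE) {
    .checkArms(arms)
    if (includedOnly)
        arms <- arms[S4Vectors::mcols(arms)$included]
    isX <- .stripChr(GenomicRanges::seqnames(arms)) == "X"
    setNames(ifelse(isX, 1, 2), S4Vectors::mcols(arms)$armName)
}

#' Log2 relative copy-number deviation per arm
#'
#' `log2(max(cn, cnFloor) / expected)`: 0 for a normal arm, 1 for a
#' doubled autosomal arm, negative for losses.  The floor bounds the log
#' for homozygous-deletion segments (cn near 0).
#'
#' @param armCn named numeric of arm copy numbers
#'   (see [segmentsToArmCN()]); `NA` entries propagate.
#' @param expectedCn named numeric of expected normal copy numbers
#'   (see [expectedCnMale()]).
#' @param cnFloor lower bound on copy number before taking logs
#'   (default 0.1 copies).
#' @return Named numeric vector of log2 deviations over the arms of
#'   `expectedCn`.
#' @export
armLog2Deviation <- function(armCn, expectedCn, cnFloor = 0.1) {
    if (any(expectedCn <= 0)) stop("expected copy numbers must be positive")
    missing <- setdiff(names(expectedCn), names(armCn))
    if (length(missing))
        stop("arm copy number missing for: ",
             paste(missing, collapse = ", "))
    cn <- armCn[names(expectedCn)]
    log2(pmax(cn, cnFloor) / expectedCn)
}

#' Tissue-cfDNA arm-level concordance
#'
#' Spearman rank correlation (average ranks for ties) between a sample's
#' tissue arm log2 copy-number deviations and its cfDNA arm Z-scores, over
#' the arms present (non-`NA`) in both inputs.
#'
#' @param tissueLog2 named numeric from [armLog2Deviation()].
#' @param z named numeric (one sample's column of [armZscores()]).
#' @param minArms minimum number of shared arms (default 10).
#' @return `data.frame` with columns `rho`, `pValue`, `nArms`.
#' @export
cnaConcordance <- function(tissueLog2, z, minArms = 10L) {
    if (is.matrix(z)) {
        if (ncol(z) != 1)
            stop("'z' must be a single sample's Z-score vector")
        z <- setNames(z[, 1], rownames(z))
    }
    shared <- intersect(names(tissueLog2)[!is.na(tissueLog2)],
                        names(z)[!is.na(z)])
    if (length(shared) < minArms)
        stop("insufficient arms: ", length(shared), " shared, need >= ",
             minArms)
    ct <- suppressWarnings(cor.test(tissueLog2[shared], z[shared],
                                    method = "spearman", exact = FALSE))
    data.frame(rho = unname(ct$estimate), pValue = ct$p.value,
               nArms = length(shared))
}
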