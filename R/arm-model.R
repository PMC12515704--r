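## Arm model: chromosome-arm definitions from cytoband annotations, per-arm
## read counting, and the library-size QC rule.

# Arms excluded from normalization and scoring: acrocentric short arms carry
# too few LINE-1 amplicons, and chrY is dropped entirely.
.DEFAULT_EXCLUDED <- c("13p", "14p", "15p", "21p", "22p", "Yp", "Yq")

.stripChr <- function(x) sub("^chr", "", as.character(x))

.checkArms <- function(arms) {
    if (!is(arms, "GRanges"))
        stop("'arms' must be a GRanges as returned by loadCytobands()")
    need <- c("armName", "arm", "included", "weight")
    if (!all(need %in% names(S4Vectors::mcols(arms))))
        stop("'arms' must carry metadata columns: ",
             paste(need, collapse = ", "))
    if (any(S4Vectors::mcols(arms)$weight[S4Vectors::mcols(arms)$included] <= 0))
        stop("included arms must have positive weight")
    invisible(arms)
}

#' Included arm labels of an arm model
#'
#' @param arms arm `GRanges` from [loadCytobands()] or [hg38Arms()].
#' @return Character vector of arm labels (e.g. `"1p"`, `"Xq"`) flagged as
#'   included.
#' @export
includedArms <- function(arms) {
    .checkArms(arms)
    S4Vectors::mcols(arms)$armName[S4Vectors::mcols(arms)$included]
}

#' Build chromosome-arm definitions from a UCSC cytoband table
#'
#' Derives one p and one q arm per chromosome from Giemsa band annotations:
#' the p arm spans from position 0 to the start of the first centromeric
#' (`acen`) band, the q arm from the end of the last `acen` band to the
#' chromosome end.  Positions inside the centromeric gap belong to no arm.
#' Coordinates are 0-based half-open in the input and are represented
#' 1-based closed in the returned `GRanges` (the usual Bioconductor
#' convention).
#'
#' The default exclusion flags mark the short arms of chromosomes 13, 14,
#' 15, 21 and 22 plus both chrY arms as excluded; all other arms of chr1-22
#' and chrX are included (41 arms).  Arm weights default to arm length, a
#' stand-in for relative LINE-1 amplicon abundance.
#'
#' @param cytobands path to a tab-separated UCSC-style cytoBand file
#'   (columns: chrom, start, end, band, stain; no header), or an equivalent
#'   `data.frame`.
#' @param excluded character vector of arm labels to flag as excluded.
#' @return `GRanges` with one range per arm and metadata columns `armName`
#'   (e.g. `"8q"`), `arm` (`"p"`/`"q"`), `included` and `weight`.
#' @examples
#' arms <- hg38Arms()
#' length(arms)              # 48 arms
#' sum(arms$included)        # 41 included
#' @export
loadCytobands <- function(cytobands, excluded = .DEFAULT_EXCLUDED) {
    if (is.character(cytobands)) {
        tab <- tryCatch(
            read.table(cytobands, sep = "\t", header = FALSE,
                       stringsAsFactors = FALSE,
                       col.names = c("chrom", "start", "end", "band",
                                     "stain")),
            error = function(e) stop("malformed cytoband file: ",
                                     conditionMessage(e)))
    } else {
        tab <- as.data.frame(cytobands)
        if (ncol(tab) < 5)
            stop("cytoband table needs 5 columns: ",
                 "chrom, start, end, band, stain")
        names(tab)[1:5] <- c("chrom", "start", "end", "band", "stain")
    }
    bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$start < 0 | tab$end <= tab$start)
    if (length(bad))
        stop("malformed cytoband row at line ", bad[1])

    chroms <- unique(tab$chrom)
    out <- lapply(chroms, function(ch) {
        sub <- tab[tab$chrom == ch, , drop = FALSE]
        acen <- sub[sub$stain == "acen", , drop = FALSE]
        if (nrow(acen) == 0)
            stop("chromosome ", ch, " has no acen (centromere) band")
        pEnd <- min(acen$start)
        qStart <- max(acen$end)
        chromEnd <- max(sub$end)
        if (pEnd <= 0 || qStart >= chromEnd)
            stop("degenerate arm on chromosome ", ch)
        base <- .stripChr(ch)
        data.frame(chrom = ch,
                   start = c(0, qStart), end = c(pEnd, chromEnd),
                   arm = c("p", "q"),
                   armName = paste0(base, c("p", "q")),
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end))
    S4Vectors::mcols(gr)$armName <- df$armName
    S4Vectors::mcols(gr)$arm <- df$arm
    base <- .stripChr(df$chrom)
    S4Vectors::mcols(gr)$included <-
        !(df$armName %in% excluded) & base %in% c(as.character(1:22), "X")
    S4Vectors::mcols(gr)$weight <- as.numeric(GenomicRanges::width(gr))
    names(gr) <- df$armName
    gr
}

#' Human (hg38) chromosome-arm model
#'
#' Arm definitions derived from a condensed hg38 cytoband annotation shipped
#' with the package (p-terminus, centromeric `acen` pair and q-terminus per
#' chromosome).  48 arms, of which 41 are included by default.
#'
#' @inheritParams loadCytobands
#' @return `GRanges`, see [loadCytobands()].
#' @export
hg38Arms <- function(excluded = .DEFAULT_EXCLUDED) {
    path <- system.file("extdata", "cytoband_hg38_condensed.tsv",
                        package = "aneuscore", mustWork = TRUE)
    loadCytobands(path, excluded = excluded)
}

#' Write arm definitions as BED
#'
#' @param arms arm `GRanges`.
#' @param path output file.  BED is 0-based half-open; names are
#'   `chrom_arm` (e.g. `chr8_q`).
#' @return `path`, invisibly.
#' @export
writeArmBed <- function(arms, path) {
    .checkArms(arms)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(arms)),
        start = GenomicRanges::start(arms) - 1L,
        end = GenomicRanges::end(arms),
        name = paste0(as.character(GenomicRanges::seqnames(arms)), "_",
                      S4Vectors::mcols(arms)$arm),
        score = as.integer(S4Vectors::mcols(arms)$included),
        strand = ".")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Construct an ArmCounts object
#'
#' Assembles raw per-arm read counts into an [ArmCounts-class] container,
#' computing `total_reads` (sum over included arms) and the `qc_pass` flag
#' per sample.  Counts for arms absent from `counts` are filled with zero;
#' rows are ordered to match `arms`.
#'
#' @param counts numeric matrix (arms x samples) with arm labels as
#'   rownames, or a named vector for a single sample.  Rows for every
#'   included arm must be present.
#' @param arms arm `GRanges` from [loadCytobands()] / [hg38Arms()].
#' @param sampleIds character, sample identifiers (defaults to the matrix
#'   column names).
#' @param timepoint `"baseline"` or `"early"`, recycled across samples.
#' @param minReads QC floor on `total_reads` (default 90,000 reads).
#' @return An [ArmCounts-class] object.
#' @examples
#' arms <- hg38Arms()
#' x <- simulateCfdna(diploidProfile(arms), arms, n = 2, seed = 1)
#' colData(x)
#' @export
ArmCounts <- function(counts, arms, sampleIds = NULL,
                      timepoint = "baseline", minReads = 90000L) {
    .checkArms(arms)
    if (is.null(dim(counts)))
        counts <- matrix(counts, ncol = 1,
                         dimnames = list(names(counts), NULL))
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("'counts' must have arm labels as rownames")
    armNames <- S4Vectors::mcols(arms)$armName
    inc <- S4Vectors::mcols(arms)$included
    missingInc <- setdiff(armNames[inc], rownames(counts))
    if (length(missingInc))
        stop("counts missing for included arm(s): ",
             paste(missingInc, collapse = ", "))
    full <- matrix(0, nrow = length(armNames), ncol = ncol(counts),
                   dimnames = list(armNames, colnames(counts)))
    keep <- intersect(rownames(counts), armNames)
    full[keep, ] <- counts[keep, , drop = FALSE]
    if (is.null(sampleIds))
        sampleIds <- colnames(counts)
    if (is.null(sampleIds))
        sampleIds <- paste0("sample", seq_len(ncol(full)))
    colnames(full) <- sampleIds
    timepoint <- match.arg(rep(timepoint, length.out = ncol(full)),
                           c("baseline", "early"), several.ok = TRUE)
    totals <- colSums(full[inc, , drop = FALSE])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = full),
        rowRanges = arms,
        colData = S4Vectors::DataFrame(
            sample_id = sampleIds,
            timepoint = timepoint,
            total_reads = as.integer(round(totals)),
            qc_pass = totals >= minReads,
            row.names = sampleIds))
    new("ArmCounts", se)
}

#' Library-size QC check
#'
#' A sample passes QC when its total read count over included arms reaches
#' `minReads` (default 90,000).  The boundary is inclusive: exactly
#' `minReads` reads pass.
#'
#' @param x an [ArmCounts-class] object.
#' @param minReads integer QC floor.
#' @return For `ArmCounts`, the object with its `qc_pass` column updated
#'   against `minReads`.  Use `colData(x)$qc_pass` to inspect the flags.
#' @export
setMethod("qcCheck", "ArmCounts", function(x, minReads = 90000L) {
    SummarizedExperiment::colData(x)$qc_pass <-
        SummarizedExperiment::colData(x)$total_reads >= minReads
    x
})

#' Count aligned reads per chromosome arm
#'
#' Assigns each read to the unique arm whose half-open interval contains
#' its leftmost aligned position.  Reads below `minMapq`, unmapped reads,
#' reads on contigs absent from the arm model, and reads falling in the
#' centromeric gap are discarded.  Counts on excluded arms are retained in
#' the profile but do not contribute to `total_reads`.
#'
#' @param reads one of: a `data.frame` with columns `chrom`, `pos`
#'   (1-based leftmost position) and optionally `mapq`; a `GRanges` (start
#'   used as leftmost position, optional `mapq` metadata column); or the
#'   path to a BAM file (requires the Rsamtools package).
#' @param arms arm `GRanges`.
#' @param minMapq minimum mapping quality (default 30).
#' @param sampleId sample identifier for the resulting profile.
#' @inheritParams ArmCounts
#' @return A single-sample [ArmCounts-class] object.  If no read passes the
#'   filters the profile has all-zero counts and fails QC (not an error).
#' @export
countReadsPerArm <- function(reads, arms, minMapq = 30L,
                             sampleId = "sample1", timepoint = "baseline",
                             minReads = 90000L) {
    .checkArms(arms)
    if (is.character(reads)) {
        if (!requireNamespace("Rsamtools", quietly = TRUE))
            stop("reading BAM input requires the Rsamtools package")
        res <- Rsamtools::scanBam(reads, param = Rsamtools::ScanBamParam(
            what = c("rname", "pos", "mapq"),
            flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
        reads <- data.frame(chrom = as.character(res$rname), pos = res$pos,
                            mapq = res$mapq)
    } else if (is(reads, "GRanges")) {
        mapq <- S4Vectors::mcols(reads)$mapq
        reads <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                            pos = GenomicRanges::start(reads),
                            mapq = if (is.null(mapq)) NA_integer_ else mapq)
    }
    if (!all(c("chrom", "pos") %in% names(reads)))
        stop("'reads' must provide 'chrom' and 'pos'")
    mapq <- if ("mapq" %in% names(reads)) reads$mapq else
        rep(NA_integer_, nrow(reads))
    keep <- !is.na(reads$pos) & (is.na(mapq) | mapq >= minMapq)
    reads <- reads[keep, , drop = FALSE]
    cnt <- setNames(numeric(length(arms)), S4Vectors::mcols(arms)$armName)
    if (nrow(reads)) {
        gp <- GenomicRanges::GRanges(reads$chrom,
                                     IRanges::IRanges(reads$pos, width = 1L))
        hits <- suppressWarnings(GenomicRanges::findOverlaps(gp, arms))
        tab <- table(S4Vectors::subjectHits(hits))
        cnt[as.integer(names(tab))] <- as.numeric(tab)
    }
    ArmCounts(cnt, arms, sampleIds = sampleId, timepoint = timepoint,
              minReads = minReads)
}

#' Read and write arm count matrices
#'
#' The TSV interchange format has arms as rows (first column `arm`) and
#' samples as columns; sample metadata travels in a companion TSV with
#' columns `sample_id`, `timepoint`, `total_reads`, `qc_pass`.
#'
#' @param x an [ArmCounts-class] object.
#' @param countsFile,metaFile file paths.
#' @param arms arm `GRanges` used to reassemble the object.
#' @param minReads QC floor applied on re-ingestion.
#' @return `writeCountMatrix` returns `countsFile` invisibly;
#'   `readCountMatrix` returns an [ArmCounts-class] object.
#' @export
writeCountMatrix <- function(x, countsFile, metaFile = NULL) {
    stopifnot(is(x, "ArmCounts"))
    cnt <- SummarizedExperiment::assay(x, "counts")
    df <- data.frame(arm = rownames(cnt), cnt, check.names = FALSE)
    write.table(df, countsFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(metaFile)) {
        cd <- as.data.frame(SummarizedExperiment::colData(x))
        write.table(cd, metaFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(countsFile)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(countsFile, arms, metaFile = NULL,
                            minReads = 90000L) {
    df <- read.table(countsFile, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
    cnt <- as.matrix(df[, -1, drop = FALSE])
    rownames(cnt) <- df[[1]]
    timepoint <- "baseline"
    if (!is.null(metaFile)) {
        meta <- read.table(metaFile, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
        idx <- match(colnames(cnt), meta$sample_id)
        if (!anyNA(idx)) timepoint <- meta$timepoint[idx]
    }
    ArmCounts(cnt, arms, timepoint = timepoint, minReads = minReads)
}
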