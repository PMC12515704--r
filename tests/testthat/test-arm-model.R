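test_that("cytoband parsing builds half-open arms around the centromere", {
    arms <- toyArms()
    expect_equal(length(arms), 4L)
    p1 <- arms[arms$armName == "1p"]
    q1 <- arms[arms$armName == "1q"]
    # [0, 50) and [60, 100) in 0-based half-open coordinates
    expect_equal(GenomicRanges::start(p1) - 1L, 0L)
    expect_equal(GenomicRanges::end(p1), 50L)
    expect_equal(GenomicRanges::start(q1) - 1L, 60L)
    expect_equal(GenomicRanges::end(q1), 100L)
    expect_true(all(arms$included))
    expect_true(all(arms$weight > 0))
})

test_that("the human arm model has 48 arms with the default exclusions", {
    arms <- hg38Arms()
    expect_equal(length(arms), 48L)
    expect_equal(sum(arms$included), 41L)
    excl <- arms$armName[!arms$included]
    expect_setequal(excl, c("13p", "14p", "15p", "21p", "22p", "Yp", "Yq"))
    expect_false(arms[arms$armName == "13p"]$included)
    expect_true(arms[arms$armName == "13q"]$included)
    expect_true(all(c("Xp", "Xq") %in% includedArms(arms)))
    # p and q arms of one chromosome never overlap
    for (ch in unique(as.character(GenomicRanges::seqnames(arms)))) {
        sub <- arms[as.character(GenomicRanges::seqnames(arms)) == ch]
        expect_true(GenomicRanges::isDisjoint(sub))
    }
})

test_that("cytoband parsing rejects broken inputs", {
    tab <- toyCytobands()
    noAcen <- tab[tab$stain != "acen" | tab$chrom != "chr2", ]
    expect_error(loadCytobands(noAcen), "chr2")
    bad <- tab
    bad$end[3] <- bad$start[3]          # zero-width band
    expect_error(loadCytobands(bad), "line 3")
})

test_that("reads are assigned to arms by leftmost position, half-open", {
    arms <- toyArms()
    reads <- data.frame(
        chrom = c("chr1", "chr1", "chr1", "chr1"),
        pos = c(1, 10, 49, 70),   # 1-based leftmost positions
        mapq = 60)
    prof <- countReadsPerArm(reads, arms)
    cnt <- SummarizedExperiment::assay(prof, "counts")[, 1]
    expect_equal(unname(cnt[c("1p", "1q")]), c(3, 1))

    # 0-based position 50 is 1p's end coordinate: falls in the centromeric
    # gap [50, 60) and is discarded; 0-based 60 is the first base of 1q.
    boundary <- data.frame(chrom = "chr1", pos = c(50, 60) + 1L, mapq = 60)
    cnt2 <- SummarizedExperiment::assay(
        countReadsPerArm(boundary, arms), "counts")[, 1]
    expect_equal(unname(cnt2[c("1p", "1q")]), c(0, 1))
})

test_that("read filters drop low-mapq, unmapped and off-model reads", {
    arms <- toyArms()
    reads <- data.frame(
        chrom = c("chr1", "chr1", "chrUn", "chr2", "chr2"),
        pos = c(5, 5, 5, 10, NA),
        mapq = c(60, 10, 60, NA, 60))
    prof <- countReadsPerArm(reads, arms, minMapq = 30)
    cnt <- SummarizedExperiment::assay(prof, "counts")[, 1]
    # low-mapq and off-contig dropped; NA mapq kept; NA pos dropped
    expect_equal(sum(cnt), 2)
    expect_equal(unname(cnt["1p"]), 1)
    expect_equal(unname(cnt["2p"]), 1)
    # no reads passing filters: all-zero profile failing QC, not an error
    empty <- countReadsPerArm(
        data.frame(chrom = "chr1", pos = 5, mapq = 1), arms)
    expect_equal(sum(SummarizedExperiment::assay(empty, "counts")), 0)
    expect_false(SummarizedExperiment::colData(empty)$qc_pass)
})

test_that("counting is order-independent and conserves filtered reads", {
    arms <- toyArms()
    set.seed(42)
    reads <- data.frame(
        chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
        pos = sample.int(120, 500, replace = TRUE),
        mapq = sample(c(0, 60), 500, replace = TRUE))
    a <- countReadsPerArm(reads, arms)
    b <- countReadsPerArm(reads[sample.int(500), ], arms)
    expect_identical(SummarizedExperiment::assay(a, "counts"),
                     SummarizedExperiment::assay(b, "counts"))
    # total over ALL arms equals the number of reads passing filters and
    # landing outside the centromeric gaps
    inGap <- (reads$chrom == "chr1" & reads$pos >= 51 & reads$pos <= 60) |
             (reads$chrom == "chr2" & reads$pos >= 41 & reads$pos <= 50)
    offEnd <- reads$chrom == "chr1" & reads$pos > 100
    kept <- reads$mapq >= 30 & !inGap & !offEnd
    expect_equal(sum(SummarizedExperiment::assay(a, "counts")), sum(kept))
})

test_that("deep uniform read sets pass QC at the 90,000-read floor", {
    arms <- hg38Arms()
    set.seed(7)
    x <- simulateCfdna(diploidProfile(arms), arms, n = 1, depth = 1e5)
    expect_equal(SummarizedExperiment::colData(x)$total_reads, 100000L)
    expect_true(SummarizedExperiment::colData(x)$qc_pass)
})

test_that("QC boundary is inclusive and configurable", {
    arms <- toyArms()
    mk <- function(n) {
        cnt <- c("1p" = n, "1q" = 0, "2p" = 0, "2q" = 0)
        ArmCounts(cnt, arms)
    }
    expect_true(SummarizedExperiment::colData(mk(90000))$qc_pass)
    expect_false(SummarizedExperiment::colData(mk(89999))$qc_pass)
    relaxed <- qcCheck(mk(1), minReads = 0L)
    expect_true(SummarizedExperiment::colData(relaxed)$qc_pass)
})

test_that("total_reads sums included arms only", {
    arms <- toyArms(excluded = c("2p", "2q"))
    x <- ArmCounts(c("1p" = 100, "1q" = 50, "2p" = 999, "2q" = 1),
                   arms, minReads = 100L)
    expect_equal(SummarizedExperiment::colData(x)$total_reads, 150L)
    # excluded-arm counts are retained for diagnostics
    expect_equal(
        unname(SummarizedExperiment::assay(x, "counts")["2p", 1]), 999)
})

test_that("count matrices round-trip through the TSV interchange format", {
    arms <- toyArms()
    set.seed(1)
    x <- simulateCfdna(diploidProfile(arms), arms, n = 3, depth = 5000,
                       minReads = 1000L)
    cf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
    writeCountMatrix(x, cf, mf)
    y <- readCountMatrix(cf, arms, mf, minReads = 1000L)
    expect_equal(SummarizedExperiment::assay(y, "counts"),
                 SummarizedExperiment::assay(x, "counts"))
    expect_equal(SummarizedExperiment::colData(y)$total_reads,
                 SummarizedExperiment::colData(x)$total_reads)
})

test_that("arm BED export is 0-based half-open", {
    arms <- toyArms()
    bed <- tempfile(fileext = ".bed")
    writeArmBed(arms, bed)
    tab <- read.table(bed, sep = "\t")
    expect_equal(tab$V2[tab$V4 == "chr1_p"], 0)
    expect_equal(tab$V3[tab$V4 == "chr1_p"], 50)
    expect_equal(tab$V2[tab$V4 == "chr1_q"], 60)
})

test_that("BAM input is counted like coordinate triples", {
    skip_if_not_installed("Rsamtools")
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        "@SQ\tSN:chr1\tLN:100",
        "@SQ\tSN:chr2\tLN:120",
        "r1\t0\tchr1\t5\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*",
        "r2\t0\tchr1\t70\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*",
        "r3\t0\tchr1\t8\t5\t10M\t*\t0\t0\tAAAAAAAAAA\t*",   # low mapq
        "r4\t4\t*\t0\t0\t*\t*\t0\t0\tAAAAAAAAAA\t*",        # unmapped
        "r5\t0\tchr2\t12\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*"),
        sam)
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
    prof <- countReadsPerArm(bam, toyArms(), minMapq = 30)
    cnt <- SummarizedExperiment::assay(prof, "counts")[, 1]
    expect_equal(unname(cnt[c("1p", "1q", "2p")]), c(1, 1, 1))
})
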