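test_that("BED dialect records map directly onto read fields", {
    tf <- withr::local_tempfile(fileext = ".bed")
    writeLines(c(
        "#chrom\tstart\tend\tname\tscore\tstrand\tsequence\tcopy_number\tedit_distance\tn_mapping_loci",
        paste("chr1", 100, 126, "seq1_x3", 0, "+",
            strrep("A", 26), sep = "\t")), tf)
    gr <- parseMappedReads(tf, "bed")
    expect_length(gr, 1)
    expect_equal(as.character(seqnames(gr)), "chr1")
    expect_equal(as.character(strand(gr)), "+")
    expect_equal(start(gr), 101)  # 0-based 100
    expect_equal(width(gr), 26)
    expect_equal(mcols(gr)$copy_number, 3L)  # from the *_xN name
    expect_equal(fivePrimeEnd(gr), 100L)
})

test_that("an empty stream parses to an empty read list", {
    tf <- withr::local_tempfile(fileext = ".bed")
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", tf)
    gr <- parseMappedReads(tf)
    expect_length(gr, 0)
    expect_true(all(c("sequence", "copy_number", "edit_distance",
        "n_mapping_loci") %in% names(mcols(gr))))
})

test_that("BED parse errors name the offending line", {
    tf <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t36\tr1\t0\t+", "chr1\t10\t36"), tf)
    expect_error(parseMappedReads(tf), "line 2")
    writeLines(c("chr1\t10\t36\tr1\t0\t?"), tf)
    expect_error(parseMappedReads(tf), "strand")
    writeLines(c(paste("chr1", 10, 36, "r1", 0, "+", "ACGT", sep = "\t")), tf)
    expect_error(parseMappedReads(tf), "sequence length")
})

test_that("SAM minus-strand coordinates follow the format's 1-based rules", {
    ## flag 16, POS 101 (1-based), 19M: 0-based start 100, 5' end at 118
    tf <- withr::local_tempfile(fileext = ".sam")
    seq19 <- strrep("C", 19)
    writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000",
        paste("r1_x2", 16, "chr1", 101, 255, "19M", "*", 0, 0, seq19, "*",
            "NM:i:0", "NH:i:1", sep = "\t")), tf)
    gr <- parseMappedReads(tf, "sam")
    expect_equal(as.character(strand(gr)), "-")
    expect_equal(start(gr) - 1L, 100L)
    expect_equal(width(gr), 19L)
    expect_equal(fivePrimeEnd(gr), 118L)
    expect_equal(mcols(gr)$copy_number, 2L)
    ## stored SEQ is genomic plus-strand; the read's own sequence is its
    ## reverse complement
    expect_equal(mcols(gr)$sequence, strrep("G", 19))
})

test_that("SAM multi-mapper status falls back to query-name collisions", {
    tf <- withr::local_tempfile(fileext = ".sam")
    seq20 <- strrep("A", 20)
    writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000",
        paste("dup", 0, "chr1", 11, 255, "20M", "*", 0, 0, seq20, "*", sep = "\t"),
        paste("dup", 0, "chr1", 211, 255, "20M", "*", 0, 0, seq20, "*", sep = "\t"),
        paste("uni", 0, "chr1", 411, 255, "20M", "*", 0, 0, seq20, "*", sep = "\t")),
        tf)
    gr <- parseMappedReads(tf, "sam")
    expect_equal(mcols(gr)$n_mapping_loci[mcols(gr)$name == "uni"], 1L)
    expect_true(all(mcols(gr)$n_mapping_loci[mcols(gr)$name == "dup"] == 2L))
})

test_that("filtering keeps exactly the unique perfect mappers", {
    set.seed(11)
    gr <- makeReads(
        chrom = c(rep("chr1", 9), "chrM"),
        strand = "+", fp = (1:10) * 100, len = 26,
        nh = c(2, 2, 2, 1, 1, 1, 1, 1, 1, 1),
        ed = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0))
    kept <- filterUniquePerfect(gr)
    expect_length(kept, 4)
    expect_true(all(mcols(kept)$n_mapping_loci == 1L))
    expect_true(all(mcols(kept)$edit_distance == 0L))
    expect_false("chrM" %in% as.character(seqnames(kept)))
    ## idempotent, order preserved
    expect_identical(filterUniquePerfect(kept), kept)
    expect_identical(fivePrimeEnd(kept), sort(fivePrimeEnd(kept)))
})

test_that("collapsing sums copy numbers per 5' position within the class", {
    set.seed(12)
    gr <- makeReads("chr1", "+", fp = c(100, 100), len = c(26, 30),
        copy = c(3, 4))
    maps <- collapseToLoci(gr, "long")
    expect_equal(unname(positionWeights(weightMap(maps, "chr1", "+"))), 7)
    expect_equal(fivePrimePositions(weightMap(maps, "chr1", "+")), 100L)
    ## same input under an exact-19 class contributes nothing
    empty <- collapseToLoci(gr, "exact19")
    expect_length(fivePrimePositions(weightMap(empty, "chr1", "+")), 0)
    expect_error(lengthClass(c(30, 20)), "interval")
})

test_that("collapsed weights match a brute-force per-position tally", {
    for (seed in 1:3) {
        set.seed(seed)
        n <- 60
        gr <- makeReads(
            chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
            strand = sample(c("+", "-"), n, replace = TRUE),
            fp = sample(50:150, n, replace = TRUE),
            len = sample(15:35, n, replace = TRUE),
            copy = sample(1:5, n, replace = TRUE))
        lc <- c(23L, 32L)
        maps <- collapseToLoci(gr, lc)
        inClass <- gr[width(gr) >= lc[1] & width(gr) <= lc[2]]
        ## conservation: weights sum to the total in-class copy number
        total <- sum(vapply(chromosomes(maps), function(chr)
            sum(positionWeights(weightMap(maps, chr, "+")),
                positionWeights(weightMap(maps, chr, "-"))), numeric(1)))
        expect_equal(total, sum(mcols(inClass)$copy_number))
        ## per-position double-loop tally
        for (chr in c("chr1", "chr2")) for (st in c("+", "-")) {
            sel <- inClass[as.character(seqnames(inClass)) == chr &
                as.character(strand(inClass)) == st]
            expected <- c(tapply(mcols(sel)$copy_number,
                fivePrimeEnd(sel), sum))
            got <- positionWeights(weightMap(maps, chr, st))
            expect_equal(got[order(as.integer(names(got)))],
                expected[order(as.integer(names(expected)))],
                tolerance = 1e-12, ignore_attr = FALSE)
        }
    }
})

test_that("the BED dialect round-trips reads exactly", {
    set.seed(13)
    gr <- makeReads(
        chrom = sample(c("chr1", "chr2"), 25, replace = TRUE),
        strand = sample(c("+", "-"), 25, replace = TRUE),
        fp = sample(100:900, 25), len = sample(15:35, 25, replace = TRUE),
        copy = sample(1:9, 25, replace = TRUE))
    tf <- withr::local_tempfile(fileext = ".bed")
    writeBedReads(gr, tf)
    back <- parseMappedReads(tf)
    expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
    expect_equal(start(back), start(gr))
    expect_equal(end(back), end(gr))
    expect_equal(as.character(strand(back)), as.character(strand(gr)))
    expect_identical(as.data.frame(mcols(back)), as.data.frame(mcols(gr)))
})

test_that("SAM output round-trips through the SAM parser", {
    set.seed(14)
    gr <- makeReads(
        chrom = "chr1", strand = sample(c("+", "-"), 10, replace = TRUE),
        fp = sample(200:800, 10), len = sample(19:30, 10, replace = TRUE),
        copy = sample(1:4, 10, replace = TRUE))
    tf <- withr::local_tempfile(fileext = ".sam")
    writeSamReads(gr, tf)
    back <- parseMappedReads(tf, "sam")
    o <- order(start(back), as.character(strand(back)))
    og <- order(start(gr), as.character(strand(gr)))
    expect_equal(start(back)[o], start(gr)[og])
    expect_equal(width(back)[o], width(gr)[og])
    expect_equal(mcols(back)$sequence[o], mcols(gr)$sequence[og])
    expect_equal(mcols(back)$copy_number[o], mcols(gr)$copy_number[og])
})
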