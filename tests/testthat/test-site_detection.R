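test_that("P9 sites require long reads at exactly a 9-nt 5' offset", {
    set.seed(41)
    gr <- makeReads("chr1", c("+", "-"), fp = c(100, 109), len = c(26, 27))
    sites <- detectP9Sites(collapseToLoci(gr, "long"))
    expect_equal(nrow(sites), 1)
    expect_equal(sites$fp_a, 100L)
    expect_equal(sites$fp_b, 109L)
    expect_equal(sites$center, 104L)
    ## one nucleotide off: no site
    gr2 <- makeReads("chr1", c("+", "-"), fp = c(100, 108), len = c(26, 27))
    expect_equal(nrow(detectP9Sites(collapseToLoci(gr2, "long"))), 0)
})

test_that("P9 detection equals a brute-force scan on random maps", {
    for (seed in 1:5) {
        set.seed(seed + 100)
        gr <- makeReads("chr1",
            strand = sample(c("+", "-"), 80, replace = TRUE),
            fp = sample(0:300, 80, replace = TRUE),
            len = sample(23:32, 80, replace = TRUE))
        maps <- collapseToLoci(gr, "long")
        sites <- detectP9Sites(maps)
        expect_equal(sites$fp_a, oracleP9Positions(
            weightMap(maps, "chr1", "+"), weightMap(maps, "chr1", "-")))
    }
})

test_that("site lists are stable under input permutation", {
    set.seed(42)
    gr <- makeReads("chr1",
        strand = sample(c("+", "-"), 60, replace = TRUE),
        fp = sample(0:200, 60, replace = TRUE),
        len = sample(c(19L, 23:32), 60, replace = TRUE))
    perm <- sample(length(gr))
    s1 <- detectP9Sites(collapseToLoci(gr, "long"))
    s2 <- detectP9Sites(collapseToLoci(gr[perm], "long"))
    expect_identical(as.data.frame(s1[, c("chrom", "fp_a", "fp_b")]),
        as.data.frame(s2[, c("chrom", "fp_a", "fp_b")]))
    p1 <- detectP28Sites(collapseToLoci(gr, 19L), collapseToLoci(gr, "long"))
    p2 <- detectP28Sites(collapseToLoci(gr[perm], 19L),
        collapseToLoci(gr[perm], "long"))
    expect_identical(as.data.frame(p1[, c("chrom", "orientation", "fp_a")]),
        as.data.frame(p2[, c("chrom", "orientation", "fp_a")]))
})

test_that("P28 sites pair a 19-mer with a long read 28 nt away", {
    set.seed(43)
    ## 19-mer on plus spanning [100,119), long minus 5' at 128: P28T
    gr <- makeReads("chr1", c("+", "-"), fp = c(100, 128), len = c(19, 30))
    sites <- detectP28Sites(collapseToLoci(gr, 19L),
        collapseToLoci(gr, "long"))
    expect_equal(nrow(sites), 1)
    expect_equal(sites$orientation, "P28T")
    expect_equal(sites$fp_a, 100L)
    expect_equal(sites$fp_b, 128L)
    ## mirror image: 19-mer on minus at 128, long plus at 100: P28B
    gr2 <- makeReads("chr1", c("-", "+"), fp = c(128, 100), len = c(19, 26))
    sites2 <- detectP28Sites(collapseToLoci(gr2, 19L),
        collapseToLoci(gr2, "long"))
    expect_equal(nrow(sites2), 1)
    expect_equal(sites2$orientation, "P28B")
    expect_equal(sites2$fp_a, 128L)
    expect_equal(sites2$fp_b, 100L)
    ## an 18-mer does not satisfy the exact-19 short class
    gr3 <- makeReads("chr1", c("+", "-"), fp = c(100, 128), len = c(18, 30))
    expect_equal(nrow(detectP28Sites(collapseToLoci(gr3, 19L),
        collapseToLoci(gr3, "long"))), 0)
    ## but is found when the short class is set to exactly 18
    expect_equal(nrow(detectP28Sites(collapseToLoci(gr3, 18L),
        collapseToLoci(gr3, "long"))), 1)
})

test_that("members at one 5' coordinate group into a single site", {
    set.seed(44)
    gr <- makeReads("chr1", c("+", "-", "-"), fp = c(100, 128, 128),
        len = c(19, 26, 30), copy = c(2, 3, 4))
    sites <- detectP28Sites(collapseToLoci(gr, 19L),
        collapseToLoci(gr, "long"))
    expect_equal(nrow(sites), 1)
    expect_equal(unname(lengths(sites$members_b)), 2L)
    expect_equal(sort(unlist(sites$lengths_b)), c(26L, 30L),
        ignore_attr = TRUE)
})

test_that("cleavage pairs put the product 3' end opposite guide position 11", {
    set.seed(45)
    ## minus guide 5' at 128 (length 30); plus short 3' end at 118 = 128 - 10
    gr <- makeReads("chr1", c("-", "+"), fp = c(128, 100), len = c(30, 19))
    pairs <- extractCleavagePairs(collapseToLoci(gr, "all"))
    expect_equal(nrow(pairs), 1)
    expect_equal(pairs$guide_length, 30L)
    expect_equal(pairs$product_length, 19L)
    expect_equal(pairs$product_3p, 118L)
    ## product 3' end at 117 misses the rule
    gr2 <- makeReads("chr1", c("-", "+"), fp = c(128, 99), len = c(30, 19))
    expect_equal(nrow(extractCleavagePairs(collapseToLoci(gr2, "all"))), 0)
})

test_that("cleavage-pair extraction equals the all-pairs oracle", {
    for (seed in 1:5) {
        set.seed(seed + 200)
        gr <- makeReads("chr1",
            strand = sample(c("+", "-"), 70, replace = TRUE),
            fp = sample(0:250, 70, replace = TRUE),
            len = sample(15:32, 70, replace = TRUE))
        maps <- collapseToLoci(gr, "all")
        pairs <- extractCleavagePairs(maps)
        oracle <- oracleCleavagePairs(
            seqRegistry(weightMap(maps, "chr1", "+")),
            seqRegistry(weightMap(maps, "chr1", "-")))
        expect_equal(nrow(pairs), nrow(oracle))
        if (nrow(pairs)) {
            got <- pairs[order(pairs$product_length, pairs$guide_length),
                c("product_length", "guide_length")]
            exp <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
            expect_equal(unname(as.matrix(got)), unname(exp))
        }
    }
})

test_that("every 19-nt P28 site implies a product-length-19 cleavage pair", {
    ## geometric identity: 5'-to-5' offset 28 = 19 + 9
    ds <- simulateDataset(simulationConfig(nTriplexLoci = 60, seed = 46))
    maps <- collapseToLoci(ds$reads, "all")
    sites <- detectP28Sites(collapseToLoci(ds$reads, 19L),
        collapseToLoci(ds$reads, "long"))
    pairs <- extractCleavagePairs(maps)
    expect_gt(nrow(sites), 0)
    key <- paste(pairs$chrom, pairs$product_5p)
    for (i in seq_len(nrow(sites)))
        expect_true(paste(sites$chrom[i], sites$fp_a[i]) %in% key)
    expect_true(all(pairs$product_length == 19L))
})

test_that("site tables serialize members in the SEQ(count) dialect", {
    set.seed(47)
    gr <- makeReads("chr1", c("+", "-"), fp = c(100, 109), len = c(26, 27),
        seq = c(strrep("A", 26), strrep("G", 27)), copy = c(3, 7))
    sites <- detectP9Sites(collapseToLoci(gr, "long"))
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeSiteTable(sites, tf)
    tab <- read.delim(tf)
    expect_equal(tab$sequences, paste0(strrep("A", 26), "(3)"))
    expect_equal(tab$opposite_sequences, paste0(strrep("G", 27), "(7)"))
    expect_equal(tab$five_prime, 100L)
})
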