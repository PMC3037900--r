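test_that("transition counts and ML estimates follow the state sequence", {
    ## T,T,T,B,B: n_TT=2, n_TB=1, n_BB=1, so p_TT=2/3, p_TB=1/3, p_BB=1
    bias <- estimateStrandBias(fakeP28Sites(c("T", "T", "T", "B", "B")))
    expect_equal(transitionCounts(bias),
        matrix(c(2L, 0L, 1L, 1L), 2, 2,
            dimnames = list(c("T", "B"), c("T", "B"))))
    expect_equal(transitionProbs(bias)["T", "T"], 2 / 3)
    expect_equal(transitionProbs(bias)["T", "B"], 1 / 3)
    expect_equal(transitionProbs(bias)["B", "B"], 1)
    expect_equal(transitionProbs(bias)["B", "T"], 0)
})

test_that("a state never visited leaves its row undefined, not 0/0", {
    bias <- estimateStrandBias(fakeP28Sites(rep("T", 5)))
    expect_equal(transitionProbs(bias)["T", "T"], 1)
    expect_true(all(is.na(transitionProbs(bias)["B", ])))
    expect_equal(bias@nTransitions, 4L)
    ## serialized table flags the undefined row
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeTransitionTable(bias, tf)
    tab <- read.delim(tf)
    expect_true(any(tab$probability == "undefined"))
})

test_that("transitions never cross a chromosome boundary", {
    s1 <- fakeP28Sites(c("T", "T"), chrom = "chr1")
    s2 <- fakeP28Sites(c("B", "B"), chrom = "chr2")
    bias <- estimateStrandBias(rbind(s1, s2))
    expect_equal(bias@nTransitions, 2L)
    expect_equal(transitionCounts(bias)["T", "B"], 0L)
})

test_that("the estimate is symmetric under relabeling T and B", {
    set.seed(61)
    states <- sample(c("T", "B"), 60, replace = TRUE)
    flip <- c(T = "B", B = "T")[states]
    a <- transitionCounts(estimateStrandBias(fakeP28Sites(states)))
    b <- transitionCounts(estimateStrandBias(fakeP28Sites(flip)))
    expect_equal(a, b[c("B", "T"), c("B", "T")], ignore_attr = TRUE)
})

test_that("stay probabilities are recovered within binomial error", {
    n <- 2000
    for (q in c(0.5, 0.9, 0.98)) {
        set.seed(round(q * 1000))
        states <- character(n)
        states[1] <- "T"
        for (k in 2:n) states[k] <- if (runif(1) < q) states[k - 1]
            else c(T = "B", B = "T")[states[k - 1]]
        bias <- estimateStrandBias(fakeP28Sites(states))
        counts <- transitionCounts(bias)
        for (s in c("T", "B")) {
            nRow <- sum(counts[s, ])
            if (nRow == 0) next
            expect_lt(abs(transitionProbs(bias)[s, s] - q),
                3 * sqrt(q * (1 - q) / nRow))
        }
    }
})

test_that("position-1 composition splits by strand relative to the 19-mer", {
    set.seed(62)
    ## one triplex whose opposite-strand (guide) piRNA starts with T -> U
    gr <- makeReads("chr1", c("+", "-", "+"), fp = c(100, 128, 119),
        len = c(19, 30, 26),
        seq = c(strrep("A", 19), paste0("T", strrep("C", 29)),
            paste0("G", strrep("C", 25))))
    long <- collapseToLoci(gr, "long")
    tri <- detectTriplexes(detectP9Sites(long),
        detectP28Sites(collapseToLoci(gr, 19L), long))
    comp <- firstNtFrequencies(tri)
    opp <- comp[comp$group == "opposite", ]
    same <- comp[comp$group == "same_strand", ]
    expect_equal(opp$U, 1)
    expect_equal(same$U, 0)
    expect_equal(same$G, 1)
    expect_equal(rowSums(comp[, c("A", "C", "G", "U")]), c(1, 1),
        ignore_attr = TRUE)
    ## empty triplex list gives an empty report
    expect_equal(nrow(firstNtFrequencies(tri[0, ])), 0)
})

test_that("copy-number weighting changes votes, not groups", {
    set.seed(63)
    gr <- makeReads("chr1", c("+", "-", "-", "+"),
        fp = c(100, 128, 128, 119), len = c(19, 30, 26, 26),
        seq = c(strrep("A", 19), paste0("T", strrep("C", 29)),
            paste0("G", strrep("C", 25)), paste0("T", strrep("C", 25))),
        copy = c(1, 9, 1, 1))
    long <- collapseToLoci(gr, "long")
    tri <- detectTriplexes(detectP9Sites(long),
        detectP28Sites(collapseToLoci(gr, 19L), long))
    un <- firstNtFrequencies(tri, "unweighted")
    wt <- firstNtFrequencies(tri, "copy_number")
    expect_equal(un[un$group == "opposite", "U"], 0.5)  # one T, one G member
    expect_equal(wt[wt$group == "opposite", "U"], 0.9)  # 9 of 10 copies
})

test_that("simulated 1U biases are recovered from triplex loci", {
    ds <- simulateDataset(simulationConfig(nTriplexLoci = 400, seed = 64))
    long <- collapseToLoci(ds$reads, "long")
    tri <- detectTriplexes(detectP9Sites(long),
        detectP28Sites(collapseToLoci(ds$reads, 19L), long))
    comp <- firstNtFrequencies(tri)
    ## binomial 3-sigma bounds at n = 400
    expect_lt(abs(comp[comp$group == "opposite", "U"] - 0.78),
        3 * sqrt(0.78 * 0.22 / 400))
    expect_lt(abs(comp[comp$group == "same_strand", "U"] - 0.44),
        3 * sqrt(0.44 * 0.56 / 400))
})

test_that("the length-pair histogram tallies (product, guide) lengths", {
    pairs <- data.frame(chrom = "chr1", guide_strand = "-",
        guide_5p = 128L, guide_length = 30L, guide_copy = 5,
        guide_seq = "x", product_strand = "+", product_5p = 100L,
        product_3p = 118L, product_length = 19L, product_copy = 2,
        product_seq = "y")
    h <- lengthPairHistogram(pairs)
    expect_equal(h["19", "30"], 1)
    expect_equal(sum(h), 1)
    expect_equal(sum(lengthPairHistogram(pairs, "min_copy")), 2)
    ## brute-force tally comparison on a mixed synthetic set
    set.seed(65)
    gr <- makeReads("chr1", sample(c("+", "-"), 100, replace = TRUE),
        fp = sample(0:400, 100, replace = TRUE),
        len = sample(15:32, 100, replace = TRUE))
    cp <- extractCleavagePairs(collapseToLoci(gr, "all"))
    h2 <- lengthPairHistogram(cp)
    expect_equal(sum(h2), nrow(cp))
    for (k in seq_len(nrow(cp)))
        expect_gte(h2[as.character(cp$product_length[k]),
            as.character(cp$guide_length[k])], 1)
    ## simulated data: the product-length marginal is a spike at 19
    ds <- simulateDataset(simulationConfig(nTriplexLoci = 100, seed = 66))
    marg <- productLengthMarginal(lengthPairHistogram(
        extractCleavagePairs(collapseToLoci(ds$reads, "all"))))
    expect_equal(names(which(marg > 0)), "19")
})
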