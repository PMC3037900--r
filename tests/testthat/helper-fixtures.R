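suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## Build a mapped-read GRanges from 0-based 5'-end coordinates.
makeReads <- function(chrom, strand, fp, len, seq = NA_character_,
        copy = 1L, ed = 0L, nh = 1L, name = NULL) {
    n <- max(length(chrom), length(strand), length(fp), length(len))
    chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
    fp <- rep_len(as.integer(fp), n); len <- rep_len(as.integer(len), n)
    seq <- rep_len(seq, n); copy <- rep_len(as.integer(copy), n)
    ed <- rep_len(as.integer(ed), n); nh <- rep_len(as.integer(nh), n)
    autoseq <- is.na(seq)
    seq[autoseq] <- vapply(len[autoseq], function(l)
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), character(1))
    start1 <- ifelse(strand == "+", fp + 1L, fp - len + 2L)
    gr <- GRanges(chrom, IRanges(start1, width = len), strand = strand)
    mcols(gr) <- DataFrame(
        name = if (is.null(name)) sprintf("r%d", seq_len(n)) else name,
        sequence = seq, copy_number = copy, edit_distance = ed,
        n_mapping_loci = nh)
    gr
}

## Random weight map on one chromosome/strand: n registry entries with
## positions drawn (with replacement) from posPool.
randomMap <- function(chrom, strand, n, posPool = 0:400, lens = 23:32,
        maxCopy = 9L) {
    pos <- sample(posPool, n, replace = TRUE)
    len <- sample(lens, n, replace = TRUE)
    StrandWeightMap(chrom, strand, data.frame(
        position = as.integer(pos),
        sequence = vapply(len, function(l) paste(
            sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), character(1)),
        copy_number = sample.int(maxCopy, n, replace = TRUE),
        length = as.integer(len)))
}

## Exhaustive all-pairs oracle for the 5'-offset spectrum: loops over every
## (plus position, minus position) combination and accumulates by offset.
oracleSpectrum <- function(plusMap, minusMap, deltaRange, mode) {
    delta <- seq(deltaRange[1], deltaRange[2])
    counts <- setNames(numeric(length(delta)), delta)
    pp <- fivePrimePositions(plusMap); wp <- unname(positionWeights(plusMap))
    pm <- fivePrimePositions(minusMap); wm <- unname(positionWeights(minusMap))
    for (i in seq_along(pp)) for (j in seq_along(pm)) {
        d <- pm[j] - pp[i]
        if (d >= deltaRange[1] && d <= deltaRange[2]) {
            key <- as.character(d)
            counts[key] <- counts[key] +
                if (mode == "pairs") min(wp[i], wm[j]) else 1
        }
    }
    counts
}

## Brute-force P9 scan: every occupied plus position with an occupied
## minus position 9 nt away.
oracleP9Positions <- function(plusMap, minusMap) {
    pp <- fivePrimePositions(plusMap)
    pm <- fivePrimePositions(minusMap)
    sort(pp[vapply(pp, function(i) (i + 9L) %in% pm, logical(1))])
}

## All-pairs scan for cleavage pairs on one chromosome: checks the 10-nt
## offset rule for every (long, short) registry entry combination.
oracleCleavagePairs <- function(plusReg, minusReg, shortRange = c(15, 22),
        longRange = c(23, 32)) {
    out <- 0L
    lens <- list()
    for (i in seq_len(nrow(plusReg))) for (j in seq_len(nrow(minusReg))) {
        a <- plusReg[i, ]; b <- minusReg[j, ]
        ## plus guide, minus product
        if (a$length >= longRange[1] && a$length <= longRange[2] &&
            b$length >= shortRange[1] && b$length <= shortRange[2] &&
            (b$position - b$length + 1L) == a$position + 10L) {
            out <- out + 1L
            lens[[out]] <- c(b$length, a$length)
        }
        ## minus guide, plus product
        if (b$length >= longRange[1] && b$length <= longRange[2] &&
            a$length >= shortRange[1] && a$length <= shortRange[2] &&
            (a$position + a$length - 1L) == b$position - 10L) {
            out <- out + 1L
            lens[[out]] <- c(a$length, b$length)
        }
    }
    if (!out) matrix(integer(), 0, 2) else do.call(rbind, lens)
}

## Minimal P28-site DataFrame for strand-bias tests: one site per state.
fakeP28Sites <- function(states, chrom = "chr1", spacing = 200L) {
    n <- length(states)
    DataFrame(kind = rep("P28", n), chrom = rep(chrom, length.out = n),
        orientation = ifelse(states == "T", "P28T", "P28B"),
        fp_a = seq_len(n) * spacing, strand_a = ifelse(states == "T", "+", "-"),
        fp_b = seq_len(n) * spacing + 28L,
        strand_b = ifelse(states == "T", "-", "+"),
        center = seq_len(n) * spacing + 14L,
        members_a = IRanges::CharacterList(as.list(rep("A", n))),
        copies_a = IRanges::NumericList(as.list(rep(1, n))),
        lengths_a = IRanges::IntegerList(as.list(rep(19L, n))),
        members_b = IRanges::CharacterList(as.list(rep("A", n))),
        copies_b = IRanges::NumericList(as.list(rep(1, n))),
        lengths_b = IRanges::IntegerList(as.list(rep(26L, n))))
}
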