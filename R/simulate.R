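#' @importFrom GenomicRanges seqnames
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom stats rgeom runif setNames
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic mapped-read generator.  Defaults plant the
#' locus structure the analysis is designed to detect: triplex loci in
#' which a guide piRNA on one strand overlaps a secondary piRNA on the
#' other by 10 nt (5'-to-5' offset 9) and a 19-nt by-product sits
#' immediately upstream of the secondary piRNA (5'-to-5' offset 28 from
#' the guide), with a 78% chance of U at guide position 1, 44% on the
#' same-strand piRNA, and a strongly persistent (stay probability 0.982)
#' two-state arrangement of by-product strands along each chromosome.
#'
#' @param nChromosomes Number of simulated chromosomes.
#' @param chromLength Chromosome length in nt.
#' @param nTriplexLoci,nP9OnlyLoci,nBackgroundReads Planted element counts.
#' @param guideLengthProbs Probabilities over guide/piRNA lengths 23-32 nt
#'   (normalized internally); default uniform.
#' @param productLength Length of the short by-product (nt), default 19.
#' @param guide1uProb Probability of U at position 1 of the
#'   opposite-strand (guide) piRNA.
#' @param sameStrand1uProb Probability of U at position 1 of the piRNA on
#'   the by-product's strand.
#' @param strandStayProb Stay probability of the two-state chain that
#'   assigns consecutive triplex loci their by-product strand.
#' @param copyMean Mean of the geometric copy-number distribution
#'   (support 1, 2, ...).
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return Validated list of class `SimulationConfig`.
#' @seealso [simulateDataset()]
#' @export
simulationConfig <- function(nChromosomes = 2L, chromLength = 1e6,
        nTriplexLoci = 0L, nP9OnlyLoci = 0L, nBackgroundReads = 0L,
        guideLengthProbs = rep(1, 10), productLength = 19L,
        guide1uProb = 0.78, sameStrand1uProb = 0.44,
        strandStayProb = 0.982, copyMean = 3, seed = 1L) {
    cfg <- list(nChromosomes = as.integer(nChromosomes),
        chromLength = as.integer(chromLength),
        nTriplexLoci = as.integer(nTriplexLoci),
        nP9OnlyLoci = as.integer(nP9OnlyLoci),
        nBackgroundReads = as.integer(nBackgroundReads),
        guideLengthProbs = guideLengthProbs / sum(guideLengthProbs),
        productLength = as.integer(productLength),
        guide1uProb = guide1uProb, sameStrand1uProb = sameStrand1uProb,
        strandStayProb = strandStayProb, copyMean = copyMean,
        seed = as.integer(seed))
    with(cfg, {
        stopifnot(nChromosomes >= 1L, chromLength >= 1000L,
            nTriplexLoci >= 0L, nP9OnlyLoci >= 0L, nBackgroundReads >= 0L,
            length(guideLengthProbs) == 10L, all(guideLengthProbs >= 0),
            productLength >= 15L, productLength <= 22L,
            guide1uProb >= 0, guide1uProb <= 1,
            sameStrand1uProb >= 0, sameStrand1uProb <= 1,
            strandStayProb >= 0, strandStayProb <= 1, copyMean >= 1)
    })
    structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:\n")
    for (n in setdiff(names(x), "guideLengthProbs"))
        cat(sprintf("  %s: %s\n", n, paste(x[[n]], collapse = " ")))
    cat(sprintf("  guideLengthProbs (23-32 nt): %s\n",
        paste(signif(x$guideLengthProbs, 3), collapse = " ")))
    invisible(x)
}

.BASES <- c("A", "C", "G", "T")

.randSeqs <- function(lens) {
    vapply(lens, function(l)
        paste(sample(.BASES, l, replace = TRUE), collapse = ""),
        character(1))
}

## Random sequences whose first base is T (i.e. U in the RNA) with
## probability pU and otherwise uniform over A/C/G.
.biasedSeqs <- function(lens, pU) {
    first <- ifelse(runif(length(lens)) < pU, "T",
        sample(c("A", "C", "G"), length(lens), replace = TRUE))
    rest <- .randSeqs(pmax(lens - 1L, 0L))
    paste0(first, rest)
}

.drawCopies <- function(n, copyMean) {
    if (copyMean <= 1) rep(1L, n)
    else rgeom(n, prob = 1 / copyMean) + 1L
}

.drawGuideLens <- function(n, probs) {
    sample(23:32, n, replace = TRUE, prob = probs)
}

#' Simulate a mapped small-RNA read set with planted loci
#'
#' Generates collapsed, uniquely and perfectly mapped reads carrying the
#' locus structure described in [simulationConfig()], plus uniform
#' background reads (random position, strand and length 15-35 nt), and a
#' ground-truth table recording every planted element.  Planted loci are
#' placed on a coarse grid so that no two configurations can overlap; an
#' error suggests a longer chromosome when they do not fit.  Reads carry
#' their own sequences (sequences are random apart from the position-1
#' bias), so no reference genome is involved.
#'
#' With the 19-mer on the plus strand at 5' coordinate m, a triplex locus
#' emits the 19-mer spanning `[m, m+19)`, a long plus-strand read with 5'
#' end at `m + 19` and a long minus-strand read with 5' end at `m + 28`;
#' mirrored for minus-strand 19-mers.  Every planted 19-mer therefore has
#' its 3' end opposite position 11 of the guide.
#'
#' @param config A `SimulationConfig`.
#' @return List with `reads` (a `GRanges` with the metadata columns of
#'   [parseMappedReads()], seqlengths set) and `truth` (a `data.frame`
#'   with one row per planted element: locus_id, chrom, type, strands,
#'   planted 5' coordinates, lengths and copy numbers).
#' @export
simulateDataset <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(config$seed)
    chroms <- sprintf("sim%d", seq_len(config$nChromosomes))

    nLoci <- config$nTriplexLoci + config$nP9OnlyLoci
    spacing <- 128L
    slots <- floor((config$chromLength - spacing) / spacing)
    if (nLoci > slots * config$nChromosomes)
        stop("cannot place ", nLoci, " loci without overlap on ",
            config$nChromosomes, " chromosome(s) of ", config$chromLength,
            " nt; use a longer chromosome or fewer loci")
    chromOf <- rep(chroms, length.out = nLoci)
    types <- sample(rep(c("triplex", "p9_only"),
        c(config$nTriplexLoci, config$nP9OnlyLoci)))

    reads <- list()
    truth <- list()
    addRead <- function(chrom, strand, fp, len, seq, copy) {
        reads[[length(reads) + 1L]] <<- data.frame(chrom = chrom,
            strand = strand, fp = fp, len = len, seq = seq, copy = copy)
    }

    for (chr in chroms) {
        idx <- which(chromOf == chr)
        if (!length(idx)) next
        anchors <- sort(sample.int(slots, length(idx))) * spacing
        tps <- types[idx]
        ## strand chain over the triplex loci of this chromosome
        isTri <- tps == "triplex"
        nTri <- sum(isTri)
        if (nTri) {
            state <- character(nTri)
            state[1] <- sample(c("+", "-"), 1)
            if (nTri > 1) {
                stay <- runif(nTri - 1) < config$strandStayProb
                for (k in 2:nTri) state[k] <- if (stay[k - 1]) state[k - 1]
                    else setdiff(c("+", "-"), state[k - 1])
            }
        }
        triK <- 0L
        for (k in seq_along(idx)) {
            a <- anchors[k]
            lid <- idx[k]
            if (tps[k] == "triplex") {
                triK <- triK + 1L
                s19 <- state[triK]
                pl <- config$productLength
                lenSame <- .drawGuideLens(1, config$guideLengthProbs)
                lenGuide <- .drawGuideLens(1, config$guideLengthProbs)
                cp <- .drawCopies(3, config$copyMean)
                seq19 <- .randSeqs(pl)
                seqSame <- .biasedSeqs(lenSame, config$sameStrand1uProb)
                seqGuide <- .biasedSeqs(lenGuide, config$guide1uProb)
                if (s19 == "+") {
                    sameFp <- a + pl; guideFp <- a + 28L
                } else {
                    sameFp <- a - pl; guideFp <- a - 28L
                }
                addRead(chr, s19, a, pl, seq19, cp[1])
                addRead(chr, s19, sameFp, lenSame, seqSame, cp[2])
                addRead(chr, setdiff(c("+", "-"), s19), guideFp, lenGuide,
                    seqGuide, cp[3])
                truth[[length(truth) + 1L]] <- data.frame(locus_id = lid,
                    chrom = chr, type = "triplex", nineteen_strand = s19,
                    short_fp = a, short_len = pl,
                    same_fp = sameFp, same_len = lenSame,
                    guide_fp = guideFp, guide_len = lenGuide,
                    short_copy = cp[1], same_copy = cp[2],
                    guide_copy = cp[3])
            } else {
                lenP <- .drawGuideLens(1, config$guideLengthProbs)
                lenM <- .drawGuideLens(1, config$guideLengthProbs)
                cp <- .drawCopies(2, config$copyMean)
                addRead(chr, "+", a, lenP,
                    .biasedSeqs(lenP, config$sameStrand1uProb), cp[1])
                addRead(chr, "-", a + 9L, lenM,
                    .biasedSeqs(lenM, config$guide1uProb), cp[2])
                truth[[length(truth) + 1L]] <- data.frame(locus_id = lid,
                    chrom = chr, type = "p9_only",
                    nineteen_strand = NA_character_,
                    short_fp = NA_integer_, short_len = NA_integer_,
                    same_fp = a, same_len = lenP,
                    guide_fp = a + 9L, guide_len = lenM,
                    short_copy = NA_integer_, same_copy = cp[1],
                    guide_copy = cp[2])
            }
        }
    }

    nb <- config$nBackgroundReads
    if (nb) {
        bChrom <- sample(chroms, nb, replace = TRUE)
        bStrand <- sample(c("+", "-"), nb, replace = TRUE)
        bLen <- sample(15:35, nb, replace = TRUE)
        bStart <- floor(runif(nb) * (config$chromLength - bLen))
        bFp <- ifelse(bStrand == "+", bStart, bStart + bLen - 1L)
        bCopy <- .drawCopies(nb, config$copyMean)
        addRead(bChrom, bStrand, as.integer(bFp), bLen, .randSeqs(bLen),
            bCopy)
        truth[[length(truth) + 1L]] <- data.frame(
            locus_id = nLoci + seq_len(nb), chrom = bChrom,
            type = "background", nineteen_strand = NA_character_,
            short_fp = NA_integer_, short_len = NA_integer_,
            same_fp = ifelse(bStrand == "+", as.integer(bFp), NA_integer_),
            same_len = ifelse(bStrand == "+", bLen, NA_integer_),
            guide_fp = ifelse(bStrand == "-", as.integer(bFp), NA_integer_),
            guide_len = ifelse(bStrand == "-", bLen, NA_integer_),
            short_copy = NA_integer_, same_copy = NA_integer_,
            guide_copy = NA_integer_)
    }

    rd <- if (length(reads)) do.call(rbind, reads) else
        data.frame(chrom = character(), strand = character(),
            fp = integer(), len = integer(), seq = character(),
            copy = integer())
    start1 <- ifelse(rd$strand == "+", rd$fp + 1L, rd$fp - rd$len + 2L)
    gr <- GRanges(factor(rd$chrom, levels = chroms),
        IRanges(start1, width = rd$len), strand = rd$strand)
    mcols(gr) <- DataFrame(
        name = sprintf("sim%d_x%d", seq_len(nrow(rd)), rd$copy),
        sequence = rd$seq, copy_number = as.integer(rd$copy),
        edit_distance = rep(0L, nrow(rd)),
        n_mapping_loci = rep(1L, nrow(rd)))
    seqlengths(gr) <- setNames(rep(config$chromLength, length(chroms)),
        chroms)
    tt <- if (length(truth)) do.call(rbind, truth) else
        data.frame(locus_id = integer(), chrom = character(),
            type = character(), nineteen_strand = character(),
            short_fp = integer(), short_len = integer(),
            same_fp = integer(), same_len = integer(),
            guide_fp = integer(), guide_len = integer(),
            short_copy = integer(), same_copy = integer(),
            guide_copy = integer())
    rownames(tt) <- NULL
    list(reads = gr, truth = tt)
}

#' Write a simulated dataset to fixture files
#'
#' Writes the reads in the BED dialect of [writeBedReads()] (and
#' optionally as SAM) and the ground-truth table as TSV.  Parsing the BED
#' file back with [parseMappedReads()] reproduces the read list.
#'
#' @param dataset List from [simulateDataset()], or any list with
#'   elements `reads` and `truth`.
#' @param bedPath Output BED-dialect file.
#' @param truthPath Optional truth-table TSV.
#' @param samPath Optional SAM output.
#' @return Named character vector of the files written, invisibly.
#' @export
writeFixture <- function(dataset, bedPath, truthPath = NULL,
        samPath = NULL) {
    written <- c(bed = writeBedReads(dataset$reads, bedPath))
    if (!is.null(truthPath)) {
        con <- file(truthPath, "w")
        writeLines(paste0("#", paste(names(dataset$truth), collapse = "\t")),
            con)
        if (nrow(dataset$truth))
            write.table(dataset$truth, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
        close(con)
        written <- c(written, truth = truthPath)
    }
    if (!is.null(samPath))
        written <- c(written, sam = writeSamReads(dataset$reads, samPath))
    invisible(written)
}

#' Write mapped reads as SAM
#'
#' Minimal single-end SAM output with `NM`/`NH` tags and the copy number
#' encoded in the read name (`*_xN`).  Minus-strand sequences are stored
#' reverse-complemented, following the SAM convention.
#'
#' @param reads `GRanges` of mapped reads.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSamReads <- function(reads, path) {
    .checkReadMcols(reads)
    sl <- seqlengths(reads)
    if (anyNA(sl)) {
        ends <- vapply(split(end(reads), as.character(seqnames(reads))),
            max, numeric(1))
        sl[names(ends)] <- pmax(sl[names(ends)], ends + 1000, na.rm = TRUE)
        sl[is.na(sl)] <- 1e6
    }
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
        sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)))
    md <- mcols(reads)
    minus <- as.character(strand(reads)) == "-"
    seqs <- md$sequence
    seqs[is.na(seqs)] <- strrep("N", width(reads)[is.na(seqs)])
    if (any(minus))
        seqs[minus] <- as.character(reverseComplement(DNAStringSet(seqs[minus])))
    nm <- if ("name" %in% names(md)) md$name else
        sprintf("read%d", seq_along(reads))
    ## SAM has no copy-number column; encode it in the read name
    noTag <- !grepl("_x[0-9]+$", nm)
    nm[noTag] <- sprintf("%s_x%d", nm[noTag], md$copy_number[noTag])
    rec <- paste(nm, ifelse(minus, 16L, 0L),
        as.character(seqnames(reads)), start(reads), 255L,
        paste0(width(reads), "M"), "*", 0L, 0L, seqs, "*",
        paste0("NM:i:", md$edit_distance),
        paste0("NH:i:", md$n_mapping_loci), sep = "\t")
    writeLines(c(hdr, rec), path)
    invisible(path)
}
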