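#' @importFrom IRanges CharacterList NumericList IntegerList
NULL

## Registry entries behind a vector of 5' positions, as parallel lists.
.membersAt <- function(map, pos) {
    reg <- map@registry
    idx <- split(seq_len(nrow(reg)), reg$position)
    hit <- idx[as.character(pos)]
    list(
        seqs = CharacterList(lapply(hit, function(i) reg$sequence[i])),
        copies = NumericList(lapply(hit, function(i) reg$copy_number[i])),
        lens = IntegerList(lapply(hit, function(i) reg$length[i]))
    )
}

.emptySites <- function() {
    DataFrame(kind = character(), chrom = character(),
        orientation = character(),
        fp_a = integer(), strand_a = character(),
        fp_b = integer(), strand_b = character(), center = integer(),
        members_a = CharacterList(), copies_a = NumericList(),
        lengths_a = IntegerList(),
        members_b = CharacterList(), copies_b = NumericList(),
        lengths_b = IntegerList())
}

.siteRows <- function(kind, chrom, orientation, fpA, strandA, mapA,
        fpB, strandB, mapB) {
    if (!length(fpA)) return(.emptySites())
    a <- .membersAt(mapA, fpA)
    b <- .membersAt(mapB, fpB)
    DataFrame(kind = rep(kind, length(fpA)), chrom = rep(chrom, length(fpA)),
        orientation = rep(orientation, length(fpA)),
        fp_a = as.integer(fpA), strand_a = rep(strandA, length(fpA)),
        fp_b = as.integer(fpB), strand_b = rep(strandB, length(fpA)),
        center = as.integer(floor((fpA + fpB) / 2)),
        members_a = a$seqs, copies_a = a$copies, lengths_a = a$lens,
        members_b = b$seqs, copies_b = b$copies, lengths_b = b$lens)
}

.sortSites <- function(sites) {
    if (!nrow(sites)) return(sites)
    o <- order(sites$chrom, sites$center, sites$fp_a)
    sites[o, ]
}

#' Detect P9 (ping-pong) sites
#'
#' A P9 site is a genomic locus with a long (23-32 nt) read 5' end on the
#' plus strand at position \eqn{i} and a long read 5' end on the minus
#' strand at \eqn{i + 9} - the 10-nt 5' overlap characteristic of
#' ping-pong amplification.  One site is emitted per qualifying position
#' pair, carrying the full sets of member sequences with their copy
#' numbers; sites are sorted by chromosome and coordinate.
#'
#' In the returned `DataFrame`, member "a" is the plus-strand member and
#' "b" the minus-strand member; `center` is the floor of the midpoint of
#' the two 5' ends.
#'
#' @param longMaps [WeightMapSet-class] built with the long (23-32 nt)
#'   length class.
#' @return `DataFrame` of sites (kind `"P9"`).
#' @seealso [detectP28Sites()], [detectTriplexes()]
#' @export
detectP9Sites <- function(longMaps) {
    stopifnot(is(longMaps, "WeightMapSet"))
    out <- lapply(chromosomes(longMaps), function(chr) {
        p <- weightMap(longMaps, chr, "+")
        m <- weightMap(longMaps, chr, "-")
        i <- p@positions[(p@positions + 9L) %in% m@positions]
        .siteRows("P9", chr, NA_character_, i, "+", p, i + 9L, "-", m)
    })
    .sortSites(do.call(rbind, c(out, list(.emptySites()))))
}

#' Detect P28 (19-mer by-product) sites
#'
#' A P28 site pairs a short read (by default exactly 19 nt) on one strand
#' with a long (23-32 nt) read on the opposite strand at a 5'-to-5' offset
#' of 28 nt.  Sites whose short member lies on the plus strand are tagged
#' `P28T` (long minus-strand 5' at short 5' + 28); short member on the
#' minus strand gives `P28B` (long plus-strand 5' at short 5' - 28).
#'
#' In the returned `DataFrame`, member "a" is the short member (19-mer)
#' and "b" the long member.
#'
#' @param shortMaps [WeightMapSet-class] built with the short length class
#'   (default exactly 19 nt; 18 for beta-eliminated libraries).
#' @param longMaps [WeightMapSet-class] built with the 23-32 nt class.
#' @return `DataFrame` of sites (kind `"P28"`, orientation `P28T`/`P28B`).
#' @export
detectP28Sites <- function(shortMaps, longMaps) {
    stopifnot(is(shortMaps, "WeightMapSet"), is(longMaps, "WeightMapSet"))
    chroms <- union(chromosomes(shortMaps), chromosomes(longMaps))
    out <- lapply(chroms, function(chr) {
        sp <- weightMap(shortMaps, chr, "+")
        sm <- weightMap(shortMaps, chr, "-")
        lp <- weightMap(longMaps, chr, "+")
        lm <- weightMap(longMaps, chr, "-")
        mT <- sp@positions[(sp@positions + 28L) %in% lm@positions]
        mB <- sm@positions[(sm@positions - 28L) %in% lp@positions]
        rbind(
            .siteRows("P28", chr, "P28T", mT, "+", sp, mT + 28L, "-", lm),
            .siteRows("P28", chr, "P28B", mB, "-", sm, mB - 28L, "+", lp))
    })
    .sortSites(do.call(rbind, c(out, list(.emptySites()))))
}

#' Extract guide/product cleavage pairs
#'
#' Enumerates every sense-antisense sequence pair in which the 3' end of
#' the shorter member (15-22 nt) lies 10 nt downstream of the 5' end of
#' the longer member (23-32 nt), measured in the longer read's own 5'->3'
#' orientation - i.e. the product's 3' end sits opposite position 11 of
#' the guide, where piRNA-directed cleavage of the target occurs.  For a
#' plus-strand guide with 5' end at g the product is a minus-strand read
#' whose 3' end (its lowest coordinate) is g + 10; for a minus-strand
#' guide the product's 3' end (highest coordinate) is g - 10.
#'
#' @param maps [WeightMapSet-class] built over a length class covering
#'   both ranges (e.g. `"all"`), with the sequence registry populated.
#' @param shortRange,longRange Inclusive length intervals for product and
#'   guide.
#' @return `data.frame` with one row per (guide sequence, product
#'   sequence) pair: chrom, guide_strand, guide_5p, guide_length,
#'   guide_copy, product_5p, product_3p, product_length, product_copy.
#' @export
extractCleavagePairs <- function(maps, shortRange = c(15L, 22L),
        longRange = c(23L, 32L)) {
    stopifnot(is(maps, "WeightMapSet"))
    out <- lapply(chromosomes(maps), function(chr) {
        pr <- weightMap(maps, chr, "+")@registry
        mr <- weightMap(maps, chr, "-")@registry
        longP <- pr[pr$length >= longRange[1] & pr$length <= longRange[2], ]
        longM <- mr[mr$length >= longRange[1] & mr$length <= longRange[2], ]
        shortP <- pr[pr$length >= shortRange[1] & pr$length <= shortRange[2], ]
        shortM <- mr[mr$length >= shortRange[1] & mr$length <= shortRange[2], ]
        ## minus-strand product: 3' end = 5' position - length + 1
        shortM$three_p <- shortM$position - shortM$length + 1L
        ## plus-strand product: 3' end = 5' position + length - 1
        shortP$three_p <- shortP$position + shortP$length - 1L
        pairUp <- function(guide, gstrand, product, pstrand, offset) {
            product$key <- product$three_p - offset
            hits <- merge(
                data.frame(key = guide$position, guide_5p = guide$position,
                    guide_length = guide$length, guide_copy = guide$copy_number,
                    guide_seq = guide$sequence),
                product[, c("key", "position", "three_p", "length",
                    "copy_number", "sequence")],
                by = "key")
            if (!nrow(hits)) return(NULL)
            data.frame(chrom = chr, guide_strand = gstrand,
                guide_5p = hits$guide_5p, guide_length = hits$guide_length,
                guide_copy = hits$guide_copy, guide_seq = hits$guide_seq,
                product_strand = pstrand, product_5p = hits$position,
                product_3p = hits$three_p, product_length = hits$length,
                product_copy = hits$copy_number, product_seq = hits$sequence)
        }
        rbind(pairUp(longP, "+", shortM, "-", 10L),
            pairUp(longM, "-", shortP, "+", -10L))
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
        out <- data.frame(chrom = character(), guide_strand = character(),
            guide_5p = integer(), guide_length = integer(),
            guide_copy = numeric(), guide_seq = character(),
            product_strand = character(), product_5p = integer(),
            product_3p = integer(), product_length = integer(),
            product_copy = numeric(), product_seq = character())
    } else {
        out <- out[order(out$chrom, out$guide_5p, out$product_5p), ]
        rownames(out) <- NULL
    }
    out
}

.fmtMembers <- function(seqs, copies) {
    mapply(function(s, cn) paste0(ifelse(is.na(s), ".", s), "(", cn, ")",
        collapse = ","), as.list(seqs), as.list(copies))
}

#' Write a site table as TSV
#'
#' Seven columns in the conventional site-table layout: chromosome, strand
#' of the first member (the 19-mer for P28 sites, the plus-strand member
#' for P9), its 5' coordinate and sequences with copy numbers in the
#' `SEQ(count)` dialect joined by commas, then the same three columns for
#' the opposite member.
#'
#' @param sites Site `DataFrame` from [detectP9Sites()] or
#'   [detectP28Sites()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
    df <- data.frame(chrom = sites$chrom, strand = sites$strand_a,
        five_prime = sites$fp_a,
        sequences = if (nrow(sites))
            .fmtMembers(sites$members_a, sites$copies_a) else character(),
        opposite_strand = sites$strand_b,
        opposite_five_prime = sites$fp_b,
        opposite_sequences = if (nrow(sites))
            .fmtMembers(sites$members_b, sites$copies_b) else character())
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
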