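#' Pattern center positions
#'
#' Anchors each site at the nucleotide midway between the 5' ends of its
#' two members, `floor((fp_a + fp_b) / 2)`.  For the odd-width P9 interval
#' the midpoint is rounded down; this single convention is what makes the
#' P9/P28T and P9/P28B cross-correlation peaks land at -9 and +10 rather
#' than -10 and +9.  Duplicate centers on a chromosome collapse to one
#' entry (the center vector is a binary indicator).
#'
#' @param sites Site `DataFrame` from [detectP9Sites()] or
#'   [detectP28Sites()] (optionally subset, e.g. by orientation).
#' @return Named list, one sorted integer vector of unique center
#'   coordinates per chromosome.
#' @export
patternCenters <- function(sites) {
    if (!nrow(sites)) return(structure(list(), names = character()))
    lapply(split(sites$center, sites$chrom), function(x) sort(unique(x)))
}

#' Positional cross-correlation of two center sets
#'
#' Raw sliding dot product of the binary indicator vectors of two sets of
#' genomic positions: `values[lag]` is the number of position pairs
#' `(a, b)` with `b = a + lag`, accumulated per chromosome (chromosomes
#' never mix) and summed.  No mean-centering or normalization is applied;
#' the readout is the peak position, which affine normalization cannot
#' move.
#'
#' @param a,b Named lists of per-chromosome position vectors, as returned
#'   by [patternCenters()].
#' @param window Maximum absolute lag; lags run from `-window` to
#'   `window`.  Default 50.
#' @return `data.frame` with columns `lag` and `value`.
#' @seealso [peakLag()]
#' @export
crossCorrelate <- function(a, b, window = 50L) {
    window <- as.integer(window)
    if (is.na(window) || window < 1L)
        stop("'window' must be a positive integer")
    lags <- seq(-window, window)
    values <- numeric(length(lags))
    for (chr in intersect(names(a), names(b))) {
        av <- a[[chr]]
        bv <- b[[chr]]
        if (!length(av) || !length(bv)) next
        values <- values + vapply(lags,
            function(l) sum((av + l) %in% bv), numeric(1))
    }
    data.frame(lag = lags, value = values)
}

#' Lag of the cross-correlation maximum
#'
#' @param cc `data.frame` from [crossCorrelate()].
#' @return The lag with the highest value (`NA` if all values are zero;
#'   ties resolve to the smallest lag).
#' @export
peakLag <- function(cc) {
    if (all(cc$value == 0)) return(NA_integer_)
    cc$lag[which.max(cc$value)]
}

#' Detect triplex loci
#'
#' A triplex locus is the joint configuration behind the co-occurring P9
#' and P28 patterns: two long piRNAs from opposite strands overlapping by
#' 10 nt (the P9 duplex) plus a short by-product immediately upstream of
#' the same-strand piRNA - the by-product's span ends exactly one
#' nucleotide before that piRNA's 5' end, and the P28 long member is the
#' piRNA on the strand opposite the by-product.  Matching is exact on 5'
#' coordinates, with no tolerance window.
#'
#' For a P28T site with 19-mer 5' at `m` and long minus-strand member at
#' `q = m + 28`, the required P9 site pairs plus 5' `q - 9 = m + 19` with
#' minus 5' `q`; mirrored for P28B.
#'
#' @param p9Sites `DataFrame` from [detectP9Sites()].
#' @param p28Sites `DataFrame` from [detectP28Sites()], from the same
#'   collapsed dataset.
#' @return `DataFrame` with one row per triplex: chrom, nineteen_strand,
#'   short_fp, guide_fp (5' of the piRNA opposite the by-product),
#'   same_fp (5' of the piRNA on the by-product's strand), center columns
#'   of the two contributing sites, and member sequence/copy-number list
#'   columns for the by-product, the same-strand piRNA and the
#'   opposite-strand (guide) piRNA.
#' @export
detectTriplexes <- function(p9Sites, p28Sites) {
    empty <- DataFrame(chrom = character(), nineteen_strand = character(),
        short_fp = integer(), guide_fp = integer(), same_fp = integer(),
        p9_center = integer(), p28_center = integer(),
        short_members = CharacterList(), short_copies = NumericList(),
        same_members = CharacterList(), same_copies = NumericList(),
        opp_members = CharacterList(), opp_copies = NumericList())
    if (!nrow(p9Sites) || !nrow(p28Sites)) return(empty)
    p9Key <- paste(p9Sites$chrom, p9Sites$fp_a)
    isT <- p28Sites$orientation == "P28T"
    ## P9 plus-strand 5' required by each P28 site
    needPlus <- ifelse(isT, p28Sites$fp_b - 9L, p28Sites$fp_b)
    hit <- match(paste(p28Sites$chrom, needPlus), p9Key)
    ok <- !is.na(hit)
    if (!any(ok)) return(empty)
    ## adjacency: one short member's span must end one nucleotide before
    ## the same-strand piRNA's 5' end
    sameFp <- ifelse(isT, needPlus, needPlus + 9L)
    needLen <- ifelse(isT, sameFp - p28Sites$fp_a, p28Sites$fp_a - sameFp)
    adj <- mapply(function(lens, l) l %in% lens,
        as.list(p28Sites$lengths_a), needLen)
    ok <- ok & adj
    if (!any(ok)) return(empty)
    i28 <- which(ok)
    i9 <- hit[ok]
    tIsT <- isT[ok]
    ## the same-strand piRNA is the P9 plus member for P28T, minus for P28B
    pick <- function(colT, colB) {
        out <- as.list(p9Sites[[colT]][i9])
        out[!tIsT] <- as.list(p9Sites[[colB]][i9][!tIsT])
        out
    }
    sameMembers <- pick("members_a", "members_b")
    sameCopies <- pick("copies_a", "copies_b")
    oppMembers <- pick("members_b", "members_a")
    oppCopies <- pick("copies_b", "copies_a")
    res <- DataFrame(chrom = p28Sites$chrom[i28],
        nineteen_strand = p28Sites$strand_a[i28],
        short_fp = p28Sites$fp_a[i28],
        guide_fp = p28Sites$fp_b[i28],
        same_fp = sameFp[ok],
        p9_center = p9Sites$center[i9],
        p28_center = p28Sites$center[i28],
        short_members = p28Sites$members_a[i28],
        short_copies = p28Sites$copies_a[i28],
        same_members = CharacterList(sameMembers),
        same_copies = NumericList(sameCopies),
        opp_members = CharacterList(oppMembers),
        opp_copies = NumericList(oppCopies))
    res[order(res$chrom, res$short_fp), ]
}

#' Write cross-correlation or triplex tables as TSV
#'
#' @param cc `data.frame` from [crossCorrelate()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeCrossCorrelation <- function(cc, path) {
    write.table(cc, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCrossCorrelation
#' @param triplexes `DataFrame` from [detectTriplexes()].
#' @export
writeTriplexTable <- function(triplexes, path) {
    df <- data.frame(chrom = triplexes$chrom,
        nineteen_strand = triplexes$nineteen_strand,
        nineteen_five_prime = triplexes$short_fp,
        plus_piRNA_five_prime = ifelse(triplexes$nineteen_strand == "+",
            triplexes$same_fp, triplexes$guide_fp),
        minus_piRNA_five_prime = ifelse(triplexes$nineteen_strand == "+",
            triplexes$guide_fp, triplexes$same_fp),
        nineteen_sequences = if (nrow(triplexes))
            .fmtMembers(triplexes$short_members, triplexes$short_copies)
            else character(),
        same_strand_sequences = if (nrow(triplexes))
            .fmtMembers(triplexes$same_members, triplexes$same_copies)
            else character(),
        opposite_strand_sequences = if (nrow(triplexes))
            .fmtMembers(triplexes$opp_members, triplexes$opp_copies)
            else character())
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
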