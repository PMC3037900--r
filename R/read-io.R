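#' @importFrom GenomicRanges GRanges strand seqnames start end width mcols
#'   mcols<- seqinfo
#' @importFrom IRanges IRanges
#' @importFrom GenomicAlignments readGAlignments cigarWidthAlongReferenceSpace
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom Biostrings reverseComplement DNAStringSet
#' @importFrom S4Vectors mcols mcols<-
NULL

## Read-length class presets.  Prototypical piRNAs are 23-32 nt; the short
## by-product of piRNA-guided cleavage is 19 nt (18 after beta-elimination).
.LENGTH_CLASSES <- list(
    all = c(15L, 35L),
    long = c(23L, 32L),
    piRNA = c(23L, 32L),
    short = c(15L, 22L),
    exact19 = c(19L, 19L),
    exact18 = c(18L, 18L)
)

#' Resolve a read-length class
#'
#' Length classes select which reads contribute to a weight map.  Presets:
#' `"all"` (15-35 nt), `"long"`/`"piRNA"` (23-32 nt), `"short"` (15-22 nt),
#' `"exact19"`, `"exact18"`.  A numeric vector gives a custom class: a
#' single value means that exact length, two values an inclusive interval.
#'
#' @param x Preset name or numeric length/interval.
#' @return Integer `c(min, max)`.
#' @examples
#' lengthClass("long")
#' lengthClass(19)
#' lengthClass(c(24, 30))
#' @export
lengthClass <- function(x) {
    if (is.character(x)) {
        x <- match.arg(x, names(.LENGTH_CLASSES))
        return(.LENGTH_CLASSES[[x]])
    }
    x <- as.integer(x)
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < 1L)
        stop("length class must be a preset name, a single length, ",
            "or a non-empty interval c(min, max)")
    x
}

.checkReadMcols <- function(gr) {
    need <- c("sequence", "copy_number", "edit_distance", "n_mapping_loci")
    miss <- setdiff(need, names(mcols(gr)))
    if (length(miss))
        stop("mapped reads must carry metadata columns: ",
            paste(miss, collapse = ", "))
    invisible(gr)
}

#' 5'-end coordinates of mapped reads
#'
#' Returns the 0-based genomic coordinate of each read's 5' end: the
#' leftmost base for plus-strand reads and the rightmost base for
#' minus-strand reads.  This convention underlies all offset arithmetic in
#' the package and is fixed.
#'
#' @param reads `GRanges` of mapped reads (1-based, as returned by
#'   [parseMappedReads()]).
#' @return Integer vector of 0-based 5'-end coordinates.
#' @export
fivePrimeEnd <- function(reads) {
    s <- as.character(strand(reads))
    if (any(s == "*"))
        stop("reads with unknown strand '*' are not supported")
    ifelse(s == "+", start(reads) - 1L, end(reads) - 1L)
}

#' Parse mapped small-RNA reads
#'
#' Reads alignment records from SAM/BAM or from the package's BED-like TSV
#' dialect into a `GRanges` (1-based Bioconductor convention) with metadata
#' columns `name`, `sequence` (in the read's own 5'->3' orientation; for
#' minus-strand SAM records the stored sequence is reverse-complemented),
#' `copy_number`, `edit_distance` and `n_mapping_loci`.
#'
#' Copy numbers follow the collapsed-FASTA convention: a read name matching
#' `*_xN` carries copy number N; otherwise (and when the BED dialect's
#' dedicated column is absent) each record counts once.  Edit distance is
#' taken from the SAM `NM` tag (0 when absent) or the dialect's column; the
#' number of mapping loci from the `NH` tag or column.  When `NH` is absent
#' from a SAM file, reads whose query name appears in several records are
#' treated as multi-mappers.
#'
#' The BED dialect has columns chrom, start (0-based), end, name, score,
#' strand, then optional sequence, copy_number, edit_distance,
#' n_mapping_loci.  Lines starting with `#` are skipped.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return `GRanges` of mapped reads.
#' @seealso [filterUniquePerfect()], [collapseToLoci()], [writeBedReads()]
#' @export
parseMappedReads <- function(path, format = c("auto", "sam", "bam", "bed")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(sub(".*\\.", "", path))
        format <- switch(ext, sam = "sam", bam = "bam",
            bed = "bed", tsv = "bed", txt = "bed",
            stop("cannot guess format from extension '.", ext,
                "'; pass format= explicitly"))
    }
    if (format %in% c("sam", "bam")) .parseSamReads(path, format)
    else .parseBedReads(path)
}

.parseSamReads <- function(path, format) {
    bam <- if (format == "sam") {
        asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    param <- ScanBamParam(what = c("qname", "seq"), tag = c("NM", "NH"),
        flag = scanBamFlag(isUnmappedQuery = FALSE))
    aln <- readGAlignments(bam, param = param)
    md <- mcols(aln)
    seqs <- md$seq
    minus <- as.character(strand(aln)) == "-"
    if (any(minus))
        seqs[minus] <- reverseComplement(seqs[minus])
    nm <- md$NM
    nm[is.na(nm)] <- 0L
    nh <- md$NH
    if (anyNA(nh)) {
        dup <- table(md$qname)
        fallback <- as.integer(dup[md$qname])
        nh[is.na(nh)] <- fallback[is.na(nh)]
    }
    gr <- GRanges(seqnames(aln), IRanges(start(aln), end(aln)),
        strand = strand(aln))
    mcols(gr) <- DataFrame(
        name = md$qname,
        sequence = as.character(seqs),
        copy_number = .copyFromName(md$qname),
        edit_distance = as.integer(nm),
        n_mapping_loci = as.integer(nh))
    gr
}

.copyFromName <- function(name) {
    cn <- rep(1L, length(name))
    hit <- grepl("_x[0-9]+$", name)
    cn[hit] <- as.integer(sub(".*_x([0-9]+)$", "\\1", name[hit]))
    cn
}

.parseBedReads <- function(path) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(name = character(), sequence = character(),
            copy_number = integer(), edit_distance = integer(),
            n_mapping_loci = integer())
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L))
        stop("malformed BED record at line ", lineno[which(nf < 6L)[1]],
            ": fewer than 6 tab-separated fields")
    col <- function(i, default = NA_character_)
        vapply(fields, function(f) if (length(f) >= i) f[i] else default,
            character(1))
    chrom <- col(1)
    start0 <- suppressWarnings(as.integer(col(2)))
    end0 <- suppressWarnings(as.integer(col(3)))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
    if (length(bad))
        stop("malformed BED record at line ", lineno[bad[1]],
            ": invalid start/end coordinates")
    name <- col(4)
    std <- col(6)
    bad <- which(!std %in% c("+", "-"))
    if (length(bad))
        stop("unknown strand symbol '", std[bad[1]], "' at line ",
            lineno[bad[1]])
    sequence <- col(7)
    sequence[sequence %in% c("", ".")] <- NA_character_
    len <- end0 - start0
    bad <- which(!is.na(sequence) & nchar(sequence) != len)
    if (length(bad))
        stop("malformed BED record at line ", lineno[bad[1]],
            ": sequence length does not match the interval")
    cn <- suppressWarnings(as.integer(col(8)))
    cn[is.na(cn)] <- .copyFromName(name[is.na(cn)])
    ed <- suppressWarnings(as.integer(col(9)))
    ed[is.na(ed)] <- 0L
    nh <- suppressWarnings(as.integer(col(10)))
    nh[is.na(nh)] <- 1L
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = std)
    mcols(gr) <- DataFrame(name = name, sequence = sequence,
        copy_number = cn, edit_distance = ed, n_mapping_loci = nh)
    gr
}

#' Write mapped reads in the BED-like dialect
#'
#' Writes the ten-column TSV dialect understood by [parseMappedReads()]
#' (chrom, 0-based start, end, name, score, strand, sequence, copy_number,
#' edit_distance, n_mapping_loci), with a `#`-prefixed header line.
#' Round-trips exactly through the parser.
#'
#' @param reads `GRanges` of mapped reads.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeBedReads <- function(reads, path) {
    .checkReadMcols(reads)
    md <- mcols(reads)
    seqcol <- ifelse(is.na(md$sequence), ".", md$sequence)
    nm <- if ("name" %in% names(md)) md$name else
        paste0("read", seq_along(reads))
    df <- data.frame(
        chrom = as.character(seqnames(reads)),
        start = start(reads) - 1L,
        end = end(reads),
        name = nm,
        score = rep(0L, length(reads)),
        strand = as.character(strand(reads)),
        sequence = seqcol,
        copy_number = md$copy_number,
        edit_distance = md$edit_distance,
        n_mapping_loci = md$n_mapping_loci)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
    if (nrow(df))
        write.table(df, con, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Keep uniquely and perfectly mapped reads
#'
#' Retains exactly the reads that mapped to a single genomic locus
#' (`n_mapping_loci == 1`) with no error (`edit_distance == 0`), dropping
#' in addition any read on an excluded chromosome (by default the
#' mitochondrial chromosome under its common names).  Input order is
#' preserved; the operation is idempotent.
#'
#' @param reads `GRanges` of mapped reads.
#' @param excludeChrom Character vector of chromosome names to drop.
#' @return Filtered `GRanges`.
#' @export
filterUniquePerfect <- function(reads, excludeChrom = c("chrM", "chrMT", "MT", "M")) {
    .checkReadMcols(reads)
    md <- mcols(reads)
    keep <- md$n_mapping_loci == 1L & md$edit_distance == 0L &
        !(as.character(seqnames(reads)) %in% excludeChrom)
    reads[keep]
}

#' Collapse reads into strand-resolved 5'-end weight maps
#'
#' Builds, for every chromosome and strand, the map from 5'-end coordinate
#' to summed copy number over the reads whose length falls in
#' `lengthClass`, together with the registry of sequences behind each
#' position.  The sum of all weights over both strands equals the total
#' copy number of in-class reads.
#'
#' @param reads `GRanges` of (filtered) mapped reads.
#' @param lengthClass Preset name or interval, see [lengthClass()].
#' @return A [WeightMapSet-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 126), "+")
#' S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = "r1",
#'     sequence = paste(rep("A", 26), collapse = ""), copy_number = 3L,
#'     edit_distance = 0L, n_mapping_loci = 1L)
#' maps <- collapseToLoci(gr, "long")
#' weightMap(maps, "chr1", "+")
#' @export
collapseToLoci <- function(reads, lengthClass = "all") {
    .checkReadMcols(reads)
    lc <- lengthClass(lengthClass)
    w <- width(reads)
    reads <- reads[w >= lc[1] & w <= lc[2]]
    if (!length(reads))
        return(new("WeightMapSet", maps = list(), lengthClass = lc))
    fp <- fivePrimeEnd(reads)
    key <- paste0(as.character(seqnames(reads)), "|",
        as.character(strand(reads)))
    idx <- split(seq_along(reads), key)
    md <- mcols(reads)
    maps <- lapply(names(idx), function(k) {
        i <- idx[[k]]
        parts <- strsplit(k, "|", fixed = TRUE)[[1]]
        StrandWeightMap(parts[1], parts[2], data.frame(
            position = fp[i],
            sequence = md$sequence[i],
            copy_number = md$copy_number[i],
            length = width(reads)[i]))
    })
    names(maps) <- names(idx)
    new("WeightMapSet", maps = maps[order(names(maps))], lengthClass = lc)
}

#' @rdname chromosomes
#' @export
setMethod("chromosomes", "WeightMapSet", function(x) {
    sort(unique(vapply(x@maps, function(m) m@chrom, character(1))))
})

#' @rdname weightMap
#' @export
setMethod("weightMap", "WeightMapSet", function(x, chrom, strand) {
    m <- x@maps[[paste0(chrom, "|", strand)]]
    if (is.null(m)) StrandWeightMap(chrom, strand) else m
})

#' Accessors for StrandWeightMap internals
#'
#' `fivePrimePositions()` returns the occupied 0-based 5'-end coordinates,
#' `positionWeights()` the parallel summed copy numbers, and
#' `seqRegistry()` the per-(position, sequence) registry.
#'
#' @param x A [StrandWeightMap-class].
#' @return See above.
#' @export
fivePrimePositions <- function(x) {
    stopifnot(is(x, "StrandWeightMap"))
    x@positions
}

#' @rdname fivePrimePositions
#' @export
positionWeights <- function(x) {
    stopifnot(is(x, "StrandWeightMap"))
    structure(x@weights, names = as.character(x@positions))
}

#' @rdname fivePrimePositions
#' @export
seqRegistry <- function(x) {
    stopifnot(is(x, "StrandWeightMap"))
    x@registry
}
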