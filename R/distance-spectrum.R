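## Core engine shared by the pairs and loci modes.  For a fixed offset d,
## a plus-strand position i contributes min(w+(i), w-(i+d)) pairs (or one
## locus) whenever i+d is occupied on the minus strand.
.spectrumEngine <- function(plus, minus, deltaRange, mode) {
    if (length(deltaRange) != 2L || anyNA(deltaRange) ||
        deltaRange[1] > deltaRange[2])
        stop("'deltaRange' must be c(min, max) with min <= max")
    delta <- seq(as.integer(deltaRange[1]), as.integer(deltaRange[2]))
    pp <- plus@positions; wp <- plus@weights
    pm <- minus@positions; wm <- minus@weights
    counts <- vapply(delta, function(d) {
        j <- match(pp + d, pm)
        k <- which(!is.na(j))
        if (!length(k)) return(0)
        if (mode == "pairs") sum(pmin(wp[k], wm[j[k]])) else length(k)
    }, numeric(1))
    list(delta = delta, counts = counts)
}

.spectrumFromMaps <- function(plus, minus, deltaRange, mode) {
    if (!identical(plus@chrom, minus@chrom))
        stop("plus and minus maps are from different chromosomes (",
            plus@chrom, " vs ", minus@chrom, ")")
    if (plus@strand != "+" || minus@strand != "-")
        stop("expected a plus-strand map and a minus-strand map, in that order")
    eng <- .spectrumEngine(plus, minus, deltaRange, mode)
    new("DistanceSpectrum", delta = eng$delta, counts = eng$counts,
        mode = mode, classPlus = NA_integer_, classMinus = NA_integer_,
        symmetrized = FALSE, preset = NA_character_)
}

.spectrumFromSets <- function(plus, minus, deltaRange, mode) {
    chroms <- union(chromosomes(plus), chromosomes(minus))
    delta <- seq(as.integer(deltaRange[1]), as.integer(deltaRange[2]))
    counts <- numeric(length(delta))
    for (chr in chroms) {
        eng <- .spectrumEngine(weightMap(plus, chr, "+"),
            weightMap(minus, chr, "-"), deltaRange, mode)
        counts <- counts + eng$counts
    }
    new("DistanceSpectrum", delta = delta, counts = counts, mode = mode,
        classPlus = plus@lengthClass, classMinus = minus@lengthClass,
        symmetrized = FALSE, preset = NA_character_)
}

#' @rdname pairSpectrum
#' @export
setMethod("pairSpectrum", signature("StrandWeightMap", "StrandWeightMap"),
    function(plus, minus, deltaRange = c(-20L, 50L))
        .spectrumFromMaps(plus, minus, deltaRange, "pairs"))

#' @rdname pairSpectrum
#' @export
setMethod("pairSpectrum", signature("WeightMapSet", "WeightMapSet"),
    function(plus, minus, deltaRange = c(-20L, 50L))
        .spectrumFromSets(plus, minus, deltaRange, "pairs"))

#' @rdname locusSpectrum
#' @export
setMethod("locusSpectrum", signature("StrandWeightMap", "StrandWeightMap"),
    function(plus, minus, deltaRange = c(-20L, 50L))
        .spectrumFromMaps(plus, minus, deltaRange, "loci"))

#' @rdname locusSpectrum
#' @export
setMethod("locusSpectrum", signature("WeightMapSet", "WeightMapSet"),
    function(plus, minus, deltaRange = c(-20L, 50L))
        .spectrumFromSets(plus, minus, deltaRange, "loci"))

## Length-class pairs behind each spectrum preset.
.SPECTRUM_PRESETS <- list(
    all_15_35 = list(a = "all", b = "all"),
    long_long = list(a = "long", b = "long"),
    long_short = list(a = "long", b = "short"),
    long_19 = list(a = "long", b = "exact19")
)

#' Genome-wide 5'-offset spectrum for a length-class preset
#'
#' Computes the 5'-end offset spectrum genome-wide after restricting each
#' strand to a length class.  Presets follow the standard read subsets:
#'
#' * `all_15_35` - all reads of 15-35 nt on both strands;
#' * `long_long` - prototypical piRNAs (23-32 nt) on both strands: shows
#'   the ping-pong peak at \eqn{\Delta = 9};
#' * `long_short` - a 23-32 nt read on one strand paired with a 15-22 nt
#'   read on the other;
#' * `long_19` - as `long_short` but the short read must be exactly 19 nt:
#'   isolates the by-product peak at \eqn{\Delta = 28}.
#'
#' For the asymmetric presets the spectrum sums both class assignments
#' (long-on-plus with short-on-minus, and short-on-plus with
#' long-on-minus), so \eqn{\Delta} keeps its meaning of (minus-strand 5')
#' minus (plus-strand 5').
#'
#' @param reads `GRanges` of filtered mapped reads.
#' @param preset One of the preset names above.
#' @param deltaRange Offset interval, default `c(-20, 50)`.
#' @param mode `"pairs"` (weighted-minimum) or `"loci"`.
#' @return A [DistanceSpectrum-class].
#' @export
classedSpectra <- function(reads, preset = names(.SPECTRUM_PRESETS),
        deltaRange = c(-20L, 50L), mode = c("pairs", "loci")) {
    preset <- match.arg(preset)
    mode <- match.arg(mode)
    cls <- .SPECTRUM_PRESETS[[preset]]
    mapsA <- collapseToLoci(reads, cls$a)
    if (identical(cls$a, cls$b)) {
        sp <- if (mode == "pairs") pairSpectrum(mapsA, mapsA, deltaRange)
            else locusSpectrum(mapsA, mapsA, deltaRange)
    } else {
        mapsB <- collapseToLoci(reads, cls$b)
        s1 <- .spectrumFromSets(mapsA, mapsB, deltaRange, mode)
        s2 <- .spectrumFromSets(mapsB, mapsA, deltaRange, mode)
        sp <- s1
        sp@counts <- s1@counts + s2@counts
        sp@symmetrized <- TRUE
    }
    sp@preset <- preset
    sp
}

#' Spectrum accessors
#'
#' `deltas()` returns the offsets covered, `spectrumCounts()` the
#' named count vector, and `argmaxDelta()` the offset with the highest
#' count (`NA` for an all-zero spectrum; ties resolve to the smallest
#' offset).
#'
#' @param x A [DistanceSpectrum-class].
#' @return See above.
#' @export
deltas <- function(x) {
    stopifnot(is(x, "DistanceSpectrum"))
    x@delta
}

#' @rdname deltas
#' @export
spectrumCounts <- function(x) {
    stopifnot(is(x, "DistanceSpectrum"))
    structure(x@counts, names = as.character(x@delta))
}

#' @rdname deltas
#' @export
argmaxDelta <- function(x) {
    stopifnot(is(x, "DistanceSpectrum"))
    if (all(x@counts == 0)) return(NA_integer_)
    x@delta[which.max(x@counts)]
}

#' @export
#' @describeIn deltas Spectrum as a data.frame with columns delta, count,
#'   mode, preset.
setMethod("as.data.frame", "DistanceSpectrum", function(x, ...) {
    data.frame(delta = x@delta, count = x@counts, mode = x@mode,
        preset = if (is.na(x@preset)) "custom" else x@preset)
})

#' Write a spectrum as TSV
#'
#' @param x A [DistanceSpectrum-class].
#' @param path Output file; columns delta, count, mode, preset.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(x, path) {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
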