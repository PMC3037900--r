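#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' StrandWeightMap: per-chromosome, per-strand 5'-end weight map
#'
#' A `StrandWeightMap` records, for one chromosome and one strand, the summed
#' copy number of all reads whose 5' end falls at each genomic position
#' (absent positions have weight zero), together with a registry of the
#' distinct sequences behind each position.  All coordinates are 0-based.
#' The 5' end of a minus-strand read is its highest genomic coordinate.
#'
#' @slot chrom Chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot positions Sorted integer vector of occupied 5'-end coordinates.
#' @slot weights Numeric vector parallel to `positions`; each entry is the
#'   sum of copy numbers of the sequences registered at that coordinate and
#'   is strictly positive.
#' @slot registry `data.frame` with columns `position`, `sequence` (may be
#'   `NA` when the input format carried none), `copy_number`, `length`; one
#'   row per distinct (position, sequence) pair.
#'
#' @seealso [collapseToLoci()], [pairSpectrum()]
#' @exportClass StrandWeightMap
setClass("StrandWeightMap",
    slots = c(
        chrom = "character",
        strand = "character",
        positions = "integer",
        weights = "numeric",
        registry = "data.frame"
    )
)

setValidity("StrandWeightMap", function(object) {
    msg <- NULL
    if (length(object@chrom) != 1L)
        msg <- c(msg, "'chrom' must be a single chromosome name")
    if (!(length(object@strand) == 1L && object@strand %in% c("+", "-")))
        msg <- c(msg, "'strand' must be \"+\" or \"-\"")
    if (length(object@positions) != length(object@weights))
        msg <- c(msg, "'positions' and 'weights' must be parallel")
    if (is.unsorted(object@positions, strictly = TRUE))
        msg <- c(msg, "'positions' must be strictly increasing")
    if (any(object@weights <= 0))
        msg <- c(msg, "all weights must be strictly positive")
    reg <- object@registry
    need <- c("position", "sequence", "copy_number", "length")
    if (!all(need %in% names(reg))) {
        msg <- c(msg, sprintf("registry must have columns %s",
            paste(need, collapse = ", ")))
    } else if (nrow(reg) || length(object@positions)) {
        tal <- rowsum(as.numeric(reg$copy_number), reg$position)
        pos <- as.integer(rownames(tal))
        o <- order(pos)
        if (!identical(pos[o], object@positions) ||
            !isTRUE(all.equal(as.numeric(tal[o]), object@weights)))
            msg <- c(msg, "weights must equal per-position sums of registry copy numbers")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a StrandWeightMap from a sequence registry
#'
#' Aggregates a per-read registry into the per-position weight map.  Rows
#' sharing both position and sequence are merged by summing copy numbers.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param registry `data.frame` with columns `position` (0-based 5'-end
#'   coordinate), `sequence`, `copy_number`, `length`.
#' @return A [StrandWeightMap-class] object.
#' @export
StrandWeightMap <- function(chrom, strand,
        registry = data.frame(position = integer(), sequence = character(),
            copy_number = integer(), length = integer())) {
    stopifnot(is.data.frame(registry))
    if (nrow(registry)) {
        key <- paste(registry$position, registry$sequence, sep = "\r")
        if (anyDuplicated(key)) {
            cn <- rowsum(as.numeric(registry$copy_number), key)
            first <- !duplicated(key)
            registry <- registry[first, , drop = FALSE]
            registry$copy_number <- as.numeric(cn[match(key[first], rownames(cn))])
        }
        registry <- registry[order(registry$position, registry$sequence), ,
            drop = FALSE]
        rownames(registry) <- NULL
        tal <- rowsum(as.numeric(registry$copy_number), registry$position)
        pos <- as.integer(rownames(tal))
        o <- order(pos)
        positions <- pos[o]
        weights <- as.numeric(tal[o])
    } else {
        positions <- integer()
        weights <- numeric()
    }
    new("StrandWeightMap", chrom = chrom, strand = strand,
        positions = positions, weights = weights, registry = registry)
}

setMethod("show", "StrandWeightMap", function(object) {
    cat(sprintf("StrandWeightMap: %s(%s), %d occupied positions, total weight %g\n",
        object@chrom, object@strand, length(object@positions),
        sum(object@weights)))
})

#' WeightMapSet: strand-resolved weight maps for a whole dataset
#'
#' Container for the plus- and minus-strand [StrandWeightMap-class] objects
#' of every chromosome, built from one length class of reads.
#'
#' @slot maps Named list of `StrandWeightMap`; names are `"<chrom>|<strand>"`.
#' @slot lengthClass Integer vector `c(min, max)` of read lengths (nt,
#'   inclusive) that contributed.
#'
#' @seealso [collapseToLoci()]
#' @exportClass WeightMapSet
setClass("WeightMapSet",
    slots = c(maps = "list", lengthClass = "integer"))

setValidity("WeightMapSet", function(object) {
    msg <- NULL
    lc <- object@lengthClass
    if (length(lc) != 2L || anyNA(lc) || lc[1] > lc[2])
        msg <- c(msg, "'lengthClass' must be c(min, max) with min <= max")
    if (length(object@maps)) {
        ok <- vapply(object@maps, is, logical(1), class2 = "StrandWeightMap")
        if (!all(ok))
            msg <- c(msg, "all elements of 'maps' must be StrandWeightMap")
        else {
            expect <- vapply(object@maps,
                function(m) paste0(m@chrom, "|", m@strand), character(1))
            if (!identical(unname(expect), names(object@maps)))
                msg <- c(msg, "map names must be \"<chrom>|<strand>\"")
        }
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "WeightMapSet", function(object) {
    cat(sprintf(
        "WeightMapSet: %d map(s) over %d chromosome(s), length class %d-%d nt\n",
        length(object@maps), length(chromosomes(object)),
        object@lengthClass[1], object@lengthClass[2]))
})

#' DistanceSpectrum: sense/antisense 5'-end offset distribution
#'
#' Counts of sense-antisense "pairs" (weighted-minimum rule) or occupied
#' loci per 5'-end offset \eqn{\Delta} = (minus-strand 5') - (plus-strand
#' 5').  The ping-pong duplex appears at \eqn{\Delta = 9}; the 19-nt
#' by-product pattern at \eqn{\Delta = 28}.
#'
#' @slot delta Integer vector of offsets covered (consecutive).
#' @slot counts Numeric vector parallel to `delta`; non-negative.
#' @slot mode `"pairs"` (weighted-minimum) or `"loci"` (locus count).
#' @slot classPlus,classMinus Integer `c(min, max)` length classes applied
#'   to the plus- and minus-strand maps.
#' @slot symmetrized Logical; `TRUE` when an asymmetric class pair was
#'   applied in both strand assignments and the two spectra summed.
#' @slot preset Name of the length-class preset used, or `NA`.
#'
#' @seealso [pairSpectrum()], [locusSpectrum()], [classedSpectra()]
#' @exportClass DistanceSpectrum
setClass("DistanceSpectrum",
    slots = c(
        delta = "integer",
        counts = "numeric",
        mode = "character",
        classPlus = "integer",
        classMinus = "integer",
        symmetrized = "logical",
        preset = "character"
    )
)

setValidity("DistanceSpectrum", function(object) {
    msg <- NULL
    if (length(object@delta) != length(object@counts))
        msg <- c(msg, "'delta' and 'counts' must be parallel")
    if (length(object@delta) == 0L)
        msg <- c(msg, "'delta' range must be non-empty")
    if (length(object@delta) && !identical(object@delta,
            seq(object@delta[1], object@delta[length(object@delta)])))
        msg <- c(msg, "'delta' must be a consecutive integer range")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (!object@mode %in% c("pairs", "loci"))
        msg <- c(msg, "'mode' must be \"pairs\" or \"loci\"")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "DistanceSpectrum", function(object) {
    pk <- argmaxDelta(object)
    cat(sprintf("DistanceSpectrum (%s mode): delta %d..%d%s\n",
        object@mode, object@delta[1], object@delta[length(object@delta)],
        if (is.na(object@preset)) "" else sprintf(", preset %s", object@preset)))
    cat(sprintf("  total count %g; argmax at delta = %s\n",
        sum(object@counts), if (is.na(pk)) "NA (flat zero)" else pk))
})

#' MarkovStrandBias: two-state strand-bias model over P28 sites
#'
#' Transition counts and maximum-likelihood transition probabilities of the
#' two-state (T = 19-mer on plus strand, B = 19-mer on minus strand) Markov
#' chain read off consecutive P28 sites along each chromosome.
#'
#' @slot counts 2x2 integer matrix of transition counts, rows = from-state,
#'   columns = to-state, dimnames `T`/`B`.
#' @slot probs 2x2 numeric matrix of row-normalized probabilities; a row
#'   with zero total is `NA` (undefined, not 0/0).
#' @slot nSites Number of sites in the chain.
#' @slot nTransitions Number of consecutive same-chromosome site pairs.
#'
#' @seealso [estimateStrandBias()]
#' @exportClass MarkovStrandBias
setClass("MarkovStrandBias",
    slots = c(counts = "matrix", probs = "matrix",
        nSites = "integer", nTransitions = "integer"))

setValidity("MarkovStrandBias", function(object) {
    msg <- NULL
    if (!identical(dim(object@counts), c(2L, 2L)) ||
        !identical(dimnames(object@counts), list(c("T", "B"), c("T", "B"))))
        msg <- c(msg, "'counts' must be 2x2 with dimnames T/B")
    if (any(object@counts < 0))
        msg <- c(msg, "transition counts must be non-negative")
    if (sum(object@counts) != object@nTransitions)
        msg <- c(msg, "'nTransitions' must equal the total transition count")
    for (s in c("T", "B")) {
        tot <- sum(object@counts[s, ])
        p <- object@probs[s, ]
        if (tot > 0) {
            if (anyNA(p) || abs(sum(p) - 1) > 1e-9)
                msg <- c(msg, sprintf("row %s of 'probs' must sum to 1", s))
        } else if (!all(is.na(p)))
            msg <- c(msg, sprintf("row %s has no counts; probs must be NA", s))
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MarkovStrandBias", function(object) {
    cat(sprintf("MarkovStrandBias: %d sites, %d transitions\n",
        object@nSites, object@nTransitions))
    cat("  counts:\n")
    print(object@counts)
    cat("  transition probabilities:\n")
    print(round(object@probs, 4))
})
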