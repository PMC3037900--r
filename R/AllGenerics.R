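#' Chromosomes represented in an object
#'
#' @param x A [WeightMapSet-class] or similar container.
#' @return Character vector of chromosome names.
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' Extract one strand's weight map
#'
#' @param x A [WeightMapSet-class].
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return The [StrandWeightMap-class] for that chromosome and strand; an
#'   empty map when no read of the set's length class had a 5' end there.
#' @export
setGeneric("weightMap", function(x, chrom, strand) standardGeneric("weightMap"))

#' Weighted-minimum pair spectrum of 5'-end offsets
#'
#' For each offset \eqn{\Delta} in `deltaRange`, counts
#' \deqn{pairs(\Delta) = \sum_i \min(weight^+(i), weight^-(i+\Delta))}
#' summed over all occupied plus-strand positions \eqn{i}, where
#' \eqn{weight^\pm} are the per-position summed copy numbers of the two
#' strand maps.  Taking the smaller of the two copy numbers keeps a few very
#' abundantly sequenced reads from dominating the spectrum.  Only the
#' distance between 5' ends matters; read lengths are ignored beyond the
#' length class the maps were built with.
#'
#' @param plus,minus Two [StrandWeightMap-class] objects from the same
#'   chromosome (plus- and minus-strand), or two [WeightMapSet-class]
#'   objects, in which case per-chromosome spectra are summed genome-wide
#'   (plus-strand maps taken from `plus`, minus-strand maps from `minus`).
#' @param deltaRange Integer `c(min, max)` of offsets \eqn{\Delta} =
#'   (minus 5') - (plus 5') to evaluate; default `c(-20, 50)`.
#' @return A [DistanceSpectrum-class] with `mode = "pairs"`.
#' @examples
#' plusMap <- StrandWeightMap("chr1", "+", data.frame(position = 100L,
#'     sequence = "A", copy_number = 3L, length = 26L))
#' minusMap <- StrandWeightMap("chr1", "-", data.frame(position = 109L,
#'     sequence = "C", copy_number = 7L, length = 27L))
#' sp <- pairSpectrum(plusMap, minusMap)
#' spectrumCounts(sp)[["9"]]  # min(3, 7) = 3 pairs at offset 9
#' @export
setGeneric("pairSpectrum", function(plus, minus, deltaRange = c(-20L, 50L))
    standardGeneric("pairSpectrum"))

#' Locus-count spectrum of 5'-end offsets
#'
#' A more restrictive variant of [pairSpectrum()]: for each offset
#' \eqn{\Delta} it counts the number of genomic loci (positions \eqn{i} with
#' `weight+` > 0 and `weight-` at \eqn{i+\Delta} > 0), regardless of copy
#' numbers.
#'
#' @inheritParams pairSpectrum
#' @return A [DistanceSpectrum-class] with `mode = "loci"`.
#' @export
setGeneric("locusSpectrum", function(plus, minus, deltaRange = c(-20L, 50L))
    standardGeneric("locusSpectrum"))
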