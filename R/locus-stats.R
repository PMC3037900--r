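#' Two-state Markov model of P28 strand bias
#'
#' Orders P28 sites by chromosome and center coordinate, reads off the
#' per-chromosome state sequence (T = 19-mer on plus strand, B = 19-mer on
#' minus strand), counts transitions between consecutive sites on the same
#' chromosome, and row-normalizes to maximum-likelihood transition
#' probabilities, e.g. \eqn{p_{T \to T} = n_{T \to T} / (n_{T \to B} +
#' n_{T \to T})}.  Under no strand bias all four probabilities are near
#' 0.5; a locus-level bias drives the stay probabilities towards 1.  A
#' state never left has an undefined row, reported as `NA`.
#'
#' @param p28Sites `DataFrame` from [detectP28Sites()].
#' @return A [MarkovStrandBias-class].
#' @export
estimateStrandBias <- function(p28Sites) {
    counts <- matrix(0L, 2, 2, dimnames = list(c("T", "B"), c("T", "B")))
    n <- nrow(p28Sites)
    if (n) {
        o <- order(p28Sites$chrom, p28Sites$center)
        chrom <- p28Sites$chrom[o]
        state <- ifelse(p28Sites$orientation[o] == "P28T", "T", "B")
        from <- state[-n]
        to <- state[-1]
        same <- chrom[-n] == chrom[-1]
        tab <- table(factor(from[same], c("T", "B")),
            factor(to[same], c("T", "B")))
        counts[] <- as.integer(tab)
    }
    probs <- counts / rowSums(counts)
    probs[rowSums(counts) == 0, ] <- NA_real_
    new("MarkovStrandBias", counts = counts, probs = probs,
        nSites = n, nTransitions = sum(counts))
}

#' Strand-bias accessors
#'
#' @param x A [MarkovStrandBias-class].
#' @return `transitionCounts()`: the 2x2 count matrix;
#'   `transitionProbs()`: the 2x2 row-stochastic probability matrix (rows
#'   with no observations are `NA`).
#' @export
transitionCounts <- function(x) {
    stopifnot(is(x, "MarkovStrandBias"))
    x@counts
}

#' @rdname transitionCounts
#' @export
transitionProbs <- function(x) {
    stopifnot(is(x, "MarkovStrandBias"))
    x@probs
}

.firstNtTally <- function(seqs, weightsList, weighting) {
    seqs <- unlist(seqs, use.names = FALSE)
    w <- unlist(weightsList, use.names = FALSE)
    if (weighting == "unweighted") w <- rep(1, length(seqs))
    keep <- !is.na(seqs) & nzchar(seqs)
    seqs <- seqs[keep]; w <- w[keep]
    nt1 <- toupper(substr(seqs, 1, 1))
    nt1[nt1 == "T"] <- "U"
    tal <- tapply(w, factor(nt1, c("A", "C", "G", "U")), sum)
    tal[is.na(tal)] <- 0
    list(tally = tal, n_members = length(seqs), n_weight = sum(w))
}

#' First-nucleotide composition at triplex loci
#'
#' Tallies the nucleotide at read position 1 of the long piRNA members of
#' triplex loci, split into the piRNAs on the same strand as the 19-mer
#' by-product and those on the opposite strand (the presumed cleavage
#' guides, which show the strong primary-piRNA 1U bias).  T in the read
#' sequence is reported as U.  Each distinct member sequence contributes
#' one vote by default; `weighting = "copy_number"` weights votes by copy
#' number instead.
#'
#' @param triplexes `DataFrame` from [detectTriplexes()]; members must
#'   carry sequences.
#' @param weighting `"unweighted"` or `"copy_number"`.
#' @return `data.frame` with one row per group (`same_strand`,
#'   `opposite`): frequencies of A, C, G, U at position 1 (each row sums
#'   to 1 when it has any votes), plus `n_members` and `n_weight`.
#'   Empty triplex input gives a zero-row frame.
#' @export
firstNtFrequencies <- function(triplexes,
        weighting = c("unweighted", "copy_number")) {
    weighting <- match.arg(weighting)
    empty <- data.frame(group = character(), A = numeric(), C = numeric(),
        G = numeric(), U = numeric(), n_members = integer(),
        n_weight = numeric())
    if (!nrow(triplexes)) return(empty)
    groups <- list(same_strand = list(triplexes$same_members,
            triplexes$same_copies),
        opposite = list(triplexes$opp_members, triplexes$opp_copies))
    rows <- lapply(names(groups), function(g) {
        tal <- .firstNtTally(groups[[g]][[1]], groups[[g]][[2]], weighting)
        tot <- sum(tal$tally)
        fr <- if (tot > 0) tal$tally / tot else tal$tally * NA_real_
        data.frame(group = g, A = fr[["A"]], C = fr[["C"]], G = fr[["G"]],
            U = fr[["U"]], n_members = tal$n_members,
            n_weight = tal$n_weight)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Guide/product length-pair histogram
#'
#' Two-dimensional tally of (product length, guide length) over cleavage
#' pairs - the raw matrix behind the length contour, in which the product
#' length is sharply peaked at 19 nt while the guide varies across the
#' piRNA range.  Weighting `"min_copy"` counts each pair with the smaller
#' of the two members' copy numbers, consistent with the weighted-minimum
#' pairing rule.
#'
#' @param pairs `data.frame` from [extractCleavagePairs()].
#' @param weighting `"unweighted"` or `"min_copy"`.
#' @param productRange,guideRange Axis ranges (inclusive).
#' @return Numeric matrix, rows = product length (15-22), columns = guide
#'   length (23-32); total equals the number (or summed weight) of pairs.
#' @seealso [productLengthMarginal()]
#' @export
lengthPairHistogram <- function(pairs,
        weighting = c("unweighted", "min_copy"),
        productRange = c(15L, 22L), guideRange = c(23L, 32L)) {
    weighting <- match.arg(weighting)
    pl <- seq(productRange[1], productRange[2])
    gl <- seq(guideRange[1], guideRange[2])
    h <- matrix(0, length(pl), length(gl),
        dimnames = list(product_length = pl, guide_length = gl))
    if (nrow(pairs)) {
        w <- if (weighting == "unweighted") rep(1, nrow(pairs))
            else pmin(pairs$guide_copy, pairs$product_copy)
        i <- match(pairs$product_length, pl)
        j <- match(pairs$guide_length, gl)
        ok <- !is.na(i) & !is.na(j)
        for (k in which(ok)) h[i[k], j[k]] <- h[i[k], j[k]] + w[k]
    }
    h
}

#' Product-length marginal of a length-pair histogram
#'
#' @param hist Matrix from [lengthPairHistogram()].
#' @return Named numeric vector over product lengths.
#' @export
productLengthMarginal <- function(hist) {
    rowSums(hist)
}

#' Write locus-statistics tables as TSV
#'
#' `writeTransitionTable()` writes one row per transition (from, to,
#' count, probability); `writeCompositionTable()` the composition report
#' as-is; `writeLengthHistogram()` the long-format histogram
#' (product_length, guide_length, count).
#'
#' @param x The corresponding object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTransitionTable <- function(x, path) {
    stopifnot(is(x, "MarkovStrandBias"))
    grid <- expand.grid(from = c("T", "B"), to = c("T", "B"),
        stringsAsFactors = FALSE)
    df <- data.frame(from = grid$from, to = grid$to,
        count = x@counts[cbind(grid$from, grid$to)],
        probability = x@probs[cbind(grid$from, grid$to)])
    df$probability <- ifelse(is.na(df$probability), "undefined",
        format(df$probability, digits = 6))
    write.table(df[order(df$from, decreasing = TRUE), ], path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTransitionTable
#' @export
writeCompositionTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTransitionTable
#' @export
writeLengthHistogram <- function(x, path) {
    df <- data.frame(
        product_length = as.integer(rownames(x)[row(x)]),
        guide_length = as.integer(colnames(x)[col(x)]),
        count = as.vector(x))
    df <- df[order(df$product_length, df$guide_length), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
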