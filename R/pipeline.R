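#' @importFrom utils write.table read.table
NULL

#' Run the full processing-signature report
#'
#' Chains every analysis stage on one read set and writes the results as
#' TSV tables into `outDir`:
#'
#' * the four classed 5'-offset spectra (`spectrum_<preset>.tsv`);
#' * P9 and P28 site tables (`sites_P9.tsv`, `sites_P28.tsv`);
#' * cross-correlation of P9 centers against all / plus-strand /
#'   minus-strand P28 centers (`crosscorrelation.tsv`);
#' * the triplex-locus table (`triplexes.tsv`);
#' * strand-bias transition counts and probabilities (`transitions.tsv`);
#' * first-nucleotide composition in both weightings
#'   (`composition_unweighted.tsv`, `composition_copy_number.tsv`);
#' * the guide/product length histogram and its product-length marginal
#'   (`length_histogram.tsv`, `product_length_marginal.tsv`);
#' * a run summary with the filter accounting (total mappers, perfect
#'   unique mappers) and per-pattern locus counts (`summary.tsv`).
#'
#' Running the report twice on the same input produces byte-identical
#' files.  If any stage fails, files already written are removed.
#'
#' @param input Path to a SAM/BAM/BED-dialect file, or a `GRanges` of
#'   mapped reads.
#' @param outDir Output directory (created if needed).
#' @param format Input format for file input, see [parseMappedReads()].
#' @param deltaRange Offset interval for spectra.
#' @param window Cross-correlation window.
#' @param shortLen Exact short-read length for P28 site detection
#'   (default 19; use 18 for beta-eliminated libraries).
#' @param excludeChrom Chromosomes dropped by [filterUniquePerfect()].
#' @param verbose Emit progress messages with the filter accounting.
#' @return Invisibly, a list with all intermediate objects (reads,
#'   spectra, sites, crossCorrelations, triplexes, strandBias,
#'   composition, lengthHistogram, summary).
#' @export
runReport <- function(input, outDir, format = "auto",
        deltaRange = c(-20L, 50L), window = 50L, shortLen = 19L,
        excludeChrom = c("chrM", "chrMT", "MT", "M"), verbose = TRUE) {
    say <- function(...) if (verbose) message(sprintf(...))
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    written <- character()
    out <- function(name) {
        p <- file.path(outDir, name)
        written <<- c(written, p)
        p
    }
    res <- tryCatch({
        rawReads <- if (is(input, "GRanges")) input
            else parseMappedReads(input, format)
        say("total mappers: %d records, %g read copies", length(rawReads),
            sum(mcols(rawReads)$copy_number))
        reads <- filterUniquePerfect(rawReads, excludeChrom)
        say("perfect unique mappers: %d records, %g read copies",
            length(reads), sum(mcols(reads)$copy_number))

        spectra <- lapply(names(.SPECTRUM_PRESETS), function(p) {
            sp <- classedSpectra(reads, p, deltaRange)
            writeSpectrum(sp, out(sprintf("spectrum_%s.tsv", p)))
            sp
        })
        names(spectra) <- names(.SPECTRUM_PRESETS)

        longMaps <- collapseToLoci(reads, "long")
        shortMaps <- collapseToLoci(reads, shortLen)
        p9 <- detectP9Sites(longMaps)
        p28 <- detectP28Sites(shortMaps, longMaps)
        say("P9 loci: %d; P28 loci: %d (%d P28T, %d P28B)", nrow(p9),
            nrow(p28), sum(p28$orientation == "P28T"),
            sum(p28$orientation == "P28B"))
        writeSiteTable(p9, out("sites_P9.tsv"))
        writeSiteTable(p28, out("sites_P28.tsv"))

        c9 <- patternCenters(p9)
        ccAll <- crossCorrelate(c9, patternCenters(p28), window)
        ccT <- crossCorrelate(c9,
            patternCenters(p28[p28$orientation == "P28T", ]), window)
        ccB <- crossCorrelate(c9,
            patternCenters(p28[p28$orientation == "P28B", ]), window)
        cc <- data.frame(lag = ccAll$lag, p28_all = ccAll$value,
            p28t = ccT$value, p28b = ccB$value)
        writeCrossCorrelation(cc, out("crosscorrelation.tsv"))

        triplexes <- detectTriplexes(p9, p28)
        say("triplex loci: %d", nrow(triplexes))
        writeTriplexTable(triplexes, out("triplexes.tsv"))

        bias <- estimateStrandBias(p28)
        writeTransitionTable(bias, out("transitions.tsv"))

        compU <- firstNtFrequencies(triplexes, "unweighted")
        compW <- firstNtFrequencies(triplexes, "copy_number")
        writeCompositionTable(compU, out("composition_unweighted.tsv"))
        writeCompositionTable(compW, out("composition_copy_number.tsv"))

        allMaps <- collapseToLoci(reads, "all")
        pairs <- extractCleavagePairs(allMaps)
        hist <- lengthPairHistogram(pairs)
        writeLengthHistogram(hist, out("length_histogram.tsv"))
        marg <- productLengthMarginal(hist)
        write.table(data.frame(product_length = as.integer(names(marg)),
            count = as.numeric(marg)), out("product_length_marginal.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

        summary <- data.frame(
            metric = c("total_records", "perfect_unique_records",
                "perfect_unique_copies", "p9_loci", "p28_loci",
                "p28t_loci", "p28b_loci", "triplex_loci",
                "cleavage_pairs"),
            value = c(length(rawReads), length(reads),
                sum(mcols(reads)$copy_number), nrow(p9), nrow(p28),
                sum(p28$orientation == "P28T"),
                sum(p28$orientation == "P28B"), nrow(triplexes),
                nrow(pairs)))
        write.table(summary, out("summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

        list(reads = reads, spectra = spectra, p9Sites = p9,
            p28Sites = p28, crossCorrelations = cc,
            triplexes = triplexes, strandBias = bias,
            composition = list(unweighted = compU, copy_number = compW),
            cleavagePairs = pairs, lengthHistogram = hist,
            summary = summary)
    }, error = function(e) {
        unlink(written)
        stop(e)
    })
    invisible(res)
}

#' Dispatch one pipeline subcommand
#'
#' Thin orchestration layer behind the command-line script
#' (`system.file("scripts", "pirnapatterns.R", package =
#' "piRNApatterns")`).  Each subcommand runs the corresponding module on
#' the options list and writes TSV output under `opts$out`:
#' `simulate` (needs `triplexes`, `p9only`, `background`, `seed`, ...),
#' `spectrum` (needs `input`, `preset`), `sites`, `colocalize`,
#' `strandbias`, `composition` and `report`.
#'
#' @param name Subcommand name.
#' @param opts Named list of options; unknown names are ignored by the
#'   subcommands that do not use them.
#' @return Invisibly, the subcommand's result object.
#' @export
runSubcommand <- function(name,
        opts = list()) {
    name <- match.arg(name, c("simulate", "spectrum", "sites",
        "colocalize", "strandbias", "composition", "report"))
    o <- function(key, default) if (!is.null(opts[[key]])) opts[[key]]
        else default
    outDir <- o("out", ".")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    if (name == "simulate") {
        cfg <- simulationConfig(
            nChromosomes = o("chromosomes", 2L),
            chromLength = o("chromlen", 1e6),
            nTriplexLoci = o("triplexes", 500L),
            nP9OnlyLoci = o("p9only", 0L),
            nBackgroundReads = o("background", 0L),
            productLength = o("shortlen", 19L),
            seed = o("seed", 1L))
        ds <- simulateDataset(cfg)
        writeFixture(ds, file.path(outDir, "reads.bed"),
            file.path(outDir, "truth.tsv"),
            if (isTRUE(o("sam", FALSE))) file.path(outDir, "reads.sam"))
        return(invisible(ds))
    }
    reads <- filterUniquePerfect(
        parseMappedReads(o("input", stop("--input is required")),
            o("format", "auto")),
        o("exclude", c("chrM", "chrMT", "MT", "M")))
    deltaRange <- c(o("deltamin", -20L), o("deltamax", 50L))
    switch(name,
        spectrum = {
            sp <- classedSpectra(reads, o("preset", "all_15_35"),
                deltaRange, o("mode", "pairs"))
            writeSpectrum(sp, file.path(outDir,
                sprintf("spectrum_%s.tsv", sp@preset)))
            invisible(sp)
        },
        sites = {
            longMaps <- collapseToLoci(reads, "long")
            shortMaps <- collapseToLoci(reads, o("shortlen", 19L))
            p9 <- detectP9Sites(longMaps)
            p28 <- detectP28Sites(shortMaps, longMaps)
            writeSiteTable(p9, file.path(outDir, "sites_P9.tsv"))
            writeSiteTable(p28, file.path(outDir, "sites_P28.tsv"))
            invisible(list(p9 = p9, p28 = p28))
        },
        colocalize = {
            longMaps <- collapseToLoci(reads, "long")
            shortMaps <- collapseToLoci(reads, o("shortlen", 19L))
            p9 <- detectP9Sites(longMaps)
            p28 <- detectP28Sites(shortMaps, longMaps)
            c9 <- patternCenters(p9)
            w <- o("window", 50L)
            cc <- data.frame(
                lag = seq(-w, w),
                p28_all = crossCorrelate(c9, patternCenters(p28), w)$value,
                p28t = crossCorrelate(c9, patternCenters(
                    p28[p28$orientation == "P28T", ]), w)$value,
                p28b = crossCorrelate(c9, patternCenters(
                    p28[p28$orientation == "P28B", ]), w)$value)
            writeCrossCorrelation(cc, file.path(outDir,
                "crosscorrelation.tsv"))
            tri <- detectTriplexes(p9, p28)
            writeTriplexTable(tri, file.path(outDir, "triplexes.tsv"))
            invisible(list(crossCorrelation = cc, triplexes = tri))
        },
        strandbias = {
            longMaps <- collapseToLoci(reads, "long")
            shortMaps <- collapseToLoci(reads, o("shortlen", 19L))
            bias <- estimateStrandBias(
                detectP28Sites(shortMaps, longMaps))
            writeTransitionTable(bias, file.path(outDir,
                "transitions.tsv"))
            invisible(bias)
        },
        composition = {
            longMaps <- collapseToLoci(reads, "long")
            shortMaps <- collapseToLoci(reads, o("shortlen", 19L))
            tri <- detectTriplexes(detectP9Sites(longMaps),
                detectP28Sites(shortMaps, longMaps))
            comp <- firstNtFrequencies(tri,
                o("weighting", "unweighted"))
            writeCompositionTable(comp, file.path(outDir,
                "composition.tsv"))
            invisible(comp)
        },
        report = runReport(reads, outDir, deltaRange = deltaRange,
            window = o("window", 50L), shortLen = o("shortlen", 19L),
            verbose = !isTRUE(o("quiet", FALSE)))
    )
}
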