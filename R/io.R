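# Readers and writers. All on-disk interval formats follow the BED
# convention (0-based half-open); in-memory GRanges and all human-facing
# reports are 1-based inclusive.

#' Write binned counts as a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, gc, count — one file per sample.
#'
#' @param bc a single-sample [BinnedCounts-class].
#' @param path output path (a \code{.gz} suffix writes gzip).
#' @export
writeBinnedCounts <- function(bc, path) {
    stopifnot(methods::is(bc, "BinnedCounts"))
    cnt <- SummarizedExperiment::assay(bc, "counts")
    if (ncol(cnt) != 1L) stop("write one sample per file")
    bins <- SummarizedExperiment::rowRanges(bc)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                     start = GenomicRanges::start(bins) - 1L,
                     end = GenomicRanges::end(bins),
                     gc = sprintf("%.6f", S4Vectors::mcols(bins)$gc),
                     count = as.integer(cnt[, 1]))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Read binned counts from a BED-like TSV
#'
#' Validates sortedness and non-negative counts; gzip input is read
#' transparently. Round-trips with [writeBinnedCounts()].
#'
#' @param path input path.
#' @param sampleId sample label (default: file name without extension).
#' @param chromLengths optional named lengths attached as seqlengths.
#' @return a [BinnedCounts-class].
#' @export
readBinnedCounts <- function(path, sampleId = NULL, chromLengths = NULL) {
    if (is.null(sampleId))
        sampleId <- sub("\\.(bed|tsv|txt)(\\.gz)?$", "", basename(path))
    df <- utils::read.table(gzfile(path), sep = "\t",
                            col.names = c("chrom", "start", "end", "gc",
                                          "count"),
                            colClasses = c("character", "integer",
                                           "integer", "numeric", "numeric"))
    bad <- which(df$count < 0)
    if (length(bad))
        stop("negative count at line ", bad[1], " of ", path)
    ord <- order(factor(df$chrom, levels = unique(df$chrom)), df$start)
    if (any(ord != seq_len(nrow(df))))
        stop("bins not sorted by (chrom, start) at line ",
             which(ord != seq_len(nrow(df)))[1], " of ", path)
    bins <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start + 1L, df$end))
    S4Vectors::mcols(bins)$gc <- df$gc
    S4Vectors::mcols(bins)$mappable <- TRUE
    if (!is.null(chromLengths))
        GenomeInfoDb::seqlengths(bins) <- chromLengths[
            GenomeInfoDb::seqlevels(bins)]
    newBinnedCounts(bins, matrix(as.integer(df$count), ncol = 1,
                                 dimnames = list(NULL, sampleId)))
}

#' Write segments as a SEG-style TSV
#'
#' Header: sample, chrom, start (0-based), end, n_bins, mean_log2, cn
#' (cn is NA before [estimateTumorFraction()]).
#'
#' @param segs a [SegmentSet-class].
#' @param path output path.
#' @export
writeSegments <- function(segs, path) {
    gr <- segs@segments
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(sample = mc$sampleId,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     n_bins = mc$nBins,
                     mean_log2 = sprintf("%.6f", mc$meanLog2),
                     cn = if (is.null(mc$cn)) NA_integer_ else mc$cn)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read segments written by [writeSegments()]
#'
#' @param path input path.
#' @return a [SegmentSet-class] (tumor fraction not estimated).
#' @export
readSegments <- function(path) {
    df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end),
                                 sampleId = as.character(df$sample),
                                 meanLog2 = as.numeric(df$mean_log2),
                                 nBins = as.integer(df$n_bins))
    if (!all(is.na(df$cn))) S4Vectors::mcols(gr)$cn <- as.integer(df$cn)
    methods::new("SegmentSet", segments = gr, tumorFraction = NA_real_,
                 tfFlag = "not estimated")
}

#' Write a log2 profile as a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, log2 (\code{NA} where masked).
#'
#' @param profile a single-sample [Log2Profile-class].
#' @param path output path.
#' @export
writeLog2Profile <- function(profile, path) {
    stopifnot(methods::is(profile, "Log2Profile"))
    bins <- SummarizedExperiment::rowRanges(profile)
    l2 <- SummarizedExperiment::assay(profile, "log2")
    if (ncol(l2) != 1L) stop("write one sample per file")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                     start = GenomicRanges::start(bins) - 1L,
                     end = GenomicRanges::end(bins),
                     log2 = l2[, 1])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Read a log2 profile written by [writeLog2Profile()]
#'
#' @param path input path.
#' @param sampleId sample label (default: file name).
#' @return a [Log2Profile-class].
#' @export
readLog2Profile <- function(path, sampleId = NULL) {
    if (is.null(sampleId))
        sampleId <- sub("\\.(bed|tsv|txt)(\\.gz)?$", "", basename(path))
    df <- utils::read.table(gzfile(path), sep = "\t",
                            col.names = c("chrom", "start", "end", "log2"),
                            colClasses = c("character", "integer",
                                           "integer", "numeric"))
    bins <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start + 1L, df$end))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = matrix(df$log2, ncol = 1,
                                    dimnames = list(NULL, sampleId))),
        rowRanges = bins)
    methods::new("Log2Profile", se)
}

#' Read a BED-like annotation table into GRanges
#'
#' Expects chrom, start (0-based), end, name and optionally score and
#' strand columns; used for arm tables, gene annotations and truth sets
#' (whose score column carries the copy number).
#'
#' @param path input path.
#' @param scoreAs optional name under which to store the score column
#'   (e.g. \code{"cn"}).
#' @return \code{GRanges} with \code{name} (and optional score, strand).
#' @export
readBedRanges <- function(path, scoreAs = NULL) {
    df <- utils::read.table(gzfile(path), sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("need at least 4 BED columns in ", path)
    gr <- GenomicRanges::GRanges(df[[1]],
                                 IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                                 name = as.character(df[[4]]))
    if (ncol(df) >= 5 && !is.null(scoreAs))
        S4Vectors::mcols(gr)[[scoreAs]] <- as.numeric(df[[5]])
    if (ncol(df) >= 6)
        GenomicRanges::strand(gr) <- df[[6]]
    gr
}

#' Write GRanges as BED (0-based half-open)
#'
#' @param gr \code{GRanges}; a \code{name} column is written if present,
#'   \code{score} (or the column named by \code{scoreFrom}) as column 5.
#' @param path output path.
#' @param scoreFrom metadata column to write as the BED score.
#' @export
writeBedRanges <- function(gr, path, scoreFrom = NULL) {
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     name = if (!is.null(mc$name)) mc$name
                            else if (!is.null(mc$sampleId)) mc$sampleId
                            else ".",
                     score = if (!is.null(scoreFrom)) mc[[scoreFrom]]
                             else 0)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Genes of a region
#'
#' \code{"contained"} mode (default) returns genes completely located
#' within the region; \code{"overlap"} mode any gene overlapping it.
#'
#' @param region \code{GRanges} of length 1.
#' @param annotation \code{GRanges} gene annotation with a \code{name}
#'   column.
#' @param mode \code{"contained"} or \code{"overlap"}.
#' @return character vector of gene names.
#' @export
genesInRegion <- function(region, annotation,
                          mode = c("contained", "overlap")) {
    mode <- match.arg(mode)
    stopifnot(length(region) == 1L)
    GenomeInfoDb::seqlevels(region) <-
        unique(c(GenomeInfoDb::seqlevels(region),
                 GenomeInfoDb::seqlevels(annotation)))
    hit <- suppressWarnings(GenomicRanges::findOverlaps(
        annotation, region,
        type = if (mode == "contained") "within" else "any"))
    S4Vectors::mcols(annotation)$name[S4Vectors::queryHits(hit)]
}

#' Write a TSS coverage matrix as TSV
#'
#' Header row holds the relative positions; first column the gene names.
#'
#' @param m a [TSSCoverageMatrix-class].
#' @param path output path.
#' @export
writeTSSMatrix <- function(m, path) {
    df <- data.frame(gene = m@genes$gene, m@coverage,
                     check.names = FALSE)
    colnames(df) <- c("gene", m@positions)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read a TSS coverage matrix written by [writeTSSMatrix()]
#'
#' @param path input path.
#' @return a raw [TSSCoverageMatrix-class].
#' @export
readTSSMatrix <- function(path) {
    df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
    methods::new("TSSCoverageMatrix", coverage = m,
                 positions = as.integer(colnames(df)[-1]),
                 genes = S4Vectors::DataFrame(gene = df$gene),
                 flankNormalized = FALSE)
}
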