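# Bundled genome tables (hg19) and the synthetic mini-genome used in
# examples and tests. All bundled annotations are hg19.

#' Chromosome lengths of the hg19 assembly
#'
#' @return named integer-like numeric vector of chromosome lengths (bp) for
#'   chr1..chr22, chrX, chrY.
#' @export
#' @examples
#' hg19ChromLengths()["chr13"]  # 115169878
hg19ChromLengths <- function() {
    c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
      chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
      chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
      chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
      chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
      chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
      chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
      chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Approximate hg19 chromosome-arm table
#'
#' Arms delimited at the (approximate, UCSC cytoband-derived) centromere
#' midpoint of each chromosome; adequate for assigning segments to arms and
#' computing arm fractions.
#'
#' @return \code{GRanges} with an \code{arm} metadata column (e.g.
#'   \code{"13q"}).
#' @export
hg19ArmTable <- function() {
    cen <- c(chr1 = 125e6, chr2 = 93.3e6, chr3 = 91e6, chr4 = 50.4e6,
             chr5 = 48.4e6, chr6 = 61e6, chr7 = 59.9e6, chr8 = 45.6e6,
             chr9 = 49e6, chr10 = 40.2e6, chr11 = 53.7e6, chr12 = 35.8e6,
             chr13 = 17.9e6, chr14 = 17.6e6, chr15 = 19e6, chr16 = 36.6e6,
             chr17 = 24e6, chr18 = 17.2e6, chr19 = 26.5e6, chr20 = 27.5e6,
             chr21 = 13.2e6, chr22 = 14.7e6, chrX = 60.6e6, chrY = 12.5e6)
    len <- hg19ChromLengths()
    armsFromCentromeres(len, cen[names(len)])
}

#' Build an arm table from chromosome lengths and centromere positions
#'
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param centromeres named vector of centromere positions (bp); defaults to
#'   the chromosome midpoints (the convention of the synthetic mini-genome).
#' @return \code{GRanges} with an \code{arm} metadata column.
#' @export
armsFromCentromeres <- function(chromLengths,
                                centromeres = chromLengths / 2) {
    stopifnot(length(chromLengths) == length(centromeres),
              all(centromeres > 0), all(centromeres < chromLengths))
    chrom <- names(chromLengths)
    gr <- GenomicRanges::GRanges(
        rep(chrom, each = 2L),
        IRanges::IRanges(
            start = as.vector(rbind(1, floor(centromeres) + 1)),
            end = as.vector(rbind(floor(centromeres), chromLengths))))
    S4Vectors::mcols(gr)$arm <- paste0(rep(sub("^chr", "", chrom), each = 2L),
                                       c("p", "q"))
    GenomeInfoDb::seqlengths(gr) <- chromLengths
    gr
}

#' Synthetic mini-genome for simulations and tests
#'
#' Three chromosomes (60, 40 and 30 Mb) — large enough that 50-kb binning,
#' segmentation and focal calling behave as on a real genome, small enough
#' for fast simulation.
#'
#' @return named numeric vector of chromosome lengths.
#' @export
miniGenome <- function() {
    c(cfs1 = 60e6, cfs2 = 40e6, cfs3 = 30e6)
}
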