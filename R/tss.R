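# Gene-expression inference from nucleosome footprints at transcription
# start sites: coverage extraction, flank normalization, the 2K-TSS and
# NDR features, and a cross-validated maximum-margin classifier.

#' Extract strand-oriented TSS coverage windows
#'
#' Pulls per-base coverage at positions -3000..+3000 around each TSS and
#' orients minus-strand genes so the position axis is transcriptional
#' (position +1 downstream of the TSS on the coding strand). Bases outside
#' the contig are filled with 0 (a warning reports how many); genes whose
#' TSS lies outside its contig are dropped with a message.
#'
#' @param coverage named list of per-base numeric coverage vectors, one per
#'   chromosome (1-based positions).
#' @param tss \code{data.frame} with columns \code{gene}, \code{chrom},
#'   \code{pos} (1-based TSS position) and \code{strand} (\code{"+"} or
#'   \code{"-"}).
#' @param flank half-window size in bp (default 3000).
#' @return a [TSSCoverageMatrix-class].
#' @export
extractTSSMatrix <- function(coverage, tss, flank = 3000) {
    stopifnot(all(c("gene", "chrom", "pos", "strand") %in% colnames(tss)))
    if (!all(tss$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    pos <- -flank:flank
    keep <- rep(TRUE, nrow(tss))
    rows <- vector("list", nrow(tss))
    nMissing <- 0L
    for (i in seq_len(nrow(tss))) {
        chrom <- tss$chrom[i]
        cov <- coverage[[chrom]]
        if (is.null(cov) || tss$pos[i] < 1 || tss$pos[i] > length(cov)) {
            keep[i] <- FALSE
            message("TSS of gene ", tss$gene[i],
                    " outside contig; gene dropped")
            next
        }
        at <- tss$pos[i] + pos
        inside <- at >= 1 & at <= length(cov)
        v <- numeric(length(at))
        v[inside] <- cov[at[inside]]
        nMissing <- nMissing + sum(!inside)
        if (tss$strand[i] == "-") v <- rev(v)
        rows[[i]] <- v
    }
    if (nMissing > 0)
        warning(nMissing, " bases outside contigs filled with 0")
    m <- do.call(rbind, rows[keep])
    genes <- S4Vectors::DataFrame(gene = tss$gene[keep],
                                  strand = tss$strand[keep])
    rownames(m) <- genes$gene
    methods::new("TSSCoverageMatrix", coverage = m,
                 positions = as.integer(pos), genes = genes,
                 flankNormalized = FALSE)
}

flankIndex <- function(positions) {
    (positions >= -3000 & positions <= -1000) |
        (positions >= 1000 & positions <= 3000)
}

#' Flank-normalize a TSS coverage matrix
#'
#' Divides each gene's coverage by its flank mean (mean over
#' [-3000, -1000] and [+1000, +3000]). Genes with a zero flank mean are
#' excluded; their names are recorded in the \code{"excluded"} attribute
#' with the reason \code{"zero flank"}.
#'
#' @param m a raw [TSSCoverageMatrix-class].
#' @return a flank-normalized [TSSCoverageMatrix-class] whose gene table
#'   gains a \code{flankMean} column; excluded genes in
#'   \code{attr(, "excluded")}.
#' @export
tssNormalize <- function(m) {
    stopifnot(methods::is(m, "TSSCoverageMatrix"))
    if (m@flankNormalized) stop("matrix is already flank-normalized")
    fi <- flankIndex(m@positions)
    fm <- rowMeans(m@coverage[, fi, drop = FALSE])
    keep <- fm > 0
    excluded <- m@genes$gene[!keep]
    norm <- m@coverage[keep, , drop = FALSE] / fm[keep]
    genes <- m@genes[keep, , drop = FALSE]
    genes$flankMean <- fm[keep]
    out <- methods::new("TSSCoverageMatrix", coverage = norm,
                        positions = m@positions, genes = genes,
                        flankNormalized = TRUE)
    attr(out, "excluded") <- excluded
    out
}

#' Footprint features: 2K-TSS and NDR coverage
#'
#' On the flank-normalized matrix, \code{tss2k} is the mean over
#' [-1000, +1000] and \code{ndr} the mean over [-150, +50] — the
#' nucleosome-depleted region of active promoters, where expressed genes
#' show a coverage dip.
#'
#' @param m a flank-normalized [TSSCoverageMatrix-class] (see
#'   [tssNormalize()]).
#' @param warnDepth warn when the mean raw flank coverage falls below this
#'   depth (shallow data make the footprint unreliable).
#' @return \code{DataFrame} with \code{gene}, \code{flankMean},
#'   \code{tss2k}, \code{ndr}.
#' @export
tssFeatures <- function(m, warnDepth = 3) {
    stopifnot(methods::is(m, "TSSCoverageMatrix"))
    if (!m@flankNormalized)
        stop("features are defined on the flank-normalized matrix")
    p <- m@positions
    i2k <- p >= -1000 & p <= 1000
    indr <- p >= -150 & p <= 50
    fm <- m@genes$flankMean
    if (mean(fm) < warnDepth)
        warning("mean flank coverage ", signif(mean(fm), 3),
                " is below ", warnDepth,
                "x; footprint calls may be unreliable")
    S4Vectors::DataFrame(
        gene = m@genes$gene,
        flankMean = unname(fm),
        tss2k = unname(rowMeans(m@coverage[, i2k, drop = FALSE])),
        ndr = unname(rowMeans(m@coverage[, indr, drop = FALSE])))
}

#' Classify genes as expressed or unexpressed from footprint features
#'
#' Within-sample cross-validated classification: the training genes
#' (constitutively expressed / unexpressed in the same sample) are split
#' into \code{k} seeded, class-stratified folds; in each fold a linear
#' maximum-margin classifier (support vector machine) on
#' \code{(tss2k, ndr)} is fit on the other folds' training genes — feature
#' scaling is learned on those genes only — and applied to every
#' non-training gene. A gene is called only when more than
#' \code{consistency} of folds agree; otherwise it is inconclusive. No
#' external training data are used.
#'
#' @param features \code{DataFrame}/\code{data.frame} from [tssFeatures()].
#' @param training named character vector: \code{gene -> "expressed"} or
#'   \code{"unexpressed"}; at least 20 genes per class.
#' @param k number of folds.
#' @param consistency fraction of folds that must agree for a call.
#' @param seed integer seed fixing the fold assignment.
#' @param kernel \code{"linear"} (default) or \code{"radial"}.
#' @return \code{DataFrame}: \code{gene}, \code{call} (\code{"expressed"},
#'   \code{"unexpressed"} or \code{"inconclusive"}), \code{consistency}
#'   (fraction of folds agreeing with the majority).
#' @export
classifyExpression <- function(features, training, k = 10,
                               consistency = 0.95, seed = NULL,
                               kernel = c("linear", "radial")) {
    kernel <- match.arg(kernel)
    features <- as.data.frame(features)
    if (!all(c("gene", "tss2k", "ndr") %in% colnames(features)))
        stop("features must carry gene, tss2k and ndr")
    if (!all(is.finite(features$tss2k)) || !all(is.finite(features$ndr)))
        stop("features must be finite")
    if (!all(training %in% c("expressed", "unexpressed")))
        stop("training labels must be 'expressed' or 'unexpressed'")
    trainIdx <- match(names(training), features$gene)
    if (any(is.na(trainIdx)))
        stop("training genes absent from features: ",
             paste(names(training)[is.na(trainIdx)][1:3], collapse = ", "))
    lab <- factor(training, levels = c("expressed", "unexpressed"))
    if (any(table(lab) < 20))
        stop("training set incomplete: need at least 20 genes per class")
    testIdx <- setdiff(seq_len(nrow(features)), trainIdx)
    x <- as.matrix(features[, c("tss2k", "ndr")])
    votes <- matrix(NA_character_, nrow = length(testIdx), ncol = k)
    withLocalSeed(seed, {
        fold <- integer(length(trainIdx))
        for (cl in levels(lab)) {    # stratified fold assignment
            i <- which(lab == cl)
            fold[i] <- sample(rep_len(seq_len(k), length(i)))
        }
        for (f in seq_len(k)) {
            inTrain <- fold != f
            fit <- e1071::svm(x = x[trainIdx[inTrain], , drop = FALSE],
                              y = lab[inTrain], kernel = kernel,
                              scale = TRUE)
            votes[, f] <- as.character(
                stats::predict(fit, x[testIdx, , drop = FALSE]))
        }
    })
    maj <- apply(votes, 1, function(v) {
        tb <- sort(table(v), decreasing = TRUE)
        c(names(tb)[1], as.numeric(tb[1]) / length(v))
    })
    agree <- as.numeric(maj[2, ])
    call <- ifelse(agree > consistency, maj[1, ], "inconclusive")
    S4Vectors::DataFrame(gene = features$gene[testIdx],
                         call = call, consistency = agree)
}

#' Tabulate expression calls for the genes of a region
#'
#' @param calls result of [classifyExpression()].
#' @param regionGenes character vector of gene names (e.g. the genes
#'   contained in a called amplicon, see [genesInRegion()]).
#' @param excluded genes excluded during normalization (zero flank
#'   coverage), as recorded by [tssNormalize()].
#' @return \code{DataFrame}: \code{gene}, \code{call}, \code{consistency};
#'   genes never featurized are \code{"not evaluated"} (with reason for
#'   zero-flank exclusions), with \code{NA} consistency.
#' @export
reportAmpliconExpression <- function(calls, regionGenes,
                                     excluded = character()) {
    if (length(regionGenes) == 0L)
        return(S4Vectors::DataFrame(gene = character(), call = character(),
                                    consistency = numeric()))
    i <- match(regionGenes, calls$gene)
    call <- ifelse(is.na(i),
                   ifelse(regionGenes %in% excluded,
                          "not evaluated (zero flank)", "not evaluated"),
                   calls$call[ifelse(is.na(i), 1L, i)])
    cons <- ifelse(is.na(i), NA_real_, calls$consistency[ifelse(is.na(i), 1L, i)])
    S4Vectors::DataFrame(gene = regionGenes, call = call,
                         consistency = cons)
}
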