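# PWM scanning of upstream regions on both strands.
#
# All scanning happens in transcription orientation: a hit on the + strand
# matches the region as written, a hit on the - strand matches its reverse
# complement. Either way the reported offset is that of the 5'-most base of
# the matched window in transcription orientation, following the reporting
# convention for single upstream positions.

emptyHits <- function() {
    data.frame(gene_id = character(), offset = integer(),
               strand = character(), score = numeric(),
               latticeScore = numeric(), word = character(),
               stringsAsFactors = FALSE)
}

# lattice scores of all windows of one sequence (character); NA where the
# window contains an unknown base
windowLatticeScores <- function(s, scheme) {
    .cpp_window_lattice(seqCodes(s), scheme@lattice)
}

#' Scan regions with a PWM
#'
#' Every window of width W with lattice score at or above `cutoff` yields
#' one hit, on the + strand (same orientation as transcription) and, with
#' `strands = "both"`, on the reverse complement (- strand). Windows
#' containing N are skipped. Overlapping hits are all reported; pairing
#' logic downstream decides what to keep. Hits are sorted by offset, `+`
#' before `-` at equal offsets.
#'
#' @param regions an [UpstreamRegionSet-class] (or a single one)
#' @param pwm a [PWM-class]
#' @param cutoff lattice score threshold; defaults to the exact-p-value
#'   cutoff at `alpha`
#' @param strands `"both"` or `"forward"`
#' @param alpha per-window p-value used when `cutoff` is missing
#' @param granularity lattice granularity used when `cutoff` is missing
#' @param scheme optionally a precomputed [ScoreScheme-class]
#' @return a data.frame of hits: `gene_id`, `offset` (ATG-relative, of the
#'   5'-most window base in transcription orientation), `strand`, `score`
#'   (natural log-odds, lattice score / granularity), `latticeScore`,
#'   `word` (as read on the hit strand)
#' @seealso [cutoffForPvalue()], [pairElements()]
#' @export
scanRegions <- function(regions, pwm, cutoff = NULL,
                        strands = c("both", "forward"), alpha = 1e-4,
                        granularity = 1000, scheme = NULL) {
    stopifnot(is(regions, "UpstreamRegionSet"), is(pwm, "PWM"))
    strands <- match.arg(strands)
    if (is.null(scheme)) scheme <- scoreScheme(pwm, granularity)
    if (is.null(cutoff))
        cutoff <- cutoffForPvalue(nullDistribution(scheme), alpha)
    info <- regionInfo(regions)
    seqs <- as.character(regionSeqs(regions))
    out <- vector("list", length(seqs))
    W <- ncol(scheme@lattice)
    for (k in seq_along(seqs)) {
        out[[k]] <- scanOneSequence(seqs[k], info$gene_id[k], scheme, W,
                                    cutoff, strands)
    }
    res <- do.call(rbind, c(list(emptyHits()), out))
    rownames(res) <- NULL
    res
}

# worker shared with elementConservation(); offsets are ATG-relative when
# the sequence is an upstream region (offset = index - L - 1)
scanOneSequence <- function(s, geneId, scheme, W, cutoff, strands) {
    L <- nchar(s)
    if (L < W) return(emptyHits())
    g <- scheme@granularity
    sc <- windowLatticeScores(s, scheme)
    keepF <- which(!is.na(sc) & sc >= cutoff)
    hits <- list()
    if (length(keepF)) {
        hits[[1]] <- data.frame(
            gene_id = geneId, offset = keepF - L - 1L, strand = "+",
            score = sc[keepF] / g, latticeScore = sc[keepF],
            word = substring(s, keepF, keepF + W - 1L),
            stringsAsFactors = FALSE)
    }
    if (strands == "both") {
        rc <- revCompChar(s)
        scR <- windowLatticeScores(rc, scheme)
        keepR <- which(!is.na(scR) & scR >= cutoff)
        if (length(keepR)) {
            # rc window i covers region positions (L-i-W+2)..(L-i+1)
            pos <- L - keepR - W + 2L
            hits[[length(hits) + 1L]] <- data.frame(
                gene_id = geneId, offset = pos - L - 1L, strand = "-",
                score = scR[keepR] / g, latticeScore = scR[keepR],
                word = substring(rc, keepR, keepR + W - 1L),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, c(list(emptyHits()), hits))
    res[order(res$offset, res$strand), , drop = FALSE]
}

#' Genomic coordinates of motif hits
#'
#' Maps ATG-relative hits back to forward-strand genomic windows using the
#' region anchoring, for BED export and for filtering against genomic
#' cis-regulatory-module intervals. The returned strand is the genomic
#' strand of the match (`+` hits lie on the gene's strand, `-` hits on the
#' opposite one).
#'
#' @param hits a hit data.frame from [scanRegions()]
#' @param regions the [UpstreamRegionSet-class] the hits came from
#' @return a [GenomicRanges::GRanges] with metadata `gene_id`, `offset`,
#'   `hit_strand`, `score`, `word`
#' @export
hitGRanges <- function(hits, regions) {
    stopifnot(is(regions, "UpstreamRegionSet"))
    info <- as.data.frame(regionInfo(regions))
    k <- match(hits$gene_id, info$gene_id)
    if (anyNA(k)) stop("hits refer to genes absent from the region set")
    W <- nchar(hits$word)
    L <- info$L[k]
    i <- hits$offset + L + 1L          # 1-based region index of window start
    plus <- info$strand[k] == "+"
    gs <- ifelse(plus, info$gstart[k] + i - 1L, info$gend[k] - (i + W - 1L) + 1L)
    ge <- gs + W - 1L
    gstrand <- ifelse((info$strand[k] == "+") == (hits$strand == "+"), "+", "-")
    gr <- GRanges(info$chrom[k], IRanges(gs, ge), strand = gstrand)
    mcols(gr) <- DataFrame(gene_id = hits$gene_id, offset = hits$offset,
                           hit_strand = hits$strand, score = hits$score,
                           word = hits$word)
    gr
}

#' Export hits as BED6
#'
#' Either genome-relative (`frame = "genomic"`, requires `regions`) or
#' region-relative (`frame = "region"`, 0-based positions within each
#' region). Scores are the natural log-odds scores.
#'
#' @param hits a hit data.frame from [scanRegions()]
#' @param path output path
#' @param regions the [UpstreamRegionSet-class] the hits came from
#' @param frame coordinate frame of the output
#' @return the path, invisibly
#' @export
writeHitsBED <- function(hits, path, regions = NULL,
                         frame = c("genomic", "region")) {
    frame <- match.arg(frame)
    if (frame == "genomic") {
        if (is.null(regions)) stop("genomic frame needs the region set")
        gr <- hitGRanges(hits, regions)
        bed <- data.frame(chrom = as.character(seqnames(gr)),
                          start = start(gr) - 1L, end = end(gr),
                          name = paste0(gr$gene_id, ":", gr$offset),
                          score = gr$score,
                          strand = as.character(strand(gr)))
    } else {
        if (is.null(regions)) stop("region frame needs the region set")
        info <- as.data.frame(regionInfo(regions))
        L <- info$L[match(hits$gene_id, info$gene_id)]
        i <- hits$offset + L + 1L
        bed <- data.frame(chrom = hits$gene_id, start = i - 1L,
                          end = i - 1L + nchar(hits$word),
                          name = paste0(hits$gene_id, ":", hits$offset),
                          score = hits$score, strand = hits$strand)
    }
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
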