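# Detection of HZA+GATA element pairs and the genome-wide screen.
#
# "Distance between elements" is the nearest-edge gap: the number of bases
# strictly between the two windows, negative when they overlap. The founder
# promoters' 0-12 bp separations and the overlapping candidates force this
# edge convention.

#' Pair HZA and GATA hits on the same gene
#'
#' All (HZA, GATA) hit combinations on the same gene whose nearest-edge gap
#' is at most `maxGap`. Overlapping pairs (gap <= 0) are included; a gene
#' may contribute several pairs.
#'
#' @param hzaHits,gataHits hit data.frames from [scanRegions()]
#' @param maxGap maximum edge gap in bp (default 20)
#' @return a data.frame with one row per qualifying pair: gene, both
#'   elements' offsets/strands/words/scores, `gap`, `orientation`
#'   (gata_strand/hza_strand), `module_start`, `module_end` (ATG-relative
#'   closed span covering both windows) and `atg_distance` (distance of the
#'   module's most ATG-distal base from the translation start)
#' @examples
#' h <- data.frame(gene_id = "g", offset = -40L, strand = "+", score = 1,
#'                 latticeScore = 1000, word = strrep("A", 15))
#' g <- data.frame(gene_id = "g", offset = -24L, strand = "-", score = 1,
#'                 latticeScore = 1000, word = strrep("T", 6))
#' pairElements(h, g)$gap  # 1
#' @export
pairElements <- function(hzaHits, gataHits, maxGap = 20) {
    if (maxGap < 0) stop("maxGap must be >= 0")
    if (nrow(hzaHits) == 0L || nrow(gataHits) == 0L) return(emptyPairs())
    h <- hzaHits; colnames(h) <- paste0("hza_", colnames(h))
    g <- gataHits; colnames(g) <- paste0("gata_", colnames(g))
    m <- merge(h, g, by.x = "hza_gene_id", by.y = "gata_gene_id")
    if (nrow(m) == 0L) return(emptyPairs())
    hs <- m$hza_offset; he <- hs + nchar(m$hza_word) - 1L
    gs <- m$gata_offset; ge <- gs + nchar(m$gata_word) - 1L
    gap <- ifelse(gs >= hs, gs - he - 1L, hs - ge - 1L)
    keep <- gap <= maxGap
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) return(emptyPairs())
    hs <- hs[keep]; he <- he[keep]; gs <- gs[keep]; ge <- ge[keep]
    out <- data.frame(
        gene_id = m$hza_gene_id,
        hza_offset = hs, hza_strand = m$hza_strand,
        hza_word = m$hza_word, hza_score = m$hza_score,
        gata_offset = gs, gata_strand = m$gata_strand,
        gata_word = m$gata_word, gata_score = m$gata_score,
        gap = gap[keep],
        orientation = paste(m$gata_strand, m$hza_strand, sep = "/"),
        module_start = pmin(hs, gs), module_end = pmax(he, ge),
        stringsAsFactors = FALSE)
    out$atg_distance <- -out$module_start
    out <- out[order(out$gene_id, out$module_start, out$hza_offset,
                     out$gata_offset), , drop = FALSE]
    rownames(out) <- NULL
    out
}

emptyPairs <- function() {
    data.frame(gene_id = character(), hza_offset = integer(),
               hza_strand = character(), hza_word = character(),
               hza_score = numeric(), gata_offset = integer(),
               gata_strand = character(), gata_word = character(),
               gata_score = numeric(), gap = integer(),
               orientation = character(), module_start = integer(),
               module_end = integer(), atg_distance = integer(),
               stringsAsFactors = FALSE)
}

#' Keep pairs inside cis-regulatory modules
#'
#' Keeps pairs where both element windows are fully contained in a single
#' interval. Intervals can be ATG-relative per gene (`frame = "atg"`: a
#' data.frame with columns `gene_id`, `start`, `end`, closed offsets such as
#' -500..-1) or genomic (`frame = "genomic"`: a [GenomicRanges::GRanges],
#' e.g. imported from BED; requires the region set to map hits back to the
#' genome).
#'
#' @param pairs a pair data.frame from [pairElements()]
#' @param crm the interval set (see Details)
#' @param frame coordinate frame of `crm`
#' @param regions the [UpstreamRegionSet-class] (genomic frame only)
#' @return the filtered pair data.frame
#' @export
filterByCRM <- function(pairs, crm, frame = c("atg", "genomic"),
                        regions = NULL) {
    frame <- match.arg(frame)
    if (nrow(pairs) == 0L) return(pairs)
    if (frame == "atg") {
        if (!is.data.frame(crm) ||
            !all(c("gene_id", "start", "end") %in% colnames(crm)))
            stop("ATG-frame CRM intervals need columns gene_id, start, end")
        keep <- vapply(seq_len(nrow(pairs)), function(r) {
            iv <- crm[crm$gene_id == pairs$gene_id[r], , drop = FALSE]
            if (nrow(iv) == 0L) return(FALSE)
            hs <- pairs$hza_offset[r]
            he <- hs + nchar(pairs$hza_word[r]) - 1L
            gs <- pairs$gata_offset[r]
            ge <- gs + nchar(pairs$gata_word[r]) - 1L
            any(iv$start <= pmin(hs, gs) & iv$end >= pmax(he, ge) &
                iv$start <= hs & iv$end >= he & iv$start <= gs & iv$end >= ge)
        }, logical(1))
    } else {
        if (!is(crm, "GRanges")) stop("genomic-frame CRM must be a GRanges")
        if (is.null(regions)) stop("genomic frame needs the region set")
        hzaGR <- hitGRanges(pairHitFrame(pairs, "hza"), regions)
        gataGR <- hitGRanges(pairHitFrame(pairs, "gata"), regions)
        crmNS <- crm
        strand(crmNS) <- "*"
        ovH <- findOverlaps(hzaGR, crmNS, type = "within", ignore.strand = TRUE)
        ovG <- findOverlaps(gataGR, crmNS, type = "within", ignore.strand = TRUE)
        keep <- vapply(seq_len(nrow(pairs)), function(r) {
            ih <- S4Vectors::subjectHits(ovH)[S4Vectors::queryHits(ovH) == r]
            ig <- S4Vectors::subjectHits(ovG)[S4Vectors::queryHits(ovG) == r]
            length(intersect(ih, ig)) > 0L
        }, logical(1))
    }
    out <- pairs[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

pairHitFrame <- function(pairs, which) {
    data.frame(gene_id = pairs$gene_id,
               offset = pairs[[paste0(which, "_offset")]],
               strand = pairs[[paste0(which, "_strand")]],
               score = pairs[[paste0(which, "_score")]],
               word = pairs[[paste0(which, "_word")]],
               stringsAsFactors = FALSE)
}

#' Keep pairs close to the translation start
#'
#' Keeps pairs whose module lies within `atgMax` bp of the ATG, measured at
#' the module's most ATG-distal base (`atg_distance`).
#'
#' @param pairs a pair data.frame from [pairElements()]
#' @param atgMax maximum distance in bp (default 1500)
#' @return the filtered pair data.frame
#' @export
filterByAtgDistance <- function(pairs, atgMax = 1500) {
    if (atgMax <= 0) stop("atgMax must be > 0")
    out <- pairs[pairs$atg_distance <= atgMax, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genome-wide screen for paired HZA and GATA elements
#'
#' Composes the full screen: extract upstream intergenic regions (up to
#' `maxLen`), scan both strands with each weight matrix at its exact-p-value
#' cutoff, pair hits with edge gap at most `maxGap`, and — in strict mode —
#' keep only pairs inside supplied cis-regulatory-module intervals and
#' within `atgMax` of the start codon. Relaxed mode applies only the
#' co-occurrence and spacing criteria.
#'
#' @param genome [Biostrings::DNAStringSet] chromosomes
#' @param genes gene annotation [GenomicRanges::GRanges] (see
#'   [readGeneAnnotation()])
#' @param hzaPwm,gataPwm [PWM-class] objects (classically 15 bp and 12 bp)
#' @param maxLen upstream extraction limit in bp (default 20000)
#' @param alphaHza per-window p-value cutoff for the HZA scan (default 1e-4)
#' @param alphaGata per-window p-value cutoff for the GATA scan (default
#'   1e-3; a 6-informative-position GATA matrix cannot attain 1e-4 — see the
#'   vignette)
#' @param maxGap maximum edge gap between the elements (default 20 bp)
#' @param atgMax strict-mode distance limit (default 1500 bp)
#' @param crm optional cis-regulatory-module intervals (strict mode), as in
#'   [filterByCRM()]
#' @param crmFrame coordinate frame of `crm`
#' @param strict apply criteria beyond co-occurrence and spacing
#' @param backgroundModel `"uniform"` or `"regions"` (0-order background
#'   estimated from the extracted regions)
#' @param granularity score lattice granularity
#' @return a [ScreenResult-class]
#' @export
screenGenome <- function(genome, genes, hzaPwm, gataPwm, maxLen = 20000,
                         alphaHza = 1e-4, alphaGata = 1e-3, maxGap = 20,
                         atgMax = 1500, crm = NULL,
                         crmFrame = c("atg", "genomic"), strict = FALSE,
                         backgroundModel = c("uniform", "regions"),
                         granularity = 1000) {
    crmFrame <- match.arg(crmFrame)
    backgroundModel <- match.arg(backgroundModel)
    regions <- extractUpstreamRegions(genes, genome, maxLen = maxLen)
    if (backgroundModel == "regions") {
        cm <- consensusMatrix(regionSeqs(regions))
        cnt <- rowSums(cm[intersect(DNA_BASES, rownames(cm)), , drop = FALSE])
        bg <- setNames(numeric(4), DNA_BASES)
        bg[names(cnt)] <- cnt
        bg <- (bg + 1) / sum(bg + 1)
        hzaPwm <- newPWM(probs(hzaPwm), bg, pseudocount(hzaPwm),
                         motifName(hzaPwm))
        gataPwm <- newPWM(probs(gataPwm), bg, pseudocount(gataPwm),
                          motifName(gataPwm))
    }
    hzaHits <- scanRegions(regions, hzaPwm, alpha = alphaHza,
                           granularity = granularity)
    gataHits <- scanRegions(regions, gataPwm, alpha = alphaGata,
                            granularity = granularity)
    pairs <- pairElements(hzaHits, gataHits, maxGap = maxGap)
    if (strict) {
        if (!is.null(crm))
            pairs <- filterByCRM(pairs, crm, frame = crmFrame,
                                 regions = regions)
        else warning("strict mode without CRM intervals: ",
                     "module-containment criterion not applied")
        pairs <- filterByAtgDistance(pairs, atgMax = atgMax)
    }
    new("ScreenResult", table = pairs,
        genes = sort(unique(pairs$gene_id)),
        params = list(maxLen = maxLen, alphaHza = alphaHza,
                      alphaGata = alphaGata, maxGap = maxGap,
                      atgMax = atgMax, strict = strict,
                      backgroundModel = backgroundModel,
                      granularity = granularity))
}
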