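#' Read a genome FASTA
#'
#' Reads a multi-record FASTA into a [Biostrings::DNAStringSet]. Residues are
#' uppercased, `U` is mapped to `T`, and any other letter is mapped to `N`
#' with a warning, so the result contains only A,C,G,T,N. Record names are
#' the first whitespace-delimited word of each header.
#'
#' @param path path to a FASTA file (any line wrap; may be empty)
#' @return a [Biostrings::DNAStringSet]
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chrI", "acgt"), tf)
#' readGenome(tf)
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    if (file.size(path) == 0L) return(DNAStringSet())
    raw <- readBStringSet(path)
    if (length(raw) == 0L) return(DNAStringSet())
    nm <- sub("\\s.*$", "", names(raw))
    if (any(!nzchar(nm)))
        stop("malformed FASTA header (empty name) at record ",
             which(!nzchar(nm))[1])
    if (any(width(raw) == 0L))
        stop("empty record body for: ",
             paste(nm[width(raw) == 0L], collapse = ", "))
    s <- toupper(as.character(raw))
    s <- chartr("U", "T", s)
    bad <- grepl("[^ACGTN]", s)
    if (any(bad)) {
        warning("non-ACGTN letters mapped to N in record(s): ",
                paste(nm[bad], collapse = ", "))
        s <- gsub("[^ACGTN]", "N", s)
    }
    out <- DNAStringSet(s)
    names(out) <- nm
    out
}

#' Read gene annotation from GFF3
#'
#' Extracts one record per gene from a GFF3 file: the gene span, strand and
#' the genomic position of the first base of the start codon read in
#' transcription orientation (`atg_pos`), taken from the 5'-most end of the
#' gene's CDS features. CDS features may name the gene directly in `Parent`
#' or go through an mRNA/transcript level. Genes without CDS are skipped
#' with a warning; a gene without strand or ID is an error.
#'
#' @param path path to a GFF3 file
#' @return a [GenomicRanges::GRanges] of gene spans, sorted per chromosome by
#'   start, with metadata columns `gene_id` and `atg_pos`
#' @seealso [extractUpstreamRegions()]
#' @export
readGeneAnnotation <- function(path) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[tolower(as.character(gr$type)) == "gene"]
    if (length(genes) == 0L)
        stop("no gene features in ", path)
    ids <- if (is.null(genes$ID)) rep(NA_character_, length(genes))
           else as.character(genes$ID)
    if (anyNA(ids) || any(!nzchar(ids)))
        stop("gene feature missing ID (gene feature #",
             which(is.na(ids) | !nzchar(ids))[1], ")")
    str <- as.character(strand(genes))
    if (any(str == "*"))
        stop("gene feature missing strand: ", ids[str == "*"][1])
    cds <- gr[tolower(as.character(gr$type)) == "cds"]
    # map CDS Parent -> gene id, optionally through one transcript level
    tx <- gr[!is.na(gr$ID) & !tolower(as.character(gr$type)) %in%
             c("gene", "cds")]
    txParent <- setNames(
        vapply(tx$Parent, function(p) if (length(p)) p[1] else NA_character_,
               character(1)),
        as.character(tx$ID))
    cdsGene <- vapply(cds$Parent, function(p) {
        if (length(p) == 0L) return(NA_character_)
        p <- p[1]
        if (p %in% ids) p
        else if (!is.na(txParent[p]) && txParent[p] %in% ids) txParent[[p]]
        else NA_character_
    }, character(1))
    atg <- vapply(seq_along(genes), function(i) {
        k <- which(cdsGene == ids[i])
        if (length(k) == 0L) return(NA_integer_)
        if (str[i] == "+") min(start(cds)[k]) else max(end(cds)[k])
    }, integer(1))
    drop <- is.na(atg)
    if (any(drop))
        warning("skipping gene(s) without CDS: ",
                paste(ids[drop], collapse = ", "))
    genes <- genes[!drop]
    out <- GRanges(seqnames(genes),
                   IRanges(start(genes), end(genes)),
                   strand = strand(genes))
    mcols(out) <- DataFrame(gene_id = ids[!drop], atg_pos = atg[!drop])
    out[order(as.character(seqnames(out)), start(out))]
}

#' Extract upstream intergenic regions
#'
#' For each gene, the sequence 5' of its start codon in transcription
#' orientation, ending at the base immediately preceding the ATG (offset -1)
#' and truncated at the nearest of: `maxLen` bases, the closest base of any
#' other gene's span on the 5' side (either strand), or the chromosome end.
#' Minus-strand regions are reverse-complemented so scanning always operates
#' in transcription orientation. A zero-length region is valid.
#'
#' @param genes [GenomicRanges::GRanges] from [readGeneAnnotation()] (or
#'   equivalent) with `gene_id` and `atg_pos` metadata columns
#' @param genome [Biostrings::DNAStringSet] of chromosomes
#' @param maxLen maximum region length in bp (default 20000, i.e. up to 20 kb
#'   of upstream sequence)
#' @param geneIds optional subset of gene ids to extract
#' @return an [UpstreamRegionSet-class]
#' @export
extractUpstreamRegions <- function(genes, genome, maxLen = 20000,
                                   geneIds = NULL) {
    stopifnot(is(genes, "GRanges"),
              all(c("gene_id", "atg_pos") %in% colnames(mcols(genes))))
    sel <- seq_along(genes)
    if (!is.null(geneIds)) {
        sel <- match(geneIds, genes$gene_id)
        if (anyNA(sel)) stop("unknown gene id(s): ",
                             paste(geneIds[is.na(sel)], collapse = ", "))
    }
    chrAll <- as.character(seqnames(genes))
    strAll <- as.character(strand(genes))
    n <- length(sel)
    seqs <- character(n)
    info <- data.frame(gene_id = genes$gene_id[sel], chrom = chrAll[sel],
                       strand = strAll[sel], atg_pos = genes$atg_pos[sel],
                       gstart = integer(n), gend = integer(n), L = integer(n),
                       truncation = character(n), stringsAsFactors = FALSE)
    for (k in seq_len(n)) {
        i <- sel[k]
        chrom <- chrAll[i]
        if (!chrom %in% names(genome))
            stop("chromosome not in genome: ", chrom)
        clen <- length(genome[[chrom]])
        atg <- genes$atg_pos[i]
        others <- which(chrAll == chrom)
        others <- others[others != i]
        if (strAll[i] == "+") {
            e <- atg - 1L
            lo <- max(1L, atg - as.integer(maxLen))
            blockEnd <- 0L
            for (o in others) {
                if (start(genes)[o] <= e && end(genes)[o] >= lo)
                    blockEnd <- max(blockEnd, min(end(genes)[o], e))
            }
            s <- max(lo, blockEnd + 1L)
            L <- max(0L, e - s + 1L)
            reason <- if (L == maxLen) "max_len"
                else if (blockEnd + 1L > lo) "neighbor_gene"
                else "chromosome_end"
            seqs[k] <- if (L > 0)
                as.character(subseq(genome[[chrom]], s, e)) else ""
            info$gstart[k] <- s; info$gend[k] <- e
        } else {
            s <- atg + 1L
            hi <- min(clen, atg + as.integer(maxLen))
            blockStart <- clen + 1L
            for (o in others) {
                if (end(genes)[o] >= s && start(genes)[o] <= hi)
                    blockStart <- min(blockStart, max(start(genes)[o], s))
            }
            e <- min(hi, blockStart - 1L)
            L <- max(0L, e - s + 1L)
            reason <- if (L == maxLen) "max_len"
                else if (blockStart <= hi) "neighbor_gene"
                else "chromosome_end"
            seqs[k] <- if (L > 0)
                revCompChar(as.character(subseq(genome[[chrom]], s, e))) else ""
            info$gstart[k] <- s; info$gend[k] <- e
        }
        info$L[k] <- L
        info$truncation[k] <- reason
    }
    ss <- DNAStringSet(seqs)
    names(ss) <- info$gene_id
    new("UpstreamRegionSet", seqs = ss, info = DataFrame(info))
}

#' Map a region index to an ATG-relative offset (and back)
#'
#' The coordinate convention of the screen: the A of the start codon is +1,
#' the base immediately 5' of it is -1, and there is no offset 0. The last
#' residue of a length-L region therefore has offset -1 and the first has
#' offset -L.
#'
#' @param L region length in bp (or an [UpstreamRegionSet-class] of length 1)
#' @param index 1-based index into the region residues
#' @param offset negative ATG-relative offset
#' @return `atgOffset`: the signed offset; `offsetToIndex`: the 1-based index
#' @examples
#' atgOffset(313, 1)    # -313
#' atgOffset(313, 313)  # -1
#' @export
atgOffset <- function(L, index) {
    L <- regionLength(L)
    if (any(index < 1 | index > L)) stop("region index out of range")
    as.integer(index - L - 1L)
}

#' @rdname atgOffset
#' @export
offsetToIndex <- function(L, offset) {
    L <- regionLength(L)
    if (any(offset > -1 | offset < -L)) stop("offset out of range")
    as.integer(offset + L + 1L)
}

regionLength <- function(L) {
    if (is(L, "UpstreamRegionSet")) {
        if (length(L) != 1L) stop("need a single region")
        L <- regionInfo(L)$L
    }
    if (!is.numeric(L) || length(L) != 1L || L < 0) stop("invalid length")
    as.integer(L)
}

#' Write upstream regions as FASTA
#'
#' Headers are `gene_id|-L..-1`, recording the offset range.
#'
#' @param regions an [UpstreamRegionSet-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeRegions <- function(regions, path) {
    stopifnot(is(regions, "UpstreamRegionSet"))
    ss <- regionSeqs(regions)
    info <- regionInfo(regions)
    names(ss) <- sprintf("%s|-%d..-1", info$gene_id, info$L)
    writeXStringSet(ss, path)
    invisible(path)
}
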