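# Ground-truthed synthetic genomes with planted HZA+GATA modules.
#
# The default study is one chromosome of 50 genes on the + strand, each with
# its own upstream intergenic region of 500-5000 bp, 20% of genes carrying a
# planted module. Gene bodies block region extraction exactly as real
# neighbours do; planting on mixed gene strands would create shared
# (divergent) promoters with an ambiguous truth table, so minus-strand
# handling is exercised by dedicated fixtures instead of the benchmark.

#' Built-in HZA-like weight matrix (synthetic stand-in)
#'
#' A 15-bp stand-in for the published HZA logo, whose numeric values are not
#' printed anywhere: 12 positions carry a high-frequency consensus base
#' (probability 0.95) — matching the description of the zinc-responsive
#' 15-bp matrix as having 12 such positions — the core is 5'-CANAAAC-3' with
#' its N position uniform, and the two outermost positions are moderately
#' informative (0.55), mirroring the loss of significance at the motif edge
#' in the cadmium-refined version. Clearly a synthetic stand-in, not the
#' published matrix.
#'
#' @return a [PWM-class] of width 15
#' @export
hzaMatrix <- function() {
    cons <- c("T", "C", "T", "G", "C", "A", "N", "A", "A", "A", "C",
              "T", "G", "T", "A")
    conf <- c(0.55, rep(0.95, 5), NA, rep(0.95, 7), 0.55)
    p <- matrix(NA_real_, 4, 15, dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(15)) {
        if (cons[j] == "N") {
            p[, j] <- 0.25
        } else {
            p[, j] <- (1 - conf[j]) / 3
            p[cons[j], j] <- conf[j]
        }
    }
    newPWM(p, name = "hza-synthetic-standin")
}

#' Built-in fallback GATA weight matrix (non-canonical)
#'
#' A 12-bp matrix with the TGATAA core (consensus probability 0.95 per core
#' position) and uniform 3-bp flanks on each side. The published
#' intestine-enriched 12-bp GATA matrix is not printed in the literature
#' this package draws on; this fallback is labelled non-canonical and should
#' be replaced by a real matrix (via [readPWM()]) when one is available.
#' With only 6 informative positions its minimum attainable per-window
#' p-value is 4^-6 (about 2.4e-4), hence the screen's separate
#' `alphaGata` default.
#'
#' @return a [PWM-class] of width 12
#' @export
gataMatrix <- function() {
    core <- c("T", "G", "A", "T", "A", "A")
    p <- matrix(0.25, 4, 12, dimnames = list(DNA_BASES, NULL))
    for (j in seq_along(core)) {
        p[, j + 3L] <- 0.05 / 3
        p[core[j], j + 3L] <- 0.95
    }
    newPWM(p, name = "gata-fallback-noncanonical")
}

#' Sample an i.i.d. background sequence
#'
#' @param length sequence length in bp (>= 0)
#' @param baseComposition length-4 probabilities for A,C,G,T
#' @param seed optional RNG seed (the caller's RNG state is restored)
#' @return a character string
#' @export
sampleBackground <- function(length, baseComposition = rep(0.25, 4),
                             seed = NULL) {
    if (length < 0) stop("length must be >= 0")
    if (length(baseComposition) != 4L || any(baseComposition < 0) ||
        abs(sum(baseComposition) - 1) > 1e-9)
        stop("baseComposition must be 4 nonnegative probabilities summing to 1")
    if (length == 0) return("")
    withSeed(seed,
        paste0(sample(DNA_BASES, length, replace = TRUE,
                      prob = baseComposition), collapse = ""))
}

sampleFromPWM <- function(pwm) {
    p <- probs(pwm)
    paste0(vapply(seq_len(ncol(p)), function(j)
        sample(DNA_BASES, 1L, prob = p[, j]), character(1)), collapse = "")
}

#' Generate a ground-truthed synthetic study
#'
#' Builds one chromosome of `nGenes` genes on the + strand, each preceded by
#' its own intergenic region of length drawn uniformly from
#' `intergenicRange`. A fraction `plantedFraction` of genes receives a
#' module: an HZA word (sampled from `hzaSource` if it is a PWM, or used
#' verbatim if a string) and the GATA word, each independently placed on
#' either strand (reverse-complemented when minus), separated by an edge gap
#' drawn from `gapRange`, with the module's most ATG-distal base at a
#' distance drawn from `atgDistanceRange`; element order (which of the two
#' sits closer to the ATG) is drawn uniformly. Everything is deterministic
#' given `seed`.
#'
#' @param nGenes number of genes (default 50)
#' @param intergenicRange intergenic length range in bp (default 500-5000)
#' @param geneLength gene body length in bp (default 1000)
#' @param baseComposition background base probabilities (default uniform)
#' @param plantedFraction fraction of genes with a planted module
#'   (default 0.2)
#' @param hzaSource [PWM-class] to sample HZA words from (default
#'   [hzaMatrix()]) or a fixed word
#' @param gataWord the GATA word (default `"TGATAA"`)
#' @param gapRange edge-gap range in bp (default 0-20, the screen's pairing
#'   window)
#' @param atgDistanceRange range for the module's ATG distance (default
#'   59-450 bp: 59 is the closest observed candidate module, 450 keeps any
#'   module inside the shortest default intergenic region)
#' @param orthologMutationRate per-base substitution rate for
#'   [makeOrthologPromoters()] when called by [writeStudy()]
#' @param seed RNG seed (full determinism)
#' @param chromName chromosome name
#' @return a [SyntheticStudy-class]
#' @examples
#' st <- syntheticStudy(nGenes = 10, seed = 1)
#' nrow(truthTable(st))
#' @export
syntheticStudy <- function(nGenes = 50, intergenicRange = c(500, 5000),
                           geneLength = 1000,
                           baseComposition = rep(0.25, 4),
                           plantedFraction = 0.2, hzaSource = hzaMatrix(),
                           gataWord = "TGATAA", gapRange = c(0, 20),
                           atgDistanceRange = c(59, 450),
                           orthologMutationRate = 0.1, seed = 1,
                           chromName = "chrS") {
    stopifnot(nGenes >= 1, diff(intergenicRange) >= 0, geneLength >= 3,
              plantedFraction >= 0, plantedFraction <= 1,
              diff(gapRange) >= 0, gapRange[1] >= 0,
              diff(atgDistanceRange) >= 0)
    withSeed(seed, {
        gapLens <- sample(intergenicRange[1]:intergenicRange[2], nGenes,
                          replace = TRUE)
        gaps <- vapply(gapLens, function(l)
            sampleBackground(l, baseComposition), character(1))
        bodies <- vapply(seq_len(nGenes), function(i)
            paste0("ATG", sampleBackground(geneLength - 3L, baseComposition)),
            character(1))
        nPlant <- round(plantedFraction * nGenes)
        planted <- sort(sample(nGenes, nPlant))
        truth <- vector("list", nPlant)
        for (k in seq_along(planted)) {
            i <- planted[k]
            res <- plantOneModule(gaps[i], hzaSource, gataWord, gapRange,
                                  atgDistanceRange, baseComposition)
            gaps[i] <- res$seq
            res$rec$gene_id <- sprintf("gene%03d", i)
            truth[[k]] <- res$rec
        }
        chrom <- paste0(paste0(gaps, bodies, collapse = ""))
        starts <- as.integer(cumsum(c(1, head(gapLens + geneLength, -1L)))
                             + gapLens)
        genes <- GRanges(chromName,
                         IRanges(starts, starts + geneLength - 1L),
                         strand = "+")
        mcols(genes) <- DataFrame(
            gene_id = sprintf("gene%03d", seq_len(nGenes)),
            atg_pos = starts)
        genome <- DNAStringSet(setNames(chrom, chromName))
        truth <- if (nPlant)
            do.call(rbind, truth)[, c("gene_id", "hza_offset", "hza_strand",
                                      "hza_word", "gata_offset",
                                      "gata_strand", "gata_word", "gap",
                                      "atg_distance")]
        else data.frame(gene_id = character(), hza_offset = integer(),
                        hza_strand = character(), hza_word = character(),
                        gata_offset = integer(), gata_strand = character(),
                        gata_word = character(), gap = integer(),
                        atg_distance = integer(), stringsAsFactors = FALSE)
        rownames(truth) <- NULL
        new("SyntheticStudy", genome = genome, genes = genes, truth = truth,
            orthologs = DNAStringSet(),
            config = list(nGenes = nGenes, intergenicRange = intergenicRange,
                          geneLength = geneLength,
                          baseComposition = baseComposition,
                          plantedFraction = plantedFraction,
                          hzaSource = if (is(hzaSource, "PWM"))
                              motifName(hzaSource) else hzaSource,
                          gataWord = gataWord, gapRange = gapRange,
                          atgDistanceRange = atgDistanceRange,
                          orthologMutationRate = orthologMutationRate,
                          seed = seed, chromName = chromName))
    })
}

# Plant one HZA+GATA module into an intergenic (upstream-region) sequence.
# The sequence is the gene's upstream region in transcription orientation,
# so region index i has ATG offset i - L - 1.
plantOneModule <- function(gapSeq, hzaSource, gataWord, gapRange,
                           atgDistanceRange, baseComposition,
                           maxTries = 100) {
    L <- nchar(gapSeq)
    Wg <- nchar(gataWord)
    for (try in seq_len(maxTries)) {
        hzaWord <- if (is(hzaSource, "PWM")) sampleFromPWM(hzaSource)
                   else toupper(hzaSource)
        Wh <- nchar(hzaWord)
        gap <- sample(gapRange[1]:gapRange[2], 1L)
        modLen <- Wh + gap + Wg
        dLo <- max(atgDistanceRange[1], modLen)
        dHi <- min(atgDistanceRange[2], L)
        if (dLo > dHi) next
        d <- sample(dLo:dHi, 1L)
        hzaStrand <- sample(c("+", "-"), 1L)
        gataStrand <- sample(c("+", "-"), 1L)
        hzaFirst <- sample(c(TRUE, FALSE), 1L)   # HZA more ATG-distal?
        modStart <- -d                           # offset of 5'-most module base
        if (hzaFirst) {
            hzaOff <- modStart
            gataOff <- modStart + Wh + gap
        } else {
            gataOff <- modStart
            hzaOff <- modStart + Wg + gap
        }
        hzaPlanted <- if (hzaStrand == "+") hzaWord else revCompChar(hzaWord)
        gataPlanted <- if (gataStrand == "+") gataWord
                       else revCompChar(gataWord)
        s <- gapSeq
        ih <- hzaOff + L + 1L
        ig <- gataOff + L + 1L
        substr(s, ih, ih + Wh - 1L) <- hzaPlanted
        substr(s, ig, ig + Wg - 1L) <- gataPlanted
        rec <- data.frame(hza_offset = hzaOff, hza_strand = hzaStrand,
                          hza_word = hzaWord, gata_offset = gataOff,
                          gata_strand = gataStrand, gata_word = gataWord,
                          gap = gap, atg_distance = d,
                          stringsAsFactors = FALSE)
        return(list(seq = s, rec = rec))
    }
    stop("could not place a module after ", maxTries,
         " draws; intergenic region too short for the configured distances")
}

#' Mutated ortholog promoters for conservation tests
#'
#' For each planted gene, a copy of its upstream region with i.i.d.
#' substitutions at `mutationRate` (a mutated base is replaced by one of the
#' other three, uniformly).
#'
#' @param study a [SyntheticStudy-class]
#' @param mutationRate per-base substitution probability in [0, 1)
#' @param seed optional RNG seed
#' @return a [Biostrings::DNAStringSet] named by gene id
#' @export
makeOrthologPromoters <- function(study, mutationRate = 0.1, seed = NULL) {
    stopifnot(is(study, "SyntheticStudy"),
              mutationRate >= 0, mutationRate < 1)
    truth <- truthTable(study)
    regions <- extractUpstreamRegions(studyGenes(study), studyGenome(study),
                                      geneIds = truth$gene_id)
    withSeed(seed, {
        out <- vapply(as.character(regionSeqs(regions)), function(s) {
            v <- strsplit(s, "", fixed = TRUE)[[1]]
            hit <- runif(length(v)) < mutationRate
            if (any(hit))
                v[hit] <- vapply(v[hit], function(b)
                    sample(setdiff(DNA_BASES, b), 1L), character(1))
            paste0(v, collapse = "")
        }, character(1), USE.NAMES = FALSE)
        ss <- DNAStringSet(out)
        names(ss) <- truth$gene_id
        ss
    })
}

#' Write a synthetic study to disk
#'
#' Emits `genome.fa`, `genes.gff3` (gene + CDS features), `truth.tsv`,
#' `truth.bed` (genomic module spans) and, if requested,
#' `orthologs.fa` — all plain text, round-tripping through [readGenome()]
#' and [readGeneAnnotation()].
#'
#' @param study a [SyntheticStudy-class]
#' @param dir output directory (created if needed)
#' @param orthologs also write mutated ortholog promoters (uses the study's
#'   configured mutation rate and seed)
#' @return the directory, invisibly
#' @export
writeStudy <- function(study, dir, orthologs = FALSE) {
    stopifnot(is(study, "SyntheticStudy"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeXStringSet(studyGenome(study), file.path(dir, "genome.fa"))
    exportStudyGFF(study, file.path(dir, "genes.gff3"))
    truth <- truthTable(study)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeTruthBED(study, file.path(dir, "truth.bed"))
    if (orthologs) {
        mo <- makeOrthologPromoters(
            study, study@config$orthologMutationRate,
            seed = study@config$seed + 1L)
        writeXStringSet(mo, file.path(dir, "orthologs.fa"))
    }
    invisible(dir)
}

exportStudyGFF <- function(study, path) {
    genes <- studyGenes(study)
    cds <- genes
    gffGenes <- genes
    mcols(gffGenes) <- DataFrame(type = "gene", ID = genes$gene_id)
    mcols(cds) <- DataFrame(type = "CDS",
                            ID = paste0(genes$gene_id, ".cds"),
                            Parent = as.character(genes$gene_id),
                            phase = 0L)
    gff <- c(gffGenes, cds)
    gff$source <- "hzascreen"
    rtracklayer::export(gff, path, format = "gff3")
    invisible(path)
}

writeTruthBED <- function(study, path) {
    truth <- truthTable(study)
    genes <- studyGenes(study)
    k <- match(truth$gene_id, genes$gene_id)
    # + genes only in the generator: offset o maps to atg_pos + o
    ms <- pmin(truth$hza_offset, truth$gata_offset)
    me <- pmax(truth$hza_offset + nchar(truth$hza_word) - 1L,
               truth$gata_offset + nchar(truth$gata_word) - 1L)
    bed <- data.frame(chrom = as.character(seqnames(genes))[k],
                      start = genes$atg_pos[k] + ms - 1L,
                      end = genes$atg_pos[k] + me,
                      name = truth$gene_id, score = 0, strand = "+")
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
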