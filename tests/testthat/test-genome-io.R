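test_that("FASTA reading folds case, maps U to T and flags odd letters", {
    tf <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">chrI some description", "acgt"), tf)
    g <- readGenome(tf)
    expect_length(g, 1L)
    expect_identical(names(g), "chrI")
    expect_identical(as.character(g[[1]]), "ACGT")

    writeLines(c(">r1", "acgu", ">r2", "AXGT"), tf)
    expect_warning(g2 <- readGenome(tf), "mapped to N")
    expect_identical(as.character(g2), c(r1 = "ACGT", r2 = "ANGT"))

    file.create(tf2 <- withr::local_tempfile(fileext = ".fa"))
    expect_length(readGenome(tf2), 0L)

    writeLines(c(">good", "ACGT", ">empty"), tf)
    expect_error(readGenome(tf), "empty")
    expect_error(readGenome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("a 3-record toy genome round-trips byte-identically", {
    set.seed(11)
    seqs <- setNames(vapply(c(40, 17, 63), randomSeq, character(1)),
                     c("c1", "c2", "c3"))
    tf <- withr::local_tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), tf)
    back <- readGenome(tf)
    expect_identical(as.character(back), seqs)
})

test_that("GFF3 annotation yields the transcription-orientation ATG", {
    tf <- withr::local_tempfile(fileext = ".gff3")
    writeToyGFF(tf, c(
        "chrI\tt\tgene\t50\t200\t.\t+\t.\tID=gA",
        "chrI\tt\tCDS\t101\t200\t.\t+\t0\tID=gA.c;Parent=gA",
        "chrI\tt\tgene\t300\t460\t.\t-\t.\tID=gB",
        "chrI\tt\tCDS\t301\t400\t.\t-\t0\tID=gB.c;Parent=gB"))
    ann <- readGeneAnnotation(tf)
    expect_identical(ann$gene_id, c("gA", "gB"))
    expect_identical(ann$atg_pos, c(101L, 400L))

    # CDS through an mRNA level resolves to the gene
    writeToyGFF(tf, c(
        "chrI\tt\tgene\t50\t200\t.\t+\t.\tID=gA",
        "chrI\tt\tmRNA\t50\t200\t.\t+\t.\tID=gA.t;Parent=gA",
        "chrI\tt\tCDS\t120\t200\t.\t+\t0\tID=gA.c;Parent=gA.t"))
    expect_identical(readGeneAnnotation(tf)$atg_pos, 120L)

    # strandless gene is an error; CDS-less gene is skipped with a warning
    writeToyGFF(tf, c("chrI\tt\tgene\t50\t200\t.\t.\t.\tID=gA",
                      "chrI\tt\tCDS\t101\t200\t.\t.\t0\tID=c;Parent=gA"))
    expect_error(readGeneAnnotation(tf), "strand")
    writeToyGFF(tf, c("chrI\tt\tgene\t50\t200\t.\t+\t.\tID=gA",
                      "chrI\tt\tgene\t300\t400\t.\t+\t.\tID=gB",
                      "chrI\tt\tCDS\t301\t400\t.\t+\t0\tID=c;Parent=gB"))
    expect_warning(ann2 <- readGeneAnnotation(tf), "gA")
    expect_identical(ann2$gene_id, "gB")
})

test_that("upstream extraction truncates at neighbours, cap and chromosome end", {
    chrom <- paste0(strrep("G", 80), randomSeq(300))
    genome <- Biostrings::DNAStringSet(setNames(chrom, "c"))
    mkGenes <- function(starts, ends, strands, atgs, ids) {
        g <- GenomicRanges::GRanges("c", IRanges::IRanges(starts, ends),
                                    strand = strands)
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = ids,
                                                    atg_pos = atgs)
        g
    }
    # + gene with ATG at 101, neighbour ending at 80: region = 81..100
    genes <- mkGenes(c(10L, 101L), c(80L, 200L), c("+", "+"),
                     c(10L, 101L), c("up", "g"))
    r <- extractUpstreamRegions(genes, genome, geneIds = "g")
    info <- regionInfo(r)
    expect_identical(info$L, 20L)
    expect_identical(info$truncation, "neighbor_gene")
    expect_identical(as.character(regionSeqs(r)[[1]]),
                     substr(chrom, 81, 100))

    # neighbour ending at atg_pos - 1: zero-length region
    genes0 <- mkGenes(c(10L, 101L), c(100L, 200L), c("+", "+"),
                      c(10L, 101L), c("up", "g"))
    r0 <- extractUpstreamRegions(genes0, genome, geneIds = "g")
    expect_identical(regionInfo(r0)$L, 0L)
    expect_identical(regionInfo(r0)$truncation, "neighbor_gene")

    # no neighbour: truncation at the chromosome start
    genes1 <- mkGenes(101L, 200L, "+", 101L, "g")
    r1 <- extractUpstreamRegions(genes1, genome)
    expect_identical(regionInfo(r1)$L, 100L)
    expect_identical(regionInfo(r1)$truncation, "chromosome_end")

    # cap at maxLen (the default cap is 20 kb)
    r2 <- extractUpstreamRegions(genes1, genome, maxLen = 30)
    expect_identical(regionInfo(r2)$L, 30L)
    expect_identical(regionInfo(r2)$truncation, "max_len")
    expect_identical(formals(extractUpstreamRegions)$maxLen, 20000)

    # minus-strand gene: region right of the ATG, reverse-complemented
    genesM <- mkGenes(c(101L, 320L), c(200L, 350L), c("-", "+"),
                      c(200L, 320L), c("g", "down"))
    rM <- extractUpstreamRegions(genesM, genome, geneIds = "g")
    infoM <- regionInfo(rM)
    expect_identical(infoM$L, 119L)  # 201..319, blocked by the + gene
    expect_identical(infoM$truncation, "neighbor_gene")
    expect_identical(
        as.character(regionSeqs(rM)[[1]]),
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(chrom, 201, 319)))))
})

test_that("ATG offsets follow the A=+1 convention and round-trip", {
    expect_identical(atgOffset(313, 313), -1L)
    expect_identical(atgOffset(313, 1), -313L)
    for (i in 1:10)
        expect_identical(offsetToIndex(10, atgOffset(10, i)), i)
    expect_error(atgOffset(10, 11), "out of range")
    expect_error(offsetToIndex(10, 0), "out of range")
})

test_that("regions map back to the genome exactly (both strands)", {
    toy <- toyTwoGeneGenome()
    regions <- extractUpstreamRegions(toy$genes, toy$genome)
    info <- as.data.frame(regionInfo(regions))
    for (k in seq_len(nrow(info))) {
        slice <- substr(toy$chrom, info$gstart[k], info$gend[k])
        if (info$strand[k] == "-")
            slice <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(slice)))
        expect_identical(as.character(regionSeqs(regions)[[k]]), slice)
        expect_lte(info$L[k], 20000L)
    }
    # neither region overlaps any gene body
    gr <- GenomicRanges::GRanges(info$chrom,
                                 IRanges::IRanges(info$gstart, info$gend))
    expect_length(GenomicRanges::findOverlaps(gr, toy$genes,
                                              type = "within"), 0L)
    expect_length(
        GenomicRanges::findOverlaps(gr, toy$genes, minoverlap = 1L), 0L)
})
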