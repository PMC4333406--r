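# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the implementation
# paths they check.

BASES <- c("A", "C", "G", "T")

randomPWM <- function(W, concentration = 1) {
    p <- matrix(rgamma(4 * W, shape = concentration), 4, W)
    p <- sweep(p, 2, colSums(p), "/")
    rownames(p) <- BASES
    hzascreen:::newPWM(p, name = "random")
}

randomBackground <- function() {
    b <- rgamma(4, 2)
    b / sum(b)
}

# exceedance by exhaustive enumeration of all 4^W words
enumNullExceedance <- function(scheme, bg) {
    lat <- scheme@lattice
    W <- ncol(lat)
    words <- as.matrix(expand.grid(rep(list(1:4), W)))
    sc <- numeric(nrow(words))
    pr <- numeric(nrow(words))
    for (r in seq_len(nrow(words))) {
        sc[r] <- sum(lat[cbind(words[r, ], seq_len(W))])
        pr[r] <- prod(bg[words[r, ]])
    }
    agg <- tapply(pr, sc, sum)
    support <- as.numeric(names(agg))
    o <- order(support)
    support <- support[o]
    prob <- as.numeric(agg)[o]
    list(support = support, prob = prob,
         exceedance = rev(cumsum(rev(prob))))
}

# brute-force both-strand scan of a single sequence (offsets ATG-relative)
bruteScan <- function(s, scheme, cutoff) {
    lat <- scheme@lattice
    W <- ncol(lat)
    L <- nchar(s)
    res <- list()
    scoreWord <- function(w) {
        v <- match(strsplit(w, "")[[1]], BASES)
        if (anyNA(v)) return(NA_real_)
        sum(lat[cbind(v, seq_len(W))])
    }
    for (i in seq_len(max(0L, L - W + 1L))) {
        w <- substr(s, i, i + W - 1L)
        sc <- scoreWord(w)
        if (!is.na(sc) && sc >= cutoff)
            res[[length(res) + 1L]] <- data.frame(
                offset = i - L - 1L, strand = "+", latticeScore = sc,
                word = w, stringsAsFactors = FALSE)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(w)))
        sc2 <- scoreWord(rc)
        if (!is.na(sc2) && sc2 >= cutoff)
            res[[length(res) + 1L]] <- data.frame(
                offset = i - L - 1L, strand = "-", latticeScore = sc2,
                word = rc, stringsAsFactors = FALSE)
    }
    if (length(res) == 0L)
        return(data.frame(offset = integer(), strand = character(),
                          latticeScore = numeric(), word = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    out[order(out$offset, out$strand), , drop = FALSE]
}

# brute-force all-pairs gap filter straight from the edge-gap definition
brutePair <- function(hza, gata, maxGap) {
    keep <- list()
    for (i in seq_len(nrow(hza))) for (j in seq_len(nrow(gata))) {
        if (hza$gene_id[i] != gata$gene_id[j]) next
        hs <- hza$offset[i]; he <- hs + nchar(hza$word[i]) - 1L
        gs <- gata$offset[j]; ge <- gs + nchar(gata$word[j]) - 1L
        gap <- if (gs >= hs) gs - he - 1L else hs - ge - 1L
        if (gap <= maxGap)
            keep[[length(keep) + 1L]] <- c(i = i, j = j, gap = gap)
    }
    if (length(keep) == 0L)
        return(data.frame(i = integer(), j = integer(), gap = integer()))
    as.data.frame(do.call(rbind, keep))
}

# exhaustive global-alignment score by memoless path recursion
exhaustiveAlignScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    rec <- function(i, j) {
        if (i == 0 && j == 0) return(0)
        best <- -Inf
        if (i > 0 && j > 0)
            best <- max(best, rec(i - 1, j - 1) +
                        if (av[i] == bv[j]) match else mismatch)
        if (i > 0) best <- max(best, rec(i - 1, j) + gap)
        if (j > 0) best <- max(best, rec(i, j - 1) + gap)
        best
    }
    rec(length(av), length(bv))
}

randomSeq <- function(L, prob = rep(0.25, 4)) {
    paste0(sample(BASES, L, replace = TRUE, prob = prob), collapse = "")
}

mutateSeq <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1)
    paste0(v, collapse = "")
}

# a toy two-gene genome with one gene on each strand, used for the
# coordinate-convention fixtures
toyTwoGeneGenome <- function() {
    # layout (1-based):  1..60 background | gene fwd 61..160 (+, ATG at 61)
    #                    161..260 background | gene rev 261..360 (-, ATG at 360)
    set.seed(42)
    chrom <- randomSeq(420)
    genes <- GenomicRanges::GRanges(
        "chrT", IRanges::IRanges(c(61L, 261L), c(160L, 360L)),
        strand = c("+", "-"))
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
        gene_id = c("gfwd", "grev"), atg_pos = c(61L, 360L))
    genome <- Biostrings::DNAStringSet(stats::setNames(chrom, "chrT"))
    list(genome = genome, genes = genes, chrom = chrom)
}

writeToyGFF <- function(path, lines) {
    writeLines(c("##gff-version 3", lines), path)
}
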