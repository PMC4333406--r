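test_that("PWM construction follows the pseudocount formula", {
    p <- buildPWM(rep("TGATAA", 4), pseudocount = 0)
    expect_equal(unname(probs(p)[cbind(match(strsplit("TGATAA", "")[[1]],
                                             c("A", "C", "G", "T")),
                                       1:6)]),
                 rep(1, 6))
    p2 <- buildPWM(c("ACGT", "AAGT"), pseudocount = 0.25)
    expect_equal(unname(probs(p2)[, 2]),
                 c(1.25, 1.25, 0.25, 0.25) / 3)
    expect_equal(colSums(probs(p2)), rep(1, 4), tolerance = 1e-12)
    expect_error(buildPWM(c("ACG", "ACGT")), "equal lengths")
    expect_error(buildPWM(character(0)), "at least one")
    expect_error(buildPWM("ACGN"), "only A,C,G,T")
})

test_that("information content matches the closed forms", {
    pU <- hzascreen:::newPWM(matrix(0.25, 4, 1,
                                    dimnames = list(c("A","C","G","T"), NULL)))
    expect_equal(informationContent(pU), 0)
    pI <- buildPWM("A", pseudocount = 0)
    expect_equal(informationContent(pI), 2)
    pH <- hzascreen:::newPWM(matrix(c(0.5, 0.5, 0, 0), 4, 1,
                                    dimnames = list(c("A","C","G","T"), NULL)))
    expect_equal(informationContent(pH), 1)
})

test_that("score lattice approximates log-odds within the stated bound", {
    set.seed(5)
    for (rep in 1:5) {
        pwm <- randomPWM(3, concentration = 2)
        sch <- scoreScheme(pwm, granularity = 1000)
        words <- as.matrix(expand.grid(rep(list(1:4), 3)))
        for (r in sample(nrow(words), 10)) {
            w <- words[r, ]
            exact <- sum(log(probs(pwm)[cbind(w, 1:3)] / 0.25))
            lat <- sum(sch@lattice[cbind(w, 1:3)])
            expect_lt(abs(lat / 1000 - exact), 3 / (2 * 1000))
        }
        expect_identical(sch@maxScore, sum(apply(sch@lattice, 2, max)))
    }
    # PWM equal to background: all-zero lattice
    pU <- hzascreen:::newPWM(matrix(0.25, 4, 4,
                                    dimnames = list(c("A","C","G","T"), NULL)))
    schU <- scoreScheme(pU)
    expect_true(all(schU@lattice == 0))
    pz <- buildPWM(c("AAAA", "AAAA"), pseudocount = 0)
    expect_error(scoreScheme(pz), "pseudocount")
})

test_that("DP null distribution equals exhaustive enumeration", {
    # single informative column, uniform background
    p1 <- hzascreen:::newPWM(
        matrix(c(0.4, 0.3, 0.2, 0.1), 4, 1,
               dimnames = list(c("A","C","G","T"), NULL)))
    s1 <- scoreScheme(p1)
    n1 <- nullDistribution(s1)
    exc <- exceedance(n1)
    expect_equal(unname(exc[as.character(max(s1@lattice))]), 0.25)
    expect_equal(unname(exc[as.character(min(s1@lattice))]), 1.0)

    set.seed(99)
    for (rep in 1:10) {
        W <- sample(2:6, 1)
        pwm <- randomPWM(W, concentration = 1.5)
        bg <- if (rep %% 2) rep(0.25, 4) else randomBackground()
        pwm <- hzascreen:::newPWM(probs(pwm), bg)
        sch <- scoreScheme(pwm)
        nd <- nullDistribution(sch)
        en <- enumNullExceedance(sch, bg)
        got <- nd@prob[nd@prob > 0]
        names(got) <- nd@support[nd@prob > 0]
        want <- en$prob[en$prob > 0]
        names(want) <- en$support[en$prob > 0]
        expect_identical(names(got), names(want))
        expect_equal(got, want, tolerance = 1e-12)
        # mass at the maximum equals the probability of the consensus path
        expect_equal(unname(exceedance(nd)[as.character(sch@maxScore)]),
                     prod(bg[apply(sch@lattice, 2, which.max)]),
                     tolerance = 1e-12)
    }
})

test_that("p-value cutoffs are exact and monotone", {
    set.seed(7)
    pwm <- randomPWM(3, concentration = 1.5)
    sch <- scoreScheme(pwm)
    nd <- nullDistribution(sch)
    expect_identical(cutoffForPvalue(nd, 1), min(nd@support))
    # alpha between two adjacent exceedance values picks the upper score
    en <- enumNullExceedance(sch, background(pwm))
    ex <- sort(unique(en$exceedance), decreasing = TRUE)
    mid <- sqrt(ex[4] * ex[5])
    cut <- cutoffForPvalue(nd, mid)
    expect_identical(cut, min(en$support[en$exceedance <= mid]))
    alphas <- c(0.5, 0.2, 0.1)
    cuts <- vapply(alphas, function(a) cutoffForPvalue(nd, a), numeric(1))
    expect_true(all(diff(cuts) >= 0))
    # unattainable alpha: nothing can pass, with a warning
    expect_warning(c0 <- cutoffForPvalue(nd, 1e-12), "no window can pass")
    expect_identical(c0, max(nd@support) + 1)
})

test_that("scanning reports consensus plants at their offsets and strands", {
    pwm <- hzaMatrix()
    sch <- scoreScheme(pwm)
    cons <- pwmConsensus(pwm)
    consActual <- sub("N", "A", cons)  # a concrete word for the N position
    set.seed(3)
    bgseq <- randomSeq(200)
    # plant at offset -50: region index 200-50+1 = 151
    s <- bgseq
    substr(s, 151, 165) <- consActual
    regions <- new("UpstreamRegionSet",
                   seqs = Biostrings::DNAStringSet(c(g1 = s)),
                   info = S4Vectors::DataFrame(
                       gene_id = "g1", chrom = "c", strand = "+",
                       atg_pos = 201L, gstart = 1L, gend = 200L, L = 200L,
                       truncation = "chromosome_end"))
    hits <- scanRegions(regions, pwm, cutoff = sch@maxScore)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$offset, -50L)
    expect_identical(hits$strand, "+")
    expect_identical(hits$word, consActual)

    # the same word planted as reverse complement is a minus-strand hit
    s2 <- bgseq
    substr(s2, 151, 165) <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(consActual)))
    regions2 <- regions
    regions2@seqs <- Biostrings::DNAStringSet(c(g1 = s2))
    hits2 <- scanRegions(regions2, pwm, cutoff = sch@maxScore)
    expect_identical(hits2$offset, -50L)
    expect_identical(hits2$strand, "-")
    expect_identical(hits2$word, consActual)

    # region shorter than the motif: no windows
    shortR <- new("UpstreamRegionSet",
                  seqs = Biostrings::DNAStringSet(c(g = "ACGT")),
                  info = S4Vectors::DataFrame(
                      gene_id = "g", chrom = "c", strand = "+",
                      atg_pos = 5L, gstart = 1L, gend = 4L, L = 4L,
                      truncation = "chromosome_end"))
    expect_identical(nrow(scanRegions(shortR, pwm, cutoff = 0)), 0L)
})

test_that("scanning equals brute force on random regions with N handling", {
    set.seed(21)
    pwm <- randomPWM(4, concentration = 1.2)
    sch <- scoreScheme(pwm)
    nd <- nullDistribution(sch)
    cutoff <- cutoffForPvalue(nd, 0.05)
    for (rep in 1:25) {
        L <- sample(3:40, 1)
        s <- randomSeq(L)
        if (rep %% 3 == 0 && L > 6) {
            i <- sample(L, 1)
            substr(s, i, i) <- "N"
        }
        regions <- new("UpstreamRegionSet",
                       seqs = Biostrings::DNAStringSet(setNames(s, "g")),
                       info = S4Vectors::DataFrame(
                           gene_id = "g", chrom = "c", strand = "+",
                           atg_pos = L + 1L, gstart = 1L, gend = L,
                           L = L, truncation = "chromosome_end"))
        got <- scanRegions(regions, pwm, cutoff = cutoff)
        want <- bruteScan(s, sch, cutoff)
        expect_identical(got$offset, want$offset)
        expect_identical(got$strand, want$strand)
        expect_identical(got$word, want$word)
        expect_equal(got$latticeScore, want$latticeScore)
    }
})

test_that("scanning is strand-symmetric under reverse complement", {
    set.seed(31)
    pwm <- randomPWM(5, concentration = 1.3)
    cutoff <- cutoffForPvalue(nullDistribution(scoreScheme(pwm)), 0.02)
    for (rep in 1:10) {
        L <- sample(20:60, 1)
        s <- randomSeq(L)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        mk <- function(x) new("UpstreamRegionSet",
            seqs = Biostrings::DNAStringSet(setNames(x, "g")),
            info = S4Vectors::DataFrame(
                gene_id = "g", chrom = "c", strand = "+", atg_pos = L + 1L,
                gstart = 1L, gend = L, L = L,
                truncation = "chromosome_end"))
        h1 <- scanRegions(mk(s), pwm, cutoff = cutoff)
        h2 <- scanRegions(mk(rc), pwm, cutoff = cutoff)
        # mirror: a window at region index i on one strand appears at
        # index L-W-i+2 on the other strand of the reverse complement
        W <- width(pwm)
        mirrored <- data.frame(
            offset = -(h1$offset + L + 1L) - W + 1L,
            strand = as.character(ifelse(h1$strand == "+", "-", "+")),
            word = h1$word, latticeScore = h1$latticeScore,
            stringsAsFactors = FALSE)
        mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
        expect_identical(h2$offset, mirrored$offset)
        expect_identical(h2$strand, mirrored$strand)
        expect_identical(h2$word, mirrored$word)
        expect_equal(h2$latticeScore, mirrored$latticeScore)
    }
})

test_that("background-only hit counts match the exact per-window rate", {
    set.seed(61)
    pwm <- hzaMatrix()
    sch <- scoreScheme(pwm)
    nd <- nullDistribution(sch)
    alpha <- 1e-3
    cutoff <- cutoffForPvalue(nd, alpha)
    pExact <- unname(exceedance(nd)[as.character(cutoff)])
    expect_lte(pExact, alpha)
    L <- 2000L; n <- 40L
    seqs <- vapply(seq_len(n), function(i) randomSeq(L), character(1))
    names(seqs) <- paste0("g", seq_len(n))
    regions <- new("UpstreamRegionSet",
                   seqs = Biostrings::DNAStringSet(seqs),
                   info = S4Vectors::DataFrame(
                       gene_id = names(seqs), chrom = "c", strand = "+",
                       atg_pos = L + 1L, gstart = 1L, gend = L, L = L,
                       truncation = rep("chromosome_end", n)))
    hits <- scanRegions(regions, pwm, cutoff = cutoff)
    nWin <- 2 * (L - width(pwm) + 1) * n
    expected <- nWin * pExact
    expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected) + 1)
})

test_that("PWM text files round-trip at the stored precision", {
    set.seed(8)
    pwm <- buildPWM(c("TGATAAGGTCAA", "TGATAACCTGCA", "TGCTAAGGTGCA"),
                    pseudocount = 0.25, name = "gata-test")
    tf <- withr::local_tempfile(fileext = ".pwm")
    writePWM(pwm, tf)
    back <- readPWM(tf)
    expect_identical(motifName(back), "gata-test")
    expect_identical(width(back), 12L)
    expect_equal(pseudocount(back), 0.25)
    expect_equal(probs(back), probs(pwm), tolerance = 2e-6)
    expect_equal(background(back), background(pwm), tolerance = 2e-6)
    # a second write is byte-stable
    tf2 <- withr::local_tempfile(fileext = ".pwm")
    writePWM(back, tf2)
    expect_identical(readLines(tf), readLines(tf2))
})
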