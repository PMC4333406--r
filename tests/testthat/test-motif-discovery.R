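plantWord <- function(L, word, pos = NULL) {
    s <- randomSeq(L)
    if (is.null(pos)) pos <- sample(seq_len(L - nchar(word) + 1), 1)
    substr(s, pos, pos + nchar(word) - 1) <- word
    list(seq = s, pos = pos)
}

test_that("noiseless planted words are recovered exactly (ZOOPS)", {
    set.seed(101)
    word <- "TGACAAACT"
    planted <- lapply(1:5, function(i) plantWord(120, word))
    seqs <- setNames(vapply(planted, `[[`, character(1), "seq"),
                     paste0("s", 1:5))
    res <- discoverMotif(seqs, width = 9, mode = "zoops",
                         bothStrands = FALSE)
    expect_identical(pwmConsensus(res@pwm), word)
    occ <- occurrences(res)
    expect_identical(nrow(occ), 5L)
    expect_identical(occ$start, vapply(planted, `[[`, integer(1), "pos"))
    expect_identical(unique(occ$word), word)
    expect_gte(res@llr, 0)
    # EM log-likelihood is nondecreasing along the winning trace
    expect_true(all(diff(res@llTrace) >= -1e-8))
})

test_that("both-strand ZOOPS recovers reverse-complemented plants", {
    set.seed(107)
    word <- "TGACAAACTGT"
    seqs <- character(4)
    pos <- integer(4)
    strands <- c("+", "-", "+", "-")
    for (i in 1:4) {
        w <- if (strands[i] == "+") word else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(word)))
        p <- plantWord(150, w)
        seqs[i] <- p$seq
        pos[i] <- p$pos
    }
    names(seqs) <- paste0("s", 1:4)
    res <- discoverMotif(seqs, width = 11, mode = "zoops",
                         bothStrands = TRUE)
    # motif discovery is phase- and strand-ambiguous: accept the planted
    # word or its reverse complement up to a 1 bp register shift
    cons <- pwmConsensus(res@pwm)
    rcCons <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cons)))
    alignedMatches <- function(a, b, shift) {
        ia <- max(1, 1 + shift); ib <- max(1, 1 - shift)
        n <- min(nchar(a) - ia, nchar(b) - ib) + 1
        sum(strsplit(substr(a, ia, ia + n - 1), "")[[1]] ==
            strsplit(substr(b, ib, ib + n - 1), "")[[1]])
    }
    best <- max(vapply(-1:1, function(s) max(
        alignedMatches(cons, word, s),
        alignedMatches(rcCons, word, s)), numeric(1)))
    expect_gte(best, 10)
    occ <- occurrences(res)
    expect_identical(nrow(occ), 4L)
    expect_true(all(abs(occ$start - pos) <= 1))
})

test_that("EM from all seeds beats every hard site placement (OOPS)", {
    set.seed(113)
    seqs <- setNames(vapply(1:3, function(i) randomSeq(8), character(1)),
                     paste0("s", 1:3))
    W <- 4
    res <- discoverMotif(seqs, width = W, mode = "oops",
                         bothStrands = FALSE, nShortlist = 100)
    # oracle: every hard placement, PWM from the placed words, OOPS marginal ll
    bgc <- table(factor(strsplit(paste0(seqs, collapse = ""), "")[[1]],
                        levels = BASES))
    bg <- as.numeric(bgc / sum(bgc))
    m <- nchar(seqs[1]) - W + 1
    placements <- expand.grid(rep(list(seq_len(m)), 3))
    placementObj <- function(starts) {
        words <- vapply(1:3, function(i)
            substr(seqs[i], starts[i], starts[i] + W - 1), character(1))
        pwm <- buildPWM(words, pseudocount = 0.25)
        lo <- log(probs(pwm)) - log(bg)
        ll <- sum(vapply(1:3, function(i) {
            sw <- vapply(seq_len(m), function(p) {
                v <- match(strsplit(substr(seqs[i], p, p + W - 1),
                                    "")[[1]], BASES)
                sum(lo[cbind(v, 1:W)])
            }, numeric(1))
            M <- max(sw)
            M + log(sum(exp(sw - M))) - log(m)
        }, numeric(1)))
        # same penalized objective the EM fit reports
        ll + 0.25 * sum(log(probs(pwm)))
    }
    bestHard <- max(apply(placements, 1, placementObj))
    expect_gte(tail(res@llTrace, 1), bestHard - 1e-6)
})

test_that("discovery is deterministic", {
    set.seed(131)
    seqs <- setNames(vapply(1:4, function(i)
        plantWord(100, "CCATAAACC")$seq, character(1)), paste0("s", 1:4))
    r1 <- discoverMotif(seqs, width = 9)
    r2 <- discoverMotif(seqs, width = 9)
    expect_identical(probs(r1@pwm), probs(r2@pwm))
    expect_identical(occurrences(r1), occurrences(r2))
    expect_identical(r1@llr, r2@llr)
})

test_that("mutated plants are recovered across seeded replicates", {
    word <- "TCTGCAGAAACTGTA"
    nOk <- 0L
    matches <- integer(20)
    for (seed in 1:20) {
        set.seed(seed)
        seqs <- setNames(vapply(1:6, function(i) {
            s <- randomSeq(600)
            pos <- sample(1:(600 - 14), 1)
            substr(s, pos, pos + 14) <- mutateSeq(word, 0.1)
            s
        }, character(1)), paste0("s", 1:6))
        res <- discoverMotif(seqs, width = 15, mode = "zoops",
                             bothStrands = FALSE)
        expect_true(all(diff(res@llTrace) >= -1e-8))
        cons <- strsplit(pwmConsensus(res@pwm), "")[[1]]
        matches[seed] <- sum(cons == strsplit(word, "")[[1]])
        if (matches[seed] >= 13L) nOk <- nOk + 1L
    }
    expect_gte(nOk, 18L)
})

test_that("iterative masking finds distinct motifs in order of support", {
    set.seed(151)
    w1 <- "TGACAAACTG"   # planted in all 6 sequences
    w2 <- "CCGTTTGGAC"   # planted in 4 of 6
    seqs <- vapply(1:6, function(i) randomSeq(200), character(1))
    names(seqs) <- paste0("s", 1:6)
    for (i in 1:6) substr(seqs[i], 20, 29) <- w1
    for (i in 1:4) substr(seqs[i], 120, 129) <- w2
    out <- discoverTopMotifs(seqs, width = 10, nMotifs = 2,
                             bothStrands = FALSE)
    cons <- vapply(out, function(r) pwmConsensus(r@pwm), character(1))
    expect_identical(cons[1], w1)
    expect_identical(cons[2], w2)
    expect_gte(significance(out[[1]]), significance(out[[2]]))
    # n = 1 reduces to a single discoverMotif call
    one <- discoverTopMotifs(seqs, width = 10, nMotifs = 1,
                             bothStrands = FALSE)
    single <- discoverMotif(seqs, width = 10, bothStrands = FALSE)
    expect_identical(probs(one[[1]]@pwm), probs(single@pwm))
})

test_that("input contracts are enforced", {
    expect_error(discoverMotif("ACGTACGT", width = 4), "at least 2")
    expect_error(discoverMotif(c(a = "ACG", b = "ACGTACGT"), width = 4),
                 "shorter")
    expect_error(discoverMotif(c(a = "ACGTA", b = "ACGTT"), width = 3),
                 ">= 4")
})
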