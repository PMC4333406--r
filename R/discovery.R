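# Deterministic substring-seeded EM motif elicitation (OOPS/ZOOPS).
#
# Every distinct W-mer of the input (both strands if enabled) is turned into
# a near-indicator seed model (probability 0.7 on the seed base, 0.1 on the
# others). Seeds are ranked by one E-step evaluation of the seed model's
# log-likelihood ratio; the best `nShortlist` seeds are refined by EM to
# convergence, and the run with the highest converged llr wins. Ties are
# broken by the lexicographically smallest consensus, then by the earliest
# seed (input order, position). Everything is deterministic given the inputs
# and the configuration.

enumerateSeeds <- function(seqs, W, bothStrands) {
    words <- character(0)
    for (s in seqs) {
        L <- nchar(s)
        if (L >= W)
            words <- c(words, substring(s, 1:(L - W + 1), W:L))
        if (bothStrands) {
            rc <- revCompChar(s)
            if (L >= W)
                words <- c(words, substring(rc, 1:(L - W + 1), W:L))
        }
    }
    words <- words[!grepl("N", words, fixed = TRUE)]
    unique(words)   # first-occurrence order: deterministic
}

# shift motif columns by s (positive = rightward), filling with background
shiftColumns <- function(p, s, bg) {
    W <- ncol(p)
    out <- matrix(bg, 4, W)
    src <- seq_len(W) - s
    ok <- src >= 1 & src <= W
    out[, ok] <- p[, src[ok]]
    rownames(out) <- DNA_BASES
    out
}

seedPWM <- function(word, pMatch = 0.7) {
    codes <- seqCodes(word) + 1L
    p <- matrix((1 - pMatch) / 3, 4, nchar(word))
    p[cbind(codes, seq_along(codes))] <- pMatch
    p
}

#' Discover one motif by seeded EM
#'
#' Fits a motif of width `width` to a small sequence set under the OOPS
#' (exactly one site per sequence) or ZOOPS (zero or one) occurrence model,
#' with a 0-order background estimated from the input. See the package
#' vignette for the model and the seeding strategy. The ranking statistic
#' (`significance`) is the converged log-likelihood ratio against the
#' background-only model, not an E-value.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#'   (at least 2 sequences, each at least `width` long)
#' @param width motif width W in bp (>= 4)
#' @param mode `"zoops"` (default) or `"oops"`
#' @param bothStrands also consider sites on the reverse strand
#'   (default TRUE)
#' @param maxIter maximum EM iterations per refined seed
#' @param tol log-likelihood convergence delta
#' @param sitePrior ZOOPS prior probability that a sequence carries a site
#' @param pseudocount pseudocount for the M-step and the returned PWM
#' @param nShortlist number of seeds refined to convergence
#' @param seedPMatch seed model probability on the seed base
#' @return a [DiscoveryResult-class]
#' @examples
#' set.seed(1)
#' seqs <- vapply(1:5, function(i) {
#'   s <- paste0(sample(c("A","C","G","T"), 60, TRUE), collapse = "")
#'   paste0(substr(s, 1, 20), "TGACAAACT", substr(s, 30, 60))
#' }, character(1))
#' res <- discoverMotif(seqs, width = 9, bothStrands = FALSE)
#' pwmConsensus(res@pwm)
#' @export
discoverMotif <- function(sequences, width, mode = c("zoops", "oops"),
                          bothStrands = TRUE, maxIter = 200, tol = 1e-6,
                          sitePrior = 0.9, pseudocount = 0.25,
                          nShortlist = 20, seedPMatch = 0.7) {
    mode <- match.arg(mode)
    seqs <- asNamedChar(sequences)
    if (length(seqs) < 2L) stop("need at least 2 sequences")
    if (width < 4L) stop("motif width must be >= 4")
    if (any(nchar(seqs) < width))
        stop("sequence(s) shorter than the motif width: ",
             paste(names(seqs)[nchar(seqs) < width], collapse = ", "))
    if (maxIter < 1L) stop("maxIter must be >= 1")
    if (tol <= 0) stop("tol must be > 0")
    if (mode == "zoops" && (sitePrior <= 0 || sitePrior >= 1))
        stop("sitePrior must be in (0,1)")

    # 0-order background from the input (shared by all runs)
    cnt <- rowSums(consensusMatrix(DNAStringSet(seqs))[DNA_BASES, ,
                                                       drop = FALSE])
    if (sum(cnt) == 0) stop("sequences contain no A,C,G,T")
    bg <- as.numeric(cnt / sum(cnt))
    bg[bg == 0] <- 1e-9; bg <- bg / sum(bg)

    fwd <- lapply(seqs, seqCodes)
    rev <- if (bothStrands) lapply(seqs, function(s) seqCodes(revCompChar(s)))
           else list()
    oops <- mode == "oops"
    gamma <- if (oops) 1 else sitePrior

    seeds <- enumerateSeeds(seqs, width, bothStrands)
    if (length(seeds) == 0L) stop("no usable seed windows (all contain N?)")
    seedMat <- do.call(rbind, lapply(seeds, seqCodes))
    pre <- .cpp_seed_ll(fwd, rev, seedMat, bg, gamma, oops, seedPMatch)
    # stable shortlist: by descending prelim llr, ties by enumeration order
    ord <- order(-pre, seq_along(pre))
    short <- seeds[ord[seq_len(min(nShortlist, length(seeds)))]]

    runs <- lapply(short, function(w)
        .cpp_em_run(fwd, rev, seedPWM(w, seedPMatch), bg, gamma, oops,
                    as.integer(maxIter), tol, pseudocount))
    llrs <- vapply(runs, function(r) r$llr, numeric(1))
    cons <- vapply(runs, function(r)
        paste0(DNA_BASES[apply(r$p, 2, which.max)], collapse = ""),
        character(1))
    best <- max(llrs)
    cand <- which(llrs >= best - 1e-9)
    cand <- cand[order(cons[cand], cand)]   # lexicographic consensus, then seed order
    win <- runs[[cand[1]]]

    # phase refinement: EM can lock onto the planted register shifted by a
    # base or two; restart from the fitted matrix shifted left/right
    # (vacated columns filled with background) and keep a strict
    # improvement in llr only, so ties stay at the unshifted solution
    for (s in c(-2L, -1L, 1L, 2L)) {
        p0 <- shiftColumns(win$p, s, bg)
        run <- .cpp_em_run(fwd, rev, p0, bg, gamma, oops,
                           as.integer(maxIter), tol, pseudocount)
        if (run$llr > win$llr + 1e-9) win <- run
    }

    occ <- buildOccurrences(win, seqs, width, oops)
    p <- win$p
    rownames(p) <- DNA_BASES
    pwm <- newPWM(p, bg, pseudocount, name = "discovered")
    new("DiscoveryResult", pwm = pwm, occurrences = occ,
        llr = win$llr, significance = win$llr,
        llTrace = as.numeric(win$objTrace), seed = short[cand[1]])
}

buildOccurrences <- function(run, seqs, W, oops) {
    n <- length(seqs)
    rows <- list()
    for (i in seq_len(n)) {
        if (is.na(run$bestStart[i])) next
        present <- oops || run$sitep[i] > 0.5
        if (!present) next
        start <- run$bestStart[i]
        onRev <- run$bestStrand[i] == 2L
        L <- nchar(seqs[i])
        if (onRev) {
            word <- substr(revCompChar(seqs[i]), start, start + W - 1L)
            start <- L - start - W + 2L   # 5'-most base on the forward strand
        } else {
            word <- substr(seqs[i], start, start + W - 1L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
            seq_id = names(seqs)[i], start = start,
            strand = if (onRev) "-" else "+", word = word,
            posterior = run$sitep[i], stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(seq_id = character(), start = integer(),
                          strand = character(), word = character(),
                          posterior = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Discover several motifs by iterative masking
#'
#' Runs [discoverMotif()] `nMotifs` times; after each round the found
#' occurrence windows are masked to N so the same motif is not rediscovered.
#' Results are ordered by decreasing significance.
#'
#' @inheritParams discoverMotif
#' @param nMotifs number of motifs to elicit (>= 1)
#' @param ... further arguments passed to [discoverMotif()]
#' @return a list of [DiscoveryResult-class], ordered by decreasing
#'   significance
#' @export
discoverTopMotifs <- function(sequences, width, nMotifs, ...) {
    if (nMotifs < 1L) stop("nMotifs must be >= 1")
    seqs <- asNamedChar(sequences)
    out <- vector("list", nMotifs)
    for (m in seq_len(nMotifs)) {
        out[[m]] <- discoverMotif(seqs, width, ...)
        occ <- occurrences(out[[m]])
        for (r in seq_len(nrow(occ))) {
            i <- occ$seq_id[r]
            from <- occ$start[r]
            substr(seqs[i], from, from + width - 1L) <-
                strrep("N", width)
        }
    }
    out[order(-vapply(out, significance, numeric(1)))]
}
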