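#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Deterministic optimal global alignment under linear gap costs. Traceback
#' ties are broken by preferring a match/mismatch step over gaps, then a gap
#' in `b` (consuming `a`) over a gap in `a`, so identical inputs always give
#' identical alignments.
#'
#' @param a,b nonempty nucleotide strings
#' @param match match score (default +1)
#' @param mismatch mismatch score (default -1)
#' @param gap per-base gap score (default -2)
#' @return a list with `aligned_a`, `aligned_b` (equal-length strings over
#'   A,C,G,T,N,-), `score`, and `identity` (fraction of non-gap-pair columns
#'   with equal symbols)
#' @examples
#' globalAlign("GATTACA", "GATTACA")$identity  # 1
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    a <- checkDNAString(a, "'a'"); b <- checkDNAString(b, "'b'")
    if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    n <- length(av); m <- length(bv)
    S <- matrix(0, n + 1L, m + 1L)
    S[, 1] <- gap * 0:n
    S[1, ] <- gap * 0:m
    for (i in seq_len(n)) {
        sub <- ifelse(bv == av[i], match, mismatch)
        for (j in seq_len(m)) {
            S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                                     S[i, j + 1L] + gap,
                                     S[i + 1L, j] + gap)
        }
    }
    # traceback with deterministic tie-breaking: diagonal, then gap in b
    # (consume a), then gap in a
    i <- n; j <- m
    ra <- character(0); rb <- character(0)
    while (i > 0L || j > 0L) {
        cur <- S[i + 1L, j + 1L]
        if (i > 0L && j > 0L &&
            cur == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
            ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
        } else if (i > 0L && cur == S[i, j + 1L] + gap) {
            ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
        } else {
            ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
        }
    }
    aligned <- ra != "-" & rb != "-"
    ident <- if (any(aligned)) mean(ra[aligned] == rb[aligned]) else 0
    list(aligned_a = paste0(ra, collapse = ""),
         aligned_b = paste0(rb, collapse = ""),
         score = S[n + 1L, m + 1L], identity = ident)
}

#' Two-row plain-text display of an alignment
#'
#' @param aln a list from [globalAlign()]
#' @return the display lines, invisibly (printed as a side effect)
#' @export
printAlignment <- function(aln) {
    mid <- paste0(ifelse(strsplit(aln$aligned_a, "")[[1]] ==
                         strsplit(aln$aligned_b, "")[[1]], "|", " "),
                  collapse = "")
    lines <- c(aln$aligned_a, mid, aln$aligned_b,
               sprintf("score %d, identity %.3f", aln$score, aln$identity))
    cat(lines, sep = "\n")
    invisible(lines)
}

#' Check conservation of an element in an ortholog promoter
#'
#' Scans the ortholog promoter on both strands with the element's weight
#' matrix, takes the best-scoring window (smallest start, then + strand, on
#' ties), aligns it to the reference element and reports the identity and a
#' conservation call at `identityThreshold`. This reproduces the
#' locate-and-compare use of multiple alignment deterministically.
#'
#' @param refElement the reference element word (e.g. the 15-bp HZA of one
#'   species)
#' @param orthologPromoter promoter sequence of the orthologous gene
#' @param pwm the element's [PWM-class]
#' @param identityThreshold identity fraction above which the element is
#'   called conserved (default 0.8)
#' @param promoterId label for the report
#' @param granularity score lattice granularity
#' @return a one-row data.frame: `ref_element`, `promoter_id`, `start`
#'   (1-based position of the best window in the promoter), `strand`,
#'   `word`, `score` (natural log-odds), `identity`, `conserved`
#' @export
elementConservation <- function(refElement, orthologPromoter, pwm,
                                identityThreshold = 0.8,
                                promoterId = "ortholog",
                                granularity = 1000) {
    stopifnot(is(pwm, "PWM"))
    refElement <- checkDNAString(refElement, "refElement")
    s <- checkDNAString(orthologPromoter, "orthologPromoter")
    W <- width(pwm)
    if (nchar(s) < W)
        stop("promoter shorter than the element width")
    scheme <- scoreScheme(pwm, granularity)
    hits <- scanOneSequence(s, promoterId, scheme, W,
                            cutoff = scheme@minScore, strands = "both")
    if (nrow(hits) == 0L)
        stop("no scoreable window in the promoter (all windows contain N?)")
    hits <- hits[order(-hits$latticeScore, hits$offset, hits$strand), ,
                 drop = FALSE]
    best <- hits[1, ]
    aln <- globalAlign(refElement, best$word)
    data.frame(ref_element = refElement, promoter_id = promoterId,
               start = best$offset + nchar(s) + 1L,
               strand = best$strand, word = best$word, score = best$score,
               identity = aln$identity,
               conserved = aln$identity >= identityThreshold,
               stringsAsFactors = FALSE)
}
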