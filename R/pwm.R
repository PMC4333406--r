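#' Build a position weight matrix from aligned sites
#'
#' Base probabilities are `(count + pseudocount) / (n_sites + 4*pseudocount)`
#' per column, so every entry is positive whenever `pseudocount > 0`.
#'
#' @param sites character vector (or [Biostrings::DNAStringSet]) of
#'   equal-length A/C/G/T strings
#' @param pseudocount nonnegative pseudocount per base (default 0.25)
#' @param background length-4 background probabilities (default uniform)
#' @param name motif label
#' @return a [PWM-class]
#' @examples
#' buildPWM(c("TGATAA", "TGATAA"), pseudocount = 0)
#' @export
buildPWM <- function(sites, pseudocount = 0.25,
                     background = rep(0.25, 4), name = "motif") {
    sites <- asNamedChar(sites)
    if (length(sites) < 1L) stop("need at least one site")
    if (length(unique(nchar(sites))) != 1L)
        stop("sites must have equal lengths")
    if (any(grepl("[^ACGT]", sites)))
        stop("sites may contain only A,C,G,T")
    counts <- consensusMatrix(DNAStringSet(sites))[DNA_BASES, , drop = FALSE]
    p <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
    newPWM(p, background, pseudocount, name)
}

newPWM <- function(p, background = rep(0.25, 4), pseudocount = 0,
                   name = "motif") {
    p <- as.matrix(p)
    rownames(p) <- DNA_BASES
    new("PWM", probs = p, background = as.numeric(background),
        pseudocount = pseudocount, name = name)
}

#' Per-column information content in bits
#'
#' `IC_j = 2 + sum_b p_bj log2 p_bj` (with `0 log 0 = 0`), the sequence-logo
#' scale for a uniform background: 0 bits for a uniform column, 2 bits for an
#' indicator column.
#'
#' @param pwm a [PWM-class]
#' @return numeric vector of length `width(pwm)`
#' @export
informationContent <- function(pwm) {
    stopifnot(is(pwm, "PWM"))
    p <- probs(pwm)
    2 + colSums(ifelse(p > 0, p * log2(p), 0))
}

#' Discretise a PWM onto an integer score lattice
#'
#' Lattice scores are `round(granularity * ln(p / background))` per base and
#' column; a window's lattice score divided by the granularity approximates
#' its natural-log-odds score with error at most `W / (2 * granularity)`.
#' The default granularity of 1000 bounds the error at W = 15 to 0.0075
#' log-odds units.
#'
#' @param pwm a [PWM-class]; all entries must be positive (apply a
#'   pseudocount when building)
#' @param granularity lattice units per natural-log-odds unit (default 1000)
#' @return a [ScoreScheme-class]
#' @export
scoreScheme <- function(pwm, granularity = 1000) {
    stopifnot(is(pwm, "PWM"))
    p <- probs(pwm)
    if (any(p <= 0))
        stop("PWM has zero entries; rebuild with a positive pseudocount")
    lat <- round(granularity * log(p / background(pwm)))
    new("ScoreScheme", lattice = lat, granularity = granularity,
        minScore = sum(apply(lat, 2, min)),
        maxScore = sum(apply(lat, 2, max)),
        background = background(pwm))
}

#' Exact null distribution of window scores
#'
#' Distribution of the lattice score of a W-mer drawn i.i.d. from the
#' background, computed exactly by column-by-column convolution over the
#' integer lattice (no sampling, no normal approximation).
#'
#' @param scheme a [ScoreScheme-class]
#' @param background length-4 base probabilities; defaults to the
#'   background stored in the scheme
#' @return a [NullScoreDistribution-class]
#' @export
nullDistribution <- function(scheme, background = NULL) {
    stopifnot(is(scheme, "ScoreScheme"))
    bg <- if (is.null(background)) scheme@background else background
    if (length(bg) != 4L || abs(sum(bg) - 1) > 1e-9)
        stop("background must be 4 probabilities summing to 1")
    lat <- scheme@lattice
    lo <- 0; hi <- 0; v <- 1
    for (j in seq_len(ncol(lat))) {
        nlo <- lo + min(lat[, j]); nhi <- hi + max(lat[, j])
        nv <- numeric(nhi - nlo + 1)
        for (b in 1:4) {
            sh <- lat[b, j]
            idx <- (lo + sh - nlo + 1):(hi + sh - nlo + 1)
            nv[idx] <- nv[idx] + v * bg[b]
        }
        lo <- nlo; hi <- nhi; v <- nv
    }
    new("NullScoreDistribution", support = as.numeric(lo:hi), prob = v,
        exceedance = rev(cumsum(rev(v))))
}

#' Score cutoff for a per-window p-value
#'
#' The smallest achievable lattice score whose exceedance probability under
#' the background model is at most `alpha` (unachievable lattice values in
#' the gaps share the exceedance of the next achievable score and are never
#' returned). If no score qualifies (possible for motifs with few
#' informative positions), `maxScore + 1` is returned with a warning: no
#' window can then pass.
#'
#' @param nulldist a [NullScoreDistribution-class]
#' @param alpha per-window, per-strand p-value in (0, 1] (default 1e-4)
#' @return a lattice score
#' @export
cutoffForPvalue <- function(nulldist, alpha = 1e-4) {
    stopifnot(is(nulldist, "NullScoreDistribution"),
              alpha > 0, alpha <= 1)
    ok <- which(nulldist@exceedance <= alpha & nulldist@prob > 0)
    if (length(ok) == 0L) {
        warning("no lattice score reaches exceedance <= ", alpha,
                "; returning maxScore + 1 (no window can pass)")
        return(max(nulldist@support) + 1)
    }
    min(nulldist@support[ok])
}

#' Read and write PWMs as plain text
#'
#' The format is a header line
#' `># <name> width=<W> pseudocount=<p> background=<b1,b2,b3,b4>` followed by
#' four whitespace-delimited probability rows labelled A, C, G, T, written
#' with six decimals. On reading, columns are renormalised to sum exactly to
#' one (the stored precision is 1e-6).
#'
#' @param pwm a [PWM-class]
#' @param path file path
#' @return `writePWM`: the path, invisibly; `readPWM`: a [PWM-class]
#' @export
writePWM <- function(pwm, path) {
    stopifnot(is(pwm, "PWM"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
        "># %s width=%d pseudocount=%g background=%s",
        motifName(pwm), width(pwm), pseudocount(pwm),
        paste(sprintf("%.6f", background(pwm)), collapse = ",")), con)
    p <- probs(pwm)
    for (b in DNA_BASES)
        writeLines(paste(b, paste(sprintf("%.6f", p[b, ]), collapse = " ")),
                   con)
    invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
    if (!file.exists(path)) stop("PWM file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 5L || !startsWith(lines[1], ">#"))
        stop("not a PWM text file (expected '>#' header + 4 rows): ", path)
    hdr <- lines[1]
    name <- sub("^>#\\s+(\\S+).*$", "\\1", hdr)
    pc <- as.numeric(sub(".*pseudocount=([0-9.eE+-]+).*", "\\1", hdr))
    bg <- as.numeric(strsplit(
        sub(".*background=([0-9.,eE+-]+).*", "\\1", hdr), ",")[[1]])
    bg <- bg / sum(bg)
    rows <- lapply(lines[2:5], function(l) strsplit(trimws(l), "\\s+")[[1]])
    lab <- vapply(rows, `[`, character(1), 1)
    if (!identical(lab, DNA_BASES))
        stop("PWM rows must be labelled A, C, G, T in order")
    p <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    p <- sweep(p, 2, colSums(p), "/")
    newPWM(p, bg, pc, name)
}
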