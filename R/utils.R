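# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All generator randomness flows through this.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

# A,C,G,T -> 0..3; N (or anything else) -> 4. Input: character scalar.
seqCodes <- function(s) {
    v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES) - 1L
    v[is.na(v)] <- 4L
    v
}

codesToSeq <- function(codes) {
    paste0(c(DNA_BASES, "N")[codes + 1L], collapse = "")
}

revCompChar <- function(s) {
    as.character(reverseComplement(DNAString(s)))
}

# strict single nucleotide-string check
checkDNAString <- function(s, what = "sequence") {
    if (!is.character(s) || length(s) != 1L || is.na(s))
        stop(what, " must be a single character string")
    if (grepl("[^ACGTNacgtn]", s))
        stop(what, " contains characters outside A,C,G,T,N")
    toupper(s)
}

# normalize inputs that may be a DNAStringSet or a (named) character vector
asNamedChar <- function(x, prefix = "seq") {
    if (is(x, "XStringSet")) x <- as.character(x)
    if (!is.character(x)) stop("sequences must be character or DNAStringSet")
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
        names(x) <- paste0(prefix, seq_along(x))
    toupper(x)
}
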