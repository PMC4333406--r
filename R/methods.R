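#' @describeIn PWM motif width in bp
#' @param x a `PWM` object
#' @export
setMethod("width", "PWM", function(x) ncol(x@probs))

#' @describeIn PWM the 4 x W probability matrix
#' @export
setMethod("probs", "PWM", function(x) x@probs)

#' @describeIn PWM background base probabilities
#' @export
setMethod("background", "PWM", function(x) x@background)

#' @describeIn PWM pseudocount used in construction
#' @export
setMethod("pseudocount", "PWM", function(x) x@pseudocount)

#' @describeIn PWM motif label
#' @export
setMethod("motifName", "PWM", function(x) x@name)

#' Consensus word of a PWM
#'
#' The column-wise most probable base; ties broken alphabetically.
#'
#' @param x a [PWM-class]
#' @return a character scalar of length `width(x)`
#' @export
pwmConsensus <- function(x) {
    stopifnot(is(x, "PWM"))
    paste0(DNA_BASES[apply(probs(x), 2, which.max)], collapse = "")
}

setMethod("show", "PWM", function(object) {
    cat(sprintf("PWM \"%s\": width %d, pseudocount %g\n",
                motifName(object), width(object), pseudocount(object)))
    cat("  consensus:", pwmConsensus(object), "\n")
    cat("  information content:",
        sprintf("%.2f", sum(informationContent(object))), "bits\n")
})

#' @describeIn ScoreScheme exceedance accessor is on NullScoreDistribution;
#'   this displays the lattice summary
#' @param object a `ScoreScheme`
setMethod("show", "ScoreScheme", function(object) {
    cat(sprintf("ScoreScheme: width %d, granularity %g, scores [%d, %d]\n",
                ncol(object@lattice), object@granularity,
                as.integer(object@minScore), as.integer(object@maxScore)))
})

#' @describeIn NullScoreDistribution upper-tail probabilities, named by score
#' @param x a `NullScoreDistribution`
#' @export
setMethod("exceedance", "NullScoreDistribution",
          function(x) setNames(x@exceedance, x@support))

setMethod("show", "NullScoreDistribution", function(object) {
    cat(sprintf(
        "NullScoreDistribution over %d lattice scores in [%d, %d]\n",
        length(object@support), as.integer(min(object@support)),
        as.integer(max(object@support))))
})

#' @describeIn UpstreamRegionSet region sequences (transcription orientation)
#' @export
setMethod("regionSeqs", "UpstreamRegionSet", function(x) x@seqs)

#' @describeIn UpstreamRegionSet per-region metadata
#' @export
setMethod("regionInfo", "UpstreamRegionSet", function(x) x@info)

#' @describeIn UpstreamRegionSet number of regions
#' @param x an `UpstreamRegionSet`
#' @export
setMethod("length", "UpstreamRegionSet", function(x) length(x@seqs))

#' @describeIn UpstreamRegionSet subset by index or gene id
#' @param i index or gene id
#' @param j,drop,... ignored
#' @export
setMethod("[", "UpstreamRegionSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@info$gene_id)
    if (anyNA(i)) stop("unknown gene id")
    new("UpstreamRegionSet", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "UpstreamRegionSet", function(object) {
    cat(sprintf("UpstreamRegionSet with %d regions (lengths %s)\n",
                length(object),
                if (length(object)) paste0(min(object@info$L), "-",
                                           max(object@info$L)) else "-"))
    tr <- table(object@info$truncation)
    if (length(tr))
        cat("  truncation:", paste(names(tr), tr, sep = "=", collapse = ", "),
            "\n")
})

#' @describeIn DiscoveryResult called motif sites
#' @export
setMethod("occurrences", "DiscoveryResult", function(x) x@occurrences)

#' @describeIn DiscoveryResult ranking statistic (converged log-likelihood
#'   ratio)
#' @param x a `DiscoveryResult`
#' @export
setMethod("significance", "DiscoveryResult", function(x) x@significance)

setMethod("show", "DiscoveryResult", function(object) {
    cat(sprintf(
        "DiscoveryResult: consensus %s, llr %.2f, %d site(s), %d EM iteration(s)\n",
        pwmConsensus(object@pwm), object@llr, nrow(object@occurrences),
        length(object@llTrace)))
})

#' @describeIn SyntheticStudy the generated chromosomes
#' @export
setMethod("studyGenome", "SyntheticStudy", function(x) x@genome)

#' @describeIn SyntheticStudy gene annotation as GRanges
#' @export
setMethod("studyGenes", "SyntheticStudy", function(x) x@genes)

#' @describeIn SyntheticStudy planted-module truth table
#' @param x a `SyntheticStudy`
#' @export
setMethod("truthTable", "SyntheticStudy", function(x) x@truth)

setMethod("show", "SyntheticStudy", function(object) {
    cat(sprintf(
        "SyntheticStudy: %d chromosome(s), %d genes, %d planted module(s)\n",
        length(object@genome), length(object@genes), nrow(object@truth)))
})

#' @describeIn ScreenResult deduplicated candidate gene list
#' @param x a `ScreenResult`
#' @export
setMethod("candidateGenes", "ScreenResult", function(x) x@genes)

#' @describeIn ScreenResult table of qualifying element pairs
#' @export
setMethod("candidateTable", "ScreenResult", function(x) x@table)

setMethod("show", "ScreenResult", function(object) {
    cat(sprintf("ScreenResult: %d pair(s) in %d candidate gene(s) [%s mode]\n",
                nrow(object@table), length(object@genes),
                if (isTRUE(object@params$strict)) "strict" else "relaxed"))
})
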