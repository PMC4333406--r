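DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' Column-stochastic base-probability matrix over A,C,G,T with the background
#' model and pseudocount used to build it. Columns are motif positions; the
#' matrix is always stored in the orientation the motif is scanned in.
#'
#' @slot probs 4 x W numeric matrix, rows A,C,G,T; each column sums to 1.
#' @slot background length-4 base probabilities of the null model.
#' @slot pseudocount nonnegative pseudocount added per base when built from
#'   aligned sites.
#' @slot name character label.
#'
#' @aliases PWM-class
#' @seealso [buildPWM()], [scanRegions()], [nullDistribution()]
#' @export
setClass("PWM", representation(
    probs = "matrix",
    background = "numeric",
    pseudocount = "numeric",
    name = "character"
))

setValidity("PWM", function(object) {
    p <- object@probs
    if (!is.numeric(p) || nrow(p) != 4L)
        return("'probs' must be a 4-row numeric matrix")
    if (!identical(rownames(p), DNA_BASES))
        return("rows of 'probs' must be named A,C,G,T")
    if (any(p < 0)) return("probabilities must be nonnegative")
    if (any(abs(colSums(p) - 1) > 1e-9))
        return("every column of 'probs' must sum to 1 (tolerance 1e-9)")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9 || any(object@background <= 0))
        return("'background' must be 4 positive probabilities summing to 1")
    if (object@pseudocount < 0) return("'pseudocount' must be >= 0")
    if (object@pseudocount > 0 && any(p == 0))
        return("all entries must be > 0 when pseudocount > 0")
    TRUE
})

#' Integer score lattice for exact p-value computation
#'
#' Discretisation of a PWM's natural-log-odds scores onto an integer lattice
#' (score = round(granularity * ln(p/background))), so that the null score
#' distribution can be computed exactly by column-wise convolution. The
#' per-window rounding error is bounded by W/(2*granularity) log-odds units.
#'
#' @slot lattice 4 x W matrix of integer-valued scores (stored numeric).
#' @slot granularity lattice units per natural-log-odds unit.
#' @slot minScore,maxScore column-wise minimal/maximal path scores.
#' @slot background the background probabilities the lattice was built with.
#'
#' @aliases ScoreScheme-class
#' @seealso [scoreScheme()], [nullDistribution()]
#' @export
setClass("ScoreScheme", representation(
    lattice = "matrix",
    granularity = "numeric",
    minScore = "numeric",
    maxScore = "numeric",
    background = "numeric"
))

setValidity("ScoreScheme", function(object) {
    if (nrow(object@lattice) != 4L) return("'lattice' must have 4 rows")
    if (any(object@lattice != round(object@lattice)))
        return("'lattice' must be integer-valued")
    if (object@granularity < 1) return("'granularity' must be >= 1")
    if (object@maxScore != sum(apply(object@lattice, 2, max)))
        return("'maxScore' must equal the column-wise maximum path")
    TRUE
})

#' Exact null distribution of window scores
#'
#' Exact distribution of the lattice score of a background-i.i.d. W-mer,
#' from column-by-column convolution. `exceedance[i]` is
#' P(score >= support[i]) under the background model.
#'
#' @slot support ascending integer lattice scores.
#' @slot prob point probabilities on the support.
#' @slot exceedance upper-tail probabilities, nonincreasing in the score.
#'
#' @aliases NullScoreDistribution-class
#' @seealso [nullDistribution()], [cutoffForPvalue()]
#' @export
setClass("NullScoreDistribution", representation(
    support = "numeric",
    prob = "numeric",
    exceedance = "numeric"
))

setValidity("NullScoreDistribution", function(object) {
    if (length(object@support) != length(object@prob) ||
        length(object@prob) != length(object@exceedance))
        return("'support', 'prob' and 'exceedance' must have equal length")
    if (is.unsorted(object@support)) return("'support' must be ascending")
    if (any(diff(object@exceedance) > 1e-12))
        return("'exceedance' must be nonincreasing")
    if (abs(object@exceedance[1] - 1) > 1e-9)
        return("exceedance at the minimum score must be 1")
    if (any(object@exceedance < -1e-12 | object@exceedance > 1 + 1e-9))
        return("exceedance values must lie in [0,1]")
    TRUE
})

#' Upstream intergenic regions in transcription orientation
#'
#' One sequence per gene, written 5'->3' in transcription orientation and
#' ending at the base immediately 5' of the start codon. The last residue has
#' ATG-relative offset -1 and the first has offset -L (the A of ATG is +1;
#' there is no offset 0). Minus-strand genes are reverse-complemented on
#' extraction so all scanning happens in transcription orientation.
#'
#' @slot seqs [Biostrings::DNAStringSet] named by gene id.
#' @slot info [S4Vectors::DataFrame] with one row per region: `gene_id`,
#'   `chrom`, `strand`, `atg_pos` (forward-strand genomic coordinate of the
#'   first base of the start codon in transcription orientation), `gstart`,
#'   `gend` (forward-strand genomic span of the region; `gstart > gend` for an
#'   empty region), `L` (region length) and `truncation` (one of
#'   `"max_len"`, `"neighbor_gene"`, `"chromosome_end"`).
#'
#' @aliases UpstreamRegionSet-class
#' @seealso [extractUpstreamRegions()], [atgOffset()]
#' @export
setClass("UpstreamRegionSet", representation(
    seqs = "DNAStringSet",
    info = "DataFrame"
))

setValidity("UpstreamRegionSet", function(object) {
    need <- c("gene_id", "chrom", "strand", "atg_pos", "gstart", "gend",
              "L", "truncation")
    if (!all(need %in% colnames(object@info)))
        return(paste("info must have columns:", paste(need, collapse = ", ")))
    if (length(object@seqs) != nrow(object@info))
        return("one info row per sequence required")
    if (!all(width(object@seqs) == object@info$L))
        return("sequence widths must match info$L")
    if (!all(object@info$truncation %in%
             c("max_len", "neighbor_gene", "chromosome_end")))
        return("unknown truncation reason")
    TRUE
})

#' Result of EM motif elicitation
#'
#' The fitted motif model from the best EM run over all substring seeds,
#' together with the site assignments and the log-likelihood-ratio ranking
#' statistic. The ranking statistic is the converged log-likelihood ratio of
#' the motif model against the background-only model; it is deliberately
#' named `significance`, not an E-value.
#'
#' @slot pwm the fitted [PWM-class].
#' @slot occurrences data.frame with columns `seq_id`, `start` (1-based
#'   position within the input sequence), `strand`, `word`, `posterior`;
#'   one row per sequence with a called site (all sequences under OOPS).
#' @slot llr converged total log-likelihood ratio versus background.
#' @slot significance ranking statistic (equal to `llr`).
#' @slot llTrace per-iteration penalized log-likelihood (the MAP-EM
#'   objective: llr plus the Dirichlet log-prior contributed by the
#'   pseudocount) of the winning run; nondecreasing by construction of EM.
#' @slot seed the substring seed the winning run started from.
#'
#' @aliases DiscoveryResult-class
#' @seealso [discoverMotif()], [discoverTopMotifs()]
#' @export
setClass("DiscoveryResult", representation(
    pwm = "PWM",
    occurrences = "data.frame",
    llr = "numeric",
    significance = "numeric",
    llTrace = "numeric",
    seed = "character"
))

#' Ground-truthed synthetic study
#'
#' A generated genome with gene annotation and a truth table of planted
#' HZA+GATA modules, used to benchmark the whole pipeline without external
#' downloads. Re-extracting the coordinates in `truth` from `genome`
#' reproduces the planted words exactly.
#'
#' @slot genome [Biostrings::DNAStringSet] chromosomes.
#' @slot genes [GenomicRanges::GRanges] gene spans with metadata columns
#'   `gene_id` and `atg_pos`.
#' @slot truth data.frame of planted modules (gene, element offsets, strands,
#'   words, gap, atg distance).
#' @slot orthologs [Biostrings::DNAStringSet] mutated copies of the planted
#'   genes' upstream regions (may be empty).
#' @slot config list of generator parameters, including the seed.
#'
#' @aliases SyntheticStudy-class
#' @seealso [syntheticStudy()], [writeStudy()]
#' @export
setClass("SyntheticStudy", representation(
    genome = "DNAStringSet",
    genes = "GRanges",
    truth = "data.frame",
    orthologs = "DNAStringSet",
    config = "list"
))

#' Result of the genome-wide HZA+GATA screen
#'
#' @slot table data.frame of qualifying element pairs (one row per pair; a
#'   gene may contribute several rows).
#' @slot genes deduplicated, sorted candidate gene ids.
#' @slot params list of screen parameters used.
#'
#' @aliases ScreenResult-class
#' @seealso [screenGenome()]
#' @export
setClass("ScreenResult", representation(
    table = "data.frame",
    genes = "character",
    params = "list"
))
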