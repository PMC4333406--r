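# Orchestration: discover -> build -> scan -> pair -> filter -> report, as a
# single reproducible run with a serialized manifest.

inputError <- function(...) {
    stop(structure(class = c("hzascreen_input_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

pipelineDefaults <- function() {
    list(genome = NULL, gff = NULL, promoters = NULL,
         hza_pwm = NULL, gata_pwm = NULL, crm = NULL,
         crm_frame = "genomic", out = NULL, seed = 1L,
         motif_width = 15L, discovery_mode = "zoops",
         discovery_both_strands = TRUE, site_prior = 0.9,
         max_len = 20000L, alpha_hza = 1e-4, alpha_gata = 1e-3,
         max_gap = 20L, atg_max = 1500L, strict = FALSE,
         background = "uniform", granularity = 1000L,
         pseudocount = 0.25)
}

#' Run the full screening pipeline
#'
#' Reads the genome and annotation, obtains the two weight matrices (from
#' files, or by discovering the HZA motif in a supplied promoter FASTA; the
#' fallback [gataMatrix()] is used with a message when no GATA matrix is
#' given), runs [screenGenome()] and writes a fixed output layout:
#' `candidates.tsv`, `hits_hza.bed`, `hits_gata.bed`, `pairs.bed`,
#' `pwm_hza.txt`, `pwm_gata.txt`, `logo_hza.tsv` (information content in
#' bits per column), `manifest.yaml` and `run.log`. A run relaunched from
#' its own manifest reproduces the outputs byte-identically.
#'
#' @param config a named list of parameters (see `pipelineDefaults` in the
#'   package source for the full set and defaults), or the path to a
#'   `manifest.yaml` from a previous run; at minimum `genome`, `gff`, `out`,
#'   and either (`hza_pwm` and `gata_pwm`) or `promoters`
#' @return the [ScreenResult-class], invisibly; outputs are written to
#'   `config$out`
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) inputError("config must be a list or a yaml path")
    cfg <- modifyList(pipelineDefaults(),
                      config[!vapply(config, is.null, logical(1))])
    for (f in c("genome", "gff", "out"))
        if (is.null(cfg[[f]])) inputError("config field '", f, "' is required")
    if (is.null(cfg$hza_pwm) && is.null(cfg$promoters))
        inputError("supply either 'hza_pwm' or 'promoters' for discovery")
    for (f in c("genome", "gff", "promoters", "hza_pwm", "gata_pwm", "crm"))
        if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
            inputError("input file not found (", f, "): ", cfg[[f]])

    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(cfg$out, "run.log")
    logLines <- c(sprintf("hzascreen %s",
                          as.character(utils::packageVersion("hzascreen"))),
                  sprintf("R %s", R.version.string))
    note <- function(...) logLines <<- c(logLines, sprintf(...))

    genome <- readGenome(cfg$genome)
    genes <- readGeneAnnotation(cfg$gff)
    note("genome: %s (%d sequence(s), md5 %s)", cfg$genome, length(genome),
         unname(tools::md5sum(cfg$genome)))
    note("annotation: %s (%d gene(s), md5 %s)", cfg$gff, length(genes),
         unname(tools::md5sum(cfg$gff)))

    withSeed(cfg$seed, {
        if (!is.null(cfg$hza_pwm)) {
            hzaPwm <- readPWM(cfg$hza_pwm)
            note("HZA matrix read from %s", cfg$hza_pwm)
        } else {
            prom <- readGenome(cfg$promoters)
            disc <- discoverMotif(prom, width = cfg$motif_width,
                                  mode = cfg$discovery_mode,
                                  bothStrands = cfg$discovery_both_strands,
                                  sitePrior = cfg$site_prior,
                                  pseudocount = cfg$pseudocount)
            hzaPwm <- disc@pwm
            note("HZA matrix discovered from %s (consensus %s, llr %.2f)",
                 cfg$promoters, pwmConsensus(hzaPwm), disc@llr)
            write.table(occurrences(disc),
                        file.path(cfg$out, "discovery_occurrences.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        if (!is.null(cfg$gata_pwm)) {
            gataPwm <- readPWM(cfg$gata_pwm)
            note("GATA matrix read from %s", cfg$gata_pwm)
        } else {
            gataPwm <- gataMatrix()
            message("no GATA matrix supplied; using the non-canonical ",
                    "fallback (TGATAA core, uniform flanks)")
            note("GATA matrix: built-in non-canonical fallback")
        }
        crm <- NULL
        if (!is.null(cfg$crm)) {
            crm <- if (cfg$crm_frame == "genomic")
                rtracklayer::import(cfg$crm, format = "bed")
            else read.table(cfg$crm, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
        }
        res <- screenGenome(genome, genes, hzaPwm, gataPwm,
                            maxLen = cfg$max_len, alphaHza = cfg$alpha_hza,
                            alphaGata = cfg$alpha_gata, maxGap = cfg$max_gap,
                            atgMax = cfg$atg_max, crm = crm,
                            crmFrame = cfg$crm_frame, strict = cfg$strict,
                            backgroundModel = cfg$background,
                            granularity = cfg$granularity)
        note("screen: %d pair(s) in %d candidate gene(s)",
             nrow(candidateTable(res)), length(candidateGenes(res)))

        regions <- extractUpstreamRegions(genes, genome, maxLen = cfg$max_len)
        hzaHits <- scanRegions(regions, hzaPwm, alpha = cfg$alpha_hza,
                               granularity = cfg$granularity)
        gataHits <- scanRegions(regions, gataPwm, alpha = cfg$alpha_gata,
                                granularity = cfg$granularity)
        writeOutputs(res, regions, hzaHits, gataHits, hzaPwm, gataPwm, cfg)
        writeLines(logLines, logFile)
        invisible(res)
    })
}

writeOutputs <- function(res, regions, hzaHits, gataHits, hzaPwm, gataPwm,
                         cfg) {
    out <- cfg$out
    tab <- candidateTable(res)
    write.table(tab, file.path(out, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeHitsBED(hzaHits, file.path(out, "hits_hza.bed"), regions)
    writeHitsBED(gataHits, file.path(out, "hits_gata.bed"), regions)
    writeModuleBED(tab, regions, file.path(out, "pairs.bed"))
    writePWM(hzaPwm, file.path(out, "pwm_hza.txt"))
    writePWM(gataPwm, file.path(out, "pwm_gata.txt"))
    ic <- data.frame(position = seq_len(width(hzaPwm)),
                     bits = informationContent(hzaPwm))
    write.table(ic, file.path(out, "logo_hza.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- cfg[order(names(cfg))]
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    invisible(out)
}

# module spans (both windows) in genomic coordinates, BED6
writeModuleBED <- function(pairs, regions, path) {
    if (nrow(pairs) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    info <- as.data.frame(regionInfo(regions))
    k <- match(pairs$gene_id, info$gene_id)
    L <- info$L[k]
    i1 <- pairs$module_start + L + 1L
    i2 <- pairs$module_end + L + 1L
    plus <- info$strand[k] == "+"
    gs <- ifelse(plus, info$gstart[k] + i1 - 1L, info$gend[k] - i2 + 1L)
    ge <- ifelse(plus, info$gstart[k] + i2 - 1L, info$gend[k] - i1 + 1L)
    bed <- data.frame(chrom = info$chrom[k], start = gs - 1L, end = ge,
                      name = sprintf("%s:%d/%s", pairs$gene_id,
                                     pairs$gap, pairs$orientation),
                      score = 0, strand = ifelse(plus, "+", "-"))
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
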