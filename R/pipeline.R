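#' Run the haploblock pipeline from a configuration
#'
#' Single entry point executing the pipeline stages in order from a YAML
#' configuration (or an equivalent named list): obtain alignments (read
#' from file or simulate), call haploblocks, optionally associate features
#' with blocks, and write summaries. Outputs are deterministic for a
#' given configuration and seed; every TSV/BED carries a header comment
#' with the package version and a digest of the resolved parameters, and
#' a copy of the resolved configuration plus a machine-readable JSON run
#' summary are written next to the outputs.
#'
#' Configuration fields: \code{out_dir} (required); \code{seed} (default
#' 1); \code{reference}, \code{query} (labels); \code{chrom_lengths}
#' (path to a two-column TSV, or an inline named list, required);
#' \code{alignments} with either \code{path} + \code{dialect} or
#' \code{simulate} (arguments for \code{\link{simConfig}}, with tracts as
#' a list of \code{[chrom, start, end, identity]} entries);
#' \code{haploblocks} (any of bin_size, min_aln_len, identity_cutoff,
#' merge_mode, median_rounding, min_bins, cutoff_strict); optional
#' \code{features} (BED path) to associate with the called blocks.
#'
#' @param config path to a YAML file, or a named list.
#' @return Invisibly, a list with the \linkS4class{HaploblockSet}, the
#'   association table (or NULL) and the paths of all files written.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a file path or a list")
    need <- function(field) {
        if (is.null(config[[field]]))
            stop("config field missing: ", field)
        config[[field]]
    }
    out_dir <- need("out_dir")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

    cl_field <- need("chrom_lengths")
    chrom_lengths <- if (is.character(cl_field) && length(cl_field) == 1L) {
        if (!file.exists(cl_field))
            stop("config field chrom_lengths: file not found: ", cl_field)
        readChromLengths(cl_field)
    } else unlist(cl_field)
    if (is.null(names(chrom_lengths)))
        stop("config field chrom_lengths: needs named lengths")

    alncfg <- need("alignments")
    aln <- if (!is.null(alncfg$path)) {
        if (!file.exists(alncfg$path))
            stop("config field alignments.path: file not found: ",
                 alncfg$path)
        readAlignments(alncfg$path,
                       if (is.null(alncfg$dialect)) "showcoords_tab"
                       else alncfg$dialect)
    } else if (!is.null(alncfg$simulate)) {
        s <- alncfg$simulate
        tracts <- do.call(rbind, lapply(s$tracts, function(t)
            data.frame(chrom = t[[1]], start = as.numeric(t[[2]]),
                       end = as.numeric(t[[3]]),
                       target_identity = as.numeric(t[[4]]))))
        sc <- simConfig(chromLengths = chrom_lengths, tracts = tracts,
                        noiseSd = if (is.null(s$noise_sd)) 0.1
                                  else s$noise_sd,
                        seed = seed)
        simulateAlignments(sc)$alignments
    } else stop("config field alignments: needs 'path' or 'simulate'")

    hb <- config$haploblocks
    getp <- function(nm, default) if (is.null(hb[[nm]])) default else hb[[nm]]
    params <- HaploblockParams(
        binSize = getp("bin_size", 5e6),
        minAlnLen = getp("min_aln_len", 20000),
        identityCutoff = getp("identity_cutoff", 95),
        mergeMode = getp("merge_mode", "identical_median"),
        medianRounding = getp("median_rounding", 2),
        minBins = getp("min_bins", 1),
        cutoffStrict = getp("cutoff_strict", TRUE))

    set <- callHaploblocks(aln, params, chrom_lengths,
                           referenceGenome = if (is.null(config$reference))
                               "reference" else config$reference,
                           queryGenome = if (is.null(config$query)) "query"
                               else config$query)

    resolved <- list(out_dir = out_dir, seed = seed,
                     reference = referenceGenome(set),
                     query = queryGenome(set),
                     chrom_lengths = as.list(chrom_lengths),
                     haploblocks = list(
                         bin_size = params@binSize,
                         min_aln_len = params@minAlnLen,
                         identity_cutoff = params@identityCutoff,
                         merge_mode = params@mergeMode,
                         median_rounding = params@medianRounding,
                         min_bins = params@minBins,
                         cutoff_strict = params@cutoffStrict))
    # the digest covers the scientific parameters, not the output location
    digest <- fnv1a(paste(deparse(resolved[setdiff(names(resolved),
                                                   "out_dir")]),
                          collapse = ""))
    version <- as.character(utils::packageVersion("haploblocks"))
    stamp <- sprintf("# haploblocks %s params=%s", version, digest)

    paths <- list(
        blocks_bed = file.path(out_dir, "haploblocks.bed"),
        blocks_tsv = file.path(out_dir, "haploblocks.tsv"),
        summary_tsv = file.path(out_dir, "summary.tsv"),
        config_yaml = file.path(out_dir, "resolved_config.yaml"),
        run_json = file.path(out_dir, "run_summary.json"))
    writeBed(set, paths$blocks_bed)
    writeHaploblockTsv(set, paths$blocks_tsv, header = stamp)
    s <- blockSummary(set)
    sum_lines <- c(stamp, "metric\tvalue",
                   paste("n_blocks", s$count, sep = "\t"),
                   paste("mean_length_bp",
                         ifelse(is.na(s$meanLength), "NA",
                                format(s$meanLength, scientific = FALSE)),
                         sep = "\t"),
                   paste("coverage_pct",
                         format(genomeCoverage(set), scientific = FALSE),
                         sep = "\t"))
    writeLines(sum_lines, paths$summary_tsv)

    assoc <- NULL
    if (!is.null(config$features)) {
        if (!file.exists(config$features))
            stop("config field features: file not found: ", config$features)
        feats <- readBed(config$features)
        assoc <- associateIntervals(set, feats)
        paths$association_tsv <- file.path(out_dir, "association.tsv")
        con <- file(paths$association_tsv, "w")
        writeLines(stamp, con)
        utils::write.table(assoc, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }

    yaml::write_yaml(resolved, paths$config_yaml)
    jsonlite::write_json(
        list(version = version, params_digest = digest,
             n_alignments = length(aln), n_blocks = s$count,
             coverage_pct = genomeCoverage(set),
             finished = format(Sys.time(), tz = "UTC")),
        paths$run_json, auto_unbox = TRUE, digits = NA)
    invisible(list(haploblocks = set, association = assoc, paths = paths))
}
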