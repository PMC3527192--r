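# Configuration handling, end-to-end orchestration and report writing.

config_fields <- c("adapter", "minLen", "maxLen", "phredFloor",
                   "minOverlap", "maxLoci", "seedLength", "windowMargin",
                   "refoldMargin", "minCopies", "minConsistency",
                   "duplexMaxMismatch", "maxBulge", "overhangRange",
                   "homologyMaxMM", "homologyMaxShift",
                   "targetReportCutoff", "validationCutoff", "alpha",
                   "enrichmentMode", "engine", "seed")

#' Construct a pipeline configuration
#'
#' All defaults reproduce the published protocol parameters; see
#' [PipelineConfig-class].
#'
#' @param adapter,minLen,maxLen,phredFloor,minOverlap,maxLoci,seedLength
#'   Pre-processing and mapping parameters.
#' @param windowMargin,refoldMargin,minCopies,minConsistency Hairpin
#'   discovery parameters.
#' @param duplexMaxMismatch,maxBulge,overhangRange Plant duplex criteria.
#' @param homologyMaxMM,homologyMaxShift Homology tolerances.
#' @param targetReportCutoff,validationCutoff Target penalty cutoffs.
#' @param alpha,enrichmentMode Enrichment test parameters.
#' @param engine Folding engine name.
#' @param seed Integer seed.
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                           minLen = 18L, maxLen = 26L, phredFloor = 20L,
                           minOverlap = 6L, maxLoci = 10L,
                           seedLength = 16L, windowMargin = 500L,
                           refoldMargin = 15L, minCopies = 25L,
                           minConsistency = 0.75, duplexMaxMismatch = 4L,
                           maxBulge = 2L, overhangRange = c(1L, 3L),
                           homologyMaxMM = 2L, homologyMaxShift = 2L,
                           targetReportCutoff = 7, validationCutoff = 4,
                           alpha = 0.001,
                           enrichmentMode = "one_vs_rest",
                           engine = "baseline", seed = 1L) {
    new("PipelineConfig", adapter = adapter,
        minLen = as.integer(minLen), maxLen = as.integer(maxLen),
        phredFloor = as.integer(phredFloor),
        minOverlap = as.integer(minOverlap),
        maxLoci = as.integer(maxLoci),
        seedLength = as.integer(seedLength),
        windowMargin = as.integer(windowMargin),
        refoldMargin = as.integer(refoldMargin),
        minCopies = as.integer(minCopies),
        minConsistency = minConsistency,
        duplexMaxMismatch = as.integer(duplexMaxMismatch),
        maxBulge = as.integer(maxBulge),
        overhangRange = as.integer(overhangRange),
        homologyMaxMM = as.integer(homologyMaxMM),
        homologyMaxShift = as.integer(homologyMaxShift),
        targetReportCutoff = targetReportCutoff,
        validationCutoff = validationCutoff,
        alpha = alpha, enrichmentMode = enrichmentMode,
        engine = engine, seed = as.integer(seed))
}

#' Read a pipeline configuration from a key-value file
#'
#' Plain-text `key = value` lines ("#" comments allowed); unknown keys are
#' an error, missing keys take their defaults, out-of-range values raise a
#' configuration error naming the key.
#'
#' @param path Configuration file; `NULL` returns the defaults.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path = NULL) {
    if (is.null(path)) return(pipelineConfig())
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    args <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "\\s*=\\s*")[[1]]
        if (length(kv) != 2L) stop("malformed configuration line: ", ln)
        key <- kv[1L]
        if (!key %in% config_fields)
            stop("unknown configuration key: ", key)
        val <- kv[2L]
        args[[key]] <- switch(key,
            adapter = , enrichmentMode = , engine = val,
            overhangRange = as.integer(strsplit(val, ",")[[1]]),
            minConsistency = , targetReportCutoff = ,
            validationCutoff = , alpha = as.numeric(val),
            as.integer(val))
    }
    tryCatch(do.call(pipelineConfig, args), error = function(e)
        stop("configuration error: ", conditionMessage(e), call. = FALSE))
}

#' Write a pipeline configuration as a key-value file
#'
#' @param config A [PipelineConfig-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePipelineConfig <- function(config, path) {
    lines <- vapply(config_fields, function(f)
        sprintf("%s = %s", f,
                paste(format(slot(config, f), scientific = FALSE),
                      collapse = ",")),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Export accepted precursors as GFF3
#'
#' One `pre_miRNA` feature per candidate with `miRNA` and `miRNA_star`
#' children, 1-based inclusive coordinates.
#'
#' @param candidates List of accepted [HairpinCandidate-class] objects.
#' @param path Output GFF3 path.
#' @return Invisibly, `path`.
#' @export
exportPrecursorsGFF3 <- function(candidates, path) {
    grs <- lapply(candidates, function(cd) {
        plen <- nchar(cd@precursor)
        offs <- function(off, len) {
            # precursor offset -> genomic interval, honouring strand
            if (cd@strand == "+")
                c(cd@start + off + 1L, cd@start + off + len)
            else
                c(cd@end - off - len + 1L, cd@end - off)
        }
        m <- offs(cd@matureOffset, cd@matureLength)
        s <- if (!is.na(cd@starOffset))
            offs(cd@starOffset, cd@starLength) else NULL
        df <- data.frame(
            seqnames = cd@seqId,
            start = c(cd@start + 1L, m[1], if (!is.null(s)) s[1]),
            end = c(cd@end, m[2], if (!is.null(s)) s[2]),
            strand = cd@strand,
            type = c("pre_miRNA", "miRNA",
                     if (!is.null(s)) "miRNA_star"),
            ID = c(cd@id, paste0(cd@id, ".mature"),
                   if (!is.null(s)) paste0(cd@id, ".star")),
            Parent = c(NA, cd@id, if (!is.null(s)) cd@id),
            stringsAsFactors = FALSE)
        df
    })
    df <- do.call(rbind, grs)
    if (is.null(df)) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    gr <- GenomicRanges::GRanges(df$seqnames,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$ID <- df$ID
    S4Vectors::mcols(gr)$Parent <- df$Parent
    rtracklayer::export(gr, path, format = "GFF3")
    invisible(path)
}

write_tsv <- function(df, path) {
    # fixed column orders, p-values already formatted by the caller
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

fmt_p <- function(p) formatC(p, format = "e", digits = 5)

#' Run the full discovery workflow
#'
#' Pre-processing, mapping, hairpin discovery, homology annotation and
#' rescue, optional target prediction, and comparative profiles, writing
#' all reports into `outDir`.
#'
#' @param reads Named list of read data.frames (one per sample, as from
#'   [readSmallRNA()] or [simulateSample()]`$reads`) or of FASTQ/FASTA
#'   paths.
#' @param genome Genome FASTA path or [Biostrings::DNAStringSet].
#' @param ncrna ncRNA reference data.frame (or FASTA path), or `NULL`.
#' @param catalogue Known-miRNA catalogue data.frame (or FASTA path).
#' @param transcripts Optional named character vector of transcript
#'   sequences (or FASTA path); when `NULL` the target stage is skipped.
#' @param config A [pipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
runPipeline <- function(reads, genome, ncrna, catalogue,
                        transcripts = NULL, config = pipelineConfig(),
                        outDir) {
    if (missing(reads) || missing(genome) || missing(catalogue))
        stop("reads, genome and catalogue inputs are required")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    message("[crossmiR] run started")
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    if (is.character(ncrna)) ncrna <- readNcRNAReference(ncrna)
    if (is.character(catalogue)) catalogue <- readCatalogue(catalogue)
    if (is.character(transcripts) && length(transcripts) == 1L &&
        file.exists(transcripts)) {
        tx <- Biostrings::readDNAStringSet(transcripts)
        transcripts <- stats::setNames(as.character(tx), names(tx))
    }
    samples <- names(reads)
    if (is.null(samples)) stop("reads must be a named list of samples")
    engine <- foldingEngine(config@engine)
    index <- buildGenomeIndex(genome, config@seedLength)

    stage_report <- list()
    annotations <- list()
    tag_sets <- list()
    all_tags <- list()
    precursors <- list()
    for (s in samples) {
        message("[crossmiR] sample ", s)
        rd <- reads[[s]]
        if (is.character(rd)) rd <- readSmallRNA(rd)
        pp <- preprocessSample(rd, s, ncrna, config)
        rep_s <- pp$report
        rep_s$sample <- s
        tags <- pp$tags
        all_tags[[s]] <- tags
        mt <- mapTags(tags, index, config@maxLoci)
        rep_s <- rbind(rep_s, data.frame(
            stage = c("mapped", "multi_locus_discarded", "unmapped"),
            reads_in = sum(tags$count),
            reads_out = c(sum(mt$kept$count), sum(mt$discarded$count),
                          sum(mt$unmapped$count)),
            sample = s, stringsAsFactors = FALSE))
        cands <- callMirnas(tags, index, config, engine, mapping = mt)
        cands <- lapply(cands, function(cd) {
            cd@id <- paste0(s, ":", cd@id); cd
        })
        precursors[[s]] <- cands
        mat <- vapply(cands, matureSequence, character(1))
        cls <- classifyCandidates(toDNA(mat), catalogue,
                                  config@homologyMaxMM,
                                  config@homologyMaxShift)
        if (nrow(cls)) {
            cls$count <- vapply(cands, function(x) x@matureCount,
                                numeric(1))
        } else cls$count <- numeric(0)
        res <- rescueUnmapped(mt$unmapped, catalogue,
                              config@homologyMaxMM, config@homologyMaxShift)
        ann <- rbind(cls[, c("sequence", "status", "family", "hit_name",
                             "mismatches", "count")],
                     res[, c("sequence", "status", "family", "hit_name",
                             "mismatches", "count")])
        ann$sample <- s
        annotations[[s]] <- ann
        tag_sets[[s]] <- unique(toRNA(ann$sequence))
        rep_s <- rbind(rep_s, data.frame(
            stage = c("predicted_mirnas", "rescued_mirnas"),
            reads_in = sum(tags$count),
            reads_out = c(length(cands), nrow(res)),
            sample = s, stringsAsFactors = FALSE))
        stage_report[[s]] <- rep_s
    }
    annotation <- do.call(rbind, annotations)
    rownames(annotation) <- NULL
    fam <- groupFamilies(annotation, maxMM = config@homologyMaxMM)
    annotation <- fam$annotation

    # count matrix: annotated miRNA tags x samples
    tags_u <- sort(unique(annotation$sequence))
    counts <- matrix(0L, nrow = length(tags_u), ncol = length(samples),
                     dimnames = list(tags_u, samples))
    for (i in seq_len(nrow(annotation)))
        counts[annotation$sequence[i], annotation$sample[i]] <-
            counts[annotation$sequence[i], annotation$sample[i]] +
            as.integer(annotation$count[i])
    totals <- vapply(samples, function(s) sum(all_tags[[s]]$count),
                     numeric(1))
    profile <- countProfile(counts, totals = pmax(totals, colSums(counts)))
    enrichment <- if (length(samples) >= 2L)
        callEnrichment(profile, config@alpha, config@enrichmentMode)
    else NULL
    venn <- conservationPartition(tag_sets)
    composition <- if (nrow(annotation))
        compositionProfile(data.frame(sequence = annotation$sequence,
                                      count = annotation$count))
    else NULL

    targets <- NULL
    if (!is.null(transcripts)) {
        message("[crossmiR] target scan")
        scheme <- scoringScheme(reportCutoff = config@targetReportCutoff,
                                validationCutoff = config@validationCutoff)
        majors <- fam$families$major
        rows <- list()
        for (mj in majors) for (txn in names(transcripts)) {
            hits <- scanTranscript(mj, transcripts[[txn]], scheme,
                                   transcriptId = txn)
            if (nrow(hits)) {
                hits$mirna <- toRNA(mj)
                rows[[length(rows) + 1L]] <- hits
            }
        }
        targets <- do.call(rbind, rows)
        if (!is.null(targets)) {
            targets <- targets[order(targets$penalty, targets$transcript,
                                     targets$start), , drop = FALSE]
            rownames(targets) <- NULL
        }
    }

    results <- list(stage_report = do.call(rbind, stage_report),
                    annotation = annotation, families = fam$families,
                    profile = profile, enrichment = enrichment,
                    venn = venn, composition = composition,
                    targets = targets,
                    precursors = unlist(precursors, recursive = FALSE),
                    target_stage = if (is.null(transcripts)) "skipped"
                                   else "run")
    paths <- writeReports(results, outDir)

    manifest <- list(
        tool = "crossmiR",
        version = as.character(utils::packageVersion("crossmiR")),
        config = stats::setNames(lapply(config_fields, function(f)
            slot(config, f)), config_fields),
        samples = as.list(stats::setNames(
            vapply(samples, function(s) sum(all_tags[[s]]$count),
                   numeric(1)), samples)),
        stage_counts = lapply(stage_report, function(r)
            stats::setNames(as.list(r$reads_out), r$stage)),
        n_predicted = vapply(precursors, length, integer(1)),
        target_stage = results$target_stage,
        outputs = stats::setNames(as.list(basename(paths)), names(paths)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message("[crossmiR] run finished")
    invisible(manifest)
}

#' Write all pipeline reports
#'
#' Fixed column orders; p-values in scientific notation with 6 significant
#' digits.  Empty result sets yield headers-only files.
#'
#' @param results Result list as assembled by [runPipeline()].
#' @param outDir Output directory.
#' @return Named character vector of the written paths.
#' @export
writeReports <- function(results, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    p <- function(name) file.path(outDir, name)

    write_tsv(results$stage_report, p("stage_report.tsv"))
    paths["stage_report"] <- p("stage_report.tsv")

    ann <- results$annotation
    ann_out <- data.frame(tag = toRNA(ann$sequence), status = ann$status,
                          family = ann$family, sample = ann$sample,
                          count = ann$count, stringsAsFactors = FALSE)
    write_tsv(ann_out, p("annotation.tsv"))
    paths["annotation"] <- p("annotation.tsv")

    write_tsv(results$families, p("families.tsv"))
    paths["families"] <- p("families.tsv")

    counts <- profileCounts(results$profile)
    cdf <- data.frame(tag = rownames(counts), counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    tot <- data.frame(tag = "library_total",
                      t(libraryTotals(results$profile)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(rbind(cdf, tot), p("counts.tsv"))
    paths["counts"] <- p("counts.tsv")

    if (!is.null(results$enrichment)) {
        enr <- results$enrichment
        enr$p <- fmt_p(enr$p)
        enr$p_adjust <- fmt_p(enr$p_adjust)
        write_tsv(enr, p("enrichment.tsv"))
        paths["enrichment"] <- p("enrichment.tsv")
    }

    write_tsv(results$venn, p("venn.tsv"))
    paths["venn"] <- p("venn.tsv")

    if (!is.null(results$composition)) {
        comp <- as.data.frame(results$composition)
        comp <- cbind(length = rownames(comp), comp)
        write_tsv(comp, p("composition.tsv"))
        paths["composition"] <- p("composition.tsv")
    }

    if (!is.null(results$targets)) {
        tg <- results$targets
        tg_out <- data.frame(mirna = tg$mirna, transcript = tg$transcript,
                             start = tg$start + 1L, end = tg$end,
                             penalty = tg$penalty,
                             cleavage = tg$cleavage + 1L,
                             gap_type = tg$gap_type,
                             stringsAsFactors = FALSE)
        write_tsv(tg_out, p("targets.tsv"))
        paths["targets"] <- p("targets.tsv")
    }

    acc <- Filter(isAccepted, results$precursors)
    exportPrecursorsGFF3(acc, p("precursors.gff3"))
    paths["precursors_gff3"] <- p("precursors.gff3")
    if (length(acc)) {
        fa <- vapply(acc, function(cd)
            c(paste0(">", cd@id), cd@precursor), character(2))
        writeLines(as.vector(fa), p("precursors.fa"))
        db <- vapply(acc, function(cd)
            c(paste0(">", cd@id), cd@precursor, cd@structure), character(3))
        writeLines(as.vector(db), p("structures.txt"))
    } else {
        writeLines(character(0), p("precursors.fa"))
        writeLines(character(0), p("structures.txt"))
    }
    paths["precursors_fa"] <- p("precursors.fa")
    paths["structures"] <- p("structures.txt")
    paths
}
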