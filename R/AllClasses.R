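#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame
NULL

#' GenomeIndex: exact-match k-mer index over a surrogate reference genome
#'
#' Holds the genome sequences together with a hash table from fixed-length
#' seed k-mers to genomic positions on the forward strand.  Lookups are
#' guaranteed to reproduce a naive full scan exactly because every seed hit
#' is verified over the full tag length (see [mapExact()]).
#'
#' @slot genome A [Biostrings::DNAStringSet] of reference sequences with
#'   unique names.
#' @slot seedLength Integer scalar, length of the indexed seed (<= 18, so
#'   that every 18-26 nt tag contains at least one full seed).
#' @slot kmers Environment mapping seed strings to a two-column integer
#'   matrix (sequence index, 0-based offset).
#'
#' @seealso [buildGenomeIndex()], [mapExact()]
#' @export
setClass("GenomeIndex",
    representation(genome = "DNAStringSet",
                   seedLength = "integer",
                   kmers = "environment"),
    validity = function(object) {
        msg <- character()
        if (length(object@genome) == 0L)
            msg <- c(msg, "genome must contain at least one sequence")
        nm <- names(object@genome)
        if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
            msg <- c(msg, "genome sequences must carry unique non-empty names")
        if (length(object@seedLength) != 1L || is.na(object@seedLength) ||
            object@seedLength < 1L || object@seedLength > 18L)
            msg <- c(msg, "seedLength must be a single integer in 1..18")
        if (length(msg)) msg else TRUE
    })

#' HairpinCandidate: a folded precursor window with its miRNA/miRNA* duplex
#'
#' The result of folding a genomic window around a mapped tag, locating the
#' star partner, trimming to the mature..star span plus a refold margin and
#' refolding.  Carries the duplex statistics used by the plant miRNA
#' annotation criteria and the read-signature score.
#'
#' @slot id Candidate identifier (locus-derived).
#' @slot seqId,start,end,strand Genomic interval of the trimmed precursor
#'   (0-based half-open, strand of transcription).
#' @slot precursor Precursor sequence (DNA alphabet, sense orientation).
#' @slot structure Dot-bracket structure of the precursor.
#' @slot energy Folding score of the engine (arbitrary units, lower is more
#'   stable for the baseline engine).
#' @slot matureOffset,matureLength,starOffset,starLength 0-based offsets and
#'   lengths of the mature and star intervals in precursor coordinates.
#' @slot duplex Named list: `mismatches`, `largest_asymmetric_bulge`,
#'   `overhang_3p_mature`, `overhang_3p_star`, `paired_fraction_mature`.
#' @slot matureCount Read count of the mature tag in the library.
#' @slot signatureConsistency Fraction of window reads whose 5' ends stack
#'   within +/-2 nt of the mature or star 5' end.
#' @slot accepted Logical; TRUE only when `rejectionReasons` is empty.
#' @slot rejectionReasons Character vector of failed criteria.
#'
#' @export
setClass("HairpinCandidate",
    representation(id = "character",
                   seqId = "character", start = "integer", end = "integer",
                   strand = "character",
                   precursor = "character", structure = "character",
                   energy = "numeric",
                   matureOffset = "integer", matureLength = "integer",
                   starOffset = "integer", starLength = "integer",
                   duplex = "list",
                   matureCount = "numeric",
                   signatureConsistency = "numeric",
                   accepted = "logical",
                   rejectionReasons = "character"),
    validity = function(object) {
        msg <- character()
        n <- nchar(object@precursor)
        if (nchar(object@structure) != n)
            msg <- c(msg, "structure length must equal precursor length")
        if (object@matureOffset < 0L ||
            object@matureOffset + object@matureLength > n)
            msg <- c(msg, "mature interval must lie within the precursor")
        if (!is.na(object@starOffset)) {
            if (object@starOffset < 0L ||
                object@starOffset + object@starLength > n)
                msg <- c(msg, "star interval must lie within the precursor")
            m1 <- object@matureOffset; m2 <- m1 + object@matureLength
            s1 <- object@starOffset;  s2 <- s1 + object@starLength
            if (max(m1, s1) < min(m2, s2))
                msg <- c(msg, "mature and star intervals must be disjoint")
        }
        if (isTRUE(object@accepted) && length(object@rejectionReasons) > 0L)
            msg <- c(msg, "accepted candidates cannot carry rejection reasons")
        if (length(msg)) msg else TRUE
    })

#' CountProfile: tag-by-sample count matrix with library totals
#'
#' Rows are miRNA tags (or families), columns are samples.  `totals` are
#' the per-sample library sizes used as the normalisation denominators of
#' the Audic-Claverie test; they may exceed the column sums because a
#' library contains reads that were never assigned to a miRNA.
#'
#' @slot counts Non-negative integer matrix, tags x samples.
#' @slot totals Named numeric vector of per-sample library totals.
#'
#' @seealso [countProfile()], [callEnrichment()]
#' @export
setClass("CountProfile",
    representation(counts = "matrix", totals = "numeric"),
    validity = function(object) {
        msg <- character()
        if (any(object@counts < 0) || any(object@counts != round(object@counts)))
            msg <- c(msg, "counts must be non-negative integers")
        if (ncol(object@counts) != length(object@totals))
            msg <- c(msg, "one total per sample column is required")
        if (!is.null(colnames(object@counts)) &&
            !identical(colnames(object@counts), names(object@totals)))
            msg <- c(msg, "totals must be named like the sample columns")
        if (nrow(object@counts) > 0L &&
            any(colSums(object@counts) > object@totals + 1e-9))
            msg <- c(msg, "totals must be >= the column sums of assigned counts")
        if (length(msg)) msg else TRUE
    })

#' PipelineConfig: all tunable parameters of the discovery pipeline
#'
#' Defaults reproduce the published protocol parameters: 18-26 nt tags,
#' adapter ATCTCGTATGCCGTCTTCTGCTTG, at most 10 genomic loci, a 500 bp
#' precursor window, a 15 bp refold margin, folding only tags with more
#' than 25 copies, an enrichment threshold of 0.001 and a target validation
#' cutoff of 4.
#'
#' @slot adapter 3' adapter sequence.
#' @slot minLen,maxLen Tag length bounds (nt).
#' @slot phredFloor Minimum per-base Phred score when qualities exist.
#' @slot minOverlap Minimum adapter prefix overlap at the read 3' end.
#' @slot maxLoci Maximum genomic loci per tag.
#' @slot seedLength Index seed length.
#' @slot windowMargin Precursor window margin each side of the tag (bp).
#' @slot refoldMargin Margin around the mature..star span on refolding (bp).
#' @slot minCopies Copy-number gate: tags must exceed this count to be folded.
#' @slot minConsistency Minimum read-signature consistency.
#' @slot duplexMaxMismatch,maxBulge,overhangRange Duplex criteria.
#' @slot homologyMaxMM,homologyMaxShift Homology search tolerances.
#' @slot targetReportCutoff,validationCutoff Target penalty cutoffs.
#' @slot alpha Enrichment significance threshold.
#' @slot enrichmentMode "one_vs_rest" or "pairwise_any".
#' @slot engine Folding engine name ("baseline" or "vienna").
#' @slot seed Integer seed for any stochastic step.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
    representation(adapter = "character",
                   minLen = "integer", maxLen = "integer",
                   phredFloor = "integer", minOverlap = "integer",
                   maxLoci = "integer", seedLength = "integer",
                   windowMargin = "integer", refoldMargin = "integer",
                   minCopies = "integer", minConsistency = "numeric",
                   duplexMaxMismatch = "integer", maxBulge = "integer",
                   overhangRange = "integer",
                   homologyMaxMM = "integer", homologyMaxShift = "integer",
                   targetReportCutoff = "numeric", validationCutoff = "numeric",
                   alpha = "numeric", enrichmentMode = "character",
                   engine = "character", seed = "integer"),
    validity = function(object) {
        msg <- character()
        chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
        chk(grepl("^[ACGT]+$", object@adapter), "adapter must be a DNA string")
        chk(object@minLen >= 15L && object@minLen <= object@maxLen &&
            object@maxLen <= 30L, "minLen/maxLen out of range")
        chk(object@minOverlap >= 1L &&
            object@minOverlap <= nchar(object@adapter),
            "minOverlap out of range")
        chk(object@maxLoci >= 1L, "maxLoci out of range")
        chk(object@seedLength >= 1L && object@seedLength <= 18L,
            "seedLength out of range")
        chk(object@windowMargin >= 0L, "windowMargin out of range")
        chk(object@refoldMargin >= 0L, "refoldMargin out of range")
        chk(object@minCopies >= 1L, "minCopies out of range")
        chk(object@minConsistency >= 0 && object@minConsistency <= 1,
            "minConsistency out of range")
        chk(object@duplexMaxMismatch >= 0L, "duplexMaxMismatch out of range")
        chk(object@maxBulge >= 0L, "maxBulge out of range")
        chk(length(object@overhangRange) == 2L &&
            object@overhangRange[1] >= 0L &&
            object@overhangRange[1] <= object@overhangRange[2],
            "overhangRange out of range")
        chk(object@homologyMaxMM >= 0L, "homologyMaxMM out of range")
        chk(object@homologyMaxShift >= 0L, "homologyMaxShift out of range")
        chk(object@targetReportCutoff >= 0, "targetReportCutoff out of range")
        chk(object@validationCutoff >= 0, "validationCutoff out of range")
        chk(object@alpha > 0 && object@alpha < 1, "alpha out of range")
        chk(object@enrichmentMode %in% c("one_vs_rest", "pairwise_any"),
            "enrichmentMode out of range")
        chk(object@engine %in% c("baseline", "vienna"),
            "engine out of range")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "GenomeIndex", function(object) {
    cat("GenomeIndex with", length(object@genome), "sequence(s),",
        sum(Biostrings::width(object@genome)), "bp, seed length",
        object@seedLength, "\n")
})

setMethod("show", "HairpinCandidate", function(object) {
    cat("HairpinCandidate ", object@id, "\n",
        " locus: ", object@seqId, ":", object@start, "-", object@end,
        " (", object@strand, ")\n", sep = "")
    cat("  precursor:", nchar(object@precursor), "nt, energy",
        object@energy, "\n")
    cat("  mature: offset", object@matureOffset, "length",
        object@matureLength, "count", object@matureCount, "\n")
    cat("  duplex mismatches:", object@duplex$mismatches,
        "bulge:", object@duplex$largest_asymmetric_bulge, "\n")
    cat("  accepted:", object@accepted,
        if (length(object@rejectionReasons))
            paste0("(", paste(object@rejectionReasons, collapse = ", "), ")")
        else "", "\n")
})

setMethod("show", "CountProfile", function(object) {
    cat("CountProfile:", nrow(object@counts), "tags x",
        ncol(object@counts), "samples\n")
    cat("  library totals:",
        paste(names(object@totals), format(object@totals), sep = "=",
              collapse = ", "), "\n")
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    for (f in c("adapter", "minLen", "maxLen", "maxLoci", "windowMargin",
                "refoldMargin", "minCopies", "minConsistency",
                "homologyMaxMM", "validationCutoff", "alpha",
                "enrichmentMode", "engine", "seed"))
        cat(" ", f, "=", format(slot(object, f)), "\n")
})

#' @describeIn CountProfile-class Access the count matrix.
#' @param object A `CountProfile`.
#' @export
setGeneric("profileCounts", function(object) standardGeneric("profileCounts"))

#' @export
setMethod("profileCounts", "CountProfile", function(object) object@counts)

#' @describeIn CountProfile-class Access the per-sample library totals.
#' @export
setGeneric("libraryTotals", function(object) standardGeneric("libraryTotals"))

#' @export
setMethod("libraryTotals", "CountProfile", function(object) object@totals)

#' @describeIn HairpinCandidate-class The mature sequence (RNA alphabet).
#' @export
setGeneric("matureSequence", function(object) standardGeneric("matureSequence"))

#' @export
setMethod("matureSequence", "HairpinCandidate", function(object) {
    toRNA(substr(object@precursor, object@matureOffset + 1L,
                 object@matureOffset + object@matureLength))
})

#' @describeIn HairpinCandidate-class The star sequence (RNA alphabet), or NA.
#' @export
setGeneric("starSequence", function(object) standardGeneric("starSequence"))

#' @export
setMethod("starSequence", "HairpinCandidate", function(object) {
    if (is.na(object@starOffset)) return(NA_character_)
    toRNA(substr(object@precursor, object@starOffset + 1L,
                 object@starOffset + object@starLength))
})

#' @describeIn HairpinCandidate-class Whether the candidate passed all filters.
#' @export
setGeneric("isAccepted", function(object) standardGeneric("isAccepted"))

#' @export
setMethod("isAccepted", "HairpinCandidate", function(object) object@accepted)
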