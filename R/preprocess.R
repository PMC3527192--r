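# Pre-processing of raw small-RNA reads: adapter trimming, quality and
# length/ambiguity filtering, collapsing to unique counted tags, removal of
# ncRNA-matching tags and low-complexity masking.

#' Trim the 3' adapter from a read
#'
#' Finds the leftmost occurrence of the adapter (either a full internal
#' match, or a prefix of the adapter of at least `minOverlap` bases anchored
#' at the read's 3' end) and returns the insert preceding it.  Reads in
#' which no adapter can be detected are rejected, because the insert length
#' cannot be confirmed; empty inserts are rejected as well.
#'
#' @param sequence Read sequence(s), DNA alphabet (vectorised).
#' @param adapter Adapter sequence; default is the 3' sequencing adapter
#'   ATCTCGTATGCCGTCTTCTGCTTG.
#' @param minOverlap Minimum adapter prefix length at the read 3' end.
#' @return Character vector of inserts, `NA` where the read was rejected.
#' @examples
#' trimAdapter("ACGTACGTACGTACGTACGTAATCTCGTATGCCGTCTTCTGCTTG")
#' @export
trimAdapter <- function(sequence, adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                        minOverlap = 6L) {
    stopifnot(nchar(adapter) >= minOverlap, minOverlap >= 1L)
    if (any(!nzchar(sequence)))
        stop("empty read")
    vapply(sequence, function(s) {
        n <- nchar(s)
        # full internal occurrence (leftmost)
        hit <- regexpr(adapter, s, fixed = TRUE)
        if (hit > 0L) {
            if (hit == 1L) return(NA_character_)  # empty insert
            return(substr(s, 1L, hit - 1L))
        }
        # adapter prefix anchored at the 3' end, longest first so the
        # reported insert is the shortest consistent one
        maxov <- min(nchar(adapter), n)
        if (maxov < minOverlap) return(NA_character_)
        for (ov in rev(seq.int(minOverlap, maxov))) {
            if (substr(s, n - ov + 1L, n) == substr(adapter, 1L, ov)) {
                if (ov == n) return(NA_character_)
                return(substr(s, 1L, n - ov))
            }
        }
        NA_character_
    }, character(1), USE.NAMES = FALSE)
}

#' Keep 18-26 nt unambiguous sequences
#'
#' @param sequence Character vector of insert sequences.
#' @param minLen,maxLen Length bounds in nt.
#' @return Logical vector: TRUE where the sequence is kept.
#' @export
filterLengthAmbiguity <- function(sequence, minLen = 18L, maxLen = 26L) {
    n <- nchar(sequence)
    n >= minLen & n <= maxLen & !grepl("N", sequence, fixed = TRUE)
}

#' Collapse identical inserts into unique counted tags
#'
#' @param sequences Character vector of filtered insert sequences.
#' @param sampleId Sample identifier attached to every tag.
#' @return A data.frame (`sequence`, `count`, `sample_id`) ordered by
#'   descending count then lexicographic sequence.
#' @export
collapseUnique <- function(sequences, sampleId = "sample") {
    if (length(sequences) == 0L)
        return(data.frame(sequence = character(), count = integer(),
                          sample_id = character(), stringsAsFactors = FALSE))
    tab <- table(sequences)
    out <- data.frame(sequence = names(tab), count = as.integer(tab),
                      sample_id = sampleId, stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Remove tags matching non-coding RNA references
#'
#' A tag is removed iff it is an exact full-length substring of any
#' reference sequence or of its reverse complement.  Removed tags carry the
#' class (rRNA, tRNA, snRNA, snoRNA, other) of the first matching entry.
#'
#' @param tags Clean-tag data.frame.
#' @param reference A data.frame with columns `name`, `class`, `sequence`
#'   (see [readNcRNAReference()]).
#' @return List with elements `kept` (tag data.frame) and `removed`
#'   (tag data.frame with an extra `class` column).
#' @export
filterNcRNA <- function(tags, reference) {
    stopifnot(nrow(reference) > 0L,
              all(reference$class %in%
                  c("rRNA", "tRNA", "snRNA", "snoRNA", "other")))
    refs <- toupper(toDNA(reference$sequence))
    both <- c(refs, revcomp(refs))
    classes <- rep(reference$class, 2L)
    hit_class <- vapply(tags$sequence, function(s) {
        i <- which(vapply(both, function(r) grepl(s, r, fixed = TRUE),
                          logical(1)))
        if (length(i)) classes[i[1L]] else NA_character_
    }, character(1), USE.NAMES = FALSE)
    removed <- tags[!is.na(hit_class), , drop = FALSE]
    if (nrow(removed)) removed$class <- hit_class[!is.na(hit_class)]
    else removed$class <- character(0)
    kept <- tags[is.na(hit_class), , drop = FALSE]
    rownames(kept) <- rownames(removed) <- NULL
    list(kept = kept, removed = removed)
}

#' Mask low-complexity tags
#'
#' Drops tags whose most frequent single nucleotide occupies strictly more
#' than 80\% of positions, or that are a pure 1-2 nt repeat.
#'
#' @param tags Clean-tag data.frame.
#' @return The kept subset of `tags`.
#' @export
maskLowComplexity <- function(tags) {
    if (nrow(tags) == 0L) return(tags)
    keep <- vapply(tags$sequence, function(s) {
        ch <- strsplit(s, "")[[1]]
        if (max(table(ch)) / length(ch) > 0.8) return(FALSE)
        # pure 1-2 nt repeat
        u1 <- substr(s, 1, 1)
        if (s == strrep(u1, nchar(s))) return(FALSE)
        u2 <- substr(s, 1, 2)
        rep2 <- substr(strrep(u2, ceiling(nchar(s) / 2)), 1, nchar(s))
        if (s == rep2) return(FALSE)
        TRUE
    }, logical(1), USE.NAMES = FALSE)
    out <- tags[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read an ncRNA reference FASTA
#'
#' Headers are expected as `>name class`; an absent or unrecognised class
#' falls back to "other".
#'
#' @param path FASTA file.
#' @return A data.frame with columns `name`, `class`, `sequence`.
#' @export
readNcRNAReference <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    parts <- strsplit(names(x), "\\s+")
    cls <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "other",
                  character(1))
    cls[!cls %in% c("rRNA", "tRNA", "snRNA", "snoRNA")] <- "other"
    data.frame(name = vapply(parts, `[`, character(1), 1L),
               class = cls, sequence = as.character(x),
               stringsAsFactors = FALSE)
}

#' Run the full pre-processing stage on one sample
#'
#' Applies, in order: quality floor (FASTQ only), adapter trimming,
#' length/ambiguity filtering, collapsing, ncRNA removal and
#' low-complexity masking, with per-stage read accounting.
#'
#' @param reads A data.frame from [readSmallRNA()].
#' @param sampleId Sample name.
#' @param ncrna Optional ncRNA reference data.frame.
#' @param config A [pipelineConfig()].
#' @return List with `tags` (clean-tag data.frame) and `report` (data.frame
#'   of stage, reads_in, reads_out).
#' @export
preprocessSample <- function(reads, sampleId, ncrna = NULL,
                             config = pipelineConfig()) {
    report <- data.frame(stage = character(), reads_in = integer(),
                         reads_out = integer(), stringsAsFactors = FALSE)
    note <- function(stage, n_in, n_out) {
        report <<- rbind(report, data.frame(stage = stage, reads_in = n_in,
                                            reads_out = n_out,
                                            stringsAsFactors = FALSE))
    }
    seqs <- toupper(toDNA(reads$sequence))
    n0 <- length(seqs)
    if (!is.null(reads$quality)) {
        ok <- vapply(phred_scores(reads$quality),
                     function(q) all(q >= config@phredFloor), logical(1))
        seqs <- seqs[ok]
        note("quality", n0, length(seqs))
    }
    n1 <- length(seqs)
    inserts <- trimAdapter(seqs, config@adapter, config@minOverlap)
    inserts <- inserts[!is.na(inserts)]
    note("adapter", n1, length(inserts))
    keep <- filterLengthAmbiguity(inserts, config@minLen, config@maxLen)
    inserts <- inserts[keep]
    note("length_ambiguity", length(keep), length(inserts))
    tags <- collapseUnique(inserts, sampleId)
    note("collapse", length(inserts), sum(tags$count))
    if (!is.null(ncrna) && nrow(ncrna) > 0L) {
        fn <- filterNcRNA(tags, ncrna)
        note("ncrna", sum(tags$count), sum(fn$kept$count))
        tags <- fn$kept
    }
    n_before <- sum(tags$count)
    tags <- maskLowComplexity(tags)
    note("masking", n_before, sum(tags$count))
    list(tags = tags, report = report)
}
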