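#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet width
NULL

# Internal sequence helpers.  The package works in the DNA alphabet (T)
# internally; mature miRNAs are reported in the RNA alphabet (U).

toRNA <- function(x) chartr("Tt", "Uu", x)

toDNA <- function(x) chartr("Uu", "Tt", x)

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic RNG scope: evaluates expr under a local seed without
# touching the caller's RNG state.
with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

random_dna <- function(n, gc = 0.5) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' FASTQ qualities are decoded as Sanger Phred+33.  FASTA headers of the
#' collapsed form `tagN_xCOUNT` are expanded so that a collapsed-tag FASTA
#' round-trips to the original read multiset.
#'
#' @param path Path to a FASTA or FASTQ file (plain text).
#' @param format "auto" (by extension), "fasta" or "fastq".
#' @return A data.frame with columns `id`, `sequence` and, for FASTQ,
#'   `quality` (raw Phred+33 strings).
#' @export
readSmallRNA <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
            "fastq" else "fasta"
    }
    if (format == "fastq") {
        x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
        data.frame(id = names(x),
                   sequence = as.character(x),
                   quality = as.character(S4Vectors::mcols(x)$qualities),
                   stringsAsFactors = FALSE, row.names = NULL)
    } else {
        x <- Biostrings::readDNAStringSet(path, format = "fasta")
        ids <- names(x)
        seqs <- toDNA(as.character(x))
        cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", ids)))
        cnt[is.na(cnt)] <- 1L
        data.frame(id = rep(ids, cnt),
                   sequence = rep(seqs, cnt),
                   stringsAsFactors = FALSE, row.names = NULL)
    }
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the collapsed-read convention `>tag<serial>_x<count>`.
#'
#' @param tags A clean-tag data.frame (columns `sequence`, `count`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeTagFasta <- function(tags, path) {
    headers <- sprintf(">tag%d_x%d", seq_len(nrow(tags)), tags$count)
    writeLines(as.vector(rbind(headers, tags$sequence)), path)
    invisible(path)
}

# Phred+33 decode to integer scores.
phred_scores <- function(qual) {
    lapply(qual, function(q) utf8ToInt(q) - 33L)
}
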