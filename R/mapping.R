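# Exact placement of tags on the surrogate genome.  A k-mer seed index
# proposes candidate positions; every hit is verified over the full tag, so
# the index reproduces a naive scan exactly.

#' Build a k-mer index over a genome
#'
#' @param genome A [Biostrings::DNAStringSet], a named character vector, or
#'   a FASTA path.
#' @param seedLength Seed length (<= 18); tags shorter than the seed cannot
#'   be queried.
#' @return A [GenomeIndex-class] object.
#' @export
buildGenomeIndex <- function(genome, seedLength = 16L) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(toupper(toDNA(genome)))
    if (anyDuplicated(names(genome)))
        stop("duplicate sequence names in genome")
    seedLength <- as.integer(seedLength)
    seqs <- as.character(genome)
    stride <- max(nchar(seqs)) + 1L
    si_all <- integer(0); pos_all <- integer(0); seed_all <- character(0)
    for (si in seq_along(seqs)) {
        n <- nchar(seqs[si])
        if (n < seedLength) next
        starts <- seq_len(n - seedLength + 1L)
        si_all <- c(si_all, rep.int(si, length(starts)))
        pos_all <- c(pos_all, starts - 1L)
        seed_all <- c(seed_all,
                      substring(seqs[si], starts, starts + seedLength - 1L))
    }
    # positions are stored as (seq index, offset) encoded in one double so
    # the whole table builds with a single split
    codes <- (si_all - 1) * as.double(stride) + pos_all
    env <- list2env(split(codes, seed_all),
                    envir = new.env(parent = emptyenv(), hash = TRUE))
    # cached metadata under keys that cannot collide with DNA k-mers
    env[[".seqs"]] <- seqs
    env[[".stride"]] <- stride
    new("GenomeIndex", genome = genome, seedLength = seedLength, kmers = env)
}

# All 0-based forward-strand occurrences of `pattern` in the index,
# returned as a two-column matrix (seq index, offset).
index_lookup <- function(index, pattern) {
    sl <- index@seedLength
    if (nchar(pattern) < sl)
        stop("query shorter than the index seed length")
    codes <- index@kmers[[substr(pattern, 1L, sl)]]
    if (is.null(codes))
        return(cbind(seq = integer(0), start = integer(0)))
    stride <- index@kmers[[".stride"]]
    seqs <- index@kmers[[".seqs"]]
    si <- as.integer(codes %/% stride) + 1L
    st <- as.integer(codes %% stride)
    L <- nchar(pattern)
    ok <- st + L <= nchar(seqs)[si] &
        substring(seqs[si], st + 1L, st + L) == pattern
    cbind(seq = si[ok], start = st[ok])
}

#' Map a tag to the genome by perfect full-length match
#'
#' Both strands are searched; a minus-strand alignment means the tag equals
#' the reverse complement of the genomic slice.  Coordinates are 0-based.
#'
#' @param sequence Tag sequence (single string, DNA alphabet).
#' @param index A [GenomeIndex-class].
#' @param rc Optional precomputed reverse complement of `sequence`.
#' @return A data.frame (`seq_id`, `start`, `strand`, `length`) sorted by
#'   (seq_id, start, strand).
#' @export
mapExact <- function(sequence, index, rc = NULL) {
    sequence <- toupper(toDNA(sequence))
    if (is.null(rc)) rc <- revcomp(sequence)
    fwd <- index_lookup(index, sequence)
    rev <- index_lookup(index, rc)
    L <- nchar(sequence)
    nm <- names(index@genome)
    n_f <- nrow(fwd); n_r <- nrow(rev)
    if (n_f + n_r == 0L)
        return(data.frame(seq_id = character(), start = integer(),
                          strand = character(), length = integer(),
                          stringsAsFactors = FALSE))
    out <- data.frame(
        seq_id = nm[c(fwd[, 1L], rev[, 1L])],
        start = c(fwd[, 2L], rev[, 2L]),
        strand = rep(c("+", "-"), c(n_f, n_r)),
        length = L,
        stringsAsFactors = FALSE)
    out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Map a set of tags and apply the multi-locus filter
#'
#' @param tags Clean-tag data.frame.
#' @param index A [GenomeIndex-class].
#' @param maxLoci Tags aligning to more than this many loci are discarded
#'   (default 10); tags with zero loci are routed to the homology path.
#' @return List with `alignments` (tag-annotated alignment data.frame for
#'   kept tags), `kept`, `discarded` and `unmapped` tag data.frames.
#' @export
mapTags <- function(tags, index, maxLoci = 10L) {
    stopifnot(maxLoci >= 1L)
    rc_all <- if (nrow(tags)) revcomp(tags$sequence) else character(0)
    aln_list <- lapply(seq_len(nrow(tags)), function(i)
        mapExact(tags$sequence[i], index, rc = rc_all[i]))
    nloci <- vapply(aln_list, nrow, integer(1))
    kept_i <- which(nloci >= 1L & nloci <= maxLoci)
    kept_alns <- aln_list[kept_i]
    n_each <- nloci[kept_i]
    aln <- data.frame(
        seq_id = as.character(unlist(lapply(kept_alns, `[[`, "seq_id"))),
        start = as.integer(unlist(lapply(kept_alns, `[[`, "start"))),
        strand = as.character(unlist(lapply(kept_alns, `[[`, "strand"))),
        length = as.integer(unlist(lapply(kept_alns, `[[`, "length"))),
        tag = rep(tags$sequence[kept_i], n_each),
        count = rep(tags$count[kept_i], n_each),
        sample_id = rep(tags$sample_id[kept_i], n_each),
        stringsAsFactors = FALSE)
    list(alignments = aln,
         kept = tags[kept_i, , drop = FALSE],
         discarded = tags[nloci > maxLoci, , drop = FALSE],
         unmapped = tags[nloci == 0L, , drop = FALSE])
}

#' Select the representative tag at each 5' genomic position
#'
#' Among tags sharing an identical 5' alignment position and strand, the
#' tag with the maximum read count represents the locus; ties break to the
#' longer tag, then to the lexicographically smaller sequence.  The 5'
#' position of a minus-strand alignment is its genomic end.
#'
#' @param alignments Alignment data.frame from [mapTags()] (columns
#'   `seq_id`, `start`, `strand`, `length`, `tag`, `count`).
#' @return The subset of `alignments` with one row per (5' position,
#'   strand) group.
#' @export
selectRepresentative <- function(alignments) {
    if (nrow(alignments) == 0L) return(alignments)
    five_prime <- ifelse(alignments$strand == "+", alignments$start,
                         alignments$start + alignments$length - 1L)
    key <- paste(alignments$seq_id, five_prime, alignments$strand)
    picked <- vapply(split(seq_len(nrow(alignments)), key), function(idx) {
        a <- alignments[idx, , drop = FALSE]
        ord <- order(-a$count, -a$length, a$tag)
        idx[ord[1L]]
    }, integer(1))
    out <- alignments[sort(unname(picked)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export alignments as BED6
#'
#' 0-based half-open intervals, score column carries the tag count.
#'
#' @param alignments Alignment data.frame from [mapTags()].
#' @param path Output BED file.
#' @return Invisibly, `path`.
#' @export
exportAlignmentsBED <- function(alignments, path) {
    gr <- GenomicRanges::GRanges(
        seqnames = alignments$seq_id,
        ranges = IRanges::IRanges(start = alignments$start + 1L,
                                  width = alignments$length),
        strand = alignments$strand,
        name = alignments$tag,
        score = alignments$count)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
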