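# Classification of candidate matures against a known-miRNA catalogue,
# homology rescue of conserved miRNAs the surrogate genome missed, and
# family grouping.

#' Read a known-miRNA catalogue FASTA
#'
#' Headers follow the miRBase-like convention `>name family species`; when
#' family or species are absent, the family is parsed from the name by
#' stripping the letter/variant suffix after "miR<number>".
#'
#' @param path FASTA file (RNA or DNA alphabet).
#' @return A data.frame with columns `name`, `family`, `species`,
#'   `sequence` (DNA alphabet).
#' @export
readCatalogue <- function(path) {
    x <- Biostrings::readBStringSet(path)  # tolerate the RNA alphabet
    parts <- strsplit(names(x), "\\s+")
    name <- vapply(parts, `[`, character(1), 1L)
    family <- vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) >= 2L) parts[[i]][2L]
        else parseFamily(name[i])
    }, character(1))
    species <- vapply(parts, function(p)
        if (length(p) >= 3L) p[3L] else NA_character_, character(1))
    data.frame(name = name, family = family, species = species,
               sequence = toupper(toDNA(as.character(x))),
               stringsAsFactors = FALSE)
}

#' Parse a miRNA family from a catalogue name
#'
#' `miR156a` and `miR156f-5p` both map to `miR156`; names that do not
#' follow the convention form singleton families (the name itself).
#'
#' @param name Character vector of miRNA names.
#' @return Character vector of family names.
#' @export
parseFamily <- function(name) {
    fam <- sub("^(?:[a-z]{3}-)?((?:miR|MIR)[0-9]+).*$", "\\1", name,
               perl = TRUE)
    ifelse(grepl("^(?:[a-z]{3}-)?(?:miR|MIR)[0-9]+", name, perl = TRUE),
           fam, name)
}

# Hamming mismatches between two equal-length strings.
hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Find the best catalogue match of a tag
#'
#' Ungapped comparison over all terminal shifts up to `maxShift`;
#' mismatches are counted over the overlapping region.  The best hit has
#' the fewest mismatches, ties broken by smaller absolute shift then
#' lexicographic catalogue name.
#'
#' @param sequence Tag sequence (DNA or RNA).
#' @param catalogue Catalogue data.frame from [readCatalogue()].
#' @param maxMM Maximum mismatches (default 2).
#' @param maxShift Maximum terminal shift in nt (default 2).
#' @return A list (`name`, `family`, `mismatches`, `shift`) or `NULL`.
#' @export
matchKnown <- function(sequence, catalogue, maxMM = 2L, maxShift = 2L) {
    if (nrow(catalogue) == 0L) stop("empty catalogue")
    stopifnot(maxMM >= 0L, maxShift >= 0L)
    tag <- toupper(toDNA(sequence))
    best <- NULL
    for (i in seq_len(nrow(catalogue))) {
        ref <- catalogue$sequence[i]
        for (shift in -maxShift:maxShift) {
            # shift > 0: tag starts `shift` nt 3' of the reference start
            t_from <- max(1L, 1L - shift)
            r_from <- max(1L, 1L + shift)
            ov <- min(nchar(tag) - t_from, nchar(ref) - r_from) + 1L
            if (ov <= 0L) next
            # both terminal shifts must respect the tolerance
            end_shift <- abs((nchar(tag) - t_from) - (nchar(ref) - r_from))
            if (end_shift > maxShift) next
            mm <- hamming(substr(tag, t_from, t_from + ov - 1L),
                          substr(ref, r_from, r_from + ov - 1L))
            if (mm > maxMM) next
            cand <- list(name = catalogue$name[i],
                         family = catalogue$family[i],
                         mismatches = mm, shift = shift)
            if (is.null(best) ||
                mm < best$mismatches ||
                (mm == best$mismatches &&
                 abs(shift) < abs(best$shift)) ||
                (mm == best$mismatches && abs(shift) == abs(best$shift) &&
                 cand$name < best$name))
                best <- cand
        }
    }
    best
}

#' Classify accepted candidates as conserved or novel
#'
#' @param matures Character vector of mature sequences (or a list of
#'   [HairpinCandidate-class] objects).
#' @param catalogue Catalogue data.frame.
#' @param maxMM,maxShift Homology tolerances.
#' @return A data.frame (`sequence`, `status`, `family`, `hit_name`,
#'   `mismatches`) with status `conserved_mapped` or `novel_mapped`;
#'   novel families are assigned later by [groupFamilies()].
#' @export
classifyCandidates <- function(matures, catalogue, maxMM = 2L,
                               maxShift = 2L) {
    if (is.list(matures) && length(matures) &&
        methods::is(matures[[1]], "HairpinCandidate"))
        matures <- vapply(matures, matureSequence, character(1))
    matures <- toupper(toDNA(matures))
    rows <- lapply(matures, function(s) {
        hit <- matchKnown(s, catalogue, maxMM, maxShift)
        if (is.null(hit))
            data.frame(sequence = s, status = "novel_mapped",
                       family = NA_character_, hit_name = NA_character_,
                       mismatches = NA_integer_, stringsAsFactors = FALSE)
        else
            data.frame(sequence = s, status = "conserved_mapped",
                       family = hit$family, hit_name = hit$name,
                       mismatches = hit$mismatches, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(sequence = character(), status = character(),
                          family = character(), hit_name = character(),
                          mismatches = integer(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Rescue conserved miRNAs among unmapped tags
#'
#' Tags that failed genome mapping but match the catalogue within
#' tolerance are annotated `conserved_rescued`; the rest are discarded
#' from the miRNA set.
#'
#' @param tags Clean-tag data.frame of unmapped tags.
#' @param catalogue Catalogue data.frame.
#' @param maxMM,maxShift Homology tolerances.
#' @return A data.frame like [classifyCandidates()]'s, rescued tags only,
#'   with the tag counts carried through.
#' @export
rescueUnmapped <- function(tags, catalogue, maxMM = 2L, maxShift = 2L) {
    if (nrow(tags) == 0L)
        return(data.frame(sequence = character(), status = character(),
                          family = character(), hit_name = character(),
                          mismatches = integer(), count = integer(),
                          stringsAsFactors = FALSE))
    rows <- lapply(seq_len(nrow(tags)), function(i) {
        hit <- matchKnown(tags$sequence[i], catalogue, maxMM, maxShift)
        if (is.null(hit)) return(NULL)
        data.frame(sequence = toupper(toDNA(tags$sequence[i])),
                   status = "conserved_rescued", family = hit$family,
                   hit_name = hit$name, mismatches = hit$mismatches,
                   count = tags$count[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(sequence = character(), status = character(),
                          family = character(), hit_name = character(),
                          mismatches = integer(), count = integer(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Group annotated miRNAs into families
#'
#' Conserved members inherit their catalogue family.  Novel members are
#' single-linkage clustered (linked when within 2 mismatches over the best
#' ungapped overlap of same-length-or-off-by-one sequences) and named
#' `Ng1`, `Ng2`, ... in order of descending total count then lexicographic
#' major sequence.  A family's major sequence is its highest-count member.
#'
#' @param annotation Data.frame with columns `sequence`, `status`,
#'   `family` (NA for novels) and `count` (total reads).
#' @param maxMM Cluster linkage threshold (default 2 mismatches).
#' @return List with `annotation` (the input with novel families filled
#'   in) and `families` (data.frame `family`, `n_members`, `major`,
#'   `total_count`).
#' @export
groupFamilies <- function(annotation, maxMM = 2L) {
    ann <- annotation
    if (is.null(ann$count)) ann$count <- 1L
    novel <- which(is.na(ann$family))
    if (length(novel)) {
        seqs <- ann$sequence[novel]
        n <- length(seqs)
        parent <- seq_len(n)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            if (abs(nchar(seqs[i]) - nchar(seqs[j])) > 1L) next
            hit <- matchKnown(seqs[i],
                              data.frame(name = "x", family = "x",
                                         sequence = seqs[j],
                                         stringsAsFactors = FALSE),
                              maxMM = maxMM, maxShift = 1L)
            if (!is.null(hit)) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[rj] <- ri
            }
        }
        roots <- vapply(seq_len(n), find, integer(1))
        # deterministic Ng numbering: descending cluster total count, then
        # lexicographic major sequence
        cl <- split(seq_len(n), roots)
        totals <- vapply(cl, function(ix) sum(ann$count[novel[ix]]),
                         numeric(1))
        majors <- vapply(cl, function(ix) {
            s <- ann$sequence[novel[ix]]
            s[order(-ann$count[novel[ix]], s)][1L]
        }, character(1))
        ord <- order(-totals, majors)
        for (k in seq_along(ord)) {
            ix <- cl[[ord[k]]]
            ann$family[novel[ix]] <- sprintf("Ng%d", k)
        }
    }
    fams <- split(seq_len(nrow(ann)), ann$family)
    families <- do.call(rbind, lapply(names(fams), function(f) {
        ix <- fams[[f]]
        s <- ann$sequence[ix]
        data.frame(family = f, n_members = length(ix),
                   major = s[order(-ann$count[ix], s)][1L],
                   total_count = sum(ann$count[ix]),
                   stringsAsFactors = FALSE)
    }))
    families <- families[order(families$family), , drop = FALSE]
    rownames(families) <- NULL
    list(annotation = ann, families = families)
}
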