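# Hairpin precursor discovery: build genomic windows around mapped tags,
# fold them, locate the miRNA* partner, trim and refold, and accept
# candidates that satisfy the plant miRNA annotation criteria and a
# read-stack signature filter.

#' Extract the precursor window around an alignment
#'
#' The window covers the tag plus `margin` nucleotides on each side,
#' clipped at the contig ends.  Minus-strand windows are
#' reverse-complemented so the tag always appears in sense orientation.
#'
#' @param alignment One alignment row (`seq_id`, `start`, `strand`,
#'   `length`); 0-based genomic start.
#' @param genome A [Biostrings::DNAStringSet].
#' @param margin Margin in bp (default 500).
#' @return List with `seq_id`, `start`, `end` (genomic, 0-based half-open),
#'   `strand`, `sequence` (transcription orientation) and `matureOffset`
#'   (0-based within `sequence`).
#' @export
extractWindow <- function(alignment, genome, margin = 500L) {
    stopifnot(margin >= 0L)
    seqlen <- nchar(as.character(genome[[alignment$seq_id]]))
    if (alignment$start < 0L || alignment$start + alignment$length > seqlen)
        stop("alignment outside the genome sequence")
    gstart <- max(0L, alignment$start - margin)
    gend <- min(seqlen, alignment$start + alignment$length + margin)
    s <- substr(as.character(genome[[alignment$seq_id]]),
                gstart + 1L, gend)
    if (alignment$strand == "-") {
        s <- revcomp(s)
        mat_off <- gend - (alignment$start + alignment$length)
    } else {
        mat_off <- alignment$start - gstart
    }
    list(seq_id = alignment$seq_id, start = gstart, end = gend,
         strand = alignment$strand, sequence = s,
         matureOffset = as.integer(mat_off),
         matureLength = as.integer(alignment$length))
}

#' Locate the miRNA* interval from a folded structure
#'
#' The star arm is the interval pairing with the mature arm, shifted so the
#' duplex carries 2-nt 3' overhangs on both ends.  Returns `NULL` when the
#' mature region lies in a loop or fewer than half its bases pair outside
#' the mature interval.
#'
#' @param structure Dot-bracket string.
#' @param matureOffset,matureLength 0-based mature interval.
#' @return List with `starOffset`, `starLength` (0-based), or `NULL`.
#' @export
findStar <- function(structure, matureOffset, matureLength) {
    p <- pairTable(structure)
    n <- length(p)
    a <- matureOffset + 1L
    b <- matureOffset + matureLength
    idx <- a:b
    outside <- p[idx] > 0L & (p[idx] < a | p[idx] > b)
    if (sum(outside) < matureLength / 2) return(NULL)
    oi <- idx[outside]
    oq <- p[oi]
    # longest helix-like run: partners strictly decrease and their spacing
    # tracks the mature spacing within a small bulge tolerance
    runs <- list(); cur <- 1L
    if (length(oi) > 1L) for (r in 2:length(oi)) {
        dq <- oq[r - 1L] - oq[r]
        di <- oi[r] - oi[r - 1L]
        if (dq >= 1L && abs(dq - di) <= 3L) next
        runs[[length(runs) + 1L]] <- cur:(r - 1L); cur <- r
    }
    runs[[length(runs) + 1L]] <- cur:length(oi)
    best <- runs[[which.max(vapply(runs, length, integer(1)))]]
    if (length(best) < matureLength / 2) return(NULL)
    ri <- oi[best]; rq <- oq[best]
    # 2-nt 3' overhang register: mature position a pairs star end - 2 and
    # mature position b - 2 pairs the star start; taking the extremes over
    # the run keeps both endpoints exact in the presence of one bulge
    d <- max(rq + (ri - a)) + 2L
    cc <- min(rq - ((b - 2L) - ri))
    if (cc > d) return(NULL)
    cc <- max(1L, cc); d <- min(n, d)
    starOffset <- cc - 1L
    starLength <- d - cc + 1L
    if (starLength < 5L) return(NULL)
    # star must not overlap the mature interval
    if (max(matureOffset, starOffset) <
        min(matureOffset + matureLength, starOffset + starLength))
        return(NULL)
    list(starOffset = as.integer(starOffset),
         starLength = as.integer(starLength))
}

#' Trim to the mature..star span and refold
#'
#' The precursor is the interval from the leftmost to the rightmost of the
#' mature and star arms extended by `refoldMargin` on each side (clipped to
#' the window), refolded with the engine; offsets are re-expressed in
#' precursor coordinates.
#'
#' @param windowSeq Window sequence.
#' @param matureOffset,matureLength,starOffset,starLength 0-based intervals
#'   in window coordinates.
#' @param refoldMargin Margin in nt (default 15).
#' @param engine A [foldingEngine()].
#' @return List with `precursor`, `structure`, `energy`, `matureOffset`,
#'   `starOffset`, lengths, and `trimOffset` (0-based precursor start in
#'   window coordinates).
#' @export
trimAndRefold <- function(windowSeq, matureOffset, matureLength,
                          starOffset, starLength, refoldMargin = 15L,
                          engine = foldingEngine()) {
    stopifnot(refoldMargin >= 0L)
    n <- nchar(windowSeq)
    lo <- max(0L, min(matureOffset, starOffset) - refoldMargin)
    hi <- min(n, max(matureOffset + matureLength,
                     starOffset + starLength) + refoldMargin)
    prec <- substr(windowSeq, lo + 1L, hi)
    fold <- engine$fold(prec)
    list(precursor = prec, structure = fold$structure, energy = fold$energy,
         matureOffset = as.integer(matureOffset - lo),
         matureLength = as.integer(matureLength),
         starOffset = as.integer(starOffset - lo),
         starLength = as.integer(starLength),
         trimOffset = as.integer(lo))
}

#' Duplex statistics of a mature/star pair
#'
#' Mismatches are unpaired mature positions whose projected star-side
#' counterpart (under the 2-nt 3' overhang register) is also unpaired; the
#' largest asymmetric bulge is the maximum difference between opposing
#' unpaired runs along the duplex; 3' overhangs are measured from the last
#' position of each arm pairing into the other.
#'
#' @param structure Dot-bracket string.
#' @param matureOffset,matureLength,starOffset,starLength 0-based intervals.
#' @return Named list: `mismatches`, `largest_asymmetric_bulge`,
#'   `overhang_3p_mature`, `overhang_3p_star`, `paired_fraction_mature`.
#' @export
duplexReport <- function(structure, matureOffset, matureLength,
                         starOffset, starLength) {
    p <- pairTable(structure)
    a <- matureOffset + 1L; b <- matureOffset + matureLength
    cc <- starOffset + 1L;  d <- starOffset + starLength
    idx <- a:b
    in_star <- p[idx] >= cc & p[idx] <= d
    paired_fraction <- mean(in_star)
    # mismatches under the overhang register: mature i projects to star
    # position d - 2 - (i - a)
    mm <- 0L
    for (i in idx) {
        if (p[i] != 0L) next
        cp <- d - 2L - (i - a)
        if (cp >= cc && cp <= d && p[cp] == 0L) mm <- mm + 1L
    }
    # asymmetric bulges between consecutive paired duplex positions
    paired_i <- idx[in_star]
    bulge <- 0L
    if (length(paired_i) >= 2L) {
        q <- p[paired_i]
        for (r in seq_len(length(paired_i) - 1L)) {
            gap_m <- paired_i[r + 1L] - paired_i[r] - 1L
            gap_s <- abs(q[r] - q[r + 1L]) - 1L
            bulge <- max(bulge, abs(gap_m - gap_s))
        }
    }
    star_idx <- cc:d
    star_in_mat <- p[star_idx] >= a & p[star_idx] <= b
    ov_m <- if (any(in_star)) b - max(idx[in_star]) else NA_integer_
    ov_s <- if (any(star_in_mat)) d - max(star_idx[star_in_mat])
            else NA_integer_
    list(mismatches = mm,
         largest_asymmetric_bulge = as.integer(bulge),
         overhang_3p_mature = as.integer(ov_m),
         overhang_3p_star = as.integer(ov_s),
         paired_fraction_mature = paired_fraction)
}

#' Check the plant miRNA annotation criteria
#'
#' A candidate passes when the mature is 18-26 nt, the duplex has at most
#' `maxMismatch` mismatches and no asymmetric bulge larger than `maxBulge`,
#' both arms sit on one stem (no multiloop between them), and each 3'
#' overhang is within `overhangRange`.
#'
#' @param structure Dot-bracket string.
#' @param matureOffset,matureLength,starOffset,starLength 0-based intervals.
#' @param duplex A [duplexReport()]; computed if missing.
#' @param maxMismatch,maxBulge,overhangRange Thresholds (defaults 4, 2,
#'   c(1, 3)).
#' @return List with `accepted` and `reasons` (character vector).
#' @export
checkPlantCriteria <- function(structure, matureOffset, matureLength,
                               starOffset, starLength, duplex = NULL,
                               maxMismatch = 4L, maxBulge = 2L,
                               overhangRange = c(1L, 3L)) {
    reasons <- character()
    if (matureLength < 18L || matureLength > 26L)
        reasons <- c(reasons, "mature_length")
    if (is.null(starOffset) || is.na(starOffset)) {
        reasons <- c(reasons, "no_star")
        return(list(accepted = FALSE, reasons = reasons))
    }
    if (max(matureOffset, starOffset) <
        min(matureOffset + matureLength, starOffset + starLength)) {
        reasons <- c(reasons, "arm_overlap")
        return(list(accepted = FALSE, reasons = reasons))
    }
    if (is.null(duplex))
        duplex <- duplexReport(structure, matureOffset, matureLength,
                               starOffset, starLength)
    if (duplex$mismatches > maxMismatch)
        reasons <- c(reasons, "duplex_mismatches")
    if (duplex$largest_asymmetric_bulge > maxBulge)
        reasons <- c(reasons, "asymmetric_bulge")
    # one stem: the mature bases pairing into the star must do so with
    # monotonically decreasing partners (a multiloop between the arms
    # breaks monotonicity), and at least half the mature must pair there
    p <- pairTable(structure)
    a <- matureOffset + 1L; b <- matureOffset + matureLength
    cc <- starOffset + 1L; d <- starOffset + starLength
    idx <- (a:b)[p[a:b] >= cc & p[a:b] <= d]
    if (length(idx) < matureLength / 2 ||
        any(diff(p[idx]) >= 0L))
        reasons <- c(reasons, "multiloop")
    ov <- c(duplex$overhang_3p_mature, duplex$overhang_3p_star)
    if (any(is.na(ov)) || any(ov < overhangRange[1]) ||
        any(ov > overhangRange[2]))
        reasons <- c(reasons, "overhang_3p")
    list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Read-stack signature filter
#'
#' Dicer products stack at the duplex ends, so reads from a genuine miRNA
#' locus should begin within +/-2 nt of the mature or star 5' end.  The
#' consistency score is the read-weighted fraction of window reads doing
#' so; loop- and elsewhere-starting reads count as inconsistent.
#'
#' @param read5p Integer vector of window-read 5' positions (any shared
#'   coordinate system).
#' @param readCounts Read counts parallel to `read5p`.
#' @param mature5p,star5p 5' end positions of the mature and star arms in
#'   the same coordinates (star may be NA).
#' @param matureCount Read count of the mature tag.
#' @param minCopies Copy gate: the mature count must strictly exceed this
#'   (default 25).
#' @param minConsistency Minimum consistency (default 0.75).
#' @return List with `accepted` and `consistency`.
#' @export
signatureFilter <- function(read5p, readCounts, mature5p, star5p,
                            matureCount, minCopies = 25L,
                            minConsistency = 0.75) {
    stopifnot(minCopies >= 1L, minConsistency >= 0, minConsistency <= 1)
    total <- sum(readCounts)
    near <- abs(read5p - mature5p) <= 2L
    if (!is.na(star5p)) near <- near | abs(read5p - star5p) <= 2L
    consistency <- if (total > 0) sum(readCounts[near]) / total else 0
    list(accepted = matureCount > minCopies && consistency >= minConsistency,
         consistency = consistency)
}

# Locate the star arm for one mapped tag.  The full window is folded
# first; when the mature arm pairs into distant window structure instead
# of a local stem (a known failure mode of loop-penalty-free folding on
# long windows), the search retries at precursor-scale margins and
# finally scans the window directly for a reverse-complement partner.
# Every candidate star is validated by refolding the excised mature..star
# segment; the first validating candidate wins.
locate_star <- function(aln, genome, config, engine) {
    validate <- function(w, st) {
        span <- max(w$matureOffset + w$matureLength,
                    st$starOffset + st$starLength) -
                min(w$matureOffset, st$starOffset)
        if (span > 250L) return(FALSE)
        arm <- trimAndRefold(w$sequence, w$matureOffset, w$matureLength,
                             st$starOffset, st$starLength, 0L, engine)
        st0 <- findStar(arm$structure, arm$matureOffset, arm$matureLength)
        if (is.null(st0)) return(FALSE)
        crit <- checkPlantCriteria(arm$structure, arm$matureOffset,
                                   arm$matureLength, st0$starOffset,
                                   st0$starLength,
                                   maxMismatch = config@duplexMaxMismatch,
                                   maxBulge = config@maxBulge,
                                   overhangRange = config@overhangRange)
        crit$accepted
    }
    margins <- unique(c(config@windowMargin,
                        pmin(config@windowMargin, c(150L, 80L))))
    first <- NULL
    best <- NULL
    for (mg in margins) {
        w <- extractWindow(aln, genome, mg)
        f <- engine$fold(w$sequence)
        if (is.null(first)) first <- list(win = w, fold = f, star = NULL)
        st <- findStar(f$structure, w$matureOffset, w$matureLength)
        if (is.null(st)) next
        cand <- list(win = w, fold = f, star = st)
        if (validate(w, st)) return(cand)
        if (is.null(best)) best <- cand
    }
    # direct reverse-complement scan around the mature within the window
    w <- first$win; f <- first$fold
    L <- w$matureLength
    seqv <- strsplit(w$sequence, "")[[1]]
    mvec <- seqv[(w$matureOffset + 1L):(w$matureOffset + L)]
    lo <- max(0L, w$matureOffset - 220L)
    hi <- min(length(seqv) - L, w$matureOffset + 220L)
    offs <- setdiff(lo:hi, (w$matureOffset - L):(w$matureOffset + L))
    if (length(offs)) {
        mm <- vapply(offs, function(s) {
            wseg <- seqv[(s + 1L):(s + L)]
            # planted register: mature position i pairs segment L - 1 - i
            sum(vapply(1:(L - 2L), function(i)
                pair_weight_r(mvec[i], wseg[L - 1L - i]) == 0L,
                logical(1)))
        }, integer(1))
        ord <- offs[order(mm)]
        for (s in ord[seq_len(min(5L, length(ord)))]) {
            if (mm[match(s, offs)] > config@duplexMaxMismatch + 4L) break
            st <- list(starOffset = as.integer(s),
                       starLength = min(L + 2L, length(seqv) - s))
            if (validate(w, st))
                return(list(win = w, fold = f, star = st))
        }
    }
    if (!is.null(best)) return(best)
    first
}

# R-side pair weight mirroring the folding engine's rule.
pair_weight_r <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3L)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2L)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1L)
    0L
}

# Genomic coordinates of a trimmed precursor given its window.
precursor_genomic <- function(window, trimOffset, precLength) {
    if (window$strand == "+") {
        start <- window$start + trimOffset
    } else {
        start <- window$end - trimOffset - precLength
    }
    c(start = as.integer(start), end = as.integer(start + precLength))
}

#' Discover miRNA hairpin candidates in one sample
#'
#' Runs mapping, multi-locus filtering, representative selection, window
#' extraction, folding, star location, trim-and-refold, the plant
#' annotation criteria and the read-signature filter; overlapping accepted
#' precursors are merged keeping the highest-count mature.
#'
#' @param tags Clean-tag data.frame for one sample.
#' @param index A [GenomeIndex-class].
#' @param config A [pipelineConfig()].
#' @param engine A [foldingEngine()]; defaults to the config's engine.
#' @param all Return rejected candidates too (default FALSE).
#' @param mapping Optional precomputed [mapTags()] result for `tags`.
#' @return List of [HairpinCandidate-class] objects (accepted only unless
#'   `all = TRUE`), ordered by (seq_id, start).
#' @export
callMirnas <- function(tags, index, config = pipelineConfig(),
                       engine = NULL, all = FALSE, mapping = NULL) {
    if (is.null(engine)) engine <- foldingEngine(config@engine)
    if (nrow(tags) == 0L) return(list())
    genome <- index@genome
    mt <- if (is.null(mapping)) mapTags(tags, index, config@maxLoci)
          else mapping
    reps <- selectRepresentative(mt$alignments)
    cand <- reps[reps$count > config@minCopies, , drop = FALSE]
    out <- list()
    for (r in seq_len(nrow(cand))) {
        aln <- cand[r, ]
        loc <- locate_star(aln, genome, config, engine)
        win <- loc$win; fold <- loc$fold; star <- loc$star
        cid <- sprintf("%s:%d:%s", aln$seq_id, aln$start, aln$strand)
        if (is.null(star)) {
            if (all) {
                gen <- precursor_genomic(win, 0L, nchar(win$sequence))
                out[[length(out) + 1L]] <- new("HairpinCandidate",
                    id = cid, seqId = aln$seq_id,
                    start = gen[["start"]], end = gen[["end"]],
                    strand = aln$strand,
                    precursor = win$sequence, structure = fold$structure,
                    energy = fold$energy,
                    matureOffset = win$matureOffset,
                    matureLength = win$matureLength,
                    starOffset = NA_integer_, starLength = NA_integer_,
                    duplex = list(mismatches = NA_integer_,
                                  largest_asymmetric_bulge = NA_integer_,
                                  overhang_3p_mature = NA_integer_,
                                  overhang_3p_star = NA_integer_,
                                  paired_fraction_mature = 0),
                    matureCount = as.numeric(aln$count),
                    signatureConsistency = NA_real_,
                    accepted = FALSE, rejectionReasons = "no_star")
            }
            next
        }
        # duplex validation on the excised mature..star segment: folding it
        # without flanks removes the end-pair degeneracy a weight-maximising
        # folder shows when random flanking bases can substitute for the
        # duplex-end pairs
        arm <- trimAndRefold(win$sequence, win$matureOffset,
                             win$matureLength, star$starOffset,
                             star$starLength, 0L, engine)
        star_a <- findStar(arm$structure, arm$matureOffset,
                           arm$matureLength)
        if (!is.null(star_a)) {
            arm$starOffset <- star_a$starOffset
            arm$starLength <- star_a$starLength
        }
        dup <- duplexReport(arm$structure, arm$matureOffset,
                            arm$matureLength, arm$starOffset,
                            arm$starLength)
        crit <- checkPlantCriteria(arm$structure, arm$matureOffset,
                                   arm$matureLength, arm$starOffset,
                                   arm$starLength, duplex = dup,
                                   maxMismatch = config@duplexMaxMismatch,
                                   maxBulge = config@maxBulge,
                                   overhangRange = config@overhangRange)
        reasons <- crit$reasons
        # the reported precursor adds the refold margin around the arms
        tr <- trimAndRefold(win$sequence, win$matureOffset, win$matureLength,
                            arm$trimOffset + arm$starOffset,
                            arm$starLength,
                            config@refoldMargin, engine)
        tr$starOffset <- arm$trimOffset + arm$starOffset - tr$trimOffset
        tr$starLength <- arm$starLength
        if (engine$thermodynamic &&
            tr$energy / nchar(tr$precursor) > -0.2)
            reasons <- c(reasons, "energy_per_nt")
        # read signature over the trimmed precursor span, same strand
        in_win <- mt$alignments$seq_id == aln$seq_id &
            mt$alignments$strand == aln$strand &
            mt$alignments$start >= win$start &
            mt$alignments$start + mt$alignments$length <= win$end
        wreads <- mt$alignments[in_win, , drop = FALSE]
        # 5' positions in window coordinates
        if (aln$strand == "+") {
            r5 <- wreads$start - win$start
            m5 <- win$matureOffset
        } else {
            r5 <- win$end - (wreads$start + wreads$length)
            m5 <- win$matureOffset
        }
        prec_lo <- tr$trimOffset
        prec_hi <- tr$trimOffset + nchar(tr$precursor)
        in_prec <- r5 >= prec_lo & r5 < prec_hi
        r5 <- r5[in_prec]
        wreads <- wreads[in_prec, , drop = FALSE]
        s5 <- tr$trimOffset + tr$starOffset
        sig <- signatureFilter(r5, wreads$count, m5, s5,
                               matureCount = aln$count,
                               minCopies = config@minCopies,
                               minConsistency = config@minConsistency)
        if (!sig$accepted) {
            reasons <- c(reasons,
                         if (aln$count <= config@minCopies) "copy_number"
                         else "signature_consistency")
        }
        gen <- precursor_genomic(win, tr$trimOffset, nchar(tr$precursor))
        cand_obj <- new("HairpinCandidate",
            id = cid, seqId = aln$seq_id,
            start = gen[["start"]], end = gen[["end"]], strand = aln$strand,
            precursor = tr$precursor, structure = tr$structure,
            energy = tr$energy,
            matureOffset = tr$matureOffset, matureLength = tr$matureLength,
            starOffset = tr$starOffset, starLength = tr$starLength,
            duplex = dup,
            matureCount = as.numeric(aln$count),
            signatureConsistency = sig$consistency,
            accepted = length(reasons) == 0L,
            rejectionReasons = reasons)
        out[[length(out) + 1L]] <- cand_obj
    }
    # keep accepted unless all requested
    acc <- Filter(isAccepted, out)
    acc <- mergeOverlapping(acc)
    if (all) {
        rej <- Filter(function(x) !isAccepted(x), out)
        res <- c(acc, rej)
    } else res <- acc
    ord <- order(vapply(res, function(x) x@seqId, character(1)),
                 vapply(res, function(x) x@start, integer(1)))
    res[ord]
}

# Merge overlapping accepted precursors (same seq_id and strand), keeping
# the candidate with the highest mature count.
mergeOverlapping <- function(candidates) {
    if (length(candidates) <= 1L) return(candidates)
    keep <- rep(TRUE, length(candidates))
    ord <- order(-vapply(candidates, function(x) x@matureCount, numeric(1)))
    for (i in seq_along(ord)) {
        ci <- ord[i]
        if (!keep[ci]) next
        for (j in seq_along(ord)) {
            cj <- ord[j]
            if (cj == ci || !keep[cj]) next
            a <- candidates[[ci]]; b <- candidates[[cj]]
            if (a@seqId == b@seqId && a@strand == b@strand &&
                max(a@start, b@start) < min(a@end, b@end)) {
                # the lower-count candidate is absorbed
                if (a@matureCount >= b@matureCount) keep[cj] <- FALSE
            }
        }
    }
    candidates[keep]
}
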