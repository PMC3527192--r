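# miRNA target prediction by additive penalty scoring of the antiparallel
# miRNA:mRNA duplex: Watson-Crick match 0, G:U wobble 0.5, mismatch 1, gap
# 1 per gapped position, all doubled within the core (miRNA positions
# 2-13 from the 5' end).  Lower is better; sites scoring <= 4 are
# validation grade.

#' The penalty scoring scheme
#'
#' @param mismatch,gu,gap Per-position penalties (defaults 1, 0.5, 1).
#' @param coreRange 1-based miRNA positions where penalties double
#'   (default 2:13).
#' @param coreMultiplier Core multiplier (default 2).
#' @param reportCutoff Maximum penalty reported by [scanTranscript()]
#'   (default 7).
#' @param validationCutoff Penalty bound for validation-grade sites
#'   (default 4).
#' @return A list of class `ScoringScheme`.
#' @export
scoringScheme <- function(mismatch = 1, gu = 0.5, gap = 1,
                          coreRange = 2:13, coreMultiplier = 2,
                          reportCutoff = 7, validationCutoff = 4) {
    stopifnot(mismatch >= 0, gu >= 0, gap >= 0, coreMultiplier >= 0)
    structure(list(mismatch = mismatch, gu = gu, gap = gap,
                   coreRange = coreRange, coreMultiplier = coreMultiplier,
                   reportCutoff = reportCutoff,
                   validationCutoff = validationCutoff),
              class = "ScoringScheme")
}

# Penalty of pairing miRNA base m (DNA alphabet) against target base t
# (transcript sense strand): the miRNA pairs the target antiparallel, so a
# Watson-Crick pair means t is the complement of m; G:U wobble means
# (m=G, t=T) or (m=T, t=G).
base_penalty <- function(m, t, scheme) {
    wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
          (m == "G" & t == "C") | (m == "C" & t == "G")
    gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
    ifelse(wc, 0, ifelse(gu, scheme$gu, scheme$mismatch))
}

#' Score a miRNA against a target site
#'
#' The miRNA (5'->3') pairs the site (transcript 5'->3') antiparallel:
#' miRNA position i pairs site position L - i + 1.  For an equal-length
#' ungapped comparison; gapped alignments are produced by
#' [scanTranscript()].
#'
#' @param mirna miRNA sequence (RNA or DNA), 5'->3'.
#' @param site Transcript window of the same length, 5'->3'.
#' @param scheme A [scoringScheme()].
#' @return The total penalty.
#' @examples
#' m <- "UGACAGAAGAGAGUGAGCAC"
#' scoreDuplex(m, as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAStringSet(
#'     chartr("U", "T", m)))))  # 0: perfect site
#' @export
scoreDuplex <- function(mirna, site, scheme = scoringScheme()) {
    m <- strsplit(toupper(toDNA(mirna)), "")[[1]]
    t <- strsplit(toupper(toDNA(site)), "")[[1]]
    if (length(m) != length(t))
        stop("ungapped scoring requires equal lengths")
    if (!all(m %in% c("A", "C", "G", "T")) ||
        !all(t %in% c("A", "C", "G", "T")))
        stop("sequences must be over the {A,C,G,U/T} alphabet")
    L <- length(m)
    pen <- base_penalty(m, rev(t), scheme)
    core <- seq_len(L) %in% scheme$coreRange
    sum(ifelse(core, pen * scheme$coreMultiplier, pen))
}

# Score one gapped alignment variant.  gap_type "target_bulge": the site
# window is L+1 nt and the target base opposite the bulge point (between
# miRNA positions gap_pos and gap_pos+1) is unpaired; "mirna_bulge": the
# window is L-1 nt and miRNA position gap_pos is unpaired.
score_gapped <- function(m, t, gap_type, gap_pos, scheme) {
    L <- length(m)
    core <- function(i) i %in% scheme$coreRange
    mult <- function(i) if (core(i)) scheme$coreMultiplier else 1
    total <- 0
    if (gap_type == "target_bulge") {
        # target positions pair miRNA antiparallel skipping one
        trev <- rev(t)                      # now 3'->5' ~ miRNA 5'->3'
        # trev index for miRNA i: i for i <= gap_pos, i+1 afterwards
        for (i in seq_len(L)) {
            j <- if (i <= gap_pos) i else i + 1L
            total <- total + base_penalty(m[i], trev[j], scheme) * mult(i)
        }
        total <- total + scheme$gap * mult(min(gap_pos + 1L, L))
    } else {
        trev <- rev(t)
        for (i in seq_len(L)) {
            if (i == gap_pos) { total <- total + scheme$gap * mult(i); next }
            j <- if (i < gap_pos) i else i - 1L
            total <- total + base_penalty(m[i], trev[j], scheme) * mult(i)
        }
    }
    total
}

#' Scan a transcript for target sites
#'
#' Evaluates every ungapped window plus alignments with at most one
#' single-nucleotide bulge on either strand, and returns non-overlapping
#' sites with penalty at most `scheme$reportCutoff`, sorted by ascending
#' penalty then position.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript Transcript sequence (sense strand).
#' @param scheme A [scoringScheme()].
#' @param gaps Allow single-nucleotide bulges (default TRUE).
#' @param transcriptId Identifier recorded in the result.
#' @return A data.frame (`transcript`, `start`, `end` 0-based half-open,
#'   `penalty`, `gap_type`, `gap_pos`, `cleavage`, `alignment`).
#' @export
scanTranscript <- function(mirna, transcript, scheme = scoringScheme(),
                           gaps = TRUE, transcriptId = "transcript") {
    m <- strsplit(toupper(toDNA(mirna)), "")[[1]]
    tr <- strsplit(toupper(toDNA(transcript)), "")[[1]]
    L <- length(m)
    if (length(tr) < L) stop("transcript shorter than the miRNA")
    core <- seq_len(L) %in% scheme$coreRange
    multv <- ifelse(core, scheme$coreMultiplier, 1)
    hits <- list()
    add_hit <- function(start0, wlen, penalty, gap_type, gap_pos) {
        hits[[length(hits) + 1L]] <<- data.frame(
            transcript = transcriptId, start = start0,
            end = start0 + wlen, penalty = penalty,
            gap_type = gap_type, gap_pos = gap_pos,
            stringsAsFactors = FALSE)
    }
    # ungapped windows
    for (s in 0:(length(tr) - L)) {
        w <- tr[(s + 1L):(s + L)]
        pen <- sum(base_penalty(m, rev(w), scheme) * multv)
        if (pen <= scheme$reportCutoff)
            add_hit(s, L, pen, "none", NA_integer_)
    }
    if (gaps) {
        # one target-side bulge: windows of length L+1
        if (length(tr) >= L + 1L) for (s in 0:(length(tr) - L - 1L)) {
            w <- tr[(s + 1L):(s + L + 1L)]
            for (g in 1:(L - 1L)) {
                pen <- score_gapped(m, w, "target_bulge", g, scheme)
                if (pen <= scheme$reportCutoff)
                    add_hit(s, L + 1L, pen, "target_bulge", g)
            }
        }
        # one miRNA-side bulge: windows of length L-1
        for (s in 0:(length(tr) - L + 1L)) {
            w <- tr[(s + 1L):(s + L - 1L)]
            for (g in 2:(L - 1L)) {
                pen <- score_gapped(m, w, "mirna_bulge", g, scheme)
                if (pen <= scheme$reportCutoff)
                    add_hit(s, L - 1L, pen, "mirna_bulge", g)
            }
        }
    }
    if (length(hits) == 0L)
        return(data.frame(transcript = character(), start = integer(),
                          end = integer(), penalty = numeric(),
                          gap_type = character(), gap_pos = integer(),
                          cleavage = integer(), alignment = character(),
                          stringsAsFactors = FALSE))
    all_hits <- do.call(rbind, hits)
    all_hits <- all_hits[order(all_hits$penalty, all_hits$start,
                               all_hits$gap_type), , drop = FALSE]
    # greedy non-overlap selection in rank order
    kept <- logical(0)
    iv <- matrix(numeric(0), ncol = 2)
    sel <- integer(0)
    for (r in seq_len(nrow(all_hits))) {
        s <- all_hits$start[r]; e <- all_hits$end[r]
        if (nrow(iv) == 0L || all(pmin(iv[, 2], e) <= pmax(iv[, 1], s))) {
            iv <- rbind(iv, c(s, e))
            sel <- c(sel, r)
        }
    }
    out <- all_hits[sel, , drop = FALSE]
    out$cleavage <- vapply(seq_len(nrow(out)), function(r)
        predictCleavage(out[r, ], mirnaLength = L), integer(1))
    out$alignment <- vapply(seq_len(nrow(out)), function(r)
        alignment_text(m, tr, out[r, ], scheme), character(1))
    rownames(out) <- NULL
    out
}

#' Keep validation-grade target sites
#'
#' @param sites A data.frame from [scanTranscript()].
#' @param scheme A [scoringScheme()]; the cutoff is inclusive
#'   (penalty <= 4 by default).
#' @return The subset of `sites` with penalty at most the cutoff.
#' @export
selectValidationCandidates <- function(sites, scheme = scoringScheme()) {
    sites[sites$penalty <= scheme$validationCutoff, , drop = FALSE]
}

#' Predict the cleavage coordinate of a target site
#'
#' Plant ARGONAUTE slices the target between the bases paired to miRNA
#' positions 10 and 11; the reported coordinate is the transcript position
#' (0-based) paired to miRNA position 10, the last base of the 5'
#' cleavage fragment.
#'
#' @param site One row from [scanTranscript()].
#' @param mirnaLength miRNA length in nt.
#' @return Integer transcript coordinate (0-based).
#' @export
predictCleavage <- function(site, mirnaLength) {
    if (mirnaLength < 11L) stop("miRNA shorter than 11 nt")
    L <- mirnaLength
    wlen <- site$end - site$start
    # window position (1-based, 5'->3') paired to miRNA position i:
    # ungapped j = wlen - i + 1; bulges shift the register
    i <- 10L
    if (site$gap_type == "none") {
        j <- wlen - i + 1L
    } else if (site$gap_type == "target_bulge") {
        # miRNA i pairs reversed-window index i (i <= gap) or i+1
        jrev <- if (i <= site$gap_pos) i else i + 1L
        j <- wlen - jrev + 1L
    } else {  # mirna_bulge
        if (i == site$gap_pos)
            stop("cleavage position falls on a bulged miRNA base")
        jrev <- if (i < site$gap_pos) i else i - 1L
        j <- wlen - jrev + 1L
    }
    as.integer(site$start + j - 1L)
}

# Three-line alignment text: target window 5'->3', pairing symbols
# (| Watson-Crick, o G:U, space otherwise), miRNA 3'->5'.
alignment_text <- function(m, tr, site, scheme) {
    w <- tr[(site$start + 1L):site$end]
    L <- length(m)
    if (site$gap_type == "none") {
        mal <- rev(m)
        tal <- w
    } else if (site$gap_type == "target_bulge") {
        mrev <- rev(m)  # 3'->5'
        gp_rev <- length(w) - site$gap_pos  # bulged target index in w
        mal <- append(mrev, "-", after = gp_rev - 1L)
        tal <- w
    } else {
        mal <- rev(m)
        tal <- append(w, "-",
                      after = length(w) - (site$gap_pos - 1L))
    }
    sym <- vapply(seq_along(mal), function(k) {
        if (mal[k] == "-" || tal[k] == "-") return(" ")
        pen <- base_penalty(mal[k], tal[k], scheme)
        if (pen == 0) "|" else if (pen == scheme$gu) "o" else " "
    }, character(1))
    paste0("5' ", toRNA(paste(tal, collapse = "")), " 3' target\n",
           "   ", paste(sym, collapse = ""), "\n",
           "3' ", toRNA(paste(mal, collapse = "")), " 5' miRNA")
}
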