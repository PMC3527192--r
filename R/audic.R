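# Digital expression comparison of tag counts between libraries of unequal
# size with the Audic-Claverie exact test, plus conservation partitions and
# length / 5'-nucleotide composition profiles.

#' Audic-Claverie conditional probability P(y | x)
#'
#' The probability of observing `y` counts in a library of `N2` total tags
#' for a transcript observed `x` times in a library of `N1` total tags:
#' \deqn{P(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' computed in log space via log-gamma.
#'
#' @param x,y Non-negative integer counts.
#' @param N1,N2 Library totals (positive).
#' @return The probability (vectorised over `y`).
#' @examples
#' audicProbability(0, 0, 1e6, 1e6)  # 0.5
#' @export
audicProbability <- function(x, y, N1, N2) {
    if (any(x != round(x)) || any(y != round(y)))
        stop("counts must be integers")
    stopifnot(x >= 0, y >= 0, N1 > 0, N2 > 0)
    r <- N2 / N1
    lp <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r)
    exp(lp)
}

#' Two-sided Audic-Claverie p-value
#'
#' Doubles the smaller tail of the conditional distribution of `y` given
#' `x`, capped at 1: `p = min(1, 2 * min(P(Y <= y), P(Y >= y)))`.  The
#' right tail is computed as `1 - P(Y < y)` with non-negative clamping.
#'
#' @inheritParams audicProbability
#' @return The two-sided p-value.
#' @examples
#' audicPvalue(0, 0, 1e6, 1e6)  # 1
#' audicPvalue(2520, 13690, 6930547, 6498879) < 0.001
#' @export
audicPvalue <- function(x, y, N1, N2) {
    if (x != round(x) || y != round(y)) stop("counts must be integers")
    stopifnot(x >= 0, y >= 0, N1 > 0, N2 > 0)
    left <- sum(audicProbability(x, 0:y, N1, N2))
    right <- if (y == 0L) 1 else max(0, 1 - sum(audicProbability(x, 0:(y - 1L), N1, N2)))
    min(1, 2 * min(left, right))
}

#' Build a CountProfile
#'
#' @param counts Tag-by-sample integer matrix (row names are tags).
#' @param totals Per-sample library totals; defaults to the column sums
#'   (every assigned read counts toward the denominator).
#' @return A [CountProfile-class].
#' @export
countProfile <- function(counts, totals = NULL) {
    counts <- as.matrix(counts)
    if (is.null(totals)) totals <- colSums(counts)
    if (!is.null(names(totals)) && !is.null(colnames(counts)))
        totals <- totals[colnames(counts)]
    totals <- stats::setNames(as.numeric(totals), colnames(counts))
    new("CountProfile", counts = counts, totals = totals)
}

#' Call per-sample miRNA enrichment
#'
#' `one_vs_rest`: sample s is enriched for tag t when the Audic-Claverie
#' p-value of (pooled rest counts, sample count) is below `alpha` and the
#' normalised rate in s exceeds the pooled rest rate.  `pairwise_any`:
#' enriched when significant and higher against at least one other sample.
#'
#' @param profile A [CountProfile-class].
#' @param alpha Significance threshold (default 0.001).
#' @param mode "one_vs_rest" (default) or "pairwise_any".
#' @return A data.frame (`tag`, `sample`, `x`, `y`, `N1`, `N2`, `p`,
#'   `p_adjust` Benjamini-Hochberg across the table, `enriched`).
#' @export
callEnrichment <- function(profile, alpha = 0.001,
                           mode = c("one_vs_rest", "pairwise_any")) {
    mode <- match.arg(mode)
    stopifnot(alpha > 0, alpha < 1)
    counts <- profileCounts(profile)
    totals <- libraryTotals(profile)
    if (ncol(counts) < 2L) stop("at least two samples are required")
    samples <- colnames(counts)
    rows <- list()
    for (t in seq_len(nrow(counts))) for (s in seq_along(samples)) {
        ys <- counts[t, s]; Ns <- totals[s]
        if (mode == "one_vs_rest") {
            xr <- sum(counts[t, -s]); Nr <- sum(totals[-s])
            p <- audicPvalue(xr, ys, Nr, Ns)
            enr <- p < alpha && (ys / Ns) > (xr / Nr)
            rows[[length(rows) + 1L]] <- data.frame(
                tag = rownames(counts)[t], sample = samples[s],
                x = xr, y = ys, N1 = Nr, N2 = Ns, p = p, enriched = enr,
                stringsAsFactors = FALSE)
        } else {
            ps <- vapply(seq_along(samples)[-s], function(o)
                audicPvalue(counts[t, o], ys, totals[o], Ns), numeric(1))
            hi <- vapply(seq_along(samples)[-s], function(o)
                (ys / Ns) > (counts[t, o] / totals[o]), logical(1))
            enr <- any(ps < alpha & hi)
            best <- which.min(ps)
            o <- seq_along(samples)[-s][best]
            rows[[length(rows) + 1L]] <- data.frame(
                tag = rownames(counts)[t], sample = samples[s],
                x = counts[t, o], y = ys, N1 = totals[o], N2 = Ns,
                p = ps[best], enriched = enr, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(tag = character(), sample = character(),
                          x = numeric(), y = numeric(), N1 = numeric(),
                          N2 = numeric(), p = numeric(),
                          enriched = logical(), stringsAsFactors = FALSE)
    # informational only: the protocol applies no multiple-testing control
    out$p_adjust <- stats::p.adjust(out$p, method = "BH")
    out <- out[, c("tag", "sample", "x", "y", "N1", "N2", "p", "p_adjust",
                   "enriched")]
    rownames(out) <- NULL
    out
}

#' Presence/absence conservation partition
#'
#' Assigns every tag to the subset signature of samples it occurs in, the
#' region structure of a Venn diagram.
#'
#' @param tagSets Named list of character vectors (tags per sample).
#' @return A data.frame (`signature`, `n`, `tags`), one row per non-empty
#'   region, signature as sample names joined by "+".
#' @export
conservationPartition <- function(tagSets) {
    stopifnot(length(tagSets) >= 1L)
    samples <- names(tagSets)
    universe <- sort(unique(unlist(tagSets)))
    member <- vapply(tagSets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    sig <- apply(member, 1L, function(row)
        paste(samples[row], collapse = "+"))
    parts <- split(universe, sig)
    out <- data.frame(signature = names(parts),
                      n = vapply(parts, length, integer(1)),
                      tags = vapply(parts, paste, character(1),
                                    collapse = ","),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n, out$signature), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Length by 5'-nucleotide composition profile
#'
#' Read-weighted fractions over tag length (18-26 nt) and first
#' nucleotide; canonical plant miRNAs concentrate at 21 nt with a 5' U.
#'
#' @param tags Clean-tag data.frame (`sequence`, `count`).
#' @param lengths Length range (default 18:26).
#' @return A matrix of fractions, lengths x c("A","C","G","U"); entries
#'   sum to 1.  Marginals via `rowSums`/`colSums`.
#' @export
compositionProfile <- function(tags, lengths = 18:26) {
    if (nrow(tags) == 0L) stop("empty input")
    len <- nchar(tags$sequence)
    first <- toRNA(substr(toupper(tags$sequence), 1L, 1L))
    mat <- matrix(0, nrow = length(lengths), ncol = 4L,
                  dimnames = list(as.character(lengths),
                                  c("A", "C", "G", "U")))
    for (i in seq_len(nrow(tags))) {
        li <- as.character(len[i])
        if (!li %in% rownames(mat)) next
        mat[li, first[i]] <- mat[li, first[i]] + tags$count[i]
    }
    mat / sum(mat)
}
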