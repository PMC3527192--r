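# Independent oracles used across the suite.  Each one deliberately takes
# a different computational path from the package implementation it
# checks.

oracle_bases <- c("A", "C", "G", "T")

oracle_weight <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) 3L
    else if (key %in% c("AT", "TA")) 2L
    else if (key %in% c("GT", "TG")) 1L
    else 0L
}

# Maximum pair weight by the "last position pairs or not" recursion, the
# mirror image of the implementation's "first position" recursion.
oracle_fold_weight <- function(seq, min_loop = 3L) {
    s <- strsplit(toupper(seq), "")[[1]]
    n <- length(s)
    if (n < min_loop + 2L) return(0L)
    wm <- matrix(0L, 4L, 4L, dimnames = list(oracle_bases, oracle_bases))
    for (a in oracle_bases) for (b in oracle_bases)
        wm[a, b] <- oracle_weight(a, b)
    W <- matrix(0L, n, n)
    for (len in (min_loop + 2L):n) {
        for (i in seq_len(n - len + 1L)) {
            j <- i + len - 1L
            best <- W[i, j - 1L]
            ks <- i:(j - min_loop - 1L)
            w <- wm[cbind(s[ks], rep(s[j], length(ks)))]
            hit <- which(w > 0L)
            for (k in ks[hit]) {
                v <- wm[s[k], s[j]] +
                    (if (k > i) W[i, k - 1L] else 0L) +
                    (if (k + 1L <= j - 1L) W[k + 1L, j - 1L] else 0L)
                if (v > best) best <- v
            }
            W[i, j] <- best
        }
    }
    W[1L, n]
}

# Exhaustive enumeration of every non-crossing pairing of a short
# sequence; returns the maximum weight and all pairings achieving it.
oracle_enumerate <- function(seq, min_loop = 3L) {
    s <- strsplit(toupper(seq), "")[[1]]
    n <- length(s)
    best <- list(weight = -1L, pairings = list())
    recurse <- function(i, pairs, weight) {
        if (i > n) {
            if (weight > best$weight) {
                best$weight <<- weight
                best$pairings <<- list(pairs)
            } else if (weight == best$weight) {
                best$pairings[[length(best$pairings) + 1L]] <<- pairs
            }
            return(invisible())
        }
        used <- unlist(pairs)
        if (i %in% used) {  # already paired by an earlier step
            recurse(i + 1L, pairs, weight)
            return(invisible())
        }
        # i unpaired
        recurse(i + 1L, pairs, weight)
        # i paired with an admissible j
        for (j in seq_len(n)) {
            if (j <= i + min_loop || j %in% used) next
            w <- oracle_weight(s[i], s[j])
            if (w == 0L) next
            ok <- TRUE
            for (p in pairs) {
                inside_i <- i > p[1] && i < p[2]
                inside_j <- j > p[1] && j < p[2]
                if (inside_i != inside_j) { ok <- FALSE; break }
            }
            if (!ok) next
            recurse(i + 1L, c(pairs, list(c(i, j))), weight + w)
        }
    }
    # to keep the recursion well-defined, position i may only pair with
    # j > i; unpaired/paired choices cover the whole space
    recurse(1L, list(), 0L)
    best
}

# Audic-Claverie probability by term recurrence (no log-gamma), and the
# two-sided p-value by direct tail summation.
oracle_audic_terms <- function(x, upto, N1, N2) {
    r <- N2 / N1
    terms <- numeric(upto + 1L)
    terms[1L] <- (1 / (1 + r))^(x + 1)
    if (upto >= 1L) for (k in seq_len(upto)) {
        terms[k + 1L] <- terms[k] * (r / (1 + r)) * (x + k) / k
    }
    terms
}

oracle_audic_pvalue <- function(x, y, N1, N2) {
    left <- sum(oracle_audic_terms(x, y, N1, N2))
    # direct right-tail summation until the terms vanish
    k <- y
    r <- N2 / N1
    term <- oracle_audic_terms(x, y, N1, N2)[y + 1L]
    right <- 0
    repeat {
        right <- right + term
        k <- k + 1L
        term <- term * (r / (1 + r)) * (x + k) / k
        if (term < right * 1e-18 && k > y + 10L) break
        if (k > y + 2e6) break
    }
    min(1, 2 * min(left, right))
}

# Naive both-strand exact scan of a tag against a genome string.
oracle_scan <- function(tag, genome_str) {
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tag)))
    f <- gregexpr(tag, genome_str, fixed = TRUE)[[1]]
    r <- gregexpr(rc, genome_str, fixed = TRUE)[[1]]
    out <- data.frame(start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    if (f[1] != -1L)
        out <- rbind(out, data.frame(start = as.integer(f) - 1L,
                                     strand = "+",
                                     stringsAsFactors = FALSE))
    if (r[1] != -1L)
        out <- rbind(out, data.frame(start = as.integer(r) - 1L,
                                     strand = "-",
                                     stringsAsFactors = FALSE))
    out[order(out$start, out$strand), , drop = FALSE]
}

# Brute-force adapter-overlap trimming: leftmost i where the rest of the
# read matches a prefix of the adapter of length >= min_overlap.
oracle_trim <- function(read, adapter, min_overlap) {
    n <- nchar(read)
    for (i in seq_len(n)) {
        ov <- min(nchar(adapter), n - i + 1L)
        if (ov < min_overlap) break
        if (substr(read, i, i + ov - 1L) == substr(adapter, 1L, ov)) {
            if (i == 1L) return(NA_character_)
            return(substr(read, 1L, i - 1L))
        }
    }
    NA_character_
}

# Brute-force best homology hit over all shifts.
oracle_match <- function(tag, catalogue, max_mm, max_shift) {
    best <- NULL
    for (i in seq_len(nrow(catalogue))) {
        ref <- catalogue$sequence[i]
        for (sh in -max_shift:max_shift) {
            tf <- max(1L, 1L - sh); rf <- max(1L, 1L + sh)
            ov <- min(nchar(tag) - tf, nchar(ref) - rf) + 1L
            if (ov <= 0L) next
            if (abs((nchar(tag) - tf) - (nchar(ref) - rf)) > max_shift) next
            a <- strsplit(substr(tag, tf, tf + ov - 1L), "")[[1]]
            b <- strsplit(substr(ref, rf, rf + ov - 1L), "")[[1]]
            mm <- sum(a != b)
            if (mm > max_mm) next
            cand <- list(name = catalogue$name[i], mismatches = mm,
                         shift = sh)
            better <- is.null(best) || mm < best$mismatches ||
                (mm == best$mismatches && abs(sh) < abs(best$shift)) ||
                (mm == best$mismatches && abs(sh) == abs(best$shift) &&
                 cand$name < best$name)
            if (better) best <- cand
        }
    }
    best
}

random_tag <- function(len = 21L) {
    paste(sample(oracle_bases, len, replace = TRUE), collapse = "")
}
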