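rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", s))))

test_that("duplex scoring applies the penalty scheme position by position", {
    m <- "UGACAGAAGAGAGUGAGCAC"
    expect_equal(scoreDuplex(m, rc(m)), 0)
    # a G:U wobble at miRNA position 15 costs 0.5, at position 5 costs 1
    site15 <- strsplit(rc(m), "")[[1]]
    L <- nchar(m)
    # miRNA position i pairs site position L - i + 1 (antiparallel)
    mv <- strsplit(chartr("U", "T", m), "")[[1]]
    gu_at <- function(i) {
        sv <- strsplit(rc(m), "")[[1]]
        stopifnot(mv[i] %in% c("G", "T"))
        sv[L - i + 1] <- if (mv[i] == "G") "T" else "G"
        paste(sv, collapse = "")
    }
    expect_equal(scoreDuplex(m, gu_at(15)), 0.5)
    expect_equal(scoreDuplex(m, gu_at(6)), 1.0)  # the same wobble in core
    expect_error(scoreDuplex(m, substr(rc(m), 1, 10)), "equal lengths")
    expect_error(scoreDuplex("UGAXAGAAGAGAGUGAGCAC", rc(m)), "alphabet")
})

test_that("duplex scores equal a position-by-position oracle", {
    set.seed(90)
    for (i in 1:100) {
        m <- random_tag(21)
        w <- random_tag(21)
        mv <- strsplit(m, "")[[1]]
        wv <- rev(strsplit(w, "")[[1]])
        pen <- 0
        for (p in 1:21) {
            b <- oracle_weight(mv[p], wv[p])
            step <- if (b == 0) 1 else if (b == 1) 0.5 else 0
            if (p >= 2 && p <= 13) step <- step * 2
            pen <- pen + step
        }
        expect_equal(scoreDuplex(m, w), pen, info = paste(m, w))
    }
})

test_that("additivity: permuting non-core penalties keeps the total", {
    set.seed(91)
    m <- random_tag(21)
    w1 <- strsplit(rc(m), "")[[1]]
    w2 <- w1
    # mismatches at two non-core positions, then swapped
    mv <- strsplit(m, "")[[1]]
    bad <- function(b) setdiff(c("A", "C", "G", "T"),
                               c(chartr("ACGT", "TGCA", b),
                                 if (b == "G") "T", if (b == "T") "G"))[1]
    w1[21 - 14 + 1] <- bad(mv[14])
    w2[21 - 18 + 1] <- bad(mv[18])
    expect_equal(scoreDuplex(m, paste(w1, collapse = "")),
                 scoreDuplex(m, paste(w2, collapse = "")))
})

test_that("transcript scanning recovers planted sites in penalty order", {
    set.seed(92)
    m <- "UGACAGAAGAGAGUGAGCAC"
    tp <- plantTarget(m, 2.0, 300L)
    hits <- scanTranscript(m, tp$transcript)
    expect_gte(nrow(hits), 1L)
    expect_equal(hits$penalty[1], 2.0)
    expect_equal(hits$start[1], tp$start)
    # several planted sites come back sorted by penalty; weak sites may be
    # re-aligned with a bulge at a lower cost, so planted scores bound the
    # reported ones from above
    pens <- c(0, 1, 2.5, 4, 6.5)
    parts <- lapply(pens, function(p) plantTarget(m, p, 120L))
    tx <- paste(vapply(parts, `[[`, character(1), "transcript"),
                collapse = "")
    hits2 <- scanTranscript(m, tx)
    expect_true(all(diff(hits2$penalty) >= 0))
    offs <- cumsum(c(0, rep(120L, 4)))
    for (k in seq_along(pens)) {
        planted_start <- offs[k] + parts[[k]]$start
        over <- hits2[hits2$end > planted_start &
                      hits2$start < planted_start + 21L, ]
        expect_gte(nrow(over), 1L)
        expect_lte(over$penalty[1], pens[k])
    }
    # a random transcript has no site under a tight cutoff
    none <- scanTranscript(m, random_tag(400),
                           scoringScheme(reportCutoff = 2))
    expect_equal(nrow(none), 0L)
    expect_error(scanTranscript(m, random_tag(10)), "shorter")
})

test_that("ungapped scanning equals exhaustive window enumeration", {
    set.seed(93)
    m <- random_tag(21)
    tx <- paste0(random_tag(120), rc(m), random_tag(120))
    scheme <- scoringScheme(reportCutoff = 100)
    hits <- scanTranscript(m, tx, scheme, gaps = FALSE)
    # oracle: score every window, sort, greedy non-overlap
    L <- nchar(m)
    all_pen <- vapply(0:(nchar(tx) - L), function(s)
        scoreDuplex(m, substr(tx, s + 1, s + L), scheme), numeric(1))
    ord <- order(all_pen, 0:(nchar(tx) - L))
    taken <- list(); sel <- c()
    for (r in ord) {
        s <- r - 1L
        if (all(vapply(taken, function(iv)
            min(iv[2], s + L) <= max(iv[1], s), logical(1)))) {
            taken[[length(taken) + 1L]] <- c(s, s + L)
            sel <- c(sel, s)
        }
    }
    expect_equal(hits$start, sel)
    expect_equal(hits$penalty, all_pen[sel + 1L])
})

test_that("cutoffs are inclusive and nested", {
    set.seed(94)
    m <- "UGACAGAAGAGAGUGAGCAC"
    sites <- data.frame(penalty = c(0, 2, 4.0, 4.5, 6))
    kept <- selectValidationCandidates(sites)
    expect_equal(kept$penalty, c(0, 2, 4.0))   # 4 kept, 4.5 excluded
    expect_equal(nrow(selectValidationCandidates(sites[0, , drop = FALSE])),
                 0L)
    # lowering the report cutoff returns a prefix of the ranked list
    tx <- paste(vapply(c(0, 1, 3, 5), function(p)
        plantTarget(m, p, 100L)$transcript, character(1)), collapse = "")
    full <- scanTranscript(m, tx, scoringScheme(reportCutoff = 7))
    low <- scanTranscript(m, tx, scoringScheme(reportCutoff = 3))
    expect_equal(low$start, full$start[full$penalty <= 3])
})

test_that("cleavage is predicted opposite miRNA positions 10/11", {
    m <- random_tag(21)
    site <- data.frame(transcript = "t", start = 0L, end = 21L,
                       penalty = 0, gap_type = "none",
                       gap_pos = NA_integer_, stringsAsFactors = FALSE)
    expect_equal(predictCleavage(site, 21L), 11L)
    # a target bulge 3' of the cleavage point shifts the coordinate by 1
    siteb <- data.frame(transcript = "t", start = 0L, end = 22L,
                        penalty = 1, gap_type = "target_bulge",
                        gap_pos = 15L, stringsAsFactors = FALSE)
    expect_equal(predictCleavage(siteb, 21L), predictCleavage(site, 21L) + 1L)
    expect_error(predictCleavage(site, 10L), "shorter")
    # generator-planted site: the cleavage coordinate walks the alignment
    set.seed(95)
    tp <- plantTarget(chartr("T", "U", m), 0, 200L)
    hit <- scanTranscript(chartr("T", "U", m), tp$transcript)
    expect_equal(hit$cleavage[1], hit$start[1] + 21L - 10L)
})
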