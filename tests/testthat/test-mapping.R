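make_genome <- function(s) {
    g <- Biostrings::DNAStringSet(s)
    names(g) <- paste0("chr", seq_along(s))
    g
}

test_that("a planted unique tag maps to exactly its locus", {
    set.seed(50)
    tag <- random_tag(21)
    g <- paste0(random_tag(500), tag, random_tag(480))
    idx <- buildGenomeIndex(make_genome(g), 16)
    hits <- mapExact(tag, idx)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, 500L)
    expect_equal(hits$strand, "+")
    expect_error(mapExact(random_tag(10), idx), "seed length")
    expect_error(buildGenomeIndex(
        Biostrings::DNAStringSet(stats::setNames(c(g, g), c("a", "a")))),
        "duplicate")
})

test_that("minus-strand hits return the reverse complement register", {
    set.seed(51)
    tag <- random_tag(22)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tag)))
    g <- paste0(random_tag(300), rc, random_tag(300))
    idx <- buildGenomeIndex(make_genome(g), 16)
    hits <- mapExact(tag, idx)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$strand, "-")
    slice <- substr(g, hits$start + 1, hits$start + hits$length)
    expect_equal(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(slice))), tag)
})

test_that("a reverse-palindromic tag maps to both strands of one locus", {
    half <- "ACGGTACCGGTA"
    pal <- paste0(half, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(half))))  # 24 nt reverse palindrome
    set.seed(52)
    g <- paste0(random_tag(200), pal, random_tag(200))
    idx <- buildGenomeIndex(make_genome(g), 16)
    hits <- mapExact(pal, idx)
    expect_equal(nrow(hits), 2L)
    expect_setequal(hits$strand, c("-", "+"))
    expect_equal(unique(hits$start), 200L)
})

test_that("index lookups equal a naive both-strand scan", {
    set.seed(53)
    g <- random_tag(20000)
    idx <- buildGenomeIndex(make_genome(g), 16)
    tags <- c(replicate(40, random_tag(sample(18:26, 1))),
              vapply(1:20, function(i) {
                  p <- sample(19900, 1)
                  substr(g, p, p + sample(17:25, 1))
              }, character(1)))
    for (tg in tags) {
        got <- mapExact(tg, idx)
        want <- oracle_scan(tg, g)
        expect_equal(nrow(got), nrow(want), info = tg)
        if (nrow(want))
            expect_equal(got[, c("start", "strand")],
                         want[, c("start", "strand")],
                         ignore_attr = TRUE, info = tg)
    }
})

test_that("strand round-trip mirrors alignment coordinates", {
    set.seed(54)
    g <- random_tag(3000)
    grc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(g)))
    idx <- buildGenomeIndex(make_genome(g), 16)
    idx_rc <- buildGenomeIndex(make_genome(grc), 16)
    for (i in 1:15) {
        p <- sample(2900, 1)
        tg <- substr(g, p, p + 20)
        a <- mapExact(tg, idx)
        b <- mapExact(tg, idx_rc)
        expect_equal(nrow(a), nrow(b))
        # mirrored coordinates with flipped strand
        flip <- data.frame(start = nchar(g) - (b$start + b$length),
                           strand = ifelse(b$strand == "+", "-", "+"),
                           stringsAsFactors = FALSE)
        flip <- flip[order(flip$start, flip$strand), ]
        expect_equal(a$start, flip$start)
        expect_equal(a$strand, flip$strand)
    }
})

test_that("the multi-locus filter keeps <= maxLoci and routes the rest", {
    set.seed(55)
    tag11 <- random_tag(20)
    tag10 <- random_tag(20)
    tag0 <- random_tag(20)
    g <- paste0(paste(rep(paste0(tag11, random_tag(30)), 11), collapse = ""),
                paste(rep(paste0(tag10, random_tag(30)), 10), collapse = ""),
                random_tag(200))
    idx <- buildGenomeIndex(make_genome(g), 16)
    tags <- data.frame(sequence = c(tag11, tag10, tag0),
                       count = c(30L, 40L, 50L), sample_id = "s",
                       stringsAsFactors = FALSE)
    mt <- mapTags(tags, idx, maxLoci = 10L)
    expect_equal(mt$discarded$sequence, tag11)
    expect_true(tag10 %in% mt$kept$sequence)
    expect_equal(mt$unmapped$sequence, tag0)
    # monotonicity: raising maxLoci never discards a previously kept tag
    mt2 <- mapTags(tags, idx, maxLoci = 11L)
    expect_true(all(mt$kept$sequence %in% mt2$kept$sequence))
})

test_that("representative selection takes the count/length/lexical argmax", {
    aln <- function(tag, count, start = 100L, len = nchar(tag),
                    strand = "+")
        data.frame(seq_id = "chr1", start = start, strand = strand,
                   length = len, tag = tag, count = count,
                   sample_id = "s", stringsAsFactors = FALSE)
    g <- rbind(aln("AAAAAAAAAAAAAAAAAAAAG", 30L),
               aln("AAAAAAAAAAAAAAAAAAAAC", 4L),
               aln("AAAAAAAAAAAAAAAAAAAAT", 1L))
    expect_equal(selectRepresentative(g)$count, 30L)
    # count tie: the longer tag wins
    t1 <- rbind(aln(strrep("A", 21), 7L), aln(strrep("A", 22), 7L))
    expect_equal(nchar(selectRepresentative(t1)$tag), 22L)
    # full tie: lexicographically smaller sequence
    t2 <- rbind(aln("TAAAAAAAAAAAAAAAAAAAA", 7L),
                aln("CAAAAAAAAAAAAAAAAAAAA", 7L))
    expect_equal(substr(selectRepresentative(t2)$tag, 1, 1), "C")
    # random groups against an argmax-with-tie-break oracle
    set.seed(56)
    for (rep in 1:20) {
        n <- sample(2:6, 1)
        grp <- do.call(rbind, lapply(seq_len(n), function(i)
            aln(random_tag(sample(19:23, 1)), sample(1:50, 1))))
        got <- selectRepresentative(grp)
        # minus-strand rows in grp would form separate groups; all "+" here
        ord <- order(-grp$count, -grp$length, grp$tag)
        expect_equal(got$tag, grp$tag[ord[1]])
    }
})
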