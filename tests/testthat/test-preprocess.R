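adapter <- "ATCTCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming recovers inserts and rejects unusable reads", {
    insert <- "ACGTACGTACGTACGTACGTA"
    expect_equal(trimAdapter(paste0(insert, adapter)), insert)
    # the adapter alone leaves an empty insert
    expect_true(is.na(trimAdapter(adapter)))
    # no adapter at all: insert length cannot be confirmed
    expect_true(is.na(trimAdapter("ACGTACGTACGTACGTACGTAA")))
    expect_error(trimAdapter(""), "empty")
    # partial adapter prefix at the 3' end
    expect_equal(trimAdapter(paste0(insert, substr(adapter, 1, 8))), insert)
})

test_that("adapter trimming agrees with a brute-force overlap scan", {
    set.seed(41)
    for (i in 1:300) {
        ins_len <- sample(0:30, 1)
        ad_len <- sample(0:nchar(adapter), 1)
        read <- paste0(random_tag(ins_len), substr(adapter, 1, ad_len))
        if (!nzchar(read)) next
        expect_identical(trimAdapter(read, adapter, 6L),
                         oracle_trim(read, adapter, 6L), info = read)
    }
})

test_that("length and ambiguity filter applies the 18-26 nt window", {
    expect_false(filterLengthAmbiguity(random_tag(17)))
    expect_true(filterLengthAmbiguity(random_tag(26)))
    expect_false(filterLengthAmbiguity(random_tag(27)))
    expect_false(filterLengthAmbiguity(paste0(random_tag(20), "N")))
})

test_that("collapsing counts unique tags like an independent tally", {
    one <- rep("ACGTACGTACGTACGTACGTA", 3)
    out <- collapseUnique(one, "s")
    expect_equal(nrow(out), 1L)
    expect_equal(out$count, 3L)
    expect_equal(nrow(collapseUnique(character(0))), 0L)
    set.seed(42)
    reads <- replicate(5000, random_tag(sample(18:26, 1)))
    out <- collapseUnique(reads, "s")
    # independent tally via an environment counter
    env <- new.env()
    for (r in reads) {
        v <- env[[r]]
        env[[r]] <- if (is.null(v)) 1L else v + 1L
    }
    expect_equal(sum(out$count), length(reads))
    for (k in sample(out$sequence, 50))
        expect_equal(out$count[out$sequence == k], env[[k]])
    # deterministic ordering: descending count, then lexicographic
    expect_true(all(diff(out$count) <= 0))
})

test_that("ncRNA filtering removes exact substrings on both strands", {
    ref <- data.frame(name = c("t1", "r1"), class = c("tRNA", "rRNA"),
                      sequence = c(random_tag(80), random_tag(90)),
                      stringsAsFactors = FALSE)
    inside <- substr(ref$sequence[1], 10, 30)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(ref$sequence[2], 5, 25))))
    free <- "TGACAGAAGAGAGTGAGCACA"
    tags <- data.frame(sequence = c(inside, rc, free),
                       count = c(5L, 2L, 9L), sample_id = "s",
                       stringsAsFactors = FALSE)
    out <- filterNcRNA(tags, ref)
    expect_equal(out$removed$sequence, c(inside, rc))
    expect_equal(out$removed$class, c("tRNA", "rRNA"))
    expect_equal(out$kept$sequence, free)
})

test_that("ncRNA partition equals a quadratic substring scan", {
    set.seed(43)
    ref <- data.frame(name = paste0("n", 1:4),
                      class = c("rRNA", "tRNA", "snRNA", "snoRNA"),
                      sequence = replicate(4, random_tag(120)),
                      stringsAsFactors = FALSE)
    tags <- data.frame(
        sequence = c(replicate(30, random_tag(20)),
                     vapply(1:10, function(i) {
                         r <- sample(4, 1)
                         p <- sample(100, 1)
                         substr(ref$sequence[r], p, p + 19)
                     }, character(1))),
        count = 1L, sample_id = "s", stringsAsFactors = FALSE)
    out <- filterNcRNA(tags, ref)
    rcs <- vapply(ref$sequence, function(s)
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s))), character(1))
    naive_hit <- vapply(tags$sequence, function(tg)
        any(vapply(c(ref$sequence, rcs), function(r)
            grepl(tg, r, fixed = TRUE), logical(1))), logical(1))
    expect_setequal(out$removed$sequence, tags$sequence[naive_hit])
    expect_setequal(out$kept$sequence, tags$sequence[!naive_hit])
})

test_that("low-complexity masking drops repeats but keeps the boundary", {
    tags <- function(s) data.frame(sequence = s, count = 1L,
                                   sample_id = "s",
                                   stringsAsFactors = FALSE)
    expect_equal(nrow(maskLowComplexity(tags(strrep("A", 21)))), 0L)
    expect_equal(nrow(maskLowComplexity(tags(strrep("TG", 10)))), 0L)
    expect_equal(nrow(maskLowComplexity(tags("TGACAGAAGAGAGTGAGCAC"))), 1L)
    # exactly 80% of one base is kept: the threshold is strict
    boundary <- paste0(strrep("A", 16), "CGTC")
    freq <- max(table(strsplit(boundary, "")[[1]])) / nchar(boundary)
    expect_equal(freq, 0.8)
    expect_equal(nrow(maskLowComplexity(tags(boundary))), 1L)
})

test_that("the pre-processing stage conserves read counts and is idempotent", {
    set.seed(44)
    config <- pipelineConfig()
    inserts <- replicate(400, random_tag(sample(c(15:28), 1)))
    reads <- data.frame(
        id = paste0("r", seq_along(inserts)),
        sequence = substr(paste0(inserts, adapter), 1, 36),
        quality = strrep("I", nchar(substr(paste0(inserts, adapter), 1, 36))),
        stringsAsFactors = FALSE)
    ncrna <- data.frame(name = "t", class = "tRNA",
                        sequence = random_tag(100),
                        stringsAsFactors = FALSE)
    out <- preprocessSample(reads, "s1", ncrna, config)
    rep <- out$report
    # chaining: every stage starts from the previous stage's survivors
    expect_equal(rep$reads_in[-1], rep$reads_out[-nrow(rep)])
    expect_equal(rep$reads_in[1], nrow(reads))
    expect_equal(sum(out$tags$count), rep$reads_out[nrow(rep)])
    # surviving tags satisfy the clean-tag invariants
    expect_true(all(nchar(out$tags$sequence) >= 18))
    expect_true(all(nchar(out$tags$sequence) <= 26))
    expect_false(any(grepl("N", out$tags$sequence)))
    expect_true(all(out$tags$count >= 1))
    expect_equal(anyDuplicated(out$tags$sequence), 0L)
    # idempotence of the tag-level filters
    again <- maskLowComplexity(filterNcRNA(out$tags, ncrna)$kept)
    expect_identical(again, out$tags)
})
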