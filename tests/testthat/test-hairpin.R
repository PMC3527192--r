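test_that("window extraction covers the tag plus margin, clipped", {
    set.seed(70)
    g <- Biostrings::DNAStringSet(random_tag(10000))
    names(g) <- "chr1"
    aln <- list(seq_id = "chr1", start = 5000L, strand = "+", length = 21L)
    w <- extractWindow(aln, g, 500L)
    expect_equal(nchar(w$sequence), 1021L)
    expect_equal(w$matureOffset, 500L)
    # left clipping at the contig start
    aln2 <- list(seq_id = "chr1", start = 100L, strand = "+", length = 21L)
    w2 <- extractWindow(aln2, g, 500L)
    expect_equal(nchar(w2$sequence), 621L)
    expect_equal(w2$matureOffset, 100L)
    expect_error(extractWindow(list(seq_id = "chr1", start = 9990L,
                                    strand = "+", length = 21L), g, 500L),
                 "outside")
})

test_that("minus-strand windows round-trip through the mirrored genome", {
    set.seed(71)
    g_str <- random_tag(4000)
    g <- Biostrings::DNAStringSet(g_str); names(g) <- "chr1"
    grc <- Biostrings::reverseComplement(g); names(grc) <- "chr1"
    aln <- list(seq_id = "chr1", start = 2000L, strand = "-", length = 21L)
    w <- extractWindow(aln, g, 300L)
    # same window from the reverse-complemented genome on the plus strand
    aln_m <- list(seq_id = "chr1",
                  start = 4000L - (2000L + 21L), strand = "+",
                  length = 21L)
    w_m <- extractWindow(aln_m, grc, 300L)
    expect_equal(w$sequence, w_m$sequence)
    expect_equal(w$matureOffset, w_m$matureOffset)
})

test_that("trim-and-refold spans the arms plus margin", {
    set.seed(72)
    win <- random_tag(1021)
    tr <- trimAndRefold(win, 480L, 21L, 560L, 21L, 15L)
    expect_equal(tr$trimOffset, 465L)
    expect_equal(nchar(tr$precursor), 596L - 465L)
    expect_equal(tr$matureOffset, 480L - 465L)
    expect_equal(tr$starOffset, 560L - 465L)
    # margin larger than the window: the precursor is the window
    small <- random_tag(80)
    tr2 <- trimAndRefold(small, 5L, 21L, 50L, 21L, 500L)
    expect_equal(tr2$precursor, small)
})

test_that("planted hairpins report their constructed duplex", {
    set.seed(73)
    # perfect duplex: no mismatches, 2-nt overhangs by construction
    m <- paste0("T", random_tag(20))
    hp <- synthesizePrecursor(m, mismatches = 0L, bulge = 0L,
                              loopLength = 20L)
    f <- foldBaseline(hp$precursor)
    st <- findStar(f$structure, hp$matureOffset, hp$matureLength)
    expect_false(is.null(st))
    expect_lte(abs(st$starOffset - hp$starOffset), 2L)
    dup <- duplexReport(f$structure, hp$matureOffset, hp$matureLength,
                        st$starOffset, st$starLength)
    expect_equal(dup$mismatches, 0L)
    expect_equal(dup$largest_asymmetric_bulge, 0L)
    expect_equal(dup$overhang_3p_mature, 2L)
    expect_equal(dup$overhang_3p_star, 2L)
    # planted mismatches stay bounded by the construction
    for (i in 1:10) {
        k <- sample(1:3, 1)
        hp <- synthesizePrecursor(paste0("T", random_tag(20)),
                                  mismatches = k, bulge = 0L,
                                  loopLength = sample(15:40, 1))
        f <- foldBaseline(hp$precursor)
        st <- findStar(f$structure, hp$matureOffset, hp$matureLength)
        dup <- duplexReport(f$structure, hp$matureOffset,
                            hp$matureLength, st$starOffset, st$starLength)
        expect_lte(dup$mismatches, k)
        expect_gte(dup$mismatches, 1L)
    }
    # a planted asymmetric bulge is reported at its size
    hp <- synthesizePrecursor(paste0("T", random_tag(20)),
                              mismatches = 0L, bulge = 2L,
                              loopLength = 25L)
    f <- foldBaseline(hp$precursor)
    st <- findStar(f$structure, hp$matureOffset, hp$matureLength)
    dup <- duplexReport(f$structure, hp$matureOffset, hp$matureLength,
                        st$starOffset, st$starLength)
    expect_equal(dup$largest_asymmetric_bulge, 2L)
    expect_error(synthesizePrecursor(m, mismatches = 5L), "design range")
})

test_that("star location refuses loops and under-paired matures", {
    hp <- synthesizePrecursor("TGACAGAAGAGAGTGAGCACA", 0L, 0L, 24L)
    f <- foldBaseline(hp$precursor)
    # an interval inside the terminal loop has no pairing partner arm
    loop_off <- hp$matureLength + 8L
    expect_null(findStar(f$structure, loop_off, 8L))
    # fewer than half the bases paired outside: all-dot structure
    expect_null(findStar(strrep(".", 60), 10L, 21L))
})

test_that("plant criteria fail for the stated defect classes", {
    hp <- synthesizePrecursor("TGACAGAAGAGAGTGAGCACA", 0L, 0L, 20L)
    f <- foldBaseline(hp$precursor)
    st <- findStar(f$structure, hp$matureOffset, hp$matureLength)
    ok <- checkPlantCriteria(f$structure, hp$matureOffset,
                             hp$matureLength, st$starOffset, st$starLength)
    expect_true(ok$accepted)
    expect_length(ok$reasons, 0L)
    # five duplex mismatches exceed the threshold
    bad_dup <- list(mismatches = 5L, largest_asymmetric_bulge = 0L,
                    overhang_3p_mature = 2L, overhang_3p_star = 2L,
                    paired_fraction_mature = 0.9)
    bad <- checkPlantCriteria(f$structure, hp$matureOffset,
                              hp$matureLength, st$starOffset,
                              st$starLength, duplex = bad_dup)
    expect_true("duplex_mismatches" %in% bad$reasons)
    # overlapping arms
    ov <- checkPlantCriteria(f$structure, 0L, 21L, 10L, 21L)
    expect_true("arm_overlap" %in% ov$reasons)
    expect_false(ov$accepted)
})

test_that("the signature filter scores read stacking at duplex ends", {
    # all reads start exactly at the mature 5' end
    s <- signatureFilter(rep(100L, 100), rep(1L, 100), 100L, 160L,
                         matureCount = 100)
    expect_equal(s$consistency, 1)
    expect_true(s$accepted)
    # the copy gate is strict: 25 copies are rejected
    s25 <- signatureFilter(100L, 25L, 100L, 160L, matureCount = 25)
    expect_false(s25$accepted)
    s26 <- signatureFilter(100L, 26L, 100L, 160L, matureCount = 26)
    expect_true(s26$accepted)
    # uniform read placement over a long window is inconsistent
    set.seed(74)
    pos <- sample(0:1020, 1000, replace = TRUE)
    su <- signatureFilter(pos, rep(1L, 1000), 500L, 560L, matureCount = 50)
    near <- sum(abs(pos - 500L) <= 2 | abs(pos - 560L) <= 2)
    expect_equal(su$consistency, near / 1000)
    expect_false(su$accepted)
})

test_that("discovery recovers planted hairpins and rejects background", {
    cfg <- simulationConfig(seed = 201, genomeLength = 20000L,
                            nHairpins = 5L,
                            samples = c(s1 = 6000))
    sim <- generateGenome(cfg)
    reads <- simulateSample(sim, "s1")
    pc <- pipelineConfig()
    pp <- preprocessSample(reads$reads, "s1", sim$ncrna, pc)
    idx <- buildGenomeIndex(sim$genome, pc@seedLength)
    acc <- callMirnas(pp$tags, idx, pc)
    mats <- vapply(acc, function(x) chartr("U", "T", matureSequence(x)), "")
    expect_gte(sum(sim$truth$mature %in% mats), 4L)
    # merging is idempotent on the accepted set
    expect_identical(crossmiR:::mergeOverlapping(acc), acc)
    # accepted candidates satisfy their class invariants
    for (cd in acc) expect_true(methods::validObject(cd))
    # empty input
    expect_equal(callMirnas(pp$tags[0, ], idx, pc), list())
})
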