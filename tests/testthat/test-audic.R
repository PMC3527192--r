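test_that("the conditional probability matches closed-form points", {
    expect_equal(audicProbability(0, 0, 1e6, 1e6), 0.5)
    expect_equal(audicProbability(1, 0, 5e5, 5e5), 0.25)
    expect_error(audicProbability(1.5, 0, 1, 1), "integer")
    # extended-precision style recurrence agreement
    p <- audicProbability(5, 15, 1e4, 1e4)
    want <- oracle_audic_terms(5, 15, 1e4, 1e4)[16]
    expect_lt(abs(p - want) / want, 1e-12)
})

test_that("the distribution normalises and the p-value caps at one", {
    expect_equal(audicPvalue(0, 0, 1e6, 1e6), 1)
    # sum over y reaches 1 for moderate x
    for (x in c(0, 10, 100)) {
        s <- sum(audicProbability(x, 0:(20 * x + 200), 1e5, 1e5))
        expect_gte(s, 1 - 1e-9)
        expect_lte(s, 1 + 1e-9)
    }
})

test_that("p-values are scale invariant in the library totals", {
    for (c_scale in c(0.5, 3.7, 10)) {
        expect_equal(audicPvalue(12, 213, 5400748, 6930547),
                     audicPvalue(12, 213, 5400748 * c_scale,
                                 6930547 * c_scale))
    }
})

test_that("p-values match direct tail summation on random inputs", {
    set.seed(100)
    for (i in 1:200) {
        x <- sample(0:120, 1)
        y <- sample(0:(200 - x), 1)
        N1 <- sample(1000:1e6, 1)
        N2 <- sample(1000:1e6, 1)
        expect_lt(abs(audicPvalue(x, y, N1, N2) -
                      oracle_audic_pvalue(x, y, N1, N2)), 1e-10)
    }
})

test_that("the doubled-tail test holds its size at high replication", {
    # tail doubling with the observed point in both tails is slightly
    # conservative; at 20,000 null pairs the size estimate is tight
    # enough (sd ~0.0015) to pin the test's true level near nominal
    set.seed(104)
    n <- 20000
    x <- stats::rpois(n, 500); y <- stats::rpois(n, 500)
    p <- vapply(seq_len(n), function(i)
        audicPvalue(x[i], y[i], 1e6, 1e6), numeric(1))
    expect_gt(mean(p < 0.05), 0.040)
    expect_lt(mean(p < 0.05), 0.055)
    expect_gt(mean(p < 0.01), 0.007)
    expect_lt(mean(p < 0.01), 0.013)
})

test_that("published count profiles flag the enriched cultivar", {
    totals <- c(Vital = 5400748, Maroussia = 6498879,
                Sympathy = 6456832, Haedang = 6930547)
    counts <- rbind(miR396e = c(6309, 13690, 7655, 2520))
    colnames(counts) <- names(totals)
    prof <- countProfile(counts, totals)
    enr <- callEnrichment(prof, alpha = 0.001, mode = "one_vs_rest")
    expect_true(enr$enriched[enr$sample == "Maroussia"])
    expect_false(enr$enriched[enr$sample == "Haedang"])
    # equal counts and totals: nothing is enriched
    flat <- countProfile(rbind(t1 = c(50, 50)), c(a = 1e5, b = 1e5))
    expect_false(any(callEnrichment(flat, 0.001)$enriched))
    expect_error(callEnrichment(countProfile(rbind(t1 = 5),
                                             c(a = 100))), "two samples")
})

test_that("conservation partitions are complete and disjoint", {
    four <- stats::setNames(rep(list(paste0("t", 1:10)), 4),
                            c("V", "M", "S", "H"))
    full <- conservationPartition(four)
    expect_equal(nrow(full), 1L)
    expect_equal(full$signature, "V+M+S+H")
    expect_equal(full$n, 10L)
    disjoint <- list(a = c("x1", "x2"), b = c("y1"), c = c("z1", "z2"))
    dj <- conservationPartition(disjoint)
    expect_setequal(dj$signature, c("a", "b", "c"))
    expect_equal(sum(dj$n), 5L)
    # random sets against membership enumeration
    set.seed(101)
    uni <- paste0("tag", 1:300)
    sets <- lapply(1:4, function(i) sample(uni, sample(50:250, 1)))
    names(sets) <- c("w", "x", "y", "z")
    part <- conservationPartition(sets)
    expect_equal(sum(part$n), length(unique(unlist(sets))))
    for (r in sample(nrow(part), 5)) {
        tag1 <- strsplit(part$tags[r], ",")[[1]][1]
        want <- paste(names(sets)[vapply(sets, function(s)
            tag1 %in% s, logical(1))], collapse = "+")
        expect_equal(part$signature[r], want)
    }
})

test_that("composition profiles recover planted fractions", {
    all_u <- data.frame(sequence = c("TGACAGAAGAGAGTGAGCACA",
                                     "TGGAGAAGCAGGGCACGTGCA"),
                        count = c(3L, 1L), stringsAsFactors = FALSE)
    cp <- compositionProfile(all_u)
    expect_equal(sum(cp), 1)
    expect_equal(unname(cp["21", "U"]), 1)
    two <- data.frame(sequence = c(random_tag(21), random_tag(24)),
                      count = c(3L, 1L), stringsAsFactors = FALSE)
    cp2 <- compositionProfile(two)
    expect_equal(unname(rowSums(cp2)[c("21", "24")]), c(0.75, 0.25))
    expect_error(compositionProfile(two[0, ]), "empty")
    # multinomial draw at n = 1e5: planted 65% 21-U / 12% 21-A recovered
    set.seed(102)
    n <- 1e5
    draw <- stats::rmultinom(1, n, c(u21 = 0.65, a21 = 0.12, other = 0.23))
    tags <- data.frame(
        sequence = c(paste0("T", random_tag(20)),
                     paste0("A", random_tag(20)),
                     paste0("C", random_tag(23))),
        count = as.integer(draw), stringsAsFactors = FALSE)
    cp3 <- compositionProfile(tags)
    expect_lt(abs(cp3["21", "U"] - 0.65), 0.01)
    expect_lt(abs(cp3["21", "A"] - 0.12), 0.01)
})
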