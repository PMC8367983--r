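test_that("detection filter masks <=5-read transcripts with the placeholder", {
    s <- data.frame(transcript_id = c("t5", "t6", "t100"),
                    n_reads = c(5L, 6L, 100L),
                    mean_tail = c(33, 44, 55), median_tail = c(33, 44, 55),
                    geom_mean_tail = c(30, 40, 50), sample_id = "s")
    f <- applyMinReadFilter(s)
    expect_equal(f$placeholder_flag, c(TRUE, FALSE, FALSE))
    expect_equal(f$mean_tail, c(0.01, 44, 55))   # 5 reads -> masked
    expect_equal(f$median_tail[1], 0.01)
    expect_equal(f$geom_mean_tail[1], 0.01)
    expect_equal(f$n_reads, c(5L, 6L, 100L))     # raw counts retained

    allLow <- applyMinReadFilter(data.frame(
        transcript_id = c("a", "b"), n_reads = c(1L, 3L),
        mean_tail = c(10, 20), median_tail = c(10, 20),
        geom_mean_tail = c(10, 20), sample_id = "s"))
    expect_true(all(allLow$placeholder_flag))
    expect_equal(nrow(allLow), 2L)               # nothing dropped
})

test_that("library-size normalization hits the display scale exactly", {
    one <- makeSummary("only", 1234L, 40)
    expect_equal(one$norm_count, 1600000)

    two <- makeSummary(c("a", "b"), c(500L, 500L), c(40, 40))
    expect_equal(two$norm_count, c(800000, 800000))

    s <- data.frame(transcript_id = letters[1:4],
                    n_reads = c(10L, 40L, 100L, 850L),
                    mean_tail = 40, median_tail = 40, geom_mean_tail = 40,
                    sample_id = "s")
    n1 <- normalizeLibrarySize(applyMinReadFilter(s), qpcrCoefficient = 1)
    n05 <- normalizeLibrarySize(applyMinReadFilter(s), qpcrCoefficient = 0.5)
    expect_equal(n05$norm_count, n1$norm_count * 0.5)
    expect_equal(n05$log2_abundance, n1$log2_abundance - 1)

    expect_error(normalizeLibrarySize(data.frame(
        transcript_id = "a", n_reads = 0L, mean_tail = 1,
        median_tail = 1, geom_mean_tail = 1, sample_id = "s")), "zero")
})

test_that("placeholder records keep 0.01 and the sum invariant holds", {
    s <- data.frame(transcript_id = letters[1:3],
                    n_reads = c(3L, 100L, 900L),
                    mean_tail = c(20, 30, 40), median_tail = c(20, 30, 40),
                    geom_mean_tail = c(20, 30, 40), sample_id = "s")
    n <- normalizeLibrarySize(applyMinReadFilter(s), qpcrCoefficient = 0.8)
    expect_equal(n$norm_count[1], 0.01)
    expect_true(is.na(n$log2_abundance[1]))
    # library total includes the masked transcript's 3 reads
    expect_equal(sum(n$norm_count[-1]),
                 1600000 * (1000 / 1003) * 0.8)
})

test_that("expression bins follow the printed boundaries", {
    bins <- binByExpression(c(-9, -10, -10.5, -11.999, -12, -13, -14, -15))
    expect_equal(as.character(bins),
                 c("high", "high",            # -10 assigned upward
                   "mod_high", "mod_high",
                   "mod_min", "mod_min",      # -12 belongs to mod_min
                   "minimal", "minimal"))     # -14 belongs to minimal
    expect_error(binByExpression(NaN), "NaN")
    expect_true(is.na(binByExpression(NA_real_)[1]))

    # monotone: higher abundance never maps to a lower bin
    x <- sort(runif(200, -20, -5))
    idx <- as.integer(factor(binByExpression(x), levels = EXPRESSION_BINS))
    expect_true(all(diff(idx) <= 0))
})

test_that("scale invariance: doubling raw counts changes no bin", {
    set.seed(9)
    s <- data.frame(transcript_id = sprintf("t%03d", 1:200),
                    n_reads = as.integer(rpois(200, 50) + 6L),
                    mean_tail = runif(200, 20, 60), median_tail = 40,
                    geom_mean_tail = 35, sample_id = "s")
    n1 <- normalizeLibrarySize(applyMinReadFilter(s))
    s2 <- s; s2$n_reads <- s$n_reads * 2L
    n2 <- normalizeLibrarySize(applyMinReadFilter(s2))
    expect_equal(n1$log2_abundance, n2$log2_abundance)
    expect_equal(as.character(n1$bin), as.character(n2$bin))
})

test_that("ncRNA load ratio counts all annotated loci of the class", {
    ann <- toyAnnotation(c("m1", "m2", "c1", "c2", "s1"),
                         c("mRNA", "mRNA", "CUT", "CUT", "sn_snoRNA"))
    s <- data.frame(transcript_id = c("m1", "m2", "c1"),
                    n_reads = c(600L, 400L, 100L),
                    mean_tail = 40, median_tail = 40, geom_mean_tail = 40,
                    sample_id = "s")
    r <- ncRNALoadRatio(s, ann)
    expect_equal(unname(r["CUT"]), 0.1)        # 100 / 1000
    expect_equal(unname(r["sn_snoRNA"]), 0)    # annotated but no reads
    expect_equal(unname(r["rRNA"]), 0)

    # random toy table vs brute-force two-sum recomputation
    set.seed(13)
    for (i in 1:5) {
        ids <- sprintf("f%02d", 1:30)
        bts <- sample(c("mRNA", "CUT", "SUT", "rRNA"), 30, replace = TRUE)
        bts[1] <- "mRNA"
        ann <- toyAnnotation(ids, bts)
        cnt <- as.integer(rpois(30, 40) + 1L)
        s <- data.frame(transcript_id = ids, n_reads = cnt, mean_tail = 40,
                        median_tail = 40, geom_mean_tail = 40,
                        sample_id = "s")
        r <- ncRNALoadRatio(s, ann)
        for (b in c("CUT", "SUT", "rRNA"))
            expect_equal(unname(r[b]),
                         sum(cnt[bts == b]) / sum(cnt[bts == "mRNA"]))
    }
    expect_error(ncRNALoadRatio(
        data.frame(transcript_id = "c1", n_reads = 5L, mean_tail = 1,
                   median_tail = 1, geom_mean_tail = 1, sample_id = "s"),
        toyAnnotation("c1", "CUT")), "denominator")
})
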