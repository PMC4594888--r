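test_that("alignment scoring matches hand evaluation of the rules", {
    mir <- "UGACAGAAGAGAGUGAGCACA"     # 21 nt
    site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(chartr("U", "T", mir))))
    expect_equal(scoreAlignment(mir, site)$score, 0)
    # G:U opposite miRNA position 5: 0.5 doubled inside [2,13] -> 1.0
    # miRNA pos 5 is "A"; make it G so target T gives a wobble
    mir5 <- sub("^(....)A", "\\1G", mir)
    site5 <- site  # target still has T at the pairing position
    stopifnot(substr(mir5, 5, 5) == "G",
              substr(site5, 21 - 5 + 1, 21 - 5 + 1) == "T")
    a5 <- scoreAlignment(mir5, site5)
    expect_equal(a5$score, 1.0)
    expect_equal(a5$gu, 1L)
    expect_equal(a5$mismatches, 0L)
    # plain mismatch at position 20 (outside the doubled region) -> 1.0
    b <- strsplit(site, "")[[1]]
    pos20 <- 21 - 20 + 1
    b[pos20] <- "C"  # miRNA pos 20 is "C"; C:C never pairs
    stopifnot(substr(mir, 20, 20) == "C")
    a20 <- scoreAlignment(mir, paste(b, collapse = ""))
    expect_equal(a20$score, 1.0)
    expect_equal(a20$mismatches, 1L)
    expect_error(scoreAlignment(mir, "ACGU"), "equal lengths")
})

test_that("scoring equals the per-position penalty oracle on random pairs", {
    set.seed(44)
    for (i in 1:200) {
        mir <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
        site <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
        expect_equal(scoreAlignment(mir, site)$score,
                     oracleAlignmentScore(mir, site))
    }
})

test_that("candidate scanning finds planted sites and respects thresholds", {
    set.seed(6)
    tx <- replicate(10, paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                              collapse = ""))
    names(tx) <- sprintf("t%02d", 1:10)
    mir <- c(m1 = paste(sample(c("A", "C", "G", "U"), 21, TRUE),
                        collapse = ""))
    site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(chartr("U", "T", mir))))
    substr(tx["t03"], 301, 321) <- site
    hits <- scanCandidates(mir, tx, maxScore = 4)
    planted <- hits[hits$transcript_id == "t03" & hits$score == 0, ]
    expect_equal(nrow(planted), 1L)
    expect_equal(planted$target_start, 301L)
    expect_equal(planted$slice_pos, 301L + 21L - 10L)
    # unsatisfiable threshold
    expect_equal(nrow(scanCandidates(mir, tx, maxScore = -1)), 0L)
    # shuffled miRNA against random transcripts: essentially no hits
    shuf <- c(s1 = paste(sample(strsplit(as.character(mir), "")[[1]]),
                         collapse = ""))
    expect_lt(nrow(scanCandidates(shuf, tx, maxScore = 4)), 5L)
})

test_that("degradome categories rank the slice signal correctly", {
    prof <- numeric(400)
    prof[10] <- 50; prof[200] <- 3; prof[300] <- 2
    expect_equal(categorize(prof, 10), 0L)   # unique maximum
    prof2 <- prof; prof2[90] <- 50
    expect_equal(categorize(prof2, 10), 1L)  # tied maximum
    # masses {50, 10, 3, 2}: median 6.5, so 10 is above-median (cat 2)
    # and 3 is at/below median (cat 3)
    prof4 <- numeric(400)
    prof4[10] <- 50; prof4[90] <- 10; prof4[200] <- 3; prof4[300] <- 2
    expect_equal(categorize(prof4, 90), 2L)
    expect_equal(categorize(prof4, 200), 3L)
    prof3 <- numeric(400); prof3[10] <- 1; prof3[50] <- 10
    expect_equal(categorize(prof3, 10), 4L)  # single read
    expect_true(is.na(categorize(prof3, 11)))
    expect_error(categorize(prof3, 500), "outside")
})

test_that("degradome validation applies read thresholds and tolerance", {
    cand <- data.frame(mirna_id = "m1", transcript_id = "t1",
                       target_start = 90L, target_end = 110L,
                       slice_pos = 101L, score = 0, mismatches = 0L,
                       gu = 0L)
    mkProf <- function(v) SignalProfileSet(list(t1 = v), libraryId = "Dc")
    v <- numeric(300); v[101] <- 100
    hit <- validateWithDegradome(cand, mkProf(v))
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$peak_reads, 100)
    expect_equal(hit$category, 0L)
    # zero profile -> no hit
    expect_equal(nrow(validateWithDegradome(cand, mkProf(numeric(300)))), 0L)
    # peak displaced by 2 nt: missed at tolerance 0, found at tolerance 2
    v2 <- numeric(300); v2[103] <- 100
    expect_equal(nrow(validateWithDegradome(cand, mkProf(v2))), 0L)
    hit2 <- validateWithDegradome(cand, mkProf(v2), offsetTolerance = 2)
    expect_equal(nrow(hit2), 1L)
    expect_equal(hit2$matched_pos, 103L)
    # single-read slice: category 4 accepted at >= 1 read
    v3 <- numeric(300); v3[101] <- 1; v3[50] <- 30
    hit3 <- validateWithDegradome(cand, mkProf(v3))
    expect_equal(hit3$category, 4L)
    # fractional sub-read mass is not a category-4 hit
    v4 <- numeric(300); v4[101] <- 0.5; v4[50] <- 30
    expect_equal(nrow(validateWithDegradome(cand, mkProf(v4))), 0L)
    # candidate without a profile is dropped and counted
    cand2 <- rbind(cand, within(cand, transcript_id <- "t9"))
    out <- validateWithDegradome(cand2, mkProf(v))
    expect_equal(attr(out, "dropped"), 1L)
})

test_that("hit tables are deterministically ordered", {
    set.seed(9)
    tx <- replicate(4, paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                             collapse = ""))
    names(tx) <- c("b", "d", "a", "c")
    mir <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(chartr("U", "T", mir))))
    for (nm in names(tx)) substr(tx[nm], 101, 121) <- site
    mirs <- c(m2 = mir, m1 = mir)
    hits <- scanCandidates(mirs, tx, maxScore = 0)
    expect_equal(hits$mirna_id, sort(hits$mirna_id))
    ord <- order(hits$mirna_id, hits$transcript_id, hits$slice_pos)
    expect_equal(ord, seq_len(nrow(hits)))
})
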