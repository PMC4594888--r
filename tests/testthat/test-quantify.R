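test_that("mapTags agrees with the brute-force scan oracle", {
    set.seed(7)
    ts <- makeToyTranscripts()
    seqs <- as.character(sequences(ts))
    # tags: exact substrings, 1-mismatch variants, 2-mismatch variants,
    # and random 20-mers
    mk <- function(tx, s) substr(seqs[tx], s, s + 19L)
    mut <- function(tag, k) {
        b <- strsplit(tag, "")[[1]]
        at <- sample(20, k)
        b[at] <- vapply(b[at], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
        paste(b, collapse = "")
    }
    tags <- c(mk("t1", 31), mk("t1", 5), mk("t2", 2),
              mut(mk("t1", 12), 1), mut(mk("t2", 25), 1),
              mut(mk("t1", 40), 2),
              replicate(5, paste(sample(c("A", "C", "G", "T"), 20,
                                        TRUE), collapse = "")))
    for (mm in c(0L, 1L)) {
        got <- mapTags(tags, ts, maxMismatch = mm)$assignments
        want <- bruteForceMap(tags, seqs, maxMismatch = mm)
        expect_equal(got[, c("tag", "reference_id", "pos")], want,
                     ignore_attr = TRUE)
    }
})

test_that("multi-mapping tags report every locus and 2-mismatch tags none", {
    ts <- makeToyTranscripts()
    seqs <- as.character(sequences(ts))
    shared <- substr(seqs["t1"], 31, 50)   # present in both transcripts
    res <- mapTags(shared, ts)
    expect_equal(nrow(res$assignments), 2L)
    expect_setequal(res$assignments$reference_id, c("t1", "t2"))
    expect_equal(res$assignments$n_loci, c(2L, 2L))
    two <- sub("^..", "GG", substr(seqs["t1"], 5, 24))
    stopifnot(substr(seqs["t1"], 5, 6) != "GG")
    res2 <- mapTags(two, ts, maxMismatch = 1)
    expect_equal(nrow(res2$assignments), 0L)
    expect_equal(res2$unmatchedTags, 1)
})

test_that("tags with non-ACGT letters are skipped and counted", {
    ts <- makeToyTranscripts()
    res <- mapTags(c("ACGTNACGTNACGTNACGTN"), ts)
    expect_equal(res$skippedTags, 1)
    expect_equal(nrow(res$assignments), 0L)
})

test_that("profile mass is conserved and split equally across loci", {
    ts <- makeToyTranscripts()
    seqs <- as.character(sequences(ts))
    shared <- substr(seqs["t1"], 31, 50)
    uniqueTag <- substr(seqs["t1"], 5, 24)
    tags <- c(rep(shared, 10), rep(uniqueTag, 7))
    asg <- mapTags(tags, ts)
    prof <- buildProfiles(asg, ts, libraryId = "lib")
    p1 <- profiles(prof)[["t1"]]; p2 <- profiles(prof)[["t2"]]
    expect_equal(p1[31], 5.0)    # 10 copies split over 2 loci
    expect_equal(p2[11], 5.0)
    expect_equal(p1[5], 7.0)     # unique tag keeps full mass
    expect_equal(sum(p1) + sum(p2), asg$totalMatchedMass)
    expect_equal(totalMass(prof), 17)
})

test_that("RPM follows its definition and is scale invariant", {
    ts <- makeToyTranscripts()
    prof <- SignalProfileSet(
        list(t1 = c(numeric(100), 50),
             t2 = numeric(50)), libraryId = "x", totalMass = 1e6)
    rpm <- geneRPM(prof, ts, totalMapped = 1e6)
    expect_equal(unname(rpm["g1"]), 50)
    expect_equal(unname(rpm["g2"]), 0)
    dbl <- SignalProfileSet(list(t1 = c(numeric(100), 100),
                                 t2 = numeric(50)),
                            libraryId = "x", totalMass = 2e6)
    expect_equal(geneRPM(dbl, ts, totalMapped = 2e6), rpm)
    expect_error(geneRPM(prof, ts, totalMapped = 0), "> 0")
})

test_that("RPM table sums to 1e6 times the matched fraction", {
    sim <- simulateExperiment(smallSimConfig())
    asg <- mapTags(sim$pareLibraries$Dc_rep1, sim$transcripts)
    prof <- buildProfiles(asg, sim$transcripts, "Dc_rep1")
    rpm <- geneRPM(prof, sim$transcripts)
    expect_equal(sum(rpm), 1e6)          # denominator = matched mass
    tot <- length(sim$pareLibraries$Dc_rep1)
    rpm2 <- geneRPM(prof, sim$transcripts, totalMapped = tot)
    expect_equal(sum(rpm2), 1e6 * totalMass(prof) / tot)
})

test_that("FPKM follows its definition", {
    ts <- TranscriptSet(
        c(a = strrep("ACGT", 500), b = strrep("ACGT", 250)),
        data.frame(transcript_id = c("a", "b"), gene_id = c("ga", "gb"),
                   utr5_start = c(1, 1), utr5_end = c(30, 30),
                   cds_start = c(31, 31), cds_end = c(1930, 930),
                   utr3_start = c(1931, 931), utr3_end = c(2000, 1000),
                   intron_count = 0))
    counts <- c(ga = 100, gb = 100)
    f <- geneFPKM(counts, ts, libraryTotal = 1e6)
    expect_equal(unname(f["ga"]), 50)            # 100 / (2 * 1)
    expect_equal(unname(f["ga"] / f["gb"]), 0.5) # length 2:1 -> FPKM 1:2
    expect_equal(unname(geneFPKM(c(ga = 0, gb = 0), ts, 1e6)["ga"]), 0)
    expect_error(geneFPKM(counts, ts, libraryTotal = 0), "> 0")
})

test_that("replicate merging averages values and reports log-scale r^2", {
    a <- c(g1 = 10, g2 = 20, g3 = 0)
    expect_error(mergeReplicates(list(a)), ">= 2")
    m <- mergeReplicates(list(a, a))
    expect_equal(m$r_squared, 1.0)
    expect_equal(unname(m$mean["g1"]), 10)
    m2 <- mergeReplicates(list(c(g1 = 10, g2 = 20), c(g1 = 20, g2 = 10)))
    expect_equal(m2$r_squared, 1.0)   # two points are always collinear
    expect_equal(unname(m2$mean), c(15, 15))
    expect_error(mergeReplicates(list(a, c(g9 = 1, g2 = 2, g3 = 3))),
                 "identical gene sets")
})

test_that("replicates of a simulated library correlate strongly", {
    sim <- simulateExperiment(smallSimConfig())
    rpm <- lapply(c("Dc_rep1", "Dc_rep2"), function(nm) {
        asg <- mapTags(sim$pareLibraries[[nm]], sim$transcripts)
        geneRPM(buildProfiles(asg, sim$transcripts, nm), sim$transcripts)
    })
    m <- mergeReplicates(rpm)
    expect_gt(m$r_squared, 0.9)
})
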