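test_that("the generator is deterministic under a fixed seed", {
    cfg <- smallSimConfig()
    a <- simulateExperiment(cfg)
    b <- simulateExperiment(cfg)
    expect_identical(as.character(sequences(a$transcripts)),
                     as.character(sequences(b$transcripts)))
    expect_identical(a$truth, b$truth)
    expect_identical(as.character(a$pareLibraries$Dc_rep1),
                     as.character(b$pareLibraries$Dc_rep1))
    expect_identical(a$rnaseqCounts, b$rnaseqCounts)
})

test_that("transcript construction rules hold and GC tracks the target", {
    cfg <- simConfig(nGenes = 500, gcTarget = 0.5, seed = 2,
                     nPlantedTargets = 0)
    ts <- simulateTranscriptome(cfg)
    ft <- featureTable(ts)
    seqs <- as.character(sequences(ts))
    cds <- substr(seqs, ft$cds_start, ft$cds_end)
    expect_true(all(substr(cds, 1, 3) == "ATG"))
    expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                    c("TAA", "TAG", "TGA")))
    expect_true(all(nchar(cds) %% 3 == 0))
    gc <- mean(vapply(seqs, function(s)
        nchar(gsub("[^GC]", "", s)) / nchar(s), numeric(1)))
    expect_lt(abs(gc - 0.5), 0.02)
    # ordered region structure
    expect_true(all(ft$utr5_end < ft$cds_start &
                    ft$cds_end < ft$utr3_start))
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(lengthRange = c(100, 300)), "200")
    expect_error(simConfig(peakFraction = 1.5), "fraction")
    expect_error(simConfig(decayTypeFractions = c(I = 0.8, II = 0.4)),
                 "sum")
    expect_error(simConfig(pareDepth = 0), "depth")
    expect_error(simConfig(hairpinModeFractions = c(loop_last = 0.5)),
                 "sum to 1")
})

test_that("hairpins have stem-loop geometry with a near-complementary star", {
    cfg <- smallSimConfig()
    mset <- simulateMirnaSet(cfg)
    expect_true(all(Biostrings::width(mset$mirnas) %in% 20:22))
    info <- hairpinInfo(mset$hairpins)
    seqs <- as.character(sequences(mset$hairpins))
    # miRNA interval never overlaps the loop
    expect_true(all(info$mir_end < info$loop_start |
                    info$mir_start > info$loop_end))
    expect_true(all(info$loop_end - info$loop_start + 1L >= 8L))
    # reverse complement of the 5'-arm strand aligned to the 3'-arm
    # strand has <= 3 mispairs (2-nt overhang shifts the register by 2)
    for (i in seq_len(nrow(info))) {
        iv5 <- if (info$mir_start[i] < info$loop_start[i])
            c(info$mir_start[i], info$mir_end[i]) else
            c(info$star_start[i], info$star_end[i])
        iv3 <- if (info$mir_start[i] > info$loop_end[i])
            c(info$mir_start[i], info$mir_end[i]) else
            c(info$star_start[i], info$star_end[i])
        # the 3' strand pairs the region two nt upstream of the 5' strand
        paired <- substr(seqs[i], iv5[1] - 2L, iv5[2] - 2L)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(paired)))
        a <- strsplit(rc, "")[[1]]
        b <- strsplit(substr(seqs[i], iv3[1], iv3[2]), "")[[1]]
        expect_lte(sum(a != b), 3L)
    }
})

test_that("planted sites are perfect complements at the recorded slice", {
    cfg <- smallSimConfig()
    ts <- simulateTranscriptome(cfg)
    mset <- simulateMirnaSet(cfg)
    pl <- plantTargets(ts, mset$mirnas, cfg)
    expect_equal(nrow(pl$targets) + pl$skipped, cfg$nPlantedTargets)
    seqs <- as.character(sequences(pl$transcripts))
    for (k in seq_len(nrow(pl$targets))) {
        tr <- pl$targets[k, ]
        site <- substr(seqs[tr$transcript_id], tr$site_start, tr$site_end)
        mir <- as.character(mset$mirnas[[tr$mirna_id]])
        expect_equal(scoreAlignment(mir, site)$score, 0)
        # slice position bookkeeping: site start + (L - 10)
        expect_equal(tr$slice_pos, tr$site_start + nchar(mir) - 10L)
    }
})

test_that("PARE libraries have fixed depth and planted peak mass", {
    cfg <- smallSimConfig()
    sim <- simulateExperiment(cfg)
    for (lib in names(sim$pareLibraries))
        expect_equal(length(sim$pareLibraries[[lib]]), cfg$pareDepth)
    # degenerate mixture: peakFraction = 1 puts every tag of a target
    # transcript at its planted slice site
    cfg1 <- simConfig(nGenes = 10, nMirnas = 2, nPlantedTargets = 10,
                      pareDepth = 2000, peakFraction = 1, seed = 9)
    ts <- simulateTranscriptome(cfg1)
    mset <- simulateMirnaSet(cfg1)
    pl <- plantTargets(ts, mset$mirnas, cfg1)
    decay <- plantDecayTypes(pl$transcripts, cfg1)
    lib <- simulatePareLibrary(pl$transcripts, decay, pl$targets, cfg1)
    tp <- lib$truthProfile
    byTx <- split(tp, tp$transcript_id)
    slice <- split(pl$targets$slice_pos, pl$targets$transcript_id)
    for (tx in names(byTx))
        expect_true(all(byTx[[tx]]$pos %in% slice[[tx]]))
})

test_that("planted degradation effects show the expected tag ratio", {
    # a type-I up gene with effect 2 should have Dd/Dc tag ratio near 4
    cfg <- simConfig(nGenes = 100, nPlantedTargets = 0, pareDepth = 1e5,
                     decayTypeFractions = c(I = 0.2), seed = 31)
    ts <- simulateTranscriptome(cfg)
    decay <- plantDecayTypes(ts, cfg)
    dc <- simulatePareLibrary(ts, decay, NULL, cfg, "control", 1)
    dd <- simulatePareLibrary(ts, decay, NULL, cfg, "treated", 1)
    nC <- vapply(split(dc$truthProfile$count, dc$truthProfile$transcript_id),
                 sum, numeric(1))
    nT <- vapply(split(dd$truthProfile$count, dd$truthProfile$transcript_id),
                 sum, numeric(1))
    up <- decay$gene_id[decay$decay_type == "I" & decay$direction == 1]
    txUp <- featureTable(ts)$transcript_id[
        featureTable(ts)$gene_id %in% up]
    for (tx in txUp) {
        cC <- nC[tx]; cT <- nT[tx]
        if (is.na(cC) || cC < 25) next
        # binomial sampling bound on the ratio: 3 SD on each count
        expect_lt(abs(cT / cC - 4), 3 * sqrt(4 / cC + 16 / cT) + 0.5)
    }
})

test_that("RNA-seq counts approach the Poisson limit as dispersion -> 0", {
    cfg <- simConfig(nGenes = 500, nPlantedTargets = 0, nbDispersion = 0,
                     rnaseqDepth = 5e5, seed = 17)
    ts <- simulateTranscriptome(cfg)
    decay <- plantDecayTypes(ts, cfg)
    m <- simulateRnaseqCounts(ts, decay, cfg)
    # replicate pairs share a mean; (x1 - x2)^2 / 2 estimates the variance
    x1 <- m[, "Rc_rep1"]; x2 <- m[, "Rc_rep2"]
    mu <- (x1 + x2) / 2
    keep <- mu > 5
    ratio <- mean(((x1 - x2)[keep]) ^ 2 / 2) / mean(mu[keep])
    expect_lt(abs(ratio - 1), 0.15)
    # type-II genes have no transcription effect
    cfg2 <- simConfig(nGenes = 200, nPlantedTargets = 0,
                      decayTypeFractions = c(II = 0.5), seed = 18)
    ts2 <- simulateTranscriptome(cfg2)
    d2 <- plantDecayTypes(ts2, cfg2)
    m2 <- simulateRnaseqCounts(ts2, d2, cfg2)
    ii <- d2$decay_type == "II"
    rat <- sum(m2[ii, c("Rd_rep1", "Rd_rep2")]) /
           sum(m2[ii, c("Rc_rep1", "Rc_rep2")])
    expect_lt(abs(log2(rat)), 0.2)
})
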