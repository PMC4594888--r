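test_that("cut sites follow the PARE fragment bookkeeping", {
    # duplex strands at [39,59] (5' arm) and [80,100] (3' arm)
    seqs <- paste(rep("A", 140), collapse = "")
    hp <- HairpinSet(c(h = seqs),
        data.frame(hairpin_id = "h", mir_start = 39, mir_end = 59,
                   star_start = 80, star_end = 100,
                   loop_start = 60, loop_end = 79, arm = "five_prime"))
    s <- locateCutSites(hp, 1)
    expect_equal(s$proximal_pos, 80L)   # upper cut of the 3' arm
    expect_equal(s$distal_pos, 101L)    # one past the 3' strand end
    expect_equal(s$arm5_distal, 39L)
    expect_equal(s$arm5_proximal, 60L)
    # sites are defined by the duplex, not by which strand is mature
    hp2 <- HairpinSet(c(h = seqs),
        data.frame(hairpin_id = "h", mir_start = 80, mir_end = 100,
                   star_start = 39, star_end = 59,
                   loop_start = 60, loop_end = 79, arm = "three_prime"))
    s2 <- locateCutSites(hp2, 1)
    expect_equal(s2[c("proximal_pos", "distal_pos")],
                 s[c("proximal_pos", "distal_pos")])
    # all four positions within the sequence
    len <- nchar(seqs)
    expect_true(all(unlist(s[1:4]) >= 1 & unlist(s[1:4]) <= len))
})

test_that("hairpin profiling shares the global multi-mapper split", {
    hp <- makeToyHairpin()
    hseq <- as.character(sequences(hp))
    tag <- substr(hseq, 11, 30)
    prof <- profileHairpins(rep(tag, 4), hp)
    expect_equal(profiles(prof)[["hp1"]][11], 4)
    # a tag present in both a hairpin and an mRNA splits 0.5/0.5
    ts <- makeToyTranscripts()
    seqs <- as.character(sequences(ts))
    shared <- substr(seqs["t1"], 5, 24)
    hp2seq <- paste0(substr(hseq, 1, 40), shared,
                     substr(hseq, 61, nchar(hseq)))
    hp2 <- HairpinSet(c(hp1 = hp2seq), as.data.frame(hairpinInfo(hp)))
    prof2 <- profileHairpins(shared, hp2, transcripts = ts)
    expect_equal(profiles(prof2)[["hp1"]][41], 0.5)
    # no matching tags: empty profile
    prof3 <- profileHairpins("TTTTTTTTTTTTTTTTTTTT", hp)
    expect_equal(sum(profiles(prof3)[["hp1"]]), 0)
})

test_that("mode classification follows the decision cascade", {
    sites <- list(proximal_pos = 80L, distal_pos = 101L)
    mk <- function(d, p, extra = 0, extraPos = 10L) {
        v <- numeric(140); v[101] <- d; v[80] <- p; v[extraPos] <- extra
        v
    }
    expect_equal(classifyMode(mk(20, 1), sites)$mode, "loop_last")
    expect_equal(classifyMode(mk(1, 20), sites)$mode, "loop_first")
    expect_equal(classifyMode(mk(10, 10), sites)$mode, "ambiguous")
    expect_equal(classifyMode(mk(2, 1), sites)$mode, "no_signal")
    # signal away from both cut sites -> dispersed
    expect_equal(classifyMode(mk(2, 2, extra = 20), sites)$mode,
                 "dispersed")
    # bookkeeping: distal + proximal + other = total
    v <- mk(12, 5, extra = 7)
    cm <- classifyMode(v, sites)
    expect_equal(cm$distal_mass + cm$proximal_mass + 7, cm$total_mass)
})

test_that("raising the dominance never rescues an ambiguous call", {
    sites <- list(proximal_pos = 80L, distal_pos = 101L)
    set.seed(10)
    for (i in 1:30) {
        v <- numeric(140)
        v[101] <- rpois(1, 10); v[80] <- rpois(1, 10); v[30] <- rpois(1, 3)
        m1 <- classifyMode(v, sites, dominance = 1.5)$mode
        m2 <- classifyMode(v, sites, dominance = 3)$mode
        if (m1 == "ambiguous")
            expect_true(m2 %in% c("ambiguous", "dispersed", "no_signal"))
    }
})

test_that("5'-arm fraction drives the simultaneity verdict", {
    v <- numeric(140); v[101] <- 30
    a <- armSimultaneity(v, loopStart = 60)
    expect_equal(a$arm5_fraction, 0)
    expect_equal(a$verdict, "simultaneous-compatible")
    v2 <- v; v2[20] <- 30
    a2 <- armSimultaneity(v2, loopStart = 60)
    expect_equal(a2$arm5_fraction, 0.5)
    expect_equal(a2$verdict, "non-simultaneous signal")
    expect_equal(armSimultaneity(numeric(140), 60)$verdict, "no_signal")
})

test_that("mid-duplex signals are flagged away from interval ends", {
    hp <- makeToyHairpin()   # mir [11,31], star [47,67]
    v <- numeric(97); v[21] <- 10
    out <- detectMidDuplex(v, hp, 1)
    expect_true(out$flag)
    expect_equal(out$positions, 21L)
    # boundary positions are excluded by the margin
    v2 <- numeric(97); v2[11] <- 10; v2[31] <- 10; v2[12] <- 10
    expect_false(detectMidDuplex(v2, hp, 1)$flag)
    expect_false(detectMidDuplex(numeric(97), hp, 1)$flag)
    # below the read threshold
    v3 <- numeric(97); v3[21] <- 2
    expect_false(detectMidDuplex(v3, hp, 1, minReads = 3)$flag)
})

test_that("planted processing modes are recovered from simulated tags", {
    cfg <- simConfig(nGenes = 10, nMirnas = 2, nPlantedTargets = 0,
                     pareDepth = 1000, nHairpins = 40,
                     hairpinTagFraction = 1, seed = 77)
    mset <- simulateMirnaSet(cfg)
    hp <- simulateHairpinTags(mset$hairpins, cfg)
    prof <- profileHairpins(hp$tags, mset$hairpins)
    calls <- classifyHairpins(prof, mset$hairpins)
    m <- merge(calls, hp$truth, by = "hairpin_id")
    planted <- m[m$has_tags & m$mode.y %in% c("loop_last", "loop_first"), ]
    expect_gt(nrow(planted), 10)
    expect_true(all(planted$mode.x == planted$mode.y))
    expect_gte(mean(planted$arm5_verdict == "simultaneous-compatible"),
               0.95)
})
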