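# Tiny hand-built fixtures shared across test files.

makeToyTranscripts <- function() {
    # two transcripts; t2 shares a 20-mer with t1 (positions 31..50 of t1
    # == positions 11..30 of t2) so multi-mapping is exercised
    core <- "ACGTACGGTTCAGGCATCAA"
    s1 <- paste0(strrep("A", 4), "ATG",
                 "GGCATTACGGATCTAGCCGTAAA", core, strrep("C", 17),
                 "TAA", strrep("T", 10))
    s2 <- paste0(strrep("G", 4), "ATG", "TTT", core, strrep("A", 27),
                 "TGA", strrep("C", 10))
    TranscriptSet(
        c(t1 = s1, t2 = s2),
        data.frame(
            transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
            utr5_start = c(1, 1), utr5_end = c(4, 4),
            cds_start = c(5, 5), cds_end = c(nchar(s1) - 10, nchar(s2) - 10),
            utr3_start = c(nchar(s1) - 9, nchar(s2) - 9),
            utr3_end = c(nchar(s1), nchar(s2)),
            intron_count = c(2, 0)))
}

# a hairpin with pad5 1..10, 5'-arm strand 11..31, loop 32..46,
# 3'-arm strand 47..67, pad3 68..97
makeToyHairpin <- function(arm = "five_prime") {
    pad5 <- "ACGTACGTAC"
    arm5 <- "GGCAUUACGGAUCUAGCCGUA"
    arm5 <- chartr("U", "T", arm5)
    loop <- "TTTTTAAAAATTTTT"
    arm3 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(arm5)))
    pad3 <- strrep("A", 30)
    seqs <- paste0(pad5, arm5, loop, arm3, pad3)
    iv5 <- c(11L, 31L); iv3 <- c(47L, 67L)
    mi <- if (arm == "five_prime") iv5 else iv3
    st <- if (arm == "five_prime") iv3 else iv5
    HairpinSet(c(hp1 = seqs),
               data.frame(hairpin_id = "hp1",
                          mir_start = mi[1], mir_end = mi[2],
                          star_start = st[1], star_end = st[2],
                          loop_start = 32L, loop_end = 46L, arm = arm))
}

smallSimConfig <- function(...) {
    simConfig(nGenes = 40, nMirnas = 4, nPlantedTargets = 8,
              pareDepth = 2e4, rnaseqDepth = 1e5, nHairpins = 12,
              hairpinTagFraction = 0.5, seed = 42, ...)
}
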