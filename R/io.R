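#' @include AllClasses.R
#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom rtracklayer import export
NULL

#' Read PARE tag reads from FASTA or FASTQ
#'
#' @param path File path; `.fastq`/`.fq` (optionally gzipped) is read as
#'   FASTQ, anything else as FASTA.
#' @return A [Biostrings::DNAStringSet].
#' @export
readTags <- function(path) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
    readDNAStringSet(path, format = fmt)
}

.tsGRanges <- function(transcripts) {
    ft <- featureTable(transcripts)
    mk <- function(type, s, e, id) {
        keep <- !is.na(s) & !is.na(e)
        GRanges(ft$transcript_id[keep], IRanges(s[keep], e[keep]),
                strand = "+", type = type,
                ID = paste0(id, ft$transcript_id[keep]),
                Parent = ft$transcript_id[keep])
    }
    lens <- transcriptLengths(transcripts)
    mrna <- GRanges(ft$transcript_id, IRanges(1L, unname(lens)),
                    strand = "+", type = "mRNA",
                    ID = ft$transcript_id, Parent = ft$gene_id)
    mrna$intron_count <- ft$intron_count
    mrna$gene_id <- ft$gene_id
    u5 <- mk("five_prime_UTR", ft$utr5_start, ft$utr5_end, "utr5:")
    cds <- mk("CDS", ft$cds_start, ft$cds_end, "cds:")
    cds$phase <- 0L
    u3 <- mk("three_prime_UTR", ft$utr3_start, ft$utr3_end, "utr3:")
    suppressWarnings(c(mrna, u5, cds, u3))
}

#' Write a TranscriptSet as FASTA + GFF3
#'
#' Coordinates are transcript-space, 1-based inclusive; the mRNA feature
#' carries `gene_id` and `intron_count` attributes.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param fastaPath,gffPath Output paths.
#' @return Invisibly, the paths.
#' @export
writeTranscriptSet <- function(transcripts, fastaPath, gffPath) {
    writeXStringSet(sequences(transcripts), fastaPath)
    export(.tsGRanges(transcripts), gffPath, format = "gff3")
    invisible(c(fastaPath, gffPath))
}

#' Read a TranscriptSet from FASTA + GFF3
#'
#' Expects the layout written by [writeTranscriptSet()]: transcript-space
#' `mRNA`, `five_prime_UTR`, `CDS` and `three_prime_UTR` features with
#' the transcript id as the sequence name.
#'
#' @param fastaPath,gffPath Input paths.
#' @return A [TranscriptSet-class].
#' @export
readTranscriptSet <- function(fastaPath, gffPath) {
    seqs <- readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    gr <- import(gffPath, format = "gff3")
    byType <- split(gr, gr$type)
    mrna <- byType[["mRNA"]]
    ids <- as.character(GenomicRanges::seqnames(mrna))
    pick <- function(type, col) {
        g <- byType[[type]]
        if (is.null(g)) return(rep(NA_integer_, length(ids)))
        i <- match(ids, as.character(GenomicRanges::seqnames(g)))
        v <- if (col == "start") GenomicRanges::start(g) else
            GenomicRanges::end(g)
        as.integer(v[i])
    }
    ft <- data.frame(
        transcript_id = ids,
        gene_id = as.character(mrna$gene_id),
        utr5_start = pick("five_prime_UTR", "start"),
        utr5_end = pick("five_prime_UTR", "end"),
        cds_start = pick("CDS", "start"),
        cds_end = pick("CDS", "end"),
        utr3_start = pick("three_prime_UTR", "start"),
        utr3_end = pick("three_prime_UTR", "end"),
        intron_count = as.integer(mrna$intron_count))
    TranscriptSet(seqs[ids], ft)
}

#' Write / read a HairpinSet (FASTA + TSV)
#'
#' The TSV has columns `hairpin_id`, `mir_start`, `mir_end`,
#' `star_start`, `star_end`, `arm` plus `loop_start`, `loop_end`. When
#' the loop columns are absent on read, the loop is taken to fill the gap
#' between the two duplex strands.
#'
#' @param hairpins A [HairpinSet-class].
#' @param fastaPath,tsvPath File paths.
#' @return `writeHairpinSet`: invisibly the paths; `readHairpinSet`: a
#'   [HairpinSet-class].
#' @export
writeHairpinSet <- function(hairpins, fastaPath, tsvPath) {
    writeXStringSet(sequences(hairpins), fastaPath)
    utils::write.table(as.data.frame(hairpinInfo(hairpins)), tsvPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fastaPath, tsvPath))
}

#' @rdname writeHairpinSet
#' @export
readHairpinSet <- function(fastaPath, tsvPath) {
    seqs <- readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    info <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
    if (!"loop_start" %in% colnames(info)) {
        fiveEnd <- pmin(info$mir_end, info$star_end)
        threeStart <- pmax(info$mir_start, info$star_start)
        info$loop_start <- fiveEnd + 1L
        info$loop_end <- threeStart - 1L
    }
    HairpinSet(seqs[info$hairpin_id], info)
}

#' Write signal profiles as a sparse bedGraph-like TSV
#'
#' One row per non-zero position: `reference_id`, `pos`, `mass`.
#'
#' @param profileSet A [SignalProfileSet-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeProfiles <- function(profileSet, path) {
    prof <- profiles(profileSet)
    rows <- lapply(names(prof), function(id) {
        v <- prof[[id]]
        nz <- which(v > 0)
        if (!length(nz)) return(NULL)
        data.frame(reference_id = id, pos = nz, mass = v[nz])
    })
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(df))
        df <- data.frame(reference_id = character(), pos = integer(),
                         mass = numeric())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a complete simulated experiment to plain-text files
#'
#' Writes `transcripts.fa`, `genes.gff3`, `mirnas.fa`, `hairpins.fa`,
#' `hairpins.tsv`, `pare_<cond>_<rep>.fa`, `hairpin_tags.fa`,
#' `rnaseq_counts.tsv` and the truth tables
#' (`truth_targets.tsv`, `truth_decay.tsv`, `truth_hairpins.tsv`).
#'
#' @param sim Result of [simulateExperiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fp <- function(x) file.path(dir, x)
    writeTranscriptSet(sim$transcripts, fp("transcripts.fa"),
                       fp("genes.gff3"))
    writeXStringSet(sim$mirnas, fp("mirnas.fa"))
    writeHairpinSet(sim$hairpins, fp("hairpins.fa"), fp("hairpins.tsv"))
    for (nm in names(sim$pareLibraries))
        writeXStringSet(sim$pareLibraries[[nm]],
                        fp(sprintf("pare_%s.fa", nm)))
    if (length(sim$hairpinTags))
        writeXStringSet(sim$hairpinTags, fp("hairpin_tags.fa"))
    utils::write.table(sim$rnaseqCounts, fp("rnaseq_counts.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    wt <- function(x, f) if (!is.null(x))
        utils::write.table(x, fp(f), sep = "\t", quote = FALSE,
                           row.names = FALSE)
    wt(sim$truth$targets, "truth_targets.tsv")
    wt(sim$truth$decay, "truth_decay.tsv")
    wt(sim$truth$hairpins, "truth_hairpins.tsv")
    invisible(dir)
}
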