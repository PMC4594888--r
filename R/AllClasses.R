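#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges NumericList
#' @importFrom Biostrings DNAStringSet width
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges NumericList
#' @importClassesFrom Biostrings DNAStringSet
NULL

## Central containers. TranscriptSet couples the (spliced) transcript
## sequences with the gene-model bookkeeping every per-gene quantity needs:
## UTR/CDS coordinates in transcript space and the intron count carried over
## from the genomic model. HairpinSet does the same for miRNA precursors
## (duplex-strand and loop coordinates). SignalProfileSet holds one PARE
## library's per-position 5'-end signal after multi-mapper splitting.

#' TranscriptSet: transcript sequences plus gene-model annotation
#'
#' Couples spliced transcript sequences with per-transcript annotation:
#' gene assignment, 1-based inclusive 5'UTR/CDS/3'UTR intervals in
#' transcript coordinates (NA start/end when the region is absent) and the
#' intron count of the genomic model. All per-gene quantities downstream
#' (signal profiles, RPM/FPKM, sequence features) are keyed on this object.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of spliced transcripts,
#'   names are transcript identifiers.
#' @slot features A [S4Vectors::DataFrame] with one row per transcript:
#'   `transcript_id`, `gene_id`, `utr5_start`, `utr5_end`, `cds_start`,
#'   `cds_end`, `utr3_start`, `utr3_end`, `intron_count`.
#'
#' @seealso [TranscriptSet()], [readTranscriptSet()], [simulateTranscriptome()]
#' @exportClass TranscriptSet
setClass("TranscriptSet",
    slots = c(sequences = "DNAStringSet", features = "DataFrame"))

.validTranscriptSet <- function(object) {
    msg <- character()
    ft <- object@features
    need <- c("transcript_id", "gene_id", "utr5_start", "utr5_end",
              "cds_start", "cds_end", "utr3_start", "utr3_end",
              "intron_count")
    if (!all(need %in% colnames(ft)))
        return(paste("features must have columns:",
                     paste(setdiff(need, colnames(ft)), collapse = ", ")))
    if (length(object@sequences) != nrow(ft))
        msg <- c(msg, "one feature row per sequence required")
    else {
        if (!identical(names(object@sequences),
                       as.character(ft$transcript_id)))
            msg <- c(msg, "sequence names must equal features$transcript_id")
        len <- width(object@sequences)
        cs <- ft$cds_start; ce <- ft$cds_end
        if (any(is.na(cs) | is.na(ce)))
            msg <- c(msg, "every transcript needs a CDS interval")
        else {
            if (any(cs < 1L | ce > len | cs > ce))
                msg <- c(msg, "CDS interval out of bounds")
            has5 <- !is.na(ft$utr5_start)
            if (any(has5 & (ft$utr5_start < 1L | ft$utr5_end >= cs)))
                msg <- c(msg, "5'UTR must precede the CDS within bounds")
            has3 <- !is.na(ft$utr3_start)
            if (any(has3 & (ft$utr3_start <= ce | ft$utr3_end > len)))
                msg <- c(msg, "3'UTR must follow the CDS within bounds")
        }
        if (any(ft$intron_count < 0L, na.rm = TRUE))
            msg <- c(msg, "intron_count must be >= 0")
        bad <- grepl("[^ACGTN]", as.character(object@sequences))
        if (any(bad))
            msg <- c(msg, "sequences must be uppercase ACGT(N)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of spliced transcript sequences.
#' @param features `data.frame` or `DataFrame` of per-transcript annotation
#'   (see the class description for required columns). Missing UTRs are
#'   encoded as `NA` start/end.
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet(
#'   c(t1 = "AAAAATGGGTTGATTT"),
#'   data.frame(transcript_id = "t1", gene_id = "g1",
#'              utr5_start = 1, utr5_end = 4, cds_start = 5, cds_end = 13,
#'              utr3_start = 14, utr3_end = 16, intron_count = 2))
#' transcriptLengths(ts)
#' @export
TranscriptSet <- function(sequences, features) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- DNAStringSet(sequences)
    ft <- DataFrame(features)
    ft$transcript_id <- as.character(ft$transcript_id)
    ft$gene_id <- as.character(ft$gene_id)
    for (col in c("utr5_start", "utr5_end", "cds_start", "cds_end",
                  "utr3_start", "utr3_end", "intron_count"))
        ft[[col]] <- as.integer(ft[[col]])
    new("TranscriptSet", sequences = sequences, features = ft)
}

#' HairpinSet: miRNA precursor sequences with duplex coordinates
#'
#' Precursor (pre-miRNA) hairpin sequences annotated with the 1-based
#' inclusive intervals of the miRNA and miRNA* duplex strands, the loop
#' interval separating them, and which arm (5' or 3') carries the mature
#' miRNA. A miR319-like precursor releasing two distinct duplexes is
#' represented as two records sharing one sequence.
#'
#' @slot sequences [Biostrings::DNAStringSet] of hairpin sequences, names
#'   are hairpin identifiers.
#' @slot info [S4Vectors::DataFrame] with columns `hairpin_id`, `mir_start`,
#'   `mir_end`, `star_start`, `star_end`, `loop_start`, `loop_end`, `arm`
#'   (`"five_prime"` or `"three_prime"`, the arm of the mature miRNA).
#'
#' @seealso [HairpinSet()], [locateCutSites()], [classifyMode()]
#' @exportClass HairpinSet
setClass("HairpinSet",
    slots = c(sequences = "DNAStringSet", info = "DataFrame"))

.validHairpinSet <- function(object) {
    msg <- character()
    info <- object@info
    need <- c("hairpin_id", "mir_start", "mir_end", "star_start",
              "star_end", "loop_start", "loop_end", "arm")
    if (!all(need %in% colnames(info)))
        return(paste("info must have columns:",
                     paste(setdiff(need, colnames(info)), collapse = ", ")))
    if (length(object@sequences) != nrow(info))
        return("one info row per sequence required")
    len <- width(object@sequences)
    with_int <- function(s, e) !is.na(s) & !is.na(e)
    ok <- with_int(info$mir_start, info$mir_end) &
          with_int(info$star_start, info$star_end) &
          with_int(info$loop_start, info$loop_end)
    if (!all(ok)) return("all intervals must be defined")
    if (any(info$mir_start > info$mir_end |
            info$star_start > info$star_end |
            info$loop_start > info$loop_end))
        msg <- c(msg, "interval starts must not exceed ends")
    if (any(info$mir_start < 1L | info$mir_end > len |
            info$star_start < 1L | info$star_end > len))
        msg <- c(msg, "duplex intervals out of bounds")
    ## the loop must lie strictly between the two duplex strands
    lo <- pmin(info$mir_end, info$star_end)
    hi <- pmax(info$mir_start, info$star_start)
    five_end <- ifelse(info$mir_start < info$star_start,
                       info$mir_end, info$star_end)
    three_start <- ifelse(info$mir_start < info$star_start,
                          info$star_start, info$mir_start)
    if (any(info$loop_start <= five_end | info$loop_end >= three_start))
        msg <- c(msg, "loop must lie strictly between the duplex strands")
    if (!all(info$arm %in% c("five_prime", "three_prime")))
        msg <- c(msg, "arm must be 'five_prime' or 'three_prime'")
    if (length(msg)) msg else TRUE
}
setValidity("HairpinSet", .validHairpinSet)

#' Construct a HairpinSet
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of precursor sequences.
#' @param info `data.frame` or `DataFrame` of duplex/loop coordinates (see
#'   the class description).
#' @return A [HairpinSet-class] object.
#' @export
HairpinSet <- function(sequences, info) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- DNAStringSet(sequences)
    info <- DataFrame(info)
    info$hairpin_id <- as.character(info$hairpin_id)
    for (col in c("mir_start", "mir_end", "star_start", "star_end",
                  "loop_start", "loop_end"))
        info[[col]] <- as.integer(info[[col]])
    info$arm <- as.character(info$arm)
    new("HairpinSet", sequences = sequences, info = info)
}

#' SignalProfileSet: per-position PARE 5'-end signal for one library
#'
#' For one tag library, the per-reference vector of PARE-tag 5'-end signal
#' mass by position (fractional after multi-mapper splitting). The sum of
#' all profile mass equals the number of matched tag copies.
#'
#' @slot profiles An [IRanges::NumericList], one numeric vector per
#'   reference sequence (length = reference length), named by reference id.
#' @slot libraryId Library identifier, e.g. `"Dc_rep1"`.
#' @slot totalMass Total matched tag mass in the library (copies).
#' @slot unmatchedTags Number of tag copies that matched nowhere.
#' @slot skippedTags Number of tag copies skipped (non-ACGT letters).
#'
#' @seealso [buildProfiles()], [mapTags()]
#' @exportClass SignalProfileSet
setClass("SignalProfileSet",
    slots = c(profiles = "NumericList", libraryId = "character",
              totalMass = "numeric", unmatchedTags = "numeric",
              skippedTags = "numeric"))

.validSignalProfileSet <- function(object) {
    msg <- character()
    if (length(object@libraryId) != 1L)
        msg <- c(msg, "libraryId must be a single string")
    if (any(unlist(lapply(object@profiles, function(x) any(x < 0)))))
        msg <- c(msg, "profile mass must be non-negative")
    if (length(msg)) msg else TRUE
}
setValidity("SignalProfileSet", .validSignalProfileSet)

#' Construct a SignalProfileSet
#'
#' Usually produced by [buildProfiles()]; the constructor is exported for
#' tests and for assembling profiles from external sources.
#'
#' @param profiles Named list (or [IRanges::NumericList]) of per-position
#'   numeric mass vectors.
#' @param libraryId Library identifier.
#' @param totalMass Total matched mass; defaults to the sum over profiles.
#' @param unmatchedTags,skippedTags Bookkeeping counts (default 0).
#' @return A [SignalProfileSet-class] object.
#' @export
SignalProfileSet <- function(profiles, libraryId = "library",
                             totalMass = NULL, unmatchedTags = 0,
                             skippedTags = 0) {
    if (!is(profiles, "NumericList"))
        profiles <- NumericList(profiles)
    if (is.null(totalMass))
        totalMass <- sum(vapply(profiles, sum, numeric(1)))
    new("SignalProfileSet", profiles = profiles,
        libraryId = as.character(libraryId), totalMass = as.numeric(totalMass),
        unmatchedTags = as.numeric(unmatchedTags),
        skippedTags = as.numeric(skippedTags))
}
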