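#' @include AllClasses.R
NULL

#' Accessors for TranscriptSet, HairpinSet and SignalProfileSet
#'
#' `sequences()` returns the underlying `DNAStringSet`; `featureTable()`
#' (TranscriptSet) and `hairpinInfo()` (HairpinSet) return the annotation
#' `DataFrame`; `transcriptIds()` / `geneIds()` return identifier vectors;
#' `transcriptLengths()` returns widths named by transcript;
#' `profiles()` returns a `SignalProfileSet`'s `NumericList`;
#' `libraryId()` and `totalMass()` return its bookkeeping scalars.
#'
#' @param x A `TranscriptSet`, `HairpinSet` or `SignalProfileSet`.
#' @return See the description; accessors never expose slots for writing.
#' @name accessors
#' @examples
#' ts <- TranscriptSet(
#'   c(t1 = "AAAAATGGGTTGATTT"),
#'   data.frame(transcript_id = "t1", gene_id = "g1",
#'              utr5_start = 1, utr5_end = 4, cds_start = 5, cds_end = 13,
#'              utr3_start = 14, utr3_end = 16, intron_count = 0))
#' geneIds(ts)
NULL

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))
#' @rdname accessors
#' @export
setGeneric("hairpinInfo", function(x) standardGeneric("hairpinInfo"))
#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' @rdname accessors
setMethod("sequences", "TranscriptSet", function(x) x@sequences)
#' @rdname accessors
setMethod("sequences", "HairpinSet", function(x) x@sequences)
#' @rdname accessors
setMethod("featureTable", "TranscriptSet", function(x) x@features)
#' @rdname accessors
setMethod("transcriptIds", "TranscriptSet",
    function(x) x@features$transcript_id)
#' @rdname accessors
setMethod("geneIds", "TranscriptSet", function(x) x@features$gene_id)
#' @rdname accessors
setMethod("transcriptLengths", "TranscriptSet", function(x) {
    w <- Biostrings::width(x@sequences)
    names(w) <- names(x@sequences)
    w
})
#' @rdname accessors
setMethod("hairpinInfo", "HairpinSet", function(x) x@info)
#' @rdname accessors
setMethod("profiles", "SignalProfileSet", function(x) x@profiles)
#' @rdname accessors
setMethod("libraryId", "SignalProfileSet", function(x) x@libraryId)
#' @rdname accessors
setMethod("totalMass", "SignalProfileSet", function(x) x@totalMass)

setMethod("show", "TranscriptSet", function(object) {
    ft <- object@features
    cat("TranscriptSet with", length(object@sequences), "transcripts (",
        length(unique(ft$gene_id)), "genes )\n")
    cat("  length range:",
        paste(range(Biostrings::width(object@sequences)), collapse = "-"),
        "nt\n")
    n5 <- sum(!is.na(ft$utr5_start)); n3 <- sum(!is.na(ft$utr3_start))
    cat("  with 5'UTR:", n5, " with 3'UTR:", n3, "\n")
})

setMethod("show", "HairpinSet", function(object) {
    cat("HairpinSet with", length(object@sequences), "hairpin records\n")
    cat("  mature miRNA on 5' arm:",
        sum(object@info$arm == "five_prime"), ", 3' arm:",
        sum(object@info$arm == "three_prime"), "\n")
})

setMethod("show", "SignalProfileSet", function(object) {
    cat("SignalProfileSet [", object@libraryId, "] over",
        length(object@profiles), "references\n")
    cat("  matched mass:", format(object@totalMass),
        " unmatched tags:", format(object@unmatchedTags),
        " skipped:", format(object@skippedTags), "\n")
})
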