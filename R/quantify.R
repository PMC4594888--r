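#' @include AllClasses.R
#' @importFrom Biostrings DNAStringSet PDict matchPDict
NULL

## Matching with <= 1 substitution uses the pigeonhole split: a 1-mismatch
## hit must match one half of the tag exactly, so two PDict scans with
## complementary trusted bands cover every locus; candidates are then
## verified by edit-distance-at-position.

.collapseTags <- function(tags) {
    if (is(tags, "DNAStringSet")) tags <- as.character(tags)
    tags <- unname(tags)
    bad <- grepl("[^ACGT]", tags)
    skipped <- sum(bad)
    tags <- tags[!bad]
    tb <- table(tags)
    list(seq = names(tb), copies = as.integer(tb), skipped = skipped)
}

#' Map PARE tags to reference sequences
#'
#' Reports every sense-strand locus at which a tag aligns end-to-end with
#' at most `maxMismatch` substitutions. Tags containing non-ACGT letters
#' are skipped (counted); tags matching nowhere are counted as unmatched.
#' Duplicate tag sequences are collapsed to one row with a copy number.
#'
#' @param tags A [Biostrings::DNAStringSet] or character vector of tag
#'   reads (duplicates allowed; copy numbers are derived by collapsing).
#' @param references A [TranscriptSet-class], [HairpinSet-class] or named
#'   [Biostrings::DNAStringSet] of reference sequences.
#' @param maxMismatch Maximum substitutions per alignment (0 or 1).
#' @return An object of class `"tagAssignments"`: a list with
#'   `assignments` (data.frame `tag`, `copies`, `reference_id`, `pos`,
#'   `n_loci`), `unmatchedTags` and `skippedTags` (copy counts), and
#'   `totalMatchedMass`.
#' @seealso [buildProfiles()]
#' @export
mapTags <- function(tags, references, maxMismatch = 1L) {
    if (is(references, "TranscriptSet") || is(references, "HairpinSet"))
        references <- sequences(references)
    if (!is(references, "DNAStringSet"))
        references <- DNAStringSet(references)
    if (is.null(names(references)))
        stop("references must be named")
    if (!maxMismatch %in% c(0L, 1L))
        stop("maxMismatch must be 0 or 1")
    cl <- .collapseTags(tags)
    if (length(cl$seq) == 0L)
        return(structure(list(
            assignments = data.frame(tag = character(), copies = integer(),
                                     reference_id = character(),
                                     pos = integer(), n_loci = integer()),
            unmatchedTags = 0, skippedTags = cl$skipped,
            totalMatchedMass = 0), class = "tagAssignments"))

    ## one scan per dictionary over all references, concatenated with N
    ## spacers (N always mismatches; windows straddling a boundary are
    ## removed by the coordinate bounds check below)
    refChar <- as.character(references)
    refLen <- nchar(refChar)
    byW <- split(seq_along(cl$seq), nchar(cl$seq))
    hitList <- list()
    for (w in names(byW)) {
        idx <- byW[[w]]
        wd <- as.integer(w)
        tset <- DNAStringSet(cl$seq[idx])
        half <- wd %/% 2L
        dicts <- if (maxMismatch == 0L) list(list(pd = PDict(tset), mm = 0L))
        else list(
            list(pd = PDict(tset, tb.start = 1L, tb.end = half), mm = 1L),
            list(pd = PDict(tset, tb.start = half + 1L, tb.end = wd),
                 mm = 1L))
        sep <- strrep("N", wd)
        combined <- Biostrings::DNAString(paste(refChar, collapse = sep))
        offset <- cumsum(c(0, refLen[-length(refLen)] + wd))
        pairT <- integer(0); pairG <- integer(0)
        for (d in seq_along(dicts)) {
            ## the trusted band bounds mismatches per dict, so every
            ## reported locus already satisfies the threshold
            m <- matchPDict(dicts[[d]]$pd, combined,
                            max.mismatch = dicts[[d]]$mm)
            si <- Biostrings::startIndex(m)
            ln <- lengths(si)
            nz <- which(ln > 0L)
            if (!length(nz)) next
            pairT <- c(pairT, rep.int(nz, ln[nz]))
            pairG <- c(pairG, unlist(si[nz], use.names = FALSE))
        }
        if (!length(pairT)) next
        ## exact matches are found by both dicts: deduplicate
        keep <- !duplicated(as.numeric(pairT) * (length(combined) + 1) +
                            pairG)
        pairT <- pairT[keep]; pairG <- pairG[keep]
        r <- findInterval(pairG, offset + 1L)
        pos <- pairG - offset[r]
        ok <- pos >= 1L & pos + wd - 1L <= refLen[r]
        if (!any(ok)) next
        hitList[[length(hitList) + 1L]] <- data.frame(
            tagIdx = idx[pairT[ok]],
            reference_id = names(references)[r[ok]],
            pos = pos[ok])
    }
    if (length(hitList)) {
        hits <- do.call(rbind, hitList)
        nl <- table(hits$tagIdx)
        hits$n_loci <- as.integer(nl[as.character(hits$tagIdx)])
        hits$tag <- cl$seq[hits$tagIdx]
        hits$copies <- cl$copies[hits$tagIdx]
        matched <- unique(hits$tagIdx)
        hits <- hits[order(hits$tag, hits$reference_id, hits$pos),
                     c("tag", "copies", "reference_id", "pos", "n_loci")]
        rownames(hits) <- NULL
    } else {
        hits <- data.frame(tag = character(), copies = integer(),
                           reference_id = character(), pos = integer(),
                           n_loci = integer())
        matched <- integer()
    }
    unmatched <- sum(cl$copies[setdiff(seq_along(cl$seq), matched)])
    structure(list(assignments = hits,
                   unmatchedTags = unmatched,
                   skippedTags = cl$skipped,
                   totalMatchedMass = sum(cl$copies[matched])),
              class = "tagAssignments")
}

#' @export
print.tagAssignments <- function(x, ...) {
    cat("tagAssignments:", nrow(x$assignments), "tag-locus pairs,",
        format(x$totalMatchedMass), "matched copies,",
        format(x$unmatchedTags), "unmatched,",
        format(x$skippedTags), "skipped\n")
    invisible(x)
}

#' Build per-position 5'-end signal profiles from tag assignments
#'
#' Each tag contributes total mass equal to its copy number, divided
#' equally (1/k per locus) among its k match loci, accumulated at the
#' 1-based coordinate of the tag's 5' end. Total profile mass therefore
#' equals the matched tag copies exactly.
#'
#' @param assignments A `"tagAssignments"` object from [mapTags()].
#' @param references The reference set used for mapping (lengths are
#'   needed to size the profiles).
#' @param libraryId Library identifier stored in the result.
#' @return A [SignalProfileSet-class] with one profile per reference.
#' @export
buildProfiles <- function(assignments, references, libraryId = "library") {
    if (is(references, "TranscriptSet") || is(references, "HairpinSet"))
        references <- sequences(references)
    if (!is(references, "DNAStringSet"))
        references <- DNAStringSet(references)
    lens <- Biostrings::width(references)
    names(lens) <- names(references)
    prof <- lapply(lens, numeric)
    a <- assignments$assignments
    if (nrow(a)) {
        mass <- a$copies / a$n_loci
        key <- split(seq_len(nrow(a)), a$reference_id)
        for (ref in names(key)) {
            rows <- key[[ref]]
            v <- prof[[ref]]
            agg <- rowsum(mass[rows], a$pos[rows])
            v[as.integer(rownames(agg))] <- agg[, 1]
            prof[[ref]] <- v
        }
    }
    SignalProfileSet(prof, libraryId = libraryId,
                     totalMass = assignments$totalMatchedMass,
                     unmatchedTags = assignments$unmatchedTags,
                     skippedTags = assignments$skippedTags)
}

#' Per-gene degradation abundance in reads per million (RPM)
#'
#' Sums profile mass over each gene's transcript and normalises against
#' the total matched tag copies of the library:
#' `RPM = mass * 1e6 / totalMapped`. By convention `totalMapped` defaults
#' to the library's matched tag mass, so the RPM table sums to 1e6 when
#' every mapped tag is assigned to a transcript.
#'
#' @param profileSet A [SignalProfileSet-class].
#' @param transcripts A [TranscriptSet-class] giving the transcript-to-gene
#'   map.
#' @param totalMapped Normalisation denominator; defaults to
#'   `totalMass(profileSet)`. Must be > 0.
#' @return Named numeric vector of RPM per gene.
#' @export
geneRPM <- function(profileSet, transcripts,
                    totalMapped = totalMass(profileSet)) {
    if (totalMapped <= 0) stop("totalMapped must be > 0")
    ft <- featureTable(transcripts)
    mass <- vapply(profiles(profileSet)[ft$transcript_id], sum, numeric(1))
    rpm <- rowsum(mass * 1e6 / totalMapped, ft$gene_id)[, 1]
    rpm[unique(ft$gene_id)]
}

#' Per-gene transcription abundance in FPKM
#'
#' `FPKM = count / ((length/1000) * (libraryTotal/1e6))` with transcript
#' length taken from the annotation (genes with several transcripts use
#' the summed length of their transcripts' union; here one transcript per
#' gene).
#'
#' @param counts Named numeric vector of raw fragment counts per gene for
#'   one library.
#' @param transcripts A [TranscriptSet-class].
#' @param libraryTotal Total fragments in the library; defaults to
#'   `sum(counts)`. Must be > 0.
#' @return Named numeric vector of FPKM per gene.
#' @export
geneFPKM <- function(counts, transcripts, libraryTotal = sum(counts)) {
    if (libraryTotal <= 0) stop("libraryTotal must be > 0")
    ft <- featureTable(transcripts)
    lens <- rowsum(as.numeric(transcriptLengths(transcripts)),
                   ft$gene_id)[, 1]
    lens <- lens[names(counts)]
    if (any(is.na(lens)))
        stop("counts contain genes absent from the annotation")
    if (any(lens == 0)) stop("zero-length transcript")
    counts / ((lens / 1000) * (libraryTotal / 1e6))
}

#' Merge replicate abundance tables with correlation QC
#'
#' Averages per-gene values across replicates and reports the squared
#' Pearson correlation of `log2(value + 1)` between replicates (the mean
#' of pairwise r-squared values when more than two replicates are given).
#'
#' @param tables List of >= 2 named numeric vectors over an identical gene
#'   set.
#' @return List with `mean` (named numeric vector) and `r_squared`.
#' @export
mergeReplicates <- function(tables) {
    if (length(tables) < 2L) stop("need >= 2 replicates")
    genes <- names(tables[[1]])
    for (t in tables[-1])
        if (!identical(sort(names(t)), sort(genes)))
            stop("replicates must cover identical gene sets")
    m <- vapply(tables, function(t) t[genes], numeric(length(genes)))
    lg <- log2(m + 1)
    pairs <- utils::combn(ncol(m), 2)
    r2 <- mean(apply(pairs, 2, function(p)
        stats::cor(lg[, p[1]], lg[, p[2]]) ^ 2))
    list(mean = rowMeans(m), r_squared = r2)
}
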