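#' @include AllClasses.R
NULL

## Plant-target complementarity scoring: miRNA base i pairs the target
## site base (L - i + 1) (both read 5'->3', gapless). Per-position
## penalties: 0 Watson-Crick, 0.5 G:U wobble, 1 otherwise; the penalty is
## doubled inside the functionally critical miRNA region [2, 13].

.baseIdx <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)

## penalty[mirna base, target base (DNA)]
.penaltyTable <- local({
    m <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "T")))
    m["A", "T"] <- 0; m["U", "A"] <- 0
    m["G", "C"] <- 0; m["C", "G"] <- 0
    m["G", "T"] <- 0.5; m["U", "G"] <- 0.5   # G:U wobble
    m
})

.positionWeights <- function(L, doubledRegion = c(2L, 13L)) {
    w <- rep(1, L)
    idx <- seq(doubledRegion[1], min(doubledRegion[2], L))
    w[idx] <- 2
    w
}

#' Score a miRNA-target site alignment
#'
#' Gapless scoring of a miRNA against a candidate target site (both
#' 5'->3', equal lengths): miRNA base i pairs target base `L - i + 1`.
#' Penalties per position: 0 for Watson-Crick, 0.5 for G:U wobble, 1
#' otherwise, doubled for miRNA positions 2-13.
#'
#' @param mirna miRNA sequence 5'->3' (ACGU or ACGT).
#' @param targetSite Target site sequence 5'->3', same length.
#' @param doubledRegion miRNA positions whose penalty is doubled
#'   (default `c(2, 13)`).
#' @return List: `score`, `mismatches` (count of non-paired, non-wobble
#'   positions), `gu` (wobble count), `paired` (three-line alignment
#'   string).
#' @examples
#' m <- "ACGUACGUACGUACGUACGUA"
#' site <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAStringSet(m)))
#' scoreAlignment(m, site)$score  # 0: perfect complement
#' @export
scoreAlignment <- function(mirna, targetSite, doubledRegion = c(2L, 13L)) {
    mir <- chartr("Tacgu", "UACGU", mirna)
    tgt <- chartr("Uacgt", "TACGT", targetSite)
    L <- nchar(mir)
    if (nchar(tgt) != L)
        stop("miRNA and target site must have equal lengths (gapless)")
    mb <- strsplit(mir, "")[[1]]
    tb <- strsplit(tgt, "")[[1]]
    opp <- tb[L - seq_len(L) + 1L]   # target base pairing miRNA base i
    pen <- .penaltyTable[cbind(mb, opp)]
    w <- .positionWeights(L, doubledRegion)
    sym <- ifelse(pen == 0, "|", ifelse(pen == 0.5, "o", " "))
    paired <- paste0("5' ", tgt, " 3' target\n   ",
                     paste(rev(sym), collapse = ""), "\n3' ",
                     paste(rev(strsplit(mir, "")[[1]]), collapse = ""),
                     " 5' miRNA")
    list(score = sum(pen * w),
         mismatches = sum(pen == 1),
         gu = sum(pen == 0.5),
         paired = paired)
}

## Vectorised scan of one miRNA against one transcript: returns the score
## of every gapless window. score[s] = sum_i w_i * P_i[s + L - i] where
## P_i[t] is the penalty of miRNA base i against transcript base t.
.scanScores <- function(mirBases, w, tgtIdx) {
    L <- length(mirBases)
    n <- length(tgtIdx)
    if (n < L) return(numeric(0))
    nWin <- n - L + 1L
    score <- numeric(nWin)
    for (i in seq_len(L)) {
        pen <- .penaltyTable[mirBases[i], ][tgtIdx]
        off <- L - i
        score <- score + w[i] * pen[(1L + off):(nWin + off)]
    }
    score
}

#' Scan transcripts for miRNA complementarity sites
#'
#' Exhaustive gapless scan of every miRNA against every transcript
#' window, reporting all sites with [scoreAlignment()] score
#' `<= maxScore`. The slice position — the transcript nucleotide paired
#' with miRNA base 10, where a cleavage-derived PARE tag 5' end maps — is
#' recorded per site. Output is stably sorted by
#' (mirna_id, transcript_id, slice_pos).
#'
#' @param mirnas Named [Biostrings::DNAStringSet] (or character) of
#'   mature miRNAs.
#' @param transcripts A [TranscriptSet-class] or named
#'   [Biostrings::DNAStringSet].
#' @param maxScore Score threshold (default 4).
#' @param doubledRegion Passed to the scoring scheme.
#' @return data.frame: `mirna_id`, `transcript_id`, `target_start`,
#'   `target_end`, `slice_pos`, `score`, `mismatches`, `gu`.
#' @export
scanCandidates <- function(mirnas, transcripts, maxScore = 4,
                           doubledRegion = c(2L, 13L)) {
    if (is(transcripts, "TranscriptSet")) {
        tseq <- as.character(sequences(transcripts))
    } else {
        nm <- names(transcripts)
        tseq <- as.character(transcripts)
        names(tseq) <- nm
        if (is.null(names(tseq))) stop("transcripts must be named")
    }
    nm <- names(mirnas)
    mseq <- as.character(mirnas)
    names(mseq) <- nm
    if (is.null(names(mseq))) stop("mirnas must be named")
    rows <- list()
    tgtSplit <- lapply(tseq, function(s)
        unname(.baseIdx[strsplit(s, "")[[1]]]))
    for (m in names(mseq)) {
        mir <- chartr("Tacgu", "UACGU", mseq[[m]])
        mb <- strsplit(mir, "")[[1]]
        L <- length(mb)
        w <- .positionWeights(L, doubledRegion)
        for (tx in names(tseq)) {
            sc <- .scanScores(mb, w, tgtSplit[[tx]])
            hit <- which(sc <= maxScore)
            if (!length(hit)) next
            for (s in hit) {
                aln <- scoreAlignment(mseq[[m]],
                                      substr(tseq[[tx]], s, s + L - 1L),
                                      doubledRegion)
                rows[[length(rows) + 1L]] <- data.frame(
                    mirna_id = m, transcript_id = tx,
                    target_start = s, target_end = s + L - 1L,
                    slice_pos = s + L - 10L,
                    score = aln$score, mismatches = aln$mismatches,
                    gu = aln$gu)
            }
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(mirna_id = character(), transcript_id = character(),
                   target_start = integer(), target_end = integer(),
                   slice_pos = integer(), score = numeric(),
                   mismatches = integer(), gu = integer())
    out <- out[order(out$mirna_id, out$transcript_id, out$slice_pos), ]
    rownames(out) <- NULL
    out
}

#' Degradome category of a candidate slice position
#'
#' Ranks the signal at a slice position against the transcript's whole
#' profile (positions with mass > 0): category 4 when the slice mass is
#' at most one read; otherwise 0 when it equals the unique maximum, 1
#' when it ties the maximum, 2 when it exceeds the median, 3 when at or
#' below the median. Masses are fractional (post multi-mapper
#' splitting).
#'
#' @param profile Numeric vector of per-position signal mass.
#' @param slicePos 1-based position within the profile.
#' @return Integer category 0-4, or `NA` when the slice carries no
#'   signal.
#' @export
categorize <- function(profile, slicePos) {
    if (slicePos < 1 || slicePos > length(profile))
        stop("slice position outside the profile")
    m <- profile[slicePos]
    if (m <= 0) return(NA_integer_)
    if (m <= 1) return(4L)
    pos <- profile[profile > 0]
    mx <- max(pos)
    if (m == mx) {
        if (sum(pos == mx) == 1L) return(0L) else return(1L)
    }
    if (m > stats::median(pos)) return(2L)
    3L
}

#' Validate candidate sites against a degradome signal profile
#'
#' A candidate becomes a hit when the profile carries enough mass at its
#' slice position (the maximum within `+/- offsetTolerance` nt is used):
#' at least `minReads` for categories 0-3, or at least one read for
#' category 4. Candidates on transcripts without a profile are dropped
#' and counted.
#'
#' @param candidates data.frame from [scanCandidates()].
#' @param profileSet A [SignalProfileSet-class] from one library
#'   (conventionally the control degradome library).
#' @param minReads Minimum signal mass at the slice site (default 2).
#' @param offsetTolerance Positional tolerance in nt (default 0).
#' @return data.frame of hits: candidate columns plus `matched_pos`,
#'   `peak_reads`, `category`, `library_id`; attribute `"dropped"` counts
#'   candidates without a profile.
#' @export
validateWithDegradome <- function(candidates, profileSet, minReads = 2,
                                  offsetTolerance = 0L) {
    prof <- profiles(profileSet)
    keep <- candidates$transcript_id %in% names(prof)
    dropped <- sum(!keep)
    cand <- candidates[keep, , drop = FALSE]
    n <- nrow(cand)
    matchedPos <- integer(n); peak <- numeric(n); categ <- integer(n)
    hit <- logical(n)
    for (i in seq_len(n)) {
        v <- prof[[cand$transcript_id[i]]]
        sl <- cand$slice_pos[i]
        win <- max(1L, sl - offsetTolerance):min(length(v),
                                                 sl + offsetTolerance)
        if (sl < 1L || sl > length(v) || !length(win)) next
        best <- win[which.max(v[win])]
        mass <- v[best]
        if (mass <= 0) next
        cat_i <- categorize(v, best)
        ok <- if (!is.na(cat_i) && cat_i == 4L) mass >= 1 else
            mass >= minReads
        if (ok) {
            hit[i] <- TRUE
            matchedPos[i] <- best; peak[i] <- mass; categ[i] <- cat_i
        }
    }
    out <- cand[hit, , drop = FALSE]
    out$matched_pos <- matchedPos[hit]
    out$peak_reads <- peak[hit]
    out$category <- categ[hit]
    out$library_id <- rep(libraryId(profileSet), sum(hit))
    out <- out[order(out$mirna_id, out$transcript_id, out$slice_pos), ]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}

#' Full degradome-guided target identification
#'
#' Runs [scanCandidates()] then [validateWithDegradome()].
#'
#' @inheritParams scanCandidates
#' @inheritParams validateWithDegradome
#' @return The validated hit table (see [validateWithDegradome()]).
#' @export
findTargets <- function(mirnas, transcripts, profileSet, maxScore = 4,
                        minReads = 2, offsetTolerance = 0L) {
    cand <- scanCandidates(mirnas, transcripts, maxScore = maxScore)
    validateWithDegradome(cand, profileSet, minReads = minReads,
                          offsetTolerance = offsetTolerance)
}
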