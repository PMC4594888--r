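#' @include AllClasses.R
NULL

#' Locate precursor cut sites in PARE coordinates
#'
#' A DCL cut on a hairpin leaves a polyadenylated 3' fragment whose 5'
#' end is the nucleotide just after the cut, which is where a PARE tag
#' maps. For the 3'-arm duplex strand occupying `[b1, b2]` the
#' loop-proximal (upper) site is `b1` and the loop-distal (lower) site is
#' `b2 + 1`; mirror sites on the 5'-arm strand `[a1, a2]` are `a1`
#' (loop-distal) and `a2 + 1` (loop-proximal). Sites are defined by the
#' duplex geometry, not by which strand is the mature miRNA.
#'
#' @param hairpins A [HairpinSet-class].
#' @param which Index or hairpin id of the record to use.
#' @return List: `proximal_pos`, `distal_pos` (3'-arm signal positions),
#'   `arm5_distal`, `arm5_proximal` (mirror 5'-arm positions),
#'   `arm5_interval`, `arm3_interval` (the duplex strand intervals).
#' @export
locateCutSites <- function(hairpins, which = 1L) {
    info <- hairpinInfo(hairpins)
    i <- if (is.character(which)) match(which, info$hairpin_id) else which
    if (is.na(i) || i < 1L || i > nrow(info))
        stop("no such hairpin")
    mir <- c(info$mir_start[i], info$mir_end[i])
    star <- c(info$star_start[i], info$star_end[i])
    if (mir[1] < star[1]) { a <- mir; b <- star } else { a <- star; b <- mir }
    list(proximal_pos = b[1],
         distal_pos = b[2] + 1L,
         arm5_distal = a[1],
         arm5_proximal = a[2] + 1L,
         arm5_interval = a, arm3_interval = b)
}

#' Map PARE tags onto miRNA precursors
#'
#' Same matching and multi-mapper-splitting semantics as [mapTags()] +
#' [buildProfiles()], restricted to the hairpin sequences. When
#' `transcripts` is supplied, tags are mapped against the combined
#' hairpin + transcript universe so that a tag matching both splits its
#' mass globally, and only the hairpin profiles are returned.
#'
#' @param tags Tag reads ([Biostrings::DNAStringSet] or character).
#' @param hairpins A [HairpinSet-class].
#' @param transcripts Optional [TranscriptSet-class] sharing the mapping
#'   universe.
#' @param maxMismatch Maximum substitutions (default 0: exact matching).
#' @param libraryId Library identifier for the result.
#' @return A [SignalProfileSet-class] over the hairpin sequences.
#' @export
profileHairpins <- function(tags, hairpins, transcripts = NULL,
                            maxMismatch = 0L, libraryId = "hairpins") {
    refs <- sequences(hairpins)
    if (!is.null(transcripts)) {
        tx <- sequences(transcripts)
        combined <- c(refs, tx)
        asg <- mapTags(tags, combined, maxMismatch = maxMismatch)
        full <- buildProfiles(asg, combined, libraryId = libraryId)
        hp <- profiles(full)[names(refs)]
        return(SignalProfileSet(hp, libraryId = libraryId,
                                totalMass = full@totalMass,
                                unmatchedTags = full@unmatchedTags,
                                skippedTags = full@skippedTags))
    }
    asg <- mapTags(tags, refs, maxMismatch = maxMismatch)
    buildProfiles(asg, refs, libraryId = libraryId)
}

#' Classify a hairpin's processing mode from its PARE signal
#'
#' Compares signal mass within `+/- window` nt of the loop-distal versus
#' loop-proximal cut sites of the 3' arm. With total mass below
#' `minTotal` the call is `no_signal`; when the two cut sites jointly
#' hold less than `dispersalFraction` of the total the call is
#' `dispersed`; otherwise `loop_last` when distal mass dominates
#' proximal by at least `dominance` (first cut loop-distal), `loop_first`
#' for the converse, and `ambiguous` in between.
#'
#' @param profile Numeric per-position signal vector for one hairpin.
#' @param sites Cut sites from [locateCutSites()].
#' @param minTotal Minimum total mass to call anything (default 5).
#' @param dominance Required mass ratio between the two sites (default 2).
#' @param window Cut-site tolerance in nt (default 1; DCL ends are
#'   heterogeneous by about a nucleotide).
#' @param dispersalFraction Minimum fraction of mass at the two sites for
#'   a mode call (default 0.5).
#' @return List (one ProcessingCall): `mode`, `distal_mass`,
#'   `proximal_mass`, `total_mass`.
#' @export
classifyMode <- function(profile, sites, minTotal = 5, dominance = 2.0,
                         window = 1L, dispersalFraction = 0.5) {
    total <- sum(profile)
    winMass <- function(p) {
        w <- max(1L, p - window):min(length(profile), p + window)
        sum(profile[w])
    }
    distal <- winMass(sites$distal_pos)
    proximal <- winMass(sites$proximal_pos)
    mode <- if (total < minTotal) "no_signal"
    else if ((distal + proximal) < dispersalFraction * total) "dispersed"
    else if (distal >= dominance * proximal) "loop_last"
    else if (proximal >= dominance * distal) "loop_first"
    else "ambiguous"
    list(mode = mode, distal_mass = distal, proximal_mass = proximal,
         total_mass = total)
}

#' Fraction of hairpin signal on the 5' arm
#'
#' If the two first-step cuts happen on both arms simultaneously, only
#' 3'-arm fragments survive to be sequenced, so 5'-arm signal should be
#' scarce. Reports the 5'-arm mass fraction (positions up to the loop
#' start) and a verdict: `"simultaneous-compatible"` below `maxFraction`,
#' otherwise `"non-simultaneous signal"`; `"no_signal"` when the profile
#' is empty.
#'
#' @param profile Numeric per-position signal vector.
#' @param loopStart 1-based loop start of the hairpin.
#' @param maxFraction Verdict threshold (default 0.1).
#' @return List: `arm5_fraction` (`NA` when empty), `verdict`.
#' @export
armSimultaneity <- function(profile, loopStart, maxFraction = 0.1) {
    total <- sum(profile)
    if (total == 0)
        return(list(arm5_fraction = NA_real_, verdict = "no_signal"))
    frac <- sum(profile[seq_len(min(loopStart, length(profile)))]) / total
    list(arm5_fraction = frac,
         verdict = if (frac < maxFraction) "simultaneous-compatible"
                   else "non-simultaneous signal")
}

#' Detect mid-duplex cleavage signals
#'
#' Flags signal strictly inside the miRNA- or miRNA*-coding interval, at
#' least `margin` nt away from either interval end, with mass at least
#' `minReads` — the signature of miRNA/miRNA*-guided self-regulation of
#' the precursor rather than DCL processing remnants.
#'
#' @param profile Numeric per-position signal vector.
#' @param hairpins A [HairpinSet-class].
#' @param which Index or id of the hairpin record.
#' @param minReads Minimum mass at a mid-duplex position (default 3).
#' @param margin Distance from interval ends excluded (default 2 nt).
#' @return List: `flag` (logical), `positions` (integer vector).
#' @export
detectMidDuplex <- function(profile, hairpins, which = 1L, minReads = 3,
                            margin = 2L) {
    info <- hairpinInfo(hairpins)
    i <- if (is.character(which)) match(which, info$hairpin_id) else which
    inner <- function(s, e) {
        lo <- s + margin; hi <- e - margin
        if (lo > hi) integer() else lo:hi
    }
    posSet <- c(inner(info$mir_start[i], info$mir_end[i]),
                inner(info$star_start[i], info$star_end[i]))
    posSet <- posSet[posSet >= 1L & posSet <= length(profile)]
    hits <- posSet[profile[posSet] >= minReads]
    list(flag = length(hits) > 0L, positions = sort(hits))
}

#' Classify processing modes for every hairpin in a set
#'
#' Runs [locateCutSites()], [classifyMode()], [armSimultaneity()] and
#' [detectMidDuplex()] per hairpin record against one profile set.
#'
#' @param profileSet A [SignalProfileSet-class] over the hairpin
#'   sequences (see [profileHairpins()]).
#' @param hairpins A [HairpinSet-class].
#' @param ... Passed to [classifyMode()].
#' @return data.frame: `hairpin_id`, `mode`, `distal_mass`,
#'   `proximal_mass`, `total_mass`, `arm5_fraction`, `arm5_verdict`,
#'   `mid_duplex_flag`.
#' @export
classifyHairpins <- function(profileSet, hairpins, ...) {
    info <- hairpinInfo(hairpins)
    prof <- profiles(profileSet)
    rows <- lapply(seq_len(nrow(info)), function(i) {
        v <- prof[[info$hairpin_id[i]]]
        if (is.null(v)) v <- numeric(Biostrings::width(
            sequences(hairpins))[i])
        sites <- locateCutSites(hairpins, i)
        cm <- classifyMode(v, sites, ...)
        arm <- armSimultaneity(v, info$loop_start[i])
        md <- detectMidDuplex(v, hairpins, i)
        data.frame(hairpin_id = info$hairpin_id[i], mode = cm$mode,
                   distal_mass = cm$distal_mass,
                   proximal_mass = cm$proximal_mass,
                   total_mass = cm$total_mass,
                   arm5_fraction = arm$arm5_fraction,
                   arm5_verdict = arm$verdict,
                   mid_duplex_flag = md$flag)
    })
    do.call(rbind, rows)
}
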