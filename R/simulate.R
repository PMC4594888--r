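#' @include AllClasses.R
NULL

## Seeded RNG discipline: every generator derives a private seed from
## cfg$seed plus a small fixed offset, and restores the caller's RNG state,
## so all outputs are pure functions of the configuration.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Simulation configuration for a planted-truth degradome experiment
#'
#' Bundles every knob of the synthetic-data generator: transcriptome shape,
#' planted miRNA targets, condition effects per decay type, PARE and
#' RNA-seq depths, and hairpin processing modes. Defaults emulate a
#' scaled-down two-condition, two-replicate PARE + RNA-seq study: 500
#' genes, a two-fold-change (|log2FC| = 2) planted effect, sharp cleavage
#' peaks holding 80% of a target's tags, and a 5'-to-3' decay background.
#'
#' @param nGenes Number of genes (one transcript per gene).
#' @param lengthRange Length range (nt) of transcripts; min must be >= 200
#'   so every transcript can host a 5'UTR, CDS and 3'UTR.
#' @param gcTarget Target GC fraction of generated sequence.
#' @param nMirnas Number of mature miRNAs available for target planting.
#' @param mirnaLengths Candidate mature miRNA lengths (nt).
#' @param nPlantedTargets Number of planted miRNA cleavage sites.
#' @param targetMismatches Substitutions introduced into each planted site
#'   (never opposite miRNA bases 10-11).
#' @param decayTypeFractions Named fractions of genes planted as decay
#'   types `I` (degradation and transcription respond together), `II`
#'   (degradation only) and `IV` (transcription only); the remainder are
#'   unresponsive. Must sum to <= 1.
#' @param effectSizeLog2 Planted |log2 fold change| of responsive genes.
#' @param pareDepth PARE tags per library.
#' @param rnaseqDepth Expected RNA-seq fragments per library.
#' @param nbDispersion Negative-binomial dispersion of RNA-seq counts
#'   (0 gives Poisson counts).
#' @param peakFraction Fraction of a target transcript's tags placed
#'   exactly at its planted slice site.
#' @param backgroundModel `"exp5to3"` (5' ends increasingly frequent
#'   toward the 3' end, emulating 5'->3' exonucleolysis survivors) or
#'   `"uniform"`.
#' @param abundanceSdLog Log-normal sd of baseline gene abundance.
#' @param nHairpins Number of miRNA precursor hairpins.
#' @param hairpinModeFractions Named fractions of hairpins planted as
#'   `loop_last`, `loop_first` and `dispersed` processing modes (sum 1).
#' @param hairpinTagFraction Fraction of hairpins that receive PARE tags.
#' @param hairpinTagsPer Tags generated per tagged hairpin.
#' @param hairpinPurity Fraction of a tagged hairpin's tags placed at its
#'   mode-defining cut site.
#' @param arm5Leak Fraction of a tagged hairpin's tags leaking onto the
#'   5' arm (loop-last/loop-first modes).
#' @param seed Integer seed; all outputs are deterministic given the
#'   configuration.
#' @return A validated list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(nGenes = 20, nMirnas = 3, nPlantedTargets = 5,
#'                  pareDepth = 5000, rnaseqDepth = 10000, nHairpins = 6)
#' @export
simConfig <- function(nGenes = 500,
                      lengthRange = c(600L, 2500L),
                      gcTarget = 0.5,
                      nMirnas = 20,
                      mirnaLengths = 20:22,
                      nPlantedTargets = 50,
                      targetMismatches = 0,
                      decayTypeFractions = c(I = 0.06, II = 0.02, IV = 0.06),
                      effectSizeLog2 = 2,
                      pareDepth = 1e5,
                      rnaseqDepth = 5e5,
                      nbDispersion = 0.01,
                      peakFraction = 0.8,
                      backgroundModel = c("exp5to3", "uniform"),
                      abundanceSdLog = 0.8,
                      nHairpins = 100,
                      hairpinModeFractions = c(loop_last = 0.5,
                                               loop_first = 0.5,
                                               dispersed = 0),
                      hairpinTagFraction = 0.4,
                      hairpinTagsPer = 40,
                      hairpinPurity = 0.8,
                      arm5Leak = 0.02,
                      seed = 1L) {
    backgroundModel <- match.arg(backgroundModel)
    cfg <- list(nGenes = as.integer(nGenes),
                lengthRange = as.integer(lengthRange),
                gcTarget = gcTarget, nMirnas = as.integer(nMirnas),
                mirnaLengths = as.integer(mirnaLengths),
                nPlantedTargets = as.integer(nPlantedTargets),
                targetMismatches = as.integer(targetMismatches),
                decayTypeFractions = decayTypeFractions,
                effectSizeLog2 = effectSizeLog2,
                pareDepth = as.numeric(pareDepth),
                rnaseqDepth = as.numeric(rnaseqDepth),
                nbDispersion = nbDispersion,
                peakFraction = peakFraction,
                backgroundModel = backgroundModel,
                abundanceSdLog = abundanceSdLog,
                nHairpins = as.integer(nHairpins),
                hairpinModeFractions = hairpinModeFractions,
                hairpinTagFraction = hairpinTagFraction,
                hairpinTagsPer = as.integer(hairpinTagsPer),
                hairpinPurity = hairpinPurity,
                arm5Leak = arm5Leak,
                seed = as.integer(seed))
    fr01 <- c(gcTarget = gcTarget, peakFraction = peakFraction,
              hairpinTagFraction = hairpinTagFraction,
              hairpinPurity = hairpinPurity, arm5Leak = arm5Leak,
              decayTypeFractions, hairpinModeFractions)
    if (any(fr01 < 0 | fr01 > 1))
        stop("all fractions must lie in [0, 1]")
    if (sum(decayTypeFractions) > 1 + 1e-9)
        stop("decayTypeFractions must sum to <= 1")
    if (length(hairpinModeFractions) &&
        abs(sum(hairpinModeFractions) - 1) > 1e-9)
        stop("hairpinModeFractions must sum to 1")
    if (!all(names(decayTypeFractions) %in% c("I", "II", "IV")))
        stop("decayTypeFractions must be named with types I, II, IV")
    if (!all(names(hairpinModeFractions) %in%
             c("loop_last", "loop_first", "dispersed")))
        stop("hairpinModeFractions names must be loop_last/loop_first/dispersed")
    if (cfg$pareDepth <= 0 || cfg$rnaseqDepth <= 0)
        stop("depths must be > 0")
    if (length(cfg$lengthRange) != 2L || cfg$lengthRange[1] < 200L)
        stop("lengthRange must be a pair with min >= 200 nt")
    if (cfg$lengthRange[1] > cfg$lengthRange[2])
        stop("lengthRange must be increasing")
    class(cfg) <- "SimConfig"
    cfg
}

.randomBases <- function(n, gc) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic transcriptome with gene models
#'
#' Each transcript carries a 5'UTR, a CDS (length divisible by 3, starting
#' `ATG` and ending in a stop codon) and a 3'UTR; an intron count is drawn
#' per gene and recorded in the annotation (sequences are spliced mRNA).
#' Base composition follows `cfg$gcTarget`.
#'
#' @param cfg A [simConfig()] object.
#' @return A [TranscriptSet-class].
#' @export
simulateTranscriptome <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed + 11L, {
        n <- cfg$nGenes
        len <- sample(seq(cfg$lengthRange[1], cfg$lengthRange[2]), n,
                      replace = TRUE)
        utr5 <- pmax(30L, as.integer(round(len * 0.15)))
        utr3 <- pmax(30L, as.integer(round(len * 0.25)))
        cds <- len - utr5 - utr3
        rem <- cds %% 3L
        utr3 <- utr3 + rem          # keep CDS length divisible by 3
        cds <- cds - rem
        if (any(cds < 60L))
            stop("lengthRange too small to host minimal UTRs and CDS")
        stops <- c("TAA", "TAG", "TGA")
        seqs <- vapply(seq_len(n), function(i) {
            s <- .randomBases(len[i], cfg$gcTarget)
            cs <- utr5[i] + 1L
            ce <- utr5[i] + cds[i]
            s[cs:(cs + 2L)] <- c("A", "T", "G")
            s[(ce - 2L):ce] <- strsplit(sample(stops, 1L), "")[[1]]
            paste(s, collapse = "")
        }, character(1))
        ids <- sprintf("Tx%04d", seq_len(n))
        names(seqs) <- ids
        ft <- data.frame(
            transcript_id = ids,
            gene_id = sprintf("G%04d", seq_len(n)),
            utr5_start = 1L, utr5_end = utr5,
            cds_start = utr5 + 1L, cds_end = utr5 + cds,
            utr3_start = utr5 + cds + 1L, utr3_end = len,
            intron_count = stats::rpois(n, 3))
        TranscriptSet(seqs, ft)
    })
}

.revcompChr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Generate mature miRNAs and precursor hairpins with planted geometry
#'
#' Mature miRNAs are random 20-22-nt sequences. Each hairpin is built as a
#' single stem-loop: a 5'-arm duplex strand, a loop of at least 8 nt, and a
#' near-reverse-complement 3'-arm strand with classic 2-nt 3'-overhang
#' duplex geometry (up to 2 mispairs introduced); miRNA/miRNA* intervals
#' and the mature arm are recorded.
#'
#' @param cfg A [simConfig()] object.
#' @return A list with `mirnas` (named [Biostrings::DNAStringSet] of
#'   matures used for target planting) and `hairpins` (a
#'   [HairpinSet-class]).
#' @export
simulateMirnaSet <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed + 23L, {
        mir <- vapply(seq_len(cfg$nMirnas), function(i)
            paste(.randomBases(sample(cfg$mirnaLengths, 1L), 0.5),
                  collapse = ""), character(1))
        names(mir) <- sprintf("miR%03d", seq_len(cfg$nMirnas))

        n <- cfg$nHairpins
        seqs <- character(n); info <- vector("list", n)
        arms <- rep(c("five_prime", "three_prime"), length.out = n)
        for (i in seq_len(n)) {
            L <- sample(cfg$mirnaLengths, 1L)
            pad5 <- paste(.randomBases(sample(10:20, 1L), 0.5), collapse = "")
            arm5 <- paste(.randomBases(L, 0.5), collapse = "")
            loopLen <- sample(12:20, 1L)
            loop <- paste(.randomBases(loopLen, 0.5), collapse = "")
            ## 3' strand pairs arm5[1..L-2] plus the last 2 pad5 bases,
            ## leaving a 2-nt 3' overhang on each duplex strand
            pairedWith <- paste0(substr(pad5, nchar(pad5) - 1L, nchar(pad5)),
                                 substr(arm5, 1L, L - 2L))
            arm3 <- strsplit(.revcompChr(pairedWith), "")[[1]]
            nmut <- sample(0:2, 1L)
            if (nmut > 0) {
                at <- sample(seq_along(arm3), nmut)
                arm3[at] <- vapply(arm3[at], function(b)
                    sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
            }
            arm3 <- paste(arm3, collapse = "")
            pad3 <- paste(.randomBases(sample(25:35, 1L), 0.5), collapse = "")
            seqs[i] <- paste0(pad5, arm5, loop, arm3, pad3)
            P <- nchar(pad5)
            a <- c(P + 1L, P + L)
            lp <- c(P + L + 1L, P + L + loopLen)
            b <- c(P + L + loopLen + 1L, P + L + loopLen + nchar(arm3))
            if (arms[i] == "five_prime") {
                mi <- a; st <- b
            } else {
                mi <- b; st <- a
            }
            info[[i]] <- data.frame(
                hairpin_id = sprintf("hp%03d", i),
                mir_start = mi[1], mir_end = mi[2],
                star_start = st[1], star_end = st[2],
                loop_start = lp[1], loop_end = lp[2],
                arm = arms[i])
        }
        info <- do.call(rbind, info)
        names(seqs) <- info$hairpin_id
        list(mirnas = Biostrings::DNAStringSet(mir),
             hairpins = HairpinSet(seqs, info))
    })
}

#' Plant miRNA cleavage sites into transcripts
#'
#' Writes the reverse complement of a miRNA (with up to
#' `cfg$targetMismatches` substitutions, never opposite miRNA bases 10-11)
#' into a transcript's CDS and records the slice position: the transcript
#' nucleotide paired with miRNA base 10, i.e. the first nucleotide of the
#' 3' cleavage fragment whose 5' end a PARE tag marks.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param mirnas Named [Biostrings::DNAStringSet] of mature miRNAs.
#' @param cfg A [simConfig()] object.
#' @return A list with `transcripts` (sequences updated in place) and
#'   `targets`: a data.frame with `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end`, `slice_pos` (1-based), plus `skipped`,
#'   the count of transcripts too short to host their site.
#' @export
plantTargets <- function(transcripts, mirnas, cfg) {
    stopifnot(is(transcripts, "TranscriptSet"))
    .withSeed(cfg$seed + 37L, {
        ft <- featureTable(transcripts)
        n <- cfg$nPlantedTargets
        if (n > nrow(ft))
            stop("more planted targets than transcripts")
        idx <- sample(nrow(ft), n)
        mirAssign <- sample(length(mirnas), n, replace = TRUE)
        seqs <- as.character(sequences(transcripts))
        rows <- vector("list", n)
        skipped <- 0L
        for (k in seq_len(n)) {
            i <- idx[k]; m <- mirAssign[k]
            mirSeq <- as.character(mirnas[[m]])
            L <- nchar(mirSeq)
            len <- nchar(seqs[i])
            ## site must sit inside the CDS (clear of start/stop codons)
            ## and leave room for a 20-nt tag starting at the slice site
            smin <- ft$cds_start[i] + 3L
            smax <- min(ft$cds_end[i] - 3L - L + 1L,
                        len - 19L - (L - 10L))
            if (smax < smin) { skipped <- skipped + 1L; next }
            s <- sample(smin:smax, 1L)
            site <- strsplit(.revcompChr(mirSeq), "")[[1]]
            if (cfg$targetMismatches > 0) {
                ## positions pairing miRNA bases 10 and 11 are protected
                prot <- L - c(10L, 11L) + 1L
                free <- setdiff(seq_len(L), prot)
                at <- sample(free, min(cfg$targetMismatches, length(free)))
                site[at] <- vapply(site[at], function(b)
                    sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
            }
            substr(seqs[i], s, s + L - 1L) <- paste(site, collapse = "")
            rows[[k]] <- data.frame(
                mirna_id = names(mirnas)[m],
                transcript_id = ft$transcript_id[i],
                site_start = s, site_end = s + L - 1L,
                slice_pos = s + L - 10L)
        }
        targets <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
        ts <- TranscriptSet(seqs, ft)
        list(transcripts = ts, targets = targets, skipped = skipped)
    })
}

## Baseline gene abundances shared by every library of an experiment.
.geneAbundances <- function(cfg) {
    .withSeed(cfg$seed + 101L, {
        a <- stats::rlnorm(cfg$nGenes, meanlog = 0,
                           sdlog = cfg$abundanceSdLog)
        a / sum(a)
    })
}

#' Plant per-gene decay types and response directions
#'
#' Samples genes into decay types I (degradation and transcription respond
#' in the same direction), II (degradation only) and IV (transcription
#' only) according to `cfg$decayTypeFractions`, with up/down direction
#' drawn 50/50.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param cfg A [simConfig()] object.
#' @return data.frame with `gene_id`, `decay_type` (`"I"`, `"II"`, `"IV"`,
#'   `"none"`) and `direction` (+1, -1, or 0 for `"none"`).
#' @export
plantDecayTypes <- function(transcripts, cfg) {
    .withSeed(cfg$seed + 53L, {
        genes <- geneIds(transcripts)
        n <- length(genes)
        counts <- round(cfg$decayTypeFractions * n)
        type <- rep("none", n)
        pool <- sample(n)
        off <- 0L
        for (tp in names(counts)) {
            k <- counts[[tp]]
            if (k > 0) type[pool[(off + 1L):(off + k)]] <- tp
            off <- off + k
        }
        dir <- ifelse(type == "none", 0L,
                      sample(c(-1L, 1L), n, replace = TRUE))
        data.frame(gene_id = genes, decay_type = type, direction = dir)
    })
}

.backgroundWeights <- function(maxStart, model) {
    if (model == "uniform") rep(1, maxStart)
    else exp(3 * seq_len(maxStart) / maxStart)
}

#' Generate one PARE tag library
#'
#' Tags are exact 20-nt 5' signatures of cleavage products. Per-gene tag
#' totals are multinomial with probabilities proportional to baseline
#' abundance, scaled in the treated condition by the planted effect for
#' decay types I and II (the degradation layer). Within a target
#' transcript a `cfg$peakFraction` share of tags sits exactly at the
#' planted slice site(s); the remainder follows the background model.
#' Replicates differ only by their sampling seed.
#'
#' @param transcripts A [TranscriptSet-class] (with planted sites).
#' @param decay data.frame from [plantDecayTypes()].
#' @param targets data.frame of planted sites from [plantTargets()] (or
#'   `NULL` for none).
#' @param cfg A [simConfig()] object.
#' @param condition `"control"` or `"treated"`.
#' @param replicate Replicate number (1, 2, ...).
#' @return A list: `tags` (a [Biostrings::DNAStringSet], one entry per tag
#'   copy) and `truthProfile` (data.frame `transcript_id`, `pos`, `count`
#'   of planted 5'-end positions).
#' @export
simulatePareLibrary <- function(transcripts, decay, targets, cfg,
                                condition = c("control", "treated"),
                                replicate = 1L) {
    condition <- match.arg(condition)
    condIdx <- match(condition, c("control", "treated"))
    .withSeed(cfg$seed + 997L * condIdx + as.integer(replicate), {
        ab <- .geneAbundances(cfg)
        if (condition == "treated") {
            onD <- decay$decay_type %in% c("I", "II")
            ab[onD] <- ab[onD] *
                2 ^ (decay$direction[onD] * cfg$effectSizeLog2)
        }
        probs <- ab / sum(ab)
        nPer <- as.vector(stats::rmultinom(1, cfg$pareDepth, probs))
        seqs <- as.character(sequences(transcripts))
        ids <- transcriptIds(transcripts)
        lens <- nchar(seqs)
        sliceBy <- if (is.null(targets)) list() else
            split(targets$slice_pos, targets$transcript_id)
        allTags <- vector("list", length(ids))
        truth <- vector("list", length(ids))
        for (i in seq_along(ids)) {
            ni <- nPer[i]
            if (ni == 0) next
            maxStart <- lens[i] - 19L
            sl <- sliceBy[[ids[i]]]
            npk <- if (length(sl)) stats::rbinom(1L, ni, cfg$peakFraction)
                   else 0L
            pkPos <- if (npk > 0)
                sl[sample.int(length(sl), npk, replace = TRUE)] else integer()
            nbg <- ni - npk
            bgPos <- if (nbg > 0) {
                w <- .backgroundWeights(maxStart, cfg$backgroundModel)
                sample.int(maxStart, nbg, replace = TRUE, prob = w)
            } else integer()
            pos <- c(pkPos, bgPos)
            allTags[[i]] <- substring(seqs[i], pos, pos + 19L)
            tb <- table(pos)
            truth[[i]] <- data.frame(
                transcript_id = ids[i],
                pos = as.integer(names(tb)),
                count = as.integer(tb))
        }
        tags <- Biostrings::DNAStringSet(unlist(allTags, use.names = FALSE))
        names(tags) <- sprintf("tag%07d", seq_along(tags))
        list(tags = tags,
             truthProfile = do.call(
                 rbind, truth[!vapply(truth, is.null, logical(1))]))
    })
}

#' Generate an RNA-seq count table with planted transcription effects
#'
#' Counts are negative binomial with mean proportional to baseline
#' abundance times transcript length (dispersion `cfg$nbDispersion`; 0
#' gives Poisson). Decay types I and IV receive the planted condition
#' effect on the transcription layer.
#'
#' @inheritParams simulatePareLibrary
#' @return Integer matrix, genes x 4 libraries
#'   (`Rc_rep1`, `Rc_rep2`, `Rd_rep1`, `Rd_rep2`), rownames = gene ids.
#' @export
simulateRnaseqCounts <- function(transcripts, decay, cfg) {
    .withSeed(cfg$seed + 211L, {
        ab <- .geneAbundances(cfg)
        lens <- transcriptLengths(transcripts)
        base <- ab * lens
        base <- base / sum(base)
        onR <- decay$decay_type %in% c("I", "IV")
        eff <- rep(1, length(base))
        eff[onR] <- 2 ^ (decay$direction[onR] * cfg$effectSizeLog2)
        draw <- function(mu) {
            if (cfg$nbDispersion <= 0) stats::rpois(length(mu), mu)
            else stats::rnbinom(length(mu), mu = mu,
                                size = 1 / cfg$nbDispersion)
        }
        muC <- cfg$rnaseqDepth * base
        pT <- base * eff
        muT <- cfg$rnaseqDepth * pT / sum(pT)
        m <- cbind(Rc_rep1 = draw(muC), Rc_rep2 = draw(muC),
                   Rd_rep1 = draw(muT), Rd_rep2 = draw(muT))
        rownames(m) <- geneIds(transcripts)
        m
    })
}

#' Generate hairpin-derived PARE tags with planted processing modes
#'
#' A `cfg$hairpinTagFraction` share of hairpins receives tags. Loop-last
#' hairpins place `cfg$hairpinPurity` of their tags at the loop-distal cut
#' of the 3' arm, loop-first at the loop-proximal cut; `cfg$arm5Leak`
#' leaks onto the 5' arm and the rest is spread uniformly. Dispersed
#' hairpins spread all tags uniformly.
#'
#' @param hairpins A [HairpinSet-class].
#' @param cfg A [simConfig()] object.
#' @return A list: `tags` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame `hairpin_id`, `mode`, `has_tags`, `n_tags`).
#' @export
simulateHairpinTags <- function(hairpins, cfg) {
    stopifnot(is(hairpins, "HairpinSet"))
    .withSeed(cfg$seed + 307L, {
        info <- hairpinInfo(hairpins)
        n <- nrow(info)
        modes <- names(cfg$hairpinModeFractions)
        mode <- sample(rep(modes, times = round(
            cfg$hairpinModeFractions * n))[seq_len(n)])
        tagged <- logical(n)
        tagged[sample(n, round(cfg$hairpinTagFraction * n))] <- TRUE
        seqs <- as.character(sequences(hairpins))
        lens <- nchar(seqs)
        out <- vector("list", n)
        nTags <- integer(n)
        for (i in seq_len(n)) {
            if (!tagged[i]) next
            cuts <- locateCutSites(hairpins, i)
            maxStart <- lens[i] - 19L
            nt <- cfg$hairpinTagsPer
            if (mode[i] == "dispersed") {
                pos <- sample.int(maxStart, nt, replace = TRUE)
            } else {
                site <- if (mode[i] == "loop_last") cuts$distal_pos
                        else cuts$proximal_pos
                kind <- sample(c("site", "arm5", "bg"), nt, replace = TRUE,
                               prob = c(cfg$hairpinPurity, cfg$arm5Leak,
                                        1 - cfg$hairpinPurity - cfg$arm5Leak))
                arm5Max <- info$loop_start[i] - 1L
                pos <- integer(nt)
                pos[kind == "site"] <- site
                k5 <- sum(kind == "arm5")
                if (k5 > 0)
                    pos[kind == "arm5"] <-
                        sample.int(min(arm5Max, maxStart), k5, replace = TRUE)
                kb <- sum(kind == "bg")
                if (kb > 0) {
                    ## only 3' cleavage fragments carry a poly(A) tail and
                    ## are cloned, so off-site background stays 3' of the
                    ## loop start
                    bgPos <- seq(min(info$loop_start[i], maxStart), maxStart)
                    pos[kind == "bg"] <-
                        bgPos[sample.int(length(bgPos), kb, replace = TRUE)]
                }
            }
            out[[i]] <- substring(seqs[i], pos, pos + 19L)
            nTags[i] <- nt
        }
        tags <- Biostrings::DNAStringSet(unlist(out, use.names = FALSE))
        if (length(tags))
            names(tags) <- sprintf("hptag%06d", seq_along(tags))
        list(tags = tags,
             truth = data.frame(hairpin_id = info$hairpin_id, mode = mode,
                                has_tags = tagged, n_tags = nTags))
    })
}

#' Simulate a complete planted-truth degradome experiment
#'
#' Runs the whole generator: transcriptome, miRNA/hairpin sets, planted
#' cleavage sites and decay types, two conditions x two replicates of PARE
#' tags, RNA-seq counts, and hairpin-derived tags (kept as a separate
#' library so transcript-library depths stay exactly `cfg$pareDepth`).
#'
#' @param cfg A [simConfig()] object.
#' @return A list with elements `config`, `transcripts`, `mirnas`,
#'   `hairpins`, `truth` (list: `targets`, `decay`, `hairpins`),
#'   `pareLibraries` (named list `Dc_rep1`, `Dc_rep2`, `Dd_rep1`,
#'   `Dd_rep2` of tag `DNAStringSet`s), `hairpinTags`, `rnaseqCounts`.
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 30, nMirnas = 3,
#'     nPlantedTargets = 5, pareDepth = 5000, rnaseqDepth = 2e4,
#'     nHairpins = 6, seed = 7))
#' names(sim$pareLibraries)
#' @export
simulateExperiment <- function(cfg = simConfig()) {
    ts <- simulateTranscriptome(cfg)
    mset <- simulateMirnaSet(cfg)
    pl <- plantTargets(ts, mset$mirnas, cfg)
    decay <- plantDecayTypes(pl$transcripts, cfg)
    libs <- list()
    for (cond in c("control", "treated"))
        for (r in 1:2) {
            nm <- sprintf("%s_rep%d",
                          if (cond == "control") "Dc" else "Dd", r)
            libs[[nm]] <- simulatePareLibrary(
                pl$transcripts, decay, pl$targets, cfg, cond, r)
        }
    hp <- simulateHairpinTags(mset$hairpins, cfg)
    counts <- simulateRnaseqCounts(pl$transcripts, decay, cfg)
    list(config = cfg,
         transcripts = pl$transcripts,
         mirnas = mset$mirnas,
         hairpins = mset$hairpins,
         truth = list(targets = pl$targets, decay = decay,
                      hairpins = hp$truth, skippedTargets = pl$skipped),
         pareLibraries = lapply(libs, `[[`, "tags"),
         pareTruthProfiles = lapply(libs, `[[`, "truthProfile"),
         hairpinTags = hp$tags,
         rnaseqCounts = counts)
}
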