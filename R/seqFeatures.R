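#' @include AllClasses.R
#' @useDynLib degradomeKit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = MFE / length * 100 / (GC%)` where GC% is the GC fraction
#' expressed in percentage points — i.e. MFE per nucleotide per GC
#' percentage point. A length- and composition-normalised folding
#' stability measure.
#'
#' @param mfe Minimum free energy (kcal/mol, <= 0 for foldable sequences).
#' @param length Sequence length in nt (> 0).
#' @param gc GC content as a fraction in (0, 1].
#' @return The MFEI (vectorised).
#' @examples
#' mfei(-40, 100, 0.5)  # -0.8
#' @export
mfei <- function(mfe, length, gc) {
    if (any(length <= 0)) stop("length must be > 0")
    if (any(gc <= 0)) stop("MFEI undefined for GC content of 0")
    mfe / length * 100 / (gc * 100)
}

#' Folding score of an RNA sequence
#'
#' Delegates to a folding backend. `engine = "fallback"` (default) uses
#' the built-in base-pair maximisation dynamic program (-1 per canonical
#' pair including G:U, hairpin loops >= 3 nt) — an approximate,
#' thermodynamics-free score, clearly labelled as such in outputs.
#' `engine = "vienna"` shells out to `RNAfold` when the binary is on the
#' PATH and returns its thermodynamic MFE in kcal/mol. A custom backend
#' can be injected as a function `function(sequence) mfe`.
#'
#' @param sequence Character scalar (ACGT or ACGU; T is read as U).
#' @param engine `"fallback"`, `"vienna"`, or a function.
#' @return Numeric score (kcal/mol for `"vienna"`), with attribute
#'   `"engine"` recording the backend used.
#' @examples
#' foldMFE("GGGAAACCC")  # -3: three G:C pairs around a 3-nt loop
#' @export
foldMFE <- function(sequence, engine = c("fallback", "vienna")) {
    if (is.function(engine)) {
        v <- engine(sequence)
        attr(v, "engine") <- "custom"
        return(v)
    }
    engine <- match.arg(engine)
    if (!nzchar(sequence)) stop("sequence must be non-empty")
    if (grepl("[^ACGUTacgut]", sequence))
        stop("sequence must be ACGU/ACGT only")
    if (engine == "vienna") {
        bin <- Sys.which("RNAfold")
        if (!nzchar(bin))
            stop("RNAfold not found on PATH; use engine = 'fallback'")
        out <- system2(bin, args = "--noPS", input = sequence,
                       stdout = TRUE)
        last <- out[length(out)]
        v <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", last))
        attr(v, "engine") <- "vienna"
        return(v)
    }
    v <- .nussinovScore(sequence)
    attr(v, "engine") <- "fallback"
    v
}

.gcFraction <- function(seq) {
    n <- nchar(seq)
    gc <- nchar(gsub("[^GCgc]", "", seq))
    ifelse(n > 0, gc / n, NA_real_)
}

#' Per-transcript structural features
#'
#' Computes, for every transcript: mRNA/5'UTR/3'UTR lengths, regional GC
#' fractions, the annotated intron count, and regional MFEI values via
#' [foldMFE()] + [mfei()]. Missing UTRs yield `NA` features (absent, not
#' zero). Folding a full mRNA with the fallback engine is cubic in length;
#' sequences longer than `maxFoldLength` get `NA` MFEI instead.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param engine Folding backend passed to [foldMFE()].
#' @param maxFoldLength Longest sequence the backend is asked to fold
#'   (default 3000 nt).
#' @param regions Which regions to fold (subset of
#'   `c("mrna", "utr5", "utr3")`).
#' @return data.frame keyed by `transcript_id` with columns `gene_id`,
#'   `mrna_len`, `utr5_len`, `utr3_len`, `gc_mrna`, `gc_utr5`, `gc_utr3`,
#'   `intron_count`, `mfei_mrna`, `mfei_utr5`, `mfei_utr3`; attribute
#'   `"fold_engine"` records the backend.
#' @export
computeFeatures <- function(transcripts, engine = c("fallback", "vienna"),
                            maxFoldLength = 3000L,
                            regions = c("mrna", "utr5", "utr3")) {
    ft <- featureTable(transcripts)
    seqs <- as.character(sequences(transcripts))
    len <- nchar(seqs)
    sub5 <- ifelse(is.na(ft$utr5_start), NA_character_,
                   substr(seqs, ft$utr5_start, ft$utr5_end))
    sub3 <- ifelse(is.na(ft$utr3_start), NA_character_,
                   substr(seqs, ft$utr3_start, ft$utr3_end))
    engineName <- if (is.function(engine)) "custom" else match.arg(engine)
    foldOne <- function(s) {
        if (is.na(s) || !nzchar(s) || nchar(s) > maxFoldLength)
            return(NA_real_)
        as.numeric(foldMFE(s, engine))
    }
    regionMfei <- function(ss) {
        gc <- .gcFraction(ss)
        m <- vapply(ss, foldOne, numeric(1), USE.NAMES = FALSE)
        out <- rep(NA_real_, length(ss))
        ok <- !is.na(m) & !is.na(gc) & gc > 0
        if (any(ok)) out[ok] <- mfei(m[ok], nchar(ss[ok]), gc[ok])
        out
    }
    out <- data.frame(
        transcript_id = ft$transcript_id, gene_id = ft$gene_id,
        mrna_len = len,
        utr5_len = ifelse(is.na(ft$utr5_start), NA_integer_,
                          ft$utr5_end - ft$utr5_start + 1L),
        utr3_len = ifelse(is.na(ft$utr3_start), NA_integer_,
                          ft$utr3_end - ft$utr3_start + 1L),
        gc_mrna = .gcFraction(seqs),
        gc_utr5 = .gcFraction(sub5),
        gc_utr3 = .gcFraction(sub3),
        intron_count = ft$intron_count,
        mfei_mrna = NA_real_, mfei_utr5 = NA_real_, mfei_utr3 = NA_real_,
        row.names = NULL)
    if ("mrna" %in% regions) out$mfei_mrna <- regionMfei(seqs)
    if ("utr5" %in% regions) out$mfei_utr5 <- regionMfei(sub5)
    if ("utr3" %in% regions) out$mfei_utr3 <- regionMfei(sub3)
    attr(out, "fold_engine") <- engineName
    out
}

#' Compare a feature between gene groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests of a per-gene
#' feature between each named group and each control group. The
#' `"random"` control is a size-matched uniform sample without
#' replacement (seeded; size defaults to the mean size of the test
#' groups, rounded); the `"all"` control is every gene. Groups smaller
#' than 3 are skipped with a warning.
#'
#' @param featureValues Named numeric vector of the feature, names =
#'   gene ids.
#' @param groups Named list of gene-id vectors (the decay-type groups).
#' @param controls Which controls to include: any of `"random"`, `"all"`.
#' @param randomSize Size of the random control; default mean group size.
#' @param seed Seed for the random control draw.
#' @return data.frame: `group`, `control`, `n_group`, `n_control`,
#'   `mean_group`, `mean_control`, `p_value`.
#' @export
compareFeature <- function(featureValues, groups,
                           controls = c("random", "all"),
                           randomSize = NULL, seed = 1L) {
    if (!length(groups) || is.null(names(groups)))
        stop("groups must be a named list")
    universe <- names(featureValues)
    ctrl <- list()
    if ("all" %in% controls) ctrl$all <- universe
    if ("random" %in% controls) {
        if (is.null(randomSize))
            randomSize <- round(mean(lengths(groups)))
        ctrl$random <- .withSeed(seed,
            sample(universe, min(randomSize, length(universe))))
    }
    rows <- list()
    for (g in names(groups)) {
        vg <- featureValues[intersect(groups[[g]], universe)]
        vg <- vg[!is.na(vg)]
        for (cn in names(ctrl)) {
            vc <- featureValues[ctrl[[cn]]]
            vc <- vc[!is.na(vc)]
            p <- if (length(vg) < 3 || length(vc) < 3) {
                warning("group smaller than 3; p-value omitted")
                NA_real_
            } else stats::wilcox.test(vg, vc, exact = FALSE)$p.value
            rows[[length(rows) + 1L]] <- data.frame(
                group = g, control = cn,
                n_group = length(vg), n_control = length(vc),
                mean_group = mean(vg), mean_control = mean(vc),
                p_value = p)
        }
    }
    do.call(rbind, rows)
}
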