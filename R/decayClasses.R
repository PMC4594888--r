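#' @include AllClasses.R
NULL

## The canonical 3x3 grid of joint (degradation, transcription) statuses.
## Rows: D status up/unchanged/down; columns: R status down/unchanged/up;
## letters A..I row-major. The letter layout satisfies all textual
## constraints of the class system: E central (both unchanged), C/G the
## concordant cells (type I), B/H degradation-only (type II), A/I the
## discordant cells (type III), D/F transcription-only (type IV).
.classGrid <- local({
    dLev <- c("up", "unchanged", "down")
    rLev <- c("down", "unchanged", "up")
    g <- expand.grid(r_status = rLev, d_status = dLev,
                     stringsAsFactors = FALSE)[, 2:1]
    g$class_letter <- LETTERS[1:9]
    typeOf <- c(A = "III", B = "II", C = "I", D = "IV", E = "none",
                F = "IV", G = "I", H = "II", I = "III")
    g$decay_type <- unname(typeOf[g$class_letter])
    g
})

#' Assign decay class letters and types from joint status calls
#'
#' Maps each gene's degradation-layer (D) and transcription-layer (R)
#' status pair onto the nine-class grid (letters A-I, rows D
#' up/unchanged/down by columns R down/unchanged/up) and the four decay
#' types: I = concordant response (classes C, G), II = degradation-only
#' (B, H), III = discordant (A, I), IV = transcription-only (D, F); the
#' central class E (both unchanged) has type `"none"`. Genes with an
#' ambiguous status in either layer receive no class (`NA`) and are
#' reported in a separate bin.
#'
#' @param dStatus,rStatus Character vectors of statuses from
#'   [callStatus()] (same length, same gene order).
#' @return data.frame: `d_status`, `r_status`, `class_letter`,
#'   `decay_type` (`NA` for ambiguous input).
#' @examples
#' assignClass("up", "up")        # class C, type I
#' assignClass("up", "unchanged") # class B, type II
#' @export
assignClass <- function(dStatus, rStatus) {
    ok <- c("up", "down", "unchanged", "ambiguous")
    if (!all(dStatus %in% ok) || !all(rStatus %in% ok))
        stop("statuses must be up/down/unchanged/ambiguous")
    key <- paste(dStatus, rStatus)
    gridKey <- paste(.classGrid$d_status, .classGrid$r_status)
    i <- match(key, gridKey)
    data.frame(d_status = dStatus, r_status = rStatus,
               class_letter = .classGrid$class_letter[i],
               decay_type = .classGrid$decay_type[i])
}

#' Classify genes by joint degradation/transcription response
#'
#' Joins per-layer differential calls (only genes present in both layers
#' are classified) and assigns decay classes and types via
#' [assignClass()].
#'
#' @param dCalls,rCalls data.frames from [diffCalls()] for the D and R
#'   layers.
#' @return data.frame: `gene_id`, `d_status`, `r_status`, `class_letter`,
#'   `decay_type`, `d_log2fc`, `r_log2fc`; attribute `"ambiguous"` holds
#'   the ids of genes left unclassified.
#' @export
classifyDecay <- function(dCalls, rCalls) {
    shared <- intersect(dCalls$gene_id, rCalls$gene_id)
    d <- dCalls[match(shared, dCalls$gene_id), ]
    r <- rCalls[match(shared, rCalls$gene_id), ]
    cls <- assignClass(d$status, r$status)
    out <- data.frame(gene_id = shared, cls,
                      d_log2fc = d$log2fc, r_log2fc = r$log2fc,
                      row.names = NULL)
    attr(out, "ambiguous") <- shared[is.na(cls$class_letter)]
    out
}

#' Summarise decay-type counts by response direction
#'
#' Produces the standard decay-pattern summary: one row per (type,
#' direction pattern), e.g. type I splits into D-up/R-up versus
#' D-down/R-down.
#'
#' @param assignments data.frame from [classifyDecay()].
#' @return data.frame: `decay_type`, `pattern` (e.g. `"D^R^"` rendered as
#'   `"D+R+"` style arrows `up`/`down`/`-`), `n_genes`.
#' @export
summarizeTypes <- function(assignments) {
    a <- assignments[!is.na(assignments$class_letter), ]
    up <- "\u2191"; dn <- "\u2193"
    arrow <- function(s) c(up = up, down = dn, unchanged = "-")[s]
    pat <- paste0("D", arrow(a$d_status), "R", arrow(a$r_status))
    tmpl <- data.frame(
        decay_type = c("I", "I", "II", "II", "III", "III", "IV", "IV",
                       "none"),
        pattern = c(paste0("D", up, "R", up), paste0("D", dn, "R", dn),
                    paste0("D", up, "R-"), paste0("D", dn, "R-"),
                    paste0("D", up, "R", dn), paste0("D", dn, "R", up),
                    paste0("D-R", up), paste0("D-R", dn), "D-R-"))
    key <- paste(a$decay_type, pat)
    tb <- table(factor(key, levels = paste(tmpl$decay_type, tmpl$pattern)))
    tmpl$n_genes <- as.integer(tb)
    tmpl
}

#' Ratio of uncapped (RPM) to total (FPKM) mRNA abundance
#'
#' Computes per-gene `RPM / FPKM` and, when two gene sets are supplied,
#' compares their ratio distributions with a two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test. Genes with `FPKM = 0` are excluded and
#' counted.
#'
#' @param rpm,fpkm Named numeric vectors covering the genes of interest.
#' @param geneSets Either a character vector of gene ids (ratios only) or
#'   a named list of exactly two gene-id vectors to compare.
#' @return List with `ratios` (named numeric, excluded genes dropped),
#'   `excluded` (count of FPKM-zero genes), and when two sets are given,
#'   `p_value` plus per-set `medians`.
#' @export
uncappedTotalRatio <- function(rpm, fpkm, geneSets) {
    sets <- if (is.list(geneSets)) geneSets else list(all = geneSets)
    genes <- unique(unlist(sets))
    if (length(genes) == 0L) stop("empty gene set")
    if (!all(genes %in% names(rpm)) || !all(genes %in% names(fpkm)))
        stop("rpm and fpkm must cover every requested gene")
    keep <- genes[fpkm[genes] > 0]
    excluded <- length(genes) - length(keep)
    ratios <- rpm[keep] / fpkm[keep]
    out <- list(ratios = ratios, excluded = excluded)
    if (length(sets) == 2L) {
        g1 <- intersect(sets[[1]], keep); g2 <- intersect(sets[[2]], keep)
        out$p_value <- stats::wilcox.test(ratios[g1], ratios[g2],
                                          exact = FALSE)$p.value
        out$medians <- c(stats::median(ratios[g1]),
                         stats::median(ratios[g2]))
        names(out$medians) <- names(sets)
    }
    out
}
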