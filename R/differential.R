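#' @include AllClasses.R
NULL

#' Two-library differential test for count proportions
#'
#' Tests, per gene, whether the sampling proportion of its reads is equal
#' in two libraries under the random-sampling model, using the pooled
#' two-proportion z statistic
#' \deqn{z = \frac{c_1/n_1 - c_2/n_2}{\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#'   \quad \hat p = \frac{c_1 + c_2}{n_1 + n_2}}
#' with the two-sided p-value \eqn{p = 2\Phi(-|z|)}. Genes with
#' `c1 = c2 = 0` (and the degenerate all-reads case) return p = 1.
#' Vectorised over genes.
#'
#' @param c1,c2 Gene counts in library 1 and 2 (vectors).
#' @param n1,n2 Library totals (scalars or vectors).
#' @return Numeric vector of two-sided raw p-values.
#' @examples
#' twoLibraryTest(c(200, 100), 1e6, c(50, 100), 1e6)
#' @export
twoLibraryTest <- function(c1, n1, c2, n2) {
    if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be > 0")
    if (any(c1 < 0) || any(c2 < 0)) stop("counts must be >= 0")
    if (any(c1 > n1) || any(c2 > n2))
        stop("counts cannot exceed library totals")
    phat <- (c1 + c2) / (n1 + n2)
    se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
    z <- (c1 / n1 - c2 / n2) / se
    z[!is.finite(z)] <- 0      # c1 = c2 = 0 (or saturated): no evidence
    2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment controlling the false discovery rate: monotone and
#' capped at 1.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Moderated log2 fold change
#'
#' `log2((treated + eps) / (control + eps))` with a pseudo-abundance `eps`
#' (same unit as the values, e.g. RPM) so zero-abundance genes yield
#' finite ratios.
#'
#' @param vTreated,vControl Non-negative abundances (vectors).
#' @param eps Pseudo-abundance added to both (default 0.5); must be > 0.
#' @return Numeric vector of log2 fold changes, treated over control.
#' @export
log2FoldChange <- function(vTreated, vControl, eps = 0.5) {
    if (eps <= 0) stop("eps must be > 0")
    if (any(vTreated < 0) || any(vControl < 0))
        stop("abundances must be >= 0")
    log2((vTreated + eps) / (vControl + eps))
}

#' Call up/down/unchanged status from fold change and adjusted p-value
#'
#' `up` when `log2fc >= fcThresh` and `pAdj < pThresh`; `down` when
#' `log2fc <= -fcThresh` and `pAdj < pThresh`; `unchanged` when
#' `|log2fc| < fcThresh` and `pAdj > pThresh`. Grid cells covered by
#' neither rule (e.g. a large fold change with a non-significant p) are
#' `ambiguous` and excluded from decay-class assignment downstream.
#'
#' @param log2fc Log2 fold change (vector).
#' @param pAdj Adjusted p-value (vector).
#' @param fcThresh Fold-change threshold (default 1).
#' @param pThresh Significance threshold (default 0.001).
#' @return Character vector: `"up"`, `"down"`, `"unchanged"`,
#'   `"ambiguous"`.
#' @export
callStatus <- function(log2fc, pAdj, fcThresh = 1, pThresh = 0.001) {
    status <- rep("ambiguous", length(log2fc))
    status[log2fc >= fcThresh & pAdj < pThresh] <- "up"
    status[log2fc <= -fcThresh & pAdj < pThresh] <- "down"
    status[abs(log2fc) < fcThresh & pAdj > pThresh] <- "unchanged"
    status
}

#' Differential calls for one data layer (degradation or transcription)
#'
#' Convenience wrapper running [twoLibraryTest()] on summed replicate
#' counts per condition, [bhAdjust()], [log2FoldChange()] on the
#' per-million normalised summed counts, and [callStatus()].
#'
#' @param countsControl,countsTreated Named numeric vectors of per-gene
#'   counts (replicates already summed) over the same gene set.
#' @param layer `"D"` (degradation) or `"R"` (transcription); recorded in
#'   the output.
#' @param eps Pseudo-abundance for the fold change (in per-million units).
#' @param fcThresh,pThresh Thresholds passed to [callStatus()].
#' @return data.frame: `gene_id`, `layer`, `c_control`, `c_treated`,
#'   `log2fc`, `p_raw`, `p_adj`, `status`.
#' @export
diffCalls <- function(countsControl, countsTreated, layer = c("D", "R"),
                      eps = 0.5, fcThresh = 1, pThresh = 0.001) {
    layer <- match.arg(layer)
    genes <- names(countsControl)
    if (!identical(genes, names(countsTreated)))
        stop("control and treated must cover the same genes in order")
    n1 <- sum(countsControl); n2 <- sum(countsTreated)
    p <- twoLibraryTest(countsTreated, n2, countsControl, n1)
    padj <- bhAdjust(p)
    fc <- log2FoldChange(countsTreated * 1e6 / n2,
                         countsControl * 1e6 / n1, eps = eps)
    data.frame(gene_id = genes, layer = layer,
               c_control = as.numeric(countsControl),
               c_treated = as.numeric(countsTreated),
               log2fc = fc, p_raw = p, p_adj = padj,
               status = callStatus(fc, padj, fcThresh, pThresh),
               row.names = NULL)
}
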