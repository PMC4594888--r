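# Independent oracles used across the suite. Each one recomputes the
# quantity from first principles with no shared code path into the package
# internals it checks.

# Brute-force tag mapping: slide every tag over every position of every
# reference and count substitutions directly.
bruteForceMap <- function(tags, refs, maxMismatch = 1L) {
    nm <- names(refs)
    tags <- as.character(tags); refs <- as.character(refs)
    names(refs) <- nm
    out <- list()
    for (tg in unique(tags)) {
        tb <- strsplit(tg, "")[[1]]
        w <- length(tb)
        for (r in names(refs)) {
            rb <- strsplit(refs[[r]], "")[[1]]
            if (length(rb) < w) next
            for (s in seq_len(length(rb) - w + 1L)) {
                mm <- sum(tb != rb[s:(s + w - 1L)])
                if (mm <= maxMismatch)
                    out[[length(out) + 1L]] <- data.frame(
                        tag = tg, reference_id = r, pos = s)
            }
        }
    }
    if (!length(out))
        return(data.frame(tag = character(), reference_id = character(),
                          pos = integer()))
    df <- do.call(rbind, out)
    df[order(df$tag, df$reference_id, df$pos), , drop = FALSE]
}

# Per-position penalty sum for plant miRNA-target scoring, written
# longhand against the rule statement.
oracleAlignmentScore <- function(mirna, site) {
    mir <- chartr("T", "U", toupper(mirna))
    tgt <- chartr("U", "T", toupper(site))
    L <- nchar(mir)
    stopifnot(nchar(tgt) == L)
    total <- 0
    for (i in seq_len(L)) {
        mb <- substr(mir, i, i)
        ob <- substr(tgt, L - i + 1L, L - i + 1L)
        wc <- (mb == "A" && ob == "T") || (mb == "U" && ob == "A") ||
              (mb == "G" && ob == "C") || (mb == "C" && ob == "G")
        gu <- (mb == "G" && ob == "T") || (mb == "U" && ob == "G")
        pen <- if (wc) 0 else if (gu) 0.5 else 1
        if (i >= 2 && i <= 13) pen <- pen * 2
        total <- total + pen
    }
    total
}

# Exhaustive enumeration of nested pairings (canonical incl. G:U wobble,
# hairpin loop >= 3 i.e. pair (i, j) needs j - i >= 4). Recursion over
# whether the last base is unpaired or paired with some earlier base.
oracleMaxPairs <- function(seq) {
    s <- chartr("T", "U", toupper(seq))
    b <- strsplit(s, "")[[1]]
    pairOK <- function(x, y)
        paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    rec <- function(i, j) {
        if (j - i < 4L) return(0L)
        best <- rec(i, j - 1L)
        for (k in i:(j - 4L)) {
            if (!pairOK(b[k], b[j])) next
            left <- if (k > i) rec(i, k - 1L) else 0L
            best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
        }
        best
    }
    n <- length(b)
    if (n < 5L) 0L else rec(1L, n)
}

# Exact conditional two-sided binomial test for equal library totals:
# conditional on k = c1 + c2, c1 ~ Bin(k, n1 / (n1 + n2)).
oracleExactBinomP <- function(c1, c2, n1, n2) {
    k <- c1 + c2
    pr <- n1 / (n1 + n2)
    mapply(function(ci, ki) {
        if (ki == 0) return(1)
        stats::binom.test(ci, ki, pr)$p.value
    }, c1, k)
}

# Vectorised version of the same exact test for the symmetric case
# n1 == n2 (null calibration at scale): p = P(X <= min) + P(X >= k - min).
oracleExactBinomPSym <- function(c1, c2) {
    k <- c1 + c2
    m <- pmin(c1, c2)
    p <- pbinom(m, k, 0.5) + pbinom(k - m - 1, k, 0.5, lower.tail = FALSE)
    p[k == 0] <- 1
    pmin(p, 1)
}

# Hand Benjamini-Hochberg: sort, p * m / rank, cumulative min from the
# largest rank, cap at 1, return in input order.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}
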