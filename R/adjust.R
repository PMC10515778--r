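#' Multiple-testing corrections
#'
#' `benjaminiHochberg()` applies the Benjamini-Hochberg step-up FDR
#' correction, `bonferroniAdjust()` the Bonferroni correction
#' (min(1, m * p)), and `holmSidak()` the Holm-Šidák step-down procedure:
#' with p-values sorted ascending, adjusted_(i) = max over j <= i of
#' 1 - (1 - p_(j))^(m - j + 1), clipped to 1, returned in the input order.
#' All three dominate the raw p-values.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' holmSidak(c(0.01, 0.04, 0.03))
#' @export
benjaminiHochberg <- function(pvals) {
    stopIfNotProb(pvals, "pvals")
    stats::p.adjust(pvals, method = "BH")
}

#' @rdname benjaminiHochberg
#' @export
bonferroniAdjust <- function(pvals) {
    stopIfNotProb(pvals, "pvals")
    stats::p.adjust(pvals, method = "bonferroni")
}

#' @rdname benjaminiHochberg
#' @export
holmSidak <- function(pvals) {
    stopIfNotProb(pvals, "pvals")
    m <- length(pvals)
    ord <- order(pvals)
    ps <- pvals[ord]
    adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
    adj <- pmin(1, cummax(adj))
    out <- numeric(m)
    out[ord] <- adj
    out
}
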