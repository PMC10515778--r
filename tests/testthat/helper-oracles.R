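# Independent brute-force oracles used to check the package's optimized
# implementations. These deliberately share no code with R/.

# Sliding-window n-gram counter: explicit loops over tuples, after
# independently re-implementing the exclusion + merge rule.
oracleNgramCounts <- function(labelList, n, included) {
    counts <- list()
    total <- 0L
    for (lab in labelList) {
        lab <- lab[lab %in% included]
        if (length(lab) > 1L) {
            keep <- c(TRUE, diff(lab) != 0)
            lab <- lab[keep]
        }
        if (length(lab) < n) next
        for (i in seq_len(length(lab) - n + 1L)) {
            key <- paste(lab[i:(i + n - 1L)], collapse = "-")
            counts[[key]] <- (counts[[key]] %||% 0L) + 1L
            total <- total + 1L
        }
    }
    list(counts = unlist(counts), total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook step-up BH: q_(i) = min over j >= i of m * p_(j) / j, clipped.
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
    out <- numeric(m)
    out[ord] <- q
    out
}

oracleBonferroni <- function(p) pmin(1, length(p) * p)

# Step-down Holm-Sidak: adj_(i) = max over j <= i of 1-(1-p_(j))^(m-j+1).
oracleHolmSidak <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    adj <- numeric(m)
    cur <- 0
    for (i in seq_len(m)) {
        cur <- max(cur, 1 - (1 - ps[i])^(m - i + 1))
        adj[i] <- min(1, cur)
    }
    out <- numeric(m)
    out[ord] <- adj
    out
}

# Random frame-label sequence over IDs 0..(K-1) with occasional -1 frames.
randomFrameSeq <- function(id, nframes, K, pNoise = 0.05) {
    lab <- sample.int(K, nframes, replace = TRUE) - 1L
    lab[stats::runif(nframes) < pNoise] <- -1L
    FrameLabels(id, lab)
}

# Random run sequence (no consecutive duplicates by construction).
randomRunSeq <- function(id, nruns, K) {
    lab <- sample.int(K, nruns * 2L, replace = TRUE)
    lab <- rle(lab)$values
    lab <- lab[seq_len(min(nruns, length(lab)))]
    RunSeq(id, lab, sample.int(10L, length(lab), replace = TRUE))
}
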