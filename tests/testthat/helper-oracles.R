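# Independent brute-force oracles, loop-based on purpose: they must not share
# code paths with the package implementations they check.

knn_oracle <- function(m, k = 10L) {
    out <- m
    for (i in seq_len(nrow(m))) {
        for (j in seq_len(ncol(m))) {
            if (!is.na(m[i, j])) next
            d <- rep(NA_real_, nrow(m))
            for (r in seq_len(nrow(m))) {
                if (r == i || is.na(m[r, j])) next
                sh <- which(!is.na(m[i, ]) & !is.na(m[r, ]))
                if (!length(sh)) next
                d[r] <- sqrt(sum((m[i, sh] - m[r, sh])^2) / length(sh))
            }
            cand <- which(!is.na(d))
            nn <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
            dn <- d[nn]
            vals <- m[nn, j]
            out[i, j] <- if (any(dn == 0)) {
                mean(vals[dn == 0])
            } else {
                sum(vals / dn) / sum(1 / dn)
            }
        }
    }
    out
}

# Step-up false-discovery-rate adjustment, from the definition:
# adjusted p of the i-th smallest p-value = min_{j >= i} min(1, n p_(j) / j).
bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
        best <- Inf
        for (j in i:n) best <- min(best, n * p[o[j]] / j)
        adj[o[i]] <- min(1, best)
    }
    adj
}

# random beta matrix with a few masked cells
masked_matrix <- function(nr, nc, nmask, seed) {
    withr::with_seed(seed, {
        m <- matrix(runif(nr * nc), nr, nc,
                    dimnames = list(sprintf("cg%03d", seq_len(nr)),
                                    sprintf("S%02d", seq_len(nc))))
        m[sample(length(m), nmask)] <- NA_real_
        # keep every row partially observed
        gone <- rowSums(!is.na(m)) == 0
        m[gone, 1] <- runif(sum(gone))
        m
    })
}
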