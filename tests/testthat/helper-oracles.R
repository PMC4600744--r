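# Independent oracles used by several test files. These deliberately use
# plain arithmetic (no log-space tricks) and exhaustive enumeration, so they
# are only usable at tiny problem sizes.

# unsigned Stirling numbers of the first kind, s1[n, k], by the recurrence
stirling_unsigned <- function(n) {
    s <- matrix(0, n, n)
    s[1, 1] <- 1
    if (n > 1) for (m in 2:n) {
        s[m, 1] <- (m - 1) * s[m - 1, 1]
        for (k in 2:m)
            s[m, k] <- (if (k > 1) s[m - 1, k - 1] else 0) + (m - 1) * s[m - 1, k]
    }
    s
}

# K(D, A) by brute-force enumeration over all ancestor assignments a_i
brute_K <- function(n) {
    S <- length(n); J <- sum(n)
    st <- stirling_unsigned(max(n))
    grids <- expand.grid(lapply(n, seq_len))
    A <- rowSums(grids)
    K <- numeric(J - S + 1)
    for (r in seq_len(nrow(grids))) {
        a <- as.numeric(grids[r, ])
        v <- prod(mapply(function(ni, ai)
            st[ni, ai] * factorial(ai - 1) / factorial(ni - 1), n, a))
        K[A[r] - S + 1] <- K[A[r] - S + 1] + v
    }
    K
}

# all integer partitions of J (abundance configurations)
partitions <- function(J, max = J) {
    if (J == 0) return(list(integer(0)))
    out <- list()
    for (k in min(J, max):1)
        for (p in partitions(J - k, k))
            out[[length(out) + 1]] <- c(k, p)
    out
}

# a small deterministic peak table spanning several samples
example_peaks <- function() {
    peak_table(data.frame(
        sample_id = rep(c("s1", "s2"), c(4, 3)),
        fragment_size = c(100, 150, 200, 250, 100.2, 300, 420),
        height = c(1000, 60, 500, 90, 800, 400, 120),
        stringsAsFactors = FALSE))
}
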