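#' Filter T-RFLP peaks
#'
#' Applies the standard fingerprint cleaning rules sequentially, per sample:
#' keep fragments sized within `[min_size, max_size]` base pairs, drop peaks
#' with height below `min_height` fluorescence units, then drop peaks whose
#' height is below `min_frac` of the sample's total peak height, the total
#' being computed after the size and absolute-height filters.
#'
#' The operation is idempotent: a second application leaves a filtered table
#' unchanged. Samples that lose all their peaks are recorded in the
#' `empty_samples` attribute (and warned about), not silently dropped.
#'
#' @param peaks a [peak_table()].
#' @param min_size,max_size retained fragment-size window in bp.
#' @param min_height absolute fluorescence threshold.
#' @param min_frac relative threshold as a fraction of per-sample total height.
#' @return filtered peak table with attribute `empty_samples`.
#' @export
filter_peaks <- function(peaks, min_size = 35, max_size = 550,
                         min_height = 50, min_frac = 0.02) {
    stopifnot(min_size < max_size, min_frac >= 0, min_frac < 1)
    peaks <- peak_table(as.data.frame(peaks))
    if (nrow(peaks) == 0) {
        warning("empty peak table")
        out <- peaks
        attr(out, "empty_samples") <- character(0)
        return(out)
    }
    samples <- unique(peaks$sample_id)
    keep <- peaks$fragment_size >= min_size & peaks$fragment_size <= max_size &
        peaks$height >= min_height
    out <- peaks[keep, , drop = FALSE]
    if (nrow(out) > 0) {
        totals <- tapply(out$height, out$sample_id, sum)
        out <- out[out$height >= min_frac * totals[as.character(out$sample_id)], ,
                   drop = FALSE]
    }
    empty <- setdiff(samples, unique(out$sample_id))
    if (length(empty))
        warning("samples with no surviving peaks: ", paste(empty, collapse = ", "))
    rownames(out) <- NULL
    out <- peak_table(out)
    attr(out, "empty_samples") <- as.character(empty)
    out
}

#' Bin aligned fragments into taxa
#'
#' Groups fragment sizes across samples into shared bins (operational taxa)
#' by greedy single-linkage: sizes are sorted and a fragment joins the current
#' bin while it lies within `(1 - clustering_threshold) * reference` base
#' pairs of the bin's reference (its smallest member); otherwise it opens a
#' new bin. This approximates fingerprint-alignment clustering at a relative
#' threshold (0.99 gives a 1 bp tolerance at 100 bp). Cell values are the
#' relative height of the bin within each sample, so rows sum to 1.
#'
#' @param peaks filtered [peak_table()] (run [filter_peaks()] first).
#' @param clustering_threshold relative clustering threshold in (0, 1].
#' @param size_range permitted fragment-size window; out-of-range fragments
#'   raise an error advising to filter first.
#' @return a relative-abundance [community_matrix()].
#' @export
bin_fragments <- function(peaks, clustering_threshold = 0.99,
                          size_range = c(35, 550)) {
    stopifnot(clustering_threshold > 0, clustering_threshold <= 1)
    peaks <- peak_table(as.data.frame(peaks))
    if (nrow(peaks) == 0)
        return(community_matrix(matrix(numeric(0), 0, 0), is_counts = FALSE))
    if (any(peaks$fragment_size < size_range[1] |
            peaks$fragment_size > size_range[2]))
        stop("fragments outside the size range; run filter_peaks() first")

    sizes <- sort(unique(peaks$fragment_size))
    tol_of <- function(ref) (1 - clustering_threshold) * ref
    bin_id <- integer(length(sizes))
    ref <- sizes[1]; b <- 1L; bin_id[1] <- 1L
    refs <- ref
    for (i in seq_along(sizes)[-1]) {
        if (sizes[i] - ref <= tol_of(ref)) {
            bin_id[i] <- b
        } else {
            b <- b + 1L
            ref <- sizes[i]
            refs[b] <- ref
            bin_id[i] <- b
        }
    }
    bins <- setNames(bin_id, as.character(sizes))
    samples <- unique(peaks$sample_id)
    m <- matrix(0, length(samples), b,
                dimnames = list(samples, sprintf("TRF_%g", refs)))
    pb <- bins[as.character(peaks$fragment_size)]
    for (k in seq_len(nrow(peaks)))
        m[as.character(peaks$sample_id[k]), pb[k]] <-
            m[as.character(peaks$sample_id[k]), pb[k]] + peaks$height[k]
    m <- m / rowSums(m)
    community_matrix(m, is_counts = FALSE)
}

#' Convert relative abundances to integer counts
#'
#' Rescales every sample to integer counts summing exactly to `total` using
#' largest-remainder rounding, guaranteeing that every originally positive
#' taxon keeps a count of at least 1. Needed because the neutral sampling
#' formula is defined on integer abundance configurations; the choice of
#' `total` is an explicit modelling decision.
#'
#' @param cm a [community_matrix()] (counts or relative abundances).
#' @param total target row total; must be at least the number of positive taxa
#'   in every sample.
#' @return integer-count [community_matrix()].
#' @export
to_counts <- function(cm, total) {
    stopifnot(length(total) == 1, total >= 1, total == round(total))
    x <- unclass(cm)
    s_pos <- rowSums(x > 0)
    if (any(total < s_pos))
        stop(sprintf("total = %d too small to keep all positive taxa (max richness %d)",
                     total, max(s_pos)))
    out <- t(apply(x, 1, function(row) {
        p <- row / sum(row)
        raw <- p * total
        base <- floor(raw)
        rem <- total - sum(base)
        if (rem > 0) {
            ord <- order(raw - base, decreasing = TRUE)
            base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
        }
        # restore positivity for taxa rounded to zero
        zero <- which(row > 0 & base == 0)
        for (i in zero) {
            donor <- which.max(base)
            base[donor] <- base[donor] - 1
            base[i] <- 1
        }
        base
    }))
    dimnames(out) <- dimnames(x)
    community_matrix(out, is_counts = TRUE)
}
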