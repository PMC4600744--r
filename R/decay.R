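#' Distance decay of similarity
#'
#' Fits the turnover model `log10(chi_d) = b + z * log10(d)`: similarity
#' declines as a power law of geographic distance, `z` being the turnover
#' rate. The default regresses the log10 mean similarity per log-spaced
#' distance bin on the log10 bin midpoint, weighted by the number of pairs in
#' each bin; `binning = "none"` regresses over raw pairs instead, and
#' `transform = "lin-log"` fits similarity (untransformed) against log10
#' distance.
#'
#' Pairs at non-positive distance are excluded from log-distance fits; bins
#' (or pairs) with non-positive mean similarity are dropped with a warning.
#'
#' @param sim similarity matrix.
#' @param dist distance matrix in metres, aligned with `sim` (same ids and
#'   order).
#' @param transform `"log-log"` (default) or `"lin-log"`.
#' @param binning `"log"` (log-spaced distance bins, default) or `"none"`.
#' @param bins number of distance bins when `binning = "log"`.
#' @param weighting `"pairs"` (bin pair counts as regression weights) or
#'   `"none"`.
#' @return object of class `decay_fit` with elements `z` (slope), `b`
#'   (intercept), `r_squared`, `n_pairs`, `n_bins`, `transform`, `binning`,
#'   `weighting` and the per-bin table.
#' @export
fit_distance_decay <- function(sim, dist, transform = c("log-log", "lin-log"),
                               binning = c("log", "none"), bins = 20,
                               weighting = c("pairs", "none")) {
    transform <- match.arg(transform)
    binning <- match.arg(binning)
    weighting <- match.arg(weighting)
    check_aligned(sim, dist)
    s <- lower_tri(as.matrix(sim))
    d <- lower_tri(as.matrix(dist))
    ok <- is.finite(s) & is.finite(d) & d > 0
    s <- s[ok]; d <- d[ok]
    if (length(s) < 3) stop("fewer than 3 usable pairs")

    if (binning == "log") {
        br <- 10^seq(log10(min(d)), log10(max(d)), length.out = bins + 1)
        br[1] <- br[1] * (1 - 1e-9); br[length(br)] <- br[length(br)] * (1 + 1e-9)
        grp <- cut(d, br, labels = FALSE)
        tab <- data.frame(
            midpoint = sqrt(br[-length(br)] * br[-1])[sort(unique(grp))],
            mean_sim = as.numeric(tapply(s, grp, mean)),
            n = as.numeric(table(grp)))
        drop <- tab$mean_sim <= 0 & transform == "log-log"
        if (any(drop)) {
            warning(sum(drop), " bins with non-positive mean similarity dropped")
            tab <- tab[!drop, , drop = FALSE]
        }
        if (nrow(tab) < 3) stop("fewer than 3 usable distance bins")
        x <- log10(tab$midpoint)
        y <- if (transform == "log-log") log10(tab$mean_sim) else tab$mean_sim
        w <- if (weighting == "pairs") tab$n else rep(1, nrow(tab))
        fit <- lm(y ~ x, weights = w)
        n_pairs <- sum(tab$n)
        n_bins <- nrow(tab)
    } else {
        if (transform == "log-log") {
            bad <- s <= 0
            if (any(bad)) {
                warning(sum(bad), " pairs with non-positive similarity dropped")
                d <- d[!bad]; s <- s[!bad]
            }
        }
        if (length(s) < 3) stop("fewer than 3 usable pairs")
        x <- log10(d)
        y <- if (transform == "log-log") log10(s) else s
        fit <- lm(y ~ x)
        n_pairs <- length(s)
        n_bins <- NA_integer_
        tab <- NULL
    }
    cf <- coef(fit)
    # summary.lm warns on exact fits, which are expected for noiseless input
    r2 <- suppressWarnings(summary(fit)$r.squared)
    structure(list(z = unname(cf[2]), b = unname(cf[1]),
                   r_squared = r2,
                   n_pairs = n_pairs, n_bins = n_bins,
                   transform = transform, binning = binning,
                   weighting = weighting, bins = tab),
              class = "decay_fit")
}

check_aligned <- function(a, b) {
    ra <- rownames(as.matrix(a)); rb <- rownames(as.matrix(b))
    if (nrow(as.matrix(a)) != nrow(as.matrix(b)))
        stop("matrices are not aligned (different sizes)")
    if (!is.null(ra) && !is.null(rb) && !identical(ra, rb))
        stop("matrices are not aligned (different sample ids)")
    invisible(TRUE)
}

#' @export
print.decay_fit <- function(x, ...) {
    cat(sprintf("Distance-decay fit (%s, binning = %s, weights = %s)\n",
                x$transform, x$binning, x$weighting))
    cat(sprintf("  z (slope)  = %.6g\n  b (intercept) = %.6g\n  R^2 = %.4f  (n pairs = %d)\n",
                x$z, x$b, x$r_squared, x$n_pairs))
    invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(b = object$b, z = object$z)

#' Neighbourhood turnover analysis
#'
#' For each focal sample, restricts the data to samples within `radius`
#' metres and computes the mean community similarity, mean habitat similarity
#' and both distance-decay slopes within that neighbourhood. Neighbourhoods
#' with fewer than `min_neighbors` other samples are flagged (and should be
#' excluded from downstream regressions).
#'
#' @param sim_comm community similarity matrix.
#' @param sim_hab habitat similarity matrix (aligned with `sim_comm`).
#' @param dist geographic distance matrix (aligned).
#' @param radius neighbourhood radius in metres (default 140 km, the scale at
#'   which spatial autocorrelation is typically exhausted in regional soil
#'   surveys).
#' @param min_neighbors minimum neighbour count for an unflagged record.
#' @param ... passed to [fit_distance_decay()].
#' @return data.frame with one row per focal sample: `focal_id`, `mean_chi`,
#'   `mean_E`, `z_community`, `z_habitat`, `n_neighbors`, `flagged`.
#' @export
neighborhood_analysis <- function(sim_comm, sim_hab, dist, radius = 140000,
                                  min_neighbors = 5, ...) {
    stopifnot(radius > 0)
    check_aligned(sim_comm, dist)
    check_aligned(sim_hab, dist)
    ids <- rownames(as.matrix(dist))
    n <- length(ids)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        idx <- which(dist[i, ] <= radius)
        n_nb <- length(idx) - 1
        zc <- zh <- mc <- me <- NA_real_
        if (n_nb >= 1) {
            sc <- as.matrix(sim_comm)[idx, idx, drop = FALSE]
            sh <- as.matrix(sim_hab)[idx, idx, drop = FALSE]
            mc <- mean(lower_tri(sc))
            me <- mean(lower_tri(sh), na.rm = TRUE)
            dd <- dist[idx, idx, drop = FALSE]
            zc <- tryCatch(fit_distance_decay(sc, dd, ...)$z, error = function(e) NA_real_)
            zh <- tryCatch(fit_distance_decay(sh, dd, ...)$z, error = function(e) NA_real_)
        }
        out[[i]] <- data.frame(focal_id = ids[i], mean_chi = mc, mean_E = me,
                               z_community = zc, z_habitat = zh,
                               n_neighbors = n_nb,
                               flagged = n_nb < min_neighbors,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Type II linear regression
#'
#' Ordinary least squares (the default, matching the convention of reporting
#' type II model fits by their OLS estimate), major-axis (MA) and standardized
#' major-axis (SMA) slopes, for regressions where both variables carry error.
#'
#' @param x,y numeric vectors (at least 3 finite pairs).
#' @param method `"OLS"`, `"MA"` or `"SMA"`.
#' @return object of class `typeII_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided test of the correlation), `method`, `n`.
#' @export
typeII_regression <- function(x, y, method = c("OLS", "MA", "SMA")) {
    method <- match.arg(method)
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 finite pairs")
    if (var(x) == 0) stop("zero variance in x")
    r <- cor(x, y)
    slope <- switch(method,
        OLS = cov(x, y) / var(x),
        SMA = sign(if (r == 0) 1 else r) * sd(y) / sd(x),
        MA = {
            sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
            if (sxy == 0) 0
            else (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
        })
    intercept <- mean(y) - slope * mean(x)
    p <- if (var(y) == 0) 0 else cor.test(x, y)$p.value
    structure(list(slope = slope, intercept = intercept, r_squared = r^2,
                   p_value = p, method = method, n = length(x)),
              class = "typeII_fit")
}

#' @export
print.typeII_fit <- function(x, ...) {
    cat(sprintf("Type II regression (%s): slope = %.6g, intercept = %.6g, R^2 = %.4f, p = %.4g, n = %d\n",
                x$method, x$slope, x$intercept, x$r_squared, x$p_value, x$n))
    invisible(x)
}

#' @export
coef.typeII_fit <- function(object, ...)
    c(intercept = object$intercept, slope = object$slope)

#' Mantel test between two similarity/distance matrices
#'
#' Pearson correlation of the strict lower triangles, with a one-sided
#' permutation p-value obtained by shuffling the sample labels of the second
#' matrix (the standard Mantel procedure).
#'
#' @param simA,simB aligned square matrices (same sample ids).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for reproducible p-values.
#' @return list with `statistic` (Mantel r), `p_value`, `n_perm`.
#' @export
mantel_test <- function(simA, simB, n_perm = 9999, seed = NULL) {
    check_aligned(simA, simB)
    if (!is.null(seed)) set.seed(seed)
    a <- as.matrix(simA); b <- as.matrix(simB)
    va <- lower_tri(a)
    r <- cor(va, lower_tri(b))
    n <- nrow(a)
    cnt <- 0L
    for (k in seq_len(n_perm)) {
        p <- sample.int(n)
        if (cor(va, lower_tri(b[p, p])) >= r) cnt <- cnt + 1L
    }
    list(statistic = r, p_value = (cnt + 1) / (n_perm + 1), n_perm = n_perm)
}
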