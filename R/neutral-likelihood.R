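#' Abundance configuration of one sample
#'
#' Strips a count vector to its positive entries, the form the neutral
#' sampling formula operates on.
#'
#' @param counts integer abundance vector (zeros allowed, dropped).
#' @return list with `n` (positive abundances), `J` (total individuals),
#'   `S` (species count) and `phi` (multiplicities: `phi[j]` = number of
#'   species with abundance j).
#' @export
abundance_config <- function(counts) {
    counts <- as.numeric(counts)
    if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    n <- as.integer(counts[counts > 0])
    if (!length(n)) stop("configuration has no individuals")
    list(n = n, J = sum(n), S = length(n), phi = tabulate(n))
}

#' Etienne sampling-formula coefficients K(D, A)
#'
#' `K(D, A)` sums, over all ways of assigning each species i a number of
#' immigrant ancestors `a_i` (with `sum(a_i) = A`, `1 <= a_i <= n_i`), the
#' product of `s1(n_i, a_i) * (a_i - 1)! / (n_i - 1)!` where `s1` is the
#' unsigned Stirling number of the first kind. Computed by log-space
#' convolution of per-species coefficient polynomials, so no overflow occurs
#' at any configuration size.
#'
#' @param D an [abundance_config()] (or an integer count vector).
#' @param max_J guard on the O(J^2) convolution; raise explicitly for larger
#'   configurations.
#' @return numeric vector `log K(D, A)` for `A = S, ..., J`.
#' @export
compute_logK <- function(D, max_J = 20000) {
    if (is.numeric(D)) D <- abundance_config(D)
    if (D$J > max_J)
        stop("J = ", D$J, " exceeds the guard (max_J = ", max_J,
             "); pass a larger max_J to override")
    lk <- logK_cpp(as.integer(D$n))
    names(lk) <- as.character(seq.int(D$S, D$J))
    lk
}

#' Ewens sampling-formula log-likelihood
#'
#' Probability of an abundance configuration in a neutral metacommunity
#' sample without dispersal limitation; the I -> Inf limit of the Etienne
#' formula. `log P = log J! - sum log n_i - sum log phi_j! + S log theta -
#' log (theta)_J`.
#'
#' @param D an [abundance_config()] (or count vector).
#' @param theta fundamental biodiversity number, > 0.
#' @return log-likelihood.
#' @export
ewens_loglik <- function(D, theta) {
    if (is.numeric(D)) D <- abundance_config(D)
    stopifnot(theta > 0)
    lgamma(D$J + 1) - sum(log(D$n)) - sum(lgamma(D$phi + 1)) +
        D$S * log(theta) - log_rising(theta, D$J)
}

#' Etienne sampling-formula log-likelihood of one local community
#'
#' `log P(D | theta, I, J) = log J! - sum log n_i - sum log phi_j! +
#' S log theta - log (I)_J + log sum_A K(D,A) I^A / (theta)_A`, with rising
#' factorials and the A-sum evaluated in log space. `I = Inf` returns the
#' Ewens limit.
#'
#' @param D an [abundance_config()] (or count vector).
#' @param theta fundamental biodiversity number, > 0.
#' @param I immigration parameter, > 0 (may be `Inf`).
#' @param logK optional precomputed [compute_logK()] output for `D` (cached
#'   by callers that evaluate many (theta, I) pairs).
#' @return log-likelihood (finite for valid parameters).
#' @export
loglik_single <- function(D, theta, I, logK = NULL) {
    if (is.numeric(D)) D <- abundance_config(D)
    stopifnot(theta > 0, I > 0)
    if (!is.finite(I)) return(ewens_loglik(D, theta))
    if (is.null(logK)) logK <- compute_logK(D)
    A <- seq.int(D$S, D$J)
    ll <- lgamma(D$J + 1) - sum(log(D$n)) - sum(lgamma(D$phi + 1)) +
        D$S * log(theta) - log_rising(I, D$J) +
        logsumexp(logK + A * log(I) - log_rising(theta, A))
    if (!is.finite(ll))
        stop(sprintf("non-finite log-likelihood at theta = %g, I = %g", theta, I))
    ll
}

# Ewens ML for theta on a single (pooled) configuration: maximizes
# S log theta - log (theta)_J. Returns list(theta, boundary).
fit_theta_ewens <- function(D, interval = log(c(1e-4, 1e7)), tol = 1e-8) {
    if (is.numeric(D)) D <- abundance_config(D)
    if (D$S == D$J && D$S > 1) {
        # all singletons: likelihood increases without bound in theta
        return(list(theta = exp(interval[2]), boundary = TRUE))
    }
    f <- function(lt) D$S * lt - log_rising(exp(lt), D$J)
    op <- optimize(f, interval, maximum = TRUE, tol = tol)
    boundary <- min(abs(op$maximum - interval)) < 1e-4
    list(theta = exp(op$maximum), boundary = boundary)
}
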