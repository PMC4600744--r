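#' Principal-component scores
#'
#' First `n_components` PCA score vectors of a samples x variables matrix,
#' with a deterministic sign convention (the largest-magnitude loading of
#' each component is made positive). Columns are centred; set `scale = TRUE`
#' for variables on heterogeneous scales (habitat data).
#'
#' @param x numeric matrix (rows with missing values are not allowed; drop or
#'   complete them first).
#' @param n_components number of components requested; if the matrix rank is
#'   lower, fewer are returned with a message.
#' @param scale logical; scale columns to unit variance.
#' @return samples x components score matrix with attribute `sdev` (component
#'   standard deviations).
#' @export
pc_scores <- function(x, n_components = 5, scale = FALSE) {
    x <- as.matrix(unclass(x))
    if (anyNA(x)) stop("missing values; complete the matrix before PCA")
    if (nrow(x) < n_components + 1)
        stop("need at least n_components + 1 samples")
    p <- prcomp(x, center = TRUE, scale. = scale)
    k <- min(n_components, sum(p$sdev > max(p$sdev) * 1e-10))
    if (k < n_components)
        message("rank ", k, " < ", n_components, " requested components")
    sc <- p$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(p$rotation[, j]))
        if (p$rotation[i, j] < 0) sc[, j] <- -sc[, j]
    }
    attr(sc, "sdev") <- p$sdev[seq_len(k)]
    sc
}

#' Empirical (Matheron) variogram
#'
#' Semivariance `gamma(h) = mean((z_i - z_j)^2) / 2` over site pairs within
#' equal-width lag bins up to `max_lag`.
#'
#' @param values numeric vector, one value per site.
#' @param sites site table (or any data.frame with `x`, `y` in metres).
#' @param n_lags number of lag bins.
#' @param max_lag maximum lag distance; default half the maximum inter-site
#'   distance (beyond that, pair counts are too low to be informative).
#' @return data.frame of class `empirical_variogram`: `lag` (bin midpoint,
#'   m), `gamma`, `n_pairs`; empty bins are dropped with a warning.
#' @export
empirical_variogram <- function(values, sites, n_lags = 12, max_lag = NULL) {
    stopifnot(length(values) == nrow(sites), n_lags >= 1)
    d <- lower_tri(as.matrix(dist(cbind(sites$x, sites$y))))
    g <- lower_tri(outer(values, values, "-")^2) / 2
    if (is.null(max_lag)) max_lag <- max(d) / 2
    stopifnot(max_lag > 0)
    keep <- d > 0 & d <= max_lag
    d <- d[keep]; g <- g[keep]
    if (!length(d)) stop("no site pairs within max_lag")
    br <- seq(0, max_lag, length.out = n_lags + 1)
    grp <- cut(d, br, labels = FALSE, include.lowest = TRUE)
    present <- sort(unique(grp))
    if (length(present) < n_lags) warning("empty lag bins dropped")
    out <- data.frame(
        lag = (br[-1] + br[-length(br)])[present] / 2,
        gamma = as.numeric(tapply(g, grp, mean)),
        n_pairs = as.numeric(table(grp)))
    class(out) <- c("empirical_variogram", "data.frame")
    out
}

variogram_curve <- function(h, model, c0, c1, a) {
    str_part <- switch(model,
        spherical = ifelse(h <= a, 1.5 * h / a - 0.5 * (h / a)^3, 1),
        exponential = 1 - exp(-h / a),
        stop("unknown model"))
    c0 + c1 * str_part
}

#' Fit a variogram model
#'
#' Fits nugget `c0`, partial sill `c1` and range `a` of a spherical or
#' exponential model to an empirical variogram by weighted least squares with
#' Cressie weights (`n_pairs / gamma_model^2`), using multi-start bounded
#' optimization; `method = "ml"` instead maximizes the Gaussian likelihood of
#' the site values under the implied covariance (requires `values` and
#' `sites`). The nugget/sill ratio `100 * c0 / (c0 + c1)` is the percentage
#' of spatially unstructured variance and is classified by
#' [classify_dependence()].
#'
#' @param ev an [empirical_variogram()] with at least 4 usable lags.
#' @param model `"spherical"` or `"exponential"`.
#' @param method `"wls"` (default) or `"ml"`.
#' @param values,sites required for `method = "ml"` only.
#' @return object of class `variogram_fit`: `model`, `nugget`,
#'   `partial_sill`, `range`, `nugget_sill_ratio`, `dependence_class`,
#'   `converged`, `objective`, `method`.
#' @export
fit_variogram <- function(ev, model = c("spherical", "exponential"),
                          method = c("wls", "ml"),
                          values = NULL, sites = NULL) {
    model <- match.arg(model)
    method <- match.arg(method)
    if (nrow(ev) < 4) stop("need at least 4 usable lags")
    svar <- max(ev$gamma)
    hmax <- max(ev$lag)

    if (method == "wls") {
        obj <- function(p) {
            g <- variogram_curve(ev$lag, model, p[1], p[2], p[3])
            sum(ev$n_pairs * (ev$gamma - g)^2 / pmax(g, 1e-12)^2)
        }
    } else {
        if (is.null(values) || is.null(sites))
            stop("method = 'ml' needs `values` and `sites`")
        h <- as.matrix(dist(cbind(sites$x, sites$y)))
        n <- length(values)
        obj <- function(p) {
            # covariance implied by the variogram model: sill - gamma(h)
            sill <- p[1] + p[2]
            C <- sill - variogram_curve(h, model, p[1], p[2], p[3])
            diag(C) <- sill + 1e-8 * max(sill, 1)
            ch <- tryCatch(chol(C), error = function(e) NULL)
            if (is.null(ch)) return(1e10)
            z <- values - mean(values)
            q <- backsolve(ch, forwardsolve(t(ch), z))
            sum(log(diag(ch))) + 0.5 * sum(z * q)
        }
    }

    starts <- expand.grid(c0 = c(1e-3 * svar, 0.3 * svar, 0.8 * svar),
                          c1 = c(0.2 * svar, svar),
                          a = c(hmax / 4, hmax / 2, hmax))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
        op <- tryCatch(
            optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                  lower = c(0, 0, hmax * 1e-3),
                  upper = c(2 * svar, 5 * svar, 10 * hmax)),
            error = function(e) NULL)
        if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("variogram optimization failed at every start")
    p <- pmax(best$par, c(0, 0, hmax * 1e-3))
    ratio <- 100 * p[1] / (p[1] + p[2])
    structure(list(model = model, nugget = p[1], partial_sill = p[2],
                   range = p[3], nugget_sill_ratio = ratio,
                   dependence_class = classify_dependence(ratio),
                   converged = best$convergence == 0,
                   objective = best$value, method = method),
              class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
    cat(sprintf("%s variogram (%s): nugget = %.4g, partial sill = %.4g, range = %.4g m\n",
                x$model, x$method, x$nugget, x$partial_sill, x$range))
    cat(sprintf("  nugget/sill ratio = %.1f%% -> %s spatial dependence%s\n",
                x$nugget_sill_ratio, x$dependence_class,
                if (x$converged) "" else "  [NOT converged]"))
    invisible(x)
}

#' @export
predict.variogram_fit <- function(object, h, ...)
    variogram_curve(h, object$model, object$nugget, object$partial_sill,
                    object$range)

#' Classify spatial dependence from the nugget/sill ratio
#'
#' Cambardella classes: ratios below 25% indicate strong spatial dependence,
#' 25 to 75% (closed interval) moderate, and above 75% weak.
#'
#' @param ratio nugget/sill ratio as a percentage, in \code{[0, 100]}.
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_dependence <- function(ratio) {
    if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 100))
        stop("ratio must be in [0, 100]")
    ifelse(ratio < 25, "strong", ifelse(ratio <= 75, "moderate", "weak"))
}
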