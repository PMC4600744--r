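similarity_matrix <- function(m, kind) {
    m <- as.matrix(m)
    diag(m) <- 1
    structure(m, class = c("similarity_matrix", class(m)), kind = kind)
}

#' Pairwise Sorensen community similarity
#'
#' Binary mode computes 2a/(2a + b + c) on presence/absence (a shared taxa,
#' b and c unique taxa); abundance mode computes 1 - Bray-Curtis
#' dissimilarity. Distances are delegated to [vegan::vegdist()].
#'
#' @param cm a [community_matrix()] with at least two samples.
#' @param mode `"binary"` (default, the classical Sorensen index) or
#'   `"abundance"`.
#' @return symmetric similarity matrix in \code{[0, 1]} with unit diagonal,
#'   attribute `kind = "community_sorensen"`.
#' @export
sorensen_similarity <- function(cm, mode = c("binary", "abundance")) {
    mode <- match.arg(mode)
    x <- unclass(cm)
    if (nrow(x) < 2) stop("need at least two samples")
    empty <- rownames(x)[rowSums(x) == 0]
    if (length(empty))
        stop("all-zero samples: ", paste(empty, collapse = ", "))
    d <- vegan::vegdist(x, method = "bray", binary = (mode == "binary"))
    similarity_matrix(1 - as.matrix(d), kind = "community_sorensen")
}

#' Pairwise habitat similarity
#'
#' Euclidean distance on standardized habitat variables, rescaled to a
#' similarity by the maximum observed distance:
#' `E_d = 1 - Euc_d / Euc_max`, so the most dissimilar pair of samples scores
#' exactly 0. Missing values are handled pairwise-complete (the distance over
#' shared complete variables is scaled up to the full variable count, the
#' behaviour of [stats::dist()]); a pair with no shared complete variable
#' yields `NA` and a warning.
#'
#' @param hm a habitat matrix; standardized internally (with a message) if not
#'   already.
#' @return symmetric similarity matrix, attribute `kind = "habitat_euclidean"`.
#' @export
habitat_similarity <- function(hm) {
    if (!isTRUE(attr(hm, "standardized"))) {
        message("standardizing habitat variables")
        hm <- standardize_habitat(hm)
    }
    d <- as.matrix(dist(unclass(hm)))
    if (anyNA(d)) warning("sample pairs with no shared complete habitat variable")
    emax <- max(d, na.rm = TRUE)
    if (emax == 0) stop("all habitat rows identical; similarity undefined")
    similarity_matrix(1 - d / emax, kind = "habitat_euclidean")
}

#' Pairwise geographic distance in metres
#'
#' Euclidean distance on projected planar coordinates (the default; use an
#' equal-area projection in metres). `method = "haversine"` treats `x` as
#' longitude and `y` as latitude in degrees and returns great-circle metres.
#'
#' @param sites site table with columns `sample_id`, `x`, `y`.
#' @param method `"euclidean"` (projected metres) or `"haversine"`.
#' @return symmetric distance matrix with zero diagonal, dimnames = sample ids.
#' @export
geographic_distance <- function(sites, method = c("euclidean", "haversine")) {
    method <- match.arg(method)
    if (anyNA(sites$x) || anyNA(sites$y) ||
        any(!is.finite(sites$x)) || any(!is.finite(sites$y)))
        stop("non-finite coordinates")
    if (method == "euclidean") {
        d <- as.matrix(dist(cbind(sites$x, sites$y)))
    } else {
        rad <- pi / 180
        lon <- sites$x * rad; lat <- sites$y * rad
        n <- length(lon)
        d <- matrix(0, n, n)
        for (i in seq_len(n)) {
            a <- sin((lat - lat[i]) / 2)^2 +
                cos(lat[i]) * cos(lat) * sin((lon - lon[i]) / 2)^2
            d[i, ] <- 2 * 6371008.8 * asin(pmin(1, sqrt(a)))
        }
    }
    dimnames(d) <- list(sites$sample_id, sites$sample_id)
    d
}
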