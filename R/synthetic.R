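#' Scenario configuration for the synthetic-data generator
#'
#' Bundles (and validates) all ground-truth parameters the generator needs.
#' The defaults emulate a national-scale soil survey: 183 sites on a 20 km
#' grid, four soil layers, neutral parameters of the magnitude reported for
#' soil bacterial metacommunities (theta about 35, per-layer immigration
#' declining with depth), local communities of J = 1000 individuals, and 51
#' spatially autocorrelated habitat variables whose variance grows with
#' depth.
#'
#' @param n_sites number of sites.
#' @param layout `"grid"` (square lattice) or `"random"` (uniform in the same
#'   extent).
#' @param grid_spacing lattice spacing in metres.
#' @param n_layers soil layers (1-4); every site is sampled in every layer.
#' @param theta metacommunity biodiversity number.
#' @param I immigration parameter; scalar or one value per layer.
#' @param J individuals per local community.
#' @param lambda niche strength in \code{[0, 1]}: 0 = pure neutral assembly,
#'   1 = pure niche assembly along the first habitat gradient.
#' @param n_habitat_vars number of habitat variables.
#' @param habitat_range range parameter (m) of the exponential spatial
#'   covariance of habitat variables (effective range about 3x this).
#' @param habitat_nugget fraction of habitat variance that is spatially
#'   unstructured noise.
#' @param layer_var_mult per-layer habitat variance multipliers; default
#'   `1 + 0.5 * (layer - 1)` (deeper layers more variable).
#' @param niche_width width of the Gaussian species response on the
#'   standardized habitat gradient.
#' @param height_scale fluorescence units per individual when emitting
#'   fingerprint peaks.
#' @param clustering_threshold fragment-binning threshold for
#'   [add_fingerprint_noise()].
#' @param seed RNG seed recorded in all outputs.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 183, layout = c("grid", "random"),
                            grid_spacing = 20000, n_layers = 4,
                            theta = 34.68,
                            I = c(18.60, 14.43, 10.12, 11.88),
                            J = 1000, lambda = 0,
                            n_habitat_vars = 51, habitat_range = 50000,
                            habitat_nugget = 0.1, layer_var_mult = NULL,
                            niche_width = 0.3, height_scale = 20,
                            clustering_threshold = 0.99, seed = 1) {
    layout <- match.arg(layout)
    stopifnot(n_sites >= 1, grid_spacing > 0, n_layers >= 1, n_layers <= 4,
              theta > 0, all(I > 0), J >= 1,
              lambda >= 0, lambda <= 1,
              n_habitat_vars >= 1, habitat_range >= 0,
              habitat_nugget >= 0, habitat_nugget <= 1,
              niche_width > 0, height_scale > 0)
    if (is.null(layer_var_mult)) layer_var_mult <- 1 + 0.5 * (seq_len(n_layers) - 1)
    I <- rep_len(I, n_layers)
    layer_var_mult <- rep_len(layer_var_mult, n_layers)
    structure(list(n_sites = n_sites, layout = layout,
                   grid_spacing = grid_spacing, n_layers = n_layers,
                   theta = theta, I = I, J = J, lambda = lambda,
                   n_habitat_vars = n_habitat_vars,
                   habitat_range = habitat_range,
                   habitat_nugget = habitat_nugget,
                   layer_var_mult = layer_var_mult,
                   niche_width = niche_width, height_scale = height_scale,
                   clustering_threshold = clustering_threshold,
                   seed = as.integer(seed)),
              class = "scenario_config")
}

#' Generate a site table
#'
#' Grid layout places `n_sites` on a square lattice at `grid_spacing` metres
#' (row-major, truncated to `n_sites`); random layout draws uniform
#' coordinates over the same extent. Every site is replicated across
#' `n_layers` soil layers with layer-indexed sample ids. Land-use classes are
#' assigned in six contiguous spatial blocks (west-to-east), so land use
#' correlates with space as in real landscapes.
#'
#' @param config a [scenario_config()].
#' @return site table data.frame (`sample_id, site_id, x, y, layer,
#'   land_use`) with attribute `seed`.
#' @export
make_sites <- function(config) {
    stopifnot(inherits(config, "scenario_config"))
    set.seed(config$seed)
    n_side <- ceiling(sqrt(config$n_sites))
    extent <- config$grid_spacing * (n_side - 1)
    if (config$layout == "grid") {
        g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
        g <- g[order(g$y, g$x), ][seq_len(config$n_sites), ]
        x <- (g$x - 1) * config$grid_spacing
        y <- (g$y - 1) * config$grid_spacing
    } else {
        x <- runif(config$n_sites, 0, max(extent, config$grid_spacing))
        y <- runif(config$n_sites, 0, max(extent, config$grid_spacing))
    }
    site_id <- sprintf("S%03d", seq_len(config$n_sites))
    blocks <- cut(rank(x + 1e-9 * y, ties.method = "first"), 6, labels = FALSE)
    land_use <- land_use_classes[blocks]
    out <- do.call(rbind, lapply(seq_len(config$n_layers), function(l)
        data.frame(sample_id = paste0(site_id, "_L", l), site_id = site_id,
                   x = x, y = y, layer = l, land_use = land_use,
                   stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    attr(out, "seed") <- config$seed
    validate_site_table(out)
}

# Gaussian random field on the given coordinates: exponential covariance of
# the given range plus an independent nugget component.
grf_exponential <- function(x, y, range, nugget) {
    n <- length(x)
    if (range <= 0) return(rnorm(n))
    h <- as.matrix(dist(cbind(x, y)))
    C <- (1 - nugget) * exp(-h / range)
    diag(C) <- 1 + 1e-8
    L <- chol(C)
    drop(crossprod(L, rnorm(n)))
}

#' Generate spatially autocorrelated habitat variables
#'
#' Each variable is an independent Gaussian random field over the site
#' coordinates with exponential spatial covariance of range
#' `habitat_range` plus a `habitat_nugget` fraction of unstructured noise;
#' values in layer l are scaled by `sqrt(layer_var_mult[l])`, so deeper
#' layers show larger sample-to-sample variance.
#'
#' @param sites site table from [make_sites()].
#' @param config the [scenario_config()].
#' @return unstandardized habitat matrix (samples x variables) with attribute
#'   `seed`.
#' @export
make_habitat <- function(sites, config) {
    stopifnot(inherits(config, "scenario_config"))
    set.seed(config$seed + 1L)
    vars <- sprintf("hab%02d", seq_len(config$n_habitat_vars))
    m <- matrix(NA_real_, nrow(sites), config$n_habitat_vars,
                dimnames = list(sites$sample_id, vars))
    for (l in sort(unique(sites$layer))) {
        rows <- which(sites$layer == l)
        sc <- sqrt(config$layer_var_mult[l])
        for (v in seq_len(config$n_habitat_vars))
            m[rows, v] <- sc * grf_exponential(sites$x[rows], sites$y[rows],
                                               config$habitat_range,
                                               config$habitat_nugget)
    }
    out <- habitat_matrix(m, standardized = FALSE)
    attr(out, "seed") <- config$seed
    out
}

#' Generate communities along the neutral-to-niche continuum
#'
#' Per layer: a neutral component is drawn with [simulate_neutral()] (shared
#' metacommunity, the layer's immigration parameter), and a niche component
#' assigns each species a Gaussian response (random optimum, common width
#' `niche_width`) to the layer's first habitat gradient, weighted by the
#' species' regional abundance. With niche strength `lambda = 0` the neutral
#' counts are returned unchanged (exactly the [simulate_neutral()]
#' distribution); for `lambda > 0` each community is a multinomial draw of
#' size J from the mixture `(1 - lambda) * neutral + lambda * niche` of
#' relative abundances. Species pools are independent between layers.
#'
#' @param sites site table from [make_sites()].
#' @param habitat habitat matrix from [make_habitat()]; may be `NULL` when
#'   `lambda = 0`.
#' @param config the [scenario_config()].
#' @return counts [community_matrix()] (rows follow `sites$sample_id`; every
#'   row sums to J) with attribute `seed`.
#' @export
make_communities <- function(sites, habitat, config) {
    stopifnot(inherits(config, "scenario_config"))
    lambda <- config$lambda
    if (lambda > 0 && is.null(habitat))
        stop("habitat matrix required when lambda > 0")
    set.seed(config$seed + 2L)
    blocks <- list()
    for (l in sort(unique(sites$layer))) {
        rows <- which(sites$layer == l)
        neutral <- unclass(simulate_neutral(length(rows), config$J,
                                            config$theta, config$I[l]))
        colnames(neutral) <- sprintf("L%d_%s", l, colnames(neutral))
        if (lambda == 0) {
            counts <- neutral
        } else {
            p_neutral <- neutral / rowSums(neutral)
            g <- unclass(habitat)[rows, 1]
            g <- (g - mean(g)) / sd(g)
            S <- ncol(neutral)
            optima <- runif(S, min(g), max(g))
            f <- exp(-outer(g, optima, "-")^2 / (2 * config$niche_width^2))
            regional <- colSums(neutral) / sum(neutral)
            p_niche <- f * rep(regional, each = length(rows))
            p_niche <- p_niche / rowSums(p_niche)
            p <- (1 - lambda) * p_neutral + lambda * p_niche
            counts <- t(apply(p, 1, function(pr) rmultinom(1, config$J, pr)))
            dimnames(counts) <- dimnames(neutral)
        }
        rownames(counts) <- sites$sample_id[rows]
        blocks[[as.character(l)]] <- counts
    }
    taxa <- unlist(lapply(blocks, colnames), use.names = FALSE)
    m <- matrix(0L, nrow(sites), length(taxa),
                dimnames = list(sites$sample_id, taxa))
    for (b in blocks) m[rownames(b), colnames(b)] <- b
    out <- community_matrix(m, is_counts = TRUE,
                            require_positive_rows = FALSE)
    attr(out, "seed") <- config$seed
    out
}

#' Add fingerprint (T-RFLP) observation noise
#'
#' Emulates fingerprint observation of a known community: every taxon is
#' assigned a random terminal-fragment size in 35-550 bp, peak heights are
#' proportional to abundance (`height_scale` fluorescence units per
#' individual), and the peak table is pushed through the standard processing
#' chain ([filter_peaks()] then [bin_fragments()]), which coalesces taxa
#' whose fragments fall within the binning tolerance and removes small
#' peaks — the resolution loss and detection-threshold censoring inherent in
#' fingerprint data.
#'
#' @param cm counts [community_matrix()] (the ground truth).
#' @param config the [scenario_config()].
#' @return list with `peaks` (the raw emitted peak table) and `community`
#'   (the post-filter, binned relative-abundance matrix).
#' @export
add_fingerprint_noise <- function(cm, config) {
    stopifnot(inherits(config, "scenario_config"), is_counts(cm))
    set.seed(config$seed + 3L)
    x <- unclass(cm)
    sizes <- runif(ncol(x), 35, 550)
    recs <- which(x > 0, arr.ind = TRUE)
    peaks <- peak_table(data.frame(
        sample_id = rownames(x)[recs[, 1]],
        fragment_size = sizes[recs[, 2]],
        height = x[recs] * config$height_scale,
        stringsAsFactors = FALSE))
    peaks <- peaks[order(peaks$sample_id, peaks$fragment_size), ]
    rownames(peaks) <- NULL
    filtered <- suppressWarnings(filter_peaks(peaks))
    community <- bin_fragments(filtered,
                               clustering_threshold = config$clustering_threshold)
    list(peaks = peaks, community = community)
}
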