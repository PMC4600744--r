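#' Simulate neutral local communities (sequential urn scheme)
#'
#' Builds each local community individual by individual: individual k is a
#' new immigrant ancestor with probability `I/(I + k - 1)`, otherwise it
#' copies the species of a uniformly chosen earlier individual of the same
#' community. Each new ancestor draws its metacommunity species from an Ewens
#' urn with parameter theta (ancestor a founds a new species with probability
#' `theta/(theta + a - 1)`, otherwise copies a uniformly chosen earlier
#' ancestor). With `shared_metacommunity = TRUE` (default) the ancestor urn
#' is shared across communities, so communities sample one common
#' metacommunity and share species identities; with `FALSE` every community
#' gets an independent metacommunity (an exact Ewens sample when `I = Inf`).
#'
#' @param n_communities number of local communities.
#' @param J individuals per community.
#' @param theta fundamental biodiversity number, > 0.
#' @param I immigration parameter (> 0, may be `Inf`); scalar or one value
#'   per community.
#' @param seed optional RNG seed.
#' @param shared_metacommunity share the metacommunity urn across
#'   communities.
#' @return integer-count [community_matrix()] (`sim1..simN` x `sp1..spS`);
#'   every row sums to `J`.
#' @export
simulate_neutral <- function(n_communities, J, theta, I, seed = NULL,
                             shared_metacommunity = TRUE) {
    stopifnot(n_communities >= 1, J >= 1, theta > 0, all(I > 0),
              length(I) %in% c(1L, n_communities))
    if (!is.null(seed)) set.seed(seed)
    m <- urn_sim_cpp(as.integer(n_communities), as.integer(J),
                     as.numeric(theta), as.numeric(I),
                     isTRUE(shared_metacommunity))
    dimnames(m) <- list(paste0("sim", seq_len(nrow(m))),
                        paste0("sp", seq_len(ncol(m))))
    community_matrix(m, is_counts = TRUE)
}
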