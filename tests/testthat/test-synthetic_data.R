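test_that("site layouts have the right geometry and determinism", {
    cfg <- scenario_config(n_sites = 9, n_layers = 1, grid_spacing = 20000,
                           seed = 1)
    sites <- make_sites(cfg)
    expect_equal(nrow(sites), 9)
    d <- geographic_distance(sites)
    expect_equal(max(d), 20000 * 2 * sqrt(2))  # 3x3 lattice diagonal

    cfg4 <- scenario_config(n_sites = 9, n_layers = 4, seed = 1)
    s4 <- make_sites(cfg4)
    expect_equal(nrow(s4), 36)
    expect_equal(unname(table(s4$layer)), rep(9L, 4), ignore_attr = TRUE)

    expect_identical(make_sites(cfg4), make_sites(cfg4))

    # land use is assigned in contiguous west-to-east blocks
    cfgL <- scenario_config(n_sites = 60, n_layers = 1, seed = 2)
    sL <- make_sites(cfgL)
    ord <- sL[order(sL$x, sL$y), "land_use"]
    expect_equal(length(unique(sL$land_use)), 6)
    expect_equal(sum(ord[-1] != ord[-length(ord)]), 5)  # exactly 5 boundaries
})

test_that("generators are fully deterministic under a fixed seed", {
    cfg <- scenario_config(n_sites = 12, n_layers = 2, J = 100,
                           n_habitat_vars = 4, lambda = 0.5, seed = 7)
    s <- make_sites(cfg)
    h1 <- make_habitat(s, cfg); h2 <- make_habitat(s, cfg)
    expect_identical(h1, h2)
    c1 <- make_communities(s, h1, cfg); c2 <- make_communities(s, h2, cfg)
    expect_identical(c1, c2)
    f1 <- add_fingerprint_noise(c1, cfg); f2 <- add_fingerprint_noise(c2, cfg)
    expect_identical(f1, f2)
})

test_that("habitat fields show more variance in deeper layers and spatial structure", {
    cfg <- scenario_config(n_sites = 49, n_layers = 3, n_habitat_vars = 8,
                           habitat_range = 60000, seed = 10)
    sites <- make_sites(cfg)
    hab <- make_habitat(sites, cfg)
    v <- vapply(1:3, function(l)
        mean(apply(unclass(hab)[sites$layer == l, ], 2, var)), 0)
    expect_gt(v[3], v[1])  # deeper layers more variable on average

    # habitat similarity decays with distance when the range is moderate
    l1 <- sites$layer == 1
    e <- suppressMessages(habitat_similarity(
        habitat_matrix(unclass(hab)[l1, , drop = FALSE])))
    d <- geographic_distance(sites[l1, ])
    expect_lt(cor(lower_tri(as.matrix(e)), lower_tri(d)), -0.2)
})

test_that("habitat spatial dependence tracks the configured range", {
    # near-zero range: unstructured field, weak dependence
    cfg0 <- scenario_config(n_sites = 100, n_layers = 1, habitat_range = 1,
                            n_habitat_vars = 2, seed = 3)
    s0 <- make_sites(cfg0)
    h0 <- make_habitat(s0, cfg0)
    f0 <- suppressWarnings(fit_variogram(
        empirical_variogram(unclass(h0)[, 1], s0, n_lags = 12), "exponential"))
    expect_gt(f0$nugget_sill_ratio, 75)
    expect_identical(f0$dependence_class, "weak")

    # range far beyond the extent (and no nugget): strong dependence
    cfgG <- scenario_config(n_sites = 100, n_layers = 1, habitat_range = 5e5,
                            habitat_nugget = 0, n_habitat_vars = 2, seed = 3)
    sG <- make_sites(cfgG)
    hG <- make_habitat(sG, cfgG)
    fG <- suppressWarnings(fit_variogram(
        empirical_variogram(unclass(hG)[, 1], sG, n_lags = 12), "exponential"))
    expect_lt(fG$nugget_sill_ratio, 25)
    expect_identical(fG$dependence_class, "strong")
})

test_that("communities conserve J and interpolate between neutral and niche", {
    cfg <- scenario_config(n_sites = 10, n_layers = 2, J = 200, lambda = 0.5,
                           n_habitat_vars = 3, seed = 5)
    sites <- make_sites(cfg)
    hab <- make_habitat(sites, cfg)
    cm <- make_communities(sites, hab, cfg)
    expect_equal(unname(rowSums(unclass(cm))), rep(200, 20))
    expect_identical(rownames(cm), sites$sample_id)

    # lambda = 0 is exactly the neutral simulator's output distribution:
    # compare richness across independent replicates
    rich0 <- vapply(1:60, function(s) {
        cfg0 <- scenario_config(n_sites = 6, n_layers = 1, J = 80, lambda = 0,
                                seed = 1000 + s)
        mean(rowSums(unclass(make_communities(make_sites(cfg0), NULL, cfg0)) > 0))
    }, 0)
    set.seed(2000)
    richS <- vapply(1:60, function(s)
        mean(rowSums(unclass(simulate_neutral(6, 80, cfg$theta, cfg$I[1])) > 0)), 0)
    expect_gt(wilcox.test(rich0, richS)$p.value, 0.01)
})

test_that("pure niche assembly separates habitat clusters", {
    cfg <- scenario_config(n_sites = 12, n_layers = 1, J = 300, lambda = 1,
                           niche_width = 0.2, seed = 17)
    sites <- make_sites(cfg)
    # two well-separated habitat clusters, imposed directly
    hab <- habitat_matrix(matrix(rep(c(-4, 4), each = 6), 12, 1,
                                 dimnames = list(sites$sample_id, "hab01")))
    cm <- make_communities(sites, hab, cfg)
    s <- as.matrix(sorensen_similarity(cm))
    cl <- rep(c(1, 2), each = 6)
    within <- mean(s[outer(cl, cl, "==") & lower.tri(s)])
    between <- mean(s[outer(cl, cl, "!=") & lower.tri(s)])
    expect_lt(between, within)
})

test_that("fingerprint observation loses resolution and censors rare taxa", {
    # lossless limit: clustering threshold 1 (zero tolerance), unique sizes,
    # all peaks above the absolute and relative thresholds
    x <- matrix(c(20L, 30L, 50L,
                  40L, 40L, 20L), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a", "b", "c")))
    cm <- community_matrix(x)
    cfg <- scenario_config(n_sites = 2, n_layers = 1, clustering_threshold = 1,
                           height_scale = 20, seed = 9)
    out <- add_fingerprint_noise(cm, cfg)
    rel <- unclass(x) / rowSums(x)
    got <- unclass(out$community)
    got <- got[rownames(rel), order(colSums(got), decreasing = TRUE)]
    expect_equal(sort(as.numeric(got)), sort(as.numeric(rel)), tolerance = 1e-12)

    # heavy binning: observed richness below true richness
    set.seed(31)
    big <- community_matrix(matrix(rpois(5 * 80, 20) + 1L, 5, 80,
        dimnames = list(paste0("s", 1:5), paste0("t", 1:80))))
    cfg2 <- scenario_config(n_sites = 5, n_layers = 1,
                            clustering_threshold = 0.9, seed = 9)
    out2 <- add_fingerprint_noise(big, cfg2)
    expect_lt(ncol(out2$community), 80)

    # a taxon below 2% of total height is censored by the filter chain
    y <- matrix(c(500L, 5L), 1, 2, dimnames = list("s1", c("big", "rare")))
    cfg3 <- scenario_config(n_sites = 1, n_layers = 1, height_scale = 20,
                            clustering_threshold = 1, seed = 2)
    out3 <- add_fingerprint_noise(community_matrix(y), cfg3)
    expect_equal(ncol(out3$community), 1)
})

test_that("niche strength drives increasing divergence from the neutral null", {
    one_run <- function(lam, seed) {
        cfg <- scenario_config(n_sites = 14, n_layers = 1, J = 300,
                               lambda = lam, n_habitat_vars = 3, seed = seed)
        sites <- make_sites(cfg)
        hab <- make_habitat(sites, cfg)
        cm <- make_communities(sites, hab, cfg)
        fit <- fit_neutral(cm)
        es <- null_effect_sizes(cm, fit, n_sim = 100, seed = seed)
        es$point[es$statistic == "median"]
    }
    # average the median effect over a small seed batch per niche strength
    pts <- vapply(c(0, 0.4, 0.8), function(lam)
        mean(vapply(30:32, function(s) one_run(lam, s), 0)), 0)
    expect_true(all(diff(abs(pts)) > 0))
    expect_lt(pts[3], 0)
})

test_that("end-to-end turnover signs match the generating process", {
    cfg <- scenario_config(n_sites = 60, n_layers = 1, J = 300, lambda = 0.6,
                           n_habitat_vars = 5, habitat_range = 60000, seed = 2)
    sites <- make_sites(cfg)
    hab <- make_habitat(sites, cfg)
    cm <- make_communities(sites, hab, cfg)
    d <- geographic_distance(sites)
    zc <- fit_distance_decay(sorensen_similarity(cm), d)$z
    zh <- suppressWarnings(fit_distance_decay(
        suppressMessages(habitat_similarity(hab)), d))$z
    expect_lt(zc, 0)
    expect_lt(zh, 0)
})
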