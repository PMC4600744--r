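make_cm <- function(...) community_matrix(rbind(...))

test_that("Sorensen similarity matches hand computations", {
    cm <- make_cm(A = c(1, 1, 1, 0), B = c(0, 1, 1, 1))
    s <- sorensen_similarity(cm, "binary")
    expect_equal(s["A", "B"], 2 * 2 / (3 + 3))     # shared {2}, sizes 3 and 3
    expect_equal(diag(as.matrix(s)), c(A = 1, B = 1))

    same <- make_cm(A = c(3, 1, 0), B = c(3, 1, 0))
    expect_equal(sorensen_similarity(same)["A", "B"], 1)

    disjoint <- make_cm(A = c(1, 1, 0, 0), B = c(0, 0, 2, 5))
    expect_equal(sorensen_similarity(disjoint)["A", "B"], 0)

    # abundance mode = 1 - Bray-Curtis, hand value
    ab <- make_cm(A = c(6, 2), B = c(2, 4))
    bc <- (abs(6 - 2) + abs(2 - 4)) / (8 + 6)
    expect_equal(sorensen_similarity(ab, "abundance")["A", "B"], 1 - bc)

    zero <- community_matrix(rbind(A = c(1, 0), B = c(0, 0)),
                             require_positive_rows = FALSE)
    expect_error(sorensen_similarity(zero), "B")
})

test_that("habitat similarity is anchored by the maximum-distance pair", {
    m <- habitat_matrix(matrix(c(0, 1, 2), 3, 1,
                               dimnames = list(c("a", "b", "c"), "v")),
                        standardized = TRUE)
    e <- habitat_similarity(m)
    expect_equal(e["a", "b"], 0.5)  # distances {1,1,2}, Euc_max = 2
    expect_equal(e["b", "c"], 0.5)
    expect_equal(e["a", "c"], 0)

    dup <- habitat_matrix(matrix(c(1, 1, 5, 2, 2, 9), 3, 2,
                                 dimnames = list(c("a", "b", "c"), c("u", "v"))),
                          standardized = TRUE)
    expect_equal(habitat_similarity(dup)["a", "b"], 1)  # identical rows

    # unstandardized input is standardized internally, with a message
    raw <- habitat_matrix(matrix(rnorm(20), 5, 4,
                                 dimnames = list(paste0("s", 1:5), paste0("v", 1:4))))
    expect_message(habitat_similarity(raw), "standardizing")
})

test_that("geographic distances are Euclidean metres", {
    sites <- data.frame(sample_id = c("p", "q"), x = c(0, 3000), y = c(0, 4000))
    d <- geographic_distance(sites)
    expect_equal(d["p", "q"], 5000)
    expect_equal(d["p", "p"], 0)
    expect_identical(d, t(d))
    expect_error(geographic_distance(data.frame(sample_id = "p", x = NaN, y = 0)),
                 "finite")
})

test_that("distance decay recovers a noiseless power law to machine precision", {
    n <- 30
    set.seed(1)
    sites <- data.frame(sample_id = paste0("s", 1:n),
                        x = runif(n, 0, 2e5), y = runif(n, 0, 2e5))
    d <- geographic_distance(sites)
    chi <- 10^(-0.1) * (d / 1)^(-0.05)
    chi <- similarity_matrix(chi, kind = "community_sorensen")
    f <- fit_distance_decay(chi, d, binning = "none")
    expect_equal(f$z, -0.05, tolerance = 1e-12)
    expect_equal(f$b, -0.1, tolerance = 1e-12)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)

    # slope invariant under rescaling the distances (only b changes)
    f10 <- fit_distance_decay(chi, d * 10, binning = "none")
    expect_equal(f10$z, f$z, tolerance = 1e-10)

    # constant similarity: z = 0
    const <- similarity_matrix(matrix(0.4, n, n), kind = "community_sorensen")
    expect_equal(fit_distance_decay(const, d, binning = "none")$z, 0,
                 tolerance = 1e-12)

    # binned weighted fit agrees closely on exact power-law input
    fb <- fit_distance_decay(chi, d, binning = "log", bins = 15)
    expect_equal(fb$z, -0.05, tolerance = 2e-2)
})

test_that("neighbourhood analysis counts neighbours and degenerates correctly", {
    g <- expand.grid(x = 0:9, y = 0:9) * 20000
    sites <- data.frame(sample_id = paste0("s", 1:100), g)
    d <- geographic_distance(sites)
    set.seed(2)
    # synthetic decaying similarity with noise so decay fits are well-defined
    s <- similarity_matrix(0.8 * exp(-d / 2e5) +
                               matrix(runif(1e4, 0, 0.05), 100, 100),
                           kind = "community_sorensen")
    s <- similarity_matrix((as.matrix(s) + t(as.matrix(s))) / 2,
                           kind = "community_sorensen")
    nb <- neighborhood_analysis(s, s, d, radius = 140000)
    corner <- nb[nb$focal_id == "s1", ]
    expect_equal(corner$n_neighbors, 44)  # brute-force lattice count

    # radius below the site spacing: everything flagged
    tiny <- neighborhood_analysis(s, s, d, radius = 10000)
    expect_true(all(tiny$flagged))

    # infinite radius reproduces the global fit at every focal site
    glob <- fit_distance_decay(s, d)
    inf <- neighborhood_analysis(s, s, d, radius = Inf)
    expect_equal(unique(round(inf$z_community, 10)), round(glob$z, 10))
    expect_equal(unique(round(inf$mean_chi, 12)),
                 round(mean(as.matrix(s)[lower.tri(as.matrix(s))]), 12))
})

test_that("type II regression matches closed forms", {
    x <- c(1, 2, 3, 4, 5)
    y <- 2 * x
    for (m in c("OLS", "MA", "SMA")) {
        f <- typeII_regression(x, y, m)
        expect_equal(f$slope, 2, tolerance = 1e-12)
        expect_equal(f$intercept, 0, tolerance = 1e-12)
        expect_equal(f$r_squared, 1)
    }

    set.seed(9)
    x <- rnorm(40); y <- 0.7 * x + rnorm(40)
    sma <- typeII_regression(x, y, "SMA")
    expect_equal(sma$slope, sign(cor(x, y)) * sd(y) / sd(x), tolerance = 1e-12)
    ma <- typeII_regression(x, y, "MA")
    # MA slope equals the first principal axis of the covariance matrix
    ev <- eigen(cov(cbind(x, y)))$vectors[, 1]
    expect_equal(ma$slope, ev[2] / ev[1], tolerance = 1e-10)

    expect_error(typeII_regression(c(1, 1, 1), c(1, 2, 3)), "variance")

    # under independence the slope test rejects at roughly the nominal rate
    set.seed(10)
    rej <- mean(replicate(60, {
        typeII_regression(rnorm(30), rnorm(30))$p_value < 0.05
    }))
    expect_lt(rej, 0.2)
})

test_that("Mantel test statistic and permutation behave correctly", {
    set.seed(21)
    n <- 15
    a <- matrix(runif(n * n), n, n); a <- (a + t(a)) / 2; diag(a) <- 1
    dimnames(a) <- list(paste0("s", 1:n), paste0("s", 1:n))
    b <- 1 - a

    expect_equal(mantel_test(a, a, n_perm = 99, seed = 1)$statistic, 1)
    expect_equal(mantel_test(a, b, n_perm = 99, seed = 1)$statistic, -1)

    # statistic agrees with the vegan implementation on dissimilarities
    c2 <- matrix(runif(n * n), n, n); c2 <- (c2 + t(c2)) / 2; diag(c2) <- 1
    dimnames(c2) <- dimnames(a)
    r_pkg <- mantel_test(a, c2, n_perm = 99, seed = 1)$statistic
    r_veg <- vegan::mantel(as.dist(1 - a), as.dist(1 - c2),
                           permutations = 9)$statistic
    expect_equal(r_pkg, unname(r_veg), tolerance = 1e-12)

    # p-value invariant (in distribution) under identical joint relabelling
    p <- sample(n)
    m1 <- mantel_test(a, c2, n_perm = 999, seed = 5)
    m2 <- mantel_test(a[p, p], c2[p, p], n_perm = 999, seed = 5)
    expect_equal(m1$statistic, m2$statistic, tolerance = 1e-12)
    expect_lt(abs(m1$p_value - m2$p_value), 0.08)

    expect_error(mantel_test(a, c2[-1, -1]), "aligned")
})
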