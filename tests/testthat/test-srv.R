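test_that("srvCluster finds a planted correlated run and nothing else", {
    set.seed(7)
    n <- 100; p <- 30
    m <- matrix(rnorm(n * p), n, p)
    shared <- rnorm(n)
    for (j in 10:14)
        m[, j] <- shared * runif(1, 0.5, 2) + rnorm(n, sd = 1e-3)
    rownames(m) <- sprintf("s%03d", seq_len(n))
    ds <- SpectralSet(m, seq_len(p))
    cl <- srvCluster(ds, corr_threshold = 0.9, min_size = 3)
    expect_identical(nrow(cl), 1L)
    expect_equal(cl$start, 10)
    expect_equal(cl$end, 14)
    ## brute-force oracle: consecutive correlations at/above threshold
    land <- vapply(seq_len(p - 1), function(j) cor(m[, j], m[, j + 1]),
                   numeric(1))
    expect_true(all(land[10:13] >= 0.9))
    expect_true(all(land[-(10:13)] < 0.9))
})

test_that("srvCluster yields no clusters on independent noise", {
    zeros <- vapply(1:20, function(s) {
        set.seed(s)
        m <- matrix(rnorm(100 * 40), 100, 40,
                    dimnames = list(sprintf("s%03d", 1:100), NULL))
        nrow(srvCluster(SpectralSet(m, 1:40), corr_threshold = 0.9,
                        min_size = 3))
    }, integer(1))
    expect_gte(sum(zeros == 0), 18)
})

test_that("srvCluster limiting behaviour and contracts", {
    set.seed(2)
    f <- rexp(50)
    m <- outer(f, runif(12, 0.5, 2)) + matrix(rnorm(600, sd = 1e-4), 50)
    rownames(m) <- sprintf("s%02d", 1:50)
    ds <- SpectralSet(m, 1:12)
    ## threshold -> 0, min_size 1: one cluster spans everything
    cl <- srvCluster(ds, corr_threshold = 1e-6, min_size = 1)
    expect_identical(nrow(cl), 1L)
    expect_equal(c(cl$start, cl$end), c(1, 12))

    expect_error(srvCluster(SpectralSet(m[1:2, ], 1:12), 0.9, 3),
                 ">= 3 samples")
    expect_error(srvCluster(ds, corr_threshold = 1.2, min_size = 3),
                 "corr_threshold")
})

test_that("cluster boundaries tile compact planted peaks exactly", {
    ## noise-free simulator output with truncated Lorentzian support:
    ## clusters must match the planted supports to within one column
    mets <- data.frame(name = c("A", "B", "C"),
                       baseline_mean = c(5, 3, 2), baseline_sd = 0.4,
                       marker_loading = 0)
    pks <- data.frame(name = c("A", "B", "C"), center = c(2, 5, 8),
                      relative_intensity = 1, half_width = 0.05)
    lib0 <- MetaboliteLibrary(mets, pks)
    cfg <- cohortConfig(n_animals = 30, n_ppm_points = 500,
                        ppm_range = c(0.5, 9.5), noise_sd = 0,
                        baseline_amplitude = 0, dilution_log_sd = 0,
                        jitter_max = 0, effect_size = 0, tail_cutoff = 6,
                        seed = 17)
    coh <- simulateCohort(cfg, lib0)
    ss <- spectra(coh)[["0"]]
    cl <- srvCluster(ss, corr_threshold = 0.9, min_size = 3)
    expect_identical(nrow(cl), 3L)
    ax <- ppm(ss)
    step <- diff(ax)[1]
    for (k in 1:3) {
        ctr <- c(2, 5, 8)[k]
        lo <- which(ax >= ctr - 6 * 0.05)[1]          # planted support
        hi <- rev(which(ax <= ctr + 6 * 0.05))[1]
        expect_lte(abs(cl$start[k] - lo), 1)
        expect_lte(abs(cl$end[k] - hi), 1)
    }
})

test_that("clusterIntensities reduces clusters by mean or sum", {
    m <- rbind(a = c(1, 2, 3, 10), b = c(4, 5, 6, 20))
    ds <- SpectralSet(m, 1:4)
    cl <- data.frame(start = c(1, 4), end = c(3, 4),
                     ppm_lo = c(1, 4), ppm_hi = c(3, 4),
                     label = c("x", "y"))
    ftMean <- clusterIntensities(ds, cl, mode = "mean")
    expect_equal(unname(featureMatrix(ftMean)),
                 rbind(c(2, 10), c(5, 20)))
    ftSum <- clusterIntensities(ds, cl, mode = "sum")
    expect_equal(unname(featureMatrix(ftSum)),
                 rbind(c(6, 10), c(15, 20)))
    ## single-column cluster equals the column
    one <- clusterIntensities(ds, cl[2, ], mode = "mean")
    expect_equal(unname(featureMatrix(one))[, 1], unname(m[, 4]))
    expect_error(clusterIntensities(ds, cl[0, ]), "empty cluster")

    ## permuting sample order permutes feature rows identically
    dsPerm <- SpectralSet(m[c(2, 1), ], 1:4)
    expect_equal(featureMatrix(clusterIntensities(dsPerm, cl))[c(2, 1), ],
                 featureMatrix(ftMean))
})

test_that("feature values ignore within-cluster column order (mean mode)", {
    set.seed(9)
    m <- matrix(rexp(40), 5, 8, dimnames = list(sprintf("s%d", 1:5), NULL))
    ds <- SpectralSet(m, 1:8)
    cl <- data.frame(start = 2, end = 6, ppm_lo = 2, ppm_hi = 6,
                     label = "x")
    mShuf <- m
    mShuf[, 2:6] <- m[, c(5, 3, 6, 2, 4)]
    dsShuf <- SpectralSet(mShuf, 1:8)
    expect_equal(featureMatrix(clusterIntensities(ds, cl)),
                 featureMatrix(clusterIntensities(dsShuf, cl)))
})

test_that("logTransform applies log(x + offset) and stabilizes variance", {
    m <- matrix(c(0, exp(1) - 1, 1, 3), 2, 2,
                dimnames = list(c("a", "b"), c("f1", "f2")))
    lt <- logTransform(m, offset = 1)
    expect_equal(lt[1, 1], 0)            # log(0 + 1)
    expect_equal(lt[2, 1], 1)            # log(e - 1 + 1)
    ## strictly monotone per cell
    expect_true(all(logTransform(m + 0.5, offset = 1) > lt))
    mpos <- matrix(c(1, 3, 0.5, 4), 2, 2,
                   dimnames = list(c("a", "b"), c("f1", "f2")))
    expect_error(logTransform(mpos, offset = -1), "value \\+ offset")

    ## multiplicative noise becomes additive: variance of log features is
    ## independent of the mean (regression slope ~ 0)
    set.seed(21)
    mu <- rep(c(1, 5, 25, 125), each = 3)
    big <- vapply(mu, function(m0) m0 * exp(rnorm(400, sd = 0.3)),
                  numeric(400))
    lv <- apply(log(big), 2, var)
    rawSlope <- coef(lm(apply(big, 2, var) ~ mu))[2]
    logSlope <- coef(lm(lv ~ mu))[2]
    expect_lt(abs(logSlope), 1e-3)
    expect_gt(rawSlope, 1)

    ## default offset recorded in metadata for feature sets
    ds <- SpectralSet(rbind(a = c(1, 10), b = c(2, 20), c = c(3, 30)), 1:2)
    cl <- data.frame(start = 1:2, end = 1:2, ppm_lo = 1:2, ppm_hi = 1:2,
                     label = "u")
    ft <- logTransform(clusterIntensities(ds, cl))
    expect_true(S4Vectors::metadata(ft)$log_offset > 0)
})

test_that("annotateClusters labels by contained peak centers", {
    lib <- defaultMetaboliteLibrary()
    cl <- data.frame(start = c(1, 1, 1),
                     end = c(2, 2, 2),
                     ppm_lo = c(3.25, 0.60, 3.20),
                     ppm_hi = c(3.30, 0.70, 3.30),
                     label = "unassigned")
    out <- annotateClusters(cl, lib)
    expect_identical(out$label[1], "TMAO")        # contains 3.27
    expect_identical(out$label[2], "unassigned")  # empty region
    ## contains choline (3.21) and TMAO (3.27); midpoint 3.25 is nearer TMAO
    expect_identical(out$label[3], "TMAO")

    ## exact tie broken lexicographically
    mets <- data.frame(name = c("beta", "alpha"), baseline_mean = 1,
                       baseline_sd = 0, marker_loading = 0)
    pks <- data.frame(name = c("beta", "alpha"), center = c(2.9, 3.1),
                      relative_intensity = 1, half_width = 0.01)
    tie <- annotateClusters(
        data.frame(start = 1, end = 2, ppm_lo = 2.8, ppm_hi = 3.2,
                   label = "unassigned"),
        MetaboliteLibrary(mets, pks))
    expect_identical(tie$label, "alpha")
})
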