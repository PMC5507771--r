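test_that("selectReference picks the most representative sample", {
    ## two identical samples: lexicographic tie-break
    m <- rbind(b = c(1, 2, 3, 2, 1), a = c(1, 2, 3, 2, 1))
    ds <- SpectralSet(m, 1:5)
    expect_identical(selectReference(ds), "a")

    ## the in-between sample wins on mean pairwise correlation
    set.seed(4)
    s1 <- c(0, 1, 5, 1, 0, 0, 2, 0)
    s3 <- c(0, 0, 2, 0, 0, 1, 5, 1)
    s2 <- (s1 + s3) / 2 + rnorm(8, sd = 1e-4)
    ds3 <- SpectralSet(rbind(x1 = s1, x2 = s2, x3 = s3), 1:8)
    ## oracle: direct mean-correlation computation
    cc <- cor(t(rbind(s1, s2, s3)))
    diag(cc) <- NA
    expect_identical(unname(which.max(rowMeans(cc, na.rm = TRUE))), 2L)
    expect_identical(selectReference(ds3), "x2")

    expect_error(selectReference(SpectralSet(m[1, , drop = FALSE], 1:5)),
                 ">= 2 samples")
    const <- SpectralSet(rbind(a = rep(1, 5), b = rep(2, 5)), 1:5)
    expect_error(selectReference(const), "constant")
})

test_that("rspaAlign recovers planted integer shifts exactly", {
    n_pts <- 200
    ref <- as.numeric(singletFixture(1, n_pts, centers = c(50, 120),
                                     amps = list(10, 6)))
    shifted <- metaboPredict:::shiftVector(ref * 0.8, 3L)  # +3 points
    ds <- SpectralSet(rbind(ref = ref, samp = shifted), seq_len(n_pts))

    al <- rspaAlign(ds, reference_id = "ref", max_shift = 5)
    sh <- shifts(al)$samp
    ## top-level segment undoes the planted +3 shift
    expect_identical(sh$shift[1], -3L)
    m <- intensityMatrix(alignedSpectra(al))
    interior <- 10:(n_pts - 10)
    expect_equal(unname(m["samp", interior]), 0.8 * ref[interior],
                 tolerance = 1e-12)
    ## alignment never lowers correlation to the reference
    corBefore <- cor(shifted, ref)
    corAfter <- cor(m["samp", ], ref)
    expect_gte(corAfter, corBefore)

    ## identity sample: all recorded shifts are zero
    ds2 <- SpectralSet(rbind(ref = ref, same = ref), seq_len(n_pts))
    al2 <- rspaAlign(ds2, reference_id = "ref", max_shift = 5)
    expect_true(all(shifts(al2)$same$shift == 0L))
    expect_equal(intensityMatrix(alignedSpectra(al2)),
                 intensityMatrix(ds2))
})

test_that("rspaAlign honours its contracts at the boundaries", {
    n_pts <- 128
    ref <- as.numeric(singletFixture(1, n_pts, centers = 60,
                                     amps = list(8)))
    ## a shift beyond max_shift cannot be recovered
    far <- metaboPredict:::shiftVector(ref, 7L)
    ds <- SpectralSet(rbind(ref = ref, samp = far), seq_len(n_pts))
    al <- rspaAlign(ds, reference_id = "ref", max_shift = 5,
                    min_segment = 64)
    expect_true(all(abs(shifts(al)$samp$shift) <= 5L))
    expect_error(rspaAlign(ds, reference_id = "ref", max_shift = 40,
                           min_segment = 32),
                 "smaller than the segment length")
    expect_error(rspaAlign(ds, reference_id = "ref", min_segment = 4),
                 ">= 8")
})

test_that("rspaAlign undoes simulator jitter on noise-free cohorts", {
    cfg <- cohortConfig(n_animals = 14, n_ppm_points = 400, noise_sd = 0,
                        baseline_amplitude = 0, dilution_log_sd = 0,
                        jitter_max = 3, seed = 8)
    coh <- simulateCohort(cfg)
    ss <- spectra(coh)[["0"]]
    al <- rspaAlign(ss, max_shift = 6)
    refId <- al@referenceId
    m0 <- intensityMatrix(ss)
    m1 <- intensityMatrix(alignedSpectra(al))
    ref <- m1[refId, ]
    worse <- sum(1 - apply(m0, 1, cor, y = m0[refId, ]))
    better <- sum(1 - apply(m1, 1, cor, y = ref))
    expect_lte(better, worse + 1e-12)
})

test_that("excludeRegions uses the half-open [lo, hi) convention", {
    ds <- SpectralSet(rbind(a = 0:10, b = 10:0), 0:10)
    expect_identical(excludeRegions(ds, list()), ds)

    out <- excludeRegions(ds, list(c(4.5, 6.0)))
    expect_equal(ppm(out), c(0:4, 6:10))  # 5 removed, 6 kept

    ## overlapping regions remove the union without error
    out2 <- excludeRegions(ds, list(c(2, 5), c(4, 7)))
    expect_equal(ppm(out2), c(0, 1, 7:10))

    expect_error(excludeRegions(ds, list(c(-1, 11))), "every axis point")
    expect_error(excludeRegions(ds, list(c(5, 5))), "lo < hi")
})

test_that("pqnNormalize matches the quotient definition", {
    ## pure scaling: sample = 3 x reference
    ref <- c(1, 2, 4, 8)
    m <- rbind(a = ref, b = 3 * ref)
    res <- pqnNormalize(m, reference = ref)
    expect_equal(unname(res$dilutions), c(1, 3))
    expect_equal(unname(res$normalized["b", ]), ref)

    ## hand evaluation: quotients (2, 2, 1), median 2
    res2 <- pqnNormalize(matrix(c(2, 4, 4), 1, 3,
                                dimnames = list("s", NULL)),
                         reference = c(1, 2, 4))
    expect_equal(unname(res2$dilutions), 2)
    expect_equal(unname(res2$normalized[1, ]), c(1, 2, 2))

    ## single sample against itself
    res3 <- pqnNormalize(matrix(ref, 1, 4, dimnames = list("s", NULL)),
                         reference = ref)
    expect_equal(unname(res3$dilutions), 1)

    ## error names the offending sample
    m4 <- rbind(good = ref, dead = c(0, 0, 0, 0))
    expect_error(pqnNormalize(m4, reference = ref), "dead")
})

test_that("pqnNormalize is scale-equivariant", {
    set.seed(11)
    m <- matrix(rexp(60), 6, 10,
                dimnames = list(sprintf("s%d", 1:6), NULL))
    ref <- apply(m, 2, median)
    ## fixed reference: scaling the data scales the dilution estimates
    a <- pqnNormalize(m, reference = ref)
    b <- pqnNormalize(5 * m, reference = ref)
    expect_equal(b$dilutions, 5 * a$dilutions, tolerance = 1e-12)
    expect_equal(b$normalized, a$normalized, tolerance = 1e-12)
    ## recomputed median reference absorbs the scale instead: estimates are
    ## invariant and the normalized matrix carries the factor
    a2 <- pqnNormalize(m)
    b2 <- pqnNormalize(5 * m)
    expect_equal(b2$dilutions, a2$dilutions, tolerance = 1e-12)
    expect_equal(b2$normalized, 5 * a2$normalized, tolerance = 1e-12)
})

test_that("PQN recovers simulator dilutions exactly in the clean limit", {
    ## identical undiluted spectra: estimates equal truth up to the global
    ## median scale (the only identifiable normalization)
    mets <- data.frame(name = c("A", "B"), baseline_mean = c(5, 2),
                       baseline_sd = 0, marker_loading = 0)
    pks <- data.frame(name = c("A", "B"), center = c(3, 7),
                      relative_intensity = 1, half_width = 0.05)
    lib0 <- MetaboliteLibrary(mets, pks)
    cfg <- cohortConfig(n_animals = 20, n_ppm_points = 500, noise_sd = 0,
                        baseline_amplitude = 0, jitter_max = 0,
                        effect_size = 0, within_sd = 0,
                        dilution_log_sd = 0.3, seed = 13)
    coh <- simulateCohort(cfg, lib0)
    truth <- groundTruth(coh)$dilutions[["0"]]
    est <- pqnNormalize(spectra(coh)[["0"]])$dilutions
    expect_equal(unname(est / median(est)), unname(truth / median(truth)),
                 tolerance = 1e-9)
})

test_that("excluding regions commutes with PQN on the kept columns", {
    set.seed(3)
    m <- matrix(rexp(80), 8, 10,
                dimnames = list(sprintf("s%d", 1:8), NULL))
    ds <- SpectralSet(m, seq(1, 10))
    kept <- excludeRegions(ds, list(c(4, 7)))
    route1 <- pqnNormalize(kept)
    route2 <- pqnNormalize(intensityMatrix(kept))
    expect_equal(intensityMatrix(route1$normalized), route2$normalized)
    expect_equal(route1$dilutions, route2$dilutions)
})
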