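lib <- defaultMetaboliteLibrary()

test_that("synthesizeSpectrum follows the Lorentzian mixture definition", {
    ax <- seq(0.5, 9.5, length.out = 2000)

    ## empty mixture
    y0 <- synthesizeSpectrum(c(TMAO = 0, citrate = 0), lib, ax)
    expect_identical(y0, numeric(2000))

    ## singlet: apex at the grid point nearest the center, half height at
    ## center +/- half_width (within grid discretization)
    y <- synthesizeSpectrum(c(TMAO = 2), lib, ax)
    expect_equal(length(y), length(ax))
    apex <- which.max(y)
    expect_equal(ax[apex], 3.27, tolerance = diff(ax)[1])
    hw <- peakTable(lib)$half_width[peakTable(lib)$name == "TMAO"]
    half <- approx(ax, y, xout = 3.27 + hw)$y
    expect_equal(half, max(y) / 2, tolerance = 0.02 * max(y))

    ## linearity: doubling a concentration doubles its contribution
    base <- synthesizeSpectrum(c(TMAO = 1, citrate = 2), lib, ax)
    noTmao <- synthesizeSpectrum(c(citrate = 2), lib, ax)
    dbl <- synthesizeSpectrum(c(TMAO = 2, citrate = 2), lib, ax)
    expect_equal(dbl - noTmao, 2 * (base - noTmao), tolerance = 1e-12)

    ## errors
    expect_error(synthesizeSpectrum(c(unobtanium = 1), lib, ax),
                 "unobtanium")
    expect_error(synthesizeSpectrum(c(TMAO = -1), lib, ax), "negative")
    expect_error(synthesizeSpectrum(c(TMAO = 1), lib, c(1, 3, 2)),
                 "monotone")
})

test_that("synthesizeSpectrum noise and baseline are seed-deterministic", {
    ax <- seq(1, 9, length.out = 300)
    a <- synthesizeSpectrum(c(TMAO = 1), lib, ax, noise_sd = 0.1,
                            baseline_amplitude = 0.5, seed = 42)
    b <- synthesizeSpectrum(c(TMAO = 1), lib, ax, noise_sd = 0.1,
                            baseline_amplitude = 0.5, seed = 42)
    d <- synthesizeSpectrum(c(TMAO = 1), lib, ax, noise_sd = 0.1,
                            baseline_amplitude = 0.5, seed = 43)
    expect_identical(a, b)
    expect_false(identical(a, d))
})

test_that("derivePhenotypes computes trapezoidal GTT summaries", {
    ## constant curve: CG = 5 mM * 120 min, dG = 0
    g <- matrix(5, 1, 5, dimnames = list("a", NULL))
    ph <- derivePhenotypes(g, times = c(0, 30, 60, 90, 120))
    expect_equal(ph$CG, 600)
    expect_equal(ph$dG, 0)

    ## hand trapezoid: (0,15,30) min, (5,10,5) mM -> 112.5 + 112.5
    g2 <- matrix(c(5, 10, 5), 1, 3, dimnames = list("a", NULL))
    expect_equal(derivePhenotypes(g2, c(0, 15, 30))$CG, 225)

    ## zero organ weight -> zero ratio
    ph3 <- derivePhenotypes(g2, c(0, 15, 30),
                            organ_weights = cbind(EPD = 0), bw = 25)
    expect_equal(ph3$EPD_ratio, 0)

    ## contract violations
    expect_error(derivePhenotypes(g2, c(5, 15, 30)), "time 0")
    expect_error(derivePhenotypes(-g2, c(0, 15, 30)), "negative")
    expect_error(derivePhenotypes(g2, c(0, 15, 30),
                                  insulin = matrix(1, 1, 2)),
                 "same sampling times")
})

test_that("simulateCohort is bit-reproducible given config and seed", {
    cfg <- cohortConfig(n_animals = 14, n_ppm_points = 200, seed = 99)
    a <- simulateCohort(cfg, lib)
    b <- simulateCohort(cfg, lib)
    expect_identical(intensityMatrix(spectra(a)[["0"]]),
                     intensityMatrix(spectra(b)[["0"]]))
    expect_identical(as.data.frame(phenotypes(a)),
                     as.data.frame(phenotypes(b)))
    expect_identical(groundTruth(a), groundTruth(b))
    c2 <- simulateCohort(cohortConfig(n_animals = 14, n_ppm_points = 200,
                                      seed = 100), lib)
    expect_false(identical(groundTruth(a)$z, groundTruth(c2)$z))
})

test_that("degenerate noise settings reproduce the noiseless mixture", {
    cfg <- cohortConfig(n_animals = 14, n_ppm_points = 300,
                        noise_sd = 0, baseline_amplitude = 0,
                        dilution_log_sd = 0, jitter_max = 0, seed = 5)
    coh <- simulateCohort(cfg, lib)
    gt <- groundTruth(coh)
    ax <- ppm(spectra(coh)[["0"]])
    m <- intensityMatrix(spectra(coh)[["0"]])
    for (i in c(1, 7, 14)) {
        expected <- synthesizeSpectrum(gt$concentrations[["0"]][i, ], lib,
                                       ax)
        expect_equal(unname(m[i, ]), expected, tolerance = 1e-12)
    }
    expect_true(all(unlist(gt$dilutions) == 1))
    expect_true(all(unlist(gt$jitters) == 0))
})

test_that("planted extremes exceed the 2-SD thresholds when noise is off", {
    cfg <- cohortConfig(n_ppm_points = 64, pheno_noise = 0, seed = 21)
    coh <- simulateCohort(cfg, lib)
    gt <- groundTruth(coh)
    ph <- as.data.frame(phenotypes(coh))
    ob <- names(gt$group)[gt$group == "Ob-IGT"]
    expect_gte(length(ob), 1)
    tcg <- mean(ph$CG) + 2 * sd(ph$CG)
    tbw <- mean(ph$BW) + 2 * sd(ph$BW)
    expect_true(all(ph[ob, "CG"] > tcg))
    expect_true(all(ph[ob, "BW"] > tbw))
    ## and the stratifier recovers them exactly
    st <- stratifyPhenotypes(phenotypes(coh))
    expect_identical(sort(names(groupLabels(st))[
        groupLabels(st) == "Ob-IGT"]), sort(ob))
})

test_that("two-driver mode plants L-IGT animals dissociating the traits", {
    cfg <- cohortConfig(n_ppm_points = 64, n_drivers = 2, pheno_noise = 0,
                        group_fractions = c(LNG = 0.08, `L-IGT` = 0.06,
                                            `Ob-IGT` = 0.06),
                        seed = 31)
    coh <- simulateCohort(cfg, lib)
    gt <- groundTruth(coh)
    ligt <- names(gt$group)[gt$group == "L-IGT"]
    expect_gte(length(ligt), 1)
    st <- stratifyPhenotypes(phenotypes(coh))
    expect_true(all(groupLabels(st)[ligt] == "L-IGT"))
})

test_that("effect_size 0 leaves baseline markers uncoupled from outcome", {
    nullBound <- function(n) qnorm(0.975) / sqrt(n - 1)
    inside <- vapply(1:100, function(s) {
        coh <- simulateCohort(cohortConfig(
            n_animals = 20, n_ppm_points = 32, effect_size = 0,
            seed = 1000 + s), lib)
        rho <- cor(groundTruth(coh)$concentrations[["0"]][, "TMAO"],
                   phenotypes(coh)$CG, method = "spearman")
        abs(rho) < nullBound(20)
    }, logical(1))
    ## nominal coverage is 95%; allow binomial fluctuation over 100 draws
    expect_gte(sum(inside), 88)
})

test_that("cohortConfig rejects infeasible settings", {
    expect_error(cohortConfig(n_animals = 10), ">= 14")
    expect_error(cohortConfig(ppm_range = c(9, 1)), "low < high")
    expect_error(cohortConfig(noise_sd = -1), "SDs")
    expect_error(cohortConfig(group_fractions = c(
        LNG = 0, `L-IGT` = 0, `Ob-IGT` = 0)), "fewer than 1 planted")
    expect_error(cohortConfig(group_fractions = c(
        LNG = 0, `L-IGT` = 0.06, `Ob-IGT` = 0.06)), "n_drivers = 2")
})

test_that("cohort components share animal identity and ordering", {
    coh <- simulateCohort(cohortConfig(n_animals = 16, n_ppm_points = 64,
                                       seed = 2), lib)
    ids <- rownames(phenotypes(coh))
    for (tp in names(spectra(coh)))
        expect_identical(
            SummarizedExperiment::colData(spectra(coh)[[tp]])$animal, ids)
    expect_identical(names(groundTruth(coh)$z), ids)
    expect_true(validObject(coh))
})
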